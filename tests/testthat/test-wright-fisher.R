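test_that("the neutral chain has binomial rows and absorbing boundaries", {
  ch <- build_wf_chain(1)
  expect_equal(ch$transition[2, ], c(0.25, 0.5, 0.25))
  ch2 <- build_wf_chain(2)
  expect_equal(ch2$transition[2, 1], (3 / 4)^4)
  for (N in c(1, 2, 5)) {
    ch <- build_wf_chain(N)
    expect_equal(rowSums(ch$transition), rep(1, 2 * N + 1), tolerance = 1e-12)
    expect_equal(ch$transition[1, 1], 1)
    expect_equal(ch$transition[2 * N + 1, 2 * N + 1], 1)
  }
  expect_error(build_wf_chain(0), ">= 1")
})

test_that("neutral fixation probability equals the allele frequency", {
  for (N in c(1, 2, 4, 8, 16)) {
    ch <- build_wf_chain(N)
    for (i0 in seq_len(2 * N - 1)) {
      a <- absorption_summary(ch, i0)
      expect_equal(a$p_fix, i0 / (2 * N), tolerance = 1e-10)
      expect_equal(a$p_fix + a$p_loss, 1, tolerance = 1e-10)
      expect_gt(a$t_loss, 0)
      expect_gt(a$t_fix, 0)
    }
  }
  expect_error(absorption_summary(build_wf_chain(2), 4), "strictly between")
})

test_that("conditional absorption times for the smallest populations", {
  a1 <- absorption_summary(build_wf_chain(1), 1)
  expect_equal(a1$t_loss, 2, tolerance = 1e-10)
  expect_equal(a1$t_fix, 2, tolerance = 1e-10)
  a2 <- absorption_summary(build_wf_chain(2), 1)
  expect_equal(a2$t_loss, 2.9931, tolerance = 1e-4)
  expect_equal(a2$t_fix, 5.7793, tolerance = 1e-4)
})

test_that("conditional times agree with direct absorption-time summation", {
  # independent route: propagate the transient mass and sum t * Pr(absorb at t)
  for (N in c(2, 4)) {
    ch <- build_wf_chain(N)
    n <- 2 * N
    tr <- 2:n
    Qm <- ch$transition[tr, tr, drop = FALSE]
    rf <- ch$transition[tr, n + 1]
    v <- numeric(length(tr)); v[1] <- 1
    s0 <- 0; s1 <- 0
    for (t in 1:3000) {
      m <- sum(v * rf)
      s0 <- s0 + m; s1 <- s1 + t * m
      v <- as.vector(v %*% Qm)
    }
    a <- absorption_summary(ch, 1)
    expect_equal(s1 / s0, a$t_fix, tolerance = 1e-8)
    expect_equal(s0, a$p_fix, tolerance = 1e-10)
  }
})

test_that("Kimura-Ohta diffusion values and convergence with N", {
  ko1 <- kimura_ohta_times(1, 1 / 2)
  expect_equal(ko1$t_fix, 4 * log(2), tolerance = 1e-12)
  expect_equal(ko1$t_loss, 4 * log(2), tolerance = 1e-12)
  expect_equal(ko1$t_fix, 2.7726, tolerance = 1e-4)
  ko16 <- kimura_ohta_times(16, 1 / 32)
  expect_equal(ko16$t_fix, 62.9894, tolerance = 1e-5)
  expect_equal(ko16$t_loss, 7.1551, tolerance = 1e-5)
  expect_equal(kimura_ohta_times(4, 1 / 8)$t_loss, 4.7530, tolerance = 1e-4)
  expect_equal(kimura_ohta_times(4, 1 / 8)$t_fix, 14.9555, tolerance = 1e-4)
  # relative gap between chain and diffusion shrinks as N grows
  gap <- function(N) {
    a <- absorption_summary(build_wf_chain(N), 1)
    ko <- kimura_ohta_times(N, 1 / (2 * N))
    c(abs(a$t_loss - ko$t_loss) / a$t_loss,
      abs(a$t_fix - ko$t_fix) / a$t_fix)
  }
  expect_true(all(gap(16) < gap(1)))
  expect_error(kimura_ohta_times(4, 0), "strictly")
})

test_that("chain times match Monte Carlo of the conditioned chain", {
  set.seed(1845)
  N <- 2; n <- 2 * N
  ch <- build_wf_chain(N)
  reps <- 50000
  tf <- c(); tl <- c()
  state <- rep(1L, reps); time <- integer(reps); active <- seq_len(reps)
  while (length(active)) {
    u <- vapply(state[active], function(s)
      sample.int(n + 1L, 1L, prob = ch$transition[s + 1L, ]) - 1L, integer(1))
    time[active] <- time[active] + 1L
    state[active] <- u
    fixed <- active[u == n]; lost <- active[u == 0L]
    tf <- c(tf, time[fixed]); tl <- c(tl, time[lost])
    active <- active[u != 0L & u != n]
  }
  a <- absorption_summary(ch, 1)
  expect_lt(abs(mean(tf) - a$t_fix), 3 * sd(tf) / sqrt(length(tf)))
  expect_lt(abs(mean(tl) - a$t_loss), 3 * sd(tl) / sqrt(length(tl)))
  expect_equal(length(tf) / reps, a$p_fix, tolerance = 0.05)
})

test_that("gamete selection shifts allele frequency as expected", {
  expect_identical(gamete_selection_delta_p(0.5, 0), 0)
  pp <- 0.5 + gamete_selection_delta_p(0.5, 0.01)
  expect_lt(abs(pp - 0.497512), 5e-7)
  expect_lt(abs(pp^2 - 0.247519), 5e-7)
  expect_error(gamete_selection_delta_p(1.5, 0.1), "\\[0, 1\\]")
  expect_error(gamete_selection_delta_p(0.5, -1), "> -1")
})

test_that("selfing-model extinction probability in neutral and selected cases", {
  m0 <- selfing_model()
  expect_equal(c(m0$P_AA, m0$P_AB, m0$P_BB), c(0.25, 0.5, 0.25))
  expect_identical(selfing_extinction_probability(m0), 0.25 / (1 - 0.5))
  m <- selfing_model(s = 0.01)
  expect_equal(selfing_extinction_probability(m), 0.495025, tolerance = 1e-6)
  mp <- selfing_model(probs = c(0.5, 0, 0.5))
  expect_equal(selfing_extinction_probability(mp), 0.5)
  expect_error(selfing_extinction_probability(selfing_model(probs = c(0, 1, 0))),
               "degenerate")
})

test_that("heterozygote extinction reduces to the single-type fixed point", {
  expect_equal(heterozygote_extinction(law_poisson(1.1)), 0.82391,
               tolerance = 1e-4)
  expect_lt(abs(heterozygote_extinction(law_poisson(2)) - 0.20319), 1e-5)
  expect_identical(heterozygote_extinction(law_poisson(1)), 1)
})
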