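test_that("q_t iterates reproduce hand-computed compositions", {
  q <- iterate_q(hornet_law())
  expect_identical(q[1], 0)
  expect_equal(q[2:5], c(0.5, 0.7, 0.808, 0.872973), tolerance = 1e-6)
  expect_true(all(diff(q) >= 0))
  expect_equal(iterate_q(galton_law())[3], 0.132661, tolerance = 1e-6)
  expect_equal(iterate_q(law_poisson(1.1))[2], 0.3328710837, tolerance = 1e-10)
  expect_equal(iterate_q(law_poisson(1.1))[3], 0.4800611401, tolerance = 1e-10)
  # bounded by the limiting extinction probability
  expect_true(all(iterate_q(law_poisson(2)) <=
                    extinction_probability_poisson(2) + 1e-12))
})

test_that("extinction-time pmf and bookkeeping are consistent", {
  d <- extinction_time_distribution(hornet_law())
  expect_equal(d$pmf[2], 0.2)
  expect_equal(d$pmf, diff(d$q))
  expect_true(all(d$pmf >= 0))
  expect_equal(sum(d$pmf) + d$tail_mass, d$Q_ref, tolerance = 1e-10)
  dp <- extinction_time_distribution(law_poisson(0.7))
  expect_equal(dp$pmf[1], 0.4966, tolerance = 1e-4)
  expect_equal(dp$pmf[2], 0.2064, tolerance = 1e-4)
  ds <- extinction_time_distribution(super3_law())
  expect_equal(sum(ds$pmf) + ds$tail_mass, 0.2, tolerance = 1e-10)
})

test_that("conditional mean and variance match the printed references", {
  expect_equal(mean_extinction_time(hornet_law()), 2.3954, tolerance = 1e-4)
  d <- extinction_time_distribution(hornet_law())
  expect_equal(d$ET2, 10.7818, tolerance = 1e-4)
  expect_equal(d$T_var, 5.0439, tolerance = 1e-4)
  expect_equal(mean_extinction_time(law_poisson(0.7)), 2.3762,
               tolerance = 1e-4)
  expect_equal(mean_extinction_time(law_poisson(1.1)), 4.102,
               tolerance = 1e-3)
  expect_equal(var_extinction_time(law_poisson(1.1)), 33.550,
               tolerance = 1e-4)
  expect_equal(mean_extinction_time(law_poisson(2)), 1.545, tolerance = 1e-3)
  expect_equal(var_extinction_time(law_poisson(2)), 0.953, tolerance = 1e-3)
  expect_equal(mean_extinction_time(law_poisson(3.9165)), 1.089,
               tolerance = 1e-3)
  expect_equal(var_extinction_time(law_poisson(3.9165)), 0.097,
               tolerance = 5e-3)
  expect_equal(mean_extinction_time(super3_law()), 2.159, tolerance = 5e-4)
  expect_equal(var_extinction_time(super3_law()), 3.026, tolerance = 5e-4)
  expect_equal(mean_extinction_time(galton_law()), 1.547654,
               tolerance = 1e-6)
  expect_equal(var_extinction_time(galton_law()), 0.916671, tolerance = 1e-5)
})

test_that("trivial and degenerate extinction-time cases", {
  # certain immediate extinction
  d <- extinction_time_distribution(law_empirical(1))
  expect_equal(d$T_mean, 1)
  expect_equal(d$T_var, 0)
  # extinction impossible when p0 = 0
  d0 <- extinction_time_distribution(law_empirical(c(0, 0.5, 0.5)))
  expect_identical(d0$Q_ref, 0)
  expect_true(all(d0$pmf == 0))
  expect_true(is.na(d0$T_mean))
})

test_that("critical laws are flagged divergent rather than summed", {
  d <- extinction_time_distribution(law_poisson(1), t_max = 2000)
  expect_true(d$divergent)
  expect_true(is.na(d$T_mean))
  expect_error(mean_extinction_time(law_poisson(1), tol = 1e-6), "diverges")
})

test_that("subcritical moment identities hold across a lambda grid", {
  for (lam in c(0.3, 0.5, 0.7, 0.9)) {
    d <- extinction_time_distribution(law_poisson(lam))
    expect_identical(d$regime, "subcritical")
    alt <- d$subcritical_alt
    expect_equal(alt[["mean"]], d$T_mean, tolerance = 1e-6)
    expect_equal(alt[["ET2"]], d$ET2, tolerance = 1e-6)
  }
})

test_that("zero-size coefficients of the composed distribution equal q_t", {
  q <- iterate_q(galton_law())
  for (t in c(1, 2, 4, 8)) {
    sd <- compose_size_distribution(galton_law(), t, max_size = 200)
    expect_equal(sd$probs[1], q[t + 1], tolerance = 1e-10)
  }
})

test_that("conditional quantiles follow the cumulative iterates", {
  d <- extinction_time_distribution(hornet_law())
  expect_identical(quantile(d, 0.5), 1)   # q_1 = 0.5 already covers the median
  expect_identical(quantile(d, 0.7), 2)
  q95 <- quantile(d, 0.95)
  expect_gte(d$q[q95 + 1] / d$Q_ref, 0.95)
  expect_lt(d$q[q95] / d$Q_ref, 0.95)
})

test_that("Monte Carlo extinction generations agree with the analytic mean", {
  reps <- 20000
  ts <- simulate_gw(law_poisson(2), t_max = 100, reps = reps, seed = 4202)
  eg <- ts$extinction_generation[ts$extinct]
  se <- sd(eg) / sqrt(length(eg))
  expect_lt(abs(mean(eg) - mean_extinction_time(law_poisson(2))), 3 * se)
})
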