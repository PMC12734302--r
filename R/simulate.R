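#' Monte Carlo simulation of Galton-Watson trajectories
#'
#' Simulates `reps` independent populations: every individual in generation
#' `t` draws an independent offspring count from the law and the draws sum to
#' `Z_{t+1}`. Per-generation totals use exact superposition identities where
#' they exist (a Poisson generation total is one Poisson draw with mean
#' `lambda * Z_t`; geometric and negative binomial totals are single negative
#' binomial draws); empirical laws draw all offspring counts for a
#' generation in one vectorized sample and aggregate per replicate.
#'
#' A trajectory that exceeds `size_cap` is frozen at the cap and flagged:
#' supercritical runs are about extinction-or-escape, and a population that
#' large never returns to 0 on any horizon of interest, so capping does not
#' bias extinction statistics.
#'
#' @param law an [offspring_law] object.
#' @param z0 founding population size, `>= 1`.
#' @param t_max horizon in generations, `>= 1`.
#' @param reps number of replicate trajectories, `>= 1`.
#' @param seed integer seed; fixed seed reproduces the output exactly.
#' @param size_cap per-trajectory population cap.
#' @return An object of class `"gw_trajectories"`: list with the
#'   `reps x (t_max + 1)` size matrix `Z` (column `t + 1` is generation `t`),
#'   logical `extinct`, integer `extinction_generation` (`NA` when not
#'   extinct by `t_max`), logical `capped`, and the call parameters.
#' @examples
#' ts <- simulate_gw(law_poisson(0.7), t_max = 50, reps = 1000, seed = 1)
#' mean(ts$extinct)  # ~1: subcritical extinction is certain
#' @export
simulate_gw <- function(law, z0 = 1, t_max = 100, reps = 1, seed = NULL,
                        size_cap = 1e7) {
  .check_law(law)
  if (z0 < 1 || z0 != floor(z0)) stop("'z0' must be an integer >= 1", call. = FALSE)
  if (t_max < 1) stop("'t_max' must be >= 1", call. = FALSE)
  if (reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  Z <- matrix(0, nrow = reps, ncol = t_max + 1L)
  Z[, 1] <- z0
  cur <- rep(as.numeric(z0), reps)
  capped <- logical(reps)

  for (t in seq_len(t_max)) {
    alive <- which(cur > 0 & !capped)
    if (length(alive)) {
      zz <- cur[alive]
      nxt <- switch(law$family,
        poisson = stats::rpois(length(zz), law$lambda * zz),
        geometric = stats::rnbinom(length(zz), size = zz, prob = law$p),
        negbinomial = stats::rnbinom(length(zz), size = law$r * zz,
                                     prob = law$p),
        empirical = .empirical_generation(zz, law$probs)
      )
      over <- nxt > size_cap
      if (any(over)) {
        nxt[over] <- size_cap
        capped[alive[over]] <- TRUE
      }
      cur[alive] <- nxt
    }
    Z[, t + 1L] <- cur
  }

  zero <- Z == 0
  first0 <- apply(zero, 1L, function(r) if (any(r)) which(r)[1L] - 1L else NA_integer_)
  structure(list(Z = Z, extinct = !is.na(first0),
                 extinction_generation = first0, capped = capped,
                 law = law, z0 = z0, t_max = t_max, reps = reps,
                 seed = seed, size_cap = size_cap),
            class = "gw_trajectories")
}

# one generation for an empirical law: draw all offspring counts at once and
# sum per parent population; chunked so no single draw exceeds ~1e7 values
.empirical_generation <- function(zz, probs) {
  out <- numeric(length(zz))
  i <- 1L
  n <- length(zz)
  while (i <= n) {
    tot <- 0
    j <- i
    while (j <= n && (j == i || tot + zz[j] <= 1e7)) {
      tot <- tot + zz[j]
      j <- j + 1L
    }
    idx <- i:(j - 1L)
    draws <- sample.int(length(probs), tot, replace = TRUE, prob = probs) - 1L
    grp <- rep(seq_along(idx), times = zz[idx])
    out[idx] <- as.vector(rowsum(draws, grp))
    i <- j
  }
  out
}

#' Empirical extinction curve from simulated trajectories
#'
#' The fraction of replicates extinct by each generation `t`; a Monte Carlo
#' estimate of the analytic iterates `q_t` (for `z0 = 1`), and the
#' independent check used against [iterate_q()].
#'
#' @param ts a [simulate_gw()] result.
#' @return Nondecreasing vector of extinct fractions for `t = 0..t_max`.
#' @examples
#' ts <- simulate_gw(law_empirical(c(0.5, 0.3, 0.2)), t_max = 5,
#'                   reps = 2000, seed = 1)
#' empirical_extinction_curve(ts)[2]  # ~0.5 = q_1
#' @export
empirical_extinction_curve <- function(ts) {
  if (!inherits(ts, "gw_trajectories"))
    stop("'ts' must come from simulate_gw()", call. = FALSE)
  colMeans(ts$Z == 0)
}

#' @export
print.gw_trajectories <- function(x, ...) {
  cat("Galton-Watson simulation:", x$reps, "replicates, z0 =", x$z0,
      ", t_max =", x$t_max, "\n")
  cat("  extinct by horizon:", mean(x$extinct),
      "  capped:", sum(x$capped), "\n")
  invisible(x)
}
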