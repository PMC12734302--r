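#' Principal branch of the Lambert W function
#'
#' Solves `w * exp(w) = z` for the principal branch `W0` (`w >= -1`), defined
#' on `z >= -1/e`. Near the branch point the series expansion in
#' `p = sqrt(2 (e z + 1))` is used directly; elsewhere a series or
#' logarithmic initial guess is polished by Halley iteration to full double
#' precision.
#'
#' For a supercritical Poisson offspring law the extinction probability has
#' the closed form `Q = -W0(-lambda * exp(-lambda)) / lambda`.
#'
#' @param z numeric vector, each element `>= -1/e`.
#' @return `W0(z)`, same length as `z`.
#' @examples
#' lambert_w0(0)                      # 0
#' lambert_w0(-exp(-1))               # -1 (branch point)
#' lambert_w0(-2 * exp(-2))           # -0.4063757 (Poisson lambda = 2)
#' @export
lambert_w0 <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("'z' must be finite numeric", call. = FALSE)
  if (any(z < -exp(-1) - 1e-14))
    stop("lambert_w0 requires z >= -1/e", call. = FALSE)
  vapply(z, .lw0_scalar, numeric(1))
}

.lw0_scalar <- function(z) {
  b <- -exp(-1)
  if (z <= b) return(-1)
  if (z == 0) return(0)
  # initial guess
  if (z < -0.32) {
    # branch-point series in p = sqrt(2(ez + 1)); error O(p^5)
    p <- sqrt(2 * (exp(1) * z + 1))
    w <- -1 + p - p^2 / 3 + 11 * p^3 / 72 - 43 * p^4 / 540
    if (p < 1e-4) return(w)
  } else if (z < 1) {
    w <- z * (1 - z + 1.5 * z^2)
  } else {
    w <- log(z)
    if (w > 1) w <- w - log(w)
  }
  for (i in 1:100) {
    ew <- exp(w)
    f <- w * ew - z
    # Halley step; falls back to Newton when the correction term degenerates
    den <- ew * (w + 1) - (w + 2) * f / (2 * w + 2)
    if (!is.finite(den) || den == 0) den <- ew * (w + 1)
    dw <- f / den
    w <- w - dw
    if (abs(dw) <= 1e-15 * max(1, abs(w))) break
  }
  w
}

#' Extinction probability of a Galton-Watson process
#'
#' The probability `Q` that the line of descent of a single founder
#' eventually dies out is the smallest non-negative root of the fixed-point
#' equation `Q = G(Q)`, where `G` is the offspring-law PGF. Monotone
#' iteration `q <- G(q)` started from 0 converges to that smallest root from
#' below for every valid law; supercritical Poisson and geometric laws
#' dispatch to their closed forms (`-W0(-lambda e^-lambda)/lambda` and `1/R`).
#'
#' Subcritical and critical laws have `Q = 1` (for a non-degenerate law).
#' Critical laws short-circuit rather than iterate, because fixed-point
#' convergence at criticality is sublinearly slow. The degenerate critical
#' law `P(X = 1) = 1` has `Q = 0` (the population never changes size).
#'
#' @param law an [offspring_law] object.
#' @param tol convergence tolerance on successive iterates.
#' @param max_iter iteration cap; non-convergence within it is an error.
#' @param method `"auto"` dispatches to closed forms where available;
#'   `"fixed_point"` forces the iteration.
#' @return An object of class `"extinction_result"`: list with `Q`, `regime`,
#'   `method` (one of `"fixed_point"`, `"lambert_w"`,
#'   `"geometric_closed_form"`, `"analytic"`), `iterations` and
#'   `residual` (`|Q - G(Q)|`).
#' @examples
#' extinction_probability(law_empirical(c(0.5, 0.3, 0.2)))$Q   # 1
#' extinction_probability(law_poisson(2))$Q                    # 0.2031879
#' galton <- law_empirical(c(0.1, 0.3, 0.25, 0.15, 0.1, 0.1))
#' extinction_probability(galton)$Q                            # 0.1519416038
#' @export
extinction_probability <- function(law, tol = 1e-14, max_iter = 1e6,
                                   method = c("auto", "fixed_point")) {
  .check_law(law)
  method <- match.arg(method)
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be > 0", call. = FALSE)
  regime <- classify_regime(law)

  make <- function(Q, meth, iter) {
    structure(list(Q = Q, regime = regime, method = meth, iterations = iter,
                   residual = abs(Q - pgf(law, Q)), law = law),
              class = "extinction_result")
  }

  if (regime == "critical") {
    # degenerate one-offspring law never goes extinct; all others are certain to
    if (offspring_variance(law) == 0) return(make(0, "analytic", 0L))
    return(make(1, "analytic", 0L))
  }
  if (method == "auto") {
    if (law$family == "poisson")
      return(make(extinction_probability_poisson(law$lambda), "lambert_w", 0L))
    if (law$family == "geometric")
      return(make(extinction_probability_geometric(law$R),
                  "geometric_closed_form", 0L))
  }

  q <- 0
  for (i in seq_len(max_iter)) {
    qn <- pgf(law, q)
    if (qn - q < tol) return(make(qn, "fixed_point", i))
    q <- qn
  }
  stop("fixed-point iteration for Q did not converge within 'max_iter'",
       call. = FALSE)
}

#' Closed-form extinction probabilities
#'
#' For a Poisson offspring law with mean `lambda`,
#' `Q = -W0(-lambda exp(-lambda)) / lambda` when `lambda > 1` and 1
#' otherwise. For a geometric law with mean `R`, `Q = min(1, 1/R)`.
#'
#' @param lambda Poisson mean, `> 0`.
#' @param R geometric mean, `> 0`.
#' @return The extinction probability.
#' @examples
#' extinction_probability_poisson(2)     # 0.2031879
#' extinction_probability_poisson(1.01)  # 0.9802636
#' extinction_probability_geometric(2)   # 0.5
#' @export
extinction_probability_poisson <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("'lambda' must be a single value > 0", call. = FALSE)
  if (lambda <= 1) return(1)
  -lambert_w0(-lambda * exp(-lambda)) / lambda
}

#' @rdname extinction_probability_poisson
#' @export
extinction_probability_geometric <- function(R) {
  if (!is.numeric(R) || length(R) != 1L || R <= 0)
    stop("'R' must be a single value > 0", call. = FALSE)
  min(1, 1 / R)
}

#' Extinction probability of a group of independent founders
#'
#' Lineages founded by `n` individuals reproduce independently, so the whole
#' group dies out with probability `Q^n`.
#'
#' @param Q single-founder extinction probability in `[0, 1]`.
#' @param n_founders number of founders, `>= 1`.
#' @return `Q^n_founders`.
#' @examples
#' group_extinction(0.82391, 100)  # ~4e-9: 100 founders essentially persist
#' @export
group_extinction <- function(Q, n_founders) {
  if (!is.numeric(Q) || Q < 0 || Q > 1)
    stop("'Q' must lie in [0, 1]", call. = FALSE)
  if (n_founders < 1 || n_founders != floor(n_founders))
    stop("'n_founders' must be an integer >= 1", call. = FALSE)
  Q^n_founders
}

#' @export
print.extinction_result <- function(x, ...) {
  cat("Extinction probability Q =", format(x$Q, digits = 12), "\n")
  cat("  regime:", x$regime, "  method:", x$method,
      "  iterations:", x$iterations,
      "  residual:", format(x$residual, digits = 3), "\n")
  invisible(x)
}
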