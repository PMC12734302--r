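#' Maximum-likelihood offspring mean from a census trajectory
#'
#' For consecutive censuses `Z_0, ..., Z_n` of a branching process, the MLE
#' of the offspring mean (the Lotka-Nagaev/Harris ratio estimator) is the sum
#' of the later censuses over the sum of the earlier ones:
#' `lambda_hat = sum(Z_1..Z_n) / sum(Z_0..Z_{n-1})`. It is invariant to
#' rescaling all censuses by a common factor.
#'
#' @param sizes ordered vector of at least two non-negative integer
#'   population sizes at consecutive generations.
#' @return The estimate `lambda_hat`.
#' @examples
#' estimate_lambda_mle(c(138057, 248503, 546707, 1158576))  # 2.09349093
#' @export
estimate_lambda_mle <- function(sizes) {
  if (!is.numeric(sizes) || length(sizes) < 2L)
    stop("'sizes' must contain at least two censuses", call. = FALSE)
  if (any(sizes < 0) || any(sizes != floor(sizes)))
    stop("census sizes must be non-negative integers", call. = FALSE)
  denom <- sum(sizes[-length(sizes)])
  if (denom <= 0)
    stop("all pre-final censuses are zero; the offspring mean is undefined",
         call. = FALSE)
  sum(sizes[-1]) / denom
}

#' Generations since founding of a growing population
#'
#' Inverts supercritical growth from a single founder: given the final
#' census `Z`, the estimated offspring mean `lambda_hat > 1` and the
#' extinction probability `Q` of the fitted law, the MLE of the number of
#' elapsed generations is `ln((1 - Q) Z + Q) / ln(lambda_hat)`. The value is
#' returned unrounded. For a Poisson law, obtain `Q` with
#' [extinction_probability_poisson()].
#'
#' @param Z_final final census, `>= 1`.
#' @param lambda_hat estimated offspring mean, `> 1`.
#' @param Q extinction probability in `[0, 1)`.
#' @return Real-valued generation estimate.
#' @examples
#' lam <- estimate_lambda_mle(c(138057, 248503, 546707, 1158576))
#' Q <- extinction_probability_poisson(lam)                 # 0.179463
#' estimate_generations_since_founding(1158576, lam, Q)     # 18.63
#' @export
estimate_generations_since_founding <- function(Z_final, lambda_hat, Q) {
  if (!is.numeric(Z_final) || Z_final < 1)
    stop("'Z_final' must be >= 1", call. = FALSE)
  if (!is.numeric(lambda_hat) || lambda_hat <= 1)
    stop("'lambda_hat' must exceed 1 (no growth to invert)", call. = FALSE)
  if (!is.numeric(Q) || Q < 0 || Q >= 1)
    stop("'Q' must lie in [0, 1)", call. = FALSE)
  log((1 - Q) * Z_final + Q) / log(lambda_hat)
}

#' Fit a Poisson offspring law to a top-coded family-size table
#'
#' Census fertility tables report the fraction of individuals with
#' `0, 1, ..., K-1` children and a final aggregated `K+` bin. The default
#' treats the top bin as right-censored and maximizes the censored Poisson
#' likelihood; `method = "least_squares"` instead minimizes the squared
#' distance between observed and model bin probabilities.
#'
#' @param fractions numeric vector: fractions (or percentages) for
#'   `0..K-1` children followed by the `K+` bin; normalized to sum to 1
#'   (deviations up to `1e-6` after normalization by the total are accepted
#'   silently, since published tables are rounded).
#' @param method `"censored_mle"` (default) or `"least_squares"`.
#' @return List with `lambda` (the fitted mean) and `objective` (the
#'   achieved log-likelihood, or negative sum of squares).
#' @examples
#' fit_poisson_binned(c(16.2, 16, 36.1, 20.2, 7.8, 3.8))$lambda  # ~2.004
#' fit_poisson_binned(dpois(0:4, 2) * c(1, 1, 1, 1, 1 / dpois(4, 2) *
#'   ppois(3, 2, lower.tail = FALSE)))$lambda                    # 2
#' @export
fit_poisson_binned <- function(fractions,
                               method = c("censored_mle", "least_squares")) {
  method <- match.arg(method)
  if (!is.numeric(fractions) || length(fractions) < 2L)
    stop("'fractions' needs at least one plain bin and the top-coded bin",
         call. = FALSE)
  if (any(fractions < 0) || any(!is.finite(fractions)))
    stop("bin fractions must be finite and non-negative", call. = FALSE)
  f <- fractions / sum(fractions)
  K <- length(f) - 1L                  # plain bins are 0..K-1, last bin is K+
  if (sum(f[-1]) == 0)
    return(list(lambda = 0, objective = 0, method = method))
  kk <- 0:(K - 1L)
  obj <- if (method == "censored_mle") {
    function(l) {
      ll <- sum(f[kk + 1L][f[kk + 1L] > 0] *
                  stats::dpois(kk[f[kk + 1L] > 0], l, log = TRUE))
      if (f[K + 1L] > 0)
        ll <- ll + f[K + 1L] *
          stats::ppois(K - 1L, l, lower.tail = FALSE, log.p = TRUE)
      ll
    }
  } else {
    function(l) {
      m <- c(stats::dpois(kk, l), stats::ppois(K - 1L, l, lower.tail = FALSE))
      -sum((f - m)^2)
    }
  }
  naive <- sum(c(kk, K) * f)
  opt <- stats::optimize(obj, c(1e-8, max(50, 10 * naive)), maximum = TRUE,
                         tol = 1e-10)
  list(lambda = opt$maximum, objective = opt$objective, method = method)
}
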