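# Direct shift-and-add polynomial product. Deliberately not FFT-based:
# convolve(type = "open") introduces ~1e-17 absolute noise, which destroys
# genuinely tiny coefficients (e.g. Pr(Z_3 = 125) = 1e-31 for a degree-5 law).
.polymul <- function(a, b, max_len = Inf) {
  n <- length(a)
  m <- length(b)
  L <- min(n + m - 1L, max_len)
  out <- numeric(L)
  for (i in seq_len(min(n, L))) {
    j <- min(m, L - i + 1L)
    idx <- i:(i + j - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(j)]
  }
  out
}

# coefficients of G(v(s)) = sum_k f_k v(s)^k, truncated at degree max_len - 1;
# powers of v are built incrementally by repeated convolution
.pgf_compose <- function(f, v, max_len) {
  acc <- numeric(max_len)
  acc[1] <- f[1]
  pw <- 1
  for (k in seq_len(length(f) - 1L)) {
    pw <- .polymul(pw, v, max_len)
    L <- length(pw)
    acc[seq_len(L)] <- acc[seq_len(L)] + f[k + 1L] * pw
  }
  acc
}

#' Population-size distribution after t generations
#'
#' The PGF of the population size `Z_t` founded by one individual is the
#' t-fold composite `G_t(s) = G(G_{t-1}(s))`; its power-series coefficients
#' are `Pr(Z_t = m)`. They are computed by exact polynomial composition:
#' powers of the previous generation's coefficient vector are formed by
#' repeated direct convolution and combined with weights `P(X = k)`.
#'
#' For a finite (empirical) law the exact support is `k_max^t`; when that
#' exceeds `max_size` (or `max_size` is given), coefficients are truncated
#' and the missing probability is tracked in `tail_mass`. Truncation never
#' affects the low-order coefficients' role as lower bounds, and leaves the
#' zero coefficient (`q_t`) exact. Parametric laws have infinite support and
#' require an explicit `max_size`; their base PMF is truncated there with the
#' deficit likewise tracked, so all reported coefficients are lower bounds.
#'
#' @param law an [offspring_law] object.
#' @param t number of generations, `>= 1`.
#' @param max_size largest population size to track. Default (`NULL`) keeps
#'   the full support `k_max^t` of a finite law, capped at 32768; required
#'   for parametric laws.
#' @return An object of class `"size_distribution"`: list with `generation`,
#'   `probs` (element `m + 1` is `Pr(Z_t = m)`), `truncation_M` and
#'   `tail_mass`.
#' @examples
#' galton <- law_empirical(c(0.1, 0.3, 0.25, 0.15, 0.1, 0.1))
#' d2 <- compose_size_distribution(galton, 2)
#' d2$probs[1]  # Pr(Z_2 = 0) = q_2 = 0.132661
#' d2$probs[3]  # Pr(Z_2 = 2) = 0.1159
#' @export
compose_size_distribution <- function(law, t, max_size = NULL) {
  .check_law(law)
  if (t < 1 || t != floor(t)) stop("'t' must be an integer >= 1", call. = FALSE)
  if (law$family == "empirical") {
    full <- law$k_max^t
    M <- if (is.null(max_size)) min(full, 32768) else min(max_size, full)
    f <- law$probs
  } else {
    if (is.null(max_size))
      stop("a parametric law has infinite support: supply 'max_size'",
           call. = FALSE)
    M <- max_size
    f <- pmf(law, 0:M)
  }
  v <- f
  if (length(v) > M + 1L) v <- v[seq_len(M + 1L)]
  if (t > 1) for (g in 2:t) v <- .pgf_compose(f, v, M + 1L)
  neg <- v < 0
  if (any(v < -1e-15))
    stop("negative size-distribution coefficient beyond tolerance", call. = FALSE)
  v[neg] <- 0
  structure(list(generation = as.integer(t), probs = v,
                 truncation_M = length(v) - 1L,
                 tail_mass = max(0, 1 - sum(v)), law = law),
            class = "size_distribution")
}

#' Expected number of founder lines of each size
#'
#' Galton's surname question: with `n_founders` independent founders (each a
#' distinct surname), the expected number of surnames borne by exactly `m`
#' people at generation `t` is `n_founders * Pr(Z_t = m)`.
#'
#' @param dist a `"size_distribution"` object.
#' @param n_founders number of independent founders, `>= 1`.
#' @return Vector of expected counts, element `m + 1` for size `m`.
#' @examples
#' galton <- law_empirical(c(0.1, 0.3, 0.25, 0.15, 0.1, 0.1))
#' expected_name_counts(compose_size_distribution(galton, 1), 10000)
#' # 1000 3000 2500 1500 1000 1000
#' @export
expected_name_counts <- function(dist, n_founders) {
  if (!inherits(dist, "size_distribution"))
    stop("'dist' must be a size_distribution", call. = FALSE)
  if (n_founders < 1 || n_founders != floor(n_founders))
    stop("'n_founders' must be an integer >= 1", call. = FALSE)
  n_founders * dist$probs
}

#' Upper-tail probability of the population size
#'
#' `Pr(Z_t >= m_min)`, including any truncated tail mass (so the value is
#' exact for untruncated finite laws and an upper-inclusive bound otherwise).
#'
#' @param dist a `"size_distribution"` object.
#' @param m_min smallest size included in the tail.
#' @return A probability.
#' @examples
#' galton <- law_empirical(c(0.1, 0.3, 0.25, 0.15, 0.1, 0.1))
#' tail_probability(compose_size_distribution(galton, 3), 50)  # 3.24e-4
#' @export
tail_probability <- function(dist, m_min) {
  if (!inherits(dist, "size_distribution"))
    stop("'dist' must be a size_distribution", call. = FALSE)
  if (m_min < 0 || m_min > dist$truncation_M)
    stop("'m_min' must lie in [0, truncation_M]", call. = FALSE)
  if (m_min == 0) return(sum(dist$probs) + dist$tail_mass)
  sum(dist$probs[(m_min + 1L):length(dist$probs)]) + dist$tail_mass
}

#' Mean of a size distribution
#'
#' For an untruncated finite law this equals `mu^t` exactly
#' (`E(Z_t) = E(X)^t`).
#'
#' @param x a `"size_distribution"` object.
#' @param ... unused.
#' @return `sum(m * Pr(Z_t = m))` over the tracked support.
#' @export
mean.size_distribution <- function(x, ...) {
  sum((seq_along(x$probs) - 1) * x$probs)
}

#' @export
print.size_distribution <- function(x, ...) {
  cat("Population-size distribution at generation", x$generation, "\n")
  cat("  support tracked: 0..", x$truncation_M,
      "  tail mass: ", format(x$tail_mass, digits = 3), "\n", sep = "")
  cat("  Pr(Z_t = 0) =", format(x$probs[1], digits = 8),
      "  mean =", format(mean(x), digits = 8), "\n")
  invisible(x)
}
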