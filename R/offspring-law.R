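#' Offspring laws for Galton-Watson branching processes
#'
#' An offspring law (reproduction law) is the probability mass function of the
#' number of offspring an individual leaves in the next generation. Four
#' families are supported: a finite empirical PMF on counts `0..k_max`, and the
#' Poisson, geometric and negative binomial distributions, all with support
#' starting at 0.
#'
#' The geometric law is parameterized by its mean `R = (1 - p) / p`, the
#' natural scale when it stands in for a basic reproduction number; the
#' success-probability form `p` is accepted as an alternative. The negative
#' binomial has no closed-form extinction probability and participates in all
#' downstream computations through numeric PGF evaluation only.
#'
#' Empirical probabilities that sum to 1 within `1e-6` are renormalized with a
#' warning (published tables are often rounded); larger deviations are errors.
#'
#' @param probs numeric vector of probabilities for offspring counts
#'   `0, 1, ..., length(probs) - 1`.
#' @param lambda Poisson mean, `> 0`.
#' @param R mean of the geometric law, `> 0`. Exactly one of `R` and `p` must
#'   be given.
#' @param p success probability in `(0, 1)`: for the geometric law
#'   `P(X = k) = p (1 - p)^k`; for the negative binomial,
#'   `P(X = k) = choose(k + r - 1, k) p^r (1 - p)^k`.
#' @param r negative binomial shape parameter, `> 0`.
#'
#' @return An object of class `"offspring_law"`: a list with elements
#'   `family` (one of `"empirical"`, `"poisson"`, `"geometric"`,
#'   `"negbinomial"`) and the family's parameters (`probs` and `k_max`, or
#'   `lambda`, or `R` and `p`, or `r` and `p`).
#'
#' @examples
#' hornet <- law_empirical(c(0.5, 0.3, 0.2))
#' offspring_mean(hornet)      # 0.7
#' offspring_variance(hornet)  # 0.61
#' law_poisson(2)
#' law_geometric(R = 2)
#' @name offspring_law
NULL

#' @rdname offspring_law
#' @export
law_empirical <- function(probs) {
  if (!is.numeric(probs) || length(probs) < 1L)
    stop("'probs' must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(probs)))
    stop("offspring probabilities must be finite", call. = FALSE)
  if (any(probs < 0))
    stop("offspring probabilities must be non-negative", call. = FALSE)
  s <- sum(probs)
  if (abs(s - 1) > 1e-6)
    stop(sprintf("offspring probabilities sum to %.8f, not 1 (tolerance 1e-6)", s),
         call. = FALSE)
  if (abs(s - 1) > 1e-12) {
    warning(sprintf("offspring probabilities sum to %.8f; renormalizing", s),
            call. = FALSE)
    probs <- probs / s
  }
  structure(list(family = "empirical", probs = as.numeric(probs),
                 k_max = length(probs) - 1L),
            class = "offspring_law")
}

#' @rdname offspring_law
#' @export
law_poisson <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    stop("'lambda' must be a single finite value > 0", call. = FALSE)
  structure(list(family = "poisson", lambda = as.numeric(lambda)),
            class = "offspring_law")
}

#' @rdname offspring_law
#' @export
law_geometric <- function(R = NULL, p = NULL) {
  if (is.null(R) == is.null(p))
    stop("supply exactly one of 'R' (mean) or 'p' (success probability)",
         call. = FALSE)
  if (is.null(R)) {
    if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
      stop("'p' must be a single value in (0, 1)", call. = FALSE)
    R <- (1 - p) / p
  } else {
    if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
      stop("'R' must be a single finite value > 0", call. = FALSE)
    p <- 1 / (1 + R)
  }
  structure(list(family = "geometric", R = as.numeric(R), p = as.numeric(p)),
            class = "offspring_law")
}

#' @rdname offspring_law
#' @export
law_negbinom <- function(r, p) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("'r' must be a single finite value > 0", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("'p' must be a single value in (0, 1)", call. = FALSE)
  structure(list(family = "negbinomial", r = as.numeric(r), p = as.numeric(p)),
            class = "offspring_law")
}

.check_law <- function(law) {
  if (!inherits(law, "offspring_law"))
    stop("'law' must be an offspring_law object", call. = FALSE)
  law
}

#' Offspring-count probability mass function
#'
#' @param law an [offspring_law] object.
#' @param k vector of non-negative integer offspring counts.
#' @return `P(X = k)` for each `k`; 0 for counts outside an empirical law's
#'   support.
#' @examples
#' pmf(law_empirical(c(0.5, 0.3, 0.2)), 0:3)  # 0.5 0.3 0.2 0.0
#' pmf(law_poisson(0.7), 0)                   # exp(-0.7)
#' @export
pmf <- function(law, k) {
  .check_law(law)
  if (any(k < 0) || any(k != floor(k)))
    stop("'k' must contain non-negative integers", call. = FALSE)
  switch(law$family,
    empirical = ifelse(k <= law$k_max, law$probs[pmin(k, law$k_max) + 1], 0),
    poisson = stats::dpois(k, law$lambda),
    geometric = stats::dgeom(k, law$p),
    negbinomial = stats::dnbinom(k, size = law$r, prob = law$p)
  )
}

#' Probability generating function of an offspring law
#'
#' `G(s) = sum_k P(X = k) s^k` evaluated on `[0, 1]`, where every caller in
#' this package needs it. `pgf_deriv()` gives the first or second derivative,
#' from closed forms in every family.
#'
#' @param law an [offspring_law] object.
#' @param s evaluation points in `[0, 1]`.
#' @param order derivative order, 1 or 2.
#' @return `G(s)`, `G'(s)` or `G''(s)` for each `s`.
#' @examples
#' G <- law_empirical(c(0.5, 0.3, 0.2))
#' pgf(G, 0.5)           # 0.7
#' pgf_deriv(G, 1)       # 0.7  (the offspring mean)
#' pgf_deriv(G, 1, 2)    # 0.4
#' @export
pgf <- function(law, s) {
  .check_law(law)
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("'s' must lie in [0, 1]", call. = FALSE)
  switch(law$family,
    empirical = vapply(s, function(si) {
      # Horner evaluation of the probability polynomial
      acc <- 0
      for (a in rev(law$probs)) acc <- acc * si + a
      acc
    }, numeric(1)),
    poisson = exp(law$lambda * (s - 1)),
    geometric = law$p / (1 - (1 - law$p) * s),
    negbinomial = (law$p / (1 - (1 - law$p) * s))^law$r
  )
}

#' @rdname pgf
#' @export
pgf_deriv <- function(law, s, order = 1) {
  .check_law(law)
  if (!order %in% c(1, 2))
    stop("'order' must be 1 or 2", call. = FALSE)
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("'s' must lie in [0, 1]", call. = FALSE)
  q <- switch(law$family, geometric = 1 - law$p, negbinomial = 1 - law$p, NULL)
  switch(law$family,
    empirical = {
      k <- seq_along(law$probs) - 1
      co <- if (order == 1) law$probs * k else law$probs * k * (k - 1)
      vapply(s, function(si)
        sum(co * ifelse(k >= order, si^pmax(k - order, 0), 0)), numeric(1))
    },
    poisson = law$lambda^order * exp(law$lambda * (s - 1)),
    geometric = if (order == 1) law$p * q / (1 - q * s)^2
                else 2 * law$p * q^2 / (1 - q * s)^3,
    negbinomial = if (order == 1)
        law$r * q * law$p^law$r / (1 - q * s)^(law$r + 1)
      else
        law$r * (law$r + 1) * q^2 * law$p^law$r / (1 - q * s)^(law$r + 2)
  )
}

#' Mean and variance of an offspring law
#'
#' The mean is `G'(1)` and the variance `G''(1) + G'(1) - G'(1)^2`; both are
#' computed from family closed forms.
#'
#' @param law an [offspring_law] object.
#' @return A single number.
#' @examples
#' offspring_mean(law_empirical(c(0.5, 0.3, 0.2)))      # 0.7
#' offspring_variance(law_empirical(c(0.5, 0.3, 0.2)))  # 0.61
#' @export
offspring_mean <- function(law) {
  .check_law(law)
  switch(law$family,
    empirical = sum((seq_along(law$probs) - 1) * law$probs),
    poisson = law$lambda,
    geometric = law$R,
    negbinomial = law$r * (1 - law$p) / law$p
  )
}

#' @rdname offspring_mean
#' @export
offspring_variance <- function(law) {
  .check_law(law)
  switch(law$family,
    empirical = {
      k <- seq_along(law$probs) - 1
      mu <- sum(k * law$probs)
      sum((k - mu)^2 * law$probs)
    },
    poisson = law$lambda,
    geometric = law$R * (1 + law$R),
    negbinomial = law$r * (1 - law$p) / law$p^2
  )
}

#' Criticality regime of an offspring law
#'
#' Classifies by the offspring mean: subcritical (`mu < 1`), critical
#' (`mu = 1` within `tol`) or supercritical (`mu > 1`). Extinction is certain
#' in the first two regimes (when the law is non-degenerate) and has
#' probability `Q < 1` in the third.
#'
#' @param law an [offspring_law] object.
#' @param tol equality tolerance for `mu = 1`.
#' @return `"subcritical"`, `"critical"` or `"supercritical"`.
#' @examples
#' classify_regime(law_empirical(c(0.5, 0.3, 0.2)))  # subcritical
#' classify_regime(law_poisson(1))                   # critical
#' @export
classify_regime <- function(law, tol = 1e-12) {
  mu <- offspring_mean(.check_law(law))
  if (abs(mu - 1) <= tol) "critical" else if (mu < 1) "subcritical" else "supercritical"
}

#' @export
print.offspring_law <- function(x, ...) {
  cat("Offspring law:", x$family, "\n")
  switch(x$family,
    empirical = cat("  probs (k = 0..", x$k_max, "): ",
                    paste(signif(x$probs, 6), collapse = " "), "\n", sep = ""),
    poisson = cat("  lambda:", x$lambda, "\n"),
    geometric = cat("  mean R:", x$R, " (p =", x$p, ")\n"),
    negbinomial = cat("  r:", x$r, " p:", x$p, "\n")
  )
  cat("  mean:", offspring_mean(x), " variance:", offspring_variance(x),
      " regime:", classify_regime(x), "\n")
  invisible(x)
}
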