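# shared fixture laws, built in code

hornet_law <- function() law_empirical(c(0.5, 0.3, 0.2))
galton_law <- function() law_empirical(c(0.1, 0.3, 0.25, 0.15, 0.1, 0.1))
super3_law <- function() law_empirical(c(0.1, 0.4, 0.5))

# brute-force moments by direct summation over the PMF, truncated where the
# tail mass drops below 1e-12; independent of the closed-form routes
brute_moments <- function(law, k_hi = 4000) {
  k <- 0:k_hi
  p <- pmf(law, k)
  stopifnot(1 - sum(p) < 1e-12)
  mu <- sum(k * p)
  c(mean = mu, var = sum((k - mu)^2 * p))
}
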