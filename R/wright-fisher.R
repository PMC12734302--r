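#' Neutral Wright-Fisher Markov chain on allele counts
#'
#' A diploid population of constant size `N` carries `2N` gene copies; under
#' neutrality the next generation's count of a focal allele is binomial,
#' `j | i ~ Binom(2N, i / 2N)`, on states `0..2N`. States 0 (loss) and `2N`
#' (fixation) are absorbing.
#'
#' @param N diploid population size, `>= 1` (dense solves are practical to a
#'   few hundred).
#' @return An object of class `"wf_chain"`: list with `N`, `n_states = 2N + 1`
#'   and the `(2N+1) x (2N+1)` transition matrix (rows = current count).
#' @examples
#' ch <- build_wf_chain(1)
#' ch$transition[2, ]  # from 1 copy of 2: 0.25 0.50 0.25
#' @export
build_wf_chain <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != floor(N))
    stop("'N' must be an integer >= 1", call. = FALSE)
  n <- 2L * as.integer(N)
  P <- outer(0:n, 0:n, function(i, j) stats::dbinom(j, n, i / n))
  structure(list(N = as.integer(N), n_states = n + 1L, transition = P),
            class = "wf_chain")
}

#' Absorption probabilities and conditional absorption times
#'
#' For a chain started from `i0` copies, solves the absorption-probability
#' linear system for the fixation probability (`i0 / 2N` under neutrality)
#' and the fixation- and loss-conditioned expected absorption times via the
#' conditioned-chain (Doob h-transform) method: with `Q` the
#' transient-to-transient block and `h` the vector of target-absorption
#' probabilities, `w = (I - Q)^{-1} h` gives the conditional mean time
#' `w[i0] / h[i0]`.
#'
#' @param chain a [build_wf_chain()] object.
#' @param i0 initial allele count, strictly between 0 and `2N`.
#' @return An object of class `"absorption_summary"`: list with `N`, `i0`,
#'   `p_fix`, `p_loss`, `t_fix` and `t_loss` (generations).
#' @examples
#' absorption_summary(build_wf_chain(2), 1)  # p_fix 0.25, t_loss 2.9931
#' @export
absorption_summary <- function(chain, i0) {
  if (!inherits(chain, "wf_chain"))
    stop("'chain' must be a wf_chain", call. = FALSE)
  n <- 2L * chain$N
  if (i0 <= 0 || i0 >= n || i0 != floor(i0))
    stop("'i0' must be an integer strictly between 0 and 2N", call. = FALSE)
  tr <- 2:n                            # transient states 1..2N-1 (1-based rows)
  P <- chain$transition
  Qm <- P[tr, tr, drop = FALSE]
  A <- diag(length(tr)) - Qm
  h_fix <- solve(A, P[tr, n + 1L])
  h_loss <- solve(A, P[tr, 1L])
  w_fix <- solve(A, h_fix)
  w_loss <- solve(A, h_loss)
  structure(list(N = chain$N, i0 = as.integer(i0),
                 p_fix = h_fix[i0], p_loss = h_loss[i0],
                 t_fix = w_fix[i0] / h_fix[i0],
                 t_loss = w_loss[i0] / h_loss[i0]),
            class = "absorption_summary")
}

#' Kimura-Ohta diffusion approximations for a neutral allele
#'
#' Mean conditional times, in generations, from the diffusion limit of the
#' neutral Wright-Fisher model at initial frequency `p`:
#' `t_fix(p) = -(4N / p) (1 - p) ln(1 - p)` and
#' `t_loss(p) = -4N (p / (1 - p)) ln(p)`. They converge on the exact
#' Markov-chain values as `N` grows.
#'
#' @param N diploid population size.
#' @param p initial allele frequency, strictly between 0 and 1.
#' @return List with `t_loss` and `t_fix`.
#' @examples
#' kimura_ohta_times(1, 1 / 2)    # both 4 log 2 = 2.7726
#' kimura_ohta_times(16, 1 / 32)  # t_fix 62.9894
#' @export
kimura_ohta_times <- function(N, p) {
  if (!is.numeric(N) || N < 1) stop("'N' must be >= 1", call. = FALSE)
  if (!is.numeric(p) || p <= 0 || p >= 1)
    stop("'p' must lie strictly in (0, 1)", call. = FALSE)
  list(t_loss = -4 * N * p / (1 - p) * log(p),
       t_fix = -(4 * N / p) * (1 - p) * log(1 - p))
}

#' @export
print.absorption_summary <- function(x, ...) {
  cat("Wright-Fisher absorption from", x$i0, "of", 2 * x$N, "copies\n")
  cat("  p_fix =", format(x$p_fix, digits = 8),
      " p_loss =", format(x$p_loss, digits = 8), "\n")
  cat("  t_fix =", format(x$t_fix, digits = 8),
      " t_loss =", format(x$t_loss, digits = 8), "generations\n")
  invisible(x)
}
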