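#' Haploid-phase selection on gamete frequencies
#'
#' In a single selfing individual producing one offspring per generation,
#' selection can act only in the haploid (gamete) phase. With fitness 1 for
#' allele A and `1 + s` for allele B, the change in the frequency `p` of
#' allele A in the gamete pool is
#' `delta_p = -s p (1 - p) / (1 + s (1 - p))`.
#'
#' @param p frequency of allele A in `[0, 1]`.
#' @param s selection coefficient favoring B, `> -1`.
#' @return The change `delta_p` (0 under neutrality).
#' @examples
#' 0.5 + gamete_selection_delta_p(0.5, 0.01)  # 0.497512
#' @export
gamete_selection_delta_p <- function(p, s) {
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]", call. = FALSE)
  if (any(s <= -1)) stop("'s' must be > -1", call. = FALSE)
  -s * p * (1 - p) / (1 + s * (1 - p))
}

#' Single selfing-individual model for a new allele
#'
#' A population of one AB heterozygote reproduces by selfing, producing
#' exactly one offspring per generation. An AA offspring means loss of the B
#' allele, a BB offspring means fixation (both absorbing), and an AB
#' offspring restarts the process, so the B-allele extinction probability
#' solves `Q = P_AA + P_AB Q`, i.e. `Q = P_AA / (1 - P_AB)`. This sidesteps
#' the branching-process independence assumption, which a BB zygote in a
#' one-individual population would violate.
#'
#' With haploid-phase selection `s` on the B allele, both gametes of the
#' selfing parent are independently selected, so the genotype probabilities
#' are Hardy-Weinberg at the post-selection gamete frequency
#' `p' = p + delta_p`: `P_AA = p'^2`, `P_AB = 2 p' (1 - p')`,
#' `P_BB = (1 - p')^2`.
#'
#' @param s haploid-phase selection coefficient favoring B (default 0 gives
#'   the neutral Mendelian 1/4, 1/2, 1/4).
#' @param probs optional explicit genotype probabilities
#'   `c(P_AA, P_AB, P_BB)` (non-negative, summing to 1); overrides `s`.
#' @return An object of class `"selfing_model"`: list with `P_AA`, `P_AB`,
#'   `P_BB` and `s`.
#' @examples
#' selfing_extinction_probability(selfing_model())          # 0.5
#' selfing_extinction_probability(selfing_model(s = 0.01))  # 0.495025
#' @export
selfing_model <- function(s = 0, probs = NULL) {
  if (!is.null(probs)) {
    if (length(probs) != 3L || any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
      stop("'probs' must be 3 non-negative values summing to 1", call. = FALSE)
    m <- list(P_AA = probs[1], P_AB = probs[2], P_BB = probs[3], s = NA_real_)
  } else {
    if (!is.numeric(s) || length(s) != 1L || s <= -1)
      stop("'s' must be a single value > -1", call. = FALSE)
    pp <- 0.5 + gamete_selection_delta_p(0.5, s)
    m <- list(P_AA = pp^2, P_AB = 2 * pp * (1 - pp), P_BB = (1 - pp)^2, s = s)
  }
  structure(m, class = "selfing_model")
}

#' @rdname selfing_model
#' @param model a `"selfing_model"` object.
#' @export
selfing_extinction_probability <- function(model) {
  if (!inherits(model, "selfing_model"))
    stop("'model' must be a selfing_model", call. = FALSE)
  if (model$P_AB >= 1)
    stop("degenerate model: P_AB = 1 never resolves", call. = FALSE)
  model$P_AA / (1 - model$P_AB)
}

#' Extinction probability of a new allele carried by heterozygotes
#'
#' In a large diploid population every copy of a rare new B allele sits in an
#' independently reproducing AB heterozygote, so its fate reduces to the
#' standard single-type fixed point `Q = sum_k p_k Q^k = G(Q)`; this simply
#' delegates to [extinction_probability()] and documents the diploid reading.
#'
#' @param law the offspring law of an AB heterozygote.
#' @return The extinction probability of the B allele.
#' @examples
#' heterozygote_extinction(law_poisson(1.1))  # 0.823866
#' @export
heterozygote_extinction <- function(law) {
  extinction_probability(law)$Q
}

#' @export
print.selfing_model <- function(x, ...) {
  cat("Selfing single-individual model\n")
  cat("  P_AA =", format(x$P_AA, digits = 8),
      " P_AB =", format(x$P_AB, digits = 8),
      " P_BB =", format(x$P_BB, digits = 8), "\n")
  if (!is.na(x$s)) cat("  haploid-phase s =", x$s, "\n")
  cat("  Q(B allele) =", format(selfing_extinction_probability(x), digits = 8),
      "\n")
  invisible(x)
}
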