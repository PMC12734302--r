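#' Read an empirical offspring law from a two-column TSV
#'
#' The file must have a header line `k<TAB>prob` and one row per offspring
#' count; counts absent from the file get probability 0, duplicates are
#' rejected, and validation (non-negativity, sum to 1 within tolerance with
#' renormalization of rounded tables) is delegated to [law_empirical()].
#'
#' @param path path to the TSV file.
#' @return An empirical [offspring_law].
#' @seealso [write_pmf_table()] for the exact-round-trip writer.
#' @export
read_pmf_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "numeric")
  if (!identical(sort(names(df)), sort(c("k", "prob"))))
    stop("PMF table must have exactly the columns 'k' and 'prob'",
         call. = FALSE)
  if (nrow(df) == 0) stop("PMF table has no rows", call. = FALSE)
  if (any(!is.finite(df$k)) || any(df$k < 0) || any(df$k != floor(df$k)))
    stop("column 'k' must contain non-negative integers", call. = FALSE)
  if (anyDuplicated(df$k))
    stop("duplicate offspring count in PMF table", call. = FALSE)
  if (any(!is.finite(df$prob)))
    stop("column 'prob' contains non-numeric or non-finite values",
         call. = FALSE)
  if (any(df$prob < 0))
    stop("negative probability in PMF table", call. = FALSE)
  probs <- numeric(max(df$k) + 1L)
  probs[df$k + 1L] <- df$prob
  law_empirical(probs)
}

#' @rdname read_pmf_table
#' @param law an empirical [offspring_law] to write.
#' @export
write_pmf_table <- function(law, path) {
  .check_law(law)
  if (law$family != "empirical")
    stop("only empirical laws are written as PMF tables", call. = FALSE)
  lines <- c("k\tprob",
             sprintf("%d\t%.17g", seq_along(law$probs) - 1L, law$probs))
  writeLines(lines, path)
  invisible(path)
}

# tabular views of result objects, used by write_report and the CLI ----------

#' Tabular view of a result object
#'
#' Converts the package's result objects into a data frame with a
#' deterministic column order, the layout used by [write_report()] and the
#' command-line interface. Extinction-time distributions use the layout
#' `t, q_t, Pr(T = t), 1 - q_t, (2t + 1)(1 - q_t)`.
#'
#' @param x a result object (`extinction_result`, `extinction_time_dist`,
#'   `size_distribution` or `absorption_summary`).
#' @param ... passed on (`n_founders` for size distributions).
#' @return A data frame.
#' @export
report_table <- function(x, ...) UseMethod("report_table")

#' @export
report_table.extinction_result <- function(x, ...) {
  data.frame(Q = x$Q, regime = x$regime, method = x$method,
             iterations = x$iterations, residual = x$residual)
}

#' @export
report_table.extinction_time_dist <- function(x, ...) {
  tt <- seq_along(x$q) - 1L
  data.frame(t = tt, q_t = x$q, pr_T_eq_t = c(NA, x$pmf),
             surv = 1 - x$q, wsurv = (2 * tt + 1) * (1 - x$q))
}

#' @export
report_table.size_distribution <- function(x, n_founders = NULL, ...) {
  df <- data.frame(m = seq_along(x$probs) - 1L, prob = x$probs)
  if (!is.null(n_founders)) df$expected_count <- n_founders * x$probs
  df
}

#' @export
report_table.absorption_summary <- function(x, ...) {
  data.frame(N = x$N, i0 = x$i0, p_fix = x$p_fix, p_loss = x$p_loss,
             t_loss = x$t_loss, t_fix = x$t_fix)
}

#' Write a result object to TSV or JSON
#'
#' TSV is the canonical output (tab-separated, header, floats at 10
#' significant digits); JSON mirrors the same content, with any summary
#' statistics carried alongside the table.
#'
#' @param x a result object supported by [report_table()].
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @param ... passed to [report_table()].
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json"), ...) {
  format <- match.arg(format)
  df <- report_table(x, ...)
  summ <- if (inherits(x, "extinction_time_dist"))
    list(T_mean = x$T_mean, T_var = x$T_var, Q = x$Q_ref,
         divergent = x$divergent)
  else NULL
  if (format == "tsv") {
    fmt <- df
    num <- vapply(fmt, is.numeric, logical(1))
    fmt[num] <- lapply(fmt[num], function(col) signif(col, 10))
    con <- file(path, "w")
    on.exit(close(con))
    utils::write.table(fmt, con, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(summ))
      writeLines(sprintf("# %s\t%s", names(summ),
                         vapply(summ, function(v) format(v, digits = 10),
                                character(1))), con)
  } else {
    payload <- if (is.null(summ)) list(table = df)
               else list(table = df, summary = summ)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}
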