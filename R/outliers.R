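#' Flag residual outliers by median absolute deviation
#'
#' A residual is flagged when it lies more than `cutoff` consistency-scaled
#' MADs from the residual median: `|r - median(r)| > cutoff * 1.4826 *
#' median(|r - median(r)|)`. The 1.4826 constant makes the MAD estimate the
#' SD under normality, so a 3.5 MAD cutoff is commensurate with 3.5 SD while
#' remaining robust to the very outliers being sought. When the MAD is zero
#' (at least half the residuals identical) nothing is flagged and a warning
#' is raised.
#'
#' @param residuals Numeric vector.
#' @param cutoff Cutoff in MAD multiples (default 3.5).
#' @return Logical vector, `TRUE` where flagged.
#' @export
mad_outlier_flags <- function(residuals, cutoff = 3.5) {
  stopifnot(cutoff > 0)
  if (!length(residuals)) return(logical(0))
  m <- median(residuals)
  s <- mad(residuals, center = m)  # 1.4826-scaled by default
  if (s == 0) {
    warning("MAD of residuals is zero; no outliers flagged", call. = FALSE)
    return(rep(FALSE, length(residuals)))
  }
  abs(residuals - m) > cutoff * s
}

#' Remove demographically corrected outliers
#'
#' Scores can be abnormal for a 25-year-old yet unremarkable for an
#' 85-year-old, so outliers are judged on the residuals of the selected
#' demographic model, not on raw scores. Rows whose residual exceeds
#' `cutoff` MADs from the residual median are removed; only the offending
#' score's row for this variable is dropped (per-score removal). The MAD is
#' used instead of the SD because a few extreme values inflate the SD and
#' mask themselves.
#'
#' @param table The table the model was fitted to (row order preserved).
#' @param fitted `norm_fit` from [fit_multilevel()] on `table`.
#' @param cutoff MAD multiples (default 3.5).
#' @param residual_type `"conditional"` (default; subtracts the predicted
#'   study intercept as well as the fixed effects) or `"marginal"`.
#' @return List with `table` (cleaned) and `report`, an `outlier_report`:
#'   variable, n_input, n_removed, fraction_removed, cutoff_used,
#'   residual_type.
#' @export
remove_mad_outliers <- function(table, fitted, cutoff = 3.5,
                                residual_type = c("conditional", "marginal")) {
  residual_type <- match.arg(residual_type)
  stopifnot(inherits(fitted, "norm_fit"), nrow(table) == fitted$n_obs)
  r <- norm_residuals(fitted, residual_type)
  flags <- mad_outlier_flags(r, cutoff)
  clean <- table[!flags, , drop = FALSE]
  rownames(clean) <- NULL
  attr(clean, "variable") <- attr(table, "variable")
  report <- structure(
    list(variable = attr(table, "variable") %||% "score",
         n_input = nrow(table), n_removed = sum(flags),
         fraction_removed = if (nrow(table) > 0) sum(flags) / nrow(table) else 0,
         cutoff_used = cutoff, residual_type = residual_type),
    class = "outlier_report"
  )
  list(table = clean, report = report)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "<outlier_report> %s: %d of %d scores beyond %.1f MAD of %s residuals (%.2f%%)\n",
    x$variable, x$n_removed, x$n_input, x$cutoff_used, x$residual_type,
    100 * x$fraction_removed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
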