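#' Remove impossible scores using extreme borders
#'
#' Drops rows whose score lies strictly outside the variable's extreme
#' borders: above the maximum possible score (coding errors) or below the
#' worst score compatible with cognitive health (pathology or typing
#' errors). A score exactly on a border is attainable and is kept. Only the
#' offending score's row for this variable is removed; the participant's
#' other variables (in other tables) are untouched.
#'
#' @param table Long table from [assemble_variable()].
#' @param spec [variable_spec] with both borders.
#' @return List with `table` (cleaned) and `report`, a `cleaning_report`:
#'   variable, n_input, n_removed_upper, n_removed_lower, fraction_removed.
#' @export
#' @examples
#' tab <- data.frame(study = "s1", age = 70, sex = factor("female"),
#'                   edu = 5L, score = c(16, 2, 10))
#' remove_impossible(tab, variable_spec("avlt_delayed", 3, 15))
remove_impossible <- function(table, spec) {
  stopifnot(inherits(spec, "variable_spec"), "score" %in% names(table))
  above <- table$score > spec$upper_border
  below <- table$score < spec$lower_border
  n_input <- nrow(table)
  clean <- table[!above & !below, , drop = FALSE]
  rownames(clean) <- NULL
  attr(clean, "variable") <- attr(table, "variable")
  report <- structure(
    list(variable = spec$name, n_input = n_input,
         n_removed_upper = sum(above), n_removed_lower = sum(below),
         fraction_removed = if (n_input > 0) (sum(above) + sum(below)) / n_input else 0),
    class = "cleaning_report"
  )
  list(table = clean, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "<cleaning_report> %s: %d of %d scores removed (%.2f%%; %d above upper border, %d below lower border)\n",
    x$variable, x$n_removed_upper + x$n_removed_lower, x$n_input,
    100 * x$fraction_removed, x$n_removed_upper, x$n_removed_lower))
  invisible(x)
}
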