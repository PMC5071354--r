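#' Tabulate demographic cell counts and decide which effects are estimable
#'
#' Before any statistical selection, each demographic effect must be
#' estimable at all: the donated data must cover a reasonable range of the
#' variable. Participants are tabulated by sex (2 cells), by age bands
#' (younger than 55; 55-75; older than 75) and by education level (1-7,
#' absent levels counting 0). An effect is considered estimable when its
#' summary cell count is at least `threshold` (default 5): the minimum count
#' for sex, the median count for age and education.
#'
#' Age enters the regression models as continuous years; the three bands
#' exist only for this tabulation.
#'
#' @param table Long table with `age`, `sex`, `edu` columns.
#' @param threshold Minimum summary cell count (default 5; counts below it
#'   mark the effect as too sparse to estimate).
#' @param age_breaks Two increasing cut points for the age bands (default
#'   `c(55, 75)`: bands are `< 55`, `[55, 75]`, `> 75`).
#' @return An `estimability_report`: the cell counts, the summary statistics
#'   (`sex_min`, `age_median`, `edu_median`) and the per-effect verdict in
#'   `$estimable`.
#' @export
tabulate_estimability <- function(table, threshold = 5, age_breaks = c(55, 75)) {
  stopifnot(length(age_breaks) == 2, age_breaks[1] < age_breaks[2])
  sex <- factor(table$sex, levels = SEX_LEVELS)
  sex_counts <- as.integer(table(sex))
  names(sex_counts) <- SEX_LEVELS
  age_counts <- c(
    sum(table$age < age_breaks[1]),
    sum(table$age >= age_breaks[1] & table$age <= age_breaks[2]),
    sum(table$age > age_breaks[2])
  )
  names(age_counts) <- c(paste0("<", age_breaks[1]),
                         paste0(age_breaks[1], "-", age_breaks[2]),
                         paste0(">", age_breaks[2]))
  edu_counts <- vapply(1:7, function(l) sum(table$edu == l), integer(1))
  names(edu_counts) <- as.character(1:7)
  estimability_from_counts(sex_counts, age_counts, edu_counts,
                           threshold = threshold)
}

#' Estimability verdict from printed cell counts
#'
#' Same rule as [tabulate_estimability()], applied directly to cell counts
#' (e.g. counts published in a tabulation) without raw data.
#'
#' @param sex_counts Two counts (female, male order is immaterial).
#' @param age_counts Three counts for the age bands.
#' @param edu_counts Up to seven counts for education levels.
#' @param threshold Minimum summary cell count (default 5).
#' @return An `estimability_report`.
#' @export
#' @examples
#' estimability_from_counts(c(2249, 2349), c(993, 2485, 1120),
#'                          c(17, 323, 119, 938, 1755, 1111, 335))
estimability_from_counts <- function(sex_counts, age_counts, edu_counts,
                                     threshold = 5) {
  stopifnot(length(sex_counts) == 2, length(age_counts) == 3,
            length(edu_counts) >= 1, length(edu_counts) <= 7,
            threshold > 0)
  sex_min <- min(sex_counts)
  age_median <- median(as.numeric(age_counts))
  edu_median <- median(as.numeric(edu_counts))
  structure(
    list(sex_counts = sex_counts, age_counts = age_counts,
         edu_counts = edu_counts,
         sex_min = sex_min, age_median = age_median, edu_median = edu_median,
         threshold = threshold,
         estimable = c(age = age_median >= threshold,
                       sex = sex_min >= threshold,
                       edu = edu_median >= threshold)),
    class = "estimability_report"
  )
}

#' @export
print.estimability_report <- function(x, ...) {
  cat("<estimability_report>\n")
  cat(sprintf("  sex: min %g across cells -> %s\n", x$sex_min,
              if (x$estimable[["sex"]]) "estimable" else "too sparse"))
  cat(sprintf("  age: median %g across bands -> %s\n", x$age_median,
              if (x$estimable[["age"]]) "estimable" else "too sparse"))
  cat(sprintf("  education: median %g across levels -> %s\n", x$edu_median,
              if (x$estimable[["edu"]]) "estimable" else "too sparse"))
  invisible(x)
}

#' Effects marked estimable in a report
#'
#' @param report An `estimability_report`.
#' @return Character vector, a subset of `c("age", "sex", "edu")`.
#' @export
estimable_effects <- function(report) {
  stopifnot(inherits(report, "estimability_report"))
  names(report$estimable)[report$estimable]
}
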