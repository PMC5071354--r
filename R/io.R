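#' @section File conventions:
#' Study files are UTF-8 delimited text (comma or tab, auto-detected from the
#' header line) with columns `study`, `age`, `sex`, `edu`, followed by one
#' column per test variable. Missing scores are empty fields or `NA`.
#' @name normforge-io
#' @keywords internal
NULL

DEMOGRAPHIC_COLS <- c("study", "age", "sex", "edu")
SEX_LEVELS <- c("female", "male")

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("f", "female", "0", "v", "w")] <- "female"
  out[x %in% c("m", "male", "1")] <- "male"
  factor(out, levels = SEX_LEVELS)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Define cleaning metadata for one test variable
#'
#' Extreme borders delimit the scores that are possible for a cognitively
#' healthy participant: the upper border is the maximum attainable score (so
#' anything above it is a coding error), the lower border the worst score
#' still compatible with cognitive health. Scores exactly on a border are
#' attainable and are kept by [remove_impossible()].
#'
#' @param name Variable identifier (column name in the study files).
#' @param lower_border Worst score still compatible with cognitive health.
#' @param upper_border Maximum possible score.
#' @param higher_is_better Whether larger raw scores indicate better
#'   performance. Recorded for reporting; the pipeline itself is
#'   direction-agnostic.
#' @return An object of class `variable_spec`.
#' @export
#' @examples
#' variable_spec("avlt_delayed", lower_border = 3, upper_border = 15)
variable_spec <- function(name, lower_border, upper_border, higher_is_better = TRUE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(lower_border), is.numeric(upper_border))
  if (!(lower_border < upper_border)) {
    stop("lower_border must be strictly below upper_border for variable '",
         name, "'")
  }
  structure(
    list(name = name, lower_border = as.numeric(lower_border),
         upper_border = as.numeric(upper_border),
         higher_is_better = isTRUE(higher_is_better)),
    class = "variable_spec"
  )
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s: borders [%g, %g], higher is %s\n",
              x$name, x$lower_border, x$upper_border,
              if (x$higher_is_better) "better" else "worse"))
  invisible(x)
}

#' Read per-variable cleaning specifications from YAML or JSON
#'
#' The config maps variable names to `{lower_border, upper_border,
#' higher_is_better}` entries.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of [variable_spec] objects.
#' @export
read_variable_specs <- function(path) {
  if (!file.exists(path)) stop("variable spec file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  specs <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    variable_spec(nm,
                  lower_border = entry$lower_border,
                  upper_border = entry$upper_border,
                  higher_is_better = if (is.null(entry$higher_is_better)) TRUE
                                     else isTRUE(entry$higher_is_better))
  })
  names(specs) <- names(raw)
  specs
}

#' Write variable specifications to YAML
#'
#' @param specs Named list of [variable_spec] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variable_specs <- function(specs, path) {
  out <- lapply(specs, function(s) {
    list(lower_border = s$lower_border, upper_border = s$upper_border,
         higher_is_better = s$higher_is_better)
  })
  names(out) <- vapply(specs, `[[`, "", "name")
  yaml::write_yaml(out, path)
  invisible(path)
}

validate_study_dataset <- function(d, study_id = NULL) {
  missing_cols <- setdiff(DEMOGRAPHIC_COLS, names(d))
  if (length(missing_cols)) {
    stop("study dataset missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.null(study_id) && nrow(d) && !all(d$study == study_id)) {
    stop("study column disagrees with dataset identifier '", study_id, "'")
  }
  invisible(d)
}

read_one_study_file <- function(path) {
  if (!file.exists(path)) stop("cannot read study file: ", path)
  delim <- detect_delim(path)
  d <- read.delim(path, sep = delim, stringsAsFactors = FALSE,
                  na.strings = c("NA", ""), check.names = FALSE,
                  fileEncoding = "UTF-8")
  validate_study_dataset(d)
  d$study <- as.character(d$study)
  d$age <- suppressWarnings(as.numeric(d$age))
  d$sex <- normalize_sex(d$sex)
  d$edu <- suppressWarnings(as.integer(d$edu))
  d
}

#' Load multi-study control data from delimited files
#'
#' Reads one file per study, or pooled files with a `study` column. Only
#' participants with all three demographic variables (age, sex, education)
#' are retained; education codes outside 1-7 are treated as unknown and the
#' record is dropped with a warning. Drop counts per file are collected in a
#' load report (attribute `"load_report"` of the result).
#'
#' @param paths Character vector of file paths.
#' @param specs Optional named list of [variable_spec]s; score columns not
#'   named in any spec raise a warning.
#' @return Named list of study datasets (one data frame per study), with a
#'   `load_report` attribute (data frame: file, n_rows, n_dropped).
#' @export
load_datasets <- function(paths, specs = NULL) {
  datasets <- list()
  report <- data.frame(file = character(), n_rows = integer(),
                       n_dropped = integer(), stringsAsFactors = FALSE)
  for (path in paths) {
    d <- read_one_study_file(path)
    n_in <- nrow(d)
    bad_edu <- !is.na(d$edu) & !(d$edu %in% 1:7)
    if (any(bad_edu)) {
      warning(sum(bad_edu), " record(s) with unknown education code dropped in ",
              basename(path), call. = FALSE)
      d$edu[bad_edu] <- NA_integer_
    }
    keep <- !is.na(d$age) & !is.na(d$sex) & !is.na(d$edu)
    d <- d[keep, , drop = FALSE]
    report <- rbind(report, data.frame(
      file = basename(path), n_rows = n_in, n_dropped = n_in - nrow(d),
      stringsAsFactors = FALSE))
    for (sid in unique(d$study)) {
      if (sid %in% names(datasets)) {
        stop("duplicate study identifier: '", sid, "' (in ", basename(path), ")")
      }
      datasets[[sid]] <- d[d$study == sid, , drop = FALSE]
      rownames(datasets[[sid]]) <- NULL
    }
  }
  if (!is.null(specs)) {
    known <- vapply(specs, `[[`, "", "name")
    score_cols <- setdiff(unique(unlist(lapply(datasets, names))),
                          DEMOGRAPHIC_COLS)
    unknown <- setdiff(score_cols, known)
    if (length(unknown)) {
      warning("score column(s) without a variable spec: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  attr(datasets, "load_report") <- report
  datasets
}

#' Write study datasets to one CSV per study
#'
#' @param datasets Named list of study data frames (as from [load_datasets()]
#'   or [simulate_studies()]).
#' @param dir Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_study_files <- function(datasets, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (sid in names(datasets)) {
    d <- datasets[[sid]]
    validate_study_dataset(d, sid)
    path <- file.path(dir, paste0(sid, ".csv"))
    write.csv(d, path, row.names = FALSE, na = "")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Assemble one variable's long table across studies
#'
#' Concatenates, over all studies, the participants with a non-missing score
#' on `variable`, yielding the per-variable analysis table the rest of the
#' pipeline operates on.
#'
#' @param datasets Named list of study data frames.
#' @param variable Name of the score column to assemble.
#' @return Data frame with columns `study`, `age`, `sex`, `edu`, `score` and
#'   attribute `"variable"`.
#' @export
assemble_variable <- function(datasets, variable) {
  has_var <- vapply(datasets, function(d) variable %in% names(d), logical(1))
  if (!any(has_var)) {
    stop("variable '", variable, "' not present in any study dataset")
  }
  pieces <- lapply(datasets[has_var], function(d) {
    keep <- !is.na(d[[variable]])
    data.frame(study = d$study[keep], age = d$age[keep], sex = d$sex[keep],
               edu = d$edu[keep], score = as.numeric(d[[variable]][keep]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, pieces)
  rownames(tab) <- NULL
  tab$sex <- factor(tab$sex, levels = SEX_LEVELS)
  attr(tab, "variable") <- variable
  tab
}
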