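#' Build the normative model for a single variable
#'
#' Runs the per-variable construction pipeline on an assembled long table:
#' extreme-border cleaning, estimability tabulation, backward-AIC selection
#' of demographic effects in the multilevel model, 3.5-MAD residual outlier
#' removal, Box-Cox search for the residual-normalizing power, and the final
#' refit on the standardized transformed scale. The returned `norm_model`
#' carries all stage reports as provenance.
#'
#' @param table Long table from [assemble_variable()].
#' @param spec [variable_spec] with the extreme borders.
#' @param mad_cutoff Outlier cutoff in MAD multiples (default 3.5).
#' @param threshold Estimability cell-count threshold (default 5).
#' @param grid,step,coarse_step,criterion Passed to [search_lambda()].
#' @param age_breaks Age-band cut points for the estimability tabulation.
#' @return A `norm_model` with `variance_partition` attached when the
#'   variable came from multiple studies.
#' @export
build_norm_model <- function(table, spec, mad_cutoff = 3.5, threshold = 5,
                             grid = c(-3, 3), step = 0.001, coarse_step = 0.01,
                             criterion = "profile", age_breaks = c(55, 75)) {
  cleaned <- remove_impossible(table, spec)
  if (!nrow(cleaned$table)) stop("no scores remain after border cleaning")
  est <- tabulate_estimability(cleaned$table, threshold = threshold,
                               age_breaks = age_breaks)
  sel <- backward_aic(cleaned$table, estimable_effects(est))
  out <- remove_mad_outliers(cleaned$table, sel$fit, cutoff = mad_cutoff)
  params <- search_lambda(out$table, sel$spec$included_effects,
                          grid = grid, step = step, coarse_step = coarse_step,
                          criterion = criterion)
  model <- refit_transformed(
    out$table, sel$spec$included_effects, params,
    variable = spec$name,
    borders = c(spec$lower_border, spec$upper_border),
    provenance = list(cleaning = cleaned$report, estimability = est,
                      selection_trace = sel$trace, outliers = out$report))
  if (model$spec$random_intercept_study) {
    model$variance_partition <- partition_variance(model)
  }
  model
}

#' Run the full normative-database construction over many variables
#'
#' For every variable: assemble across studies, then
#' [build_norm_model()]. A failure in any variable is logged and that
#' variable skipped; the run never aborts as a whole. The aggregate report
#' mirrors the usual construction summaries: percent removed by borders,
#' percent removed by MAD, selected effects, the chosen power, and the
#' between-study variance share for multi-study variables.
#'
#' @param datasets Named list of study data frames ([load_datasets()] or
#'   [simulate_studies()]`$datasets`).
#' @param specs Named list of [variable_spec]s.
#' @param variables Variables to process (default: all spec names).
#' @param ... Passed to [build_norm_model()].
#' @return A `norm_store`: `models` (named `norm_model` list), `failed`
#'   (named character vector of error messages), `report` (one-row-per-
#'   variable data frame), `log` (character lines).
#' @export
run_pipeline <- function(datasets, specs, variables = names(specs), ...) {
  models <- list()
  failed <- character(0)
  log <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    message(line)
  }
  for (v in variables) {
    spec <- specs[[v]]
    if (is.null(spec)) {
      failed[v] <- "no variable spec"
      say("[%s] skipped: no variable spec", v)
      next
    }
    res <- tryCatch({
      tab <- assemble_variable(datasets, v)
      model <- build_norm_model(tab, spec, ...)
      models[[v]] <- model
      prov <- model$provenance
      say("[%s] n = %d; borders removed %.2f%%; MAD removed %.2f%%; effects {%s}; lambda = %g",
          v, prov$cleaning$n_input, 100 * prov$cleaning$fraction_removed,
          100 * prov$outliers$fraction_removed,
          paste(model$spec$included_effects, collapse = ", "),
          model$transform$lambda)
      if (!model$spec$random_intercept_study) {
        say("[%s] single study: no random intercept, variance partition skipped", v)
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      failed[v] <- res
      say("[%s] FAILED: %s", v, res)
    }
  }
  structure(
    list(models = models, failed = failed,
         report = store_report(models), log = log),
    class = "norm_store"
  )
}

store_report <- function(models) {
  if (!length(models)) {
    return(data.frame(variable = character(), n_obs = integer()))
  }
  do.call(rbind, lapply(models, function(m) {
    prov <- m$provenance
    data.frame(
      variable = m$variable,
      n_input = prov$cleaning$n_input,
      n_obs = m$n_obs,
      n_studies = m$n_studies,
      pct_removed_borders = 100 * prov$cleaning$fraction_removed,
      pct_removed_mad = 100 * prov$outliers$fraction_removed,
      effects = paste(m$spec$included_effects, collapse = "+"),
      lambda = m$transform$lambda,
      between_study_fraction = if (!is.null(m$variance_partition))
        unname(m$variance_partition[["between_study"]]) else NA_real_,
      row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' @export
print.norm_store <- function(x, ...) {
  cat(sprintf("<norm_store> %d model(s), %d failed variable(s)\n",
              length(x$models), length(x$failed)))
  if (nrow(x$report)) {
    print(x$report, row.names = FALSE, digits = 4)
    cat(sprintf("mean %% removed: borders %.2f, MAD %.2f\n",
                mean(x$report$pct_removed_borders),
                mean(x$report$pct_removed_mad)))
  }
  invisible(x)
}

model_to_list <- function(m) {
  prov <- m$provenance
  list(
    variable = m$variable,
    spec = m$spec,
    transform = unclass(m$transform),
    coefficients = as.list(m$coefficients),
    sigma_study = m$sigma_study, sigma_resid = m$sigma_resid,
    aic = m$aic, n_obs = m$n_obs, n_studies = m$n_studies,
    training = m$training,
    borders = m$borders,
    variance_partition = if (!is.null(m$variance_partition))
      as.list(m$variance_partition) else NULL,
    provenance = list(
      cleaning = if (!is.null(prov$cleaning)) unclass(prov$cleaning) else NULL,
      estimability = if (!is.null(prov$estimability)) {
        e <- prov$estimability
        list(sex_counts = as.list(e$sex_counts),
             age_counts = as.list(e$age_counts),
             edu_counts = as.list(e$edu_counts),
             sex_min = e$sex_min, age_median = e$age_median,
             edu_median = e$edu_median, threshold = e$threshold,
             estimable = as.list(e$estimable))
      } else NULL,
      selection_trace = prov$selection_trace,
      outliers = if (!is.null(prov$outliers)) unclass(prov$outliers) else NULL),
    schema = m$schema)
}

list_to_model <- function(l) {
  params <- transform_params(l$transform$lambda, l$transform$offset,
                             l$transform$z_mean, l$transform$z_sd)
  prov <- list()
  if (!is.null(l$provenance$cleaning)) {
    prov$cleaning <- structure(l$provenance$cleaning, class = "cleaning_report")
  }
  if (!is.null(l$provenance$estimability)) {
    e <- l$provenance$estimability
    prov$estimability <- estimability_from_counts(
      unlist(e$sex_counts), unlist(e$age_counts), unlist(e$edu_counts),
      threshold = e$threshold)
  }
  prov$selection_trace <- l$provenance$selection_trace
  if (!is.null(l$provenance$outliers)) {
    prov$outliers <- structure(l$provenance$outliers, class = "outlier_report")
  }
  structure(
    list(variable = l$variable,
         spec = list(included_effects = as.character(unlist(l$spec$included_effects)),
                     random_intercept_study = isTRUE(l$spec$random_intercept_study)),
         transform = params,
         coefficients = unlist(l$coefficients),
         sigma_study = l$sigma_study, sigma_resid = l$sigma_resid,
         aic = l$aic, n_obs = l$n_obs, n_studies = l$n_studies,
         training = list(age_range = unlist(l$training$age_range),
                         edu_range = unlist(l$training$edu_range)),
         borders = if (!is.null(l$borders)) unlist(l$borders) else NULL,
         variance_partition = if (!is.null(l$variance_partition))
           unlist(l$variance_partition) else NULL,
         provenance = prov,
         schema = l$schema %||% "normforge-model/1"),
    class = "norm_model"
  )
}

#' Write a norm store (or single model) to versioned JSON
#'
#' The JSON norm store is the hand-off between database construction and
#' patient scoring: each entry is self-contained (selected effects, z-scale
#' coefficients, variance components, transform parameters, standardization
#' constants, training ranges, borders, stage reports). Output is
#' deterministic: rerunning an identical pipeline yields byte-identical
#' files.
#'
#' @param store A `norm_store` or a single `norm_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_norm_store <- function(store, path) {
  if (inherits(store, "norm_model")) {
    store <- structure(list(models = setNames(list(store), store$variable),
                            failed = character(0),
                            report = store_report(list(store)),
                            log = character(0)),
                       class = "norm_store")
  }
  stopifnot(inherits(store, "norm_store"))
  payload <- list(
    schema = "normforge-store/1",
    models = lapply(store$models, model_to_list),
    failed = as.list(store$failed))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a norm store written by [write_norm_store()]
#'
#' @param path Path to the JSON store.
#' @return A `norm_store` with `norm_model` entries ready for
#'   [compare_patient()].
#' @export
read_norm_store <- function(path) {
  if (!file.exists(path)) stop("norm store not found: ", path)
  payload <- jsonlite::read_json(path)
  if (!identical(payload$schema, "normforge-store/1")) {
    stop("unrecognized norm store schema: ", payload$schema %||% "<missing>")
  }
  models <- lapply(payload$models, list_to_model)
  structure(
    list(models = models, failed = unlist(payload$failed) %||% character(0),
         report = store_report(models), log = character(0)),
    class = "norm_store"
  )
}
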