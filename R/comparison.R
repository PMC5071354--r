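#' Compare a patient's raw score against a stored normative model
#'
#' The raw score is transformed and standardized with the model's stored
#' parameters (the same procedure the norms were built with), the expected
#' z-scale value for the patient's demographics is computed from the fixed
#' effects alone (a new patient belongs to no contributing study, so the
#' random intercept's expectation is zero), and the demographically
#' corrected z is the deviation divided by the normative SD. By default the
#' normative SD is the total `sqrt(sigma_study^2 + sigma_resid^2)`: the
#' patient's hypothetical study is unknown, so between-study variability is
#' part of normative uncertainty. `sd_type = "residual"` uses the
#' within-study SD only.
#'
#' No small-sample correction is applied to the z; these norms
#' are built from large samples, where the normal approximation is accurate
#' (a t-based correction matters for traditional small normative samples).
#'
#' @param model A `norm_model` (from [refit_transformed()] or a norm store).
#' @param age Age in years.
#' @param sex `"female"` or `"male"` (or `f`/`m`).
#' @param edu Education level 1-7 (Verhage-type ordinal scale).
#' @param score Raw test score.
#' @param sd_type `"total"` (default) or `"residual"`.
#' @return A `comparison_result`: `z_corrected`, `percentile`
#'   (`100 * pnorm(z)`), the transformed score, the expected z-scale value,
#'   and `flags` (`"outside_borders"` when the raw score violates the
#'   stored extreme borders; `"extrapolated"` when the demographics fall
#'   outside the training range).
#' @export
compare_patient <- function(model, age, sex, edu, score,
                            sd_type = c("total", "residual")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(model, "norm_model"), length(score) == 1)
  sex <- as.character(normalize_sex(sex))
  if (is.na(sex)) stop("sex must be female/f or male/m")
  if (!(edu %in% 1:7)) stop("education must be an integer 1-7")
  if (!is.finite(age) || age < 0) stop("age must be a non-negative number")

  flags <- character(0)
  if (!is.null(model$borders) &&
      (score > max(model$borders) || score < min(model$borders))) {
    flags <- c(flags, "outside_borders")
    warning("raw score ", score, " lies outside the extreme borders [",
            min(model$borders), ", ", max(model$borders), "]", call. = FALSE)
  }
  tr <- model$training
  if (!is.null(tr) &&
      (age < tr$age_range[1] || age > tr$age_range[2] ||
       edu < tr$edu_range[1] || edu > tr$edu_range[2])) {
    flags <- c(flags, "extrapolated")
  }

  z_score <- apply_power(score, model$transform)
  expected <- predict_fixed(model$coefficients, age, sex, edu)
  norm_sd <- if (sd_type == "total") {
    sqrt(model$sigma_study^2 + model$sigma_resid^2)
  } else {
    model$sigma_resid
  }
  z_corrected <- (z_score - expected) / norm_sd
  structure(
    list(variable = model$variable, raw_score = score,
         transformed_score = z_score, expected = unname(expected),
         z_corrected = unname(z_corrected),
         percentile = unname(100 * pnorm(z_corrected)),
         sd_type = sd_type, flags = flags),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: raw %g -> z = %.3f, percentile %.1f\n",
              x$variable, x$raw_score, x$z_corrected, x$percentile))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Export a continuous-age normative table
#'
#' Because age is a continuous predictor, expected scores change smoothly
#' with age instead of leaping between age bands. For each age on the grid,
#' the raw scores at the requested percentiles are obtained by placing
#' normal quantiles around the fixed-effect prediction on the z-scale and
#' back-transforming.
#'
#' @param model A `norm_model`.
#' @param ages Numeric vector of ages (default: 40 points over the training
#'   range).
#' @param sex,edu Demographics the table is conditioned on.
#' @param percentiles Percentile bands (default
#'   `c(2, 5, 10, 25, 50, 75, 90, 95, 98)`).
#' @param sd_type `"total"` (default) or `"residual"`, as in
#'   [compare_patient()].
#' @return Data frame: `age` plus one `p<q>` column per percentile holding
#'   raw scores.
#' @export
export_norm_table <- function(model, ages = NULL, sex = "female", edu = 5,
                              percentiles = c(2, 5, 10, 25, 50, 75, 90, 95, 98),
                              sd_type = c("total", "residual")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(model, "norm_model"),
            all(percentiles > 0), all(percentiles < 100))
  if (is.null(ages)) {
    ages <- seq(model$training$age_range[1], model$training$age_range[2],
                length.out = 40)
  }
  sex <- as.character(normalize_sex(sex))
  expected <- predict_fixed(model$coefficients, ages, sex, edu)
  norm_sd <- if (sd_type == "total") {
    sqrt(model$sigma_study^2 + model$sigma_resid^2)
  } else {
    model$sigma_resid
  }
  out <- data.frame(age = ages)
  for (p in percentiles) {
    z <- expected + qnorm(p / 100) * norm_sd
    out[[paste0("p", p)]] <- back_transform(z, model$transform)
  }
  attr(out, "sex") <- sex
  attr(out, "edu") <- edu
  attr(out, "variable") <- model$variable
  out
}
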