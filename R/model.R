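EFFECTS_ALL <- c("age", "sex", "edu")

model_formula <- function(effects, multilevel) {
  rhs <- if (length(effects)) paste(effects, collapse = " + ") else "1"
  if (multilevel) rhs <- paste(rhs, "+ (1 | study)")
  as.formula(paste("score ~", rhs))
}

check_design <- function(table, effects) {
  for (e in effects) {
    vals <- table[[e]]
    if (length(unique(vals[!is.na(vals)])) < 2) {
      stop("singular design: effect '", e, "' takes a single value", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Fit the normative multilevel regression for one variable
#'
#' Fits `score ~ <effects> + (1 | study)` by maximum likelihood: fixed
#' demographic effects (age in continuous years, sex contrast-coded with
#' female = 0 / male = 1, education as an interval 1-7 scale) plus a random
#' intercept per donating study that absorbs between-study differences in
#' recruitment, motivation and selection. When the table holds a single
#' study the model reduces to ordinary least squares with a between-study SD
#' of zero.
#'
#' ML (not REML) is used so that AIC values are comparable across
#' fixed-effect structures during backward selection; `REML = TRUE` is
#' available for final variance-component reporting.
#'
#' @param table Long table (`study`, `age`, `sex`, `edu`, `score`).
#' @param effects Character subset of `c("age", "sex", "edu")` to include as
#'   fixed effects.
#' @param REML Logical; fit by REML instead of ML (default `FALSE`).
#' @return A `norm_fit`: the underlying fit plus `coefficients` (named,
#'   including `"(Intercept)"`, `"age"`, `"sexmale"`, `"edu"` as included),
#'   `sigma_study`, `sigma_resid`, `aic`, `n_obs`, `effects`, `multilevel`.
#' @export
fit_multilevel <- function(table, effects = EFFECTS_ALL, REML = FALSE) {
  stopifnot(all(effects %in% EFFECTS_ALL))
  effects <- EFFECTS_ALL[EFFECTS_ALL %in% effects]  # canonical order
  if (!nrow(table)) stop("cannot fit a model to an empty table")
  check_design(table, effects)
  multilevel <- length(unique(table$study)) > 1
  if (multilevel) {
    fit <- lme4::lmer(model_formula(effects, TRUE), data = table, REML = REML,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular = "ignore"))
    vc <- lme4::VarCorr(fit)
    sigma_study <- attr(vc$study, "stddev")[[1]]
    coefs <- lme4::fixef(fit)
  } else {
    fit <- lm(model_formula(effects, FALSE), data = table)
    sigma_study <- 0
    coefs <- coef(fit)
  }
  structure(
    list(fit = fit, effects = effects, multilevel = multilevel,
         coefficients = coefs,
         sigma_study = unname(sigma_study),
         sigma_resid = unname(sigma(fit)),
         aic = AIC(fit), loglik = as.numeric(logLik(fit)),
         n_obs = nrow(table), REML = REML),
    class = "norm_fit"
  )
}

#' @export
print.norm_fit <- function(x, ...) {
  cat(sprintf("<norm_fit> score ~ %s%s (n = %d, %s)\n",
              if (length(x$effects)) paste(x$effects, collapse = " + ") else "1",
              if (x$multilevel) " + (1 | study)" else "",
              x$n_obs, if (x$REML) "REML" else "ML"))
  print(round(x$coefficients, 4))
  cat(sprintf("  sigma_study = %.4f, sigma_resid = %.4f, AIC = %.1f\n",
              x$sigma_study, x$sigma_resid, x$aic))
  invisible(x)
}

#' Residuals of a normative fit
#'
#' Conditional residuals (the default) subtract both the fixed-effect
#' prediction and the predicted study intercept, so a score is judged
#' against its own study's level; marginal residuals subtract the
#' fixed-effect prediction only.
#'
#' @param fitted A `norm_fit`.
#' @param type `"conditional"` or `"marginal"`.
#' @return Numeric residual vector, one per row of the fitted table.
#' @export
norm_residuals <- function(fitted, type = c("conditional", "marginal")) {
  type <- match.arg(type)
  stopifnot(inherits(fitted, "norm_fit"))
  if (!fitted$multilevel || type == "conditional") {
    as.numeric(resid(fitted$fit))
  } else {
    as.numeric(resid(fitted$fit) + lme4::ranef(fitted$fit)$study[
      as.character(fitted$fit@frame$study), 1])
  }
}

#' Backward AIC selection of demographic fixed effects
#'
#' Starting from all estimable effects, repeatedly refits the model with each
#' remaining effect removed in turn and drops the removal that lowers the
#' Akaike Information Criterion the most; stops when no single removal
#' lowers the AIC. All fits use maximum likelihood so AIC values are
#' comparable across fixed-effect structures; the AIC counts every estimated
#' parameter, variance components included. The random study intercept is
#' never a selection candidate.
#'
#' @param table Long table for one variable.
#' @param estimable Character vector of candidate effects (typically
#'   [estimable_effects()] of the tabulation report).
#' @return A `model_selection` list: `spec` (`included_effects`,
#'   `random_intercept_study`), `fit` (the final ML `norm_fit`), and `trace`
#'   (data frame with one row per examined model: step, effects, AIC,
#'   action).
#' @export
backward_aic <- function(table, estimable = EFFECTS_ALL) {
  stopifnot(nrow(table) > 0, all(estimable %in% EFFECTS_ALL))
  effects <- EFFECTS_ALL[EFFECTS_ALL %in% estimable]
  current <- fit_multilevel(table, effects)
  trace <- data.frame(step = 0L,
                      effects = paste(effects, collapse = "+"),
                      aic = current$aic, action = "start",
                      stringsAsFactors = FALSE)
  step <- 0L
  while (length(effects) > 0) {
    step <- step + 1L
    candidates <- lapply(effects, function(e) {
      fit_multilevel(table, setdiff(effects, e))
    })
    aics <- vapply(candidates, `[[`, numeric(1), "aic")
    best <- which.min(aics)
    if (aics[best] < current$aic) {
      dropped <- effects[best]
      effects <- setdiff(effects, dropped)
      current <- candidates[[best]]
      trace <- rbind(trace, data.frame(
        step = step, effects = paste(effects, collapse = "+"),
        aic = current$aic, action = paste0("drop ", dropped),
        stringsAsFactors = FALSE))
    } else {
      break
    }
  }
  structure(
    list(spec = list(included_effects = effects,
                     random_intercept_study = current$multilevel),
         fit = current, trace = trace),
    class = "model_selection"
  )
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> included: {%s}; AIC %.1f\n",
              paste(x$spec$included_effects, collapse = ", "), x$fit$aic))
  invisible(x)
}
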