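#' Transformation parameters for a normative variable
#'
#' Bundles everything needed to map a raw score to the standardized
#' transformed scale: the Box-Cox power `lambda`, the positivity `offset`
#' added before exponentiation, the sign flip applied when `lambda < 0`
#' (a negative power reverses score order; multiplying by -1 restores it),
#' and the standardization constants mapping the transformed scores to mean
#' 0, SD 1.
#'
#' @param lambda Nonzero power.
#' @param offset Additive constant (>= 0) making all scores positive.
#' @param z_mean,z_sd Standardization constants of the transformed scores.
#' @return A `transform_params` object (`sign_flip` is derived from
#'   `lambda`).
#' @export
transform_params <- function(lambda, offset = 0, z_mean = 0, z_sd = 1) {
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda != 0,
            offset >= 0, z_sd > 0)
  structure(
    list(lambda = lambda, offset = offset, sign_flip = lambda < 0,
         z_mean = z_mean, z_sd = z_sd),
    class = "transform_params"
  )
}

#' @export
print.transform_params <- function(x, ...) {
  cat(sprintf(
    "<transform_params> lambda = %g, offset = %g%s, standardized by (mean %.4g, sd %.4g)\n",
    x$lambda, x$offset, if (x$sign_flip) ", order-restoring sign flip" else "",
    x$z_mean, x$z_sd))
  invisible(x)
}

# offset making all scores strictly positive: |min| + epsilon when min <= 0
compute_offset <- function(scores, epsilon = 0.001) {
  m <- min(scores)
  if (m <= 0) abs(m) + epsilon else 0
}

#' Apply the power transform and standardization to raw scores
#'
#' Computes `t = (score + offset)^lambda`, multiplies by -1 when
#' `lambda < 0` to restore the original score order, then standardizes:
#' `z = (t - z_mean) / z_sd`. Strictly order-preserving in the raw score for
#' every nonzero `lambda`.
#'
#' @param scores Numeric raw scores.
#' @param params [transform_params()].
#' @return Standardized transformed scores.
#' @export
apply_power <- function(scores, params) {
  stopifnot(inherits(params, "transform_params"))
  base <- scores + params$offset
  if (any(base <= 0)) {
    stop("score plus offset must be positive; the stored offset is stale ",
         "for this input")
  }
  t <- base^params$lambda
  if (params$sign_flip) t <- -t
  (t - params$z_mean) / params$z_sd
}

#' Invert the power transform: standardized scale back to raw scores
#'
#' Exact inverse of [apply_power()]: destandardize, undo the sign flip,
#' raise to `1/lambda`, subtract the offset.
#'
#' @param z Values on the standardized transformed scale.
#' @param params [transform_params()].
#' @return Raw-scale values.
#' @export
back_transform <- function(z, params) {
  stopifnot(inherits(params, "transform_params"))
  t <- z * params$z_sd + params$z_mean
  if (params$sign_flip) t <- -t
  if (any(t <= 0)) {
    stop("back-transform undefined: value maps to a non-positive base for ",
         "power 1/lambda")
  }
  t^(1 / params$lambda) - params$offset
}

# design matrix for the lambda search: selected fixed effects plus study as
# a predictor (so residuals are normalized within every study, not across)
search_design <- function(table, effects, include_study = TRUE) {
  terms <- effects
  if (include_study && length(unique(table$study)) > 1) {
    terms <- c(terms, "factor(study)")
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  model.matrix(as.formula(paste("~", rhs)), data = table)
}

# evaluate the selection criterion on a vector of lambdas; chunked so the
# n x k transform matrix stays small
eval_lambda_grid <- function(lams, ly, qrX, criterion, max_cells = 5e6) {
  n <- length(ly)
  sly <- sum(ly)
  nscores <- qnorm(ppoints(n))
  out <- numeric(length(lams))
  chunk <- max(1L, floor(max_cells / n))
  for (start in seq(1L, length(lams), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(lams))
    lam <- lams[idx]
    # scaled Box-Cox form ((y^l - 1)/l): same argmax, Jacobian term is exact
    W <- (exp(outer(ly, lam)) - 1) / rep(lam, each = n)
    R <- qr.resid(qrX, W)
    if (criterion == "profile") {
      rss <- colSums(R^2)
      out[idx] <- -n / 2 * log(rss / n) + (lam - 1) * sly
    } else {
      out[idx] <- vapply(seq_along(idx), function(j) {
        cor(sort(R[, j]), nscores)^2
      }, numeric(1))
    }
  }
  out
}

#' Search for the residual-normalizing Box-Cox power
#'
#' Scans a grid of powers; for each, transforms the raw scores, fits the
#' selected demographic model with study included as a predictor (so
#' residuals are judged within every study), and scores residual normality.
#' Four adjustments adapt the classic Box-Cox search to normative raw
#' scores: (1) a positivity constant `|min| + 0.001` is added first when any
#' score is non-positive; (2) a negative winning power gets an
#' order-restoring sign flip; (3) study enters the regression as a
#' predictor; (4) the winning transform's scores are standardized to mean 0,
#' SD 1.
#'
#' The default criterion is the Box-Cox profile log-likelihood of the
#' residual model; `"shapiro_francia"` instead maximizes the
#' Shapiro-Francia W' statistic (squared correlation between sorted
#' residuals and normal scores). A coarse pass (step `coarse_step`) locates
#' the optimum, a fine pass at `step` refines it; `lambda = 0` (the log) is
#' outside the pure power family and is skipped if the grid lands on it.
#'
#' @param table Cleaned, outlier-removed long table.
#' @param effects Fixed effects of the selected model.
#' @param grid Length-2 numeric range of powers (default `c(-3, 3)`).
#' @param step Fine grid resolution (default 0.001).
#' @param coarse_step First-pass resolution (default 0.01); set equal to
#'   `step` for a single-stage scan.
#' @param criterion `"profile"` or `"shapiro_francia"`.
#' @return [transform_params()] for the winning power, with attributes
#'   `criterion` and `criterion_value`.
#' @export
search_lambda <- function(table, effects = EFFECTS_ALL,
                          grid = c(-3, 3), step = 0.001, coarse_step = 0.01,
                          criterion = c("profile", "shapiro_francia")) {
  criterion <- match.arg(criterion)
  stopifnot(length(grid) == 2, grid[1] < grid[2], step > 0,
            coarse_step >= step, nrow(table) > 0)
  y <- table$score
  off <- compute_offset(y)
  ly <- log(y + off)
  X <- search_design(table, effects)
  qrX <- qr(X)

  make_grid <- function(lo, hi, by) {
    lams <- seq(lo, hi, by = by)
    zero <- abs(lams) < by / 2
    if (any(zero)) {
      message("lambda = 0 (log) is outside the power family; skipped")
      lams <- lams[!zero]
    }
    lams
  }
  coarse <- make_grid(grid[1], grid[2], coarse_step)
  if (!length(coarse)) stop("empty lambda grid")
  crit <- eval_lambda_grid(coarse, ly, qrX, criterion)
  if (all(!is.finite(crit))) stop("criterion undefined on the whole grid")
  best <- coarse[which.max(crit)]
  if (coarse_step > step) {
    fine <- make_grid(max(grid[1], best - coarse_step),
                      min(grid[2], best + coarse_step), step)
    fcrit <- eval_lambda_grid(fine, ly, qrX, criterion)
    best <- fine[which.max(fcrit)]
    best_val <- max(fcrit, na.rm = TRUE)
  } else {
    best_val <- max(crit, na.rm = TRUE)
  }

  t <- (y + off)^best
  if (best < 0) t <- -t
  params <- transform_params(best, offset = off,
                             z_mean = mean(t), z_sd = sd(t))
  attr(params, "criterion") <- criterion
  attr(params, "criterion_value") <- best_val
  params
}

#' Refit the selected model on the standardized transformed scale
#'
#' Transforms the scores with `params`, refits the selected multilevel model
#' by maximum likelihood on the z-scale, and packages everything a patient
#' comparison needs into a self-contained `norm_model`.
#'
#' @param table Cleaned, outlier-removed long table.
#' @param effects Included fixed effects (the selected spec).
#' @param params [transform_params()] from [search_lambda()].
#' @param variable Variable name to record (defaults to the table's
#'   `"variable"` attribute).
#' @param borders Optional numeric `c(lower, upper)` extreme borders,
#'   recorded so patient inputs can be border-checked.
#' @param provenance Optional named list of upstream reports (cleaning,
#'   outliers, estimability, selection trace) stored verbatim.
#' @return A `norm_model`: selected spec, transform, z-scale coefficients,
#'   variance components, sample size, training demographic ranges,
#'   borders and provenance.
#' @export
refit_transformed <- function(table, effects, params,
                              variable = attr(table, "variable"),
                              borders = NULL, provenance = list()) {
  stopifnot(inherits(params, "transform_params"))
  ztab <- table
  ztab$score <- apply_power(table$score, params)
  fit <- fit_multilevel(ztab, effects)
  structure(
    list(variable = variable %||% "score",
         spec = list(included_effects = fit$effects,
                     random_intercept_study = fit$multilevel),
         transform = params,
         coefficients = fit$coefficients,
         sigma_study = fit$sigma_study,
         sigma_resid = fit$sigma_resid,
         aic = fit$aic, n_obs = fit$n_obs,
         n_studies = length(unique(table$study)),
         training = list(age_range = range(table$age),
                         edu_range = range(table$edu)),
         borders = borders,
         provenance = provenance,
         schema = "normforge-model/1"),
    class = "norm_model"
  )
}

#' @export
print.norm_model <- function(x, ...) {
  cat(sprintf("<norm_model> %s: n = %d from %d study(ies)\n",
              x$variable, x$n_obs, x$n_studies))
  cat(sprintf("  effects: {%s}; lambda = %g, offset = %g\n",
              paste(x$spec$included_effects, collapse = ", "),
              x$transform$lambda, x$transform$offset))
  cat(sprintf("  z-scale sigma_study = %.4f, sigma_resid = %.4f\n",
              x$sigma_study, x$sigma_resid))
  invisible(x)
}

# fixed-effect prediction on the z-scale for demographics
predict_fixed <- function(coefs, age, sex, edu) {
  n <- max(length(age), length(sex), length(edu))
  pred <- rep(unname(coefs[["(Intercept)"]]), length.out = n)
  if ("age" %in% names(coefs)) pred <- pred + coefs[["age"]] * age
  if ("sexmale" %in% names(coefs)) pred <- pred + coefs[["sexmale"]] * (sex == "male")
  if ("edu" %in% names(coefs)) pred <- pred + coefs[["edu"]] * edu
  pred
}

#' Partition residual variance into between- and within-study shares
#'
#' For variables administered in multiple studies, the share of residual
#' variance due to study membership is
#' `sigma_study^2 / (sigma_study^2 + sigma_resid^2)`; the complement is the
#' within-study (between-participant) share. The two always sum to one.
#'
#' @param model A `norm_model` or `norm_fit` from a multi-study table.
#' @return Named numeric: `between_study`, `within_study`.
#' @export
partition_variance <- function(model) {
  multilevel <- if (inherits(model, "norm_model")) {
    model$spec$random_intercept_study
  } else if (inherits(model, "norm_fit")) {
    model$multilevel
  } else stop("expected a norm_model or norm_fit")
  if (!multilevel) stop("variance partition undefined for a single-study model")
  v_between <- model$sigma_study^2
  v_within <- model$sigma_resid^2
  between <- v_between / (v_between + v_within)
  c(between_study = between, within_study = 1 - between)
}

#' Plot-ready model-fit diagnostics on the raw scale
#'
#' Pairs the raw observations with back-transformed model predictions over
#' the observed age range, one curve per education level and sex, for visual
#' inspection of fit (prediction curves through the raw data cloud).
#'
#' @param model A `norm_model`.
#' @param table The table the model was built from (raw scores).
#' @param age_points Number of ages per curve (default 50).
#' @return A `norm_diagnostics` list: `points` (study, age, sex, edu, score)
#'   and `curves` (age, sex, edu, predicted_z, predicted_raw).
#' @export
fit_diagnostics <- function(model, table, age_points = 50) {
  stopifnot(inherits(model, "norm_model"))
  ages <- seq(min(table$age), max(table$age), length.out = age_points)
  combos <- expand.grid(sex = SEX_LEVELS, edu = sort(unique(table$edu)),
                        stringsAsFactors = FALSE)
  curves <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    z <- predict_fixed(model$coefficients, ages, combos$sex[i], combos$edu[i])
    data.frame(age = ages, sex = combos$sex[i], edu = combos$edu[i],
               predicted_z = z,
               predicted_raw = back_transform(z, model$transform),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(points = table[, c("study", "age", "sex", "edu", "score")],
         curves = curves, variable = model$variable),
    class = "norm_diagnostics"
  )
}

#' @export
print.norm_diagnostics <- function(x, ...) {
  cat(sprintf("<norm_diagnostics> %s: %d observations, %d prediction curves\n",
              x$variable, nrow(x$points),
              nrow(unique(x$curves[, c("sex", "edu")]))))
  invisible(x)
}

#' @export
plot.norm_diagnostics <- function(x, ...) {
  edus <- sort(unique(x$curves$edu))
  old <- graphics::par(mfrow = c(ceiling(length(edus) / 4), min(4, length(edus))),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (e in edus) {
    pts <- x$points[x$points$edu == e, ]
    plot(pts$age, pts$score, pch = ifelse(pts$sex == "male", 121, 120),
         cex = 0.4, col = "grey40", xlab = "age (years)", ylab = x$variable,
         main = paste("education", e), ...)
    for (s in SEX_LEVELS) {
      cv <- x$curves[x$curves$edu == e & x$curves$sex == s, ]
      graphics::lines(cv$age, cv$predicted_raw,
                      lty = if (s == "male") 2 else 1, lwd = 2)
    }
  }
  invisible(x)
}
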