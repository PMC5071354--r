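test_that("a noiseless single-study age model is interpolated exactly", {
  tab <- data.frame(study = "s1", age = seq(20, 90, length.out = 50),
                    sex = factor("female", c("female", "male")), edu = 4L)
  tab$score <- 2 - 0.1 * tab$age
  fit <- fit_multilevel(tab, "age")
  expect_false(fit$multilevel)
  expect_equal(unname(fit$coefficients[["age"]]), -0.1, tolerance = 1e-10)
  expect_equal(fit$sigma_study, 0)
})

test_that("a single-study multilevel fit equals ordinary least squares", {
  tab <- make_linear_table(n = 300, n_studies = 1, sigma = 2, seed = 8)
  fit <- fit_multilevel(tab)
  ols <- lm(score ~ age + sex + edu, data = tab)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(fit$aic, AIC(ols))
})

test_that("multi-study fits recover generator betas and the study SD", {
  cfg <- generator_config(n_studies = 20, n_per_study = 200, lambda_true = 1,
                          seed = 14)
  sim <- simulate_studies(cfg)
  tab <- assemble_variable(sim$datasets, "score")
  fit <- fit_multilevel(tab)
  expect_true(fit$multilevel)
  est <- fit$coefficients
  se <- sqrt(diag(as.matrix(vcov(fit$fit))))
  truth <- c(cfg$intercept, cfg$beta_age, cfg$beta_sex, cfg$beta_edu)
  expect_true(all(abs(est - truth) < 3 * se))
  expect_equal(fit$sigma_study, cfg$sigma_study, tolerance = 0.3)
})

test_that("with no fixed effects the balanced-design intercept is the grand mean", {
  set.seed(5)
  tab <- data.frame(study = rep(sprintf("s%d", 1:8), each = 50))
  u <- rnorm(8, 0, 2)
  tab$score <- 10 + u[as.integer(factor(tab$study))] + rnorm(400, 0, 3)
  tab$age <- runif(400, 20, 90)
  tab$sex <- factor("female", c("female", "male"))
  tab$edu <- 4L
  fit <- fit_multilevel(tab, character(0))
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), mean(tab$score),
               tolerance = 1e-8)
})

test_that("a constant demographic is reported as a singular design", {
  tab <- make_linear_table(n = 100, seed = 2)
  tab$edu <- 4L
  expect_error(fit_multilevel(tab), "edu")
})

test_that("backward selection never ends above the full model's AIC", {
  sim <- simulate_studies(generator_config(n_studies = 5, n_per_study = 150,
                                           seed = 25))
  tab <- assemble_variable(sim$datasets, "score")
  full <- fit_multilevel(tab)
  sel <- backward_aic(tab)
  expect_lte(sel$fit$aic, full$aic)
  expect_equal(sel$trace$aic[1], full$aic)
  expect_true(all(diff(sel$trace$aic) < 0))
})

test_that("greedy backward agrees with the exhaustive all-subsets oracle", {
  subsets <- list(character(0), "age", "sex", "edu", c("age", "sex"),
                  c("age", "edu"), c("sex", "edu"), c("age", "sex", "edu"))
  agree <- 0
  for (r in 1:12) {
    sim <- simulate_studies(generator_config(
      n_studies = 4, n_per_study = 100,
      beta_age = runif(1, -0.1, 0), beta_sex = runif(1, -0.6, 0),
      beta_edu = runif(1, 0, 0.6), seed = 1000 + r))
    tab <- assemble_variable(sim$datasets, "score")
    sel <- backward_aic(tab)
    aics <- vapply(subsets, function(s) {
      rhs <- if (length(s)) paste(s, collapse = " + ") else "1"
      f <- as.formula(paste("score ~", rhs, "+ (1 | study)"))
      AIC(suppressMessages(lme4::lmer(f, tab, REML = FALSE)))
    }, numeric(1))
    best <- subsets[[which.min(aics)]]
    # greedy may legitimately stop off the global optimum, but not often
    if (identical(sort(sel$spec$included_effects), sort(best))) {
      agree <- agree + 1
      expect_equal(sel$fit$aic, min(aics), tolerance = 1e-6)
    }
  }
  expect_gte(agree, 10)
})

test_that("three strong effects are all retained", {
  sim <- simulate_studies(generator_config(
    n_studies = 10, n_per_study = 200, beta_age = -0.09, beta_sex = -0.8,
    beta_edu = 0.8, seed = 77))
  tab <- assemble_variable(sim$datasets, "score")
  sel <- backward_aic(tab)
  expect_setequal(sel$spec$included_effects, c("age", "sex", "edu"))
})
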