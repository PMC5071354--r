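test_that("identity parameters leave scores untouched", {
  p <- transform_params(lambda = 1, offset = 0, z_mean = 0, z_sd = 1)
  x <- c(0.5, 3, 12)
  expect_equal(apply_power(x, p), x)
  expect_equal(back_transform(x, p), x)
})

test_that("a negative power flips sign to restore score order", {
  p <- transform_params(lambda = -1)
  expect_true(p$sign_flip)
  expect_equal(apply_power(c(1, 2, 4), p), c(-1, -0.5, -0.25))
})

test_that("the transform is strictly order-preserving for any nonzero power", {
  set.seed(3)
  for (i in 1:50) {
    lam <- runif(1, -3, 3)
    if (abs(lam) < 0.05) lam <- 0.05
    off <- runif(1, 0, 5)
    p <- transform_params(lam, offset = off, z_mean = runif(1, -2, 2),
                          z_sd = runif(1, 0.2, 3))
    x <- sort(runif(20, 0.1, 30))
    z <- apply_power(x, p)
    expect_true(all(diff(z) > 0))
  }
})

test_that("non-positive shifted scores are rejected as a stale offset", {
  p <- transform_params(0.5, offset = 0)
  expect_error(apply_power(c(2, -1), p), "offset")
})

test_that("back_transform inverts apply_power to high precision", {
  set.seed(9)
  for (lam in c(0.5, 0.75, 1.3, -0.6, -2)) {
    p <- transform_params(lam, offset = 1.5, z_mean = 0.7, z_sd = 2.2)
    x <- runif(200, 0.2, 40)
    expect_equal(back_transform(apply_power(x, p), p), x, tolerance = 1e-10)
    # monotone inverse
    z <- sort(apply_power(x, p))
    expect_true(all(diff(back_transform(z, p)) > 0))
  }
})

test_that("the search standardizes the winning transform to mean 0, sd 1", {
  sim <- simulate_studies(generator_config(n_studies = 4, n_per_study = 200,
                                           lambda_true = 0.75, seed = 41))
  tab <- assemble_variable(sim$datasets, "score")
  p <- quiet_search(tab, step = 0.01, coarse_step = 0.05)
  z <- apply_power(tab$score, p)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("the positivity offset generalizes the add-just-over-the-minimum rule", {
  sim <- simulate_studies(generator_config(n_studies = 3, n_per_study = 150,
                                           lambda_true = 1, offset_true = 15,
                                           seed = 43))
  tab <- assemble_variable(sim$datasets, "score")
  expect_lt(min(tab$score), 0)
  p <- quiet_search(tab, step = 0.01, coarse_step = 0.05)
  expect_equal(p$offset, abs(min(tab$score)) + 0.001)
  # all-positive scores need no offset
  sim2 <- simulate_studies(generator_config(n_studies = 3, n_per_study = 150,
                                            lambda_true = 0.75, seed = 44))
  tab2 <- assemble_variable(sim2$datasets, "score")
  p2 <- quiet_search(tab2, step = 0.01, coarse_step = 0.05)
  expect_equal(p2$offset, 0)
})

test_that("profile search matches the classic Box-Cox oracle without covariates", {
  skip_if_not_installed("MASS")
  set.seed(15)
  y <- (rnorm(2000, 10, 2))^2          # true power 0.5
  tab <- data.frame(study = "s1", age = 50, sex = factor("female"), edu = 4L,
                    score = y)
  p <- quiet_search(tab, effects = character(0), grid = c(-2, 2), step = 0.001)
  bc <- MASS::boxcox(y ~ 1, lambda = seq(-2, 2, 0.001), plotit = FALSE)
  oracle <- bc$x[which.max(bc$y)]
  expect_equal(p$lambda, oracle, tolerance = 0.002)
})

test_that("both criteria recover the generator power on skewed data", {
  sim <- simulate_studies(generator_config(n_studies = 10, n_per_study = 400,
                                           lambda_true = 0.75, seed = 47))
  tab <- assemble_variable(sim$datasets, "score")
  p_prof <- quiet_search(tab)
  p_sf <- quiet_search(tab, criterion = "shapiro_francia",
                       step = 0.005, coarse_step = 0.05)
  expect_equal(p_prof$lambda, 0.75, tolerance = 0.1)
  expect_equal(p_sf$lambda, 0.75, tolerance = 0.15)
})

test_that("a coarse grid lands on the exact true power for identity data", {
  hits <- 0
  for (r in 1:10) {
    sim <- simulate_studies(generator_config(n_studies = 5, n_per_study = 300,
                                             lambda_true = 1, seed = 500 + r))
    tab <- assemble_variable(sim$datasets, "score")
    p <- quiet_search(tab, grid = c(0.5, 1.5), step = 0.25, coarse_step = 0.25)
    if (p$lambda == 1) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("search is invariant to study relabeling", {
  sim <- simulate_studies(generator_config(n_studies = 4, n_per_study = 150,
                                           lambda_true = 0.75, seed = 51))
  tab <- assemble_variable(sim$datasets, "score")
  relabeled <- tab
  relabeled$study <- chartr("0123", "wxyz", tab$study)
  p1 <- quiet_search(tab, step = 0.01, coarse_step = 0.05)
  p2 <- quiet_search(relabeled, step = 0.01, coarse_step = 0.05)
  expect_equal(p1$lambda, p2$lambda)
  expect_equal(p1$z_mean, p2$z_mean)
})

test_that("refit on a noiseless identity transform rescales coefficients by the raw SD", {
  tab <- make_linear_table(n = 120, n_studies = 1, sigma = 0, seed = 6)
  p <- transform_params(1, offset = 0, z_mean = mean(tab$score),
                        z_sd = sd(tab$score))
  model <- refit_transformed(tab, c("age", "sex", "edu"), p, variable = "toy")
  expect_equal(unname(model$coefficients[["age"]]), -0.05 / sd(tab$score),
               tolerance = 1e-8)
  expect_equal(unname(model$coefficients[["edu"]]), 0.5 / sd(tab$score),
               tolerance = 1e-8)
})

test_that("refit residuals on generator data are close to symmetric", {
  sim <- simulate_studies(generator_config(lambda_true = 0.75, seed = 53))
  tab <- assemble_variable(sim$datasets, "score")
  p <- quiet_search(tab)
  model <- refit_transformed(tab, c("age", "sex", "edu"), p)
  zt <- tab
  zt$score <- apply_power(tab$score, p)
  fit <- fit_multilevel(zt)
  expect_lt(abs(sample_skewness(norm_residuals(fit))), 0.1)
})

test_that("variance partition fractions behave and sum to one", {
  sim <- simulate_studies(generator_config(n_studies = 10, n_per_study = 100,
                                           sigma_study = 0, lambda_true = 1,
                                           seed = 55))
  tab <- assemble_variable(sim$datasets, "score")
  fit <- fit_multilevel(tab)
  vp <- partition_variance(fit)
  expect_equal(sum(vp), 1)
  expect_lt(vp[["between_study"]], 0.02)

  single <- make_linear_table(n = 80, n_studies = 1, sigma = 1, seed = 3)
  fit1 <- fit_multilevel(single)
  expect_error(partition_variance(fit1), "single-study")
})

test_that("diagnostic curves track the truth and order education levels", {
  tab <- make_linear_table(n = 150, n_studies = 1, sigma = 0, seed = 10)
  p <- transform_params(1, offset = 0, z_mean = mean(tab$score),
                        z_sd = sd(tab$score))
  model <- refit_transformed(tab, c("age", "sex", "edu"), p, variable = "toy")
  diag <- fit_diagnostics(model, tab, age_points = 20)
  lin <- 10 - 0.05 * diag$curves$age - 0.4 * (diag$curves$sex == "male") +
    0.5 * diag$curves$edu
  expect_equal(diag$curves$predicted_raw, lin, tolerance = 1e-6)
  e7 <- diag$curves[diag$curves$edu == 7 & diag$curves$sex == "female", ]
  e1 <- diag$curves[diag$curves$edu == 1 & diag$curves$sex == "female", ]
  if (nrow(e7) && nrow(e1)) {
    expect_true(all(e7$predicted_raw > e1$predicted_raw))
  }
  expect_true(all(diff(e7$predicted_raw) < 0))  # age declines
})
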