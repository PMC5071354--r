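# one moderately sized trained model shared across comparison tests
trained_model <- local({
  sim <- simulate_studies(generator_config(n_studies = 8, n_per_study = 250,
                                           lambda_true = 0.75, seed = 61))
  tab <- assemble_variable(sim$datasets, "score")
  suppressMessages(build_norm_model(tab, sim$truth$spec,
                                    step = 0.005, coarse_step = 0.05))
})

test_that("a score equal to the demographic expectation sits at the 50th percentile", {
  m <- trained_model
  expected_z <- m$coefficients[["(Intercept)"]] +
    m$coefficients[["age"]] * 70 + m$coefficients[["edu"]] * 5
  raw <- back_transform(expected_z, m$transform)
  res <- compare_patient(m, age = 70, sex = "female", edu = 5, score = raw)
  expect_equal(res$z_corrected, 0, tolerance = 1e-8)
  expect_equal(res$percentile, 50, tolerance = 1e-6)
})

test_that("percentile is the normal CDF of the corrected z", {
  res <- compare_patient(trained_model, age = 55, sex = "m", edu = 3, score = 8)
  expect_equal(res$percentile, 100 * pnorm(res$z_corrected))
})

test_that("equal raw scores favor the less educated patient when education helps", {
  lo <- compare_patient(trained_model, age = 60, sex = "female", edu = 1, score = 9)
  hi <- compare_patient(trained_model, age = 60, sex = "female", edu = 7, score = 9)
  expect_gt(trained_model$coefficients[["edu"]], 0)
  expect_gt(lo$z_corrected, hi$z_corrected)
})

test_that("the residual-only SD gives more extreme z than the total SD", {
  z_tot <- compare_patient(trained_model, 60, "f", 4, 6)$z_corrected
  z_res <- compare_patient(trained_model, 60, "f", 4, 6,
                           sd_type = "residual")$z_corrected
  expect_gt(abs(z_res), abs(z_tot))
  expect_equal(sign(z_res), sign(z_tot))
})

test_that("demographics outside the training range flag, never error", {
  res <- compare_patient(trained_model, age = 110, sex = "female", edu = 4,
                         score = 9)
  expect_true("extrapolated" %in% res$flags)
  expect_true(is.finite(res$percentile))
})

test_that("scores beyond the stored extreme borders warn and flag", {
  bad <- trained_model$borders[2] + 5
  expect_warning(res <- compare_patient(trained_model, 60, "f", 4, bad),
                 "borders")
  expect_true("outside_borders" %in% res$flags)
})

test_that("invalid patient demographics are rejected", {
  expect_error(compare_patient(trained_model, 60, "female", 9, 9), "1-7")
  expect_error(compare_patient(trained_model, 60, "unknown", 4, 9), "sex")
  expect_error(compare_patient(trained_model, -3, "f", 4, 9), "age")
})

test_that("norm tables are median-anchored, monotone, and continuous in age", {
  m <- trained_model
  ages <- seq(30, 80, by = 0.5)
  tab <- export_norm_table(m, ages = ages, sex = "female", edu = 5)
  expected_z <- m$coefficients[["(Intercept)"]] + m$coefficients[["age"]] * ages +
    m$coefficients[["edu"]] * 5
  expect_equal(tab$p50, back_transform(expected_z, m$transform),
               tolerance = 1e-10)
  pcols <- grep("^p", names(tab))
  for (i in seq_len(nrow(tab))) {
    expect_true(all(diff(as.numeric(tab[i, pcols])) > 0))
  }
  # halving the grid step halves the largest adjacent-age jump (no leaps)
  jump <- max(abs(diff(tab$p50)))
  tab2 <- export_norm_table(m, ages = seq(30, 80, by = 0.25), sex = "f", edu = 5)
  expect_lt(max(abs(diff(tab2$p50))), 0.6 * jump)
})

test_that("reading a percentile band off the table round-trips through scoring", {
  m <- trained_model
  tab <- export_norm_table(m, ages = 64, sex = "male", edu = 6)
  for (p in c(5, 25, 75)) {
    raw <- tab[[paste0("p", p)]]
    res <- compare_patient(m, 64, "male", 6, raw)
    expect_equal(res$percentile, p, tolerance = 1e-6)
  }
})

test_that("norm models survive a store write/read round trip byte-identically", {
  path <- withr::local_tempfile(fileext = ".json")
  write_norm_store(trained_model, path)
  store <- read_norm_store(path)
  m2 <- store$models[[1]]
  r1 <- compare_patient(trained_model, 68, "f", 5, 7)
  r2 <- compare_patient(m2, 68, "f", 5, 7)
  expect_equal(r2$z_corrected, r1$z_corrected, tolerance = 1e-10)
  expect_equal(r2$percentile, r1$percentile, tolerance = 1e-10)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_norm_store(store, path2)
  expect_identical(readLines(path2), readLines(path))
})
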