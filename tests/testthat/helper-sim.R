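# shared fixtures built in code

# small deterministic long table with known linear structure
make_linear_table <- function(n = 200, n_studies = 2, intercept = 10,
                              beta_age = -0.05, beta_sex = -0.4, beta_edu = 0.5,
                              sigma = 0, sigma_study = 0, seed = 1) {
  set.seed(seed)
  study <- rep(sprintf("s%02d", seq_len(n_studies)), length.out = n)
  age <- runif(n, 17, 95)
  sex <- factor(ifelse(runif(n) < 0.5, "male", "female"),
                levels = c("female", "male"))
  edu <- sample(1:7, n, replace = TRUE)
  u <- rnorm(n_studies, 0, sigma_study)
  names(u) <- sprintf("s%02d", seq_len(n_studies))
  score <- intercept + beta_age * age + beta_sex * (sex == "male") +
    beta_edu * edu + u[study] + rnorm(n, 0, sigma)
  data.frame(study = study, age = age, sex = sex, edu = edu, score = score,
             stringsAsFactors = FALSE)
}

# write a list of study data frames to a temp dir of CSVs
write_temp_studies <- function(datasets) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_study_files(datasets, dir)
  list.files(dir, pattern = "\\.csv$", full.names = TRUE)
}

sample_skewness <- function(x) {
  z <- (x - mean(x)) / sd(x)
  mean(z^3)
}

quiet_search <- function(...) suppressMessages(search_lambda(...))
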