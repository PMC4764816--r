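# small covariate design for model tests: a handful of smooth predictors
make_design <- function(n, seed = 1, p = 6) {
  set.seed(seed)
  tbl <- tibble::as_tibble(stats::setNames(
    purrr::map(seq_len(p), ~ runif(n, -1, 1)),
    paste0("cov", seq_len(p))
  ))
  tbl
}

test_that("the classifier separates a threshold rule and matches a permutation null", {
  tbl <- make_design(200, seed = 2)
  tbl$has_mattic <- tbl$cov1 > 0.2
  cfg <- rf_config(ntree = 500, mtry_class = 2, seed = 9)
  fit <- train_mattic_classifier(tbl, cfg, covariates = paste0("cov", 1:6))
  expect_lt(fit$oob, 0.05)

  # permuted labels: OOB error near the class-imbalance baseline
  set.seed(3)
  tbl$has_mattic <- sample(tbl$has_mattic)
  null_fit <- train_mattic_classifier(tbl, cfg, covariates = paste0("cov", 1:6))
  baseline <- min(mean(tbl$has_mattic), 1 - mean(tbl$has_mattic))
  expect_lt(abs(null_fit$oob - baseline), 0.1)

  one_class <- dplyr::mutate(tbl, has_mattic = TRUE)
  expect_error(train_mattic_classifier(one_class, cfg, paste0("cov", 1:6)), "single class")
})

test_that("regressors learn exact signals and plateau at noise for uninformative ones", {
  tbl <- make_design(500, seed = 4)
  cfg <- rf_config(ntree = 500, mtry_reg = 3, seed = 11)

  # target an exact monotone function of one covariate (positive for the log)
  tbl$target <- exp(1 + 2 * tbl$cov1)
  fit <- train_param_regressor(tbl, "target", cfg, covariates = paste0("cov", 1:6))
  expect_lt(fit$oob, 0.05 * stats::var(log(tbl$target)))

  # target independent of all covariates: OOB MSE ~ population variance
  set.seed(12)
  tbl$noisey <- exp(rnorm(500, 0, 0.5))
  fit0 <- train_param_regressor(tbl, "noisey", cfg, covariates = paste0("cov", 1:6))
  expect_lt(abs(fit0$oob - stats::var(log(tbl$noisey))) / stats::var(log(tbl$noisey)), 0.15)

  # constant target: OOB MSE ~ 0
  tbl$flat <- 5
  fitc <- train_param_regressor(tbl, "flat", cfg, covariates = paste0("cov", 1:6))
  expect_lt(fitc$oob, 1e-12)

  tbl$bad <- tbl$target
  tbl$bad[7] <- 0
  expect_error(train_param_regressor(tbl, "bad", cfg, paste0("cov", 1:6)), "non-positive")
})

test_that("repeated OOB runs give valid order statistics and zero SD when degenerate", {
  tbl <- make_design(80, seed = 6)
  tbl$has_mattic <- tbl$cov1 + 0.3 * rnorm(80) > 0
  cfg <- rf_config(ntree = 200, n_runs = 8, seed = 21)
  summ <- repeat_oob(function(d, c) train_mattic_classifier(d, c, paste0("cov", 1:6)), tbl, cfg)
  expect_true(summ$min <= summ$q1 && summ$q1 <= summ$median)
  expect_true(summ$median <= summ$q3 && summ$q3 <= summ$max)
  expect_true(summ$min <= summ$mean && summ$mean <= summ$max)
  expect_gte(summ$sd, 0)

  # a trainer pinned to one seed has zero spread
  pinned <- function(d, c) {
    c$seed <- 1L
    train_mattic_classifier(d, c, paste0("cov", 1:6))
  }
  summ0 <- repeat_oob(pinned, tbl, rf_config(ntree = 200, n_runs = 4, seed = 5))
  expect_equal(summ0$sd, 0)
  expect_error(repeat_oob(pinned, tbl, rf_config(n_runs = 1)), "n_runs")
})

test_that("permutation importance ranks generative covariates above pure noise", {
  wins <- 0L
  for (s in 1:20) {
    tbl <- make_design(150, seed = 100 + s, p = 3)
    set.seed(200 + s)
    tbl$noise_cov <- runif(150, -1, 1)
    tbl$target <- exp(0.5 + 1.5 * tbl$cov1 + rnorm(150, 0, 0.2))
    fit <- train_param_regressor(tbl, "target", rf_config(ntree = 300, seed = s),
      covariates = c("cov1", "cov2", "cov3", "noise_cov")
    )
    imp <- variable_importance(fit)
    if (imp$covariate[1] == "cov1") wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("importance of uninformative covariates is indistinguishable from zero", {
  tbl <- make_design(200, seed = 31)
  set.seed(32)
  tbl$target <- exp(rnorm(200, 0, 0.5))
  fit <- train_param_regressor(tbl, "target", rf_config(ntree = 500, seed = 33),
    covariates = paste0("cov", 1:6)
  )
  imp <- variable_importance(fit)
  # all importances tiny relative to the target variance
  expect_lt(max(abs(imp$importance)), 0.15 * stats::var(log(tbl$target)))
})

test_that("parameter prediction back-transforms positively and flags nodata rows", {
  sc <- small_scenario(seed = 21, n_rows = 40, n_cols = 40, n_cal = 60)
  fits <- fit_depth_functions(sc$calibration)
  cov_tbl <- extract_at_points(sc$stack, pedon_sites(sc$calibration))
  training <- dplyr::inner_join(
    dplyr::select(fits, site_id, has_mattic, d_mat_m, c_a_kg_m3, k_per_m),
    cov_tbl,
    by = "site_id"
  )
  models <- train_model_set(training, rf_config(ntree = 300, seed = 2))

  pred <- predict_parameters(models, training)
  expect_true(all(pred$c_a_kg_m3 > 0 & pred$k_per_m > 0))
  expect_true(all(pred$d_mat_m[!pred$has_mattic] == 0))
  # in-bag memorization: training rows are recovered well on the log scale
  expect_gt(stats::cor(log(pred$c_a_kg_m3), log(training$c_a_kg_m3)), 0.9)

  holey <- training
  holey$NDVI[2] <- NA
  pred2 <- predict_parameters(models, holey)
  expect_true(pred2$nodata[2])
  expect_true(is.na(pred2$c_a_kg_m3[2]))
  expect_error(predict_parameters(models, training[setdiff(names(training), "NDVI")]), "NDVI")
})

test_that("training and prediction are bit-reproducible and order-invariant", {
  sc <- small_scenario(seed = 22, n_rows = 40, n_cols = 40, n_cal = 60)
  fits <- fit_depth_functions(sc$calibration)
  cov_tbl <- extract_at_points(sc$stack, pedon_sites(sc$calibration))
  training <- dplyr::inner_join(
    dplyr::select(fits, site_id, has_mattic, d_mat_m, c_a_kg_m3, k_per_m),
    cov_tbl,
    by = "site_id"
  )
  cfg <- rf_config(ntree = 200, seed = 17)
  m1 <- train_model_set(training, cfg)
  m2 <- train_model_set(training, cfg)
  p1 <- predict_parameters(m1, cov_tbl)
  p2 <- predict_parameters(m2, cov_tbl)
  expect_identical(p1, p2)

  # OOB statistic invariant to row order of the training table (same seed
  # reshuffles rows, so compare distributional summaries over repeats)
  set.seed(1)
  shuffled <- training[sample(nrow(training)), ]
  s1 <- repeat_oob(
    function(d, c) train_param_regressor(d, "c_a_kg_m3", c, m1$covariates),
    training, rf_config(ntree = 200, n_runs = 6, seed = 3)
  )
  s2 <- repeat_oob(
    function(d, c) train_param_regressor(d, "c_a_kg_m3", c, m1$covariates),
    shuffled, rf_config(ntree = 200, n_runs = 6, seed = 3)
  )
  expect_lt(abs(s1$mean - s2$mean) / s1$mean, 0.5)
})

test_that("a model set persists to disk and predicts identically after reload", {
  sc <- small_scenario(seed = 23, n_rows = 40, n_cols = 40, n_cal = 60)
  fits <- fit_depth_functions(sc$calibration)
  cov_tbl <- extract_at_points(sc$stack, pedon_sites(sc$calibration))
  training <- dplyr::inner_join(
    dplyr::select(fits, site_id, has_mattic, d_mat_m, c_a_kg_m3, k_per_m),
    cov_tbl,
    by = "site_id"
  )
  models <- train_model_set(training, rf_config(ntree = 100, seed = 4))
  dir <- withr::local_tempdir()
  write_model_set(models, dir)
  models2 <- read_model_set(dir)
  expect_identical(
    predict_parameters(models2, cov_tbl),
    predict_parameters(models, cov_tbl)
  )
})
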