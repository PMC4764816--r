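test_that("the three indices match hand-computed values and conventions", {
  expect_equal(mean_error(c(1, 2), c(2, 4)), 1.5)
  expect_equal(mean_error(c(2, 4), c(1, 2)), -1.5) # antisymmetry: under-prediction is negative
  expect_equal(mean_error(1:5, 1:5), 0)

  expect_equal(rmse(c(1, 2), c(2, 4)), sqrt(2.5))
  expect_equal(rmse(1:4, 1:4), 0)
  set.seed(1)
  o <- rnorm(20)
  p <- rnorm(20)
  perm <- sample(20)
  expect_equal(rmse(o, p), rmse(o[perm], p[perm]))

  expect_equal(lccc(c(1, 2, 3), c(1.5, 2.5, 3.5)), 16 / 19, tolerance = 1e-12)
  expect_equal(lccc(o, o), 1)
  expect_equal(lccc(c(-1, 1), c(1, -1)), -1)
  expect_error(lccc(rep(1, 5), rep(2, 5)), "constant")
  expect_error(lccc(1, 2), "pair")
  expect_error(mean_error(numeric(0), numeric(0)), "pair")
})

test_that("index identities hold on random vectors", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    o <- rnorm(n, 10, 3)
    p <- o + rnorm(n, 0.5, 1)
    # RMSE^2 = ME^2 + population variance of the errors
    e <- p - o
    expect_equal(rmse(o, p)^2, mean_error(o, p)^2 + mean((e - mean(e))^2),
      tolerance = 1e-12
    )
    # concordance never exceeds |Pearson r|
    expect_lte(abs(lccc(o, p)), abs(cor(o, p)) + 1e-12)
    # symmetric in its arguments
    expect_equal(lccc(o, p), lccc(p, o))
  }
  # location/scale shifts away from identity strictly reduce concordance
  o <- rnorm(30)
  expect_lt(lccc(o, o + 1), 1)
  expect_lt(lccc(o, 2 * o), 1)
  expect_equal(lccc(o, o), 1)
})

test_that("internal validation compares fitted-function stocks to the map", {
  sc <- small_scenario(seed = 41, n_rows = 40, n_cols = 40, n_cal = 60)
  pl <- run_soc_pipeline(sc$calibration, sc$stack, cfg = rf_config(ntree = 300, seed = 3))
  v <- pl$internal
  expect_equal(nrow(v$pairs), 60)
  expect_equal(v$indices$me, mean(v$pairs$predicted - v$pairs$observed))
  obs1 <- integrate_stock(pl$fits$fit[[1]]$params, 0, 1)
  expect_equal(v$pairs$observed[v$pairs$site_id == pl$fits$site_id[1]], obs1)
})

test_that("independent validation sums 5-cm increments and demands full coverage", {
  sc <- small_scenario(seed = 42, n_rows = 40, n_cols = 40, n_cal = 60)
  # a perfect model: truth maps themselves
  v <- validate_independent(sc$independent, sc$pmaps, 0, 1)
  expect_equal(nrow(v$pairs), 3)
  # observed sums match the generating function's integral within noise
  truth <- dplyr::filter(sc$sites, dataset == "independent")
  true_stock <- purrr::pmap_dbl(truth, function(has_mattic, d_mat, c_a, k, ...) {
    integrate_stock(soc_params(c_a, k, has_mattic, d_mat), 0, 1)
  })
  expect_equal(v$pairs$observed, true_stock, tolerance = 0.15)
  # and prediction error against the truth map is small (noise only)
  expect_lt(v$indices$rmse, 0.15 * mean(v$pairs$observed))

  gap <- sc$independent[-3, ] # remove one increment
  expect_error(validate_independent(gap, sc$pmaps, 0, 1), "gaps")
  expect_error(validate_independent(sc$independent, sc$pmaps, 0, 0), "z_top")
})

test_that("a noise-free dense pedon reproduces its generating stock to quadrature error", {
  sc0 <- small_scenario(seed = 43, n_rows = 30, n_cols = 30, n_cal = 25, noise_cv = 0)
  v <- validate_independent(sc0$independent, sc0$pmaps, 0, 1)
  expect_lt(v$indices$rmse, 0.01 * mean(v$pairs$observed))
  expect_gt(v$indices$lccc, 0.999)
})

test_that("repeated validation summarises per dataset and index with zero SD when frozen", {
  frozen <- function(seed) {
    tibble::tibble(dataset = c("training", "independent"), me = c(-0.1, -0.5), rmse = c(1, 2), lccc = c(0.9, 0.6))
  }
  rep <- repeat_validation(frozen, n_runs = 3, seed = 1)
  expect_equal(nrow(rep), 6) # 2 datasets x 3 indices
  expect_true(all(rep$sd == 0))
  expect_true(all(rep$min <= rep$median & rep$median <= rep$max))
  expect_error(repeat_validation(frozen, n_runs = 1), "n_runs")
})

test_that("the semivariogram is flat for white noise and rising for smooth fields", {
  set.seed(7)
  n <- 120
  xy <- tibble::tibble(x = runif(n, 0, 1000), y = runif(n, 0, 1000))

  slopes_white <- replicate(20, {
    d <- dplyr::mutate(xy, residual = rnorm(n))
    v <- residual_semivariogram(d, n_bins = 8)
    coef(lm(gamma ~ lag, data = v, weights = v$n_pairs))[2]
  })
  # white residuals: mean slope not significantly greater than zero
  tstat <- mean(slopes_white) / (sd(slopes_white) / sqrt(length(slopes_white)))
  expect_lt(tstat, 2)

  # a smooth spatial field: variance grows at short lags
  d2 <- dplyr::mutate(xy, residual = sin(x / 200) + cos(y / 250))
  v2 <- residual_semivariogram(d2, n_bins = 8)
  expect_gt(mean(v2$gamma[6:8]), mean(v2$gamma[1:2]))

  # identically zero residuals: gamma = 0 in every bin
  v0 <- residual_semivariogram(dplyr::mutate(xy, residual = 0), n_bins = 6)
  expect_true(all(v0$gamma == 0))

  expect_error(residual_semivariogram(dplyr::mutate(xy[1:5, ], residual = 1)), "10")
})
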