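test_that("the depth function plateaus over the mat and decays continuously below", {
  # a typical mat-covered profile: 41.56 kg/m^3 through an 18-cm mat,
  # falling to 7.03 kg/m^3 at the 90-100 cm midpoint
  k <- log(41.56 / 7.03) / 0.77
  p <- soc_params(c_a = 41.56, k = k, has_mattic = TRUE, d_mat = 0.18)
  expect_equal(evaluate_soc(p, 0.10), 41.56)
  expect_equal(evaluate_soc(p, 0.95), 7.03, tolerance = 1e-12)

  pn <- soc_params(c_a = 22.15, k = 1.5)
  expect_equal(evaluate_soc(pn, 0), 22.15)
  expect_error(evaluate_soc(pn, -0.1), "z")

  # continuity at d_mat and monotonicity, over random draws
  set.seed(42)
  for (i in 1:50) {
    pr <- random_params()
    eps <- 1e-9
    if (pr$has_mattic) {
      expect_equal(evaluate_soc(pr, pr$d_mat), evaluate_soc(pr, pr$d_mat + eps),
        tolerance = 1e-6
      )
    }
    v <- evaluate_soc(pr, seq(0, 1.5, length.out = 400))
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("parameter validation enforces the mattic/d_mat coupling", {
  expect_error(soc_params(c_a = 10, k = 1, has_mattic = TRUE, d_mat = 0), "d_mat")
  expect_error(soc_params(c_a = 10, k = 1, has_mattic = FALSE, d_mat = 0.1), "d_mat")
  expect_error(soc_params(c_a = -1, k = 1), "c_a")
  expect_error(soc_params(c_a = 10, k = 0), "k")
})

test_that("closed-form stock integration matches quadrature and is additive", {
  p <- soc_params(c_a = 40, k = 2, has_mattic = TRUE, d_mat = 0.15)
  # hand-derived: 40*0.15 + 20*(1 - exp(-1.7))
  expect_equal(integrate_stock(p, 0, 1), 6 + 20 * (1 - exp(-1.7)), tolerance = 1e-12)
  expect_equal(integrate_stock(p, 0, 0.10), 4.0) # constant x thickness
  # enormous k: the decay segment vanishes, stock -> c_a * d_mat
  pk <- soc_params(c_a = 40, k = 1e8, has_mattic = TRUE, d_mat = 0.15)
  expect_equal(integrate_stock(pk, 0, 1), 6, tolerance = 1e-6)

  set.seed(7)
  for (i in 1:25) {
    pr <- random_params()
    expect_equal(integrate_stock(pr, 0, 1), quad_stock(pr, 0, 1, step = 1e-5),
      tolerance = 1e-8
    )
    # additivity over adjacent intervals
    a <- stats::runif(1, 0.05, 0.9)
    expect_equal(
      integrate_stock(pr, 0, a) + integrate_stock(pr, a, 1.2),
      integrate_stock(pr, 0, 1.2),
      tolerance = 1e-12
    )
  }
  expect_error(integrate_stock(p, 0.5, 0.5), "z_top")
})

test_that("profile discretization gives midpoint slices consistent with the integral", {
  p <- soc_params(c_a = 30, k = 3, has_mattic = TRUE, d_mat = 0.12)
  slices <- discretize_profile(p, dz = 0.01, z_max = 1)
  expect_length(slices, 100)
  expect_equal(slices[1:12], rep(30, 12)) # inside the mat
  # midpoint-rule sum approximates the closed form within 0.5% for moderate k
  for (k in c(0.5, 2, 5)) {
    pk <- soc_params(c_a = 30, k = k)
    expect_equal(sum(discretize_profile(pk)) * 0.01, integrate_stock(pk, 0, 1),
      tolerance = 5e-3
    )
  }
  expect_error(discretize_profile(p, dz = 0.03, z_max = 1), "multiple")
})

test_that("fitting recovers exact parameters from noiseless profiles", {
  # no-mattic and mattic cases
  for (p in list(
    soc_params(c_a = 35, k = 2.4),
    soc_params(c_a = 50, k = 1.2, has_mattic = TRUE, d_mat = 0.15)
  )) {
    ped <- as_pedon_table(make_exact_pedon(p))
    fit <- fit_depth_function(ped)
    expect_equal(fit$params$c_a, p$c_a, tolerance = 1e-6)
    expect_equal(fit$params$k, p$k, tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("the two-point fit equals the closed-form inversion", {
  # midpoints 0.1 and 0.5 m with contents 30 and 10 kg/m^3
  ped <- as_pedon_table(tibble::tibble(
    site_id = "T", lat = 0, lon = 0,
    hz_top_m = c(0.05, 0.45), hz_bottom_m = c(0.15, 0.55),
    soc_g_kg = c(30, 10), bd_g_cm3 = 1, gravel_frac = 0,
    mattic = 0, mattic_depth_m = NA_real_
  ))
  fit <- fit_depth_function(ped)
  k_exact <- log(3) / 0.4
  expect_equal(fit$params$k, k_exact, tolerance = 1e-6)
  expect_equal(fit$params$c_a, 30 * exp(k_exact * 0.1), tolerance = 1e-6)
})

test_that("degenerate profiles raise identifiability errors", {
  # all observations inside the mat: k undetermined
  p <- soc_params(c_a = 40, k = 2, has_mattic = TRUE, d_mat = 0.5)
  ped <- as_pedon_table(make_exact_pedon(p, mids = c(0.1, 0.25, 0.4)))
  expect_error(fit_depth_function(ped), "undetermined")
  # a single horizon is never enough
  one <- as_pedon_table(make_exact_pedon(soc_params(c_a = 20, k = 1), mids = 0.3))
  expect_error(fit_depth_function(one), "undetermined")
})

test_that("fits on noisy horizon data keep high explanatory power", {
  set.seed(101)
  r2 <- replicate(40, {
    p <- random_params()
    mids <- c(0.06, 0.2, 0.4, 0.65, 0.9)
    vals <- evaluate_soc(p, mids) * exp(rnorm(5, 0, 0.1))
    ped <- as_pedon_table(tibble::tibble(
      site_id = "N", lat = 0, lon = 0,
      hz_top_m = mids - 0.05, hz_bottom_m = mids + 0.05,
      soc_g_kg = vals, bd_g_cm3 = 1, gravel_frac = 0,
      mattic = as.numeric(p$has_mattic),
      mattic_depth_m = if (p$has_mattic) max(p$d_mat, 0.06) else NA_real_
    ))
    fit_depth_function(ped)$r_squared
  })
  expect_gte(mean(r2), 0.85)
})

test_that("fit tables and broom methods carry the per-site summary", {
  ped <- as_pedon_table(make_raw_pedons())
  tbl <- fit_depth_functions(ped)
  expect_equal(nrow(tbl), 3)
  expect_named(tbl, c("site_id", "has_mattic", "d_mat_m", "c_a_kg_m3", "k_per_m", "r2", "n_obs", "fit"))
  expect_true(all(tbl$c_a_kg_m3 > 0 & tbl$k_per_m > 0))
  expect_true(all(tbl$r2 <= 1))

  fit <- tbl$fit[[1]]
  td <- tidy(fit)
  expect_setequal(td$term, c("c_a", "k", "d_mat", "has_mattic"))
  expect_equal(glance(fit)$r2, fit$r_squared)
})

test_that("parameters round-trip through JSON", {
  p <- soc_params(c_a = 41.56, k = 2.3066, has_mattic = TRUE, d_mat = 0.18)
  q <- params_from_json(params_to_json(p))
  expect_equal(q, p)
})
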