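#' Configuration of the synthetic study area
#'
#' Defines the simulated landscape and sampling campaign used to exercise
#' the full pipeline: a 200 x 200 grid of 90-m cells (a ~324 km^2 alpine
#' catchment), 96 calibration pedons sampled by genetic horizons and 3
#' independent pedons sampled at a contiguous 5-cm interval — mirroring a
#' typical regional survey where mat-bearing alpine meadows cover roughly
#' 40% of sites.
#'
#' Latent structure (standardized covariates written `z()`):
#' * `P(mattic) = plogis(beta0 + beta1 z(NDVI) + beta2 z(MAT))` — the mat
#'   forms under productive, cold meadow.
#' * `log d_mat = gamma0 + gamma1 z(NDVI) + N(0, gamma_sd)`, clamped to
#'   0.06-0.30 m (mean ~0.15 m).
#' * `log c_a = delta0 + delta1 z(NDVI) + delta2 z(elevation) + N(0,
#'   delta_sd)`, clamped to 5-100 kg/m^3; the defaults put mat-covered
#'   meadow near 30-40 kg/m^3 and sparse steppe near 10-15 kg/m^3.
#' * `log k = eta0 + eta1 z(MAT) + N(0, eta_sd)` — decay near 2 1/m,
#'   slightly faster under warmer regimes.
#'
#' Horizon SOC observations are the *average* of the true function over the
#' horizon (its integral divided by thickness) times multiplicative
#' mean-one lognormal noise with coefficient of variation `noise_cv`;
#' fitting at horizon midpoints therefore faces a small, realistic
#' model discrepancy rather than a tautology.
#'
#' @param n_rows,n_cols,cell_size Grid shape (default 200 x 200 at 90 m).
#' @param n_calibration,n_independent Pedon counts (96 / 3).
#' @param beta Length-3 logit coefficients (intercept, z(NDVI), z(MAT)).
#' @param gamma,gamma_sd Log mattic-depth link (intercept, z(NDVI)) and
#'   noise SD.
#' @param delta,delta_sd Log `c_a` link (intercept, z(NDVI), z(elevation))
#'   and noise SD.
#' @param eta,eta_sd Log `k` link (intercept, z(MAT)) and noise SD.
#' @param noise_cv CV of the multiplicative lognormal measurement noise.
#' @param horizon_n_range Range of genetic-horizon counts per calibration
#'   pedon.
#' @param smooth_sigma Gaussian smoothing radius of the random fields, in
#'   pixels.
#' @param mattic_flag_error Probability that a sampled pedon's field mattic
#'   flag is recorded wrongly (0: field identification treated as ground
#'   truth).
#' @param seed Master seed; every random draw descends from it.
#' @return An object of class `soc_sim_config`.
#' @export
sim_config <- function(n_rows = 200, n_cols = 200, cell_size = 90,
                       n_calibration = 96, n_independent = 3,
                       beta = c(-0.4, 1.5, -1.5),
                       gamma = c(log(0.15), 0.25), gamma_sd = 0.10,
                       delta = c(log(18), 0.45, -0.10), delta_sd = 0.15,
                       eta = c(log(2), 0.20), eta_sd = 0.15,
                       noise_cv = 0.10,
                       horizon_n_range = c(4L, 6L),
                       smooth_sigma = 12,
                       mattic_flag_error = 0,
                       seed = 1) {
  stopifnot(
    length(beta) == 3, length(gamma) == 2, length(delta) == 3, length(eta) == 2,
    gamma_sd >= 0, delta_sd >= 0, eta_sd >= 0, noise_cv >= 0,
    mattic_flag_error >= 0, mattic_flag_error <= 1
  )
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols), cell_size = cell_size,
      n_calibration = as.integer(n_calibration), n_independent = as.integer(n_independent),
      beta = beta, gamma = gamma, gamma_sd = gamma_sd,
      delta = delta, delta_sd = delta_sd, eta = eta, eta_sd = eta_sd,
      noise_cv = noise_cv, horizon_n_range = as.integer(horizon_n_range),
      smooth_sigma = smooth_sigma, mattic_flag_error = mattic_flag_error,
      seed = as.integer(seed)
    ),
    class = "soc_sim_config"
  )
}

# sub-seed derivation: distinct, reproducible streams per generator stage,
# kept well below 2^31
derive_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stage)
}

# standardized smooth Gaussian random field: white noise convolved with a
# separable Gaussian kernel (reflection padding), then centered and scaled
smooth_gaussian_field <- function(n_rows, n_cols, sigma) {
  w <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (sigma > 0) {
    half <- max(1L, as.integer(ceiling(3 * sigma)))
    kern <- stats::dnorm(-half:half, sd = sigma)
    kern <- kern / sum(kern)
    pad_conv <- function(v) {
      n <- length(v)
      idx <- c(rev(seq_len(half)), seq_len(n), n + 1 - seq_len(half)) # reflect
      vp <- v[pmin(pmax(idx, 1), n)]
      stats::convolve(vp, rev(kern), type = "filter")
    }
    w <- apply(w, 2, pad_conv)
    w <- t(apply(w, 1, pad_conv))
  }
  (w - mean(w)) / stats::sd(w)
}

std_layer <- function(m) (m - mean(m, na.rm = TRUE)) / stats::sd(m, na.rm = TRUE)

#' Simulate an environmental covariate stack
#'
#' Generates the 18 standard covariate layers as spatially smooth seeded
#' random fields with the field's characteristic dependencies: temperature
#' follows an elevation lapse (MAT-elevation correlation strongly
#' negative), precipitation declines with elevation, NDVI is an independent
#' smooth vegetation field, and the red/NIR bands are back-solved so
#' [compute_ndvi()] reproduces the NDVI layer exactly. Terrain derivatives
#' are independent smooth fields on plausible scales; `Lat`/`Lon` come from
#' the grid.
#'
#' @param cfg A [sim_config()].
#' @return A [covariate_stack()].
#' @export
simulate_covariates <- function(cfg) {
  stopifnot(inherits(cfg, "soc_sim_config"))
  g <- grid_def(cfg$n_rows, cfg$n_cols,
    x_origin = 0, y_origin = cfg$n_rows * cfg$cell_size,
    cell_size = cfg$cell_size, crs = "synthetic-local-m"
  )
  set.seed(derive_seed(cfg$seed, 1L))
  f <- function() smooth_gaussian_field(cfg$n_rows, cfg$n_cols, cfg$smooth_sigma)

  # draw order is fixed and documented: changing it changes every stream
  f_elev <- f(); f_mat <- f(); f_map <- f(); f_ndvi <- f(); f_bsum <- f(); f_b5 <- f()
  f_aspect <- f(); f_slope <- f(); f_sl <- f(); f_plan <- f(); f_prof <- f()
  f_ca <- f(); f_twi <- f(); f_mrvbf <- f(); f_vd <- f()

  elevation <- 3100 + 500 * f_elev
  MAT <- 17.5 - 0.006 * elevation + 0.5 * f_mat
  MAP <- pmax(760 - 0.15 * elevation + 30 * f_map, 10)
  NDVI <- pmin(pmax(0.35 + 0.25 * f_ndvi, -1), 1)
  b_sum <- pmax(0.4 + 0.08 * f_bsum, 0.05)
  B4 <- b_sum * (1 + NDVI) / 2
  B3 <- b_sum - B4
  B5 <- pmax(0.25 + 0.07 * f_b5, 0)
  aspect <- fold_aspect(359.999 * stats::pnorm(f_aspect))
  slope <- pmax(8 + 6 * f_slope, 0)
  SL <- exp(3 + 0.8 * f_sl)
  Plan_cur <- 0.01 * f_plan
  Prof_cur <- 0.01 * f_prof
  CA <- exp(10 + 1.5 * f_ca)
  TWI <- 8 + 2 * f_twi
  MrVBF <- pmax(2.5 + 1.8 * f_mrvbf, 0)
  VD <- pmax(60 + 40 * f_vd, 0)
  coords <- make_coordinate_layers(g)

  covariate_stack(g, list(
    elevation = elevation, aspect = aspect, slope = slope, SL = SL,
    Plan_cur = Plan_cur, Prof_cur = Prof_cur, CA = CA, TWI = TWI,
    MrVBF = MrVBF, VD = VD, MAT = MAT, MAP = MAP,
    B3 = B3, B4 = B4, B5 = B5, NDVI = NDVI,
    Lat = coords$Lat, Lon = coords$Lon
  ))
}

#' Simulate the latent depth-function parameter fields
#'
#' Draws the true per-pixel parameters from the link functions documented
#' in [sim_config()]: Bernoulli mattic occurrence from a logistic link on
#' standardized NDVI and MAT, and lognormal fields for `d_mat`, `c_a` and
#' `k` with smooth means and pixelwise noise.
#'
#' @param stack A [simulate_covariates()] stack.
#' @param cfg The same [sim_config()].
#' @return List: `pmaps` (true [parameter_maps()]), `prob` (matrix of
#'   mattic probabilities).
#' @export
simulate_parameter_fields <- function(stack, cfg) {
  stopifnot(inherits(stack, "soc_stack"), inherits(cfg, "soc_sim_config"))
  set.seed(derive_seed(cfg$seed, 2L))
  z_ndvi <- std_layer(stack$layers$NDVI)
  z_mat <- std_layer(stack$layers$MAT)
  z_elev <- std_layer(stack$layers$elevation)
  nr <- stack$grid$n_rows
  nc <- stack$grid$n_cols

  prob <- stats::plogis(cfg$beta[1] + cfg$beta[2] * z_ndvi + cfg$beta[3] * z_mat)
  has_mattic <- matrix(stats::runif(nr * nc) < prob, nr, nc)

  d_mat <- exp(cfg$gamma[1] + cfg$gamma[2] * z_ndvi + stats::rnorm(nr * nc, 0, cfg$gamma_sd))
  d_mat <- pmin(pmax(d_mat, 0.06), 0.30)
  d_mat[!has_mattic] <- 0

  c_a <- exp(cfg$delta[1] + cfg$delta[2] * z_ndvi + cfg$delta[3] * z_elev +
    stats::rnorm(nr * nc, 0, cfg$delta_sd))
  c_a <- pmin(pmax(c_a, 5), 100)

  k <- exp(cfg$eta[1] + cfg$eta[2] * z_mat + stats::rnorm(nr * nc, 0, cfg$eta_sd))

  list(
    pmaps = parameter_maps(stack$grid,
      has_mattic = has_mattic, d_mat = d_mat, c_a = c_a, k = k, p_mattic = prob
    ),
    prob = prob
  )
}

# horizon boundaries for one calibration pedon: first horizon is the mat
# (or a thin A horizon), remaining thicknesses scaled to reach max_depth
draw_horizons <- function(has_mattic, d_mat, n_h, max_depth) {
  h1 <- if (has_mattic) d_mat else min(max(stats::rnorm(1, 0.12, 0.03), 0.05), 0.25)
  rest <- pmin(pmax(stats::rnorm(n_h - 1, 0.25, 0.07), 0.10), 0.45)
  rest <- rest * (max_depth - h1) / sum(rest)
  cumsum(c(0, h1, rest))
}

#' Sample synthetic pedons from the truth fields
#'
#' Draws site locations uniformly over valid pixels without replacement,
#' then builds (a) calibration pedons with 4-6 genetic horizons down to
#' ~1.0-1.2 m whose SOC is the horizon-average of the true depth function
#' under multiplicative lognormal noise, and (b) independent pedons with
#' contiguous 5-cm increments to 1 m under the same noise. Bulk density and
#' gravel increase with depth; SOC mass content is back-computed so that
#' the mass-to-volume conversion reproduces the noisy volumetric value.
#' Mattic flag and depth are copied from the truth (with optional flag
#' error).
#'
#' @param pmaps True [parameter_maps()].
#' @param stack The covariate stack (for the grid and masking).
#' @param cfg The [sim_config()].
#' @return List: `calibration` and `independent` (validated pedon tibbles),
#'   `sites` (manifest tibble: `site_id`, `dataset`, `row`, `col`, `x`,
#'   `y`, true `has_mattic`, `d_mat`, `c_a`, `k`).
#' @export
sample_pedons <- function(pmaps, stack, cfg) {
  stopifnot(inherits(pmaps, "soc_parameter_maps"), inherits(cfg, "soc_sim_config"))
  set.seed(derive_seed(cfg$seed, 3L))
  valid <- which(!pmaps$mask)
  n_total <- cfg$n_calibration + cfg$n_independent
  if (n_total > length(valid)) stop("more sites requested than valid pixels", call. = FALSE)
  cells <- sample(valid, n_total)
  rc <- arrayInd(cells, dim(pmaps$mask))
  xy <- xy_from_cell(pmaps$grid, rc[, 1], rc[, 2])

  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  noise <- function(n) if (cfg$noise_cv == 0) rep(1, n) else exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))

  sites <- tibble::tibble(
    site_id = sprintf("S%03d", seq_len(n_total)),
    dataset = rep(c("calibration", "independent"), c(cfg$n_calibration, cfg$n_independent)),
    row = rc[, 1], col = rc[, 2], x = xy$x, y = xy$y,
    has_mattic = pmaps$has_mattic[cells],
    d_mat = pmaps$d_mat[cells], c_a = pmaps$c_a[cells], k = pmaps$k[cells]
  )
  if (cfg$mattic_flag_error > 0) {
    flip <- stats::runif(n_total) < cfg$mattic_flag_error
    sites$flag_mattic <- xor(sites$has_mattic, flip)
  } else {
    sites$flag_mattic <- sites$has_mattic
  }

  build <- function(i, dense) {
    s <- sites[i, ]
    true <- soc_params(
      c_a = s$c_a, k = s$k,
      has_mattic = s$has_mattic, d_mat = s$d_mat
    )
    if (dense) {
      bounds <- seq(0, 1, by = 0.05)
    } else {
      n_h <- sample(seq(cfg$horizon_n_range[1], cfg$horizon_n_range[2]), 1)
      max_depth <- stats::runif(1, 1.0, 1.2)
      bounds <- draw_horizons(s$flag_mattic, if (s$flag_mattic) max(s$d_mat, 0.06) else 0, n_h, max_depth)
    }
    top <- bounds[-length(bounds)]
    bottom <- bounds[-1]
    mid <- (top + bottom) / 2
    avg <- stock_closed_form(true$c_a, true$k, true$d_mat, top, bottom) / (bottom - top)
    soc_vol <- avg * noise(length(mid))
    gravel <- pmin(0.6, pmax(0, 0.05 + 0.15 * mid + 0.05 * stats::rnorm(length(mid))))
    bd <- pmin(pmax(0.6 + 0.6 * mid + stats::rnorm(length(mid), 0, 0.05), 0.4), 1.6)
    tibble::tibble(
      site_id = s$site_id, lat = s$y, lon = s$x,
      hz_top_m = top, hz_bottom_m = bottom,
      soc_g_kg = soc_vol / (bd * (1 - gravel)),
      bd_g_cm3 = bd, gravel_frac = gravel,
      mattic = as.numeric(s$flag_mattic),
      mattic_depth_m = if (s$flag_mattic) max(s$d_mat, 0.06) else NA_real_
    )
  }

  cal <- purrr::map_dfr(which(sites$dataset == "calibration"), build, dense = FALSE)
  ind <- purrr::map_dfr(which(sites$dataset == "independent"), build, dense = TRUE)
  list(
    calibration = as_pedon_table(cal),
    independent = as_pedon_table(ind),
    sites = sites
  )
}

#' Simulate a complete synthetic scenario
#'
#' Runs the three generator stages under one master seed and bundles
#' covariates, truth fields, sampled pedons and analytic truth summaries.
#' Regenerating with the same configuration reproduces the bundle
#' bit-exactly.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `soc_truth_bundle`: `cfg`, `stack`, `pmaps`
#'   (truth), `prob`, `calibration`, `independent`, `sites`, `truth`
#'   ([truth_summary()] output).
#' @export
simulate_soc_scenario <- function(cfg = sim_config()) {
  stack <- simulate_covariates(cfg)
  fields <- simulate_parameter_fields(stack, cfg)
  ped <- sample_pedons(fields$pmaps, stack, cfg)
  bundle <- structure(
    list(
      cfg = cfg, stack = stack, pmaps = fields$pmaps, prob = fields$prob,
      calibration = ped$calibration, independent = ped$independent,
      sites = ped$sites
    ),
    class = "soc_truth_bundle"
  )
  bundle$truth <- truth_summary(bundle)
  bundle
}

#' Analytic truth summary of a synthetic scenario
#'
#' Applies the mapping operations to the *true* parameter fields: stock maps
#' and the layer report for the standard layers (mattic, 0-30, 0-50,
#' 0-100 cm), the total 0-100 cm stock and the mattic area. These are the
#' recovery targets against which the fitted pipeline is judged.
#'
#' @param bundle A `soc_truth_bundle` (or any list with `pmaps`).
#' @return List: `report` (layer tibble as [relative_stock_report()]),
#'   `total_Tg_0_100`, `mean_kg_m2_0_100`, `mattic_area_km2`.
#' @export
truth_summary <- function(bundle) {
  pmaps <- bundle$pmaps
  ref <- map_stock(pmaps, 0, 1)
  smaps <- list(
    map_stock(pmaps, layer = "mattic"),
    map_stock(pmaps, 0, 0.3),
    map_stock(pmaps, 0, 0.5),
    ref
  )
  report <- relative_stock_report(smaps, ref)
  tot <- total_stock(ref)
  list(
    report = report,
    total_Tg_0_100 = tot$total_Tg,
    mean_kg_m2_0_100 = tot$mean_kg_m2,
    mattic_area_km2 = mattic_area(pmaps)
  )
}
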