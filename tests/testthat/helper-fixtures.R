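# shared fixtures: built in code at test time

# a small raw pedon table: two ordinary profiles, one mattic profile
make_raw_pedons <- function() {
  tibble::tribble(
    ~site_id, ~lat, ~lon, ~hz_top_m, ~hz_bottom_m, ~soc_g_kg, ~bd_g_cm3, ~gravel_frac, ~mattic, ~mattic_depth_m,
    "P1", 100, 200, 0.00, 0.15, 30, 0.9, 0.00, 0, NA,
    "P1", 100, 200, 0.15, 0.40, 18, 1.1, 0.05, 0, NA,
    "P1", 100, 200, 0.40, 0.80, 8, 1.3, 0.10, 0, NA,
    "P1", 100, 200, 0.80, 1.10, 4, 1.4, 0.20, 0, NA,
    "P2", 300, 400, 0.00, 0.12, 25, NA, 0.00, 0, NA,
    "P2", 300, 400, 0.12, 0.50, 12, NA, 0.02, 0, NA,
    "P2", 300, 400, 0.50, 1.00, 5, NA, 0.10, 0, NA,
    "M1", 500, 600, 0.00, 0.18, 45, 0.8, 0.00, 1, 0.18,
    "M1", 500, 600, 0.18, 0.45, 22, 1.0, 0.02, 1, 0.18,
    "M1", 500, 600, 0.45, 0.80, 10, 1.2, 0.05, 1, 0.18,
    "M1", 500, 600, 0.80, 1.15, 5, 1.3, 0.10, 1, 0.18
  )
}

# exact noiseless pedon generated from known parameters, horizons located so
# that midpoint values equal the function exactly (bd = 1, gravel = 0 keeps
# soc_g_kg == soc_kg_m3)
make_exact_pedon <- function(params, mids = c(0.05, 0.2, 0.4, 0.7, 0.95),
                             site_id = "X1", half = 0.05) {
  vals <- evaluate_soc(params, mids)
  tibble::tibble(
    site_id = site_id, lat = 0, lon = 0,
    hz_top_m = mids - half, hz_bottom_m = mids + half,
    soc_g_kg = vals, bd_g_cm3 = 1, gravel_frac = 0,
    mattic = as.numeric(params$has_mattic),
    mattic_depth_m = if (params$has_mattic) params$d_mat else NA_real_
  )
}

# random but valid depth-function parameters
random_params <- function(mattic = NA) {
  hm <- if (is.na(mattic)) stats::runif(1) < 0.5 else mattic
  soc_params(
    c_a = stats::runif(1, 5, 100),
    k = stats::runif(1, 0.2, 8),
    has_mattic = hm,
    d_mat = if (hm) stats::runif(1, 0.06, 0.3) else 0
  )
}

# trapezoid quadrature of the depth function: the independent integration
# oracle; the integrand is piecewise smooth, so a node is placed at the mat
# base (standard treatment of a breakpoint in composite quadrature)
quad_stock <- function(params, z_top, z_bottom, step = 1e-4) {
  trap <- function(a, b) {
    if (b <= a) {
      return(0)
    }
    z <- seq(a, b, by = step)
    if (z[length(z)] < b) z <- c(z, b)
    v <- evaluate_soc(params, z)
    sum((v[-1] + v[-length(v)]) / 2 * diff(z))
  }
  brk <- min(max(params$d_mat, z_top), z_bottom)
  trap(z_top, brk) + trap(brk, z_bottom)
}

# small synthetic scenario for fast module tests
small_scenario <- function(seed = 11, n_rows = 50, n_cols = 50, n_cal = 48, ...) {
  simulate_soc_scenario(sim_config(
    n_rows = n_rows, n_cols = n_cols, n_calibration = n_cal, seed = seed, ...
  ))
}

# uniform constant-parameter maps for mapping tests
const_pmaps <- function(grid, c_a = 40, k = 2, d_mat = 0.15, mattic = TRUE) {
  m <- function(v) matrix(v, grid$n_rows, grid$n_cols)
  parameter_maps(grid,
    has_mattic = m(mattic), d_mat = m(if (mattic) d_mat else 0),
    c_a = m(c_a), k = m(k)
  )
}
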