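#' Step-wise exponential depth-function parameters
#'
#' The vertical distribution of volumetric SOC content at a site is described
#' by four parameters: occurrence of the mattic epipedon (a dense organic
#' root mat at the surface), its depth `d_mat` (m), the surface SOC content
#' `c_a` (kg/m^3), and a decay rate `k` (1/m). Within the mat the content is
#' constant at `c_a` (the mat is a near-homogeneous root/organic mixture);
#' below it the content decays exponentially,
#' `C(z) = c_a * exp(-k * (z - d_mat))`. Anchoring the decay at `d_mat`
#' makes the function continuous there, with the mat content equal to the
#' surface content. Sites without a mattic epipedon have `d_mat = 0` and a
#' pure exponential profile.
#'
#' @param c_a Surface SOC content, kg/m^3 (> 0).
#' @param k Decay rate with depth, 1/m (> 0).
#' @param has_mattic Logical; does the profile carry a mattic epipedon?
#' @param d_mat Mattic depth in m; must be > 0 exactly when `has_mattic`.
#' @return An object of class `soc_params`.
#' @examples
#' p <- soc_params(c_a = 41.56, k = 2.31, has_mattic = TRUE, d_mat = 0.18)
#' evaluate_soc(p, c(0.1, 0.5, 0.95))
#' @export
soc_params <- function(c_a, k, has_mattic = FALSE, d_mat = 0) {
  stopifnot(length(c_a) == 1, length(k) == 1, length(d_mat) == 1, length(has_mattic) == 1)
  if (!is.finite(c_a) || c_a <= 0) stop("c_a must be a positive finite number", call. = FALSE)
  if (!is.finite(k) || k <= 0) stop("k must be a positive finite number", call. = FALSE)
  if (isTRUE(has_mattic) != (d_mat > 0)) {
    stop("d_mat must be > 0 exactly when has_mattic is TRUE", call. = FALSE)
  }
  structure(
    list(
      has_mattic = isTRUE(has_mattic), d_mat = as.numeric(d_mat),
      c_a = as.numeric(c_a), k = as.numeric(k)
    ),
    class = "soc_params"
  )
}

#' @export
print.soc_params <- function(x, ...) {
  cat(sprintf(
    "<soc_params> c_a = %.3f kg/m^3, k = %.4f 1/m, %s\n",
    x$c_a, x$k,
    if (x$has_mattic) sprintf("mattic to %.3f m", x$d_mat) else "no mattic epipedon"
  ))
  invisible(x)
}

#' Evaluate the SOC depth function
#'
#' Volumetric SOC content at depth `z`: constant at `c_a` within the mattic
#' layer (`z <= d_mat`), then `c_a * exp(-k * (z - d_mat))`. Continuous at
#' `d_mat`, non-increasing everywhere, strictly decreasing below the mat.
#'
#' @param params A [soc_params()].
#' @param z Depth(s) in m, >= 0, positive downward.
#' @return SOC content in kg/m^3, same shape as `z`.
#' @export
evaluate_soc <- function(params, z) {
  stopifnot(inherits(params, "soc_params"))
  if (any(z < 0, na.rm = TRUE)) stop("depth z must be >= 0", call. = FALSE)
  params$c_a * exp(-params$k * pmax(0, z - params$d_mat))
}

# vectorized closed-form stock over [z_top, z_bottom]; arguments recycle.
# plateau part: c_a * overlap of [z_top, z_bottom] with [0, d_mat];
# decay part: (c_a/k) * (exp(-k*(max(z_top,d_mat)-d_mat)) - exp(-k*(max(z_bottom,d_mat)-d_mat)))
stock_closed_form <- function(c_a, k, d_mat, z_top, z_bottom) {
  plateau <- c_a * (pmin(z_bottom, d_mat) - pmin(z_top, d_mat))
  a <- pmax(z_top, d_mat) - d_mat
  b <- pmax(z_bottom, d_mat) - d_mat
  decay <- (c_a / k) * (exp(-k * a) - exp(-k * b))
  plateau + decay
}

#' Integrate the depth function into a stock
#'
#' Closed-form integral of [evaluate_soc()] over a depth interval, giving the
#' SOC stock (kg C per m^2 of land surface) held between `z_top` and
#' `z_bottom`. The plateau contributes `c_a` times the overlap with
#' `[0, d_mat]`; the exponential tail integrates analytically. Exact (no
#' quadrature), additive over adjacent intervals.
#'
#' @param params A [soc_params()].
#' @param z_top,z_bottom Interval bounds in m, `0 <= z_top < z_bottom`.
#' @return Stock in kg/m^2.
#' @examples
#' p <- soc_params(c_a = 40, k = 2, has_mattic = TRUE, d_mat = 0.15)
#' integrate_stock(p, 0, 1)
#' @export
integrate_stock <- function(params, z_top, z_bottom) {
  stopifnot(inherits(params, "soc_params"))
  if (any(z_top < 0) || any(z_top >= z_bottom)) {
    stop("need 0 <= z_top < z_bottom", call. = FALSE)
  }
  stock_closed_form(params$c_a, params$k, params$d_mat, z_top, z_bottom)
}

#' Discretize a profile into thin slices
#'
#' Evaluates the depth function at the midpoint of consecutive slices of
#' thickness `dz` down to `z_max` — the 1-cm vertical resolution used for
#' visualising vertical sections. Slices are for display; stocks are always
#' computed from the closed-form integral.
#'
#' @param params A [soc_params()].
#' @param dz Slice thickness in m (> 0); default 0.01 (1 cm).
#' @param z_max Bottom of the discretized profile in m; must be an integer
#'   multiple of `dz`.
#' @return Numeric vector of length `z_max / dz` of SOC contents (kg/m^3).
#' @export
discretize_profile <- function(params, dz = 0.01, z_max = 1.0) {
  if (dz <= 0) stop("dz must be > 0", call. = FALSE)
  n <- z_max / dz
  if (abs(n - round(n)) > 1e-8) stop("z_max must be a multiple of dz", call. = FALSE)
  n <- as.integer(round(n))
  evaluate_soc(params, (seq_len(n) - 0.5) * dz)
}

# Two-point closed-form inversion below the mat: k = log(v1/v2)/(z2 - z1),
# c_a = v1 * exp(k * (z1 - d_mat)). Used as a sanity anchor; the profiled
# 1-D optimisation below reproduces it exactly when only two points exist.
two_point_inversion <- function(z1, v1, z2, v2, d_mat = 0) {
  k <- log(v1 / v2) / (z2 - z1)
  list(k = k, c_a = v1 * exp(k * (z1 - d_mat)))
}

#' Fit the depth function to one pedon
#'
#' Least-squares fit of the step-wise exponential depth function to a single
#' profile's horizon observations. Each genetic horizon contributes one
#' observation: its volumetric SOC content located at the horizon midpoint
#' depth. Mattic occurrence and `d_mat` are fixed from the field record; the
#' free parameters are `(c_a, k)`. Within-mattic observations are fitted by
#' the constant `c_a`, so `c_a` couples the plateau and the decay segment.
#'
#' The minimisation is a bounded nonlinear least squares solved by variable
#' projection: for any `k` the optimal `c_a` is a linear least-squares
#' coefficient, leaving a one-dimensional profile objective in `k` that is
#' bracketed on a log-spaced grid over `k` in `(1e-3, 50)` and polished with
#' [stats::optimize()]. This is deterministic and needs no starting values.
#' `c_a` is constrained to `(1e-3, 500)` kg/m^3.
#'
#' Identifiability requires at least two distinct observation depths below
#' the mat (two points determine the exponential); a mattic profile
#' additionally needs at least one observation within the mat.
#'
#' @param pedon A validated pedon tibble restricted to one site (or a table
#'   from which the single site is taken), with `soc_kg_m3` computed.
#' @return An object of class `soc_fit`: `params` ([soc_params()]),
#'   `r_squared`, `n_obs`, `residuals` (tibble `z`, `observed`, `fitted`,
#'   `residual`), `site_id`.
#' @export
fit_depth_function <- function(pedon) {
  pedon <- tibble::as_tibble(pedon)
  if (!"soc_kg_m3" %in% names(pedon)) {
    stop("pedon must be a validated table with soc_kg_m3 (see as_pedon_table())", call. = FALSE)
  }
  if (dplyr::n_distinct(pedon$site_id) != 1) {
    stop("fit_depth_function() takes a single site; see fit_depth_functions()", call. = FALSE)
  }
  has_mattic <- pedon$mattic[1] == 1
  d_mat <- if (has_mattic) pedon$mattic_depth_m[1] else 0

  z <- (pedon$hz_top_m + pedon$hz_bottom_m) / 2
  y <- pedon$soc_kg_m3
  below <- z > d_mat
  if (length(unique(z[below])) < 2) {
    stop(
      "site ", pedon$site_id[1],
      ": need >= 2 distinct observation depths below the mattic layer; k is undetermined",
      call. = FALSE
    )
  }
  if (has_mattic && !any(z <= d_mat)) {
    stop("site ", pedon$site_id[1], ": mattic profile has no observation within the mat", call. = FALSE)
  }

  # depth past the mat; 0 on the plateau, so the design value exp(-k*m) is 1 there
  m <- pmax(0, z - d_mat)
  k_lo <- 1e-3
  k_hi <- 50
  ca_bounds <- c(1e-3, 500)

  profile_fit <- function(k) {
    e <- exp(-k * m)
    c_a <- sum(y * e) / sum(e * e)
    c_a <- min(max(c_a, ca_bounds[1]), ca_bounds[2])
    list(c_a = c_a, sse = sum((y - c_a * e)^2))
  }
  sse_of <- function(k) profile_fit(k)$sse

  grid <- exp(seq(log(k_lo), log(k_hi), length.out = 257))
  sse_grid <- vapply(grid, sse_of, 0)
  i <- which.min(sse_grid)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(function(lk) sse_of(exp(lk)), lower = log(lo), upper = log(hi), tol = 1e-12)
  k_hat <- exp(opt$minimum)
  best <- profile_fit(k_hat)
  if (!is.finite(best$c_a) || best$c_a <= 0 || !is.finite(k_hat) || k_hat <= 0) {
    stop("site ", pedon$site_id[1], ": fit produced non-positive parameters", call. = FALSE)
  }

  params <- soc_params(c_a = best$c_a, k = k_hat, has_mattic = has_mattic, d_mat = d_mat)
  fitted <- evaluate_soc(params, z)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else if (sse < 1e-12) 1 else NA_real_

  structure(
    list(
      params = params,
      r_squared = r2,
      n_obs = length(y),
      residuals = tibble::tibble(z = z, observed = y, fitted = fitted, residual = y - fitted),
      site_id = pedon$site_id[1]
    ),
    class = "soc_fit"
  )
}

#' @export
print.soc_fit <- function(x, ...) {
  cat(sprintf(
    "<soc_fit> site %s: c_a = %.2f kg/m^3, k = %.3f 1/m, R^2 = %.3f (n = %d)\n",
    x$site_id, x$params$c_a, x$params$k, x$r_squared, x$n_obs
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a depth-function fit
#'
#' @param x A `soc_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`term`, `estimate`, `fixed`);
#'   `glance()`: a one-row model summary matching the fit-table layout of
#'   [fit_depth_functions()].
#' @method tidy soc_fit
#' @export
tidy.soc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("c_a", "k", "d_mat", "has_mattic"),
    estimate = c(x$params$c_a, x$params$k, x$params$d_mat, as.numeric(x$params$has_mattic)),
    fixed = c(FALSE, FALSE, TRUE, TRUE)
  )
}

#' @rdname tidy.soc_fit
#' @method glance soc_fit
#' @export
glance.soc_fit <- function(x, ...) {
  tibble::tibble(
    site_id = x$site_id,
    has_mattic = x$params$has_mattic,
    d_mat_m = x$params$d_mat,
    c_a_kg_m3 = x$params$c_a,
    k_per_m = x$params$k,
    r2 = x$r_squared,
    n_obs = x$n_obs
  )
}

#' Fit depth functions to every pedon in a table
#'
#' Maps [fit_depth_function()] over sites and binds the one-row summaries;
#' the standard per-site fit table (`site_id`, `has_mattic`, `d_mat_m`,
#' `c_a_kg_m3`, `k_per_m`, `r2`, `n_obs`).
#'
#' @param pedons A validated pedon tibble (multiple sites).
#' @return A tibble with one row per site, and the full `soc_fit` objects in
#'   a list column `fit`.
#' @export
fit_depth_functions <- function(pedons) {
  pedons <- tibble::as_tibble(pedons)
  fits <- pedons |>
    dplyr::group_split(.data$site_id) |>
    purrr::map(fit_depth_function)
  out <- purrr::map_dfr(fits, glance)
  out$fit <- fits
  out
}

#' Serialize depth-function parameters to and from JSON
#'
#' @param params A [soc_params()] object.
#' @param json A JSON string produced by `params_to_json()`.
#' @return A JSON string / a [soc_params()].
#' @export
params_to_json <- function(params) {
  stopifnot(inherits(params, "soc_params"))
  jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  soc_params(c_a = x$c_a, k = x$k, has_mattic = x$has_mattic, d_mat = x$d_mat)
}
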