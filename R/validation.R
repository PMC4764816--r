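#' Accuracy indices: mean error, RMSE, Lin's concordance
#'
#' The three indices used to judge predicted against observed SOC stocks.
#' `mean_error()` is `mean(predicted - observed)` — negative values mean
#' under-prediction. `rmse()` is the root mean square error. `lccc()` is
#' Lin's concordance correlation coefficient,
#' `2 r s_p s_o / (s_p^2 + s_o^2 + (m_p - m_o)^2)`
#' with population (1/n) variances: Pearson correlation penalised for any
#' location or scale shift away from the 45-degree identity line, so 1 means
#' perfect agreement, not merely perfect correlation.
#'
#' @param observed,predicted Numeric vectors of equal length (kg/m^2 for
#'   stocks). `lccc()` needs `n >= 2` and nonzero variance in at least one
#'   vector.
#' @return A single number; `lccc()` lies in `[-1, 1]`.
#' @examples
#' lccc(c(1, 2, 3), c(1.5, 2.5, 3.5)) # 16/19
#' @export
mean_error <- function(observed, predicted) {
  check_pairs(observed, predicted, min_n = 1)
  mean(predicted - observed)
}

#' @rdname mean_error
#' @export
rmse <- function(observed, predicted) {
  check_pairs(observed, predicted, min_n = 1)
  sqrt(mean((predicted - observed)^2))
}

#' @rdname mean_error
#' @export
lccc <- function(observed, predicted) {
  check_pairs(observed, predicted, min_n = 2)
  n <- length(observed)
  vo <- stats::var(observed) * (n - 1) / n
  vp <- stats::var(predicted) * (n - 1) / n
  if (vo == 0 && vp == 0) stop("lccc undefined: both vectors are constant", call. = FALSE)
  so <- stats::cov(observed, predicted) * (n - 1) / n
  2 * so / (vo + vp + (mean(predicted) - mean(observed))^2)
}

check_pairs <- function(observed, predicted, min_n = 1) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (length(observed) < min_n) stop("need at least ", min_n, " pair(s)", call. = FALSE)
  if (anyNA(observed) || anyNA(predicted) ||
    any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("values must be finite and non-missing", call. = FALSE)
  }
  invisible(NULL)
}

#' All three indices for a pairs table
#'
#' @param pairs Tibble with columns `observed` and `predicted`.
#' @return One-row tibble `n`, `me`, `rmse`, `lccc`.
#' @export
validation_indices <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  tibble::tibble(
    n = nrow(pairs),
    me = mean_error(pairs$observed, pairs$predicted),
    rmse = rmse(pairs$observed, pairs$predicted),
    lccc = lccc(pairs$observed, pairs$predicted)
  )
}

site_predicted_stock <- function(smap, sites) {
  idx <- cell_from_xy(smap$grid, sites$x, sites$y)
  off <- is.na(idx$row)
  if (any(off)) {
    stop("validation site(s) outside grid: ", paste(sites$site_id[off], collapse = ", "), call. = FALSE)
  }
  smap$values[cbind(idx$row, idx$col)]
}

#' Internal validation at the calibration sites
#'
#' Compares mapped stock against the stock implied by each calibration
#' site's own fitted depth function, over a depth layer. "Observed" stock is
#' the closed-form integral of the site's fitted function; "predicted" is
#' the stock-map value at the site's pixel. In-sample by construction, so
#' its indices overstate true map accuracy — pair with
#' [validate_independent()].
#'
#' @param fits A [fit_depth_functions()] table (with the `fit` list column).
#' @param pmaps Predicted `soc_parameter_maps`.
#' @param sites Tibble `site_id`, `x`, `y` for the fitted sites.
#' @param z_top,z_bottom Depth layer in m (default 0-1 m).
#' @return List with `pairs` (tibble `site_id`, `observed`, `predicted`,
#'   `x`, `y`) and `indices` ([validation_indices()] row, tagged
#'   `dataset = "training"`).
#' @export
validate_internal <- function(fits, pmaps, sites, z_top = 0, z_bottom = 1) {
  stopifnot(inherits(pmaps, "soc_parameter_maps"))
  sites <- tibble::as_tibble(sites)
  fits <- tibble::as_tibble(fits)
  joined <- dplyr::inner_join(fits, sites, by = "site_id")
  if (nrow(joined) == 0) stop("no fitted site matches the sites table", call. = FALSE)
  observed <- purrr::map_dbl(joined$fit, function(f) integrate_stock(f$params, z_top, z_bottom))
  smap <- map_stock(pmaps, z_top, z_bottom)
  predicted <- site_predicted_stock(smap, joined)
  pairs <- tibble::tibble(
    site_id = joined$site_id, observed = observed, predicted = predicted,
    x = joined$x, y = joined$y
  )
  ind <- validation_indices(pairs)
  ind$dataset <- "training"
  list(pairs = pairs, indices = ind)
}

#' Independent validation with densely sampled pedons
#'
#' Compares mapped stock against model-free observed stocks from pedons
#' sampled at a contiguous 5-cm interval: the observed stock over the layer
#' is the depth-increment sum of `soc_kg_m3 x thickness`, requiring the
#' increments to cover `[z_top, z_bottom]` without gaps. Predicted stock is
#' the map value at the pedon's pixel.
#'
#' @param dense_pedons Validated pedon tibble of the intensively sampled
#'   profiles.
#' @param pmaps Predicted `soc_parameter_maps`.
#' @param z_top,z_bottom Depth layer in m (`z_top < z_bottom`).
#' @return As [validate_internal()], tagged `dataset = "independent"`.
#' @export
validate_independent <- function(dense_pedons, pmaps, z_top = 0, z_bottom = 1) {
  stopifnot(inherits(pmaps, "soc_parameter_maps"))
  if (!(z_top >= 0 && z_top < z_bottom)) stop("need 0 <= z_top < z_bottom", call. = FALSE)
  pedons <- tibble::as_tibble(dense_pedons)
  per_site <- pedons |>
    dplyr::arrange(.data$site_id, .data$hz_top_m) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_split()
  obs <- purrr::map_dbl(per_site, function(p) {
    inside <- p$hz_bottom_m > z_top & p$hz_top_m < z_bottom
    p <- p[inside, , drop = FALSE]
    if (nrow(p) == 0 ||
      min(p$hz_top_m) > z_top + 1e-9 || max(p$hz_bottom_m) < z_bottom - 1e-9 ||
      any(abs(p$hz_top_m[-1] - p$hz_bottom_m[-nrow(p)]) > 1e-9)) {
      stop(
        "site ", p$site_id[1] %||% "?",
        ": 5-cm increments do not cover the layer without gaps",
        call. = FALSE
      )
    }
    thick <- pmin(p$hz_bottom_m, z_bottom) - pmax(p$hz_top_m, z_top)
    sum(p$soc_kg_m3 * thick)
  })
  sites <- purrr::map_dfr(per_site, function(p) {
    tibble::tibble(site_id = p$site_id[1], x = p$lon[1], y = p$lat[1])
  })
  smap <- map_stock(pmaps, z_top, z_bottom)
  predicted <- site_predicted_stock(smap, sites)
  pairs <- tibble::tibble(
    site_id = sites$site_id, observed = obs, predicted = predicted,
    x = sites$x, y = sites$y
  )
  ind <- validation_indices(pairs)
  ind$dataset <- "independent"
  list(pairs = pairs, indices = ind)
}

#' Repeated-run validation report
#'
#' Re-runs a full validation procedure (typically retrain + remap +
#' validate) across seeds `seed + 0, ..., seed + n_runs - 1` and summarises
#' each index for each dataset with the seven statistics (min, 1st
#' quartile, mean, median, 3rd quartile, max, SD). The re-seeded forest
#' training is the only stochastic component, so the spread isolates model
#' Monte-Carlo variability.
#'
#' @param procedure Function `(seed) -> tibble` of index rows, each carrying
#'   `dataset`, `me`, `rmse`, `lccc` (e.g. row-binding the `indices` of
#'   [validate_internal()] and [validate_independent()]).
#' @param n_runs Number of runs (>= 2).
#' @param seed Base seed.
#' @return Tibble with one row per (dataset, index) and the seven summary
#'   columns.
#' @export
repeat_validation <- function(procedure, n_runs = 100, seed = 1) {
  if (n_runs < 2) stop("n_runs must be >= 2", call. = FALSE)
  runs <- purrr::map_dfr(seq_len(n_runs) - 1L, function(i) {
    out <- tibble::as_tibble(procedure(seed + i))
    out$run <- i
    out
  })
  runs |>
    tidyr::pivot_longer(c("me", "rmse", "lccc"), names_to = "index", values_to = "value") |>
    dplyr::group_by(.data$dataset, .data$index) |>
    dplyr::group_modify(function(d, key) {
      s <- seven_number_summary(d$value)
      s$n_runs <- n_runs
      s
    }) |>
    dplyr::ungroup()
}

#' Empirical semivariogram of residuals
#'
#' Classical Matheron estimator
#' `gamma(h) = (1 / (2 N(h))) * sum (r_i - r_j)^2` over point pairs binned
#' by separation distance — the check for leftover spatial structure in
#' validation residuals. A flat variogram indicates spatially white
#' residuals (no gain available from kriging them).
#'
#' @param pairs Tibble with columns `x`, `y` and either `residual` or both
#'   `observed`/`predicted` (residual = predicted - observed).
#' @param n_bins Number of equal-width distance bins.
#' @param max_lag Largest separation considered; default half the maximum
#'   pairwise distance.
#' @return Tibble `lag` (bin center), `gamma`, `n_pairs`; empty bins are
#'   dropped.
#' @export
residual_semivariogram <- function(pairs, n_bins = 10, max_lag = NULL) {
  pairs <- tibble::as_tibble(pairs)
  if (!"residual" %in% names(pairs)) {
    if (!all(c("observed", "predicted") %in% names(pairs))) {
      stop("pairs needs 'residual' or 'observed'+'predicted'", call. = FALSE)
    }
    pairs$residual <- pairs$predicted - pairs$observed
  }
  if (!all(c("x", "y") %in% names(pairs))) stop("pairs needs coordinates x, y", call. = FALSE)
  if (nrow(pairs) < 10) stop("need at least 10 located residuals", call. = FALSE)

  d <- as.matrix(stats::dist(cbind(pairs$x, pairs$y)))
  iu <- upper.tri(d)
  h <- d[iu]
  r <- pairs$residual
  sq <- (outer(r, r, `-`)^2)[iu]
  if (is.null(max_lag)) max_lag <- max(h) / 2
  keep <- h <= max_lag & h > 0
  h <- h[keep]
  sq <- sq[keep]
  breaks <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- cut(h, breaks, include.lowest = TRUE, labels = FALSE)
  out <- tibble::tibble(bin = bin, h = h, sq = sq) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      lag = (breaks[.data$bin[1]] + breaks[.data$bin[1] + 1]) / 2,
      gamma = sum(.data$sq) / (2 * dplyr::n()),
      n_pairs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("lag", "gamma", "n_pairs")
  if (all(out$n_pairs < 2)) stop("fewer than 2 pairs in every lag bin", call. = FALSE)
  out
}
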