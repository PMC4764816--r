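#' Run the full 3-D SOC mapping pipeline
#'
#' Chains every stage on a calibration dataset: per-pedon depth-function
#' fits, covariate extraction at the sites, training of the four
#' random-forest parameter models, prediction of parameter maps over the
#' stack, stock maps for the standard layers (mattic, 0-30, 0-50,
#' 0-100 cm) with the layer report, and internal plus (when dense pedons
#' are given) independent validation over 0-100 cm.
#'
#' The training table couples, per site, the field-recorded mattic
#' occurrence and depth with the fitted `c_a` and `k`; the mattic-depth
#' regressor sees only mattic-bearing sites.
#'
#' @param calibration Validated pedon tibble of genetic-horizon profiles.
#' @param stack A [covariate_stack()].
#' @param independent Optional validated pedon tibble of 5-cm profiles.
#' @param cfg An [rf_config()]; its `seed` drives all forest training.
#' @return An object of class `soc_pipeline`: `fits`, `training`,
#'   `models`, `pmaps`, `stocks` (list of stock maps), `report`,
#'   `oob` (per-model OOB tibble), `internal`, `independent`
#'   (validation lists), `indices` (bound index rows).
#' @export
run_soc_pipeline <- function(calibration, stack, independent = NULL, cfg = rf_config()) {
  stopifnot(inherits(stack, "soc_stack"))
  fits <- fit_depth_functions(calibration)
  sites <- pedon_sites(calibration)
  cov_tbl <- extract_at_points(stack, sites)
  if (any(cov_tbl$nodata)) {
    stop(
      "calibration site(s) on nodata pixels: ",
      paste(cov_tbl$site_id[cov_tbl$nodata], collapse = ", "),
      call. = FALSE
    )
  }
  training <- fits |>
    dplyr::select("site_id", "has_mattic", "d_mat_m", "c_a_kg_m3", "k_per_m") |>
    dplyr::inner_join(cov_tbl, by = "site_id")

  models <- train_model_set(training, cfg)
  pmaps <- predict_parameter_maps(models, stack)

  ref <- map_stock(pmaps, 0, 1)
  stocks <- list(
    mattic = map_stock(pmaps, layer = "mattic"),
    l030 = map_stock(pmaps, 0, 0.3),
    l050 = map_stock(pmaps, 0, 0.5),
    l0100 = ref
  )
  report <- relative_stock_report(stocks, ref)

  oob <- tibble::tibble(
    model = c("mattic_occurrence", "log_d_mat", "log_c_a", "log_k"),
    statistic = c("error_rate", "mse", "mse", "mse"),
    oob = c(models$occurrence$oob, models$d_mat$oob, models$c_a$oob, models$k$oob)
  )

  internal <- validate_internal(fits, pmaps, sites, 0, 1)
  indep <- if (!is.null(independent)) validate_independent(independent, pmaps, 0, 1) else NULL
  indices <- dplyr::bind_rows(
    internal$indices,
    if (!is.null(indep)) indep$indices
  )

  structure(
    list(
      fits = fits, training = training, models = models, pmaps = pmaps,
      stocks = stocks, report = report, oob = oob,
      internal = internal, independent = indep, indices = indices
    ),
    class = "soc_pipeline"
  )
}

#' @export
print.soc_pipeline <- function(x, ...) {
  cat("<soc_pipeline>\n")
  cat(sprintf(
    "  %d fitted pedons (mean R^2 %.3f); mattic area %.1f km^2\n",
    nrow(x$fits), mean(x$fits$r2), mattic_area(x$pmaps)
  ))
  print(x$report)
  print(x$indices)
  invisible(x)
}

#' Broom-style summaries of a pipeline run
#'
#' `tidy()` returns the layer-by-layer stock report; `glance()` a one-row
#' overview (fit quality, OOB errors, validation indices, mattic area).
#'
#' @param x A `soc_pipeline`.
#' @param ... Unused.
#' @method tidy soc_pipeline
#' @export
tidy.soc_pipeline <- function(x, ...) x$report

#' @rdname tidy.soc_pipeline
#' @method glance soc_pipeline
#' @export
glance.soc_pipeline <- function(x, ...) {
  ind <- x$indices
  pick <- function(ds, col) {
    v <- ind[[col]][ind$dataset == ds]
    if (length(v) == 0) NA_real_ else v
  }
  tibble::tibble(
    n_sites = nrow(x$fits),
    mean_fit_r2 = mean(x$fits$r2),
    oob_error_mattic = x$oob$oob[x$oob$model == "mattic_occurrence"],
    oob_mse_log_c_a = x$oob$oob[x$oob$model == "log_c_a"],
    oob_mse_log_k = x$oob$oob[x$oob$model == "log_k"],
    lccc_internal = pick("training", "lccc"),
    lccc_independent = pick("independent", "lccc"),
    rmse_independent = pick("independent", "rmse"),
    total_Tg_0_100 = x$report$total_Tg[x$report$layer == "0-100 cm"],
    mattic_area_km2 = mattic_area(x$pmaps)
  )
}
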