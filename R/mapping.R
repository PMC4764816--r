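#' Predict depth-function parameter maps across a covariate stack
#'
#' Applies the trained model set pixel-by-pixel over the stack, producing
#' the four parameter rasters (`has_mattic`, `d_mat`, `c_a`, `k`) that carry
#' the full 3-D SOC description. Pixels masked in any covariate layer stay
#' masked in every output.
#'
#' @param models A [train_model_set()] result.
#' @param stack A [covariate_stack()] whose layers include every training
#'   covariate.
#' @return An object of class `soc_parameter_maps`: `grid`, logical layer
#'   `has_mattic`, numeric layers `p_mattic`, `d_mat`, `c_a`, `k`, and
#'   `mask`.
#' @export
predict_parameter_maps <- function(models, stack) {
  stopifnot(inherits(models, "soc_model_set"), inherits(stack, "soc_stack"))
  missing_cov <- setdiff(models$covariates, names(stack$layers))
  if (length(missing_cov) > 0) {
    stop("stack lacks covariate layer(s): ", paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  g <- stack$grid
  tbl <- tibble::as_tibble(purrr::map(stack$layers[models$covariates], as.vector))
  pred <- predict_parameters(models, tbl)

  shape <- function(v) matrix(v, nrow = g$n_rows, ncol = g$n_cols)
  structure(
    list(
      grid = g,
      has_mattic = shape(as.logical(pred$has_mattic)),
      p_mattic = shape(pred$p_mattic),
      d_mat = shape(pred$d_mat_m),
      c_a = shape(pred$c_a_kg_m3),
      k = shape(pred$k_per_m),
      mask = shape(pred$nodata)
    ),
    class = "soc_parameter_maps"
  )
}

#' Construct parameter maps directly from layers
#'
#' Used for truth fields from the synthetic generator and for any externally
#' supplied parameter rasters; validates the parameter-map invariants
#' (`c_a`, `k` > 0 on valid pixels, `d_mat = 0` where no mattic).
#'
#' @param grid A [grid_def()].
#' @param has_mattic Logical matrix.
#' @param d_mat,c_a,k Numeric matrices (m, kg/m^3, 1/m).
#' @param p_mattic Optional probability matrix.
#' @return An object of class `soc_parameter_maps`.
#' @export
parameter_maps <- function(grid, has_mattic, d_mat, c_a, k, p_mattic = NULL) {
  stopifnot(inherits(grid, "soc_grid"))
  for (l in list(has_mattic, d_mat, c_a, k)) {
    stopifnot(is.matrix(l), nrow(l) == grid$n_rows, ncol(l) == grid$n_cols)
  }
  mask <- is.na(has_mattic) | is.na(d_mat) | is.na(c_a) | is.na(k)
  ok <- !mask
  if (any(c_a[ok] <= 0) || any(k[ok] <= 0)) stop("c_a and k must be > 0 on valid pixels", call. = FALSE)
  if (any(d_mat[ok][!has_mattic[ok]] != 0)) stop("d_mat must be 0 where has_mattic is FALSE", call. = FALSE)
  if (any(d_mat[ok][has_mattic[ok]] <= 0)) stop("d_mat must be > 0 where has_mattic is TRUE", call. = FALSE)
  structure(
    list(
      grid = grid, has_mattic = has_mattic,
      p_mattic = if (is.null(p_mattic)) (has_mattic * 1) else p_mattic,
      d_mat = d_mat, c_a = c_a, k = k, mask = mask
    ),
    class = "soc_parameter_maps"
  )
}

#' @export
print.soc_parameter_maps <- function(x, ...) {
  ok <- !x$mask
  cat(sprintf(
    "<soc_parameter_maps> %d x %d grid; %.1f%% mattic; c_a %.1f-%.1f kg/m^3; %d masked\n",
    x$grid$n_rows, x$grid$n_cols, 100 * mean(x$has_mattic[ok]),
    min(x$c_a[ok]), max(x$c_a[ok]), sum(x$mask)
  ))
  invisible(x)
}

#' Map SOC stock for a depth layer
#'
#' Pixelwise closed-form integration of the depth function between `z_top`
#' and `z_bottom` (meters), or over the per-pixel mattic layer `[0, d_mat]`
#' when `layer = "mattic"` (0 where no mattic). Stocks always come from the
#' analytic integral, never from summed slices.
#'
#' @param pmaps A `soc_parameter_maps`.
#' @param z_top,z_bottom Interval in m (`0 <= z_top < z_bottom`); ignored
#'   when `layer = "mattic"`.
#' @param layer `"interval"` (default) or `"mattic"`.
#' @return An object of class `soc_stock_map`: `grid`, `values` (kg/m^2
#'   matrix), `z_top`, `z_bottom` (NA for the mattic layer), `label`.
#' @export
map_stock <- function(pmaps, z_top = 0, z_bottom = 1, layer = c("interval", "mattic")) {
  stopifnot(inherits(pmaps, "soc_parameter_maps"))
  layer <- match.arg(layer)
  if (layer == "mattic") {
    values <- pmaps$c_a * pmaps$d_mat
    z_top <- NA_real_
    z_bottom <- NA_real_
    label <- "mattic"
  } else {
    if (!(z_top >= 0 && z_top < z_bottom)) stop("need 0 <= z_top < z_bottom", call. = FALSE)
    values <- stock_closed_form(pmaps$c_a, pmaps$k, pmaps$d_mat, z_top, z_bottom)
    label <- sprintf("%g-%g cm", 100 * z_top, 100 * z_bottom)
  }
  values[pmaps$mask] <- NA_real_
  structure(
    list(grid = pmaps$grid, values = values, z_top = z_top, z_bottom = z_bottom, label = label),
    class = "soc_stock_map"
  )
}

#' @export
print.soc_stock_map <- function(x, ...) {
  cat(sprintf(
    "<soc_stock_map> layer %s: mean %.2f kg/m^2 over %d valid pixels\n",
    x$label, mean(x$values, na.rm = TRUE), sum(!is.na(x$values))
  ))
  invisible(x)
}

#' Total and mean stock of a map
#'
#' Multiplies each pixel's stock by the pixel area and sums over valid
#' pixels; totals are reported in Tg (1 Tg = 1e9 kg) and the mean per valid
#' pixel in kg/m^2.
#'
#' @param smap A [map_stock()] result.
#' @return One-row tibble: `layer`, `mean_kg_m2`, `total_Tg`, `n_pixels`.
#' @export
total_stock <- function(smap) {
  stopifnot(inherits(smap, "soc_stock_map"))
  v <- smap$values
  if (all(is.na(v))) stop("stock map has no valid pixels", call. = FALSE)
  area <- smap$grid$cell_size^2
  tibble::tibble(
    layer = smap$label,
    mean_kg_m2 = mean(v, na.rm = TRUE),
    total_Tg = sum(v, na.rm = TRUE) * area / 1e9,
    n_pixels = sum(!is.na(v))
  )
}

#' Area covered by the mattic epipedon
#'
#' @param pmaps A `soc_parameter_maps`.
#' @return Area in km^2: mattic pixel count times cell area / 1e6.
#' @export
mattic_area <- function(pmaps) {
  stopifnot(inherits(pmaps, "soc_parameter_maps"))
  sum(pmaps$has_mattic & !pmaps$mask, na.rm = TRUE) * pmaps$grid$cell_size^2 / 1e6
}

#' Layer-by-layer stock report with relative shares
#'
#' The standard stock summary table: per depth layer its mean stock
#' (kg/m^2), total (Tg) and share of the reference layer's total (percent,
#' typically the 0-100 cm layer).
#'
#' @param smaps Named or unnamed list of [map_stock()] results sharing one
#'   grid.
#' @param reference The reference `soc_stock_map` (conventionally 0-100 cm).
#' @return Tibble `layer`, `mean_kg_m2`, `total_Tg`, `relative_pct`.
#' @export
relative_stock_report <- function(smaps, reference) {
  stopifnot(inherits(reference, "soc_stock_map"))
  for (s in smaps) {
    if (!grid_equal(s$grid, reference$grid)) stop("stock maps must share one grid", call. = FALSE)
  }
  ref_total <- total_stock(reference)$total_Tg
  if (ref_total == 0) stop("reference layer has zero total stock", call. = FALSE)
  purrr::map_dfr(smaps, total_stock) |>
    dplyr::mutate(relative_pct = 100 * .data$total_Tg / ref_total) |>
    dplyr::select("layer", "mean_kg_m2", "total_Tg", "relative_pct")
}

#' Vertical section through the 3-D SOC field
#'
#' Discretizes the depth function of each pixel along a path into thin
#' slices (default 1 cm) and stacks them into a depth-by-distance matrix —
#' the cross-section view of the reconstructed 3-D carbon field.
#'
#' @param pmaps A `soc_parameter_maps`.
#' @param pixels Data frame with columns `row`, `col`: the pixel path.
#' @param dz Slice thickness in m.
#' @param z_max Section depth in m.
#' @return An object of class `soc_section`: `values` (matrix, rows =
#'   depths, columns = path pixels), `depths` (slice midpoints, m),
#'   `pixels`.
#' @export
vertical_section <- function(pmaps, pixels, dz = 0.01, z_max = 1.0) {
  stopifnot(inherits(pmaps, "soc_parameter_maps"))
  pixels <- tibble::as_tibble(pixels)
  if (nrow(pixels) == 0) stop("empty pixel path", call. = FALSE)
  if (!all(c("row", "col") %in% names(pixels))) stop("pixels needs columns row, col", call. = FALSE)
  if (any(pixels$row < 1 | pixels$row > pmaps$grid$n_rows |
    pixels$col < 1 | pixels$col > pmaps$grid$n_cols)) {
    stop("path leaves the grid", call. = FALSE)
  }
  n <- as.integer(round(z_max / dz))
  depths <- (seq_len(n) - 0.5) * dz
  cols <- purrr::map(seq_len(nrow(pixels)), function(i) {
    r <- pixels$row[i]
    cl <- pixels$col[i]
    if (pmaps$mask[r, cl]) {
      return(rep(NA_real_, n))
    }
    p <- soc_params(
      c_a = pmaps$c_a[r, cl], k = pmaps$k[r, cl],
      has_mattic = pmaps$has_mattic[r, cl], d_mat = pmaps$d_mat[r, cl]
    )
    discretize_profile(p, dz = dz, z_max = z_max)
  })
  structure(
    list(values = do.call(cbind, cols), depths = depths, pixels = pixels, dz = dz),
    class = "soc_section"
  )
}

#' Section along a fixed easting
#'
#' Selects the grid column whose cell-center x coordinate is nearest to `x`
#' and builds the vertical section down that column (all rows, north to
#' south).
#'
#' @param pmaps A `soc_parameter_maps`.
#' @param x Easting in map units.
#' @inheritParams vertical_section
#' @return A `soc_section`.
#' @export
section_along_x <- function(pmaps, x, dz = 0.01, z_max = 1.0) {
  g <- pmaps$grid
  centers <- g$x_origin + (seq_len(g$n_cols) - 0.5) * g$cell_size
  col <- which.min(abs(centers - x))
  vertical_section(pmaps, tibble::tibble(row = seq_len(g$n_rows), col = col), dz = dz, z_max = z_max)
}

#' Write a stock or parameter layer to disk
#'
#' Single-band ESRI ASCII export of a stock map (or any parameter layer).
#'
#' @param smap A `soc_stock_map`.
#' @param path Output `.asc` path.
#' @export
write_stock_map <- function(smap, path) {
  stopifnot(inherits(smap, "soc_stock_map"))
  write_ascii_grid(smap$values, smap$grid, path)
}
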