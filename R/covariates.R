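#' Names of the standard environmental covariate set
#'
#' The predictor set used for depth-function parameter mapping: terrain
#' attributes from a DEM (elevation, folded aspect, slope, slope length `SL`,
#' plan/profile curvature, catchment area `CA`, wetness index `TWI`,
#' valley-bottom flatness `MrVBF`, valley depth `VD`), climate (`MAT`, `MAP`),
#' vegetation (Landsat-like bands `B3`, `B4`, `B5` and `NDVI`) and spatial
#' position (`Lat`, `Lon`).
#'
#' @return Character vector of 18 layer names.
#' @export
soc_covariate_names <- function() {
  c(
    "elevation", "aspect", "slope", "SL", "Plan_cur", "Prof_cur", "CA",
    "TWI", "MrVBF", "VD", "MAT", "MAP", "B3", "B4", "B5", "NDVI", "Lat", "Lon"
  )
}

#' Assemble a co-registered covariate raster stack
#'
#' Bundles named raster layers sharing one [grid_def()] into a stack with a
#' shared nodata mask: a pixel missing in *any* layer is excluded from both
#' training and prediction. Layers named `NDVI` and `aspect` are range-checked
#' (`[-1, 1]` and `[0, 180]` degrees).
#'
#' @param grid A [grid_def()].
#' @param layers Named list of numeric matrices, all of `dim = c(n_rows, n_cols)`.
#' @return An object of class `soc_stack` with elements `grid`, `layers` and
#'   `mask` (logical matrix, `TRUE` where a pixel is missing in any layer).
#' @export
covariate_stack <- function(grid, layers) {
  stopifnot(inherits(grid, "soc_grid"), is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    stop("all layers must be named", call. = FALSE)
  }
  if (anyDuplicated(names(layers))) stop("duplicate layer names", call. = FALSE)
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!is.matrix(l) || nrow(l) != grid$n_rows || ncol(l) != grid$n_cols) {
      stop(sprintf("layer '%s' does not conform to the grid (%d x %d)", nm, grid$n_rows, grid$n_cols),
        call. = FALSE
      )
    }
  }
  if ("NDVI" %in% names(layers)) {
    v <- layers$NDVI
    if (any(v < -1 - 1e-9 | v > 1 + 1e-9, na.rm = TRUE)) stop("NDVI outside [-1, 1]", call. = FALSE)
  }
  if ("aspect" %in% names(layers)) {
    v <- layers$aspect
    if (any(v < 0 | v > 180, na.rm = TRUE)) {
      stop("aspect must be folded to [0, 180] degrees (see fold_aspect())", call. = FALSE)
    }
  }
  mask <- Reduce(`|`, lapply(layers, is.na))
  structure(list(grid = grid, layers = layers, mask = mask), class = "soc_stack")
}

#' @export
print.soc_stack <- function(x, ...) {
  cat(sprintf(
    "<soc_stack> %d layers on %d x %d grid (%g map units); %d masked pixels\n",
    length(x$layers), x$grid$n_rows, x$grid$n_cols, x$grid$cell_size, sum(x$mask)
  ))
  cat(" layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Normalized difference vegetation index
#'
#' `NDVI = (NIR - Red) / (NIR + Red)`, computed from the red band (`b3`) and
#' near-infrared band (`b4`). The index is scale-invariant, so bands may be
#' supplied as reflectance or raw DN without calibration. Pixels where both
#' bands are zero get NA (nodata).
#'
#' @param b3 Red-band values (vector or matrix, >= 0).
#' @param b4 Near-infrared-band values, same shape as `b3` (>= 0).
#' @return NDVI in `[-1, 1]`, same shape as the inputs.
#' @examples
#' compute_ndvi(0.1, 0.3) # 0.5
#' @export
compute_ndvi <- function(b3, b4) {
  if (length(b3) != length(b4)) stop("b3 and b4 must have the same length", call. = FALSE)
  if (any(b3 < 0 | b4 < 0, na.rm = TRUE)) stop("band values must be non-negative", call. = FALSE)
  s <- b3 + b4
  out <- (b4 - b3) / s
  out[s == 0] <- NA_real_
  out
}

#' Fold aspect onto the north-south axis
#'
#' Maps compass aspect (degrees clockwise from north, `[0, 360)`) to the
#' absolute deviation from north in `[0, 180]`, so that east- and west-facing
#' slopes are equivalent and the value expresses the north (0) to south (180)
#' exposure gradient that controls insolation.
#'
#' @param aspect_deg Aspect in degrees, `0 <= aspect < 360` (vector or matrix).
#' @return Folded aspect in `[0, 180]`, same shape. Idempotent on `[0, 180]`.
#' @examples
#' fold_aspect(270) # 90
#' @export
fold_aspect <- function(aspect_deg) {
  if (any(aspect_deg < 0 | aspect_deg >= 360, na.rm = TRUE)) {
    stop("aspect must lie in [0, 360)", call. = FALSE)
  }
  ifelse(aspect_deg > 180, 360 - aspect_deg, aspect_deg)
}

#' Extract covariate vectors at point locations
#'
#' Looks up the value of every stack layer at the pixel containing each site.
#' Sites falling on a masked (nodata) pixel are kept but flagged; sites
#' outside the grid extent are an error.
#'
#' @param stack A [covariate_stack()].
#' @param sites Data frame with columns `site_id`, `x`, `y` (map coordinates
#'   in the stack's CRS).
#' @return A tibble with `site_id`, `row`, `col`, one column per layer, and a
#'   logical `nodata` column.
#' @export
extract_at_points <- function(stack, sites) {
  stopifnot(inherits(stack, "soc_stack"))
  sites <- tibble::as_tibble(sites)
  need <- c("site_id", "x", "y")
  if (!all(need %in% names(sites))) {
    stop("sites must have columns site_id, x, y", call. = FALSE)
  }
  idx <- cell_from_xy(stack$grid, sites$x, sites$y)
  off <- is.na(idx$row)
  if (any(off)) {
    stop(
      "sites outside grid extent: ",
      paste(sites$site_id[off], collapse = ", "),
      call. = FALSE
    )
  }
  ij <- cbind(idx$row, idx$col)
  vals <- purrr::map(stack$layers, ~ .x[ij])
  out <- dplyr::bind_cols(
    tibble::tibble(site_id = sites$site_id, row = idx$row, col = idx$col),
    tibble::as_tibble(vals)
  )
  out$nodata <- stack$mask[ij]
  out
}

#' Read and write a covariate stack as ASCII grids plus a manifest
#'
#' `write_covariate_stack()` writes one ESRI ASCII grid per layer and a
#' `manifest.json` recording the grid definition and the file for each layer;
#' `read_covariate_stack()` reverses it.
#'
#' @param stack A [covariate_stack()].
#' @param dir Directory to write into / read from (created if needed).
#' @return The stack (invisibly for the writer).
#' @export
write_covariate_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "soc_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- stats::setNames(paste0(names(stack$layers), ".asc"), names(stack$layers))
  for (nm in names(stack$layers)) {
    write_ascii_grid(stack$layers[[nm]], stack$grid, file.path(dir, files[[nm]]))
  }
  manifest <- list(
    grid = unclass(stack$grid),
    layers = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(stack)
}

#' @rdname write_covariate_stack
#' @export
read_covariate_stack <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  g <- do.call(grid_def, manifest$grid[c("n_rows", "n_cols", "x_origin", "y_origin", "cell_size", "crs")])
  layers <- purrr::map(manifest$layers, function(f) read_ascii_grid(file.path(dir, f))$layer)
  covariate_stack(g, layers)
}
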