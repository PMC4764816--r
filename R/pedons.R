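#' Pedo-transfer function configuration for bulk density
#'
#' Bulk density of fine earth is predicted from SOC mass content with the
#' monotone-decreasing exponential family
#' `BD(soc) = a0 + a1 * exp(-a2 * soc)` (g/cm^3): carbon-free soil has the
#' mineral density `a0 + a1`, and density falls toward the organic asymptote
#' `a0` as SOC grows. The defaults (`a0 = 0.5`, `a1 = 0.9`,
#' `a2 = 0.008` per g/kg) give 1.40 g/cm^3 for carbon-free soil, about
#' 0.90 g/cm^3 at 100 g/kg SOC, and an asymptote of 0.50 g/cm^3 for
#' root-mat organic horizons — magnitudes typical of alpine meadow soils.
#' Coefficients are configurable so a locally calibrated PTF can be swapped
#' in without code change.
#'
#' @param a0 Asymptotic bulk density, g/cm^3 (> 0).
#' @param a1 Amplitude, g/cm^3 (> 0); `a0 + a1` is the carbon-free density.
#' @param a2 Decay rate per (g/kg) of SOC (> 0).
#' @return An object of class `soc_ptf`.
#' @export
ptf_config <- function(a0 = 0.5, a1 = 0.9, a2 = 0.008) {
  stopifnot(is.numeric(a0), is.numeric(a1), is.numeric(a2))
  if (a0 <= 0 || a1 <= 0 || a2 <= 0) stop("PTF coefficients must be positive", call. = FALSE)
  # the predicted density must stay physically plausible over the SOC range
  rng <- a0 + a1 * exp(-a2 * c(0, 600))
  if (any(rng <= 0.1) || any(rng >= 2.5)) {
    stop("PTF predictions leave (0.1, 2.5) g/cm^3 over SOC in [0, 600] g/kg", call. = FALSE)
  }
  structure(list(a0 = a0, a1 = a1, a2 = a2), class = "soc_ptf")
}

#' Estimate bulk density from SOC content
#'
#' Applies the pedo-transfer function `BD = a0 + a1 * exp(-a2 * soc_mass)` to
#' fill unavailable bulk-density measurements. Strictly decreasing in SOC and
#' bounded in `(a0, a0 + a1]`.
#'
#' @param soc_mass SOC mass content, g C per kg fine earth (>= 0); vectorized.
#' @param cfg A [ptf_config()].
#' @return Bulk density in g/cm^3.
#' @examples
#' estimate_bd_ptf(c(0, 100))
#' @export
estimate_bd_ptf <- function(soc_mass, cfg = ptf_config()) {
  stopifnot(inherits(cfg, "soc_ptf"))
  if (any(soc_mass < 0, na.rm = TRUE)) stop("soc_mass must be >= 0", call. = FALSE)
  cfg$a0 + cfg$a1 * exp(-cfg$a2 * soc_mass)
}

#' Convert SOC from mass basis to volume basis
#'
#' `Cv = Cm * BD * (1 - G)`: mass content (g C/kg fine earth) times bulk
#' density (g/cm^3) gives carbon per unit fine-earth volume, and the factor
#' `(1 - G)` discounts the volume occupied by rock fragments > 2 mm. The
#' units collapse exactly: (g/kg) x (g/cm^3) = kg/m^3.
#'
#' @param soc_mass SOC mass content, g/kg (>= 0).
#' @param bulk_density Bulk density, g/cm^3 (>= 0).
#' @param gravel_frac Volume fraction of coarse fragments, in `[0, 1)`. Note:
#'   a *fraction*, not a percent.
#' @return Volumetric SOC content, kg C per m^3 of whole soil.
#' @examples
#' soc_mass_to_volume(20, 1.2, 0.5) # 12
#' @export
soc_mass_to_volume <- function(soc_mass, bulk_density, gravel_frac = 0) {
  if (any(soc_mass < 0, na.rm = TRUE)) stop("soc_mass must be >= 0", call. = FALSE)
  if (any(bulk_density < 0, na.rm = TRUE)) stop("bulk_density must be >= 0", call. = FALSE)
  if (any(gravel_frac < 0 | gravel_frac >= 1, na.rm = TRUE)) {
    stop("gravel_frac must lie in [0, 1)", call. = FALSE)
  }
  soc_mass * bulk_density * (1 - gravel_frac)
}

pedon_columns <- c(
  "site_id", "lat", "lon", "hz_top_m", "hz_bottom_m", "soc_g_kg",
  "bd_g_cm3", "gravel_frac", "mattic", "mattic_depth_m"
)

#' Validate and finalize a pedon table
#'
#' Takes a raw horizon-level pedon table (one row per genetic horizon, see
#' [read_pedons()] for the column contract), validates it, fills missing bulk
#' densities with the pedo-transfer function, and computes volumetric SOC
#' content per horizon.
#'
#' Validation enforces: `hz_bottom_m > hz_top_m`; horizons within a site
#' sorted and non-overlapping; `gravel_frac` in `[0, 1)`; measured bulk
#' density in (0.1, 2.5) g/cm^3; a mattic flag constant within a site, with
#' `mattic_depth_m > 0.05` m present whenever the flag is set (a surface mat
#' thinner than 5 cm does not qualify as a mattic epipedon).
#'
#' @param x Data frame with the pedon columns.
#' @param ptf A [ptf_config()] used where `bd_g_cm3` is missing; measured
#'   values always take precedence.
#' @return A tibble with the input columns plus `bd_source`
#'   (`"measured"`/`"ptf"`) and `soc_kg_m3`.
#' @export
as_pedon_table <- function(x, ptf = ptf_config()) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(pedon_columns, names(x))
  if (length(missing_cols) > 0) {
    stop("pedon table lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(pedon_columns, "site_id")
  for (nm in num_cols) {
    if (!is.numeric(x[[nm]]) && !all(is.na(x[[nm]]))) {
      stop(sprintf("column '%s' must be numeric", nm), call. = FALSE)
    }
    x[[nm]] <- as.numeric(x[[nm]])
  }
  rows <- seq_len(nrow(x))

  bad <- which(!(x$hz_bottom_m > x$hz_top_m))
  if (length(bad) > 0) {
    stop("inverted or zero-thickness horizon at row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(x$hz_top_m < 0)) stop("negative horizon depth", call. = FALSE)
  bad <- which(x$gravel_frac < 0 | x$gravel_frac >= 1)
  if (length(bad) > 0) stop("gravel_frac outside [0, 1) at row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(x$soc_g_kg < 0, na.rm = TRUE)) stop("negative soc_g_kg", call. = FALSE)
  meas <- !is.na(x$bd_g_cm3)
  if (any(x$bd_g_cm3[meas] <= 0.1 | x$bd_g_cm3[meas] >= 2.5)) {
    stop("measured bulk density outside (0.1, 2.5) g/cm^3", call. = FALSE)
  }

  key <- paste(x$site_id, x$hz_top_m)
  if (anyDuplicated(key)) {
    stop("duplicate site/horizon keys at row(s) ", paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  }

  x <- dplyr::arrange(x, .data$site_id, .data$hz_top_m)
  overlap <- x |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      bad = any(.data$hz_top_m[-1] < .data$hz_bottom_m[-dplyr::n()]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$bad)
  if (nrow(overlap) > 0) {
    stop("overlapping horizons in site(s): ", paste(overlap$site_id, collapse = ", "), call. = FALSE)
  }

  flag_chk <- x |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      mixed = dplyr::n_distinct(.data$mattic) > 1,
      mattic = .data$mattic[1],
      depth_na = anyNA(.data$mattic_depth_m),
      depth = .data$mattic_depth_m[1],
      .groups = "drop"
    )
  if (any(flag_chk$mixed)) {
    stop("mattic flag varies within site(s): ",
      paste(flag_chk$site_id[flag_chk$mixed], collapse = ", "),
      call. = FALSE
    )
  }
  bad <- flag_chk$mattic == 1 & (flag_chk$depth_na | !(flag_chk$depth > 0.05))
  if (any(bad)) {
    stop("mattic sites need mattic_depth_m > 0.05 m: ",
      paste(flag_chk$site_id[bad], collapse = ", "),
      call. = FALSE
    )
  }
  if (any(flag_chk$mattic == 0 & !flag_chk$depth_na)) {
    stop("mattic_depth_m given for non-mattic site(s)", call. = FALSE)
  }

  x$bd_source <- ifelse(is.na(x$bd_g_cm3), "ptf", "measured")
  x$bd_g_cm3 <- ifelse(is.na(x$bd_g_cm3), estimate_bd_ptf(x$soc_g_kg, ptf), x$bd_g_cm3)
  x$soc_kg_m3 <- soc_mass_to_volume(x$soc_g_kg, x$bd_g_cm3, x$gravel_frac)
  x
}

#' Read and write pedon tables
#'
#' The on-disk format is a UTF-8 CSV with a header row and columns `site_id`,
#' `lat`, `lon`, `hz_top_m`, `hz_bottom_m`, `soc_g_kg`, `bd_g_cm3` (blank
#' where not measured), `gravel_frac`, `mattic` (0/1), `mattic_depth_m`
#' (blank for non-mattic sites). Depths are meters positive downward;
#' horizon intervals are half-open `[top, bottom)`. One row per genetic
#' horizon. On read the table is validated and completed via
#' [as_pedon_table()].
#'
#' @param path CSV file path.
#' @param ptf A [ptf_config()] for missing bulk densities.
#' @param pedons A pedon tibble (the write side drops derived columns so a
#'   read/write cycle round-trips).
#' @return `read_pedons()`: a validated pedon tibble.
#' @export
read_pedons <- function(path, ptf = ptf_config()) {
  # base-R parsing: correctly rounded numeric conversion keeps
  # write -> read cycles bit-identical
  raw <- utils::read.csv(path, colClasses = "character", check.names = TRUE)
  raw <- tibble::as_tibble(raw)
  for (nm in setdiff(intersect(pedon_columns, names(raw)), "site_id")) {
    v <- trimws(raw[[nm]])
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & nzchar(v) & !v %in% c("NA", "na"))
    if (length(bad) > 0) {
      stop(
        "non-numeric value in column '", nm, "' at row(s) ",
        paste(bad, collapse = ", "), " of ", path,
        call. = FALSE
      )
    }
    raw[[nm]] <- num
  }
  as_pedon_table(raw, ptf = ptf)
}

#' @rdname read_pedons
#' @export
write_pedons <- function(pedons, path) {
  out <- dplyr::select(tibble::as_tibble(pedons), dplyr::all_of(pedon_columns))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Check measurable mattic-epipedon criteria
#'
#' The mattic epipedon is identified in the field by expert judgment; this
#' check inspects the flagged layer against the two criteria measurable from
#' the data model — thickness > 5 cm and topmost-horizon bulk density within
#' 0.5–1.1 g/cm^3 — and reports advisory flags. It never overrides the input
#' `mattic` flag.
#'
#' @param pedons A validated pedon tibble ([as_pedon_table()]).
#' @return A tibble with one row per (mattic site, criterion): `site_id`,
#'   `criterion`, `value`, `pass`. Non-mattic sites contribute no rows.
#' @export
check_mattic_criteria <- function(pedons) {
  pedons <- tibble::as_tibble(pedons)
  if (!"soc_kg_m3" %in% names(pedons)) pedons <- as_pedon_table(pedons)
  sites <- pedons |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      mattic = .data$mattic[1],
      mattic_depth_m = .data$mattic_depth_m[1],
      top_bd = .data$bd_g_cm3[which.min(.data$hz_top_m)],
      .groups = "drop"
    ) |>
    dplyr::filter(.data$mattic == 1)
  if (nrow(sites) > 0 && anyNA(sites$mattic_depth_m)) {
    stop("mattic site without mattic_depth_m", call. = FALSE)
  }
  sites |>
    tidyr::pivot_longer(c("mattic_depth_m", "top_bd"),
      names_to = "criterion", values_to = "value"
    ) |>
    dplyr::mutate(
      criterion = dplyr::recode(.data$criterion,
        mattic_depth_m = "thickness_gt_5cm",
        top_bd = "bulk_density_0.5_1.1"
      ),
      pass = dplyr::if_else(.data$criterion == "thickness_gt_5cm",
        .data$value > 0.05,
        .data$value >= 0.5 & .data$value <= 1.1
      )
    ) |>
    dplyr::select("site_id", "criterion", "value", "pass")
}

#' Summarise pedons at site level
#'
#' One row per site with coordinates, mattic flag/depth and profile
#' description depth — the site-level view needed for covariate extraction
#' and model training.
#'
#' @param pedons A validated pedon tibble.
#' @return Tibble with `site_id`, `x` (lon), `y` (lat), `has_mattic`,
#'   `mattic_depth_m`, `max_depth_m`, `n_horizons`.
#' @export
pedon_sites <- function(pedons) {
  tibble::as_tibble(pedons) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      x = .data$lon[1],
      y = .data$lat[1],
      has_mattic = .data$mattic[1] == 1,
      mattic_depth_m = ifelse(.data$mattic[1] == 1, .data$mattic_depth_m[1], 0),
      max_depth_m = max(.data$hz_bottom_m),
      n_horizons = dplyr::n(),
      .groups = "drop"
    )
}
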