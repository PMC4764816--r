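#' Random-forest configuration
#'
#' Settings for the four depth-function parameter models: a classifier for
#' mattic occurrence and regressors for the natural logs of mattic depth,
#' `c_a` and `k`. Defaults follow common digital-soil-mapping practice for
#' this predictor set: 1000 trees, 4 candidate covariates per split for
#' classification and 6 for regression, and 100 repeated runs for
#' out-of-bag (OOB) summaries.
#'
#' @param ntree Number of trees per forest (>= 1).
#' @param mtry_class,mtry_reg Candidate covariates per split for the
#'   classifier / the regressors; capped at the number of covariates.
#' @param n_runs Number of re-seeded training runs for OOB summaries.
#' @param seed Base RNG seed; run `i` of a repeated procedure uses
#'   `seed + i - 1`.
#' @return An object of class `soc_rf_config`.
#' @export
rf_config <- function(ntree = 1000, mtry_class = 4, mtry_reg = 6, n_runs = 100, seed = 1) {
  stopifnot(ntree >= 1, mtry_class >= 1, mtry_reg >= 1, n_runs >= 1)
  structure(
    list(
      ntree = as.integer(ntree), mtry_class = as.integer(mtry_class),
      mtry_reg = as.integer(mtry_reg), n_runs = as.integer(n_runs),
      seed = as.integer(seed)
    ),
    class = "soc_rf_config"
  )
}

check_covariates <- function(tbl, covariates) {
  missing_cov <- setdiff(covariates, names(tbl))
  if (length(missing_cov) > 0) {
    stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  if (anyNA(tbl[covariates])) stop("covariate values must not be missing", call. = FALSE)
  invisible(tbl)
}

#' Train the mattic-occurrence classifier
#'
#' Random-forest classifier (bootstrap-aggregated trees, `mtry_class`
#' candidate covariates per split) for presence of the mattic epipedon.
#' Trained as a probability forest; the OOB error rate is the
#' misclassification rate of OOB probability votes, with exact 50/50 ties
#' broken toward "no mattic" (conservative and deterministic).
#'
#' @param tbl Training tibble: covariate columns plus logical/0-1
#'   `has_mattic`.
#' @param cfg An [rf_config()].
#' @param covariates Covariate column names (defaults to
#'   [soc_covariate_names()] intersected with `tbl`).
#' @return An object of class `soc_rf`: fields `model` (ranger forest),
#'   `type = "classification"`, `covariates`, `oob` (OOB error rate),
#'   `oob_statistic = "error_rate"`.
#' @export
train_mattic_classifier <- function(tbl, cfg = rf_config(), covariates = NULL) {
  tbl <- tibble::as_tibble(tbl)
  if (is.null(covariates)) covariates <- intersect(soc_covariate_names(), names(tbl))
  check_covariates(tbl, covariates)
  if (!"has_mattic" %in% names(tbl)) stop("tbl needs a has_mattic column", call. = FALSE)
  y <- factor(as.logical(tbl$has_mattic), levels = c(FALSE, TRUE))
  if (dplyr::n_distinct(y) < 2) stop("training data contain a single class", call. = FALSE)

  fit <- ranger::ranger(
    x = as.data.frame(tbl[covariates]), y = y,
    num.trees = cfg$ntree, mtry = min(cfg$mtry_class, length(covariates)),
    probability = TRUE, importance = "permutation",
    seed = cfg$seed, num.threads = 1
  )
  oob_prob <- fit$predictions[, "TRUE"]
  oob_class <- oob_prob > 0.5 # ties (== 0.5) fall to "no mattic"
  oob_error <- mean(oob_class != as.logical(y), na.rm = TRUE)

  structure(
    list(
      model = fit, type = "classification", covariates = covariates,
      transform = "identity", oob = oob_error, oob_statistic = "error_rate",
      seed = cfg$seed
    ),
    class = "soc_rf"
  )
}

#' Train a depth-function parameter regressor
#'
#' Random-forest regressor on the natural log of a strictly positive target
#' (mattic depth, `c_a` or `k`). Predictions are averaged across trees on
#' the log scale; the OOB mean square error is reported on the log scale.
#'
#' @param tbl Training tibble with covariates and the target column.
#' @param target Name of the (untransformed, strictly positive) target
#'   column.
#' @param cfg An [rf_config()].
#' @param covariates Covariate column names (default as in
#'   [train_mattic_classifier()]).
#' @return An object of class `soc_rf` with `type = "regression"`,
#'   `transform = "log"`, `oob` (OOB MSE, log scale), `oob_statistic =
#'   "mse"`.
#' @export
train_param_regressor <- function(tbl, target, cfg = rf_config(), covariates = NULL) {
  tbl <- tibble::as_tibble(tbl)
  if (is.null(covariates)) covariates <- intersect(soc_covariate_names(), names(tbl))
  check_covariates(tbl, covariates)
  if (!target %in% names(tbl)) stop("target column '", target, "' not found", call. = FALSE)
  yraw <- tbl[[target]]
  bad <- which(!(yraw > 0))
  if (length(bad) > 0) {
    who <- if ("site_id" %in% names(tbl)) paste(tbl$site_id[bad], collapse = ", ") else paste(bad, collapse = ", ")
    stop("non-positive '", target, "' at: ", who, call. = FALSE)
  }
  if (nrow(tbl) < 20) stop("need at least 20 training rows", call. = FALSE)

  fit <- ranger::ranger(
    x = as.data.frame(tbl[covariates]), y = log(yraw),
    num.trees = cfg$ntree, mtry = min(cfg$mtry_reg, length(covariates)),
    importance = "permutation",
    seed = cfg$seed, num.threads = 1
  )
  structure(
    list(
      model = fit, type = "regression", covariates = covariates,
      transform = "log", target = target,
      oob = fit$prediction.error, oob_statistic = "mse",
      seed = cfg$seed
    ),
    class = "soc_rf"
  )
}

#' @export
print.soc_rf <- function(x, ...) {
  cat(sprintf(
    "<soc_rf> %s forest, %d trees, %d covariates; OOB %s = %.4f\n",
    x$type, x$model$num.trees, length(x$covariates), x$oob_statistic, x$oob
  ))
  invisible(x)
}

#' Train the full depth-function model set
#'
#' Trains the four models that carry the depth function across space: the
#' mattic-occurrence classifier (all sites), the log mattic-depth regressor
#' (mattic-bearing sites only — depth is undefined elsewhere), and log `c_a`
#' and log `k` regressors (all sites).
#'
#' @param tbl Training tibble with covariates plus `has_mattic`, `d_mat_m`,
#'   `c_a_kg_m3`, `k_per_m` (the fit-table names of [fit_depth_functions()]).
#' @param cfg An [rf_config()].
#' @param covariates Covariate column names.
#' @return An object of class `soc_model_set`: the four `soc_rf` models, the
#'   covariate list and the configuration.
#' @export
train_model_set <- function(tbl, cfg = rf_config(), covariates = NULL) {
  tbl <- tibble::as_tibble(tbl)
  if (is.null(covariates)) covariates <- intersect(soc_covariate_names(), names(tbl))
  need <- c("has_mattic", "d_mat_m", "c_a_kg_m3", "k_per_m")
  if (!all(need %in% names(tbl))) {
    stop("training table needs columns: ", paste(setdiff(need, names(tbl)), collapse = ", "), call. = FALSE)
  }
  mattic_tbl <- dplyr::filter(tbl, as.logical(.data$has_mattic))
  structure(
    list(
      occurrence = train_mattic_classifier(tbl, cfg, covariates),
      d_mat = train_param_regressor(mattic_tbl, "d_mat_m", cfg, covariates),
      c_a = train_param_regressor(tbl, "c_a_kg_m3", cfg, covariates),
      k = train_param_regressor(tbl, "k_per_m", cfg, covariates),
      covariates = covariates,
      cfg = cfg
    ),
    class = "soc_model_set"
  )
}

#' @export
print.soc_model_set <- function(x, ...) {
  cat("<soc_model_set> four random-forest models\n")
  cat(sprintf("  occurrence : OOB error rate %.3f\n", x$occurrence$oob))
  cat(sprintf("  log d_mat  : OOB MSE %.3f\n", x$d_mat$oob))
  cat(sprintf("  log c_a    : OOB MSE %.3f\n", x$c_a$oob))
  cat(sprintf("  log k      : OOB MSE %.3f\n", x$k$oob))
  invisible(x)
}

seven_number_summary <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(
    min = min(v), q1 = q[1], mean = mean(v), median = q[2],
    q3 = q[3], max = max(v), sd = stats::sd(v)
  )
}

#' Repeated-run out-of-bag summary
#'
#' Re-trains a model `n_runs` times with seeds `seed + 0, ..., seed +
#' n_runs - 1` and summarises the OOB statistic (error rate or MSE) with the
#' seven order/shape statistics (min, 1st quartile, mean, median, 3rd
#' quartile, max, SD). The spread across runs isolates the Monte-Carlo
#' variability of the forest itself.
#'
#' @param trainer A function `(tbl, cfg) -> soc_rf`, e.g.
#'   [train_mattic_classifier()] or a wrapper around
#'   [train_param_regressor()].
#' @param tbl Training table passed to the trainer.
#' @param cfg An [rf_config()]; `n_runs >= 2`.
#' @return A one-row tibble: `statistic`, `n_runs`, and the seven summary
#'   columns.
#' @export
repeat_oob <- function(trainer, tbl, cfg = rf_config()) {
  if (cfg$n_runs < 2) stop("n_runs must be >= 2", call. = FALSE)
  runs <- purrr::map(seq_len(cfg$n_runs) - 1L, function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    trainer(tbl, cfg_i)
  })
  vals <- purrr::map_dbl(runs, "oob")
  dplyr::bind_cols(
    tibble::tibble(statistic = runs[[1]]$oob_statistic, n_runs = cfg$n_runs),
    seven_number_summary(vals)
  )
}

#' Repeated OOB summaries for the whole model set
#'
#' Convenience wrapper applying [repeat_oob()] to all four models of the
#' depth-function set, yielding the standard four-row error-estimate table
#' (occurrence error rate; log-scale MSE for mattic depth, `c_a`, `k`).
#'
#' @inheritParams train_model_set
#' @return A tibble with rows `mattic_occurrence`, `log_d_mat`, `log_c_a`,
#'   `log_k`.
#' @export
repeat_oob_model_set <- function(tbl, cfg = rf_config(), covariates = NULL) {
  tbl <- tibble::as_tibble(tbl)
  if (is.null(covariates)) covariates <- intersect(soc_covariate_names(), names(tbl))
  mattic_tbl <- dplyr::filter(tbl, as.logical(.data$has_mattic))
  force(covariates)
  rows <- list(
    mattic_occurrence = repeat_oob(function(d, c) train_mattic_classifier(d, c, covariates), tbl, cfg),
    log_d_mat = repeat_oob(function(d, c) train_param_regressor(d, "d_mat_m", c, covariates), mattic_tbl, cfg),
    log_c_a = repeat_oob(function(d, c) train_param_regressor(d, "c_a_kg_m3", c, covariates), tbl, cfg),
    log_k = repeat_oob(function(d, c) train_param_regressor(d, "k_per_m", c, covariates), tbl, cfg)
  )
  dplyr::bind_rows(rows, .id = "model")
}

#' Permutation variable importance
#'
#' Importance of each covariate as the permutation measure computed during
#' training: the increase in OOB prediction error (Brier score for the
#' probability classifier, MSE for regressors) when the covariate's values
#' are permuted, averaged over trees. Deterministic given the training seed.
#'
#' @param model A `soc_rf` or a `soc_model_set` (then one table per model is
#'   returned, bound with a `model` column).
#' @return Tibble `covariate`, `importance`, ranked descending.
#' @export
variable_importance <- function(model) {
  if (inherits(model, "soc_model_set")) {
    parts <- purrr::map(
      model[c("occurrence", "d_mat", "c_a", "k")],
      variable_importance
    )
    return(dplyr::bind_rows(parts, .id = "model"))
  }
  stopifnot(inherits(model, "soc_rf"))
  imp <- ranger::importance(model$model)
  tibble::tibble(covariate = names(imp), importance = as.numeric(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Predict depth-function parameters for covariate rows
#'
#' Applies the four models to new covariate rows. Occurrence is the majority
#' probability vote (ties toward "no mattic"); the three regressors predict
#' on the log scale and are back-transformed with `exp` (naive
#' back-transform, no bias correction), which guarantees strictly positive
#' `c_a` and `k`. Predicted `d_mat` is forced to 0 where occurrence is
#' negative. Rows containing missing covariates are flagged (`nodata`) and
#' get NA parameters.
#'
#' @param models A [train_model_set()] result.
#' @param newdata Tibble of covariate rows (names and meaning must match
#'   training; extra columns are ignored).
#' @return Tibble `has_mattic`, `p_mattic`, `d_mat_m`, `c_a_kg_m3`,
#'   `k_per_m`, `nodata`, one row per input row.
#' @export
predict_parameters <- function(models, newdata) {
  stopifnot(inherits(models, "soc_model_set"))
  newdata <- tibble::as_tibble(newdata)
  missing_cov <- setdiff(models$covariates, names(newdata))
  if (length(missing_cov) > 0) {
    stop("newdata lacks covariate(s): ", paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(newdata[models$covariates])
  ok <- stats::complete.cases(x)
  out <- tibble::tibble(
    has_mattic = rep(NA, nrow(x)),
    p_mattic = rep(NA_real_, nrow(x)),
    d_mat_m = rep(NA_real_, nrow(x)),
    c_a_kg_m3 = rep(NA_real_, nrow(x)),
    k_per_m = rep(NA_real_, nrow(x)),
    nodata = !ok
  )
  if (!any(ok)) {
    return(out)
  }
  xv <- x[ok, , drop = FALSE]
  p <- stats::predict(models$occurrence$model, data = xv, num.threads = 1)$predictions[, "TRUE"]
  hm <- p > 0.5
  dm <- exp(stats::predict(models$d_mat$model, data = xv, num.threads = 1)$predictions)
  ca <- exp(stats::predict(models$c_a$model, data = xv, num.threads = 1)$predictions)
  kk <- exp(stats::predict(models$k$model, data = xv, num.threads = 1)$predictions)
  out$has_mattic[ok] <- hm
  out$p_mattic[ok] <- p
  out$d_mat_m[ok] <- ifelse(hm, dm, 0)
  out$c_a_kg_m3[ok] <- ca
  out$k_per_m[ok] <- kk
  out
}

#' Persist and restore a trained model set
#'
#' Writes the four forests to a directory together with a `manifest.json`
#' recording the covariate list, the target transforms and the
#' configuration.
#'
#' @param models A `soc_model_set`.
#' @param dir Directory (created if needed).
#' @return `read_model_set()` returns the restored `soc_model_set`.
#' @export
write_model_set <- function(models, dir) {
  stopifnot(inherits(models, "soc_model_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  parts <- c("occurrence", "d_mat", "c_a", "k")
  for (p in parts) saveRDS(models[[p]], file.path(dir, paste0(p, ".rds")))
  manifest <- list(
    covariates = models$covariates,
    transforms = purrr::map_chr(models[parts], "transform"),
    cfg = unclass(models$cfg),
    files = as.list(stats::setNames(paste0(parts, ".rds"), parts))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_model_set
#' @export
read_model_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  parts <- purrr::map(manifest$files, function(f) readRDS(file.path(dir, f)))
  structure(
    c(parts, list(
      covariates = manifest$covariates,
      cfg = do.call(rf_config, as.list(manifest$cfg))
    )),
    class = "soc_model_set"
  )
}
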