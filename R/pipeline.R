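## End-to-end orchestration of the per-sample workflow and the
## twelve-sample study layout.

#' Run the full spatial-econometric workflow on one sample of units
#'
#' Order of operations: variable construction, exclusion filter,
#' log/standardize, collinearity screen, simple regressions,
#' backwards-BIC OLS, SOI weights on the surviving units' centroids,
#' residual diagnostics, the specification ladder, and the selected
#' model's impacts and global measures. The spatial models use the
#' OLS-stage selected variable set.
#'
#' @param units Tibble of raw unit records (attributes plus centroids;
#'   run [project_and_measure()] first when starting from geographic
#'   geometry).
#' @param sample_id Optional label, e.g. `"ZAM:micro"`.
#' @param ppfa_mode Population-pressure convention, see
#'   [compute_variables()].
#' @param collinearity_threshold Absolute correlation triggering the
#'   screen (default 0.6).
#' @param alpha Significance level of the specification decision.
#' @param metric Distance metric for the SOI graph: `"planar"` for
#'   projected within-country samples, `"geodesic"` for pooled
#'   pantropical samples in geographic coordinates.
#' @return A `sample_run` object bundling every stage's result.
#' @export
run_sample <- function(units, sample_id = NULL,
                       ppfa_mode = "per_forest_area",
                       collinearity_threshold = 0.6,
                       alpha = 0.05,
                       metric = c("planar", "geodesic")) {
  metric <- match.arg(metric)
  vars <- compute_variables(units, ppfa_mode = ppfa_mode)
  filt <- exclusion_filter(vars)
  frame <- transform_and_standardize(filt$kept, sample_id = sample_id)
  screen <- collinearity_screen(frame, threshold = collinearity_threshold)
  r2 <- simple_regressions(frame)
  step <- stepwise_bic(frame$X_std[, screen$retained, drop = FALSE],
                       frame$FC_star)
  coords <- as.matrix(filt$kept[, if (metric == "planar") c("x", "y")
                                else c("lon", "lat")])
  rownames(coords) <- frame$units
  w <- soi_weights(coords, metric = metric)
  if (length(step$variables) == 0) {
    abort("stepwise selection kept no variables; cannot specify a spatial model")
  }
  diag_res <- spatial_diagnostics(step, w)
  spec <- specify_model(frame$X_std[, step$variables, drop = FALSE], w,
                        frame$FC_star, alpha = alpha)
  final <- spec$fits[[spec$selected]]
  structure(list(
    sample_id = sample_id,
    n = frame$units |> length(),
    variables = vars,
    exclusions = filt$excluded,
    frame = frame,
    screen = screen,
    simple_r2 = r2,
    ols = step,
    weights = w,
    weights_summary = summarize_weights(w),
    diagnostics = diag_res,
    specification = spec,
    selected = spec$selected,
    final = final
  ), class = "sample_run")
}

#' @exportS3Method base::print
print.sample_run <- function(x, ...) {
  cat("<sample_run>", x$sample_id %||% "", "\n")
  cat("  units kept:", length(x$frame$units),
      " excluded:", nrow(x$exclusions), "\n")
  cat("  screened out:", paste(x$screen$dropped$variable, collapse = ", "),
      "\n")
  cat("  OLS variables:", paste(x$ols$variables, collapse = ", "), "\n")
  cat("  selected model:", x$selected, "\n")
  invisible(x)
}

#' @export
glance.sample_run <- function(x, ...) {
  fit <- x$final
  lam <- if (inherits(fit, "spatial_fit")) fit$lambda else NA_real_
  tibble(sample_id = x$sample_id %||% NA_character_,
         n = length(x$frame$units),
         n_excluded = nrow(x$exclusions),
         selected = x$selected,
         lambda = lam,
         loglik = fit$loglik,
         adj_r_squared = fit$measures$adj_r_squared,
         SER = fit$measures$SER,
         moran_sd = x$diagnostics$moran$sd)
}

#' Run the workflow over a collection of samples
#'
#' Applies [run_sample()] to each element; a failing sample is recorded
#' as an error entry and the remaining samples continue.
#'
#' @param samples Named list of raw unit tibbles (names become sample
#'   ids, conventionally `"COUNTRY:level"`).
#' @param ... Passed to [run_sample()]; `metric` is chosen per sample:
#'   geodesic when the sample id starts with `"PAN"`, planar otherwise,
#'   unless overridden.
#' @return An `fc_study` list with `runs` (per-sample results or error
#'   records) and `summary` (one glance row per successful sample).
#' @export
run_all <- function(samples, ...) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  dots <- list(...)
  runs <- purrr::imap(samples, function(u, id) {
    args <- c(list(units = u, sample_id = id), dots)
    if (is.null(dots$metric)) {
      args$metric <- if (startsWith(id, "PAN")) "geodesic" else "planar"
    }
    tryCatch(do.call(run_sample, args),
             error = function(e) {
               structure(list(sample_id = id, error = conditionMessage(e)),
                         class = "sample_error")
             })
  })
  ok <- !vapply(runs, inherits, logical(1), "sample_error")
  summary <- dplyr::bind_rows(purrr::map(runs[ok], glance))
  failed <- purrr::map_chr(runs[!ok], "error")
  if (length(failed)) {
    warn(paste0("sample(s) failed: ",
                paste(names(failed), failed, sep = ": ",
                      collapse = "; ")))
  }
  structure(list(runs = runs, summary = summary), class = "fc_study")
}

#' @exportS3Method base::print
print.fc_study <- function(x, ...) {
  cat("<fc_study>", length(x$runs), "samples\n")
  print(x$summary)
  invisible(x)
}

#' Reproduce the twelve-sample cross-country analysis from deposited data
#'
#' Expects a directory with one CSV per country/level sample named
#' `<COUNTRY>_<level>.csv` (columns: `unit_id`, `lon`, `lat` or `x`, `y`,
#' and the raw attributes `A_TOT`, `FA`, `FA_pot`, `P_TOT`, `R_TOT`,
#' `FL_TOT`, `CSI`, optionally `CY`). Pantropical samples are pooled from
#' the three countries at each level and use geodesic distances.
#'
#' @param data_dir Directory holding the per-sample attribute tables.
#' @param ... Passed to [run_sample()].
#' @return An `fc_study` over the twelve samples.
#' @export
reproduce_study <- function(data_dir, ...) {
  if (!dir.exists(data_dir)) {
    abort(paste0("deposited geodatabase not found at '", data_dir, "'"))
  }
  samples <- list()
  per_country <- list()
  for (lv in fd_levels) {
    for (cty in fd_countries) {
      path <- file.path(data_dir, paste0(cty, "_", lv, ".csv"))
      if (!file.exists(path)) {
        abort(paste0("missing sample table: ", path))
      }
      u <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
      if (!all(c("x", "y") %in% names(u))) u <- project_and_measure(u)
      samples[[paste0(cty, ":", lv)]] <- u
      per_country[[lv]] <- c(per_country[[lv]], list(u))
    }
    pooled <- dplyr::bind_rows(per_country[[lv]])
    if (!all(c("lon", "lat") %in% names(pooled))) {
      abort("pantropical pooling needs geographic lon/lat coordinates")
    }
    samples[[paste0("PAN:", lv)]] <- pooled
  }
  run_all(samples, ...)
}

#' Write a sample run's result tables to a directory
#'
#' Emits the exclusion report, screen report, OLS coefficients, weights
#' summary and GAL file, diagnostics, specification table and the final
#' model's coefficient/impact tables as CSV, plus a JSON manifest.
#'
#' @param run A `sample_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) {
    readr::write_csv(x, file.path(dir, paste0(name, ".csv")),
                     progress = FALSE)
  }
  wcsv(run$exclusions, "exclusions")
  wcsv(run$screen$dropped, "screen_dropped")
  wcsv(run$simple_r2, "simple_regressions")
  wcsv(tidy(run$ols), "ols_coefficients")
  wcsv(dplyr::select(run$weights_summary, -"neighbor_histogram"),
       "weights_summary")
  write_gal(run$weights, file.path(dir, "weights.gal"))
  wcsv(tidy(run$diagnostics), "diagnostics")
  sp <- tidy(run$specification)
  sp$code <- significance_code(sp$p_value)
  wcsv(sp, "specification")
  wcsv(tidy(run$final), "final_coefficients")
  if (inherits(run$final, "spatial_fit")) {
    wcsv(run$final$impacts, "final_impacts")
  }
  wcsv(glance(run$final), "global_measures")
  jsonlite::write_json(
    list(sample_id = run$sample_id, n = length(run$frame$units),
         selected = run$selected,
         ols_variables = run$ols$variables,
         screened_out = run$screen$dropped$variable),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
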