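## Response and driver construction, exclusion filter, log/standardize.

#' Build the response and driver variables from raw unit attributes
#'
#' Computes forest cover `FC = FA / FA_pot` and the seven driver variables
#' from the raw per-unit quantities:
#' \describe{
#'   \item{A_TOT}{total unit area, hectares (passed through)}
#'   \item{PVA}{share of potentially forested area, `FA_pot / A_TOT`}
#'   \item{PP_FA}{population pressure, `P_TOT / FA` (persons per hectare of
#'     remaining forest; `ppfa_mode = "per_total_area"` switches to
#'     `P_TOT / A_TOT`)}
#'   \item{RD}{road density, `R_TOT / A_TOT` with area in km^2 (km/km^2)}
#'   \item{FL}{flatness, share of area under 16% slope, `FL_TOT / A_TOT`}
#'   \item{CSI}{crop suitability index, passed through}
#'   \item{CY}{maximum cereal caloric yield, passed through when present}
#' }
#' Units with `FA_pot = 0` get `FC = NA` and are flagged for the exclusion
#' filter rather than raising an error.
#'
#' @param units Tibble of unit records with raw attribute columns `A_TOT`,
#'   `FA`, `FA_pot`, `P_TOT`, `R_TOT`, `FL_TOT`, `CSI` and optionally `CY`,
#'   plus identifier and centroid columns which are carried through.
#' @param ppfa_mode Denominator for population pressure; the default uses
#'   the remaining forest area.
#' @return Tibble with identifier/centroid columns, `FC`, and the driver
#'   variables in canonical order.
#' @export
compute_variables <- function(units,
                              ppfa_mode = c("per_forest_area",
                                            "per_total_area")) {
  ppfa_mode <- match.arg(ppfa_mode)
  req <- c("A_TOT", "FA", "FA_pot", "P_TOT", "R_TOT", "FL_TOT", "CSI")
  miss <- setdiff(req, names(units))
  if (length(miss)) {
    abort(paste0("missing raw attribute column(s): ",
                 paste(miss, collapse = ", ")))
  }
  keep <- intersect(c("unit_id", "country", "level", "x", "y", "lon", "lat"),
                    names(units))
  out <- dplyr::select(as_tibble(units), dplyr::all_of(keep))
  out$FC <- ifelse(units$FA_pot > 0, units$FA / units$FA_pot, NA_real_)
  out$A_TOT <- units$A_TOT
  out$PVA <- units$FA_pot / units$A_TOT
  out$PP_FA <- if (ppfa_mode == "per_forest_area") {
    ifelse(units$FA > 0, units$P_TOT / units$FA, NA_real_)
  } else {
    units$P_TOT / units$A_TOT
  }
  out$RD <- units$R_TOT / (units$A_TOT / 100)   # A_TOT ha -> km^2
  out$FL <- units$FL_TOT / units$A_TOT
  out$CSI <- units$CSI
  if ("CY" %in% names(units)) out$CY <- units$CY
  out
}

#' Maximum cereal caloric yield per unit
#'
#' For each unit, takes the arithmetic mean of the trailing ten years of
#' area yield (t/ha) per crop, converts to caloric yield with per-crop
#' factors, and keeps the maximum over crops — the crop most likely grown
#' in the unit. Units with no yield data in the window get `NA`.
#'
#' @param yields Long tibble with columns `unit_id`, `crop`, `year`,
#'   `yield_t_ha`.
#' @param kcal_per_tonne Named vector of caloric conversion factors
#'   (kcal per tonne) per crop. There is no universal constant; the
#'   defaults follow common food-energy conversion tables for maize and
#'   rice and should be set explicitly for reproduction runs.
#' @param reference_year Last year of the ten-year averaging window.
#' @return Tibble with `unit_id` and `CY` (kcal/ha, `NA` when absent).
#' @export
compute_cereal_yield <- function(yields,
                                 kcal_per_tonne = c(maize = 3.58e6,
                                                    rice = 2.80e6),
                                 reference_year) {
  stopifnot(all(c("unit_id", "crop", "year", "yield_t_ha") %in%
                  names(yields)))
  window <- (reference_year - 9):reference_year
  inside <- dplyr::filter(yields, .data$year %in% window,
                          .data$crop %in% names(kcal_per_tonne),
                          !is.na(.data$yield_t_ha))
  if (nrow(inside) == 0) {
    return(tibble(unit_id = character(), CY = numeric()))
  }
  inside |>
    dplyr::group_by(.data$unit_id, .data$crop) |>
    dplyr::summarise(mean_yield = mean(.data$yield_t_ha), .groups = "drop") |>
    dplyr::mutate(cal = .data$mean_yield *
                    unname(kcal_per_tonne[.data$crop])) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(CY = max(.data$cal), .groups = "drop")
}

#' Drop units with missing, nil or non-linearizable extreme values
#'
#' The logistic linearization is undefined at `FC = 0` and `FC = 1`, and
#' the log transform is undefined at zero; units with `FC` outside the open
#' unit interval, or with `PVA`, `CSI` or `RD` equal to zero or missing,
#' are dismissed. Zeros in other variables are left to model selection.
#'
#' @param vars Variable tibble from [compute_variables()].
#' @return List with `kept` (surviving tibble) and `excluded` (tibble of
#'   `unit_id` and semicolon-separated `reason`).
#' @export
exclusion_filter <- function(vars) {
  reasons <- purrr::pmap_chr(
    list(vars$FC, vars$PVA, vars$CSI, vars$RD),
    function(fc, pva, csi, rd) {
      r <- character()
      if (is.na(fc)) r <- c(r, "FC missing")
      else if (fc <= 0) r <- c(r, "FC nil")
      else if (fc >= 1) r <- c(r, "FC extreme")
      for (nm in c("PVA", "CSI", "RD")) {
        v <- switch(nm, PVA = pva, CSI = csi, RD = rd)
        if (is.na(v)) r <- c(r, paste(nm, "missing"))
        else if (v == 0) r <- c(r, paste(nm, "nil"))
      }
      paste(r, collapse = "; ")
    })
  drop <- reasons != ""
  kept <- vars[!drop, , drop = FALSE]
  if (nrow(kept) == 0) abort("no units survive the exclusion filter")
  excluded <- tibble(unit_id = vars$unit_id[drop], reason = reasons[drop])
  list(kept = kept, excluded = excluded)
}

#' Logistic linearization of forest cover
#'
#' `FC* = ln(1/FC - 1)`, mapping the sigmoid forest-transition response to
#' an unbounded linear-model scale. Strictly decreasing in `FC`: low
#' forest cover maps to large positive values.
#'
#' @param fc Numeric vector strictly inside (0, 1).
#' @return Numeric vector of linearized responses.
#' @export
linearize_response <- function(fc) {
  if (any(!is.finite(fc)) || any(fc <= 0) || any(fc >= 1)) {
    abort("FC must be strictly inside (0, 1); run exclusion_filter() first")
  }
  log(1 / fc - 1)
}

#' Log-transform and standardize driver variables into a sample frame
#'
#' Applies the natural log to each driver variable and standardizes the
#' logs to zero mean and unit standard deviation (sample, n-1 denominator)
#' within the sample. Pooled pantropical samples standardize over the
#' pooled units. Variables with missing values (e.g. `CY` in samples
#' lacking yield data) are dropped with a message; zero-variance variables
#' raise an error.
#'
#' @param vars Filtered variable tibble (output `kept` of
#'   [exclusion_filter()]).
#' @param sample_id Optional label (e.g. `"PAN:micro"`).
#' @return A `sample_frame` object: list with `units` (ids), `data` (the
#'   input tibble), `FC`, `FC_star`, matrices `X_raw`, `X_log`, `X_std`,
#'   and the standardization constants `mu`, `sigma`.
#' @export
transform_and_standardize <- function(vars, sample_id = NULL) {
  present <- intersect(fd_variables, names(vars))
  complete <- present[vapply(present, function(v) !anyNA(vars[[v]]),
                             logical(1))]
  dropped <- setdiff(present, complete)
  if (length(dropped)) {
    inform(paste0("dropping variable(s) with missing values: ",
                  paste(dropped, collapse = ", ")))
  }
  X_raw <- as.matrix(vars[, complete, drop = FALSE])
  if (any(X_raw <= 0)) {
    bad <- complete[apply(X_raw <= 0, 2, any)]
    abort(paste0("non-positive values block the log transform in: ",
                 paste(bad, collapse = ", ")))
  }
  X_log <- log(X_raw)
  mu <- colMeans(X_log)
  sigma <- apply(X_log, 2, sd)
  if (any(sigma == 0)) {
    abort(paste0("zero variance in variable(s): ",
                 paste(complete[sigma == 0], collapse = ", ")))
  }
  X_std <- sweep(sweep(X_log, 2, mu), 2, sigma, "/")
  ids <- if ("unit_id" %in% names(vars)) as.character(vars$unit_id) else
    as.character(seq_len(nrow(vars)))
  rownames(X_raw) <- rownames(X_log) <- rownames(X_std) <- ids
  structure(list(
    sample_id = sample_id,
    units = ids,
    data = vars,
    FC = vars$FC,
    FC_star = linearize_response(vars$FC),
    X_raw = X_raw,
    X_log = X_log,
    X_std = X_std,
    mu = mu,
    sigma = sigma
  ), class = "sample_frame")
}

#' @exportS3Method base::print
print.sample_frame <- function(x, ...) {
  cat("<sample_frame>", x$sample_id %||% "", "\n")
  cat("  units:", length(x$units), "\n")
  cat("  variables:", paste(colnames(x$X_std), collapse = ", "), "\n")
  cat("  FC in [", signif(min(x$FC), 3), ",", signif(max(x$FC), 3), "]\n")
  invisible(x)
}

#' Serialize a sample frame to CSV matrices plus a JSON manifest
#' @param frame A `sample_frame`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sample_frame <- function(frame, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, name) {
    readr::write_csv(tibble::rownames_to_column(as.data.frame(m), "unit_id"),
                     file.path(dir, paste0(name, ".csv")), progress = FALSE)
  }
  wr(frame$X_raw, "X_raw"); wr(frame$X_log, "X_log"); wr(frame$X_std, "X_std")
  readr::write_csv(tibble(unit_id = frame$units, FC = frame$FC,
                          FC_star = frame$FC_star),
                   file.path(dir, "response.csv"), progress = FALSE)
  jsonlite::write_json(
    list(sample_id = frame$sample_id, n = length(frame$units),
         mu = as.list(frame$mu), sigma = as.list(frame$sigma)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
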