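## Synthetic nested jurisdictional samples with known spatial structure.

default_covariate_spec <- function() {
  vars <- fd_variables
  meanlog <- c(A_TOT = log(2e4), PVA = log(0.5), PP_FA = log(2),
               RD = log(0.5), FL = log(0.4), CSI = log(40),
               CY = log(5e6))
  sdlog <- c(A_TOT = 0.5, PVA = 0.25, PP_FA = 0.8, RD = 0.5,
             FL = 0.3, CSI = 0.3, CY = 0.3)
  corr <- diag(7)
  dimnames(corr) <- list(vars, vars)
  ## population pressure and road density are strongly correlated in
  ## observed jurisdictional data; the default reproduces that feature
  corr["PP_FA", "RD"] <- corr["RD", "PP_FA"] <- 0.65
  list(meanlog = meanlog, sdlog = sdlog, corr = corr)
}

#' Define a synthetic-data scenario
#'
#' A scenario fixes everything about a generated sample: the spatial
#' layout, the log-normal covariate distributions (so the log transform
#' yields exactly Gaussian regressors), and the true data-generating
#' parameters of the spatial Durbin error process on the linearized
#' response. Defaults mirror the magnitudes seen in cross-country
#' forest-cover regressions: population pressure dominates, crop
#' suitability and potential vegetation contribute moderately, the error
#' process is positively autocorrelated.
#'
#' @param n_units Number of units.
#' @param layout `"uniform_random"` centroids or a regular `"grid"`.
#' @param extent Side length of the square study region in metres.
#' @param beta0 Intercept of the linear predictor on the linearized scale.
#' @param beta,theta Named vectors of direct and neighbor (lagged-X)
#'   coefficients over the canonical variables; unnamed entries default
#'   to zero.
#' @param lambda Spatial autoregressive error coefficient.
#' @param sigma Innovation standard deviation.
#' @param meanlog,sdlog,corr Log-scale covariate means, standard
#'   deviations and correlation matrix (canonical 7 variables).
#' @param ppfa_mode Population-pressure convention used when back-solving
#'   raw attributes.
#' @param country,level Labels stamped on the generated units.
#' @return An `fd_scenario` list.
#' @export
synthetic_scenario <- function(n_units = 400,
                               layout = c("uniform_random", "grid"),
                               extent = 1e5,
                               beta0 = 1,
                               beta = c(PVA = 0.2, PP_FA = 1.2,
                                        CSI = 0.15),
                               theta = c(PP_FA = 0.1, CSI = 0.2),
                               lambda = 0.5,
                               sigma = 0.5,
                               meanlog = NULL, sdlog = NULL, corr = NULL,
                               ppfa_mode = "per_forest_area",
                               country = "ZAM", level = "micro") {
  layout <- match.arg(layout)
  spec <- default_covariate_spec()
  meanlog <- modifyList(as.list(spec$meanlog), as.list(meanlog %||% list()))
  sdlog <- modifyList(as.list(spec$sdlog), as.list(sdlog %||% list()))
  corr <- corr %||% spec$corr
  full <- function(v) {
    out <- setNames(numeric(length(fd_variables)), fd_variables)
    out[names(v)] <- v
    out
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) abort("covariate correlation matrix must be positive definite")
  if (abs(lambda) >= 1) abort("lambda must lie inside (-1, 1)")
  structure(list(
    n_units = n_units, layout = layout, extent = extent,
    beta0 = beta0, beta = full(beta), theta = full(theta),
    lambda = lambda, sigma = sigma,
    meanlog = unlist(meanlog)[fd_variables],
    sdlog = unlist(sdlog)[fd_variables],
    corr = corr,
    ppfa_mode = ppfa_mode, country = country, level = level
  ), class = "fd_scenario")
}

draw_centroids <- function(scenario) {
  n <- scenario$n_units
  side <- scenario$extent
  if (scenario$layout == "grid") {
    nc <- ceiling(sqrt(n))
    g <- expand.grid(ix = seq_len(nc), iy = seq_len(nc))[seq_len(n), ]
    cbind(x = (g$ix - 0.5) * side / nc, y = (g$iy - 0.5) * side / nc)
  } else {
    cbind(x = runif(n, 0, side), y = runif(n, 0, side))
  }
}

draw_log_covariates <- function(n, meanlog, sdlog, corr) {
  L <- chol(corr * outer(sdlog, sdlog))
  z <- matrix(rnorm(n * length(meanlog)), n)
  sweep(z %*% L, 2, meanlog, "+")
}

#' Simulate the linearized response over a fixed design
#'
#' Draws `FC* = b0 + Xb + WX theta + u`, `u = (I - lambda W)^-1 eps`,
#' `eps ~ N(0, sigma^2)`, consuming only the innovation randomness —
#' useful for replication loops that keep the lattice and covariates
#' fixed.
#'
#' @param X_std Standardized covariate matrix.
#' @param w A `soi_weights` object.
#' @param beta0,beta,theta,lambda,sigma True parameters (`beta`/`theta`
#'   named over columns of `X_std`; missing names are zero).
#' @return Numeric vector of linearized responses.
#' @export
simulate_response <- function(X_std, w, beta0 = 0, beta = NULL,
                              theta = NULL, lambda = 0, sigma = 1) {
  n <- nrow(X_std)
  bv <- setNames(numeric(ncol(X_std)), colnames(X_std))
  tv <- bv
  if (!is.null(beta)) bv[names(beta)] <- beta
  if (!is.null(theta)) tv[names(theta)] <- theta
  eps <- rnorm(n, 0, sigma)
  u <- if (lambda == 0) eps else
    as.numeric(Matrix::solve(Diagonal(n) - lambda * w$W, eps))
  unname(drop(beta0 + X_std %*% bv +
                as.matrix(w$W %*% X_std) %*% tv + u))
}

#' Generate one synthetic sample of jurisdictional units
#'
#' Random number consumption order is fixed (centroids, then covariates,
#' then errors) so a seed pins the whole sample. The raw attributes are
#' back-solved from the generated variables so that [compute_variables()]
#' plus [transform_and_standardize()] reconstruct the generator's
#' standardized design exactly.
#'
#' @param scenario An `fd_scenario`.
#' @param seed Integer seed (same seed, same sample).
#' @return List with `units` (raw attribute tibble), `w` (the
#'   `soi_weights` used), and `truth` (true parameters, the standardized
#'   design, the linearized response and the scenario).
#' @export
generate_sample <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "fd_scenario"))
  set.seed(seed)
  n <- scenario$n_units
  coords <- draw_centroids(scenario)
  rownames(coords) <- sprintf("u%05d", seq_len(n))
  w <- soi_weights(coords, metric = "planar")
  Z <- draw_log_covariates(n, scenario$meanlog, scenario$sdlog,
                           scenario$corr)
  colnames(Z) <- fd_variables
  X_raw <- exp(Z)
  ## keep shares and the index inside their admissible ranges
  X_raw[, "PVA"] <- pmin(X_raw[, "PVA"], 0.99)
  X_raw[, "FL"] <- pmin(X_raw[, "FL"], 0.99)
  X_raw[, "CSI"] <- pmin(X_raw[, "CSI"], 100)
  X_log <- log(X_raw)
  X_std <- scale(X_log)[, , drop = FALSE]
  attr(X_std, "scaled:center") <- NULL
  attr(X_std, "scaled:scale") <- NULL
  fc_star <- simulate_response(X_std, w, scenario$beta0, scenario$beta,
                               scenario$theta, scenario$lambda,
                               scenario$sigma)
  fc <- 1 / (1 + exp(fc_star))
  a_tot <- X_raw[, "A_TOT"]
  fa_pot <- X_raw[, "PVA"] * a_tot
  fa <- fc * fa_pot
  p_tot <- if (scenario$ppfa_mode == "per_forest_area") {
    X_raw[, "PP_FA"] * fa
  } else {
    X_raw[, "PP_FA"] * a_tot
  }
  units <- tibble(
    unit_id = rownames(coords),
    country = scenario$country,
    level = scenario$level,
    x = coords[, "x"], y = coords[, "y"],
    A_TOT = a_tot,
    FA = fa,
    FA_pot = fa_pot,
    P_TOT = p_tot,
    R_TOT = X_raw[, "RD"] * a_tot / 100,
    FL_TOT = X_raw[, "FL"] * a_tot,
    CSI = X_raw[, "CSI"],
    CY = X_raw[, "CY"]
  )
  list(units = units, w = w,
       truth = list(beta0 = scenario$beta0, beta = scenario$beta,
                    theta = scenario$theta, lambda = scenario$lambda,
                    sigma = scenario$sigma, X_std = X_std,
                    FC_star = fc_star, scenario = scenario,
                    seed = seed))
}

## Split a rectangle into k near-square cells (rows x cols with
## rows * cols == k, rows the largest divisor <= sqrt(k)).
split_rect <- function(xmin, xmax, ymin, ymax, k) {
  nr <- floor(sqrt(k))
  while (k %% nr != 0) nr <- nr - 1
  nc <- k / nr
  g <- expand.grid(ic = seq_len(nc), ir = seq_len(nr))
  dx <- (xmax - xmin) / nc
  dy <- (ymax - ymin) / nr
  tibble(xmin = xmin + (g$ic - 1) * dx, xmax = xmin + g$ic * dx,
         ymin = ymin + (g$ir - 1) * dy, ymax = ymin + g$ir * dy)
}

#' Generate a nested macro/meso/micro sample hierarchy
#'
#' Micro units are generated first on a nested rectangular partition of
#' the study region (one random centroid per micro cell); meso and macro
#' units aggregate their children: extensive attributes (areas,
#' population, road length) are summed, intensive ones (CSI, CY) are
#' area-weighted means, centroids are area-weighted child centroids.
#' Cross-level conservation of every extensive quantity is exact.
#'
#' @param scenario An `fd_scenario` (its `n_units` is overridden by the
#'   branching product).
#' @param branching Integer vector `c(n_macro, meso_per_macro,
#'   micro_per_meso)`, factors at least 2 except the macro count.
#' @param seed Integer seed.
#' @return List with `macro`, `meso`, `micro` unit tibbles (children
#'   carry `macro_id`/`meso_id`), `w` (micro-level weights) and `truth`
#'   (micro-level generator record).
#' @export
generate_nested <- function(scenario, branching = c(4, 4, 8), seed = 1L) {
  stopifnot(length(branching) == 3, all(branching[2:3] >= 2))
  n_macro <- branching[1]
  n_meso <- n_macro * branching[2]
  n_micro <- n_meso * branching[3]
  side <- scenario$extent
  macro_cells <- split_rect(0, side, 0, side, n_macro)
  meso_cells <- purrr::pmap(macro_cells, function(xmin, xmax, ymin, ymax) {
    split_rect(xmin, xmax, ymin, ymax, branching[2])
  })
  meso_cells <- dplyr::bind_rows(meso_cells, .id = "macro_id")
  micro_cells <- purrr::pmap(
    meso_cells[, c("xmin", "xmax", "ymin", "ymax")],
    function(xmin, xmax, ymin, ymax) {
      split_rect(xmin, xmax, ymin, ymax, branching[3])
    })
  micro_cells <- dplyr::bind_rows(micro_cells, .id = "meso_row")
  micro_cells$macro_id <- meso_cells$macro_id[
    as.integer(micro_cells$meso_row)]
  micro_cells$meso_id <- micro_cells$meso_row

  scen <- scenario
  scen$n_units <- n_micro
  set.seed(seed)
  ## centroids first: one uniform draw per micro cell
  coords <- cbind(
    x = runif(n_micro, micro_cells$xmin, micro_cells$xmax),
    y = runif(n_micro, micro_cells$ymin, micro_cells$ymax))
  rownames(coords) <- sprintf("u%05d", seq_len(n_micro))
  w <- soi_weights(coords, metric = "planar")
  Z <- draw_log_covariates(n_micro, scen$meanlog, scen$sdlog, scen$corr)
  colnames(Z) <- fd_variables
  X_raw <- exp(Z)
  X_raw[, "PVA"] <- pmin(X_raw[, "PVA"], 0.99)
  X_raw[, "FL"] <- pmin(X_raw[, "FL"], 0.99)
  X_raw[, "CSI"] <- pmin(X_raw[, "CSI"], 100)
  X_std <- scale(log(X_raw))[, , drop = FALSE]
  fc_star <- simulate_response(X_std, w, scen$beta0, scen$beta,
                               scen$theta, scen$lambda, scen$sigma)
  fc <- 1 / (1 + exp(fc_star))
  a_tot <- X_raw[, "A_TOT"]
  fa_pot <- X_raw[, "PVA"] * a_tot
  fa <- fc * fa_pot
  p_tot <- if (scen$ppfa_mode == "per_forest_area") {
    X_raw[, "PP_FA"] * fa
  } else X_raw[, "PP_FA"] * a_tot
  micro <- tibble(
    unit_id = rownames(coords),
    macro_id = paste0("M", micro_cells$macro_id),
    meso_id = paste0("m", micro_cells$meso_id),
    country = scen$country, level = "micro",
    x = coords[, "x"], y = coords[, "y"],
    A_TOT = a_tot, FA = fa, FA_pot = fa_pot, P_TOT = p_tot,
    R_TOT = X_raw[, "RD"] * a_tot / 100,
    FL_TOT = X_raw[, "FL"] * a_tot,
    CSI = X_raw[, "CSI"], CY = X_raw[, "CY"]
  )
  aggregate_level <- function(children, id_col, level_name) {
    children |>
      dplyr::group_by(unit_id = .data[[id_col]]) |>
      dplyr::summarise(
        country = dplyr::first(.data$country),
        level = level_name,
        x = sum(.data$x * .data$A_TOT) / sum(.data$A_TOT),
        y = sum(.data$y * .data$A_TOT) / sum(.data$A_TOT),
        CSI = sum(.data$CSI * .data$A_TOT) / sum(.data$A_TOT),
        CY = sum(.data$CY * .data$A_TOT) / sum(.data$A_TOT),
        dplyr::across(dplyr::all_of(c("A_TOT", "FA", "FA_pot", "P_TOT",
                                      "R_TOT", "FL_TOT")), sum),
        .groups = "drop")
  }
  meso <- aggregate_level(micro, "meso_id", "meso")
  meso$macro_id <- micro$macro_id[match(meso$unit_id, micro$meso_id)]
  macro <- aggregate_level(micro, "macro_id", "macro")
  list(macro = macro, meso = meso, micro = micro, w = w,
       truth = list(beta0 = scen$beta0, beta = scen$beta,
                    theta = scen$theta, lambda = scen$lambda,
                    sigma = scen$sigma, X_std = X_std,
                    FC_star = fc_star, scenario = scen, seed = seed))
}
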