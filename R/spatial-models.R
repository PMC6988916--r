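## Maximum-likelihood estimation of the spatial error family:
## SLX (lagged-X OLS), SEM (autoregressive error), SDEM (both).

#' Eigenvalues of a row-standardized weights matrix
#'
#' Row-standardized weights built from a symmetric binary adjacency are
#' similar to the symmetric matrix `D^-1/2 A D^-1/2`, so their eigenvalues
#' are real; the largest is 1 and the smallest bounds the admissible
#' spatial coefficient interval from below (`1/min(eigen)`). Disconnected
#' blocks (pooled pantropical samples) are handled naturally: the spectrum
#' is the union of the blocks' spectra.
#'
#' @param w A `soi_weights` object.
#' @return Sorted numeric vector of eigenvalues.
#' @export
w_eigenvalues <- function(w) {
  adj <- w$adjacency
  deg <- base::rowSums(adj)
  s <- adj / sqrt(outer(deg, deg))
  sort(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
}

#' Log-determinant of (I - lambda W)
#'
#' Uses the real spectrum of the row-standardized weights
#' (`sum(log(1 - lambda * omega))`) for moderate sample sizes and a sparse
#' LU factorization above, where the dense eigendecomposition becomes the
#' bottleneck.
#'
#' @param w A `soi_weights` object.
#' @param lambda Spatial error coefficient, inside the admissible interval.
#' @param method `"eigen"`, `"lu"`, or `"auto"` (eigen up to n = 2000).
#' @param eigenvalues Optional precomputed [w_eigenvalues()] result.
#' @return `log det(I - lambda W)`.
#' @export
log_det <- function(w, lambda, method = c("auto", "eigen", "lu"),
                    eigenvalues = NULL) {
  method <- match.arg(method)
  n <- length(w$ids)
  if (method == "auto") {
    method <- if (!is.null(eigenvalues) || n <= 2000) "eigen" else "lu"
  }
  if (method == "eigen") {
    ev <- eigenvalues %||% w_eigenvalues(w)
    hold <- 1 - lambda * ev
    if (any(hold <= 0)) abort("I - lambda W is singular or indefinite")
    sum(log(hold))
  } else {
    a <- Diagonal(n) - lambda * w$W
    d <- Matrix::determinant(a, logarithm = TRUE)
    if (d$sign <= 0) abort("I - lambda W is singular or indefinite")
    as.numeric(d$modulus)
  }
}

## Shared packaging of the mean-parameter coefficient table.
coef_table <- function(est, se, n) {
  z <- est / se
  tibble(term = names(est), estimate = unname(est),
         std_error = unname(se), statistic = unname(z),
         p_value = 2 * pnorm(-abs(unname(z))))
}

## Direct/indirect/total impact decomposition for designs carrying lag_*
## columns; vc is the covariance of the mean parameters (incl intercept).
impact_table <- function(est, vc, variables) {
  rows <- purrr::map(variables, function(v) {
    lag_v <- paste0("lag_", v)
    i <- match(v, names(est))
    j <- match(lag_v, names(est))
    direct <- est[[i]]
    d_var <- vc[i, i]
    if (!is.na(j)) {
      indirect <- est[[j]]
      i_var <- vc[j, j]
      total <- direct + indirect
      t_var <- d_var + i_var + 2 * vc[i, j]
    } else {
      indirect <- NA_real_; i_var <- NA_real_
      total <- direct; t_var <- d_var
    }
    tibble(variable = v,
           direct = direct, direct_se = sqrt(d_var),
           indirect = indirect, indirect_se = sqrt(i_var),
           total = total, total_se = sqrt(t_var),
           total_z = total / sqrt(t_var),
           total_p = 2 * pnorm(-abs(total / sqrt(t_var))))
  })
  dplyr::bind_rows(rows)
}

new_spatial_fit <- function(kind, coefs, variables, lambda, lambda_se,
                            impacts, residuals, fitted, X, y, vcov,
                            loglik, n, k_model, r_squared) {
  structure(list(
    kind = kind, coefficients = coefs, variables = variables,
    lambda = lambda, lambda_se = lambda_se, impacts = impacts,
    residuals = residuals, fitted = fitted, X = X, y = y, vcov = vcov,
    loglik = loglik, n = n, k_model = k_model,
    measures = global_measures(loglik, residuals, n, k_model, r_squared)
  ), class = "spatial_fit")
}

#' Spatially lagged X (SLX) model
#'
#' OLS on the design augmented with the neighbor averages `WX`: direct
#' coefficients from the own-unit columns, indirect (theta) coefficients
#' from the lagged columns, total impacts as their sum.
#'
#' @param x A `sample_frame` or numeric matrix of regressors (no
#'   intercept).
#' @param w A `soi_weights` object aligned to the rows of `x`.
#' @param y Response (ignored for sample frames).
#' @param variables Optional subset of columns (lags are built for the
#'   same subset).
#' @return A `spatial_fit` of kind "SLX".
#' @export
slx_fit <- function(x, w, y = NULL, variables = NULL) {
  d <- frame_xy(x, y)
  X <- d$X
  if (!is.null(variables)) X <- X[, variables, drop = FALSE]
  WX <- as.matrix(w$W %*% X)
  colnames(WX) <- paste0("lag_", colnames(X))
  Z <- cbind(X, WX)
  base <- ols_fit(Z, d$y)
  est <- setNames(base$coefficients$estimate, base$coefficients$term)
  imp <- impact_table(est, base$vcov, colnames(X))
  coefs <- base$coefficients
  coefs$role <- c("intercept",
                  rep("direct", ncol(X)), rep("lag", ncol(WX)))
  new_spatial_fit("SLX", coefs, colnames(X), NA_real_, NA_real_, imp,
                  base$residuals, base$fitted, Z, d$y, base$vcov,
                  base$loglik, base$n, base$k_model,
                  base$measures$r_squared)
}

## Core SEM likelihood machinery shared by sem_fit and sdem_fit.
## Z: mean design without intercept; kind label decides impact handling.
sem_engine <- function(Z, w, y, kind, variables, se = TRUE,
                       eigenvalues = NULL, grid_n = 200) {
  n <- length(y)
  if (nrow(Z) != n || length(w$ids) != n) {
    abort("design, response and weights dimensions disagree")
  }
  ev <- eigenvalues %||% w_eigenvalues(w)
  lo <- 1 / min(ev) + 1e-6
  hi <- 1 - 1e-6
  Zd <- cbind(`(Intercept)` = 1, Z)
  if (qr(Zd)$rank < ncol(Zd)) abort("design matrix is rank deficient")
  Wy <- as.numeric(w$W %*% y)
  WZd <- as.matrix(w$W %*% Zd)

  conc <- function(lambda) {
    yt <- y - lambda * Wy
    Zt <- Zd - lambda * WZd
    f <- lm.fit(Zt, yt)
    s2 <- sum(f$residuals^2) / n
    -n / 2 * (log(2 * pi * s2) + 1) +
      sum(log(1 - lambda * ev))
  }
  ## coarse grid guards against local optima near the interval ends;
  ## zero is always included so nested non-spatial fits are dominated
  grid <- sort(unique(c(seq(lo, hi, length.out = grid_n), 0)))
  gv <- vapply(grid, conc, numeric(1))
  ib <- which.max(gv)
  bl <- grid[max(1, ib - 1)]
  bu <- grid[min(length(grid), ib + 1)]
  opt <- optimize(conc, c(bl, bu), maximum = TRUE, tol = 1e-8)
  if (gv[ib] > opt$objective) {
    opt <- list(maximum = grid[ib], objective = gv[ib])
  }
  lambda <- opt$maximum
  if (lambda <= lo + 1e-5 || lambda >= hi - 1e-7) {
    abort("spatial error coefficient hit the admissible boundary; the likelihood did not converge to an interior optimum")
  }

  yt <- y - lambda * Wy
  Zt <- Zd - lambda * WZd
  f <- lm.fit(Zt, yt)
  beta <- f$coefficients
  eps <- f$residuals                 # innovations
  s2 <- sum(eps^2) / n
  loglik <- opt$objective
  vc_beta <- s2 * solve(crossprod(Zt))
  dimnames(vc_beta) <- list(names(beta), names(beta))

  lambda_se <- NA_real_
  if (se) {
    full_ll <- function(par) {
      la <- par[1]
      be <- par[2:(1 + ncol(Zd))]
      sg2 <- exp(par[length(par)])
      res <- (y - la * Wy) - (Zd - la * WZd) %*% be
      -n / 2 * log(2 * pi * sg2) - sum(res^2) / (2 * sg2) +
        sum(log(1 - la * ev))
    }
    par_hat <- c(lambda, beta, log(s2))
    H <- pracma::hessian(full_ll, par_hat)
    vc_full <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(vc_full) && vc_full[1, 1] > 0) {
      lambda_se <- sqrt(vc_full[1, 1])
    }
  }

  trend <- as.numeric(Zd %*% beta)
  rho <- suppressWarnings(cor(trend, y))
  r2 <- if (is.na(rho)) 0 else rho^2
  roles <- c("intercept",
             ifelse(grepl("^lag_", colnames(Z)), "lag", "direct"))
  coefs <- coef_table(beta, sqrt(diag(vc_beta)), n)
  coefs$role <- roles
  lam_row <- tibble(term = "lambda", estimate = lambda,
                    std_error = lambda_se,
                    statistic = lambda / lambda_se,
                    p_value = 2 * pnorm(-abs(lambda / lambda_se)),
                    role = "lambda")
  imp <- impact_table(setNames(beta, colnames(Zd)), vc_beta, variables)
  k_model <- ncol(Zd) + 1   # mean parameters + lambda
  new_spatial_fit(kind, dplyr::bind_rows(coefs, lam_row), variables,
                  lambda, lambda_se, imp, eps, trend, Z, y, vc_beta,
                  loglik, n, k_model, r2)
}

#' Spatial error model (SEM) by maximum likelihood
#'
#' Estimates `y = Zb + u`, `u = lambda W u + e` by maximizing the
#' concentrated log-likelihood over the spatial error coefficient, with
#' the log-determinant from the real spectrum of the row-standardized
#' weights. Coefficient covariance is the GLS covariance at the estimated
#' lambda; the lambda standard error comes from the numerical Hessian of
#' the full likelihood.
#'
#' @inheritParams slx_fit
#' @param se Compute standard errors (disable in simulation loops).
#' @param eigenvalues Optional precomputed [w_eigenvalues()] (reuse across
#'   fits on the same weights).
#' @param grid_n Number of coarse-grid evaluations of the concentrated
#'   likelihood bracketing the optimizer (reduce in replication loops).
#' @return A `spatial_fit` of kind "SEM".
#' @export
sem_fit <- function(x, w, y = NULL, variables = NULL, se = TRUE,
                    eigenvalues = NULL, grid_n = 200) {
  d <- frame_xy(x, y)
  X <- d$X
  if (!is.null(variables)) X <- X[, variables, drop = FALSE]
  sem_engine(X, w, d$y, "SEM", colnames(X), se = se,
             eigenvalues = eigenvalues, grid_n = grid_n)
}

#' Spatial Durbin error model (SDEM) by maximum likelihood
#'
#' SEM estimation on the design augmented with the neighbor averages
#' `WX`. Impacts decompose exactly: direct = own-unit coefficient,
#' indirect = lagged coefficient, total = their sum, with the total's
#' variance from the GLS covariance including the cross term.
#'
#' @inheritParams sem_fit
#' @return A `spatial_fit` of kind "SDEM".
#' @export
sdem_fit <- function(x, w, y = NULL, variables = NULL, se = TRUE,
                     eigenvalues = NULL, grid_n = 200) {
  d <- frame_xy(x, y)
  X <- d$X
  if (!is.null(variables)) X <- X[, variables, drop = FALSE]
  WX <- as.matrix(w$W %*% X)
  colnames(WX) <- paste0("lag_", colnames(X))
  sem_engine(cbind(X, WX), w, d$y, "SDEM", colnames(X), se = se,
             eigenvalues = eigenvalues, grid_n = grid_n)
}

#' @exportS3Method base::print
print.spatial_fit <- function(x, ...) {
  cat("<spatial_fit>", x$kind, " n =", x$n,
      " logLik =", round(x$loglik, 2), "\n")
  if (!is.na(x$lambda)) {
    cat("  lambda =", round(x$lambda, 4),
        " (se", round(x$lambda_se, 4), ")\n")
  }
  print(x$coefficients)
  invisible(x)
}

#' @export
logLik.spatial_fit <- function(object, ...) {
  structure(object$loglik, df = object$k_model + 1, class = "logLik")
}

#' @export
tidy.spatial_fit <- function(x, effects = c("coefficients", "impacts"),
                             ...) {
  effects <- match.arg(effects)
  if (effects == "impacts") x$impacts else x$coefficients
}

#' @export
glance.spatial_fit <- function(x, ...) {
  dplyr::bind_cols(x$measures,
                   tibble(lambda = x$lambda, n = x$n, k = x$k_model,
                          kind = x$kind))
}
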