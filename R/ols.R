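## Collinearity screening, simple regressions, stepwise-backwards BIC, OLS.

frame_xy <- function(x, y = NULL) {
  if (inherits(x, "sample_frame")) {
    list(X = x$X_std, y = x$FC_star)
  } else {
    list(X = as.matrix(x), y = y)
  }
}

#' Per-variable simple regression fits
#'
#' R-squared of the response on each single variable (plus intercept) —
#' the yardstick used to decide which member of a collinear pair to keep.
#'
#' @param x A `sample_frame` or numeric matrix of regressors.
#' @param y Response vector (ignored when `x` is a sample frame).
#' @return Tibble with `variable` and `r_squared`.
#' @export
simple_regressions <- function(x, y = NULL) {
  d <- frame_xy(x, y)
  r2 <- apply(d$X, 2, function(col) {
    f <- lm.fit(cbind(1, col), d$y)
    1 - sum(f$residuals^2) / sum((d$y - mean(d$y))^2)
  })
  tibble(variable = colnames(d$X), r_squared = unname(r2))
}

#' Screen out highly correlated driver variables
#'
#' Any pair of variables with absolute bivariate correlation at or above
#' the threshold is considered redundant; the member with the lower simple
#' regression R-squared against the response is dropped (ties drop the
#' variable later in the canonical order). The screen iterates until no
#' violating pair remains. Correlations are computed on the transformed
#' variables; standardization leaves them unchanged.
#'
#' @inheritParams simple_regressions
#' @param threshold Absolute correlation at or above which a pair counts
#'   as highly correlated (default 0.6).
#' @return List with `retained` (variable names), `dropped` (tibble of
#'   variable, partner, both R-squared values), and `correlations` (matrix).
#' @export
collinearity_screen <- function(x, y = NULL, threshold = 0.6) {
  d <- frame_xy(x, y)
  if (ncol(d$X) < 2) {
    return(list(retained = colnames(d$X),
                dropped = tibble(variable = character(),
                                 partner = character(),
                                 r = numeric(),
                                 r_squared = numeric(),
                                 partner_r_squared = numeric()),
                correlations = cor(d$X)))
  }
  r2 <- setNames(simple_regressions(d$X, d$y)$r_squared, colnames(d$X))
  cmat <- cor(d$X)
  retained <- colnames(d$X)
  dropped <- list()
  canon_rank <- function(v) {
    i <- match(v, fd_variables)
    ifelse(is.na(i), length(fd_variables) + match(v, colnames(d$X)), i)
  }
  repeat {
    cc <- abs(cmat[retained, retained, drop = FALSE])
    diag(cc) <- 0
    if (all(cc < threshold)) break
    ## among variables in violating pairs, drop the one with lowest R^2
    viol <- which(cc >= threshold, arr.ind = TRUE)
    cand <- unique(rownames(cc)[viol[, 1]])
    worst <- cand[order(r2[cand], -canon_rank(cand))][1]
    partners <- retained[abs(cmat[worst, retained]) >= threshold &
                           retained != worst]
    partner <- partners[which.max(abs(cmat[worst, partners]))]
    dropped[[length(dropped) + 1]] <- tibble(
      variable = worst, partner = partner,
      r = cmat[worst, partner],
      r_squared = unname(r2[worst]),
      partner_r_squared = unname(r2[partner]))
    retained <- setdiff(retained, worst)
  }
  list(retained = retained,
       dropped = if (length(dropped)) dplyr::bind_rows(dropped) else
         tibble(variable = character(), partner = character(),
                r = numeric(), r_squared = numeric(),
                partner_r_squared = numeric()),
       correlations = cmat)
}

## Gaussian log-likelihood at the MLE error variance e'e/n.
gaussian_loglik <- function(residuals) {
  n <- length(residuals)
  s2 <- sum(residuals^2) / n
  -n / 2 * (log(2 * pi * s2) + 1)
}

#' Global goodness-of-fit measures
#'
#' AIC, BIC, the unbiased error-variance estimate, the standard error of
#' regression, adjusted R-squared and the log-likelihood, on a common
#' parameter-counting convention: `k_model` counts mean parameters
#' (intercept, each variable, each lagged variable) plus one for a spatial
#' error coefficient when present; the information criteria additionally
#' count the error variance.
#'
#' @param loglik Maximized log-likelihood.
#' @param residuals Residual (innovation) vector.
#' @param n Sample size.
#' @param k_model Parameter count as above (excluding the error variance).
#' @param r_squared Model R-squared on which the adjustment is based.
#' @return One-row tibble of measures.
#' @export
global_measures <- function(loglik, residuals, n, k_model, r_squared) {
  if (n <= k_model) abort("sample size must exceed the parameter count")
  k_ic <- k_model + 1
  rss <- sum(residuals^2)
  ml_unb <- rss / (n - k_model)
  tibble(
    loglik = loglik,
    AIC = 2 * k_ic - 2 * loglik,
    BIC = k_ic * log(n) - 2 * loglik,
    ML_unb = ml_unb,
    SER = sqrt(ml_unb),
    r_squared = r_squared,
    adj_r_squared = 1 - (1 - r_squared) * (n - 1) / (n - k_model)
  )
}

#' Ordinary least squares fit of the linearized forest-cover response
#'
#' Least-squares fit with an always-included intercept, Gaussian
#' log-likelihood at the maximum-likelihood error variance, and the global
#' fit measures.
#'
#' @param x A `sample_frame` or numeric design matrix (no intercept
#'   column; one is added).
#' @param y Response (ignored for sample frames).
#' @param variables Optional subset of columns to use.
#' @return An `fc_ols` object with a coefficient table, residuals,
#'   log-likelihood and measures. Methods: `tidy()`, `glance()`,
#'   `logLik()`, `print()`.
#' @export
ols_fit <- function(x, y = NULL, variables = NULL) {
  d <- frame_xy(x, y)
  X <- d$X
  if (!is.null(variables)) X <- X[, variables, drop = FALSE]
  Xd <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xd)
  if (qr_x$rank < ncol(Xd)) abort("design matrix is rank deficient")
  fit <- lm.fit(Xd, d$y)
  n <- length(d$y)
  k_mean <- ncol(Xd)
  e <- fit$residuals
  rss <- sum(e^2)
  sigma2_unb <- rss / (n - k_mean)
  vc <- solve(crossprod(Xd)) * sigma2_unb
  se <- sqrt(diag(vc))
  est <- fit$coefficients
  tval <- est / se
  tss <- sum((d$y - mean(d$y))^2)
  r2 <- 1 - rss / tss
  ll <- gaussian_loglik(e)
  p_model <- k_mean - 1
  fstat <- if (p_model > 0) {
    (tss - rss) / p_model / sigma2_unb
  } else NA_real_
  coefs <- tibble(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    statistic = unname(tval),
    p_value = 2 * pt(-abs(tval), df = n - k_mean)
  )
  structure(list(
    kind = "OLS",
    coefficients = coefs,
    variables = colnames(X),
    residuals = e,
    fitted = fit$fitted.values,
    X = X, y = d$y,
    vcov = vc,
    n = n, k_model = k_mean,
    loglik = ll,
    f_statistic = fstat,
    f_p_value = if (p_model > 0) pf(fstat, p_model, n - k_mean,
                                    lower.tail = FALSE) else NA_real_,
    measures = global_measures(ll, e, n, k_mean, r2)
  ), class = "fc_ols")
}

#' @export
logLik.fc_ols <- function(object, ...) {
  structure(object$loglik, df = object$k_model + 1, class = "logLik")
}

#' @exportS3Method base::print
print.fc_ols <- function(x, ...) {
  cat("<fc_ols> n =", x$n, " variables:",
      paste(x$variables, collapse = ", "), "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.fc_ols <- function(x, ...) x$coefficients

#' @export
glance.fc_ols <- function(x, ...) {
  dplyr::bind_cols(x$measures,
                   tibble(f_statistic = x$f_statistic,
                          f_p_value = x$f_p_value,
                          n = x$n, k = x$k_model))
}

ols_bic <- function(X, y, cols) {
  f <- lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
  ll <- gaussian_loglik(f$residuals)
  (length(cols) + 2) * log(length(y)) - 2 * ll
}

#' Backwards stepwise elimination under BIC
#'
#' Starting from the full model, repeatedly removes the single variable
#' whose removal most reduces the Bayesian information criterion, stopping
#' when no removal reduces it. The intercept is always kept. Ties drop the
#' variable later in the canonical order.
#'
#' @inheritParams ols_fit
#' @return An `fc_ols` fit on the selected variables, with the elimination
#'   path in the `path` element (tibble of step, dropped variable, BIC).
#' @export
stepwise_bic <- function(x, y = NULL) {
  d <- frame_xy(x, y)
  X <- d$X
  current <- colnames(X)
  if (is.null(current) || length(current) == 0) {
    abort("no candidate variables")
  }
  bic_now <- ols_bic(X, d$y, current)
  path <- list(tibble(step = 0L, dropped = NA_character_, BIC = bic_now))
  step_i <- 0L
  while (length(current) > 0) {
    cand_bic <- vapply(current, function(v) {
      ols_bic(X, d$y, setdiff(current, v))
    }, numeric(1))
    ord <- order(cand_bic, -match(current, fd_variables,
                                  nomatch = length(fd_variables) + 1L))
    best <- ord[1]
    if (cand_bic[best] >= bic_now - 1e-10) break
    step_i <- step_i + 1L
    bic_now <- cand_bic[best]
    path[[length(path) + 1]] <- tibble(step = step_i,
                                       dropped = current[best],
                                       BIC = bic_now)
    current <- setdiff(current, current[best])
  }
  fit <- ols_fit(X[, current, drop = FALSE], d$y)
  fit$path <- dplyr::bind_rows(path)
  fit
}
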