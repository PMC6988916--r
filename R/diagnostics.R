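## Residual Moran's I (normal approximation, Cliff-Ord regression moments)
## and the four Lagrange multiplier spatial-dependence diagnostics.

w_dense <- function(w) {
  m <- if (inherits(w, "soi_weights")) w$W else w
  as.matrix(m)
}

check_alignment <- function(fit, w) {
  ids <- if (inherits(w, "soi_weights")) w$ids else rownames(w_dense(w))
  fids <- rownames(fit$X)
  if (!is.null(ids) && !is.null(fids) && length(ids) == length(fids) &&
      !all(ids == fids)) {
    abort("unit order of the weights matrix does not match the fit")
  }
  if (nrow(w_dense(w)) != fit$n) {
    abort("weights dimension does not match the sample size")
  }
}

#' Moran's I test of OLS residuals (normal approximation)
#'
#' Computes `I = (n/S0) e'We / e'e` for the OLS residuals and its null
#' moments accounting for the hat matrix (Cliff-Ord): with
#' `M = I - X(X'X)^-1 X'`,
#' `E(I) = n tr(MW) / ((n-k) S0)` and the variance from the second-moment
#' expression in `tr(MWMW')`, `tr((MW)^2)` and `(tr MW)^2`. The standard
#' deviate is tested one-sided against the "greater" alternative.
#'
#' @param fit An `fc_ols` object.
#' @param w A `soi_weights` object (row-standardized weights are used).
#' @return An `fc_moran` one-row tibble with `I`, `expectation`,
#'   `variance`, `sd` (standard deviate) and `p_value`.
#' @export
moran_residual_test <- function(fit, w) {
  check_alignment(fit, w)
  W <- w_dense(w)
  e <- fit$residuals
  n <- fit$n
  k <- ncol(fit$X) + 1
  S0 <- sum(W)
  I <- (n / S0) * drop(crossprod(e, W %*% e)) / sum(e^2)
  Xd <- cbind(1, fit$X)
  XtXi <- solve(crossprod(Xd))
  MW <- W - Xd %*% (XtXi %*% crossprod(Xd, W))
  trMW <- sum(diag(MW))
  trMWMWt <- sum(MW * MW)      # tr(MW MW') = sum of squared entries
  trMW2 <- sum(MW * t(MW))     # tr((MW)^2) = sum_ij MW_ij MW_ji
  EI <- n * trMW / ((n - k) * S0)
  VarI <- (n / S0)^2 * (trMWMWt + trMW2 + trMW^2) /
    ((n - k) * (n - k + 2)) - EI^2
  SD <- (I - EI) / sqrt(VarI)
  structure(tibble(I = I, expectation = EI, variance = VarI, sd = SD,
                   p_value = pnorm(SD, lower.tail = FALSE)),
            class = c("fc_moran", "tbl_df", "tbl", "data.frame"))
}

#' Lagrange multiplier diagnostics for spatial error and lag dependence
#'
#' The four score statistics on OLS residuals: the error and lag tests and
#' their robust variants that correct for the other alternative, each
#' referred to a chi-squared distribution with one degree of freedom. With
#' `T = tr((W'+W)W)`, `d_err = e'We/s2`, `d_lag = e'Wy/s2` and
#' `J = (WXb)'M(WXb)/s2 + T`:
#' `LM_err = d_err^2 / T`, `LM_lag = d_lag^2 / J`,
#' `RLM_lag = (d_lag - d_err)^2 / (J - T)`,
#' `RLM_err = (d_err - (T/J) d_lag)^2 / (T - T^2/J)`.
#' When `J <= T` the robust statistics are undefined and reported `NA`
#' with a warning.
#'
#' @inheritParams moran_residual_test
#' @return An `fc_lmtests` tibble with one row per statistic
#'   (`lm_err`, `lm_lag`, `rlm_err`, `rlm_lag`), the statistic value and
#'   its p-value.
#' @export
lm_tests <- function(fit, w) {
  check_alignment(fit, w)
  W <- w_dense(w)
  e <- fit$residuals
  y <- fit$y
  n <- fit$n
  s2 <- sum(e^2) / n
  Xd <- cbind(1, fit$X)
  b <- qr.coef(qr(Xd), y)
  Wxb <- W %*% (Xd %*% b)
  XtXi <- solve(crossprod(Xd))
  MWxb <- Wxb - Xd %*% (XtXi %*% crossprod(Xd, Wxb))
  TT <- sum((t(W) + W) * t(W))   # tr((W'+W)W)
  d_err <- drop(crossprod(e, W %*% e)) / s2
  d_lag <- drop(crossprod(e, W %*% y)) / s2
  J <- drop(crossprod(Wxb, MWxb)) / s2 + TT
  lm_err <- d_err^2 / TT
  lm_lag <- d_lag^2 / J
  if (J <= TT) {
    warn("J <= T: robust LM statistics are undefined")
    rlm_lag <- rlm_err <- NA_real_
  } else {
    rlm_lag <- (d_lag - d_err)^2 / (J - TT)
    rlm_err <- (d_err - (TT / J) * d_lag)^2 / (TT - TT^2 / J)
  }
  stat <- c(lm_err = lm_err, lm_lag = lm_lag,
            rlm_err = rlm_err, rlm_lag = rlm_lag)
  structure(tibble(test = names(stat), statistic = unname(stat),
                   df = 1L,
                   p_value = pchisq(unname(stat), df = 1,
                                    lower.tail = FALSE)),
            class = c("fc_lmtests", "tbl_df", "tbl", "data.frame"))
}

#' Combined residual spatial-dependence diagnostics
#'
#' Moran's I (normal approximation) plus the four LM statistics, in the
#' layout of a diagnostics report row.
#'
#' @inheritParams moran_residual_test
#' @return An `fc_diagnostics` list with elements `moran` and `lm`.
#' @export
spatial_diagnostics <- function(fit, w) {
  structure(list(moran = moran_residual_test(fit, w),
                 lm = lm_tests(fit, w),
                 n = fit$n),
            class = "fc_diagnostics")
}

#' @exportS3Method base::print
print.fc_diagnostics <- function(x, ...) {
  m <- x$moran
  cat("<fc_diagnostics> n =", x$n, "\n")
  cat(sprintf("  Moran I = %.4f  E = %.3e  Var = %.3e  SD = %.2f  p = %.3g\n",
              m$I, m$expectation, m$variance, m$sd, m$p_value))
  print(x$lm)
  invisible(x)
}

#' @export
tidy.fc_diagnostics <- function(x, ...) {
  dplyr::bind_rows(
    tibble(test = "moran_i", statistic = x$moran$sd, df = NA_integer_,
           p_value = x$moran$p_value),
    x$lm[, c("test", "statistic", "df", "p_value")]
  )
}

#' Significance codes used in the report tables
#' @param p Numeric vector of p-values.
#' @param cuts Breakpoints for the codes, most significant first.
#' @param codes Symbols matching `cuts` plus a trailing "n.s." label.
#' @return Character vector of codes.
#' @export
significance_code <- function(p, cuts = c(1e-3, 1e-2, 5e-2, 1e-1),
                              codes = c("***", "**", "*", ".", "n.s.")) {
  stopifnot(length(codes) == length(cuts) + 1)
  codes[findInterval(p, cuts, left.open = TRUE) + 1]
}
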