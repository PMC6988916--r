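## LeSage-Pace local specification ladder: LR tests of the SDEM against
## its nested restrictions (SEM: theta = 0; SLX: lambda = 0; OLS: both).

#' Likelihood-ratio test of nested fits
#'
#' `LHR = 2 (logLik_full - logLik_restricted)` against chi-squared with
#' the given degrees of freedom. A negative statistic beyond optimizer
#' slack signals a failed optimization and raises an error; small negative
#' values are clamped to zero.
#'
#' @param full,restricted Fitted models providing `logLik()` (the
#'   restricted model must be nested in the full one, same data and
#'   variable set).
#' @param df Degrees of freedom of the restriction.
#' @return One-row tibble with `LHR`, `df`, `p_value`.
#' @export
lr_test <- function(full, restricted, df) {
  lhr <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(restricted)))
  if (lhr < -1e-6) {
    abort(paste0("negative likelihood ratio (", signif(lhr, 4),
                 "): optimizer failure in the full model"))
  }
  lhr <- max(lhr, 0)
  tibble(LHR = lhr, df = as.integer(df),
         p_value = pchisq(lhr, df = df, lower.tail = FALSE))
}

#' Decision rule of the specification ladder
#'
#' Applies the nested-restriction logic to the significance pattern of the
#' three tests (each "significant" means the restriction is rejected):
#' OLS not rejected keeps OLS; otherwise a single acceptable restriction
#' picks SEM (theta = 0 acceptable) or SLX (lambda = 0 acceptable); both
#' rejected picks SDEM. When both restrictions are individually
#' acceptable but OLS is rejected, the restriction with the larger
#' p-value wins (ties default to SEM).
#'
#' @param sig_sem,sig_slx,sig_ols Logicals: was the restriction to
#'   SEM / SLX / OLS rejected at the chosen level?
#' @param p_sem,p_slx Restriction p-values, used only in the
#'   both-acceptable corner case.
#' @return One of `"OLS"`, `"SEM"`, `"SLX"`, `"SDEM"`.
#' @export
select_model_rule <- function(sig_sem, sig_slx, sig_ols,
                              p_sem = NA_real_, p_slx = NA_real_) {
  if (!sig_ols) return("OLS")
  if (!sig_sem && sig_slx) return("SEM")
  if (sig_sem && !sig_slx) return("SLX")
  if (sig_sem && sig_slx) return("SDEM")
  ## both restrictions acceptable but OLS rejected
  if (is.na(p_sem) || is.na(p_slx) || p_sem >= p_slx) "SEM" else "SLX"
}

#' Fit the model family and run the specification ladder on one sample
#'
#' Fits OLS, SLX, SEM and SDEM on the same variable set and computes the
#' three likelihood-ratio restrictions of the SDEM: to SEM (theta = 0,
#' df = number of lagged terms), to SLX (lambda = 0, df = 1), and to OLS
#' (both, df = lagged terms + 1). The selected label follows
#' [select_model_rule()] at level `alpha`.
#'
#' @inheritParams sem_fit
#' @param alpha Significance threshold for the selection decision.
#' @return An `fc_specification` object: `tests` (three-row tibble),
#'   `selected` label, and the four fits in `fits`.
#' @export
specify_model <- function(x, w, y = NULL, variables = NULL, alpha = 0.05,
                          se = TRUE, eigenvalues = NULL, grid_n = 200) {
  d <- frame_xy(x, y)
  X <- d$X
  if (!is.null(variables)) X <- X[, variables, drop = FALSE]
  ev <- eigenvalues %||% w_eigenvalues(w)
  p <- ncol(X)
  fits <- list(
    OLS = ols_fit(X, d$y),
    SLX = slx_fit(X, w, d$y),
    SEM = sem_fit(X, w, d$y, se = se, eigenvalues = ev, grid_n = grid_n),
    SDEM = sdem_fit(X, w, d$y, se = se, eigenvalues = ev, grid_n = grid_n)
  )
  tests <- dplyr::bind_rows(
    dplyr::mutate(lr_test(fits$SDEM, fits$SEM, df = p),
                  restriction = "SEM", .before = 1),
    dplyr::mutate(lr_test(fits$SDEM, fits$SLX, df = 1),
                  restriction = "SLX", .before = 1),
    dplyr::mutate(lr_test(fits$SDEM, fits$OLS, df = p + 1),
                  restriction = "OLS", .before = 1)
  )
  sig <- tests$p_value < alpha
  selected <- select_model_rule(sig[1], sig[2], sig[3],
                                p_sem = tests$p_value[1],
                                p_slx = tests$p_value[2])
  structure(list(tests = tests, selected = selected, alpha = alpha,
                 fits = fits, n = fits$OLS$n),
            class = "fc_specification")
}

#' Selected model label of a specification result
#' @param spec An `fc_specification` object.
#' @param alpha Optional different significance level to re-apply the
#'   decision rule at.
#' @return Model label string.
#' @export
select_model <- function(spec, alpha = NULL) {
  if (is.null(alpha) || alpha == spec$alpha) return(spec$selected)
  sig <- spec$tests$p_value < alpha
  select_model_rule(sig[1], sig[2], sig[3],
                    p_sem = spec$tests$p_value[1],
                    p_slx = spec$tests$p_value[2])
}

#' @exportS3Method base::print
print.fc_specification <- function(x, ...) {
  cat("<fc_specification> n =", x$n, " selected:", x$selected, "\n")
  t <- x$tests
  t$code <- significance_code(t$p_value)
  print(t)
  invisible(x)
}

#' @export
tidy.fc_specification <- function(x, ...) x$tests

#' @export
glance.fc_specification <- function(x, ...) {
  tibble(selected = x$selected, alpha = x$alpha, n = x$n,
         LHR_SEM = x$tests$LHR[1], LHR_SLX = x$tests$LHR[2],
         LHR_OLS = x$tests$LHR[3])
}
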