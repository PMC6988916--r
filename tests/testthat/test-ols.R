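test_that("simple regressions recover the squared-correlation identity", {
  set.seed(21)
  X <- matrix(rnorm(200 * 3), 200, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * X[, 1] + rnorm(200)
  r2 <- simple_regressions(X, y)
  expect_equal(r2$r_squared, unname(cor(X, y)[, 1]^2), tolerance = 1e-12)
  ## exact linear dependence gives R^2 = 1
  expect_equal(simple_regressions(X[, 1, drop = FALSE],
                                  3 * X[, 1] - 1)$r_squared, 1)
  ## a column orthogonal to the centered response gives R^2 = 0
  yc <- y - mean(y)
  v <- rnorm(200)
  v_orth <- v - drop(crossprod(v, yc) / crossprod(yc)) * yc
  expect_equal(simple_regressions(cbind(v = v_orth), y)$r_squared, 0,
               tolerance = 1e-12)
})

test_that("collinearity screen drops the weaker member of each pair", {
  set.seed(22)
  n <- 300
  A <- rnorm(n)
  B <- 0.95 * A + sqrt(1 - 0.95^2) * rnorm(n)   # r ~ 0.95 with A
  C <- rnorm(n)                                  # independent
  y <- A + 0.5 * C + rnorm(n, sd = 0.5)          # R2(A) > R2(B)
  X <- cbind(A = A, B = B, C = C)
  sc <- collinearity_screen(X, y, threshold = 0.6)
  expect_setequal(sc$retained, c("A", "C"))
  expect_equal(sc$dropped$variable, "B")
  expect_gt(sc$dropped$partner_r_squared, sc$dropped$r_squared)
  ## no retained pair above the threshold
  cc <- abs(cor(X[, sc$retained])); diag(cc) <- 0
  expect_lt(max(cc), 0.6)
  ## orthogonal design drops nothing
  sc2 <- collinearity_screen(cbind(a = rnorm(n), b = rnorm(n)), y)
  expect_equal(nrow(sc2$dropped), 0)
  ## result invariant to column order
  sc3 <- collinearity_screen(X[, c("C", "B", "A")], y, threshold = 0.6)
  expect_setequal(sc3$retained, sc$retained)
})

test_that("OLS reproduces the normal equations and textbook likelihood", {
  set.seed(23)
  n <- 60
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("x1", "x2")))
  y <- 3 + 2 * X[, 1] - X[, 2] + rnorm(n)
  fit <- ols_fit(X, y)
  ## direct linear solve oracle
  Xd <- cbind(1, X)
  beta_direct <- solve(crossprod(Xd), crossprod(Xd, y))
  expect_equal(fit$coefficients$estimate, unname(drop(beta_direct)),
               tolerance = 1e-10)
  ## residuals orthogonal to the design columns
  expect_lt(max(abs(crossprod(Xd, fit$residuals))), 1e-8)
  ## Gaussian ML log-likelihood matches lm's and the closed form
  lmfit <- lm(y ~ X)
  expect_equal(fit$loglik, as.numeric(logLik(lmfit)), tolerance = 1e-10)
  k_ic <- fit$k_model + 1
  rss <- sum(fit$residuals^2)
  expect_equal(fit$measures$AIC, n * log(2 * pi * rss / n) + n + 2 * k_ic,
               tolerance = 1e-10)
  expect_equal(fit$measures$AIC, AIC(lmfit), tolerance = 1e-10)
  expect_equal(fit$measures$BIC, BIC(lmfit), tolerance = 1e-10)
  ## exact fit: y = 3 + 2x
  ex <- ols_fit(cbind(x = X[, 1]), 3 + 2 * X[, 1])
  expect_equal(ex$coefficients$estimate, c(3, 2), tolerance = 1e-10)
  expect_equal(ex$measures$r_squared, 1)
  ## rank deficiency is an error
  expect_error(ols_fit(cbind(a = X[, 1], b = X[, 1]), y),
               "rank deficient")
})

test_that("global measures satisfy their algebraic identities", {
  set.seed(24)
  e <- rnorm(50)
  ll <- -40
  m <- global_measures(ll, e, n = 50, k_model = 3, r_squared = 0.8)
  k_ic <- 4
  expect_equal(m$AIC - m$BIC, k_ic * (2 - log(50)), tolerance = 1e-12)
  expect_equal(m$SER, sqrt(sum(e^2) / (50 - 3)))
  expect_equal(m$adj_r_squared, 1 - (1 - 0.8) * 49 / 47)
  ## perfect fit has zero regression error
  expect_equal(global_measures(0, rep(0, 10), 10, 2, 1)$SER, 0)
  expect_error(global_measures(0, rep(0, 3), 3, 3, 1), "exceed")
})

test_that("backwards-BIC elimination matches the greedy oracle", {
  set.seed(25)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 2 * x1 + rnorm(n, sd = 0.1)
  fit <- stepwise_bic(cbind(x1 = x1, x2 = x2), y)
  expect_equal(fit$variables, "x1")
  ## all-noise design collapses to the intercept-only model
  set.seed(26)
  Xn <- matrix(rnorm(500 * 4), 500,
               dimnames = list(NULL, paste0("n", 1:4)))
  fit0 <- stepwise_bic(Xn, rnorm(500))
  expect_length(fit0$variables, 0)
  ## deterministic response keeps the full model
  yd <- Xn %*% c(1, -1, 0.5, 2)
  expect_length(stepwise_bic(Xn, drop(yd))$variables, 4)
  ## selected-model BIC never exceeds the full-model BIC
  expect_lte(fit0$measures$BIC, ols_fit(Xn, rnorm(500))$measures$BIC)
})

test_that("stepwise path agrees with stats::step backwards under k = log(n)", {
  set.seed(27)
  for (rep in 1:10) {
    n <- 150
    p <- 5
    X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("v", 1:p)))
    beta <- ifelse(runif(p) < 0.5, 0, runif(p, 0.3, 1))
    y <- drop(X %*% beta) + rnorm(n)
    ours <- stepwise_bic(X, y)$variables
    df <- data.frame(y = y, X)
    ref <- stats::step(lm(y ~ ., data = df), direction = "backward",
                       k = log(n), trace = 0)
    ref_vars <- setdiff(names(coef(ref)), "(Intercept)")
    expect_setequal(ours, ref_vars)
  }
})
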