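test_that("log-determinant closed forms and cross-method agreement", {
  w2 <- soi_weights(cbind(c(0, 1), c(0, 0)))
  expect_equal(log_det(w2, 0), 0)
  ## two mutual neighbors: ln det(I - lambda W) = ln(1 - lambda^2)
  for (la in c(-0.6, 0.3, 0.9)) {
    expect_equal(log_det(w2, la), log(1 - la^2), tolerance = 1e-12)
  }
  ## dense eigen and sparse LU agree on a random lattice
  w <- random_weights(300, seed = 41)
  for (la in c(-0.4, 0.5, 0.85)) {
    expect_equal(log_det(w, la, method = "eigen"),
                 log_det(w, la, method = "lu"), tolerance = 1e-8)
  }
  ## spectrum bounds: largest eigenvalue of row-standardized W is 1
  ev <- w_eigenvalues(w)
  expect_equal(max(ev), 1, tolerance = 1e-10)
  expect_lt(min(ev), 0)
})

test_that("SLX is exactly OLS on the lag-augmented design", {
  w <- random_weights(40, seed = 42)
  set.seed(43)
  X <- matrix(rnorm(40 * 2), 40, dimnames = list(w$ids, c("a", "b")))
  y <- rnorm(40)
  fit <- slx_fit(X, w, y)
  WX <- as.matrix(w$W %*% X)
  colnames(WX) <- paste0("lag_", colnames(X))
  ref <- ols_fit(cbind(X, WX), y)
  expect_equal(fit$coefficients$estimate, ref$coefficients$estimate,
               tolerance = 1e-12)
  expect_equal(fit$loglik, ref$loglik)
  ## exact construction on a 10-unit fixture: y = 1 + 2x + 0.5 Wx
  w10 <- random_weights(10, seed = 44)
  x10 <- rnorm(10)
  y10 <- 1 + 2 * x10 + 0.5 * as.numeric(w10$W %*% x10)
  f10 <- slx_fit(cbind(x = x10), w10, y10)
  est <- setNames(f10$coefficients$estimate, f10$coefficients$term)
  expect_equal(unname(est[c("(Intercept)", "x", "lag_x")]),
               c(1, 2, 0.5), tolerance = 1e-8)
  expect_lt(max(abs(f10$residuals)), 1e-8)
})

test_that("SEM lambda equals the fine-grid argmax of the concentrated likelihood", {
  w <- random_weights(50, seed = 45)
  set.seed(46)
  X <- matrix(rnorm(50), 50, dimnames = list(w$ids, "x"))
  y <- simulate_response(X, w, beta0 = 1, beta = c(x = 1), lambda = 0.6,
                         sigma = 0.5)
  fit <- sem_fit(X, w, y)
  ## oracle: independently coded concentrated likelihood on a 0.001 grid
  W <- as.matrix(w$W)
  ev <- sort(eigen(W)$values)        # row-standardized: real spectrum
  ev <- Re(ev[abs(Im(ev)) < 1e-8])
  grid <- seq(1 / min(ev) + 1e-3, 1 - 1e-3, by = 0.001)
  n <- 50
  Xd <- cbind(1, X)
  ll <- vapply(grid, function(la) {
    A <- diag(n) - la * W
    yt <- A %*% y
    Xt <- A %*% Xd
    b <- solve(t(Xt) %*% Xt, t(Xt) %*% yt)
    s2 <- sum((yt - Xt %*% b)^2) / n
    -n / 2 * (log(2 * pi * s2) + 1) +
      as.numeric(determinant(A, logarithm = TRUE)$modulus)
  }, numeric(1))
  expect_equal(fit$lambda, grid[which.max(ll)], tolerance = 1e-3)
  ## the reported log-likelihood equals a direct full-likelihood
  ## evaluation at the reported parameters
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  beta_hat <- est[c("(Intercept)", "x")]
  s2_hat <- sum(fit$residuals^2) / n
  expect_equal(fit$loglik,
               direct_spatial_loglik(y, Xd, W, beta_hat, fit$lambda,
                                     s2_hat),
               tolerance = 1e-8)
})

test_that("SDEM decomposes impacts exactly and dominates its restrictions", {
  w <- random_weights(120, seed = 47)
  set.seed(48)
  X <- matrix(rnorm(120 * 2), 120, dimnames = list(w$ids, c("a", "b")))
  y <- simulate_response(X, w, beta0 = 1, beta = c(a = 1.5, b = 0.3),
                         theta = c(a = 0.2, b = -0.4), lambda = 0.5,
                         sigma = 0.5)
  fits <- list(ols = ols_fit(X, y), slx = slx_fit(X, w, y),
               sem = sem_fit(X, w, y), sdem = sdem_fit(X, w, y))
  ## impact identity: total = direct + indirect, exactly
  imp <- fits$sdem$impacts
  expect_identical(imp$total, imp$direct + imp$indirect)
  imp_slx <- fits$slx$impacts
  expect_identical(imp_slx$total, imp_slx$direct + imp_slx$indirect)
  ## likelihood ordering of the nested family
  expect_gte(fits$sdem$loglik, fits$sem$loglik - 1e-6)
  expect_gte(fits$sdem$loglik, fits$slx$loglik - 1e-6)
  expect_gte(fits$sem$loglik, fits$ols$loglik - 1e-6)
  expect_gte(fits$slx$loglik, fits$ols$loglik - 1e-6)
  ## lambda stays strictly inside its admissible interval
  ev <- w_eigenvalues(w)
  expect_gt(fits$sdem$lambda, 1 / min(ev))
  expect_lt(fits$sdem$lambda, 1)
  ## SDEM log-likelihood re-evaluates exactly
  est <- setNames(fits$sdem$coefficients$estimate,
                  fits$sdem$coefficients$term)
  beta_hat <- est[setdiff(names(est), "lambda")]
  Zd <- cbind(1, fits$sdem$X)
  expect_equal(fits$sdem$loglik,
               direct_spatial_loglik(y, Zd, as.matrix(w$W), beta_hat,
                                     fits$sdem$lambda,
                                     sum(fits$sdem$residuals^2) / 120),
               tolerance = 1e-8)
})

test_that("parameter recovery at moderate size is within sampling error", {
  w <- random_weights(400, seed = 49)
  ev <- w_eigenvalues(w)
  set.seed(50)
  X <- matrix(rnorm(400 * 2), 400, dimnames = list(w$ids, c("a", "b")))
  y <- simulate_response(X, w, beta0 = 1, beta = c(a = 1.5, b = 0.3),
                         theta = c(a = 0.2, b = -0.1), lambda = 0.6,
                         sigma = 0.5)
  fit <- sdem_fit(X, w, y, eigenvalues = ev)
  expect_lt(abs(fit$lambda - 0.6), 3 * fit$lambda_se)
  co <- fit$coefficients
  for (trm in c("a", "b", "lag_a", "lag_b")) {
    truth <- c(a = 1.5, b = 0.3, lag_a = 0.2, lag_b = -0.1)[[trm]]
    row <- co[co$term == trm, ]
    expect_lt(abs(row$estimate - truth), 3.5 * row$std_error)
  }
  expect_true(is.finite(fit$lambda_se) && fit$lambda_se > 0)
})

test_that("a theta = 0 process makes SDEM totals agree with SEM betas", {
  w <- random_weights(300, seed = 51)
  ev <- w_eigenvalues(w)
  set.seed(52)
  X <- matrix(rnorm(300), 300, dimnames = list(w$ids, "x"))
  y <- simulate_response(X, w, beta0 = 0.5, beta = c(x = 1),
                         lambda = 0.5, sigma = 0.5)
  sdem <- sdem_fit(X, w, y, eigenvalues = ev)
  sem <- sem_fit(X, w, y, eigenvalues = ev)
  b_sem <- sem$coefficients$estimate[sem$coefficients$term == "x"]
  tot <- sdem$impacts$total[sdem$impacts$variable == "x"]
  expect_lt(abs(tot - b_sem),
            3 * sdem$impacts$total_se[sdem$impacts$variable == "x"])
  ## the lag coefficient itself is near zero
  th <- sdem$coefficients[sdem$coefficients$term == "lag_x", ]
  expect_lt(abs(th$estimate), 3 * th$std_error)
})

test_that("degenerate inputs are rejected with informative errors", {
  w <- grid_weights(6)
  set.seed(53)
  n <- 36
  X <- matrix(rnorm(n), n, dimnames = list(w$ids, "x"))
  y <- rnorm(n)
  ## rank-deficient mean design
  expect_error(sem_fit(cbind(a = X[, 1], b = X[, 1]), w, y),
               "rank deficient")
  ## lambda outside the admissible interval makes I - lambda W singular
  w2 <- soi_weights(cbind(c(0, 1), c(0, 0)))
  expect_error(log_det(w2, 1), "singular")
  expect_error(log_det(w2, 1.5), "singular")
})
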