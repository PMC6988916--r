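# Shared in-code fixtures: no data files, everything generated.

# Regular lattice weights: fast, deterministic, well-conditioned.
grid_weights <- function(n_side, spacing = 1000) {
  g <- expand.grid(x = seq_len(n_side), y = seq_len(n_side)) * spacing
  m <- as.matrix(g)
  rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  soi_weights(m)
}

random_weights <- function(n, seed = 1, side = 1e5) {
  set.seed(seed)
  m <- cbind(x = runif(n, 0, side), y = runif(n, 0, side))
  rownames(m) <- sprintf("r%04d", seq_len(n))
  soi_weights(m)
}

# Independently coded brute-force circle-intersection test, the SOI
# oracle: nothing shared with the package implementation.
soi_brute_force <- function(coords) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    }
  }
  r <- numeric(n)
  for (i in seq_len(n)) r[i] <- min(d[i, -i])
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && d[i, j] < r[i] + r[j] && d[i, j] > abs(r[i] - r[j])) {
        adj[i, j] <- TRUE
      }
    }
  }
  adj
}

# Raw unit table with hand-pickable values, all filter-safe by default.
make_units <- function(n = 10, seed = 7) {
  set.seed(seed)
  tibble::tibble(
    unit_id = sprintf("u%03d", seq_len(n)),
    country = "ZAM", level = "meso",
    x = runif(n, 0, 5e4), y = runif(n, 0, 5e4),
    A_TOT = runif(n, 5e3, 5e4)
  ) |>
    dplyr::mutate(
      FA_pot = runif(n, 0.4, 0.8) * A_TOT,
      FA = runif(n, 0.2, 0.8) * FA_pot,
      P_TOT = runif(n, 1e3, 1e5),
      R_TOT = runif(n, 10, 500),
      FL_TOT = runif(n, 0.3, 0.7) * A_TOT,
      CSI = runif(n, 20, 80),
      CY = runif(n, 1e6, 8e6)
    )
}

# Full Gaussian SDEM/SEM likelihood evaluated from scratch (dense
# algebra, base determinant): the re-evaluation oracle for logLik.
direct_spatial_loglik <- function(y, Z_with_intercept, W, beta, lambda,
                                  sigma2) {
  n <- length(y)
  A <- diag(n) - lambda * W
  res <- A %*% (y - Z_with_intercept %*% beta)
  ld <- determinant(A, logarithm = TRUE)$modulus
  as.numeric(-n / 2 * log(2 * pi * sigma2) - sum(res^2) / (2 * sigma2) + ld)
}
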