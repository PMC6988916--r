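test_that("driver variables follow their defining ratios", {
  u <- tibble::tibble(
    unit_id = "a", country = "ZAM", level = "meso", x = 0, y = 0,
    A_TOT = 200, FA = 50, FA_pot = 100, P_TOT = 1000, R_TOT = 4 * 2,
    FL_TOT = 80, CSI = 40, CY = 2e6)
  v <- compute_variables(u)
  expect_equal(v$FC, 0.5)
  expect_equal(v$PVA, 0.5)
  expect_equal(v$PP_FA, 1000 / 50)       # persons per ha of forest
  expect_equal(v$RD, 8 / 2)              # 200 ha = 2 km^2
  expect_equal(v$FL, 0.4)
  v2 <- compute_variables(u, ppfa_mode = "per_total_area")
  expect_equal(v2$PP_FA, 1000 / 200)
  ## canonical spec case: P_TOT = 1000 over FA = 100 ha -> 10 pers/ha
  u$FA <- 100
  expect_equal(compute_variables(u)$PP_FA, 10)
  ## FA_pot = 0 flags, does not throw
  u$FA_pot <- 0; u$FA <- 0
  expect_true(is.na(compute_variables(u)$FC))
})

test_that("cereal yield takes the 10-year mean and the best crop", {
  f <- c(maize = 3.58e6, rice = 2.8e6)
  y1 <- tidyr::expand_grid(unit_id = "a", crop = "maize",
                           year = 2001:2010) |>
    dplyr::mutate(yield_t_ha = 2)
  expect_equal(compute_cereal_yield(y1, f, 2010)$CY, 2 * f[["maize"]])
  ## max rule across crops
  y2 <- dplyr::bind_rows(
    y1,
    dplyr::mutate(y1, crop = "rice", yield_t_ha = 3))
  expect_equal(compute_cereal_yield(y2, f, 2010)$CY,
               max(2 * f[["maize"]], 3 * f[["rice"]]))
  ## random series equals the independently coded mean x factor loop
  set.seed(5)
  yr <- tidyr::expand_grid(unit_id = c("a", "b"),
                           crop = c("maize", "rice"),
                           year = 1998:2012) |>
    dplyr::mutate(yield_t_ha = runif(dplyr::n(), 0.5, 6))
  got <- compute_cereal_yield(yr, f, 2009)
  for (id in c("a", "b")) {
    best <- -Inf
    for (cr in c("maize", "rice")) {
      s <- yr$yield_t_ha[yr$unit_id == id & yr$crop == cr &
                           yr$year >= 2000 & yr$year <= 2009]
      best <- max(best, mean(s) * f[[cr]])
    }
    expect_equal(got$CY[got$unit_id == id], best)
  }
  ## years outside the window are ignored entirely
  expect_equal(nrow(compute_cereal_yield(y1, f, 2025)), 0)
})

test_that("exclusion filter drops nil/extreme units with reasons", {
  u <- make_units(10)
  v <- compute_variables(u)
  f <- exclusion_filter(v)
  expect_equal(nrow(f$kept), 10)
  expect_equal(nrow(f$excluded), 0)

  u$FA[1] <- 0                       # FC = 0
  u$FA[2] <- u$FA_pot[2]             # FC = 1
  u$CSI[3] <- 0
  v <- compute_variables(u)
  v$PP_FA[1] <- 1                    # keep the FC reason isolated
  f <- exclusion_filter(v)
  expect_equal(nrow(f$kept), 7)
  expect_match(f$excluded$reason[f$excluded$unit_id == "u001"], "FC nil")
  expect_match(f$excluded$reason[f$excluded$unit_id == "u002"], "FC extreme")
  expect_match(f$excluded$reason[f$excluded$unit_id == "u003"], "CSI nil")

  ## order-independent and idempotent
  perm <- sample(nrow(v))
  f_perm <- exclusion_filter(v[perm, ])
  expect_setequal(f_perm$excluded$unit_id, f$excluded$unit_id)
  expect_equal(exclusion_filter(f$kept)$kept, f$kept)
  ## empty survivors is an error
  v$CSI <- 0
  expect_error(exclusion_filter(v), "no units survive")
})

test_that("logistic linearization and its inverse", {
  expect_equal(linearize_response(0.5), 0)
  expect_equal(linearize_response(0.25), log(3))
  expect_equal(linearize_response(0.75), -log(3))
  set.seed(9)
  fc <- runif(200, 1e-6, 1 - 1e-6)
  expect_equal(1 / (1 + exp(linearize_response(fc))), fc,
               tolerance = 1e-12)
  ## strictly decreasing
  s <- sort(fc)
  expect_true(all(diff(linearize_response(s)) < 0))
  expect_error(linearize_response(c(0.5, 1)), "strictly inside")
  expect_error(linearize_response(0), "strictly inside")
})

test_that("log transform and standardization build a coherent frame", {
  u <- make_units(40)
  v <- exclusion_filter(compute_variables(u))$kept
  fr <- transform_and_standardize(v, sample_id = "ZAM:meso")
  expect_s3_class(fr, "sample_frame")
  expect_equal(unname(colMeans(fr$X_std)), rep(0, ncol(fr$X_std)),
               tolerance = 1e-10)
  expect_equal(unname(apply(fr$X_std, 2, sd)), rep(1, ncol(fr$X_std)),
               tolerance = 1e-10)
  ## Eq-2/Eq-3 reconstruction: X_log = mu + sigma * X_std
  rec <- sweep(sweep(fr$X_std, 2, fr$sigma, "*"), 2, fr$mu, "+")
  expect_equal(rec, fr$X_log, tolerance = 1e-12)
  ## standardizing an already standardized column is a no-op
  z <- fr$X_std[, 1]
  expect_equal((z - mean(z)) / sd(z), z, tolerance = 1e-12)
  ## correlations are invariant under standardization
  expect_equal(cor(fr$X_log), cor(fr$X_std), tolerance = 1e-12)
  ## constant column errors with the variable named
  v2 <- v; v2$CSI <- 50
  expect_error(transform_and_standardize(v2), "CSI")
  ## missing CY is dropped with a message, not an error
  v3 <- v; v3$CY[2] <- NA
  expect_message(fr3 <- transform_and_standardize(v3), "CY")
  expect_false("CY" %in% colnames(fr3$X_std))
})

test_that("sample frames serialize losslessly enough to re-read", {
  u <- make_units(15)
  fr <- transform_and_standardize(
    exclusion_filter(compute_variables(u))$kept)
  td <- withr::local_tempdir()
  write_sample_frame(fr, td)
  back <- readr::read_csv(file.path(td, "X_std.csv"),
                          show_col_types = FALSE)
  expect_equal(as.matrix(back[, -1]), unclass(fr$X_std),
               ignore_attr = TRUE)
  man <- jsonlite::read_json(file.path(td, "manifest.json"))
  expect_equal(man$n, 15)
})
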