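test_that("projection reduces to the intercept at training means", {
  coefs <- c(`(Intercept)` = 2.5, a = 0.7, b = -0.4)
  mk <- function(val) grid_raster(matrix(val, 6, 6), cellsize = 30)
  rasters <- list(a = mk(0.3), b = mk(10))
  ctr <- c(a = 0.3, b = 10); scl <- c(a = 0.1, b = 2)
  eta <- linear_predictor_raster(coefs, rasters, ctr, scl)
  expect_true(all(abs(eta$values - 2.5) < 1e-12))
  # a zero coefficient contributes nothing even off-mean
  coefs0 <- c(`(Intercept)` = 2.5, a = 0)
  eta0 <- linear_predictor_raster(coefs0, list(a = mk(0.9)), ctr, scl)
  expect_true(all(eta0$values == 2.5))
})

test_that("projection equals per-cell scalar recomputation", {
  set.seed(14)
  va <- matrix(runif(64), 8, 8); vb <- matrix(rnorm(64, 5, 2), 8, 8)
  rasters <- list(a = grid_raster(va, cellsize = 30),
                  b = grid_raster(vb, cellsize = 30))
  ctr <- c(a = 0.4, b = 5); scl <- c(a = 0.2, b = 1.5)
  coefs <- c(`(Intercept)` = 1, a = 0.6, `a^2` = -0.2, b = 0.3)
  eta <- linear_predictor_raster(coefs, rasters, ctr, scl)
  za <- (va - 0.4) / 0.2; zb <- (vb - 5) / 1.5
  manual <- 1 + 0.6 * za - 0.2 * za^2 + 0.3 * zb
  expect_lt(max(abs(eta$values - manual)), 1e-10)
  # missing raster errors with the term name
  expect_error(
    linear_predictor_raster(c(`(Intercept)` = 1, q = 2), rasters, ctr, scl),
    "q"
  )
})

test_that("prediction is invariant to how the raw covariates were standardized", {
  # same raw data standardized with different constants gives the same
  # eta surface once the coefficients are back-transformed accordingly
  set.seed(15)
  raw <- matrix(runif(100, 0, 1), 10, 10)
  r <- list(a = grid_raster(raw, cellsize = 30))
  b_raw <- 0.8  # effect per raw unit
  eta_for <- function(ctr, scl) {
    coefs <- c(`(Intercept)` = 1 + b_raw * ctr, a = b_raw * scl)
    linear_predictor_raster(coefs, r, c(a = ctr), c(a = scl))$values
  }
  expect_lt(max(abs(eta_for(0.3, 0.15) - eta_for(0.6, 0.4))), 1e-8)
})

test_that("cubic back-solve zeroes the predictor at 100% crop cover", {
  # worked-example inputs: mixed-scale coefficients and training constants
  tab <- pheasant_scale_estimates()
  cs <- pheasant_cover_summary()
  coefs <- c(
    `(Intercept)` = tab$est_mixed[tab$term == "intercept"],
    rowcrop_5km = tab$est_mixed[tab$term == "rowcrop"],
    `rowcrop_5km^2` = tab$est_mixed[tab$term == "rowcrop2"],
    smallgrains_5km = tab$est_mixed[tab$term == "smallgrains"],
    `smallgrains_5km^2` = tab$est_mixed[tab$term == "smallgrains2"]
  )
  ctr <- c(rowcrop_5km = cs$mean[cs$term == "rowcrop_5km"],
           smallgrains_5km = cs$mean[cs$term == "smallgrains_5km"])
  scl <- c(rowcrop_5km = cs$sd[cs$term == "rowcrop_5km"],
           smallgrains_5km = cs$sd[cs$term == "smallgrains_5km"])
  for (tm in c("rowcrop_5km", "smallgrains_5km")) {
    cc <- back_solve_cubic(coefs, tm, ctr, scl)
    z1 <- (1 - ctr[[tm]]) / scl[[tm]]
    eta1 <- coefs[["(Intercept)"]] + coefs[[tm]] * z1 +
      coefs[[paste0(tm, "^2")]] * z1^2
    expect_lt(abs(eta1 + cc * z1^3), 1e-9)
  }
  # a predictor already zero at 100% cover needs no correction
  c0 <- back_solve_cubic(c(`(Intercept)` = 0, rowcrop_5km = 0),
                         "rowcrop_5km", ctr, scl)
  expect_equal(c0, 0)
  # training mean of 1 makes the constraint degenerate
  expect_error(
    back_solve_cubic(coefs, "rowcrop_5km", c(rowcrop_5km = 1),
                     c(rowcrop_5km = 0.2)),
    "degenerate"
  )
})

test_that("corrections act only away from the training means", {
  set.seed(16)
  raw <- matrix(runif(100, 0, 1), 10, 10)
  raw[1, 1] <- 0.33  # training mean cell
  raw[1, 2] <- 1     # complete-cover cell
  rasters <- list(rowcrop_5km = grid_raster(raw, cellsize = 30))
  ctr <- c(rowcrop_5km = 0.33); scl <- c(rowcrop_5km = 0.19)
  coefs <- c(`(Intercept)` = 3.07, rowcrop_5km = 0.51,
             `rowcrop_5km^2` = -0.05)
  eta <- linear_predictor_raster(coefs, rasters, ctr, scl)
  cc <- back_solve_cubic(coefs, "rowcrop_5km", ctr, scl)
  corr <- apply_correction(eta, c(rowcrop_5km = cc), rasters, ctr, scl)
  # zero correction leaves the surface untouched
  same <- apply_correction(eta, c(rowcrop_5km = 0), rasters, ctr, scl)
  expect_equal(same$values, eta$values)
  # at the training mean the corrected surface equals the fitted one
  expect_equal(corr$values[1, 1], eta$values[1, 1], tolerance = 1e-12)
  # at 100% cover it is zero by construction
  expect_lt(abs(corr$values[1, 2]), 1e-9)
  # beyond the fitted optimum the corrected curve declines towards zero
  sweep_raw <- seq(0.33, 1, length.out = 50)
  z <- (sweep_raw - 0.33) / 0.19
  fitted_curve <- 3.07 + 0.51 * z - 0.05 * z^2
  corrected_curve <- fitted_curve + cc * z^3
  tail_part <- corrected_curve[sweep_raw > 0.7]
  expect_true(all(diff(tail_part) < 0))
  expect_error(
    apply_correction(eta, c(unknown = 1), rasters, ctr, scl),
    "unknown"
  )
})

test_that("equal-area deciles partition valid cells evenly", {
  r <- grid_raster(matrix(sample(1:100), 10, 10), cellsize = 30)
  cls <- classify_equal_area(r)
  expect_equal(as.vector(table(cls$values)), rep(10, 10))
  # class 10 holds the largest values
  expect_equal(sort(r$values[cls$values == 10]), 91:100)
  expect_error(classify_equal_area(grid_raster(matrix(7, 5, 5))), "constant")
  # heavy ties still partition evenly under the first-occurrence policy
  rt <- grid_raster(matrix(rep(c(1, 2), each = 50), 10, 10), cellsize = 30)
  clt <- classify_equal_area(rt)
  expect_equal(as.vector(table(clt$values)), rep(10, 10))
  # ranks and hence classes are invariant to monotone transforms
  r2 <- grid_raster(exp(r$values / 20), cellsize = 30)
  expect_equal(classify_equal_area(r2)$values, cls$values)
})
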