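test_that("landscape generator hits target proportions with exclusive classes", {
  cfg <- landscape_config(nrow = 120, ncol = 120, cellsize = 30,
                          proportions = setNames(rep(1 / 6, 6), letters[1:6]),
                          corr_length_m = 120, seed = 4)
  ls <- build_landscape(cfg)
  stack <- sapply(ls$covers, function(r) as.vector(r$values))
  # mutually exclusive: at most one class per cell
  expect_true(all(rowSums(stack) <= 1))
  # realized proportions within 0.03 of targets (here: within one cell)
  expect_true(all(abs(colMeans(stack) - 1 / 6) < 0.03))
  # binary values only
  expect_true(all(stack %in% c(0, 1)))
})

test_that("degenerate compositions and invalid configs are handled", {
  cfg1 <- landscape_config(nrow = 30, ncol = 30,
                           proportions = c(a = 1, b = 0), seed = 2)
  ls1 <- build_landscape(cfg1)
  expect_true(all(ls1$covers$a$values == 1))
  expect_true(all(ls1$covers$b$values == 0))
  expect_error(
    landscape_config(proportions = c(a = 0.7, b = 0.6)),
    "sum"
  )
})

test_that("landscape generation is bit-identical under a fixed seed", {
  cfg <- landscape_config(nrow = 60, ncol = 60, seed = 77)
  a <- build_landscape(cfg); b <- build_landscape(cfg)
  expect_identical(a$covers$grass$values, b$covers$grass$values)
  expect_identical(a$dem$values, b$dem$values)
})

test_that("DEM has positive variance inside every township block", {
  cfg <- landscape_config(nrow = 64, ncol = 64, cellsize = 150,
                          township_block_m = 2400, seed = 5)
  ls <- build_landscape(cfg)
  bs <- 16  # 2400 m / 150 m
  for (br in 0:3) {
    for (bc in 0:3) {
      expect_gt(sd(ls$dem$values[br * bs + 1:bs, bc * bs + 1:bs]), 0)
    }
  }
})

test_that("survey design honors the field layout and spacing", {
  d <- generate_design(c(0, 15000, 0, 15000), n_areas = 45,
                       sites_per_area = 9, min_spacing_m = 300,
                       visits = 3, seed = 10)
  expect_equal(nrow(d$sites), 405)
  expect_equal(nrow(d$visits), 1215)
  for (k in unique(d$sites$area_id)) {
    s <- d$sites[d$sites$area_id == k, ]
    expect_gte(min(dist(cbind(s$x, s$y))), 300)
  }
  expect_true(all(d$visits$time_min >= 345 & d$visits$time_min <= 600))
  expect_true(all(d$visits$julian >= 105 & d$visits$julian <= 212))
  # one site per area: spacing constraint vacuous
  d1 <- generate_design(c(0, 8000, 0, 8000), n_areas = 4, sites_per_area = 1,
                        seed = 2)
  expect_equal(nrow(d1$sites), 4)
})

test_that("infeasible designs raise design errors", {
  expect_error(
    generate_design(c(0, 15000, 0, 15000), n_areas = 4, sites_per_area = 9,
                    min_spacing_m = 5000, area_size_m = 1500),
    "design error"
  )
  expect_error(
    generate_design(c(0, 2000, 0, 2000), n_areas = 45),
    "design error"
  )
})

test_that("transect design produces the stated validation layout", {
  ext <- c(0, 80000, 0, 80000)
  td <- generate_transect_design(ext, seed = 3)
  expect_equal(nrow(td$sites), 150)
  expect_equal(length(unique(td$sites$area_id)), 10)
  # collinear points per transect at roughly the stated spacing
  for (t in 1:10) {
    s <- td$sites[td$sites$area_id == t, ]
    expect_equal(length(unique(s$y)), 1)
    gaps <- diff(sort(s$x))
    expect_true(all(abs(gaps - 5000) < 600))
  }
  expect_equal(nrow(generate_transect_design(ext, n_transects = 0)$sites), 0)
  expect_error(generate_transect_design(ext, point_spacing_m = 0), "design error")
  expect_error(generate_transect_design(c(0, 10000, 0, 10000)), "design error")
})

test_that("simulated counts respect the detection limits and latent truth", {
  des <- make_design(60, 6, seed = 31)
  Z <- matrix(rnorm(60), 60, 1, dimnames = list(NULL, "a"))
  # zero detection: every count is zero
  p0 <- true_parameters(beta0 = log(4), beta = c(a = 0.3), sigma = 0.2,
                        fixed_p = 0)
  d0 <- simulate_counts(des, Z, p0, seed = 1)
  expect_true(all(d0$visits$count == 0))
  # perfect detection: every visit records N exactly
  p1 <- true_parameters(beta0 = log(4), beta = c(a = 0.3), sigma = 0.2,
                        fixed_p = 1)
  d1 <- simulate_counts(des, Z, p1, seed = 1)
  y <- matrix(d1$visits$count, 60, 3, byrow = TRUE)
  expect_true(all(y == d1$truth$N))
  # counts never exceed the latent abundance
  pm <- true_parameters(beta0 = log(4), beta = c(a = 0.3), sigma = 0.2)
  dm <- simulate_counts(des, Z, pm, seed = 5)
  ym <- matrix(dm$visits$count, 60, 3, byrow = TRUE)
  expect_true(all(ym <= dm$truth$N))
  # bit-identical under the same seed
  dm2 <- simulate_counts(des, Z, pm, seed = 5)
  expect_identical(dm$visits$count, dm2$visits$count)
})

test_that("simulated counts match the derived Poisson-thinning moments", {
  # lambda = 5, p = 0.4: each visit count is marginally Poisson(2), and
  # visits within a site covary through N with cov = p^2 * lambda
  n <- 4000
  des <- make_design(n, 40, seed = 41)
  Z <- matrix(0, n, 1, dimnames = list(NULL, "a"))
  pars <- true_parameters(beta0 = log(5), beta = c(a = 0), sigma = 0,
                          fixed_p = 0.4)
  d <- simulate_counts(des, Z, pars, seed = 9)
  y <- matrix(d$visits$count, n, 3, byrow = TRUE)
  m <- mean(y)
  se <- sd(y) / sqrt(length(y))        # conservative: ignores within-site cor
  expect_lt(abs(m - 2), 3 * se * sqrt(3))
  expect_lt(abs(var(as.vector(y)) - 2), 0.2)
  expect_lt(abs(cov(y[, 1], y[, 2]) - 0.4^2 * 5), 0.2)
  # conditional independence: residuals y_ij - N_i p are uncorrelated
  r <- y - d$truth$N * 0.4
  expect_lt(abs(cor(r[, 1], r[, 2])), 0.05)
})

test_that("survey datasets round-trip through the CSV interface", {
  des <- make_design(12, 3, seed = 2)
  pars <- true_parameters(beta0 = 1, beta = c(a = 0.2), sigma = 0.1)
  d <- simulate_counts(des, matrix(rnorm(12), 12, 1,
                                   dimnames = list(NULL, "a")), pars)
  dir <- tempfile()
  write_survey_csvs(d, dir)
  d2 <- read_survey_csvs(dir)
  expect_equal(d2$sites$x, d$sites$x)
  expect_equal(d2$visits$count, d$visits$count)
  unlink(dir, recursive = TRUE)
})
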