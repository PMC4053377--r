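test_that("max-count index scans rows and rejects empty sites", {
  expect_equal(unname(max_count_index(rbind(c(2, 0, 5)))), 5)
  expect_equal(unname(max_count_index(rbind(c(0, 0, 0)))), 0)
  set.seed(22)
  y <- matrix(rpois(60, 3), 20, 3)
  expect_equal(unname(max_count_index(y)), apply(y, 1, max))
  y[3, ] <- NA
  expect_error(max_count_index(y), "no visits")
  # dataset interface ignores missing visits
  des <- make_design(5, 1, seed = 1)
  des$visits$count <- rep(c(1, NA, 4), 5)
  expect_equal(unname(max_count_index(des)), rep(4, 5))
})

test_that("Spearman rho hits the exact limits and the tie formula", {
  x <- c(4, 1, 7, 3, 9)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  set.seed(23)
  a <- sample(1:5, 40, replace = TRUE)
  b <- a + sample(0:3, 40, replace = TRUE)
  expect_equal(spearman_rho(a, b), cor(rank(a), rank(b)))
  expect_warning(r <- spearman_rho(rep(2, 5), 1:5), "constant")
  expect_true(is.na(r))
})

test_that("standardized RMSE removes affine maps and matches the formula", {
  set.seed(24)
  o <- rnorm(50, 10, 3)
  expect_lt(standardized_rmse(o, 2.5 * o + 7), 1e-12)
  p <- rnorm(50)
  zo <- (o - mean(o)) / sd(o); zp <- (p - mean(p)) / sd(p)
  expect_equal(standardized_rmse(o, p), sqrt(mean((zo - zp)^2)))
  expect_error(standardized_rmse(o, rep(1, 50)), "constant")
})

test_that("calibration regression matches closed-form OLS", {
  set.seed(25)
  zp <- rnorm(30)
  zo <- 0.8 * zp + rnorm(30, 0, 0.4)
  cal <- calibration_regression(zo, zp)
  bhat <- cov(zo, zp) / var(zp)
  expect_equal(cal$slope, bhat)
  expect_equal(cal$intercept, mean(zo) - bhat * mean(zp))
  # identity data fall on the identity line (lm warns about the perfect fit)
  cal1 <- suppressWarnings(calibration_regression(zp, zp))
  expect_equal(cal1$slope, 1)
  expect_equal(cal1$intercept, 0)
  # independent noise at large n: slope near zero
  set.seed(26)
  z1 <- rnorm(4000); z2 <- rnorm(4000)
  expect_lt(abs(calibration_regression(z1, z2)$slope), 0.06)
})

test_that("Moran's I equals -1 on a checkerboard and +1 for two tight clusters", {
  g <- expand.grid(x = 1:8, y = 1:8)
  vals <- ifelse((g$x + g$y) %% 2 == 0, 1, -1)
  expect_equal(morans_i(vals, g$x, g$y, c(0, 1)), -1)
  # two identical distant clusters, within-cluster band
  x <- c(rep(0, 5) + runif(5, 0, 0.1), rep(100, 5) + runif(5, 0, 0.1))
  y2 <- runif(10, 0, 0.1)
  v <- rep(c(5, -5), each = 5)
  expect_gt(morans_i(v, x, y2, c(0, 1)), 0.99)
  expect_warning(r <- morans_i(rep(1, 9), 1:9, 1:9, c(0, 2)), "constant")
  expect_true(is.na(r))
})

test_that("Moran's I matches the double-loop formula on random data", {
  set.seed(27)
  n <- 40
  x <- runif(n, 0, 100); y <- runif(n, 0, 100); v <- rnorm(n)
  band <- c(10, 40)
  num <- 0; W <- 0
  for (i in 1:n) {
    for (j in 1:n) {
      if (i != j) {
        dij <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
        if (dij > band[1] && dij <= band[2]) {
          num <- num + (v[i] - mean(v)) * (v[j] - mean(v))
          W <- W + 1
        }
      }
    }
  }
  oracle <- (n / W) * num / sum((v - mean(v))^2)
  expect_lt(abs(morans_i(v, x, y, band) - oracle), 1e-12)
})

test_that("a single band spanning all pairs equals global Moran's I", {
  set.seed(28)
  n <- 30
  x <- runif(n); y <- runif(n); v <- rnorm(n)
  cg <- correlogram(v, x, y, band_width = 10, max_distance = 10)
  expect_equal(cg$I[1], morans_i(v, x, y, c(0, 10)))
})

test_that("iid values show no autocorrelation beyond permutation noise", {
  set.seed(29)
  n <- 120
  x <- runif(n, 0, 1000); y <- runif(n, 0, 1000); v <- rnorm(n)
  cg <- correlogram(v, x, y, band_width = 200, max_distance = 1000)
  # permutation oracle for the null spread of I in each band
  for (k in seq_len(nrow(cg))) {
    if (is.na(cg$I[k])) next
    perm <- replicate(199, morans_i(sample(v), x, y,
                                    c(cg$band_lo[k], cg$band_hi[k])))
    expect_lt(abs(cg$I[k] - mean(perm)), 4 * sd(perm))
  }
})

test_that("QQ pairs use the (i - 0.5)/n plotting convention", {
  q3 <- qq_points(c(5, -1, 2))
  expect_equal(q3$theoretical, qnorm(c(0.5, 1.5, 2.5) / 3))
  expect_equal(q3$sample, c(-1, 2, 5))
  # symmetric input: pairs antisymmetric about the median
  sym <- c(-3, -1, 0, 1, 3)
  q5 <- qq_points(sym)
  expect_equal(q5$sample, -rev(q5$sample))
  expect_equal(q5$theoretical, -rev(q5$theoretical))
  # standard normal sample tracks the theoretical line
  set.seed(30)
  qn <- qq_points(rnorm(5000))
  expect_lt(max(abs(qn$sample - qn$theoretical)[abs(qn$theoretical) < 2]), 0.15)
})

test_that("rank-based validation is invariant to monotone prediction transforms", {
  set.seed(31)
  obs <- rpois(50, 4)
  pred <- obs + rnorm(50, 0, 2)
  r1 <- spearman_rho(obs, pred)
  expect_equal(spearman_rho(obs, exp(pred / 3)), r1)
})
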