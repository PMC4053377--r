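test_that("marginal likelihood is monotone in K and stabilizes in the tail", {
  y <- c(1, 0, 2); lam <- 3; p <- c(0.3, 0.5, 0.7)
  lls <- sapply(3:60, function(K) site_marginal_loglik(y, lam, p, K))
  expect_true(all(diff(lls) >= 0))
  expect_lt(abs(site_marginal_loglik(y, lam, p, 60) -
                site_marginal_loglik(y, lam, p, 40)), 1e-12)
  expect_error(site_marginal_loglik(y, lam, p, 1), "K must be")
  expect_error(site_marginal_loglik(y, lam, c(0.3, 0.5, 1.2), 60))
})

test_that("Gelman-Rubin follows the between/within variance formula", {
  # identical chain means: statistic is sqrt((n-1)/n) < 1
  set.seed(2)
  a <- rnorm(100)
  expect_equal(gelman_rubin(cbind(a, rev(a))), sqrt(99 / 100))
  # grossly different means diverge past 1.1
  expect_gt(gelman_rubin(cbind(rnorm(100), rnorm(100, 50))), 1.1)
  # fixed small arrays match the hand-computed formula
  x <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 7))
  n <- 4
  W <- mean(apply(x, 2, var))
  B_over_n <- var(colMeans(x))
  expect_equal(gelman_rubin(x), sqrt(((n - 1) / n * W + B_over_n) / W))
  # zero variance everywhere is undefined
  expect_true(is.na(gelman_rubin(cbind(rep(1, 10), rep(1, 10)))))
})

test_that("posterior summaries use the empirical draw distribution", {
  draws <- cbind(theta = 1:100)
  s <- summarize_posterior(draws)
  expect_equal(s$mean, 50.5)
  expect_equal(s$q2.5, unname(quantile(1:100, 0.025)))
  expect_equal(s$q97.5, unname(quantile(1:100, 0.975)))
  set.seed(6)
  sym <- cbind(z = rnorm(20000))
  ss <- summarize_posterior(sym)
  expect_lt(abs(ss$mean - median(sym)), 0.03)
})

test_that("sampler agrees with the Poisson-regression oracle under perfect detection", {
  n <- 150
  des <- make_design(n, 1, seed = 51)
  Z <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "a"))
  pars <- true_parameters(beta0 = log(4), beta = c(a = 0.5), sigma = 0,
                          fixed_p = 1)
  d <- simulate_counts(des, Z, pars, seed = 3)
  fit <- run_mcmc(d, as_std(Z),
                  model_spec(abundance = "a", fixed_p = 1,
                             random_intercept = FALSE),
                  mcmc_config(n_chains = 2, n_iter = 2000, burn = 400,
                              thin = 4, seed = 8))
  # with p = 1 the mixture collapses to Poisson regression on the counts
  g <- glm(d$visits$count[d$visits$visit == 1] ~ Z, family = poisson)
  s <- fit$summary
  expect_lt(abs(s$mean[s$param == "(Intercept)"] - coef(g)[1]),
            3 * s$sd[s$param == "(Intercept)"])
  expect_lt(abs(s$mean[s$param == "a"] - coef(g)[2]),
            3 * s$sd[s$param == "a"])
})

test_that("seeded MCMC runs are exactly reproducible", {
  n <- 45
  des <- make_design(n, 5, seed = 61)
  Z <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "a"))
  pars <- true_parameters(beta0 = 1, beta = c(a = 0.4), sigma = 0.2)
  d <- simulate_counts(des, Z, pars, seed = 4)
  cfg <- mcmc_config(n_chains = 2, n_iter = 600, burn = 100, thin = 2, seed = 5)
  f1 <- run_mcmc(d, as_std(Z), model_spec(abundance = "a"), cfg)
  f2 <- run_mcmc(d, as_std(Z), model_spec(abundance = "a"), cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$D_rep, f2$D_rep)
})

test_that("doubling the truncation bound leaves the fitted likelihood unchanged", {
  n <- 45
  des <- make_design(n, 5, seed = 71)
  Z <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "a"))
  pars <- true_parameters(beta0 = 1, beta = c(a = 0.4), sigma = 0.2)
  d <- simulate_counts(des, Z, pars, seed = 6)
  fit <- run_mcmc(d, as_std(Z), model_spec(abundance = "a"),
                  mcmc_config(n_chains = 2, n_iter = 600, burn = 100,
                              thin = 2, seed = 5))
  expect_lt(abs(nmix_total_loglik(fit, fit$K) -
                nmix_total_loglik(fit, 2L * fit$K)), 1e-6)
})

test_that("relabeling sites within an area leaves posterior summaries invariant", {
  n <- 45
  des <- make_design(n, 5, seed = 81)
  Z <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "a"))
  pars <- true_parameters(beta0 = 1.2, beta = c(a = 0.4), sigma = 0.2)
  d <- simulate_counts(des, Z, pars, seed = 7)
  # swap the first two sites (same area): permute site rows, covariates,
  # and visit blocks consistently
  perm <- c(2, 1, 3:n)
  d2 <- d
  d2$sites <- d$sites[perm, ]
  vis <- do.call(rbind, split(d$visits, match(d$visits$site_id, d$sites$site_id))[perm])
  d2$visits <- vis
  cfg <- mcmc_config(n_chains = 2, n_iter = 600, burn = 100, thin = 2, seed = 5)
  f1 <- run_mcmc(d, as_std(Z), model_spec(abundance = "a"), cfg)
  f2 <- run_mcmc(d2, as_std(Z[perm, , drop = FALSE]),
                 model_spec(abundance = "a"), cfg)
  # identical data under a within-area relabeling: same posterior up to
  # floating-point summation order
  expect_equal(f1$summary$mean, f2$summary$mean, tolerance = 1e-6)
  expect_equal(f1$rhat, f2$rhat, tolerance = 1e-4)
})

test_that("posterior predictive check is directional and validates input", {
  n <- 60
  des <- make_design(n, 6, seed = 91)
  Z <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "a"))
  pars <- true_parameters(beta0 = 1.2, beta = c(a = 0.3), sigma = 0.2)
  d <- simulate_counts(des, Z, pars, seed = 8)
  # grossly inflated counts: replicated data can never look as extreme
  d10 <- d
  d10$visits$count <- d$visits$count * 10L
  fit <- run_mcmc(d10, as_std(Z), model_spec(abundance = "a"),
                  mcmc_config(n_chains = 2, n_iter = 1000, burn = 200,
                              thin = 2, seed = 9))
  expect_lt(posterior_predictive_pvalue(fit)$p, 0.05)
})
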