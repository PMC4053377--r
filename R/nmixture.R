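#' Model specification for the hierarchical N-mixture model
#'
#' Defines which standardized covariate columns enter the abundance linear
#' predictor (log link), which of them also get a quadratic term, and which
#' visit-level covariates drive detection (logit link, with a quadratic in
#' time of day). The latent-abundance sum is truncated at `K`.
#'
#' @param abundance Character vector of covariate column names entering the
#'   abundance predictor linearly.
#' @param quadratic Subset of `abundance` whose squared (standardized) value
#'   is also included.
#' @param detection Character vector of visit-covariate names; the default
#'   `c("time", "time_sq", "julian")` gives a quadratic time-of-day effect
#'   and a linear Julian-date effect. Ignored when `fixed_p` is given.
#' @param fixed_p Optional fixed detection probability in (0, 1]; when set,
#'   detection covariates are dropped and every visit shares this constant
#'   (useful for degenerate checks, e.g. perfect detection).
#' @param random_intercept Fit an area-level random intercept (default
#'   `TRUE`); the model is `log lambda_i = x_i' beta + gamma_{k(i)}` with
#'   `gamma_k ~ Normal(0, sigma^2)`.
#' @param K Truncation bound for the latent-abundance sum; `NULL` (default)
#'   uses `max(y) + ceiling(10 * sqrt(max(y))) + 50`, far into the Poisson
#'   tail.
#' @param prior_sd_beta,prior_sd_alpha SD of the mean-zero normal priors on
#'   abundance and detection coefficients (diffuse by default).
#' @param sigma_upper Upper bound of the uniform prior on the
#'   random-intercept SD.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(abundance, quadratic = character(),
                       detection = c("time", "time_sq", "julian"),
                       fixed_p = NULL, random_intercept = TRUE, K = NULL,
                       prior_sd_beta = 10, prior_sd_alpha = 10,
                       sigma_upper = 10) {
  stopifnot(all(quadratic %in% abundance))
  if (!is.null(fixed_p)) {
    stopifnot(length(fixed_p) == 1, fixed_p > 0, fixed_p <= 1)
    detection <- character()
  }
  structure(
    list(
      abundance = abundance, quadratic = quadratic, detection = detection,
      fixed_p = fixed_p, random_intercept = isTRUE(random_intercept), K = K,
      prior_sd_beta = prior_sd_beta, prior_sd_alpha = prior_sd_alpha,
      sigma_upper = sigma_upper
    ),
    class = "model_spec"
  )
}

#' MCMC settings
#'
#' Defaults follow common practice for this model class: 3 chains of 35,000
#' iterations, a 5,000-iteration burn-in, and every 50th iteration retained.
#' [smoke_mcmc_config()] gives reduced desk-scale settings for tests and
#' examples.
#'
#' @param n_chains Number of chains.
#' @param n_iter Iterations per chain.
#' @param burn Burn-in iterations discarded from each chain (proposal
#'   scales adapt only during burn-in).
#' @param thin Thinning interval.
#' @param seed Integer seed; chain `c` runs under `seed + c - 1`.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 35000, burn = 5000,
                        thin = 50, seed = 1) {
  stopifnot(n_chains >= 1, burn < n_iter, thin >= 1)
  structure(
    list(n_chains = n_chains, n_iter = n_iter, burn = burn, thin = thin,
         seed = as.integer(seed)),
    class = "mcmc_config"
  )
}

#' @rdname mcmc_config
#' @export
smoke_mcmc_config <- function(seed = 1) {
  mcmc_config(n_chains = 3, n_iter = 3000, burn = 1500, thin = 5, seed = seed)
}

#' Exact marginal log-likelihood of repeated counts at one or more sites
#'
#' Computes `log sum_{N = max(y)}^{K} Poisson(N; lambda) prod_j
#' Binomial(y_j; N, p_j)`, the site contribution to the binomial-Poisson
#' mixture likelihood with the latent abundance summed out. The full
#' truncated sum is evaluated exactly (no tail cutoff).
#'
#' @param y Integer vector of visit counts for one site, or an
#'   `n x J` matrix for `n` sites.
#' @param lambda Poisson mean(s); scalar or length-`n` vector, all positive.
#' @param p Detection probabilities, same shape as `y`, in `[0, 1]`.
#' @param K Truncation bound; must be at least `max(y)`.
#' @return Numeric vector of per-site log-likelihoods.
#' @export
site_marginal_loglik <- function(y, lambda, p, K) {
  if (!is.matrix(y)) y <- matrix(y, nrow = 1)
  if (!is.matrix(p)) p <- matrix(p, nrow = nrow(y), ncol = ncol(y), byrow = TRUE)
  stopifnot(
    all(y >= 0), all(y == round(y)),
    all(p >= 0), all(p <= 1),
    length(lambda) %in% c(1, nrow(y)), all(lambda > 0),
    length(K) == 1
  )
  if (K < max(y)) stop("K must be at least the largest observed count", call. = FALSE)
  lambda <- rep_len(lambda, nrow(y))
  storage.mode(y) <- "integer"
  cpp_site_marginal_loglik(y, log(lambda), p, as.integer(K))
}

default_K <- function(y) {
  m <- max(y)
  as.integer(m + ceiling(10 * sqrt(m)) + 50)
}

# counts matrix (sites x visits) from the visits table, ordered by site
counts_matrix <- function(dataset) {
  v <- dataset$visits
  sids <- dataset$sites$site_id
  J <- max(v$visit)
  y <- matrix(NA_integer_, length(sids), J)
  y[cbind(match(v$site_id, sids), v$visit)] <- as.integer(v$count)
  if (anyNA(y)) stop("every site needs a count for every visit", call. = FALSE)
  y
}

# detection design array (n x J x p) built from the visits table with
# covariates standardized across all site-visits; the quadratic is the
# square of the standardized time term
detection_design <- function(dataset, detection) {
  v <- dataset$visits
  sids <- dataset$sites$site_id
  J <- max(v$visit)
  n <- length(sids)
  ord <- order(match(v$site_id, sids), v$visit)
  v <- v[ord, ]
  raw <- cbind(time = v$time_min, julian = v$julian)
  s <- standardize_columns(raw)
  base <- list(
    time = matrix(s$z[, "time"], n, J, byrow = TRUE),
    time_sq = matrix(s$z[, "time"]^2, n, J, byrow = TRUE),
    julian = matrix(s$z[, "julian"], n, J, byrow = TRUE)
  )
  unknown <- setdiff(detection, names(base))
  if (length(unknown)) {
    stop("unknown detection term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  arr <- array(0, dim = c(n, J, 1 + length(detection)))
  arr[, , 1] <- 1
  for (m in seq_along(detection)) arr[, , m + 1] <- base[[detection[m]]]
  dimnames(arr) <- list(NULL, NULL, c("p_(Intercept)", paste0("p_", detection)))
  list(arr = arr, center = s$center, scale = s$scale)
}

# abundance design matrix from a std_matrix and a model_spec
abundance_design <- function(covariates, spec) {
  z <- covariates$z
  missing <- setdiff(spec$abundance, colnames(z))
  if (length(missing)) {
    stop("covariate column(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, z[, spec$abundance, drop = FALSE])
  for (q in spec$quadratic) {
    qc <- z[, q]^2
    X <- cbind(X, qc)
    colnames(X)[ncol(X)] <- paste0(q, "^2")
  }
  X
}

#' Fit the hierarchical N-mixture model by MCMC
#'
#' Runs an adaptive Metropolis-within-Gibbs sampler on the N-marginalized
#' binomial-Poisson likelihood: site abundance `N_i ~ Poisson(lambda_i)`
#' with `log lambda_i = x_i' beta + gamma_k` and area effects
#' `gamma_k ~ Normal(0, sigma^2)` (non-centered), observed counts
#' `y_ij ~ Binomial(N_i, p_ij)` with `logit p_ij` linear in the visit
#' covariates. Proposal scales adapt during burn-in only. At each retained
#' draw the latent `N_i` are sampled from their truncated conditional, and
#' chi-squared discrepancies for the observed and replicated counts are
#' accumulated for the posterior predictive check.
#'
#' @param dataset A `survey_dataset` (see [simulate_counts()] or the CSV
#'   readers); its `visits` table supplies counts and detection covariates.
#' @param covariates A `std_matrix` of standardized site covariates whose
#'   rows align with `dataset$sites`.
#' @param spec A [model_spec()].
#' @param config An [mcmc_config()].
#' @return An object of class `nmix_fit`: retained draws (all chains, with
#'   a `chain` attribute), per-parameter summary and Gelman-Rubin
#'   statistics, acceptance rates, discrepancy pairs, posterior-mean site
#'   abundance, and the data/design used.
#' @export
run_mcmc <- function(dataset, covariates, spec, config = mcmc_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "mcmc_config"),
            inherits(covariates, "std_matrix"))
  y <- counts_matrix(dataset)
  n <- nrow(y)
  stopifnot(nrow(covariates$z) == n)
  X <- abundance_design(covariates, spec)
  area <- as.integer(factor(dataset$sites$area_id))
  narea <- max(area)
  fit_sigma <- spec$random_intercept && narea > 1

  if (is.null(spec$fixed_p)) {
    dd <- detection_design(dataset, spec$detection)
    Xdet <- dd$arr
    fixed_p <- -1
  } else {
    Xdet <- array(0, dim = c(n, ncol(y), 0))
    dd <- NULL
    # the marginalized-likelihood decomposition needs p < 1; nudging by
    # 1e-9 changes log-likelihoods by O(1e-9 * sum(y))
    fixed_p <- min(spec$fixed_p, 1 - 1e-9)
  }
  pd <- dim(Xdet)[3]
  K <- if (is.null(spec$K)) default_K(y) else as.integer(spec$K)
  if (K < max(y)) stop("K must be at least the largest observed count", call. = FALSE)

  par_names <- c(
    colnames(X),
    if (pd > 0) dimnames(Xdet)[[3]],
    "sigma_area",
    sprintf("gamma[%d]", seq_len(narea))
  )

  maxc <- apply(y, 1, max)
  chains <- vector("list", config$n_chains)
  for (cc in seq_len(config$n_chains)) {
    set.seed(config$seed + cc - 1L)
    beta0 <- c(log(mean(maxc) + 0.5), rep(0, ncol(X) - 1)) +
      stats::rnorm(ncol(X), 0, 0.05)
    alpha0 <- if (pd > 0) stats::rnorm(pd, 0, 0.05) else numeric()
    sigma0 <- stats::runif(1, 0.1, 0.5)
    chains[[cc]] <- cpp_nmix_mcmc(
      y, X, as.numeric(Xdet), dim(Xdet), area - 1L, narea, K, fixed_p,
      spec$prior_sd_beta, spec$prior_sd_alpha, spec$sigma_upper, fit_sigma,
      config$n_iter, config$burn, config$thin, beta0, alpha0, sigma0
    )
  }

  n_keep <- nrow(chains[[1]]$draws)
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  colnames(draws) <- par_names
  chain_id <- rep(seq_len(config$n_chains), each = n_keep)

  rhat <- vapply(seq_len(ncol(draws)), function(j) {
    gelman_rubin(matrix(draws[, j], nrow = n_keep))
  }, 0)
  names(rhat) <- par_names
  # parameters that were not sampled (e.g. sigma when fixed) have zero
  # variance and undefined Rhat; drop them from the convergence summary
  rhat <- rhat[!is.na(rhat)]

  fit <- structure(
    list(
      draws = draws, chain = chain_id, rhat = rhat,
      accept_rate = lapply(chains, `[[`, "accept_rate"),
      D_obs = unlist(lapply(chains, `[[`, "D_obs")),
      D_rep = unlist(lapply(chains, `[[`, "D_rep")),
      N_mean = rowMeans(do.call(cbind, lapply(chains, `[[`, "N_mean"))),
      loglik = unlist(lapply(chains, `[[`, "loglik")),
      spec = spec, config = config, K = K,
      y = y, X = X, Xdet = Xdet, area = area, fixed_p = fixed_p,
      det_constants = if (!is.null(dd)) list(center = dd$center, scale = dd$scale),
      n_sites = n, n_areas = narea
    ),
    class = "nmix_fit"
  )
  fit$summary <- summarize_posterior(fit)
  fit$bayes_p <- posterior_predictive_pvalue(fit)$p
  fit
}

#' @export
print.nmix_fit <- function(x, ...) {
  cat(sprintf(
    "<nmix_fit> %d sites, %d areas, %d visits; K = %d\n",
    x$n_sites, x$n_areas, ncol(x$y), x$K
  ))
  cat(sprintf(
    "  %d chains x %d retained draws; max Rhat = %.3f; Bayesian p = %.3f\n",
    x$config$n_chains, nrow(x$draws) / x$config$n_chains,
    max(x$rhat), x$bayes_p
  ))
  print(utils::head(x$summary, 15), digits = 3)
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Compares between-chain and within-chain variance for one parameter:
#' with `m` chains of `n` draws, `W` the mean within-chain variance and
#' `B/n` the variance of the chain means, the statistic is
#' `sqrt(((n-1)/n * W + B/n) / W)`. Values below 1.1 are conventionally
#' read as convergence; with identical chain means the statistic is
#' `sqrt((n-1)/n) < 1`.
#'
#' @param x Matrix of draws (iterations x chains) or a list of equal-length
#'   numeric vectors, one per chain.
#' @return The statistic, or `NA` if within-chain variance is zero in all
#'   chains (undefined).
#' @export
gelman_rubin <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  stopifnot(is.matrix(x), ncol(x) >= 1, nrow(x) >= 2)
  if (ncol(x) < 2) {
    # single chain: split in half so the diagnostic is still informative
    h <- nrow(x) %/% 2
    x <- cbind(x[seq_len(h), 1], x[h + seq_len(h), 1])
  }
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B_over_n <- stats::var(colMeans(x))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Posterior summary table
#'
#' Mean, SD, and the 2.5%/97.5% empirical quantiles (type-7 convention) of
#' each parameter's retained draws.
#'
#' @param fit An `nmix_fit`, or a draws matrix with named columns.
#' @return Data frame with columns `param`, `mean`, `sd`, `q2.5`, `q97.5`.
#' @export
summarize_posterior <- function(fit) {
  draws <- if (inherits(fit, "nmix_fit")) fit$draws else as.matrix(fit)
  if (nrow(draws) == 0) stop("no retained draws", call. = FALSE)
  q <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), type = 7))
  data.frame(
    param = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    q2.5 = q[, 1], q97.5 = q[, 2],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Posterior predictive check (chi-squared discrepancy)
#'
#' For each retained draw, the fitting step computed the discrepancy
#' `D = sum_ij (y_ij - N_i p_ij)^2 / (N_i p_ij + 0.5)` for the observed
#' counts and for counts replicated from the fitted process (same drawn
#' `N_i`). The Bayesian p-value is the fraction of draws where the
#' replicated discrepancy exceeds the observed one; ties count 0.5. Values
#' near 0.5 indicate an adequate model; values near 0 or 1 indicate misfit.
#'
#' @param fit An `nmix_fit`.
#' @return List with `p`, and the `D_obs`/`D_rep` vectors.
#' @export
posterior_predictive_pvalue <- function(fit) {
  stopifnot(inherits(fit, "nmix_fit"))
  if (length(fit$D_obs) == 0) stop("no retained draws", call. = FALSE)
  p <- mean(fit$D_rep > fit$D_obs) + 0.5 * mean(fit$D_rep == fit$D_obs)
  list(p = p, D_obs = fit$D_obs, D_rep = fit$D_rep)
}

#' Total marginal log-likelihood at the posterior mean
#'
#' Evaluates the exact (full-sum) marginalized likelihood of the fitted
#' dataset at the posterior-mean parameters, under an arbitrary truncation
#' bound. Useful to verify that `K` was chosen far enough into the Poisson
#' tail: doubling `K` should not change the value.
#'
#' @param fit An `nmix_fit`.
#' @param K Truncation bound (default: the bound used in fitting).
#' @return Total log-likelihood (scalar).
#' @export
nmix_total_loglik <- function(fit, K = fit$K) {
  s <- summarize_posterior(fit)
  est <- stats::setNames(s$mean, s$param)
  beta <- est[colnames(fit$X)]
  eta <- drop(fit$X %*% beta)
  gam <- est[sprintf("gamma[%d]", fit$area)]
  eta <- eta + ifelse(is.na(gam), 0, gam)
  pd <- dim(fit$Xdet)[3]
  if (pd > 0) {
    alpha <- est[dimnames(fit$Xdet)[[3]]]
    etad <- matrix(0, nrow(fit$y), ncol(fit$y))
    for (m in seq_len(pd)) etad <- etad + fit$Xdet[, , m] * alpha[m]
    P <- stats::plogis(etad)
  } else {
    P <- matrix(fit$fixed_p, nrow(fit$y), ncol(fit$y))
  }
  sum(cpp_site_marginal_loglik(fit$y, eta, P, as.integer(K)))
}

#' Fitted detection probabilities and max-count residuals
#'
#' `fitted_detection` evaluates the detection model at the posterior-mean
#' coefficients for every site-visit. `nmix_residuals` returns the per-site
#' residual used for the spatial and distributional diagnostics: the
#' observed maximum count over visits minus its fitted expectation,
#' approximated by `N_mean_i * max_j p_ij` (posterior-mean abundance times
#' the best visit's detection probability).
#'
#' @param fit An `nmix_fit`.
#' @return `fitted_detection`: matrix of probabilities (sites x visits);
#'   `nmix_residuals`: data frame with `observed`, `expected`, `residual`.
#' @export
fitted_detection <- function(fit) {
  stopifnot(inherits(fit, "nmix_fit"))
  pd <- dim(fit$Xdet)[3]
  if (pd == 0) {
    return(matrix(fit$fixed_p, nrow(fit$y), ncol(fit$y)))
  }
  s <- summarize_posterior(fit)
  alpha <- stats::setNames(s$mean, s$param)[dimnames(fit$Xdet)[[3]]]
  etad <- matrix(0, nrow(fit$y), ncol(fit$y))
  for (m in seq_len(pd)) etad <- etad + fit$Xdet[, , m] * alpha[m]
  stats::plogis(etad)
}

#' @rdname fitted_detection
#' @export
nmix_residuals <- function(fit) {
  P <- fitted_detection(fit)
  obs <- apply(fit$y, 1, max)
  expected <- fit$N_mean * apply(P, 1, max)
  data.frame(observed = obs, expected = expected,
             residual = obs - expected)
}
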