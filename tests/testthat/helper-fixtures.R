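# In-code fixtures shared across test files.

# survey design skeleton without a landscape: n sites nested in areas,
# J visits with covariates drawn in the survey windows
make_design <- function(n_sites, n_areas, visits = 3, seed = 1) {
  set.seed(seed)
  sites <- data.frame(
    site_id = seq_len(n_sites),
    area_id = rep(seq_len(n_areas), length.out = n_sites),
    x = runif(n_sites, 0, 20000), y = runif(n_sites, 0, 20000),
    year = sample(2010:2012, n_sites, replace = TRUE)
  )
  sites <- sites[order(sites$area_id), ]
  sites$site_id <- seq_len(n_sites)
  visits_df <- data.frame(
    site_id = rep(sites$site_id, each = visits),
    visit = rep(seq_len(visits), n_sites),
    time_min = runif(n_sites * visits, 345, 600),
    julian = round(runif(n_sites * visits, 105, 212)),
    count = NA_integer_
  )
  structure(list(sites = sites, visits = visits_df, truth = NULL),
            class = "survey_dataset")
}

# standardized-covariate container around an already-standardized matrix
as_std <- function(Z) {
  structure(
    list(z = Z,
         center = stats::setNames(rep(0, ncol(Z)), colnames(Z)),
         scale = stats::setNames(rep(1, ncol(Z)), colnames(Z))),
    class = "std_matrix"
  )
}

# independent R oracle: brute-force truncated double sum for the
# marginalized binomial-Poisson site likelihood
brute_site_loglik <- function(y, lam, p, K) {
  tot <- 0
  for (N in max(y):K) {
    tot <- tot + stats::dpois(N, lam) * prod(stats::dbinom(y, N, p))
  }
  log(tot)
}

# independent R oracle: brute-force circular focal proportion
brute_focal <- function(values, cellsize, radius_m) {
  nr <- nrow(values); nc <- ncol(values)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      num <- 0; den <- 0
      for (rr in seq_len(nr)) {
        for (cc in seq_len(nc)) {
          d2 <- ((rr - r)^2 + (cc - c)^2) * cellsize^2
          if (d2 <= radius_m^2 && !is.na(values[rr, cc])) {
            num <- num + values[rr, cc]
            den <- den + 1
          }
        }
      }
      if (den > 0) out[r, c] <- num / den
    }
  }
  out
}
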