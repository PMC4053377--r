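# Synthetic landscapes, survey designs, and count data with the exact
# stochastic structure the hierarchical N-mixture model assumes, with known
# true parameters for recovery testing.

#' Landscape generator settings
#'
#' @param nrow,ncol Grid dimensions in cells.
#' @param cellsize Cell edge (m); default 30 m, the resolution of typical
#'   classified land-cover products.
#' @param proportions Named vector of target cover proportions (fractions
#'   summing to at most 1); the default six classes mirror an agricultural
#'   landscape: CRP grassland, other grass, trees, small grains, row crops,
#'   wetlands.
#' @param corr_length_m Spatial correlation length (m) of the smoothed
#'   Gaussian fields that are thresholded into cover patches.
#' @param township_block_m Edge (m) of the square blocks used for the
#'   elevation index (default 9,656 m).
#' @param dem_base,dem_relief Mean elevation and relief scale (m) of the
#'   synthetic DEM.
#' @param seed Integer seed.
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(nrow = 400, ncol = 400, cellsize = 30,
                             proportions = c(
                               crp = 0.08, grass = 0.35, trees = 0.08,
                               smallgrains = 0.08, rowcrop = 0.25,
                               wetland = 0.03
                             ),
                             corr_length_m = 600, township_block_m = 9656,
                             dem_base = 600, dem_relief = 30, seed = 1) {
  stopifnot(nrow >= 2, ncol >= 2, cellsize > 0,
            all(proportions >= 0), all(proportions <= 1))
  if (sum(proportions) > 1 + 1e-12) {
    stop("cover proportions must sum to at most 1", call. = FALSE)
  }
  structure(
    list(nrow = nrow, ncol = ncol, cellsize = cellsize,
         proportions = proportions, corr_length_m = corr_length_m,
         township_block_m = township_block_m, dem_base = dem_base,
         dem_relief = dem_relief, seed = as.integer(seed)),
    class = "landscape_config"
  )
}

# smoothed Gaussian random field: white noise convolved with a Gaussian
# kernel (sd = range_cells), rescaled to unit variance
gaussian_field <- function(nr, nc, range_cells) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range_cells < 0.5) return(w)
  half <- ceiling(3 * range_cells)
  g <- stats::dnorm(-half:half, sd = range_cells)
  k <- outer(g, g)
  f <- fft_convolve2(w, k / sum(k))
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic landscape: cover rasters and a DEM
#'
#' Builds one smoothed Gaussian random field per cover class and assigns
#' cells to classes in order of the `proportions` vector: each class takes
#' its target share of cells from those not yet claimed, choosing the cells
#' where its field is highest. Classes are therefore mutually exclusive and
#' realized proportions match targets to within one cell. The DEM is an
#' independent smooth surface plus fine-scale noise, so every township
#' block has positive elevation variance.
#'
#' @param config A [landscape_config()].
#' @return List with `covers` (named list of binary `grid_raster`s) and
#'   `dem` (a `grid_raster`).
#' @export
build_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  nr <- config$nrow; nc <- config$ncol
  ncell <- nr * nc
  range_cells <- config$corr_length_m / config$cellsize
  remaining <- rep(TRUE, ncell)
  covers <- list()
  for (cl in names(config$proportions)) {
    fld <- as.vector(gaussian_field(nr, nc, range_cells))
    n_take <- round(config$proportions[[cl]] * ncell)
    take <- logical(ncell)
    if (n_take > 0) {
      cand <- which(remaining)
      n_take <- min(n_take, length(cand))
      take[cand[order(fld[cand], decreasing = TRUE)[seq_len(n_take)]]] <- TRUE
    }
    remaining <- remaining & !take
    covers[[cl]] <- grid_raster(matrix(as.numeric(take), nr, nc),
                                cellsize = config$cellsize)
  }
  dem_v <- config$dem_base +
    config$dem_relief * gaussian_field(nr, nc, range_cells) +
    0.5 * matrix(stats::rnorm(ncell), nr, nc)
  dem <- grid_raster(dem_v, cellsize = config$cellsize)
  list(covers = covers, dem = dem)
}

#' True generating parameters for simulation
#'
#' Coefficients are on the standardized-covariate scale. Defaults mirror
#' the mixed-scale pheasant worked example (see
#' [pheasant_scale_estimates()]): positive CRP/grass effects at the 1-km
#' management radius, a strong negative tree effect and positive crop
#' effects at the 5-km landscape radius, an area random-intercept SD of
#' 0.3, and a detection process peaking mid-morning and declining over the
#' season.
#'
#' @param beta0 Abundance intercept (log scale).
#' @param beta Named vector of abundance coefficients; a name ending in
#'   `^2` denotes the square of that standardized covariate.
#' @param sigma Random-intercept SD (>= 0).
#' @param alpha0,alpha_time,alpha_time_sq,alpha_julian Detection intercept
#'   and coefficients (logit scale, standardized visit covariates).
#' @param fixed_p Optional fixed detection probability in `[0, 1]`,
#'   overriding the logit model (0 and 1 give the no-detection and
#'   perfect-detection limits).
#' @return An object of class `true_parameters`.
#' @export
true_parameters <- function(beta0 = 3.07,
                            beta = c(
                              crp_1km = 0.23, grass_1km = 0.13,
                              wetland_1km = -0.10, trees_5km = -0.55,
                              `trees_5km^2` = 0.13, rowcrop_5km = 0.51,
                              `rowcrop_5km^2` = -0.05, smallgrains_5km = 0.45,
                              `smallgrains_5km^2` = -0.04,
                              elevation_index = -0.07, year = -0.16
                            ),
                            sigma = 0.3, alpha0 = 0, alpha_time = 0.3,
                            alpha_time_sq = -0.3, alpha_julian = -0.2,
                            fixed_p = NULL) {
  stopifnot(sigma >= 0, is.finite(beta0), all(is.finite(beta)))
  if (!is.null(fixed_p)) stopifnot(fixed_p >= 0, fixed_p <= 1)
  structure(
    list(beta0 = beta0, beta = beta, sigma = sigma, alpha0 = alpha0,
         alpha_time = alpha_time, alpha_time_sq = alpha_time_sq,
         alpha_julian = alpha_julian, fixed_p = fixed_p),
    class = "true_parameters"
  )
}

# visit covariates: times uniform on [sunrise - 15 min, 10:00] with
# sunrise at 06:00, Julian dates uniform on mid-April .. end of July
draw_visit_covariates <- function(n) {
  list(
    time_min = stats::runif(n, 345, 600),
    julian = as.integer(round(stats::runif(n, 105, 212)))
  )
}

new_survey_dataset <- function(sites, visits, truth = NULL) {
  structure(list(sites = sites, visits = visits, truth = truth),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf(
    "<survey_dataset> %d sites in %d areas, %d visit rows%s\n",
    nrow(x$sites), length(unique(x$sites$area_id)), nrow(x$visits),
    if (is.null(x$truth)) "" else " (simulated, latent truth attached)"
  ))
  invisible(x)
}

#' Generate a nested point-count survey design
#'
#' Places `n_areas` square management areas on non-overlapping blocks of
#' the landscape, then samples `sites_per_area` survey points uniformly
#' inside each area subject to a minimum pairwise spacing (rejection
#' sampling with bounded retries). Each site receives `visits` rows of
#' visit covariates; counts are left empty for [simulate_counts()].
#'
#' @param extent Extent to place areas in: a `grid_raster`, or a numeric
#'   `c(xmin, xmax, ymin, ymax)`.
#' @param n_areas Number of management areas (default 45).
#' @param sites_per_area Survey points per area (default 9).
#' @param min_spacing_m Minimum distance between points within an area
#'   (default 300 m).
#' @param visits Repeat visits per season (default 3).
#' @param area_size_m Edge of the square area footprint (default 1,500 m).
#' @param years Calendar years sampled per site (default 2010:2012).
#' @param seed Integer seed.
#' @return A `survey_dataset` skeleton (counts `NA`).
#' @export
generate_design <- function(extent, n_areas = 45, sites_per_area = 9,
                            min_spacing_m = 300, visits = 3,
                            area_size_m = 1500, years = 2010:2012, seed = 1) {
  if (inherits(extent, "grid_raster")) extent <- raster_extent(extent)
  stopifnot(length(extent) == 4, n_areas >= 1, sites_per_area >= 1, visits >= 1)
  set.seed(seed)
  width <- extent[2] - extent[1]; height <- extent[4] - extent[3]
  nbx <- floor(width / area_size_m); nby <- floor(height / area_size_m)
  if (nbx * nby < n_areas) {
    stop("design error: extent cannot host ", n_areas,
         " non-overlapping areas of ", area_size_m, " m", call. = FALSE)
  }
  # crude feasibility bound: each point excludes a disc of r = spacing/2
  if (sites_per_area > 1 &&
      sites_per_area * pi * (min_spacing_m / 2)^2 > 2 * area_size_m^2) {
    stop("design error: cannot place ", sites_per_area,
         " points at >= ", min_spacing_m, " m spacing in a ",
         area_size_m, " m area", call. = FALSE)
  }
  blocks <- sample(nbx * nby, n_areas)
  bx <- (blocks - 1) %% nbx
  by <- (blocks - 1) %/% nbx
  sites <- NULL
  sid <- 0L
  for (k in seq_len(n_areas)) {
    x0 <- extent[1] + bx[k] * area_size_m
    y0 <- extent[3] + by[k] * area_size_m
    placed <- NULL
    for (restart in 1:20) {
      placed <- matrix(numeric(0), 0, 2)
      ok <- TRUE
      for (s in seq_len(sites_per_area)) {
        hit <- FALSE
        for (try in 1:200) {
          px <- stats::runif(1, x0, x0 + area_size_m)
          py <- stats::runif(1, y0, y0 + area_size_m)
          if (nrow(placed) == 0 ||
              min(sqrt((placed[, 1] - px)^2 + (placed[, 2] - py)^2)) >=
                min_spacing_m) {
            placed <- rbind(placed, c(px, py))
            hit <- TRUE
            break
          }
        }
        if (!hit) { ok <- FALSE; break }
      }
      if (ok) break
      placed <- NULL
    }
    if (is.null(placed)) {
      stop("design error: failed to place points in area ", k,
           " after bounded retries", call. = FALSE)
    }
    sites <- rbind(sites, data.frame(
      site_id = sid + seq_len(sites_per_area), area_id = k,
      x = placed[, 1], y = placed[, 2],
      year = years[sample.int(length(years), sites_per_area, replace = TRUE)]
    ))
    sid <- sid + sites_per_area
  }
  n <- nrow(sites)
  vc <- draw_visit_covariates(n * visits)
  visits_df <- data.frame(
    site_id = rep(sites$site_id, each = visits),
    visit = rep(seq_len(visits), n),
    time_min = vc$time_min, julian = vc$julian,
    count = NA_integer_
  )
  new_survey_dataset(sites, visits_df)
}

#' Generate a roadside transect design for independent validation
#'
#' Lays out horizontal transects of regularly spaced points (with small
#' Gaussian jitter along the line), evenly distributed over the extent,
#' each visited `visits` times.
#'
#' @param extent A `grid_raster` or `c(xmin, xmax, ymin, ymax)`.
#' @param n_transects Number of transects (default 10); 0 gives an empty
#'   dataset.
#' @param points_per_transect Survey locations per transect (default 15).
#' @param point_spacing_m Spacing between successive locations (default
#'   5,000 m); must be positive.
#' @param jitter_sd_m SD of the along-line jitter (default 2% of spacing).
#' @param visits Repeat visits (default 3).
#' @param years Calendar year(s) assigned to transect sites (default 2012).
#' @param seed Integer seed.
#' @return A `survey_dataset` skeleton; `area_id` identifies the transect.
#' @export
generate_transect_design <- function(extent, n_transects = 10,
                                     points_per_transect = 15,
                                     point_spacing_m = 5000,
                                     jitter_sd_m = 0.02 * point_spacing_m,
                                     visits = 3, years = 2012, seed = 1) {
  if (inherits(extent, "grid_raster")) extent <- raster_extent(extent)
  if (n_transects == 0) {
    return(new_survey_dataset(
      data.frame(site_id = integer(), area_id = integer(), x = numeric(),
                 y = numeric(), year = integer()),
      data.frame(site_id = integer(), visit = integer(), time_min = numeric(),
                 julian = integer(), count = integer())
    ))
  }
  if (point_spacing_m <= 0) {
    stop("design error: point spacing must be positive", call. = FALSE)
  }
  set.seed(seed)
  width <- extent[2] - extent[1]
  len <- (points_per_transect - 1) * point_spacing_m
  margin <- 0.02 * width
  if (len + 2 * margin > width) {
    stop("design error: transect of ", len,
         " m exceeds the raster extent", call. = FALSE)
  }
  ys <- extent[3] + (seq_len(n_transects) - 0.5) /
    n_transects * (extent[4] - extent[3])
  sites <- NULL
  sid <- 0L
  for (t in seq_len(n_transects)) {
    x_start <- stats::runif(1, extent[1] + margin, extent[2] - margin - len)
    xs <- x_start + (seq_len(points_per_transect) - 1) * point_spacing_m +
      stats::rnorm(points_per_transect, 0, jitter_sd_m)
    xs <- pmin(pmax(xs, extent[1]), extent[2] - 1e-9)
    sites <- rbind(sites, data.frame(
      site_id = sid + seq_len(points_per_transect), area_id = t,
      x = xs, y = ys[t],
      year = years[sample.int(length(years), points_per_transect,
                              replace = TRUE)]
    ))
    sid <- sid + points_per_transect
  }
  n <- nrow(sites)
  vc <- draw_visit_covariates(n * visits)
  visits_df <- data.frame(
    site_id = rep(sites$site_id, each = visits),
    visit = rep(seq_len(visits), n),
    time_min = vc$time_min, julian = vc$julian,
    count = NA_integer_
  )
  new_survey_dataset(sites, visits_df)
}

#' Simulate counts from the binomial-Poisson process
#'
#' Draws `gamma_k ~ Normal(0, sigma^2)` per area,
#' `log lambda_i = beta0 + gamma_k + sum_m beta_m x_im`,
#' `N_i ~ Poisson(lambda_i)`, and per visit
#' `logit p_ij = alpha0 + a_t t + a_t2 t^2 + a_j jd` (standardized visit
#' covariates) with `y_ij ~ Binomial(N_i, p_ij)`. The latent truth
#' (`N`, `lambda`, `gamma`, `p`) is attached for recovery tests.
#'
#' @param design A `survey_dataset` skeleton with visit covariates.
#' @param covariates A `std_matrix` (or plain numeric matrix, assumed
#'   already standardized) whose rows align with `design$sites`; columns
#'   must cover the names of `params$beta` (a trailing `^2` in a name
#'   squares that column).
#' @param params A [true_parameters()].
#' @param seed Integer seed.
#' @return The `survey_dataset` with counts filled in and `truth` attached.
#' @export
simulate_counts <- function(design, covariates, params, seed = 1) {
  stopifnot(inherits(design, "survey_dataset"),
            inherits(params, "true_parameters"))
  z <- if (inherits(covariates, "std_matrix")) covariates$z else as.matrix(covariates)
  n <- nrow(design$sites)
  stopifnot(nrow(z) == n)
  set.seed(seed)
  eta <- rep(params$beta0, n)
  for (nm in names(params$beta)) {
    base <- sub("\\^2$", "", nm)
    if (!base %in% colnames(z)) {
      stop("covariate column not found: ", base, call. = FALSE)
    }
    xv <- if (grepl("\\^2$", nm)) z[, base]^2 else z[, base]
    eta <- eta + params$beta[[nm]] * xv
  }
  area <- as.integer(factor(design$sites$area_id))
  gam <- stats::rnorm(max(area), 0, params$sigma)
  eta <- eta + gam[area]
  if (any(!is.finite(eta))) stop("non-finite abundance predictor", call. = FALSE)
  lambda <- exp(eta)
  N <- stats::rpois(n, lambda)

  v <- design$visits
  ord <- order(match(v$site_id, design$sites$site_id), v$visit)
  v <- v[ord, ]
  if (is.null(params$fixed_p)) {
    s <- standardize_columns(cbind(time = v$time_min, julian = v$julian))
    tz <- s$z[, "time"]; jz <- s$z[, "julian"]
    eta_p <- params$alpha0 + params$alpha_time * tz +
      params$alpha_time_sq * tz^2 + params$alpha_julian * jz
    if (any(!is.finite(eta_p))) stop("non-finite detection predictor", call. = FALSE)
    p <- stats::plogis(eta_p)
  } else {
    p <- rep(params$fixed_p, nrow(v))
  }
  Nv <- N[match(v$site_id, design$sites$site_id)]
  v$count <- stats::rbinom(nrow(v), Nv, p)
  new_survey_dataset(
    design$sites, v,
    truth = list(N = N, lambda = lambda, gamma = gam, p = p, params = params)
  )
}

#' Write / read a survey dataset as a pair of CSV files
#'
#' `sites.csv` holds `site_id, area_id, x, y, year`; `visits.csv` holds
#' `site_id, visit, time_min, julian, count`.
#'
#' @param dataset A `survey_dataset`.
#' @param dir Directory for the two files (created if needed).
#' @return `write_survey_csvs`: the directory, invisibly;
#'   `read_survey_csvs`: a `survey_dataset` (without latent truth).
#' @export
write_survey_csvs <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  utils::write.csv(dataset$visits, file.path(dir, "visits.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_survey_csvs
#' @export
read_survey_csvs <- function(dir) {
  new_survey_dataset(
    utils::read.csv(file.path(dir, "sites.csv")),
    utils::read.csv(file.path(dir, "visits.csv"))
  )
}
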