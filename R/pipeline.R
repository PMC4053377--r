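# End-to-end orchestration of the synthetic study: landscape -> design ->
# counts -> covariates -> collinearity report -> single-scale fits ->
# scale decision -> mixed-scale fit -> diagnostics -> SDM + cubic
# correction -> independent transect validation, with every stage seeded
# deterministically from one global seed and all outputs manifested.

#' Configuration of a full synthetic study run
#'
#' Bundles the landscape generator settings, survey design sizes, true
#' simulation parameters, MCMC settings, and the two covariate radii. The
#' defaults mirror the full field design (45 areas x 9 points x 3 visits,
#' 10 transects of 15 points 5 km apart, 1 km and 5 km radii);
#' [smoke_run_config()] gives a reduced desk-scale configuration.
#'
#' @param landscape A [landscape_config()].
#' @param n_areas,sites_per_area,min_spacing_m,visits,area_size_m Survey
#'   design sizes (see [generate_design()]).
#' @param n_transects,points_per_transect,point_spacing_m Validation
#'   transect design (see [generate_transect_design()]).
#' @param params A [true_parameters()].
#' @param mcmc An [mcmc_config()].
#' @param radii_m Exactly two distinct positive focal radii (m).
#' @param band_width_m,max_band_m Correlogram bands for the residual
#'   diagnostics.
#' @param seed Global integer seed; per-stage seeds are derived as
#'   `seed * 100 + stage` and recorded in the manifest.
#' @return An object of class `run_config`.
#' @export
run_config <- function(landscape = landscape_config(),
                       n_areas = 45, sites_per_area = 9, min_spacing_m = 300,
                       visits = 3, area_size_m = 1500,
                       n_transects = 10, points_per_transect = 15,
                       point_spacing_m = 5000,
                       params = true_parameters(),
                       mcmc = mcmc_config(),
                       radii_m = c(1000, 5000),
                       band_width_m = 2500, max_band_m = 30000,
                       seed = 1) {
  if (length(radii_m) != 2 || any(radii_m <= 0) || radii_m[1] == radii_m[2]) {
    stop("configuration error: exactly two distinct positive radii required",
         call. = FALSE)
  }
  structure(
    list(landscape = landscape, n_areas = n_areas,
         sites_per_area = sites_per_area, min_spacing_m = min_spacing_m,
         visits = visits, area_size_m = area_size_m,
         n_transects = n_transects,
         points_per_transect = points_per_transect,
         point_spacing_m = point_spacing_m, params = params, mcmc = mcmc,
         radii_m = sort(radii_m), band_width_m = band_width_m,
         max_band_m = max_band_m, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param write_rasters Also write the input cover/DEM rasters (large ASCII
#'   files); prediction surfaces are always written.
#' @export
smoke_run_config <- function(seed = 1, write_rasters = FALSE) {
  cfg <- run_config(
    landscape = landscape_config(nrow = 600, ncol = 600, cellsize = 150,
                                 corr_length_m = 1200, seed = seed),
    n_areas = 20, sites_per_area = 9,
    n_transects = 10, points_per_transect = 15, point_spacing_m = 5000,
    mcmc = smoke_mcmc_config(seed = seed),
    seed = seed
  )
  cfg$write_rasters <- write_rasters
  cfg
}

stage_seed <- function(config, stage) config$seed * 100L + stage

#' Run the full synthetic study end to end
#'
#' Executes every stage of the analysis on data simulated under the
#' configured true parameters and persists each stage's outputs under
#' `dir`, together with a machine-readable manifest (file checksums,
#' per-stage seeds, configuration echo). Stage failures abort with the
#' stage name; outputs written so far are left in place.
#'
#' @param config A [run_config()].
#' @param dir Output directory (created if needed).
#' @return An object of class `run_result` with all in-memory stage
#'   products (`landscape`, `training`, `covariates`, `screen`, `fit_1km`,
#'   `fit_5km`, `decision`, `fit_mixed`, `sdm`, `corrections`,
#'   `validation`, `diagnostics`, `manifest`).
#' @export
run_full_study <- function(config, dir = tempfile("nmixscape_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list()
  stage <- function(name, num, expr) {
    seeds[[name]] <<- stage_seed(config, num)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  files <- character()
  put <- function(f) { files <<- c(files, f); f }

  # 1. landscape
  lcfg <- config$landscape
  lcfg$seed <- stage_seed(config, 1L)
  landscape <- stage("landscape", 1L, build_landscape(lcfg))
  if (isTRUE(config$write_rasters)) {
    for (nm in names(landscape$covers)) {
      put(write_ascii_grid(landscape$covers[[nm]],
                           file.path(dir, paste0("cover_", nm, ".asc")),
                           digits = 1))
    }
    put(write_ascii_grid(landscape$dem, file.path(dir, "dem.asc")))
  }

  # 2. survey design; the survey frame is inset from the landscape edge by
  # the largest focal radius so every site has a complete covariate window
  ext <- raster_extent(landscape$dem)
  buf <- max(config$radii_m)
  frame <- c(ext[1] + buf, ext[2] - buf, ext[3] + buf, ext[4] - buf)
  design <- stage("design", 2L, generate_design(
    frame, n_areas = config$n_areas,
    sites_per_area = config$sites_per_area,
    min_spacing_m = config$min_spacing_m, visits = config$visits,
    area_size_m = config$area_size_m, seed = stage_seed(config, 2L)
  ))

  # 3. covariates (+ collinearity screen on the raw cover columns)
  cov <- stage("covariates", 3L, build_site_covariates(
    landscape, design$sites, radii_m = config$radii_m,
    township_block_m = config$landscape$township_block_m
  ))
  cover_cols <- grep("km$", colnames(cov$raw), value = TRUE)
  rho <- spearman_matrix(cov$raw[, cover_cols])
  screen <- collinearity_screen(rho)
  utils::write.csv(as.data.frame(rho), put(file.path(dir, "spearman_rho.csv")))
  utils::write.csv(screen, put(file.path(dir, "collinearity_flags.csv")),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(term = colnames(cov$std$z), center = cov$std$center,
               scale = cov$std$scale),
    put(file.path(dir, "standardization_constants.csv")), row.names = FALSE
  )

  # 4. simulated counts
  training <- stage("simulate", 4L, simulate_counts(
    design, cov$std, config$params, seed = stage_seed(config, 4L)
  ))
  write_survey_csvs(training, dir)
  put(file.path(dir, "sites.csv")); put(file.path(dir, "visits.csv"))

  # 5-6. single-scale fits
  mcfg <- config$mcmc
  mcfg$seed <- stage_seed(config, 5L)
  fit1 <- stage("fit_1km", 5L,
                fit_single_scale(training, cov$std, 1, config = mcfg))
  fit5 <- stage("fit_5km", 6L,
                fit_single_scale(training, cov$std, 5, config = mcfg))

  # 7. scale decision + mixed-scale fit
  decision <- stage("scale_decision", 7L,
                    choose_scale_per_cover(fit1, fit5, rhat_max = 1.2))
  utils::write.csv(decision, put(file.path(dir, "scale_decision.csv")),
                   row.names = FALSE)
  mspec <- assemble_mixed_spec(decision)
  mcfg$seed <- stage_seed(config, 7L)
  fit_mixed <- stage("fit_mixed", 7L,
                     run_mcmc(training, cov$std, mspec, mcfg))
  utils::write.csv(fit_mixed$summary,
                   put(file.path(dir, "mixed_model_summary.csv")),
                   row.names = FALSE)

  # 8. diagnostics: convergence, fit, residual spatial/distributional
  resid <- nmix_residuals(fit_mixed)
  maxc <- max_count_index(training)
  cg_raw <- correlogram(maxc, training$sites$x, training$sites$y,
                        config$band_width_m, config$max_band_m)
  cg_res <- correlogram(resid$residual, training$sites$x, training$sites$y,
                        config$band_width_m, config$max_band_m)
  qq <- qq_points(scale(resid$residual)[, 1])
  diagnostics <- list(
    rhat = as.list(fit_mixed$rhat), max_rhat = max(fit_mixed$rhat),
    bayes_p = fit_mixed$bayes_p,
    accept_rate = lapply(fit_mixed$accept_rate, as.numeric),
    seeds = seeds, K = fit_mixed$K
  )
  jsonlite::write_json(diagnostics, put(file.path(dir, "diagnostics.json")),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(cbind(series = "raw_max_count", cg_raw),
                   put(file.path(dir, "correlogram_raw.csv")), row.names = FALSE)
  utils::write.csv(cbind(series = "residual", cg_res),
                   put(file.path(dir, "correlogram_residual.csv")),
                   row.names = FALSE)
  utils::write.csv(qq, put(file.path(dir, "qq_residuals.csv")), row.names = FALSE)

  # 9. SDM projection + cubic correction + deciles
  sdm <- stage("sdm", 8L, linear_predictor_raster(
    fit_mixed, cov$rasters, cov$std$center, cov$std$scale
  ))
  crop_terms <- grep("^(rowcrop|smallgrains)_", colnames(fit_mixed$X),
                     value = TRUE)
  crop_terms <- unique(sub("\\^2$", "", crop_terms))
  corrections <- vapply(crop_terms, function(tm) {
    back_solve_cubic(fit_mixed, tm, cov$std$center, cov$std$scale)
  }, 0)
  corrected <- apply_correction(sdm, corrections, cov$rasters,
                                cov$std$center, cov$std$scale)
  classes <- classify_equal_area(corrected)
  put(write_ascii_grid(sdm, file.path(dir, "sdm_fitted.asc")))
  put(write_ascii_grid(corrected, file.path(dir, "sdm_corrected.asc")))
  put(write_ascii_grid(classes, file.path(dir, "sdm_deciles.asc"), digits = 2))
  jsonlite::write_json(
    list(corrections = as.list(corrections),
         center = as.list(cov$std$center), scale = as.list(cov$std$scale),
         note = "corrections apply to standardized-value cubes; deciles tie-break by value then cell index"),
    put(file.path(dir, "sdm_constants.json")), auto_unbox = TRUE, digits = NA
  )

  # 10. independent transect validation
  tdesign <- stage("transects", 9L, generate_transect_design(
    frame, n_transects = config$n_transects,
    points_per_transect = config$points_per_transect,
    point_spacing_m = config$point_spacing_m,
    visits = config$visits, seed = stage_seed(config, 9L)
  ))
  validation <- NULL
  if (nrow(tdesign$sites) > 0) {
    tcov_raw <- lapply(names(cov$rasters), function(nm) {
      extract_at_points(cov$rasters[[nm]], tdesign$sites$x, tdesign$sites$y)
    })
    names(tcov_raw) <- names(cov$rasters)
    tcov_raw$year <- tdesign$sites$year
    tz <- sapply(colnames(cov$std$z), function(cn) {
      (tcov_raw[[cn]] - cov$std$center[[cn]]) / cov$std$scale[[cn]]
    })
    transects <- simulate_counts(tdesign, tz, config$params,
                                 seed = stage_seed(config, 10L))
    write_survey_csvs(transects, file.path(dir, "transects"))
    put(file.path(dir, "transects", "sites.csv"))
    put(file.path(dir, "transects", "visits.csv"))
    validation <- list(
      fitted = validate_transects(transects, sdm),
      corrected = validate_transects(transects, corrected)
    )
    jsonlite::write_json(
      list(
        fitted = list(rho = validation$fitted$rho,
                      rmse = validation$fitted$rmse,
                      slope = validation$fitted$calibration$slope,
                      intercept = validation$fitted$calibration$intercept),
        corrected = list(rho = validation$corrected$rho,
                         rmse = validation$corrected$rmse,
                         slope = validation$corrected$calibration$slope,
                         intercept = validation$corrected$calibration$intercept)
      ),
      put(file.path(dir, "validation.json")), auto_unbox = TRUE, digits = NA
    )
  }

  # manifest: stage seeds, config echo, output checksums
  manifest <- list(
    seed = config$seed, stage_seeds = seeds,
    config = list(
      n_areas = config$n_areas, sites_per_area = config$sites_per_area,
      visits = config$visits, radii_m = config$radii_m,
      mcmc = unclass(config$mcmc),
      landscape = unclass(config$landscape)[c("nrow", "ncol", "cellsize")],
      n_transects = config$n_transects
    ),
    outputs = lapply(stats::setNames(files, basename(files)), function(f) {
      list(md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(
    list(dir = dir, landscape = landscape, training = training,
         covariates = cov, rho = rho, screen = screen,
         fit_1km = fit1, fit_5km = fit5, decision = decision,
         fit_mixed = fit_mixed, sdm = sdm, corrections = corrections,
         corrected = corrected, deciles = classes,
         correlogram = list(raw = cg_raw, residual = cg_res), qq = qq,
         validation = validation, diagnostics = diagnostics,
         manifest = manifest),
    class = "run_result"
  )
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result>\n")
  cat(sprintf("  artifacts: %s\n", x$dir))
  cat(sprintf("  mixed-scale fit: max Rhat %.3f, Bayesian p %.3f\n",
              x$diagnostics$max_rhat, x$diagnostics$bayes_p))
  if (!is.null(x$validation)) {
    cat(sprintf("  validation rho (fitted/corrected): %.3f / %.3f\n",
                x$validation$fitted$rho, x$validation$corrected$rho))
    cat(sprintf("  standardized RMSE (fitted/corrected): %.3f / %.3f\n",
                x$validation$fitted$rmse, x$validation$corrected$rmse))
  }
  invisible(x)
}

#' Read / write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: a
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$landscape <- unclass(x$landscape)
  x$landscape$proportions <- as.list(x$landscape$proportions)
  x$params <- unclass(x$params)
  x$params$beta <- as.list(x$params$beta)
  x$mcmc <- unclass(x$mcmc)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(
    landscape = do.call(landscape_config, c(
      x$landscape[setdiff(names(x$landscape), "proportions")],
      list(proportions = unlist(x$landscape$proportions))
    )),
    n_areas = x$n_areas, sites_per_area = x$sites_per_area,
    min_spacing_m = x$min_spacing_m, visits = x$visits,
    area_size_m = x$area_size_m, n_transects = x$n_transects,
    points_per_transect = x$points_per_transect,
    point_spacing_m = x$point_spacing_m,
    params = do.call(true_parameters, c(
      x$params[setdiff(names(x$params), "beta")],
      list(beta = unlist(x$params$beta))
    )),
    mcmc = do.call(mcmc_config, x$mcmc),
    radii_m = x$radii_m, band_width_m = x$band_width_m,
    max_band_m = x$max_band_m, seed = x$seed
  )
}
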