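# Hypothesis-testing scale selection: fit an all-1-km and an all-5-km
# model (linear cover terms only), keep the stronger radius per cover
# type, and assemble the mixed-scale specification with quadratics on the
# landscape-scale terms.

#' Fit a single-scale candidate model
#'
#' All six cover proportions at one radius enter linearly, together with
#' the elevation index and year; no quadratic cover terms are allowed at
#' this stage so the two radii can be compared coefficient by coefficient.
#'
#' @param dataset A `survey_dataset`.
#' @param covariates A `std_matrix` containing columns
#'   `<cover>_<radius>km` for every cover, plus the extra terms.
#' @param radius_km Either 1 or 5.
#' @param config An [mcmc_config()]; the chain seed is offset by the radius
#'   so the two candidate fits use distinct, reproducible streams.
#' @param covers Cover-type base names (default the six standard classes).
#' @param extras Scale-free terms always included (default elevation index
#'   and year).
#' @param ... Passed to [model_spec()] (priors, `K`, ...).
#' @return An `nmix_fit`.
#' @export
fit_single_scale <- function(dataset, covariates, radius_km,
                             config = mcmc_config(),
                             covers = c("crp", "grass", "trees",
                                        "smallgrains", "rowcrop", "wetland"),
                             extras = c("elevation_index", "year"), ...) {
  if (!radius_km %in% c(1, 5)) {
    stop("radius_km must be 1 or 5", call. = FALSE)
  }
  terms <- c(paste0(covers, "_", radius_km, "km"), extras)
  spec <- model_spec(abundance = terms, ...)
  cfg <- config
  cfg$seed <- config$seed + as.integer(radius_km)
  fit <- run_mcmc(dataset, covariates, spec, cfg)
  fit$radius_km <- radius_km
  fit$covers <- covers
  fit
}

#' Choose the stronger spatial scale per cover type
#'
#' For each cover, compares the standardized coefficient from the 1-km and
#' the 5-km single-scale fits and keeps the radius with the larger absolute
#' posterior mean; an exact tie goes to the 5-km (landscape) radius and is
#' flagged. Posterior SDs are reported alongside so fragile choices are
#' visible, and a manual override (the "biologically sensible" judgment)
#' can force a radius per cover. Both fits must have converged (all
#' Gelman-Rubin statistics below `rhat_max`).
#'
#' @param fit_1km,fit_5km `nmix_fit` objects from [fit_single_scale()].
#' @param override Optional named vector, e.g. `c(trees = 5)`, forcing the
#'   given radius for those covers.
#' @param rhat_max Convergence bound (default 1.1).
#' @return A data frame of class `scale_decision`: one row per cover with
#'   both candidate estimates, the chosen radius, and tie/override flags.
#' @export
choose_scale_per_cover <- function(fit_1km, fit_5km, override = NULL,
                                   rhat_max = 1.1) {
  stopifnot(inherits(fit_1km, "nmix_fit"), inherits(fit_5km, "nmix_fit"))
  for (f in list(fit_1km, fit_5km)) {
    bad <- f$rhat[f$rhat >= rhat_max]
    if (length(bad)) {
      stop(
        "refusing scale comparison: non-converged parameters (Rhat >= ",
        rhat_max, "): ",
        paste(sprintf("%s=%.3f", names(bad), bad), collapse = ", "),
        call. = FALSE
      )
    }
  }
  covers <- fit_1km$covers
  s1 <- fit_1km$summary; s5 <- fit_5km$summary
  pick <- function(s, term) {
    i <- match(term, s$param)
    if (is.na(i)) stop("term not found in fit: ", term, call. = FALSE)
    c(mean = s$mean[i], sd = s$sd[i])
  }
  out <- do.call(rbind, lapply(covers, function(cv) {
    e1 <- pick(s1, paste0(cv, "_1km"))
    e5 <- pick(s5, paste0(cv, "_5km"))
    tie <- abs(e1["mean"]) == abs(e5["mean"])
    chosen <- if (abs(e5["mean"]) >= abs(e1["mean"])) 5 else 1
    ov <- FALSE
    if (!is.null(override) && cv %in% names(override)) {
      chosen <- override[[cv]]
      ov <- TRUE
    }
    data.frame(
      cover = cv, est_1km = e1[["mean"]], sd_1km = e1[["sd"]],
      est_5km = e5[["mean"]], sd_5km = e5[["sd"]],
      chosen_km = chosen, tie = tie, override = ov,
      stringsAsFactors = FALSE
    )
  }))
  if (any(out$tie)) {
    message("exact tie for: ", paste(out$cover[out$tie], collapse = ", "),
            "; defaulting to the 5-km landscape radius")
  }
  class(out) <- c("scale_decision", "data.frame")
  out
}

#' Assemble the mixed-scale model specification
#'
#' Covers decided at 1 km enter linearly; covers decided at 5 km enter with
#' linear plus quadratic terms; the elevation index and year are always
#' included. All effects are retained (no further selection).
#'
#' @param decision A `scale_decision` from [choose_scale_per_cover()].
#' @param extras Scale-free terms to include (default elevation index and
#'   year).
#' @param ... Passed to [model_spec()].
#' @return A [model_spec()].
#' @export
assemble_mixed_spec <- function(decision,
                                extras = c("elevation_index", "year"), ...) {
  stopifnot(inherits(decision, "scale_decision"))
  if (anyNA(decision$chosen_km) ||
      !all(decision$chosen_km %in% c(1, 5))) {
    stop("every cover needs a decided radius of 1 or 5 km", call. = FALSE)
  }
  terms <- paste0(decision$cover, "_", decision$chosen_km, "km")
  quad <- terms[decision$chosen_km == 5]
  model_spec(abundance = c(terms, extras), quadratic = quad, ...)
}
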