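# Projecting the fitted mixed-scale model onto rasters, the back-solved
# cubic correction at complete crop cover, and equal-area decile classes.

coef_means <- function(fit) {
  if (inherits(fit, "nmix_fit")) {
    s <- summarize_posterior(fit)
    stats::setNames(s$mean, s$param)[colnames(fit$X)]
  } else {
    unlist(fit)
  }
}

# standardized value of one term's raster given training constants
term_z_raster <- function(term, rasters, center, scale) {
  base <- sub("\\^2$", "", term)
  if (!base %in% names(rasters)) {
    stop("no raster supplied for model term: ", base, call. = FALSE)
  }
  if (!base %in% names(center)) {
    stop("no standardization constants for term: ", base, call. = FALSE)
  }
  (rasters[[base]]$values - center[[base]]) / scale[[base]]
}

#' Project model coefficients onto covariate rasters
#'
#' Computes the linear-predictor (log-abundance) surface
#' `eta = beta_0 + sum_m beta_m z_m(cell)`, where each raw covariate raster
#' is standardized with the training means/SDs before the coefficient is
#' applied (the back-transformation of coefficients onto raw map units),
#' and quadratic terms square the standardized value. The area random
#' intercept is set to its population mean of zero. Terms listed in
#' `held_at_mean` (by default `year`, which has no map) contribute nothing,
#' i.e. are held at their training mean.
#'
#' @param fit An `nmix_fit`, or a named coefficient vector including
#'   `(Intercept)`.
#' @param rasters Named list of `grid_raster`s of raw covariate values, one
#'   per base term.
#' @param center,scale Named training constants per base term (from the
#'   fitted [standardize_columns()] object).
#' @param held_at_mean Terms without rasters held at their training mean.
#' @return A `grid_raster` of the fitted linear predictor.
#' @export
linear_predictor_raster <- function(fit, rasters, center, scale,
                                    held_at_mean = "year") {
  coefs <- coef_means(fit)
  stopifnot("(Intercept)" %in% names(coefs))
  template <- rasters[[1]]
  eta <- matrix(coefs[["(Intercept)"]], nrow(template$values), ncol(template$values))
  for (term in setdiff(names(coefs), "(Intercept)")) {
    base <- sub("\\^2$", "", term)
    if (base %in% held_at_mean) next
    z <- term_z_raster(term, rasters, center, scale)
    if (grepl("\\^2$", term)) z <- z^2
    eta <- eta + coefs[[term]] * z
  }
  grid_raster(eta, xll = template$xll, yll = template$yll,
              cellsize = template$cellsize)
}

#' Back-solve the cubic correction coefficient for a crop term
#'
#' Constrains predicted abundance to zero where the landscape is 100% of
#' the given crop cover: with every other covariate held at its training
#' mean, solves `eta_fit(raw = 1) + c * z(1)^3 = 0` for the cubic
#' coefficient `c = -eta_fit(1) / z(1)^3`, where `z(1)` is the
#' standardized value of complete cover. The "zero abundance" constraint is
#' applied on the linear-predictor (summed-raster) scale; rank-based
#' validation is unaffected by that choice.
#'
#' @param fit An `nmix_fit` or named coefficient vector; must contain the
#'   term's linear coefficient (and its quadratic, if present).
#' @param term Base name of the crop term, e.g. `"rowcrop_5km"`.
#' @param center,scale Named training constants per base term.
#' @param others_at Optional named vector of raw values at which to hold
#'   other terms instead of their means.
#' @return The cubic coefficient (scalar, applied to `z^3`).
#' @export
back_solve_cubic <- function(fit, term, center, scale, others_at = NULL) {
  coefs <- coef_means(fit)
  if (!term %in% names(coefs)) {
    stop("no linear coefficient for term: ", term, call. = FALSE)
  }
  if (!term %in% names(center)) {
    stop("no standardization constants for term: ", term, call. = FALSE)
  }
  z1 <- (1 - center[[term]]) / scale[[term]]
  if (z1 == 0) {
    stop("degenerate constraint: training mean of ", term, " is 1", call. = FALSE)
  }
  eta1 <- coefs[["(Intercept)"]] + coefs[[term]] * z1
  qname <- paste0(term, "^2")
  if (qname %in% names(coefs)) eta1 <- eta1 + coefs[[qname]] * z1^2
  if (!is.null(others_at)) {
    for (ot in names(others_at)) {
      zo <- (others_at[[ot]] - center[[ot]]) / scale[[ot]]
      if (ot %in% names(coefs)) eta1 <- eta1 + coefs[[ot]] * zo
      oq <- paste0(ot, "^2")
      if (oq %in% names(coefs)) eta1 <- eta1 + coefs[[oq]] * zo^2
    }
  }
  -eta1 / z1^3
}

#' Apply cubic corrections to a fitted surface
#'
#' `corrected eta = fitted eta + sum_t c_t * z_t(cell)^3` over the
#' corrected crop terms. Wherever the crop covariates sit at their training
#' means (`z = 0`) the corrected surface equals the fitted surface; at 100%
#' cover of a corrected crop (others at means) it is zero by construction.
#'
#' @param eta A `grid_raster` fitted linear-predictor surface.
#' @param corrections Named numeric vector/list of cubic coefficients, e.g.
#'   from [back_solve_cubic()], named by base term.
#' @param rasters Named list of raw covariate rasters (must include every
#'   corrected term).
#' @param center,scale Training constants per base term.
#' @return A `grid_raster` of the corrected surface.
#' @export
apply_correction <- function(eta, corrections, rasters, center, scale) {
  out <- eta$values
  for (term in names(corrections)) {
    z <- term_z_raster(term, rasters, center, scale)
    out <- out + corrections[[term]] * z^3
  }
  grid_raster(out, xll = eta$xll, yll = eta$yll, cellsize = eta$cellsize)
}

#' Equal-area decile classification of a prediction surface
#'
#' Ranks all valid cells and splits them into ten classes of equal cell
#' count (each covering 10% of the valid area, to within one cell); class
#' 10 holds the highest values. Ties are broken by value order then cell
#' index (column-major), so heavily tied surfaces still partition evenly;
#' a constant surface has no deciles and is an error.
#'
#' @param r A `grid_raster`.
#' @return A `grid_raster` of integer classes 1-10 (`NA` where input is
#'   nodata).
#' @export
classify_equal_area <- function(r) {
  v <- r$values
  valid <- !is.na(v)
  nv <- sum(valid)
  if (nv < 10) stop("need at least 10 valid cells", call. = FALSE)
  vals <- v[valid]
  if (min(vals) == max(vals)) {
    stop("constant surface: deciles are undefined", call. = FALSE)
  }
  rk <- rank(vals, ties.method = "first")
  cls <- ceiling(rk / nv * 10)
  out <- matrix(NA_real_, nrow(v), ncol(v))
  out[valid] <- cls
  grid_raster(out, xll = r$xll, yll = r$yll, cellsize = r$cellsize)
}
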