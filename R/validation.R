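# Independent-transect evaluation and residual diagnostics.

#' Maximum count over repeat visits
#'
#' The per-site abundance index used for validation: the largest count
#' recorded across the visits to a site (assuming population closure, the
#' same individuals are available on every visit). Missing visits are
#' ignored; a site with no visits is an error.
#'
#' @param x A `survey_dataset`, or a numeric matrix of counts
#'   (sites x visits).
#' @return Named numeric vector of per-site maxima.
#' @export
max_count_index <- function(x) {
  if (inherits(x, "survey_dataset")) {
    v <- x$visits[!is.na(x$visits$count), ]
    idx <- split(v$count, factor(v$site_id, levels = x$sites$site_id))
    if (any(lengths(idx) == 0)) {
      stop("site(s) with no visits: ",
           paste(utils::head(x$sites$site_id[lengths(idx) == 0]), collapse = ", "),
           call. = FALSE)
    }
    vapply(idx, max, 0)
  } else {
    x <- as.matrix(x)
    if (any(rowSums(!is.na(x)) == 0)) stop("site(s) with no visits", call. = FALSE)
    apply(x, 1, max, na.rm = TRUE)
  }
}

#' Spearman rank correlation between observed and predicted values
#'
#' Average ranks are assigned to ties. A constant vector has undefined
#' rank correlation and yields `NA` with a warning.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 3).
#' @return The rank correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (length(unique(observed)) == 1 || length(unique(predicted)) == 1) {
    warning("constant vector: Spearman rho is undefined")
    return(NA_real_)
  }
  suppressWarnings(stats::cor(observed, predicted, method = "spearman"))
}

#' RMSE between standardized observed and predicted values
#'
#' Both vectors are z-scored with their own mean and sample SD; the result
#' is `sqrt(mean((z_obs - z_pred)^2))`. Because of the z-scoring, any
#' positive affine transform of the predictions leaves the value unchanged,
#' and perfectly proportional predictions score 0.
#'
#' @param observed,predicted Equal-length non-constant numeric vectors.
#' @return The standardized RMSE (>= 0).
#' @export
standardized_rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  so <- stats::sd(observed); sp <- stats::sd(predicted)
  if (is.na(so) || so == 0 || is.na(sp) || sp == 0) {
    stop("constant vector: standardized RMSE is undefined", call. = FALSE)
  }
  zo <- (observed - mean(observed)) / so
  zp <- (predicted - mean(predicted)) / sp
  sqrt(mean((zo - zp)^2))
}

#' Calibration regression of observed on predicted (standardized)
#'
#' Ordinary least squares of standardized observed abundance on
#' standardized predicted abundance, with conventional 95% confidence
#' limits; a perfectly calibrated model follows the identity line
#' (slope 1, intercept 0).
#'
#' @param observed_z,predicted_z Standardized vectors (length >= 3).
#' @return List with `slope`, `intercept`, `ci_slope`, `ci_intercept`
#'   (95% bounds), and the `lm` fit.
#' @export
calibration_regression <- function(observed_z, predicted_z) {
  stopifnot(length(observed_z) == length(predicted_z), length(observed_z) >= 3)
  if (stats::sd(predicted_z) == 0) {
    stop("zero predictor variance", call. = FALSE)
  }
  fit <- stats::lm(observed_z ~ predicted_z)
  ci <- stats::confint(fit, level = 0.95)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    ci_slope = unname(ci[2, ]),
    ci_intercept = unname(ci[1, ]),
    fit = fit
  )
}

#' Moran's I for one distance band
#'
#' The classical statistic `I = (n/W) * sum_ij w_ij (x_i - xbar)(x_j -
#' xbar) / sum_i (x_i - xbar)^2` with binary weights `w_ij = 1` iff
#' `band[1] < d_ij <= band[2]` (half-open band, i != j). Values near -1
#' indicate perfect dispersion, near +1 perfect correlation, near 0 a
#' random pattern.
#'
#' @param values Numeric vector (non-constant).
#' @param x,y Point coordinates.
#' @param band Length-2 numeric `c(low, high)` distance interval (m).
#' @return Moran's I, or `NA` if the band contains no pairs.
#' @export
morans_i <- function(values, x, y, band) {
  n <- length(values)
  stopifnot(length(x) == n, length(y) == n, length(band) == 2)
  if (stats::sd(values) == 0) {
    warning("constant values: Moran's I is undefined")
    return(NA_real_)
  }
  d <- as.matrix(stats::dist(cbind(x, y)))
  w <- (d > band[1] & d <= band[2]) * 1
  diag(w) <- 0
  W <- sum(w)
  if (W == 0) return(NA_real_)
  zc <- values - mean(values)
  (n / W) * sum(w * outer(zc, zc)) / sum(zc^2)
}

#' Moran's I correlogram over distance bands
#'
#' Evaluates [morans_i()] on consecutive half-open bands
#' `(k-1)*band_width < d <= k*band_width` up to `max_distance`, with a
#' normal-approximation standard error under the randomization null
#' (`E[I] = -1/(n-1)`, `Var[I] ~ 1/W`) for a rough significance envelope.
#'
#' @param values Numeric vector.
#' @param x,y Point coordinates.
#' @param band_width Band width (m).
#' @param max_distance Largest distance considered (m).
#' @return Data frame with `band_lo`, `band_hi`, `I`, `n_pairs`,
#'   `expected`, `sd_approx`.
#' @export
correlogram <- function(values, x, y, band_width, max_distance) {
  n <- length(values)
  d <- as.matrix(stats::dist(cbind(x, y)))
  zc <- values - mean(values)
  denom <- sum(zc^2)
  if (denom == 0) stop("constant values: correlogram undefined", call. = FALSE)
  edges <- seq(0, max_distance, by = band_width)
  if (edges[length(edges)] < max_distance) edges <- c(edges, max_distance)
  cross <- outer(zc, zc)
  out <- lapply(seq_len(length(edges) - 1), function(k) {
    w <- (d > edges[k] & d <= edges[k + 1]) * 1
    diag(w) <- 0
    W <- sum(w)
    I <- if (W > 0) (n / W) * sum(w * cross) / denom else NA_real_
    data.frame(
      band_lo = edges[k], band_hi = edges[k + 1], I = I, n_pairs = W / 2,
      expected = -1 / (n - 1),
      sd_approx = if (W > 0) sqrt(1 / W) * sqrt(2) else NA_real_
    )
  })
  do.call(rbind, out)
}

#' Normal quantile-quantile pairs for residuals
#'
#' Sorted residuals paired with standard-normal quantiles at plotting
#' positions `(i - 0.5) / n`.
#'
#' @param residuals Numeric vector (length >= 3).
#' @return Data frame with `theoretical` and `sample` columns.
#' @export
qq_points <- function(residuals) {
  n <- length(residuals)
  stopifnot(n >= 3)
  data.frame(
    theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
    sample = sort(residuals)
  )
}

#' Validate a prediction surface against independent transect counts
#'
#' Observed abundance is the per-site maximum count over visits; predicted
#' abundance is the surface value extracted at each site's cell. Reports
#' the Spearman rank correlation, standardized RMSE, and the calibration
#' regression of standardized observed on standardized predicted values.
#'
#' @param transects A `survey_dataset` of validation counts.
#' @param surface A `grid_raster` prediction surface (any monotone image
#'   of expected abundance; rank-based measures are invariant to which).
#' @return List of class `validation_report`: `rho`, `rmse`, `calibration`,
#'   `observed`, `predicted`.
#' @export
validate_transects <- function(transects, surface) {
  obs <- max_count_index(transects)
  pred <- extract_at_points(surface, transects$sites$x, transects$sites$y)
  rep <- list(
    rho = spearman_rho(obs, pred),
    rmse = standardized_rmse(obs, pred),
    calibration = calibration_regression(
      (obs - mean(obs)) / stats::sd(obs),
      (pred - mean(pred)) / stats::sd(pred)
    ),
    observed = obs, predicted = pred
  )
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> n = %d sites\n  Spearman rho = %.3f\n  standardized RMSE = %.3f\n  calibration: slope %.3f [%.3f, %.3f], intercept %.3f\n",
    length(x$observed), x$rho, x$rmse,
    x$calibration$slope, x$calibration$ci_slope[1], x$calibration$ci_slope[2],
    x$calibration$intercept
  ))
  invisible(x)
}
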