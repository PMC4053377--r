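# Circular focal statistics and covariate preparation.

# 2-D convolution of `a` with centered kernel `k` (odd dims) by zero-padded
# FFT; returns a matrix the size of `a`.
fft_convolve2 <- function(a, k) {
  na1 <- nrow(a); na2 <- ncol(a)
  nk1 <- nrow(k); nk2 <- ncol(k)
  n1 <- stats::nextn(na1 + nk1 - 1L, c(2, 3, 5))
  n2 <- stats::nextn(na2 + nk2 - 1L, c(2, 3, 5))
  pa <- matrix(0, n1, n2); pa[seq_len(na1), seq_len(na2)] <- a
  pk <- matrix(0, n1, n2); pk[seq_len(nk1), seq_len(nk2)] <- k
  full <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) / (n1 * n2)
  off1 <- (nk1 - 1L) %/% 2L
  off2 <- (nk2 - 1L) %/% 2L
  full[off1 + seq_len(na1), off2 + seq_len(na2)]
}

# Binary disc kernel: 1 where the cell-center distance to the focal center
# is <= radius_m (inclusive).
disc_kernel <- function(radius_m, cellsize) {
  r_cells <- floor(radius_m / cellsize)
  idx <- -r_cells:r_cells
  d2 <- outer(idx^2, idx^2, `+`) * cellsize^2
  (d2 <= radius_m^2) * 1
}

#' Circular focal proportion of a binary raster
#'
#' For every cell, the proportion of 1-cells among cells whose centers lie
#' within `radius_m` of the focal cell center (inclusive). Nodata cells are
#' excluded from both numerator and denominator; at the raster boundary the
#' window shrinks to the available cells. This is the moving-window
#' proportion used to summarize land cover around survey points at the
#' management (1 km) and landscape (5 km) radii.
#'
#' The window counts are integers, so the FFT-based convolution used here is
#' rounded to integer counts and the result is exactly the brute-force
#' window mean.
#'
#' @param r A binary `grid_raster` (values 0/1, `NA` for nodata).
#' @param radius_m Window radius in metres; must be at least the cell size.
#' @return A `grid_raster` of proportions in `[0, 1]`; cells whose whole
#'   window is nodata are `NA`.
#' @export
focal_proportion <- function(r, radius_m) {
  stopifnot(inherits(r, "grid_raster"))
  if (radius_m < r$cellsize) {
    stop("radius_m must be at least one cell size", call. = FALSE)
  }
  v <- r$values
  ok <- all(is.na(v) | v == 0 | v == 1)
  if (!ok) stop("focal_proportion requires a binary (0/1/NA) raster", call. = FALSE)
  k <- disc_kernel(radius_m, r$cellsize)
  valid <- !is.na(v)
  ones <- v
  ones[!valid] <- 0
  num <- round(fft_convolve2(ones, k))
  den <- round(fft_convolve2(valid * 1, k))
  out <- ifelse(den > 0, num / den, NA_real_)
  grid_raster(out, xll = r$xll, yll = r$yll, cellsize = r$cellsize)
}

#' Township-standardized elevation index
#'
#' Standardizes a DEM within square "township" blocks: each cell's elevation
#' minus its block mean, divided by the block's sample standard deviation.
#' This yields a local topographic-relief covariate that is invariant to
#' shifting the DEM by a constant or rescaling it by a positive factor.
#' Blocks are anchored at the raster origin; a trailing partial block
#' narrower than 2 cells is merged into its neighbor. A flat block (zero SD)
#' yields index 0 for all its cells, with a warning.
#'
#' @param dem A `grid_raster` of elevations.
#' @param township_block_m Block edge length in metres (default 9,656 m, the
#'   edge of a congressional township).
#' @return A `grid_raster` of standardized elevation indices.
#' @export
elevation_index <- function(dem, township_block_m = 9656) {
  stopifnot(inherits(dem, "grid_raster"))
  bs <- max(2L, as.integer(round(township_block_m / dem$cellsize)))
  v <- dem$values
  nr <- nrow(v); nc <- ncol(v)
  block_starts <- function(n) {
    s <- seq(1L, n, by = bs)
    if (length(s) > 1 && n - s[length(s)] + 1L < 2L) s <- s[-length(s)]
    s
  }
  rs <- block_starts(nr); cs <- block_starts(nc)
  out <- v
  flat <- FALSE
  for (r0 in rs) {
    r1 <- if (r0 == rs[length(rs)]) nr else r0 + bs - 1L
    for (c0 in cs) {
      c1 <- if (c0 == cs[length(cs)]) nc else c0 + bs - 1L
      blk <- v[r0:r1, c0:c1]
      m <- mean(blk, na.rm = TRUE)
      s <- stats::sd(blk, na.rm = TRUE)
      if (is.na(s) || s == 0) {
        out[r0:r1, c0:c1] <- ifelse(is.na(blk), NA_real_, 0)
        flat <- TRUE
      } else {
        out[r0:r1, c0:c1] <- (blk - m) / s
      }
    }
  }
  if (flat) warning("flat township block(s): elevation index set to 0 there")
  grid_raster(out, xll = dem$xll, yll = dem$yll, cellsize = dem$cellsize)
}

#' Standardize covariate columns
#'
#' Centers and scales each column to mean 0 and sample standard deviation 1
#' (n - 1 denominator), storing the constants so the transform can be
#' inverted exactly and reapplied to prediction rasters.
#'
#' @param x Numeric matrix or data frame of raw covariates.
#' @return An object of class `std_matrix`: list with `z` (standardized
#'   matrix), `center` and `scale` (named vectors).
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x))
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  zero <- scl == 0 | is.na(scl)
  if (any(zero)) {
    stop(
      "constant column(s) cannot be standardized: ",
      paste(colnames(x)[zero], collapse = ", "),
      call. = FALSE
    )
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  structure(list(z = z, center = ctr, scale = scl), class = "std_matrix")
}

#' Invert a standardization
#'
#' @param s A `std_matrix` from [standardize_columns()].
#' @return The raw matrix `z * scale + center`.
#' @export
unstandardize_columns <- function(s) {
  stopifnot(inherits(s, "std_matrix"))
  sweep(sweep(s$z, 2, s$scale, `*`), 2, s$center, `+`)
}

#' Pairwise Spearman rank-correlation matrix
#'
#' @param x Numeric matrix or data frame with at least 3 rows; ties receive
#'   average ranks. Constant columns yield `NA` entries (undefined rank
#'   correlation), reported with a warning.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 3)
  const <- apply(x, 2, function(col) length(unique(col)) == 1)
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  if (any(const)) {
    warning(
      "constant column(s) have undefined rank correlation: ",
      paste(colnames(x)[const], collapse = ", ")
    )
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
  }
  d <- diag(rho)
  d[!const] <- 1
  diag(rho) <- d
  rho
}

#' Flag collinear covariate pairs within a spatial scale
#'
#' Scans a Spearman correlation matrix and reports every pair of covariates
#' measured at the same radius whose |rho| meets the threshold (inclusive,
#' reading a +/-0.6 rule as the boundary of collinearity). The screen only
#' reports; which member of a flagged pair to drop is a judgment left to the
#' analyst.
#'
#' @param rho Square symmetric correlation matrix with named rows/columns.
#' @param scales Character vector giving the scale label of each column
#'   (e.g. `"1km"`, `"5km"`, or `NA` for unscaled terms). If `NULL`, labels
#'   are parsed from trailing `_1km` / `_5km` (or `1-km` style) name
#'   suffixes.
#' @param threshold Absolute rho at or above which a pair is flagged.
#' @param same_scale_only If `TRUE` (default), only pairs sharing a scale
#'   label are compared.
#' @return A data frame with columns `var1`, `var2`, `rho`, `scale`, one row
#'   per flagged pair (zero rows if none).
#' @export
collinearity_screen <- function(rho, scales = NULL, threshold = 0.6,
                                same_scale_only = TRUE) {
  rho <- as.matrix(rho)
  if (nrow(rho) != ncol(rho)) stop("rho must be square", call. = FALSE)
  if (max(abs(rho - t(rho)), na.rm = TRUE) > 1e-8) {
    stop("rho must be symmetric", call. = FALSE)
  }
  if (max(abs(rho), na.rm = TRUE) > 1 + 1e-8) {
    stop("correlation entries must lie in [-1, 1]", call. = FALSE)
  }
  nm <- colnames(rho)
  if (is.null(nm)) nm <- paste0("v", seq_len(ncol(rho)))
  if (is.null(scales)) {
    scales <- rep(NA_character_, length(nm))
    scales[grepl("[_ .-]?1[ -]?km$", nm, ignore.case = TRUE)] <- "1km"
    scales[grepl("[_ .-]?5[ -]?km$", nm, ignore.case = TRUE)] <- "5km"
  }
  out <- data.frame(
    var1 = character(), var2 = character(),
    rho = numeric(), scale = character(), stringsAsFactors = FALSE
  )
  p <- ncol(rho)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (same_scale_only &&
          (is.na(scales[i]) || is.na(scales[j]) || scales[i] != scales[j])) next
      r <- rho[i, j]
      if (!is.na(r) && abs(r) >= threshold) {
        out[nrow(out) + 1L, ] <- list(
          nm[i], nm[j], r,
          if (is.na(scales[i])) NA_character_ else scales[i]
        )
      }
    }
  }
  out
}

#' Build the site covariate matrix from a landscape
#'
#' Computes circular focal proportions of every cover raster at each radius,
#' the township-standardized elevation index, extracts all of them at the
#' site coordinates, appends the site year, and standardizes the columns.
#' Column names follow `<cover>_<radius>km`, e.g. `grass_5km`.
#'
#' @param landscape List with `covers` (named binary `grid_raster`s) and
#'   `dem`, as from [build_landscape()].
#' @param sites Data frame with `x`, `y`, `year` columns.
#' @param radii_m Numeric vector of focal radii in metres (default 1 km and
#'   5 km).
#' @param township_block_m Block edge for the elevation index.
#' @return List with `raw` (data frame of raw covariate values), `std` (a
#'   `std_matrix`), and `rasters` (named list of the focal-proportion and
#'   elevation-index rasters, for later prediction).
#' @export
build_site_covariates <- function(landscape, sites, radii_m = c(1000, 5000),
                                  township_block_m = 9656) {
  rasters <- list()
  raw <- list()
  for (cv in names(landscape$covers)) {
    for (r in radii_m) {
      nm <- sprintf("%s_%dkm", cv, as.integer(round(r / 1000)))
      fp <- focal_proportion(landscape$covers[[cv]], r)
      rasters[[nm]] <- fp
      raw[[nm]] <- extract_at_points(fp, sites$x, sites$y)
    }
  }
  ei <- elevation_index(landscape$dem, township_block_m)
  rasters[["elevation_index"]] <- ei
  raw[["elevation_index"]] <- extract_at_points(ei, sites$x, sites$y)
  raw[["year"]] <- sites$year
  raw <- as.data.frame(raw, check.names = FALSE)
  list(raw = raw, std = standardize_columns(raw), rasters = rasters)
}
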