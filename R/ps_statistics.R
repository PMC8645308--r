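# Portilla-Simoncelli statistic set of one image: marginal moments, central
# autocorrelations of the partial lowpass images and of band magnitudes, and
# cross-orientation / cross-scale correlations of linear (real-part) and
# energy (magnitude) subbands.

#' Population moments of a map
#'
#' Mean, variance, skewness and kurtosis with divide-by-N normalization;
#' kurtosis is non-excess (a Gaussian map reads 3).  A zero-variance map
#' reports skewness 0 and kurtosis 3 by convention so the feature pipeline
#' stays total on blank inputs.
#'
#' @param map Numeric matrix or vector with finite values.
#' @return Named numeric vector `(mean, variance, skewness, kurtosis)`.
#' @export
marginal_moments <- function(map) {
  x <- as.numeric(map)
  if (!all(is.finite(x))) stop("map contains non-finite values")
  m <- mean(x)
  d <- x - m
  v <- mean(d^2)
  if (v <= 0) return(c(mean = m, variance = 0, skewness = 0, kurtosis = 3))
  c(mean = m, variance = v,
    skewness = mean(d^3) / v^1.5,
    kurtosis = mean(d^4) / v^2)
}

#' Central circular autocorrelation
#'
#' The `neighborhood` x `neighborhood` window of the circular
#' autocovariance of `map`, normalized by its variance, so the center entry
#' is 1 and entry `(i, j)` is the correlation at lag `(i - c, j - c)` with
#' `c` the center index (rows = vertical lag, columns = horizontal lag).
#' Computed via the FFT (circular boundary).  A constant map returns the
#' delta-at-center matrix by convention.
#'
#' @param map Real matrix.
#' @param neighborhood Odd window width, at most the map side.
#' @return `neighborhood` x `neighborhood` matrix, point-symmetric about its
#'   center.
#' @export
central_autocorrelation <- function(map, neighborhood = 7L) {
  neighborhood <- as.integer(neighborhood)
  if (neighborhood %% 2L == 0L) stop("neighborhood must be odd")
  if (neighborhood > min(dim(map))) stop("neighborhood exceeds map side")
  h <- (neighborhood - 1L) %/% 2L
  d <- map - mean(map)
  v <- mean(d^2)
  if (v <= 0) {
    out <- matrix(0, neighborhood, neighborhood)
    out[h + 1L, h + 1L] <- 1
    return(out)
  }
  ac <- Re(ifft2(Mod(fft2(d))^2)) / length(d)   # autocovariance, lag 0 at [1,1]
  idx <- function(n) c((n - h + 1L):n, 1L:(h + 1L))
  ac[idx(nrow(ac)), idx(ncol(ac)), drop = FALSE] / v
}

#' Upsample a complex band and double its phase
#'
#' Upsamples a complex subband by a factor of two per side with
#' frequency-domain zero padding (amplitude preserved), then doubles the
#' phase of every coefficient while leaving its magnitude untouched
#' (`b -> |b| exp(2i arg b)`).  This is the "parent" band entering the
#' cross-scale statistics: doubling the phase makes the coarse band's phase
#' progression commensurate with the next finer scale's.
#'
#' @param coarse_band Complex matrix at the coarser scale.
#' @param target_shape Integer side length of the output; must be twice the
#'   input side.
#' @return Complex matrix of side `target_shape`.
#' @export
phase_double_upsample <- function(coarse_band, target_shape = 2L * nrow(coarse_band)) {
  n <- nrow(coarse_band)
  if (!is.matrix(coarse_band) || ncol(coarse_band) != n)
    stop("coarse_band must be a square matrix")
  if (target_shape != 2L * n)
    stop(sprintf("target_shape (%d) must be twice the input side (%d)",
                 target_shape, n))
  up <- ifft2(ifftshift2(pad_center(fftshift2(fft2(coarse_band)), 2L * n))) * 4
  mag <- Mod(up)
  out <- mag * exp(2i * atan2(Im(up), Re(up)))
  out[mag == 0] <- 0 + 0i
  out
}

#' Pearson correlations between two lists of maps
#'
#' Entry `(i, j)` is the Pearson correlation between the flattened
#' `maps_a[[i]]` and `maps_b[[j]]`.  Zero-variance maps get correlation 0
#' off the diagonal; when the two lists are the same object the diagonal is
#' 1 by convention.
#'
#' @param maps_a,maps_b Non-empty lists of equally shaped real matrices.
#' @return `length(maps_a)` x `length(maps_b)` matrix with entries in
#'   `[-1, 1]`.
#' @export
cross_band_correlation <- function(maps_a, maps_b = maps_a) {
  if (length(maps_a) == 0L || length(maps_b) == 0L) stop("empty map list")
  dims <- dim(maps_a[[1]])
  ok <- vapply(c(maps_a, maps_b), function(m) identical(dim(m), dims), TRUE)
  if (!all(ok)) stop("all maps must share one shape")
  self <- identical(maps_a, maps_b)
  A <- vapply(maps_a, function(m) as.numeric(m), numeric(prod(dims)))
  B <- if (self) A else vapply(maps_b, function(m) as.numeric(m), numeric(prod(dims)))
  A <- scale(A, center = TRUE, scale = FALSE)
  B <- if (self) A else scale(B, center = TRUE, scale = FALSE)
  sa <- sqrt(colMeans(A^2)); sb <- sqrt(colMeans(B^2))
  denom <- outer(sa, sb)
  out <- crossprod(A, B) / nrow(A)
  out <- ifelse(denom > 0, out / ifelse(denom > 0, denom, 1), 0)
  out <- pmin(pmax(out, -1), 1)
  if (self) diag(out) <- 1
  out
}

#' Compute the full texture-statistic set of one image
#'
#' Builds the steerable pyramid and evaluates every statistic class: pixel
#' moments and range, highpass variance, skewness/kurtosis/variance and
#' central autocorrelation of each partial lowpass image, band magnitude
#' means/variances/autocorrelations, band-coefficient variances (power), and
#' the within-scale cross-orientation and between-scale (phase-doubled
#' parent) correlation matrices of linear and energy subbands.
#'
#' @param image Square numeric matrix of luminance values.
#' @param config A [pyramid_config()].
#' @return An object of class `ps_statistics`; see Details for fields.
#' @details Fields: `pixel_stats` (mean, variance, skewness, kurtosis, min,
#'   max); `highpass_variance`; per partial lowpass image `s = 1..n_scales+1`
#'   (coarsest last): `lowpass_skew`, `lowpass_kurt`, `lowpass_var`,
#'   `raw_autocorr[[s]]`; per band `(s, o)`: `mag_means`, `mag_var`,
#'   `band_var` (variance of the complex coefficients, the "power" carried
#'   separately from the normalized autocorrelations), `mag_autocorr[[s]][[o]]`;
#'   per scale: `cross_ori_mag[[s]]`, `cross_ori_real[[s]]` (n_ori x n_ori);
#'   per adjacent scale pair `s = 1..n_scales-1`: `cross_scale_mag[[s]]`
#'   (n_ori x n_ori, magnitudes vs upsampled parent magnitudes) and
#'   `cross_scale_real[[s]]` (n_ori x 2 n_ori, real parts vs real and
#'   imaginary parts of the phase-doubled parents).
#' @export
compute_ps_statistics <- function(image, config = pyramid_config(image_size = nrow(image))) {
  validate_image(image, config)
  if (mean((image - mean(image))^2) == 0)
    return(degenerate_ps_statistics(mean(image), config))
  pyr <- build_pyramid(image, config)
  ns <- config$n_scales
  K <- config$n_orientations
  nb <- config$neighborhood

  px <- marginal_moments(image)
  pls <- partial_lowpass_images(pyr, config)

  lp_mom <- lapply(pls, marginal_moments)
  raw_ac <- lapply(pls, central_autocorrelation, neighborhood = nb)

  mags <- lapply(pyr$bands, function(sc) lapply(sc, Mod))
  reals <- lapply(pyr$bands, function(sc) lapply(sc, Re))

  mag_means <- lapply(mags, function(sc) vapply(sc, mean, 0))
  mag_var <- lapply(mags, function(sc) vapply(sc, function(m) mean((m - mean(m))^2), 0))
  band_var <- lapply(pyr$bands, function(sc) vapply(sc, function(b) {
    mean(Mod(b - mean(b))^2)
  }, 0))
  mag_ac <- lapply(mags, function(sc) lapply(sc, central_autocorrelation, neighborhood = nb))

  xom <- lapply(mags, cross_band_correlation)
  xor <- lapply(reals, cross_band_correlation)

  xsm <- vector("list", max(ns - 1L, 0L))
  xsr <- vector("list", max(ns - 1L, 0L))
  if (ns >= 2L) for (s in seq_len(ns - 1L)) {
    parents <- lapply(pyr$bands[[s + 1L]], phase_double_upsample)
    xsm[[s]] <- cross_band_correlation(mags[[s]], lapply(parents, Mod))
    xsr[[s]] <- cross_band_correlation(
      reals[[s]], c(lapply(parents, Re), lapply(parents, Im)))
  }

  structure(list(
    pixel_stats = c(px, min = min(image), max = max(image)),
    highpass_variance = mean((pyr$highpass - mean(pyr$highpass))^2),
    lowpass_skew = vapply(lp_mom, `[[`, 0, "skewness"),
    lowpass_kurt = vapply(lp_mom, `[[`, 0, "kurtosis"),
    lowpass_var = vapply(lp_mom, `[[`, 0, "variance"),
    raw_autocorr = raw_ac,
    mag_means = mag_means,
    mag_var = mag_var,
    band_var = band_var,
    mag_autocorr = mag_ac,
    cross_ori_mag = xom,
    cross_ori_real = xor,
    cross_scale_mag = xsm,
    cross_scale_real = xsr,
    config = config
  ), class = "ps_statistics")
}

# the stated convention for blank inputs: zero variances and correlations,
# skewness 0, kurtosis 3, delta-at-center autocorrelations.  Built directly
# rather than measured, because numerically-zero subbands would otherwise
# correlate their rounding noise.
degenerate_ps_statistics <- function(level, config) {
  ns <- config$n_scales; K <- config$n_orientations
  nb <- config$neighborhood
  delta <- matrix(0, nb, nb)
  delta[(nb + 1L) %/% 2L, (nb + 1L) %/% 2L] <- 1
  structure(list(
    pixel_stats = c(mean = level, variance = 0, skewness = 0, kurtosis = 3,
                    min = level, max = level),
    highpass_variance = 0,
    lowpass_skew = rep(0, ns + 1L),
    lowpass_kurt = rep(3, ns + 1L),
    lowpass_var = rep(0, ns + 1L),
    raw_autocorr = rep(list(delta), ns + 1L),
    mag_means = rep(list(rep(0, K)), ns),
    mag_var = rep(list(rep(0, K)), ns),
    band_var = rep(list(rep(0, K)), ns),
    mag_autocorr = rep(list(rep(list(delta), K)), ns),
    cross_ori_mag = rep(list(diag(K)), ns),
    cross_ori_real = rep(list(diag(K)), ns),
    cross_scale_mag = rep(list(matrix(0, K, K)), max(ns - 1L, 0L)),
    cross_scale_real = rep(list(matrix(0, K, 2L * K)), max(ns - 1L, 0L)),
    config = config
  ), class = "ps_statistics")
}

#' @export
print.ps_statistics <- function(x, ...) {
  cat(sprintf(
    "texture statistics: %d scales x %d orientations, %dx%d window (%d scalars when flattened)\n",
    x$config$n_scales, x$config$n_orientations, x$config$neighborhood,
    x$config$neighborhood, length(ps_to_row(x))))
  invisible(x)
}

#' Flatten a statistic set to a named vector
#'
#' Serializes a `ps_statistics` object to a flat named numeric vector with a
#' stable naming scheme, suitable for one CSV row per image.  Names:
#' `pix.{mean,var,skew,kurt,min,max}`, `hp.var`, `lpSkew.s#`, `lpKurt.s#`,
#' `lpVar.s#`, `rawAC.s#.dy#.dx#`, `magMean.s#.o#`, `magVar.s#.o#`,
#' `bandVar.s#.o#`, `magAC.s#.o#.dy#.dx#`, `xOriMag.s#.o#.o#`,
#' `xOriReal.s#.o#.o#`, `xSclMag.s#.o#.o#`, `xSclReal.s#.o#.o#re` /
#' `...o#im` (lags run `dy`, `dx` in `-h..h`; `s` indexes scales finest
#' first, the extra `lp*` index `n_scales+1` being the lowpass residual).
#'
#' @param ps A `ps_statistics` object.
#' @return Named numeric vector.
#' @export
ps_to_row <- function(ps) {
  cfg <- ps$config
  ns <- cfg$n_scales; K <- cfg$n_orientations
  h <- (cfg$neighborhood - 1L) %/% 2L
  lag <- -h:h
  ac_names <- function(prefix) {
    as.vector(outer(lag, lag, function(dy, dx)
      sprintf("%s.dy%d.dx%d", prefix, dy, dx)))
  }
  out <- c(
    stats::setNames(ps$pixel_stats,
                    c("pix.mean", "pix.var", "pix.skew", "pix.kurt",
                      "pix.min", "pix.max")),
    hp.var = ps$highpass_variance,
    stats::setNames(ps$lowpass_skew, sprintf("lpSkew.s%d", seq_len(ns + 1L))),
    stats::setNames(ps$lowpass_kurt, sprintf("lpKurt.s%d", seq_len(ns + 1L))),
    stats::setNames(ps$lowpass_var, sprintf("lpVar.s%d", seq_len(ns + 1L)))
  )
  for (s in seq_len(ns + 1L))
    out <- c(out, stats::setNames(as.vector(ps$raw_autocorr[[s]]),
                                  ac_names(sprintf("rawAC.s%d", s))))
  for (s in seq_len(ns)) {
    out <- c(out,
             stats::setNames(ps$mag_means[[s]], sprintf("magMean.s%d.o%d", s, 1:K)),
             stats::setNames(ps$mag_var[[s]], sprintf("magVar.s%d.o%d", s, 1:K)),
             stats::setNames(ps$band_var[[s]], sprintf("bandVar.s%d.o%d", s, 1:K)))
    for (o in seq_len(K))
      out <- c(out, stats::setNames(as.vector(ps$mag_autocorr[[s]][[o]]),
                                    ac_names(sprintf("magAC.s%d.o%d", s, o))))
    grid <- expand.grid(oi = 1:K, oj = 1:K)
    out <- c(out,
             stats::setNames(as.vector(ps$cross_ori_mag[[s]]),
                             sprintf("xOriMag.s%d.o%d.o%d", s, grid$oi, grid$oj)),
             stats::setNames(as.vector(ps$cross_ori_real[[s]]),
                             sprintf("xOriReal.s%d.o%d.o%d", s, grid$oi, grid$oj)))
  }
  if (ns >= 2L) for (s in seq_len(ns - 1L)) {
    grid <- expand.grid(oi = 1:K, oj = 1:K)
    part <- c(sprintf("o%dre", 1:K), sprintf("o%dim", 1:K))
    grid2 <- expand.grid(oi = 1:K, oj = part, stringsAsFactors = FALSE)
    out <- c(out,
             stats::setNames(as.vector(ps$cross_scale_mag[[s]]),
                             sprintf("xSclMag.s%d.o%d.o%d", s, grid$oi, grid$oj)),
             stats::setNames(as.vector(ps$cross_scale_real[[s]]),
                             sprintf("xSclReal.s%d.o%d.%s", s, grid2$oi, grid2$oj)))
  }
  out
}
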