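# Complex steerable pyramid, built entirely in the frequency domain with
# polar-separable masks (raised-cosine radial profile, cos^(K-1) angular
# profile).  All filtering is circular; downsampling is frequency-domain
# cropping, so the real-part pyramid is a tight frame and reconstruction is
# exact to floating-point precision.

#' Pyramid configuration
#'
#' Parameters of the steerable-pyramid decomposition underlying all texture
#' statistics: number of dyadic scales, number of orientation bands, the odd
#' width of the spatial autocorrelation neighborhood, and the image side in
#' pixels.
#'
#' @param n_scales Integer number of dyadic scales (default 4).
#' @param n_orientations Integer number of orientation bands (default 4).
#' @param neighborhood Odd integer width of the central autocorrelation
#'   window, in samples (default 7).
#' @param image_size Pixels per side of the (square) input image
#'   (default 256).
#' @param n_iterations Synthesis iteration count carried for provenance only;
#'   never used by this package (default 20).
#' @return An object of class `pyramid_config`.
#' @examples
#' cfg <- pyramid_config()
#' cfg$n_scales
#' @export
pyramid_config <- function(n_scales = 4L, n_orientations = 4L,
                           neighborhood = 7L, image_size = 256L,
                           n_iterations = 20L) {
  n_scales <- as.integer(n_scales)
  n_orientations <- as.integer(n_orientations)
  neighborhood <- as.integer(neighborhood)
  image_size <- as.integer(image_size)
  if (n_scales < 1L) stop("n_scales must be >= 1")
  if (n_orientations < 2L) stop("n_orientations must be >= 2")
  if (neighborhood < 3L || neighborhood %% 2L == 0L)
    stop("neighborhood must be an odd integer >= 3")
  if (image_size %% (2L^n_scales) != 0L)
    stop(sprintf("image_size (%d) must be divisible by 2^n_scales = %d",
                 image_size, 2L^n_scales))
  if (image_size %/% 2L^n_scales < neighborhood)
    stop(sprintf(
      "coarsest level (%d px) is smaller than the autocorrelation window (%d)",
      image_size %/% 2L^n_scales, neighborhood))
  structure(list(n_scales = n_scales, n_orientations = n_orientations,
                 neighborhood = neighborhood, image_size = image_size,
                 n_iterations = as.integer(n_iterations)),
            class = "pyramid_config")
}

#' @export
print.pyramid_config <- function(x, ...) {
  cat(sprintf(
    "steerable pyramid config: %d scales x %d orientations, %dx%d window, %d px\n",
    x$n_scales, x$n_orientations, x$neighborhood, x$neighborhood,
    x$image_size))
  invisible(x)
}

# ---- frequency-domain helpers -----------------------------------------------

fft2 <- function(x) stats::fft(x)
ifft2 <- function(X) stats::fft(X, inverse = TRUE) / length(X)

# move DC from [1,1] to the center [n/2+1, n/2+1] (even n)
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  i <- c((n1 %/% 2 + 1):n1, 1:(n1 %/% 2))
  j <- c((n2 %/% 2 + 1):n2, 1:(n2 %/% 2))
  m[i, j, drop = FALSE]
}
# inverse of fftshift2 (identical for even sizes)
ifftshift2 <- fftshift2

# polar grid for an n x n centered spectrum: log2 radius (0 at Nyquist)
# and angle.  The DC sample's radius is patched to its neighbor to avoid
# log2(0); its mask values are irrelevant because the mean is removed.
polar_grid <- function(n) {
  ctr <- n %/% 2 + 1L
  v <- (seq_len(n) - ctr) / (n / 2)
  xr <- matrix(v, n, n, byrow = TRUE)
  yr <- matrix(v, n, n, byrow = FALSE)
  rad <- sqrt(xr^2 + yr^2)
  rad[ctr, ctr] <- rad[ctr, ctr - 1L]
  list(log_rad = log2(rad), angle = atan2(yr, xr))
}

# sqrt raised-cosine highpass profile: 0 below log_rad = -1, 1 above 0
rc_hi <- function(lr) {
  t <- pmin(pmax(-lr, 0), 1)
  cos(pi / 2 * t)
}
rc_lo <- function(lr) {
  t <- pmin(pmax(-lr, 0), 1)
  sin(pi / 2 * t)
}

wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

# angular normalization so that sum_k const * cos^(2K-2)(theta - theta_k) = 1
angular_const <- function(K) {
  o <- K - 1
  2^(2 * o) * factorial(o)^2 / (K * factorial(2 * o))
}

# analytic (half-plane) complex orientation mask, including the (-i)^(K-1)
# phase that makes the real part the even-symmetric oriented band
angle_mask_complex <- function(angle, k, K) {
  o <- K - 1
  d <- wrap_angle(angle - (k - 1) * pi / K)
  mag <- 2 * sqrt(angular_const(K)) * cos(d)^o * (abs(d) < pi / 2)
  phase <- complex(modulus = 1, argument = -o * pi / 2)
  phase * mag
}

# signed full-plane real orientation mask used for reconstruction
angle_mask_real <- function(angle, k, K) {
  o <- K - 1
  d <- wrap_angle(angle - (k - 1) * pi / K)
  sqrt(angular_const(K)) * cos(d)^o
}

crop_center <- function(m, n_new) {
  n <- nrow(m)
  i <- (n %/% 2 - n_new %/% 2 + 1L):(n %/% 2 + n_new %/% 2)
  m[i, i, drop = FALSE]
}
pad_center <- function(m, n_new) {
  n <- nrow(m)
  out <- matrix(0 + 0i, n_new, n_new)
  i <- (n_new %/% 2 - n %/% 2 + 1L):(n_new %/% 2 + n %/% 2)
  out[i, i] <- m
  out
}

validate_image <- function(image, config) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("image must be a square matrix")
  if (!all(is.finite(image)))
    stop("image contains non-finite pixel values")
  if (nrow(image) != config$image_size)
    stop(sprintf(
      "image side (%d) does not match config image_size (%d); side must be divisible by 2^n_scales = %d",
      nrow(image), config$image_size, 2L^config$n_scales))
  invisible(TRUE)
}

# ---- decomposition ----------------------------------------------------------

#' Build a complex steerable pyramid
#'
#' Decomposes a square luminance image into an oriented multi-scale set of
#' complex subbands plus a real highpass and lowpass residual.  The image
#' mean is removed before decomposition and stored in `dc_mean`.  Scale 1 is
#' the finest; each coarser level halves the side length.
#'
#' @param image Square numeric matrix of luminance values.
#' @param config A [pyramid_config()].
#' @return An object of class `steerable_pyramid` with elements `highpass`
#'   (real matrix at full resolution), `bands` (list of scales, each a list
#'   of `n_orientations` complex matrices), `lowpass` (real matrix at the
#'   coarsest resolution) and `dc_mean`.
#' @examples
#' cfg <- pyramid_config(image_size = 64)
#' pyr <- build_pyramid(matrix(rnorm(64^2), 64), cfg)
#' length(pyr$bands)
#' @export
build_pyramid <- function(image, config = pyramid_config(image_size = nrow(image))) {
  validate_image(image, config)
  n <- config$image_size
  K <- config$n_orientations
  dc <- mean(image)
  X <- fftshift2(fft2(image - dc))
  g <- polar_grid(n)

  hi0 <- rc_hi(g$log_rad)
  highpass <- Re(ifft2(ifftshift2(X * hi0)))
  lodft <- X * rc_lo(g$log_rad)

  bands <- vector("list", config$n_scales)
  for (s in seq_len(config$n_scales)) {
    ns <- nrow(lodft)
    gs <- polar_grid(ns)
    hm <- rc_hi(gs$log_rad + 1)          # transition one octave below Nyquist
    bands[[s]] <- lapply(seq_len(K), function(k) {
      bdft <- lodft * hm * angle_mask_complex(gs$angle, k, K)
      ifft2(ifftshift2(bdft))
    })
    lodft <- crop_center(lodft * rc_lo(gs$log_rad + 1), ns %/% 2L)
  }
  lowpass <- Re(ifft2(ifftshift2(lodft)))
  structure(list(highpass = highpass, bands = bands, lowpass = lowpass,
                 dc_mean = dc, config = config),
            class = "steerable_pyramid")
}

#' @export
print.steerable_pyramid <- function(x, ...) {
  cat(sprintf(
    "complex steerable pyramid: %d scales x %d orientations, %d px, dc = %.4g\n",
    length(x$bands), length(x$bands[[1]]), nrow(x$highpass), x$dc_mean))
  invisible(x)
}

check_pyramid_config <- function(pyr, config) {
  if (length(pyr$bands) != config$n_scales ||
      length(pyr$bands[[1]]) != config$n_orientations ||
      nrow(pyr$highpass) != config$image_size)
    stop("pyramid shapes do not match the supplied config")
  invisible(TRUE)
}

# centered spectra of the partially reconstructed lowpass images, one pass
# from coarsest to finest.  Element s is the spectrum of the lowpass
# residual plus all oriented bands at scales >= s, at scale-s resolution;
# element n_scales + 1 is the lowpass spectrum itself.
partial_lowpass_dfts <- function(pyr, config) {
  K <- config$n_orientations
  out <- vector("list", config$n_scales + 1L)
  lodft <- fftshift2(fft2(pyr$lowpass))
  out[[config$n_scales + 1L]] <- lodft
  phase <- Conj(complex(modulus = 1, argument = -(K - 1) * pi / 2))
  for (s in rev(seq_len(config$n_scales))) {
    ns <- 2L * nrow(lodft)
    gs <- polar_grid(ns)
    lodft <- pad_center(lodft, ns) * rc_lo(gs$log_rad + 1)
    hm <- rc_hi(gs$log_rad + 1)
    for (k in seq_len(K)) {
      bdft <- fftshift2(fft2(Re(pyr$bands[[s]][[k]])))
      lodft <- lodft + phase * bdft * hm * angle_mask_real(gs$angle, k, K)
    }
    out[[s]] <- lodft
  }
  out
}

#' Invert a steerable pyramid
#'
#' Recombines the real parts of the oriented bands with the highpass and
#' lowpass residuals.  Because the filters form a tight frame, this inverts
#' [build_pyramid()] to floating-point precision.
#'
#' @param pyr A `steerable_pyramid`.
#' @param config The [pyramid_config()] used to build it.
#' @return The reconstructed image (real matrix), including the stored mean.
#' @export
reconstruct_image <- function(pyr, config = pyr$config) {
  check_pyramid_config(pyr, config)
  n <- config$image_size
  g <- polar_grid(n)
  lodft <- partial_lowpass_dfts(pyr, config)[[1L]]
  out_dft <- lodft * rc_lo(g$log_rad) +
    fftshift2(fft2(pyr$highpass)) * rc_hi(g$log_rad)
  Re(ifft2(ifftshift2(out_dft))) + pyr$dc_mean
}

#' Partially reconstructed lowpass images
#'
#' Element `s` is the image rebuilt from the lowpass residual plus every
#' oriented band at scales coarser than or equal to `s`, at the resolution
#' of scale `s`; the last element is the lowpass residual itself.  These are
#' the maps whose skewness, kurtosis and central autocorrelation enter the
#' texture-statistic set.
#'
#' @inheritParams reconstruct_image
#' @return A list of `n_scales + 1` real matrices, finest first.
#' @export
partial_lowpass_images <- function(pyr, config = pyr$config) {
  check_pyramid_config(pyr, config)
  lapply(partial_lowpass_dfts(pyr, config), function(d) {
    Re(ifft2(ifftshift2(d)))
  })
}
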