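# Shared fixtures, built once per test run and cached in an environment.
# Everything is generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# the reference synthetic dataset (100 images per class, master seed 1)
# with its 34-variable summary features; reused by the screening-recovery
# and end-to-end acceptance criteria
reference_dataset <- function() fixture("reference_dataset", function() {
  ds <- make_dataset(100, master_seed = 1)
  feat <- t(vapply(ds$images,
                   function(im) summarize_features(compute_ps_statistics(im)),
                   numeric(34)))
  list(features = feat, labels = ds$manifest$label, manifest = ds$manifest)
})

# a single unit-variance white-noise image and its statistics
noise_stats <- function() fixture("noise_stats", function() {
  x <- with_seed(101, matrix(rnorm(256^2), 256))
  list(image = x, ps = compute_ps_statistics(x))
})

random_image <- function(seed, n = 256) with_seed(seed, matrix(rnorm(n * n), n))

# direct O(N * neighborhood^2) spatial-domain circular autocorrelation --
# the independent oracle for the FFT implementation
direct_autocorrelation <- function(map, neighborhood) {
  h <- (neighborhood - 1L) %/% 2L
  n1 <- nrow(map); n2 <- ncol(map)
  d <- map - mean(map)
  v <- mean(d^2)
  out <- matrix(0, neighborhood, neighborhood)
  for (dy in -h:h) for (dx in -h:h) {
    sh <- d[((seq_len(n1) - 1L + dy) %% n1) + 1L,
            ((seq_len(n2) - 1L + dx) %% n2) + 1L]
    out[dy + h + 1L, dx + h + 1L] <- mean(d * sh) / v
  }
  out
}

# Fourier-domain tally of band energies through the squared filter masks --
# the independent oracle for subband energy bookkeeping
fourier_band_energy <- function(image, config) {
  n <- config$image_size
  X <- texturality:::fftshift2(stats::fft(image - mean(image)))
  g <- texturality:::polar_grid(n)
  P <- Mod(X)^2 / n^4                       # contribution of each frequency to var
  hi0 <- texturality:::rc_hi(g$log_rad)
  lo_chain <- texturality:::rc_lo(g$log_rad)
  bands <- matrix(0, config$n_scales, config$n_orientations)
  for (s in seq_len(config$n_scales)) {
    lr <- g$log_rad + s - 1               # masks expressed on the full-res grid
    hm <- texturality:::rc_hi(lr + 1)
    for (k in seq_len(config$n_orientations)) {
      m <- texturality:::angle_mask_real(g$angle, k, config$n_orientations)
      bands[s, k] <- sum(P * (lo_chain * hm * m)^2)
    }
    lo_chain <- lo_chain * texturality:::rc_lo(lr + 1)
  }
  list(highpass = sum(P * hi0^2), bands = bands, lowpass = sum(P * lo_chain^2))
}

# Bhattacharyya coefficient between two samples via shared histogram bins
bhattacharyya_coefficient <- function(a, b, bins = 20) {
  br <- seq(min(a, b), max(a, b), length.out = bins + 1)
  pa <- hist(a, breaks = br, plot = FALSE)$counts / length(a)
  pb <- hist(b, breaks = br, plot = FALSE)$counts / length(b)
  sum(sqrt(pa * pb))
}

# independent box-constrained dual maximizer (penalized equality constraint,
# L-BFGS-B) used as the reference maximum-margin solver
reference_dual_solver <- function(K, y, C, mu = 1e7) {
  Q <- K * tcrossprod(y)
  obj <- function(a) -(sum(a) - 0.5 * sum(a * (Q %*% a)) - mu * sum(a * y)^2 / 2)
  grad <- function(a) -(1 - Q %*% a - mu * sum(a * y) * y)
  fit <- stats::optim(rep(C / 2, length(y)), obj, grad, method = "L-BFGS-B",
                      lower = 0, upper = C,
                      control = list(maxit = 2000, factr = 1e4))
  list(alpha = fit$par,
       objective = sum(fit$par) - 0.5 * sum(fit$par * (Q %*% fit$par)))
}
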