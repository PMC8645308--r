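# Synthetic stimulus generators and a simulated observer.
#
# The behavioral image set behind the method is not distributable, so the
# generators are built around the causal claim the classifier tests:
# texture images are realizations of (approximately) stationary processes,
# non-texture images impose global, position-dependent structure.  All
# generators are circular where possible (consistent with the periodic
# filtering), deterministic given their seed, and emit luminance in [0, 1].

texture_kinds <- c("filtered_noise", "gabor_field", "binarized_noise", "dot_field")
nontexture_kinds <- c("single_blob", "horizon_scene", "big_polygon", "symmetric_layout")

#' Stimulus specification
#'
#' @param kind Generator name; one of the texture kinds
#'   (`filtered_noise`, `gabor_field`, `binarized_noise`, `dot_field`) or
#'   non-texture kinds (`single_blob`, `horizon_scene`, `big_polygon`,
#'   `symmetric_layout`).
#' @param size Pixels per side (default 256; must satisfy pyramid
#'   divisibility).
#' @param seed Integer seed; the same spec yields a bit-identical image.
#' @param params Named list of generator-specific parameters.
#' @return Object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind, size = 256L, seed = 1L, params = list()) {
  if (!kind %in% c(texture_kinds, nontexture_kinds))
    stop("unknown generator kind: ", kind)
  structure(list(kind = kind, size = as.integer(size),
                 seed = as.integer(seed), params = params),
            class = "stimulus_spec")
}

# map a zero-mean field to [0, 1]: mean 0.5, +/- 3.5 sd spans the range,
# hard-clipped beyond that (preserves stationarity, keeps contrast stable)
to_luminance <- function(x, sd_span = 3.5) {
  s <- stats::sd(as.numeric(x))
  if (s == 0) return(matrix(0.5, nrow(x), ncol(x)))
  pmin(pmax(0.5 + (x - mean(x)) / (2 * sd_span * s), 0), 1)
}

# circular convolution of an impulse map with a kernel map (same size)
circ_convolve <- function(impulses, kernel) {
  Re(ifft2(fft2(impulses) * fft2(kernel)))
}

# 1/f^alpha Gaussian noise field (zero mean)
noise_1of <- function(n, alpha) {
  g <- polar_grid(n)
  amp <- (2^g$log_rad)^(-alpha)
  ctr <- n %/% 2 + 1L
  amp[ctr, ctr] <- 0
  spec <- ifftshift2(amp) * fft2(matrix(stats::rnorm(n * n), n))
  Re(ifft2(spec))
}

gabor_kernel <- function(n, wavelength, sigma, theta) {
  ctr <- n %/% 2 + 1L
  cx <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
  cy <- matrix(seq_len(n) - ctr, n, n)
  u <- cx * cos(theta) + cy * sin(theta)
  k <- exp(-(cx^2 + cy^2) / (2 * sigma^2)) * cos(2 * pi * u / wavelength)
  ifftshift2(k)   # center the kernel at [1,1] for circular convolution
}

gauss_blob <- function(n, cx, cy, sigma, circular = FALSE) {
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  dx <- xs - cx; dy <- ys - cy
  if (circular) {
    dx <- ((dx + n / 2) %% n) - n / 2
    dy <- ((dy + n / 2) %% n) - n / 2
  }
  exp(-(dx^2 + dy^2) / (2 * sigma^2))
}

gen_texture <- function(kind, n, params) {
  p <- params
  switch(kind,
    filtered_noise = {
      alpha <- if (is.null(p$alpha)) 1 else p$alpha
      if (alpha < 0.5 || alpha > 2) stop("filtered_noise: alpha must be in [0.5, 2]")
      to_luminance(noise_1of(n, alpha))
    },
    gabor_field = {
      wavelength <- if (is.null(p$wavelength)) 8 else p$wavelength
      sigma <- if (is.null(p$sigma)) wavelength / 2 else p$sigma
      mixed <- if (is.null(p$mixed_orientation)) TRUE else p$mixed_orientation
      density <- if (is.null(p$density)) 0.004 else p$density
      n_el <- max(1L, stats::rpois(1, density * n * n))
      theta0 <- stats::runif(1, 0, pi)
      field <- matrix(0, n, n)
      thetas <- if (mixed) stats::runif(n_el, 0, pi) else rep(theta0, n_el)
      # group micropatterns by orientation bins so placement stays O(bins) FFTs
      bins <- if (mixed) 8L else 1L
      bin_of <- pmin(1L + floor(thetas / pi * bins), bins)
      for (b in unique(bin_of)) {
        idx <- which(bin_of == b)
        imp <- matrix(0, n, n)
        pos <- cbind(sample.int(n, length(idx), replace = TRUE),
                     sample.int(n, length(idx), replace = TRUE))
        amp <- sample(c(-1, 1), length(idx), replace = TRUE)
        for (i in seq_along(idx)) imp[pos[i, 1], pos[i, 2]] <-
          imp[pos[i, 1], pos[i, 2]] + amp[i]
        field <- field + circ_convolve(imp, gabor_kernel(n, wavelength, sigma,
                                                         mean(thetas[idx])))
      }
      to_luminance(field)
    },
    binarized_noise = {
      alpha <- if (is.null(p$alpha)) 1 else p$alpha
      lo <- if (is.null(p$low)) 0.15 else p$low
      hi <- if (is.null(p$high)) 0.85 else p$high
      x <- noise_1of(n, alpha)
      ifelse(x > stats::median(x), hi, lo)
    },
    dot_field = {
      rate <- if (is.null(p$rate)) 3e-3 else p$rate
      sigma <- if (is.null(p$sigma)) 2.5 else p$sigma
      bright <- if (is.null(p$bright)) TRUE else p$bright
      n_dots <- max(1L, stats::rpois(1, rate * n * n))
      imp <- matrix(0, n, n)
      pos <- cbind(sample.int(n, n_dots, replace = TRUE),
                   sample.int(n, n_dots, replace = TRUE))
      for (i in seq_len(n_dots)) imp[pos[i, 1], pos[i, 2]] <-
        imp[pos[i, 1], pos[i, 2]] + 1
      blobs <- circ_convolve(imp, ifftshift2(gauss_blob(n, n %/% 2 + 1,
                                                        n %/% 2 + 1, sigma)))
      base <- if (bright) 0.3 else 0.7
      sgn <- if (bright) 1 else -1
      pmin(pmax(base + sgn * 0.6 * blobs / max(blobs), 0), 1)
    },
    stop("unknown texture kind: ", kind))
}

gen_nontexture <- function(kind, n, params) {
  p <- params
  xs <- matrix(seq_len(n) / n, n, n, byrow = TRUE)
  ys <- matrix(seq_len(n) / n, n, n)
  switch(kind,
    single_blob = {
      sigma <- if (is.null(p$sigma)) n / 6 else p$sigma
      cx <- n * stats::runif(1, 0.35, 0.65); cy <- n * stats::runif(1, 0.35, 0.65)
      fg <- stats::runif(1, 0.7, 0.95); bg <- stats::runif(1, 0.05, 0.3)
      bg + (fg - bg) * gauss_blob(n, cx, cy, sigma)
    },
    horizon_scene = {
      hline <- stats::runif(1, 0.35, 0.65)
      top <- stats::runif(1, 0.65, 0.95); bottom <- stats::runif(1, 0.05, 0.35)
      img <- ifelse(ys < hline, top - 0.25 * ys, bottom + 0.15 * ys)
      for (i in seq_len(5)) {   # hard-edged foreground objects on the ground
        cx <- n * stats::runif(1, 0.1, 0.9)
        cy <- n * stats::runif(1, hline, 0.95)
        sg <- n * stats::runif(1, 0.04, 0.1)
        lev <- stats::runif(1, 0, 1)
        mask <- gauss_blob(n, cx, cy, sg) > 0.4
        img[mask] <- lev
      }
      img
    },
    big_polygon = {
      nv <- if (is.null(p$n_vertices)) sample(5:8, 1) else p$n_vertices
      ang <- sort(stats::runif(nv, 0, 2 * pi))
      rad <- n * stats::runif(nv, 0.25, 0.4)
      cx <- n * 0.5 + n * stats::runif(1, -0.05, 0.05)
      cy <- n * 0.5 + n * stats::runif(1, -0.05, 0.05)
      vx <- cx + rad * cos(ang); vy <- cy + rad * sin(ang)
      bg <- stats::runif(1, 0.55, 0.75); fill <- stats::runif(1, 0.3, 0.5)
      img <- matrix(bg, n, n)
      # convex-ish fill by winding test on the grid
      inside <- matrix(TRUE, n, n)
      for (i in seq_len(nv)) {
        j <- if (i == nv) 1L else i + 1L
        ex <- vx[j] - vx[i]; ey <- vy[j] - vy[i]
        gx <- matrix(seq_len(n), n, n, byrow = TRUE) - vx[i]
        gy <- matrix(seq_len(n), n, n) - vy[i]
        inside <- inside & (ex * gy - ey * gx >= 0)
      }
      img[inside] <- fill
      # thick dark outline: points near any edge segment
      d2min <- matrix(Inf, n, n)
      gx <- matrix(seq_len(n), n, n, byrow = TRUE)
      gy <- matrix(seq_len(n), n, n)
      for (i in seq_len(nv)) {
        j <- if (i == nv) 1L else i + 1L
        ex <- vx[j] - vx[i]; ey <- vy[j] - vy[i]
        len2 <- ex^2 + ey^2
        t <- pmin(pmax(((gx - vx[i]) * ex + (gy - vy[i]) * ey) / len2, 0), 1)
        d2 <- (gx - (vx[i] + t * ex))^2 + (gy - (vy[i] + t * ey))^2
        d2min <- pmin(d2min, d2)
      }
      img[d2min < (0.008 * n)^2] <- 0.05
      img
    },
    symmetric_layout = {
      half <- matrix(stats::runif(1, 0.4, 0.6), n, n %/% 2)
      for (i in seq_len(4)) {
        cx <- (n %/% 2) * stats::runif(1, 0.1, 0.9)
        cy <- n * stats::runif(1, 0.1, 0.9)
        sg <- n * stats::runif(1, 0.03, 0.08)
        lev <- stats::runif(1, 0.05, 0.95)
        blob <- gauss_blob(n, cx, cy, sg)[, seq_len(n %/% 2)]
        half <- half * (1 - blob) + lev * blob
      }
      cbind(half, half[, rev(seq_len(n %/% 2))])
    },
    stop("unknown non-texture kind: ", kind))
}

#' Generate a texture stimulus
#'
#' Stationary, statistically homogeneous images: `filtered_noise`
#' (1/f^alpha Gaussian noise, `alpha` in `[0.5, 2]`), `gabor_field` (dense
#' randomly positioned micropatterns, fixed or mixed orientation),
#' `binarized_noise` (median-thresholded filtered noise) and `dot_field`
#' (Poisson-positioned Gaussian blobs, polarity `bright`).
#'
#' @param spec A [stimulus_spec()] with a texture `kind`.
#' @return Luminance matrix in `[0, 1]`, deterministic given the spec.
#' @export
make_texture <- function(spec) {
  if (!spec$kind %in% texture_kinds)
    stop("not a texture kind: ", spec$kind)
  with_seed(spec$seed, gen_texture(spec$kind, spec$size, spec$params))
}

#' Generate a non-texture stimulus
#'
#' Globally structured images: `single_blob` (one large smooth shape),
#' `horizon_scene` (two luminance regions, gradients, a few large shapes),
#' `big_polygon` (one large outlined convex shape) and `symmetric_layout`
#' (mirror-symmetric arrangement of a few elements).
#'
#' @param spec A [stimulus_spec()] with a non-texture `kind`.
#' @return Luminance matrix in `[0, 1]`, deterministic given the spec.
#' @export
make_nontexture <- function(spec) {
  if (!spec$kind %in% nontexture_kinds)
    stop("not a non-texture kind: ", spec$kind)
  with_seed(spec$seed, gen_nontexture(spec$kind, spec$size, spec$params))
}

#' Generate a labeled synthetic dataset
#'
#' Produces `2 * n_per_class` images, cycling through the texture and
#' non-texture generator kinds, with per-image seeds derived from
#' `master_seed` by a counter scheme (reproducible, independent across
#' images).  If `dir` is given, images are written as 16-bit PGM files and
#' the manifest as `manifest.csv` plus a JSON config snapshot; otherwise
#' images are returned in memory.
#'
#' @param n_per_class Images per class (>= 1).
#' @param master_seed Integer master seed.
#' @param size Pixels per side.
#' @param dir Optional output directory.
#' @return List with `manifest` (data frame: id, file, kind, seed, label —
#'   texture = 1) and `images` (named list of matrices; file-backed when
#'   `dir` is given).
#' @export
make_dataset <- function(n_per_class, master_seed = 1L, size = 256L, dir = NULL) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  kinds <- c(rep_len(texture_kinds, n_per_class),
             rep_len(nontexture_kinds, n_per_class))
  label <- rep(c(1L, 0L), each = n_per_class)
  id <- sprintf("img%04d", seq_along(kinds))
  seeds <- vapply(seq_along(kinds), function(i) derive_seed(master_seed, i), 0L)
  images <- lapply(seq_along(kinds), function(i) {
    spec <- stimulus_spec(kinds[i], size = size, seed = seeds[i])
    if (label[i] == 1L) make_texture(spec) else make_nontexture(spec)
  })
  names(images) <- id
  file <- sprintf("%s.pgm", id)
  manifest <- data.frame(id = id, file = file, kind = kinds, seed = seeds,
                         label = label, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir)
    for (i in seq_along(images))
      write_pgm(images[[i]], file.path(dir, file[i]), bits = 16L)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    jsonlite::write_json(list(generator = "texturality_synth", version = 1L,
                              master_seed = master_seed, size = size,
                              n_per_class = n_per_class),
                         file.path(dir, "dataset_config.json"),
                         auto_unbox = TRUE)
  }
  list(manifest = manifest, images = images)
}

#' Simulate observer response proportions
#'
#' Generates per-image 'texture' response proportions with the logistic
#' structure the screening analysis assumes: features are z-scored across
#' images, a sparse weight vector plus intercept and Gaussian decision
#' noise define `p_true = plogis(a + w . z + noise)`, and the reported
#' proportion is the mean of `n_trials` Bernoulli draws.
#'
#' @param features Matrix, rows = images, labeled columns = summary
#'   features.
#' @param weights Named numeric vector over a subset of the feature labels.
#' @param intercept Intercept `a` (default 0).
#' @param noise_sd Standard deviation of the per-image decision noise
#'   (default 0.5).
#' @param n_trials Binary responses per image (default 32).
#' @param seed Integer seed.
#' @return List with `proportion`, `p_true` and `n_trials`.
#' @export
simulate_observer <- function(features, weights, intercept = 0,
                              noise_sd = 0.5, n_trials = 32L, seed = 1L) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  unknown <- setdiff(names(weights), colnames(features))
  if (length(unknown))
    stop("weights reference unknown feature label(s): ",
         paste(unknown, collapse = ", "))
  z <- scale(features[, names(weights), drop = FALSE])
  z[is.nan(z)] <- 0
  with_seed(seed, {
    eta <- intercept + as.numeric(z %*% weights) +
      stats::rnorm(nrow(features), 0, noise_sd)
    p_true <- stats::plogis(eta)
    prop <- stats::rbinom(length(p_true), n_trials, p_true) / n_trials
    list(proportion = prop, p_true = p_true, n_trials = n_trials)
  })
}
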