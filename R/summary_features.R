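# Collapse the full texture-statistic set into class-by-spatial-frequency
# summary variables, and screen them against behavioral judgments.
#
# Layout (4 scales x 4 orientations only): seven per-band classes
# (power, skew, kurt, cpL, cpE, coL, coE) at 64/32/16/8 cycles per image,
# plus two cross-scale classes (cfE, cfL) labeled by the coarser member of
# each adjacent pair (32/16/8 cpi): 7 x 4 + 2 x 3 = 34 variables; the
# moment classes alone give the 12-variable subset.

#' Scale-to-frequency map
#'
#' Associates each pyramid scale with its band center frequency in cycles
#' per image: `band_freq[s] = image_size / 2^(s+1)`, finest first (256 px,
#' 4 scales: 64, 32, 16, 8 cpi).  The visual angle subtended by the image
#' is recorded for provenance; all labels stay in cpi.
#'
#' @param image_size Pixels per side (default 256).
#' @param n_scales Number of scales (default 4).
#' @param deg_per_image Degrees of visual angle subtended (default 4.1).
#' @return Object of class `frequency_map` with `band_freq` in cpi.
#' @export
frequency_map <- function(image_size = 256L, n_scales = 4L,
                          deg_per_image = 4.1) {
  structure(list(image_size = as.integer(image_size),
                 n_scales = as.integer(n_scales),
                 deg_per_image = deg_per_image,
                 band_freq = as.integer(image_size) / 2^(seq_len(n_scales) + 1)),
            class = "frequency_map")
}

summary_classes_per_band <- c("power", "skew", "kurt", "cpL", "cpE", "coL", "coE")
summary_classes_cross <- c("cfE", "cfL")

#' Canonical summary-feature labels
#'
#' The fixed label order of the 34-variable summary vector: per-band
#' classes (`power`, `skew`, `kurt`, `cpL`, `cpE`, `coL`, `coE`), each
#' finest-to-coarsest frequency, then the cross-scale classes (`cfE`,
#' `cfL`) labeled by the coarser band of each adjacent pair.
#'
#' @param fmap A [frequency_map()].
#' @return Character vector of 34 labels such as `"power@64"`, `"cfE@8"`.
#' @export
summary_feature_labels <- function(fmap = frequency_map()) {
  f <- fmap$band_freq
  c(as.vector(vapply(summary_classes_per_band,
                     function(cl) sprintf("%s@%g", cl, f), character(length(f)))),
    as.vector(vapply(summary_classes_cross,
                     function(cl) sprintf("%s@%g", cl, f[-1]), character(length(f) - 1))))
}

off_center_mean <- function(m, abs_values = FALSE) {
  ctr <- (nrow(m) + 1L) %/% 2L
  v <- if (abs_values) abs(m) else m
  (sum(v) - v[ctr, ctr]) / (length(v) - 1L)
}
off_diag_mean <- function(m, abs_values = FALSE) {
  v <- if (abs_values) abs(m) else m
  (sum(v) - sum(diag(v))) / (length(v) - nrow(v))
}

#' Summarize texture statistics into the 34 class-by-frequency variables
#'
#' Averages the full statistic set within class and spatial frequency:
#' `power` is the orientation-averaged band-coefficient variance; `skew` /
#' `kurt` are the partial-lowpass moments; `cpL` / `cpE` are the mean
#' off-center central autocorrelations of the partial lowpass images and of
#' the band magnitudes (orientation-averaged); `coL` / `coE` are mean
#' off-diagonal within-scale cross-orientation correlations of real parts
#' and magnitudes; `cfE` is the mean adjacent-scale magnitude correlation
#' and `cfL` the mean absolute adjacent-scale linear (real/imaginary)
#' correlation — absolute because the signed terms cancel under phase.
#'
#' @param ps A `ps_statistics` computed with 4 scales and 4 orientations.
#' @param fmap A [frequency_map()] consistent with the statistics.
#' @return Named numeric vector of length 34 (class `summary_features`),
#'   names from [summary_feature_labels()].
#' @export
summarize_features <- function(ps, fmap = frequency_map(ps$config$image_size,
                                                        ps$config$n_scales)) {
  cfg <- ps$config
  if (cfg$n_scales != 4L || cfg$n_orientations != 4L)
    stop("the 34-variable summary layout requires 4 scales x 4 orientations")
  if (fmap$n_scales != cfg$n_scales || fmap$image_size != cfg$image_size)
    stop("frequency map does not match the statistics' config")
  ns <- cfg$n_scales
  vals <- c(
    vapply(seq_len(ns), function(s) mean(ps$band_var[[s]]), 0),          # power
    ps$lowpass_skew[seq_len(ns)],                                        # skew
    ps$lowpass_kurt[seq_len(ns)],                                        # kurt
    vapply(seq_len(ns), function(s) off_center_mean(ps$raw_autocorr[[s]]), 0),
    vapply(seq_len(ns), function(s)
      mean(vapply(ps$mag_autocorr[[s]], off_center_mean, 0)), 0),
    vapply(seq_len(ns), function(s) off_diag_mean(ps$cross_ori_real[[s]]), 0),
    vapply(seq_len(ns), function(s) off_diag_mean(ps$cross_ori_mag[[s]]), 0),
    vapply(seq_len(ns - 1L), function(s) mean(ps$cross_scale_mag[[s]]), 0),
    vapply(seq_len(ns - 1L), function(s) mean(abs(ps$cross_scale_real[[s]])), 0)
  )
  structure(stats::setNames(vals, summary_feature_labels(fmap)),
            class = c("summary_features", "numeric"))
}

#' Moment-statistic subset of a summary vector
#'
#' Restricts a 34-variable summary vector to the `power`, `skew` and `kurt`
#' classes — the 12 moment variables of the reduced classifier.
#'
#' @param v Summary vector with the default 34-label layout (a matrix with
#'   those column names is also accepted, rows = images).
#' @return The 12 moment entries (or columns), order and labels preserved.
#' @export
moment_subset <- function(v) {
  labs <- if (is.matrix(v)) colnames(v) else names(v)
  expected <- summary_feature_labels()
  if (is.null(labs) || !identical(sort(labs), sort(expected)))
    stop("input does not have the default 34-variable summary layout")
  keep <- labs[sub("@.*$", "", labs) %in% c("power", "skew", "kurt")]
  if (is.matrix(v)) v[, keep, drop = FALSE] else v[keep]
}

#' Logistic correlation between a feature and response proportions
#'
#' Standardizes the feature, fits the two-parameter logistic
#' `p = 1 / (1 + exp(-(a + b z)))` by binomial maximum likelihood (each
#' proportion treated as the mean of `n_trials` binary responses), and
#' returns `sign(b)` times the Pearson correlation between fitted and
#' observed proportions — a signed measure in `[-1, 1]` of how well the
#' feature alone explains the judgments.
#'
#' @param x Feature value per image (length >= 10, finite).
#' @param p Response proportion per image, in `[0, 1]`.
#' @param n_trials Number of binary responses behind each proportion.
#' @return Signed correlation in `[-1, 1]`; 0 (with a warning) for a
#'   zero-variance feature or degenerate responses.
#' @export
logistic_correlation <- function(x, p, n_trials = 1L) {
  if (length(x) != length(p) || length(x) < 10L)
    stop("need >= 10 paired observations")
  if (!all(is.finite(x))) stop("feature contains non-finite values")
  if (any(p < 0 | p > 1)) stop("proportions must lie in [0, 1]")
  if (stats::sd(x) == 0) {
    warning("zero-variance feature; logistic correlation set to 0")
    return(0)
  }
  z <- as.numeric(scale(x))
  fit <- suppressWarnings(
    stats::glm(p ~ z, family = stats::binomial(),
               weights = rep(n_trials, length(p)),
               control = stats::glm.control(maxit = 100)))
  # a perfectly separating feature drives the deviance to 0 before the
  # coefficient path converges; that is a perfect fit, not a failure
  if (!fit$converged && fit$deviance > 1e-6)
    stop("logistic fit did not converge for this feature")
  b <- stats::coef(fit)[["z"]]
  ph <- stats::fitted(fit)
  if (stats::sd(ph) == 0 || stats::sd(p) == 0) {
    warning("degenerate logistic fit; correlation set to 0")
    return(0)
  }
  sign(b) * stats::cor(ph, p)
}

#' Screen every summary feature against judgments
#'
#' Applies [logistic_correlation()] to each column of a feature matrix.
#'
#' @param features Numeric matrix, rows = images, columns = labeled summary
#'   features.
#' @param p Response proportion per image.
#' @param n_trials Responses per image.
#' @return Named numeric vector of signed logistic correlations.
#' @export
screen_features <- function(features, p, n_trials = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(p))
  vapply(colnames(features), function(lab)
    logistic_correlation(features[, lab], p, n_trials), 0)
}

#' Select the k most highly correlated features
#'
#' Orders features by decreasing absolute correlation, breaking ties by the
#' fixed label order, and returns the first `k` labels.
#'
#' @param correlations Named numeric vector, one signed correlation per
#'   feature label.
#' @param k Number of features to keep (default 6).
#' @return Character vector of `k` labels.
#' @export
select_top_k <- function(correlations, k = 6L) {
  k <- as.integer(k)
  if (k <= 0L) stop("k must be positive")
  if (k > length(correlations)) stop("k exceeds the number of features")
  ord <- order(-abs(correlations), seq_along(correlations))
  names(correlations)[ord][seq_len(k)]
}
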