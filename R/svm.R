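# RBF-kernel C-SVC for the texture / non-texture discriminant.
#
# No SVM solver ships with the supported environment, so the dual problem
# is solved here directly: sequential minimal optimization with
# maximal-violating-pair working-set selection on the precomputed kernel
# matrix.  Feature vectors are z-scored (training statistics only) before
# the kernel, matching the magnitude of the shipped kernel-scale presets.

#' SVM hyperparameters
#'
#' The misclassification penalty (box constraint, C) and the width of the
#' Gaussian radial-basis kernel `K(x, z) = exp(-||x - z||^2 / s^2)` applied
#' to z-scored features.
#'
#' @param box_constraint Positive C.
#' @param kernel_scale Positive kernel width s.
#' @return Object of class `svm_hyperparams`.
#' @seealso [svm_preset()] for the published preset pairs.
#' @export
svm_hyperparams <- function(box_constraint, kernel_scale) {
  if (!is.numeric(box_constraint) || box_constraint <= 0)
    stop("box_constraint must be > 0")
  if (!is.numeric(kernel_scale) || kernel_scale <= 0)
    stop("kernel_scale must be > 0")
  structure(list(box_constraint = as.numeric(box_constraint),
                 kernel_scale = as.numeric(kernel_scale)),
            class = "svm_hyperparams")
}

svm_presets <- list(
  texturality_top6   = c(box_constraint = 916.85,  kernel_scale = 0.0543),
  similarity_top6    = c(box_constraint = 0.0142,  kernel_scale = 0.0015),
  texturality_moments = c(box_constraint = 351.74, kernel_scale = 1.2965),
  similarity_moments  = c(box_constraint = 9.6800, kernel_scale = 1.7189)
)

#' Published hyperparameter presets
#'
#' Named (box constraint, kernel scale) pairs reported for the
#' texturality and synthesis-similarity classifiers, on the top-6 feature
#' set and on the 12 moment statistics.  They are presets only; the
#' behavioral data they were tuned on are not distributed, so no accuracy
#' claim attaches to them here.
#'
#' @param name One of `"texturality_top6"`, `"similarity_top6"`,
#'   `"texturality_moments"`, `"similarity_moments"`.
#' @return An [svm_hyperparams()] object.
#' @export
svm_preset <- function(name = names(svm_presets)) {
  name <- match.arg(name)
  p <- svm_presets[[name]]
  svm_hyperparams(p[["box_constraint"]], p[["kernel_scale"]])
}

#' Binarize response proportions
#'
#' Labels images 1 when the proportion exceeds the threshold and 0 when it
#' falls below; proportions exactly at the threshold are excluded and
#' reported rather than assigned.
#'
#' @param proportions Numeric vector in `[0, 1]`, optionally named.
#' @param threshold Cut point (default 0.5).
#' @return List with `labels` (0/1 vector over retained entries),
#'   `kept` (indices retained) and `excluded` (ids or indices at the
#'   threshold).
#' @export
binarize_judgments <- function(proportions, threshold = 0.5) {
  if (any(proportions < 0 | proportions > 1, na.rm = TRUE) ||
      any(!is.finite(proportions)))
    stop("proportions must be finite and in [0, 1]")
  ids <- if (is.null(names(proportions))) seq_along(proportions)
         else names(proportions)
  at <- proportions == threshold
  list(labels = as.integer(proportions[!at] > threshold),
       kept = ids[!at], excluded = ids[at])
}

rbf_kernel <- function(A, B, kernel_scale) {
  # exp(-||a - b||^2 / s^2) for rows of A against rows of B
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / kernel_scale^2)
}

# SMO for min 1/2 a'Qa - e'a, 0 <= a <= C, y'a = 0 (Q = yy' * K).
# Maximal-violating-pair selection; returns alpha and bias.
smo_solve <- function(K, y, C, tol = 1e-5, max_iter = 2e5) {
  n <- length(y)
  alpha <- numeric(n)
  G <- rep(-1, n)                       # gradient of the dual objective
  Q <- K * tcrossprod(y)
  for (it in seq_len(max_iter)) {
    yG <- -y * G
    up <- (y > 0 & alpha < C) | (y < 0 & alpha > 0)
    low <- (y > 0 & alpha > 0) | (y < 0 & alpha < C)
    if (!any(up) || !any(low)) break
    i <- which(up)[which.max(yG[up])]
    j <- which(low)[which.min(yG[low])]
    if (yG[i] - yG[j] < tol) break
    quad <- K[i, i] + K[j, j] - 2 * y[i] * y[j] * K[i, j]
    if (quad <= 0) quad <- 1e-12
    ai <- alpha[i]; aj <- alpha[j]
    if (y[i] != y[j]) {
      delta <- (-G[i] - G[j]) / quad
      diff <- ai - aj
      ai <- ai + delta; aj <- aj + delta
      if (diff > 0 && aj < 0) { aj <- 0; ai <- diff }
      if (diff <= 0 && ai < 0) { ai <- 0; aj <- -diff }
      if (diff > 0 && ai > C) { ai <- C; aj <- C - diff }
      if (diff <= 0 && aj > C) { aj <- C; ai <- C + diff }
    } else {
      delta <- (G[i] - G[j]) / quad
      s <- ai + aj
      ai <- ai - delta; aj <- aj + delta
      if (s > C && ai > C) { ai <- C; aj <- s - C }
      if (s > C && aj > C) { aj <- C; ai <- s - C }
      if (s <= C && aj < 0) { aj <- 0; ai <- s }
      if (s <= C && ai < 0) { ai <- 0; aj <- s }
    }
    G <- G + Q[, i] * (ai - alpha[i]) + Q[, j] * (aj - alpha[j])
    alpha[i] <- ai; alpha[j] <- aj
  }
  yG <- -y * G
  free <- alpha > 1e-12 & alpha < C - 1e-12
  b <- if (any(free)) mean(yG[free]) else {
    up <- (y > 0 & alpha < C) | (y < 0 & alpha > 0)
    low <- (y > 0 & alpha > 0) | (y < 0 & alpha < C)
    (max(yG[up]) + min(yG[low])) / 2
  }
  list(alpha = alpha, bias = b)
}

#' Train the RBF support vector classifier
#'
#' Z-scores the feature columns (training statistics only), precomputes the
#' Gaussian kernel and solves the C-SVC dual by sequential minimal
#' optimization.  Only support vectors are retained.
#'
#' @param x Numeric matrix, rows = images, labeled columns = features.
#' @param y Labels in `{0, 1}`, both classes present, >= 2 rows per class.
#' @param hyper An [svm_hyperparams()] (or [svm_preset()]).
#' @return Object of class `trained_svm` holding standardized support
#'   vectors, dual coefficients, bias, per-feature centers and scales,
#'   hyperparameters and the feature label list.
#' @export
train_svm <- function(x, y, hyper) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%d", seq_len(ncol(x)))
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("training data must contain >= 2 rows of each class")
  if (anyNA(x) || !all(is.finite(x))) stop("features must be finite")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  ys <- ifelse(y == 1L, 1, -1)
  K <- rbf_kernel(z, z, hyper$kernel_scale)
  sol <- smo_solve(K, ys, hyper$box_constraint)
  sv <- sol$alpha > 1e-12
  structure(list(support_vectors = z[sv, , drop = FALSE],
                 coefficients = (sol$alpha * ys)[sv],
                 bias = sol$bias,
                 centers = ctr, scales = scl,
                 hyper = hyper,
                 feature_labels = colnames(x)),
            class = "trained_svm")
}

#' @export
print.trained_svm <- function(x, ...) {
  cat(sprintf(
    "RBF-SVM: %d support vectors over %d features (C = %g, kernel scale = %g)\n",
    nrow(x$support_vectors), length(x$feature_labels),
    x$hyper$box_constraint, x$hyper$kernel_scale))
  invisible(x)
}

#' Predict texture / non-texture labels
#'
#' @param object A `trained_svm`.
#' @param newdata Numeric matrix (or vector for a single image) whose
#'   columns match the model's feature labels.
#' @param ... Unused.
#' @return Data frame with `decision` (signed decision value) and `label`
#'   (1 iff decision > 0).
#' @export
predict.trained_svm <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
    dimnames = list(NULL, names(newdata)))
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$feature_labels))
      stop("newdata has the wrong number of features")
    colnames(newdata) <- object$feature_labels
  }
  missing <- setdiff(object$feature_labels, colnames(newdata))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  newdata <- newdata[, object$feature_labels, drop = FALSE]
  z <- sweep(sweep(newdata, 2, object$centers), 2, object$scales, "/")
  K <- rbf_kernel(z, object$support_vectors, object$hyper$kernel_scale)
  dec <- as.numeric(K %*% object$coefficients + object$bias)
  data.frame(decision = dec, label = as.integer(dec > 0))
}

stratified_folds <- function(y, folds, seed) {
  if (folds < 2L) stop("folds must be >= 2")
  if (length(y) < folds) stop("need at least as many rows as folds")
  assign <- integer(length(y))
  rng <- with_seed(seed, lapply(split(seq_along(y), y), sample))
  for (idx in rng)
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  assign
}

#' Stratified k-fold cross-validation
#'
#' Assigns rows to folds stratified by class (seeded, reproducible),
#' refits the standardization and the SVM inside each training fold, and
#' scores the held-out fold.
#'
#' @inheritParams train_svm
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return List with `mean_accuracy`, `fold_accuracy`, and `fold` (the
#'   per-row fold assignment).
#' @export
cross_validate <- function(x, y, hyper, folds = 10L, seed = 1L) {
  x <- as.matrix(x); y <- as.integer(y)
  fold <- stratified_folds(y, folds, seed)
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    model <- train_svm(x[tr, , drop = FALSE], y[tr], hyper)
    pred <- predict(model, x[!tr, , drop = FALSE])
    mean(pred$label == y[!tr])
  }, 0)
  list(mean_accuracy = mean(acc), fold_accuracy = acc, fold = fold)
}

#' Grid search over SVM hyperparameters
#'
#' Evaluates every (C, kernel scale) pair by cross-validation and returns
#' the best pair, ties broken toward smaller C then larger kernel scale,
#' together with the full table for audit.
#'
#' @inheritParams cross_validate
#' @param box_constraints,kernel_scales Numeric vectors defining the grid.
#' @return List with `best` (an [svm_hyperparams()]) and `table` (a data
#'   frame of C, kernel scale and mean CV accuracy).
#' @export
tune_svm <- function(x, y, box_constraints = c(1, 10, 100),
                     kernel_scales = c(0.5, 1, 2, 4),
                     folds = 10L, seed = 1L) {
  grid <- expand.grid(box_constraint = box_constraints,
                      kernel_scale = kernel_scales)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid")
  grid$mean_accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    cross_validate(x, y, svm_hyperparams(grid$box_constraint[i],
                                         grid$kernel_scale[i]),
                   folds = folds, seed = seed)$mean_accuracy
  }, 0)
  ord <- order(-grid$mean_accuracy, grid$box_constraint, -grid$kernel_scale)
  best <- grid[ord[1L], ]
  list(best = svm_hyperparams(best$box_constraint, best$kernel_scale),
       table = grid)
}

#' Save / load a trained model
#'
#' Serializes the full model (support vectors, coefficients, bias,
#' standardization, hyperparameters, labels) to a single JSON document with
#' 17-significant-digit numbers, which round-trips doubles exactly.
#'
#' @param model A `trained_svm`.
#' @param path File path.
#' @return `load_svm` returns the restored `trained_svm`.
#' @export
save_svm <- function(model, path) {
  payload <- list(
    format = "texturality_svm", version = 1L,
    feature_labels = model$feature_labels,
    hyper = unclass(model$hyper),
    centers = unname(model$centers), scales = unname(model$scales),
    bias = model$bias, coefficients = model$coefficients,
    support_vectors = model$support_vectors)
  # digits = I(17): decimal-exact round trip for doubles
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_svm
#' @export
load_svm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "texturality_svm"))
    stop("not a serialized texturality SVM: ", path)
  sv <- matrix(as.numeric(p$support_vectors),
               nrow = NROW(p$support_vectors),
               dimnames = list(NULL, p$feature_labels))
  structure(list(support_vectors = sv,
                 coefficients = as.numeric(p$coefficients),
                 bias = as.numeric(p$bias),
                 centers = stats::setNames(as.numeric(p$centers), p$feature_labels),
                 scales = stats::setNames(as.numeric(p$scales), p$feature_labels),
                 hyper = svm_hyperparams(p$hyper$box_constraint,
                                         p$hyper$kernel_scale),
                 feature_labels = p$feature_labels),
            class = "trained_svm")
}
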