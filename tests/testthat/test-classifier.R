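test_that("judgment binarization follows the strict-threshold rule", {
  b <- binarize_judgments(c(a = 0.75, b = 0.25, c = 0.5, d = 1, e = 0))
  expect_equal(b$labels, c(1L, 0L, 1L, 0L))
  expect_equal(b$kept, c("a", "b", "d", "e"))
  expect_equal(b$excluded, "c")
  expect_error(binarize_judgments(c(0.2, 1.2)), "\\[0, 1\\]")
})

test_that("hyperparameter containers and presets are wired up", {
  h <- svm_preset("texturality_top6")
  expect_equal(h$box_constraint, 916.85)
  expect_equal(h$kernel_scale, 0.0543)
  expect_equal(svm_preset("texturality_moments")$kernel_scale, 1.2965)
  expect_equal(svm_preset("similarity_top6")$box_constraint, 0.0142)
  expect_equal(svm_preset("similarity_moments")$box_constraint, 9.68)
  expect_error(svm_hyperparams(-1, 1), "box_constraint")
  expect_error(svm_hyperparams(1, 0), "kernel_scale")
})

test_that("training solves the dual: closed-form and reference solvers agree", {
  # separable 1-D data: perfect training accuracy
  xs <- matrix(c(-2, -1, 1, 2), ncol = 1)
  ys <- c(0, 0, 1, 1)
  m <- train_svm(xs, ys, svm_hyperparams(100, 1))
  expect_equal(predict(m, xs)$label, ys)
  # XOR clusters: RBF capability, checked against an independent
  # box-constrained dual maximizer on the same standardized data
  cl <- with_seed(33, {
    n <- 25
    rbind(cbind(rnorm(n, -1, .1), rnorm(n, -1, .1)),
          cbind(rnorm(n, 1, .1), rnorm(n, 1, .1)),
          cbind(rnorm(n, -1, .1), rnorm(n, 1, .1)),
          cbind(rnorm(n, 1, .1), rnorm(n, -1, .1)))
  })
  yx <- c(rep(1L, 50), rep(0L, 50))
  mx <- train_svm(cl, yx, svm_hyperparams(10, 1))
  expect_gte(mean(predict(mx, cl)$label == yx), 0.98)
  z <- scale(cl)
  K <- exp(-as.matrix(dist(z))^2)
  ysgn <- ifelse(yx == 1, 1, -1)
  ref <- reference_dual_solver(K, ysgn, C = 10)
  smo <- texturality:::smo_solve(K, ysgn, C = 10)
  obj_smo <- sum(smo$alpha) - 0.5 * sum(smo$alpha *
    ((K * tcrossprod(ysgn)) %*% smo$alpha))
  # the SMO solution must be feasible and at least as good as the
  # independent (penalty-method, hence slightly conservative) maximizer
  expect_true(all(smo$alpha >= -1e-9 & smo$alpha <= 10 + 1e-9))
  expect_lt(abs(sum(smo$alpha * ysgn)), 1e-8)
  expect_gte(obj_smo, ref$objective - 1e-6)
  expect_lt(abs(obj_smo - ref$objective) / ref$objective, 0.05)
  expect_error(train_svm(cl, rep(1L, 100), svm_hyperparams(1, 1)), "class")
})

test_that("duplicating rows leaves the decision function unchanged", {
  # separable data with a clear margin and a non-binding box constraint:
  # duplication then only duplicates inactive constraints
  x <- with_seed(41, matrix(rnorm(60 * 2), 60))
  y <- as.integer(x[, 1] > 0)
  x[, 1] <- x[, 1] + ifelse(y == 1, 0.5, -0.5)
  h <- svm_hyperparams(1000, 1.5)
  m1 <- train_svm(x, y, h)
  m2 <- train_svm(rbind(x, x), c(y, y), h)
  probe <- with_seed(42, matrix(rnorm(200 * 2), 200,
                                dimnames = list(NULL, c("f1", "f2"))))
  expect_equal(predict(m1, probe)$label, predict(m2, probe)$label)
  # decision values agree up to the dual solver's convergence tolerance
  expect_gt(cor(predict(m1, probe)$decision, predict(m2, probe)$decision),
            0.999)
})

test_that("prediction is deterministic, continuous and validated", {
  x <- matrix(c(-2, -1, 1, 2), ncol = 1, dimnames = list(NULL, "f"))
  m <- train_svm(x, c(0, 0, 1, 1), svm_hyperparams(100, 1))
  # stored support vectors predict their own training labels
  sv_raw <- sweep(sweep(m$support_vectors, 2, m$scales, "*"), 2, m$centers, "+")
  labs <- predict(m, sv_raw)$label
  expect_equal(labs, as.integer(m$coefficients > 0))
  d1 <- predict(m, matrix(0.5, 1, 1, dimnames = list(NULL, "f")))$decision
  d2 <- predict(m, matrix(0.5 + 1e-9, 1, 1, dimnames = list(NULL, "f")))$decision
  expect_lt(abs(d1 - d2), 1e-6)
  expect_error(predict(m, matrix(1, 1, 1, dimnames = list(NULL, "g"))),
               "missing feature")
})

test_that("model serialization round-trips decision values exactly", {
  x <- with_seed(51, matrix(rnorm(80 * 3), 80,
                            dimnames = list(NULL, c("a", "b", "c"))))
  y <- as.integer(x[, 1] - x[, 2] > 0)
  m <- train_svm(x, y, svm_hyperparams(10, 2))
  path <- tempfile(fileext = ".json")
  save_svm(m, path)
  m2 <- load_svm(path)
  expect_identical(predict(m, x)$decision, predict(m2, x)$decision)
  expect_error(load_svm({p <- tempfile(); writeLines('{"a":1}', p); p}),
               "not a serialized")
})

test_that("cross-validation is stratified, deterministic and calibrated", {
  # well-separated classes: every fold perfect
  xs <- with_seed(61, matrix(c(rnorm(50, -3), rnorm(50, 3)), ncol = 1))
  ys <- rep(c(0L, 1L), each = 50)
  cv <- cross_validate(xs, ys, svm_hyperparams(100, 1), folds = 10, seed = 1)
  expect_equal(cv$mean_accuracy, 1)
  # determinism and fold integrity
  cv2 <- cross_validate(xs, ys, svm_hyperparams(100, 1), folds = 10, seed = 1)
  expect_identical(cv$fold_accuracy, cv2$fold_accuracy)
  expect_equal(sort(unique(cv$fold)), 1:10)
  expect_equal(as.vector(table(cv$fold)), rep(10L, 10))
  for (f in 1:10)
    expect_equal(sum(ys[cv$fold == f]), 5L)   # class balance per fold
  cv3 <- cross_validate(xs, ys, svm_hyperparams(100, 1), folds = 10, seed = 2)
  expect_false(identical(cv$fold, cv3$fold))
  # permuted labels: accuracy inside the central 95% binomial band at n=200
  x2 <- with_seed(62, matrix(rnorm(200 * 2), 200))
  y2 <- rep(c(0L, 1L), 100)
  accs <- vapply(1:5, function(s) {
    yp <- with_seed(100 + s, sample(y2))
    cross_validate(x2, yp, svm_hyperparams(5, 1), folds = 10, seed = 1)$mean_accuracy
  }, 0)
  expect_true(all(abs(accs - 0.5) < 1.96 * sqrt(0.25 / 200) + 0.03))
  expect_error(cross_validate(xs, ys, svm_hyperparams(1, 1), folds = 1), "folds")
})

test_that("label-noise flips degrade accuracy monotonically", {
  ref <- reference_dataset()
  cors <- screen_features(ref$features, ref$labels, 1L)
  top6 <- select_top_k(cors, 6)
  x <- ref$features[, top6]
  h <- svm_hyperparams(10, 2)
  acc <- vapply(c(0, 0.1, 0.3), function(rate) {
    mean(vapply(1:5, function(s) {
      y <- ref$labels
      if (rate > 0) {
        flip <- with_seed(200 + s, sample(length(y), round(rate * length(y))))
        y[flip] <- 1L - y[flip]
      }
      cross_validate(x, y, h, folds = 10, seed = s)$mean_accuracy
    }, 0))
  }, 0)
  expect_true(all(diff(acc) < 0))
})

test_that("hyperparameter tuning is an exhaustive audited search", {
  xs <- with_seed(71, matrix(c(rnorm(30, -2), rnorm(30, 2)), ncol = 1))
  ys <- rep(c(0L, 1L), each = 30)
  tn <- tune_svm(xs, ys, box_constraints = c(1, 10),
                 kernel_scales = c(0.5, 2), folds = 5, seed = 3)
  expect_equal(nrow(tn$table), 4L)
  expect_equal(max(tn$table$mean_accuracy),
               cross_validate(xs, ys, tn$best, folds = 5, seed = 3)$mean_accuracy)
  # one-point grid returns that point
  tn1 <- tune_svm(xs, ys, box_constraints = 7, kernel_scales = 1.3,
                  folds = 5, seed = 3)
  expect_equal(tn1$best$box_constraint, 7)
  expect_equal(tn1$best$kernel_scale, 1.3)
  # ties break toward smaller C then larger kernel scale
  expect_equal(tn$best$box_constraint,
               min(tn$table$box_constraint[tn$table$mean_accuracy ==
                                             max(tn$table$mean_accuracy)]))
})
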