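# brute-force evaluation of the complement-count formula, independent of
# the package implementation
cnb_oracle_weights <- function(mat, labels, alpha, normalize = FALSE) {
  V <- ncol(mat)
  out <- matrix(NA_real_, 2, V,
                dimnames = list(c("include", "exclude"), colnames(mat)))
  for (cls in c("include", "exclude")) {
    comp_rows <- which(labels != cls)
    n_ci <- numeric(V)
    for (j in seq_len(V)) n_ci[j] <- sum(mat[comp_rows, j])
    w <- log((n_ci + alpha) / (sum(n_ci) + alpha * V))
    if (normalize) w <- w / sum(abs(w))
    out[cls, ] <- w
  }
  out
}

two_doc_fixture <- function() {
  m <- matrix(c(2, 0, 0, 3), nrow = 2,
              dimnames = list(c("d1", "d2"), c("fa", "fb")))
  feature_matrix(Matrix::Matrix(m, sparse = TRUE), "tf")
}

test_that("log-weights match the complement-count oracle exactly", {
  fm <- two_doc_fixture()
  labels <- c("include", "exclude")
  for (alpha in c(0.001, 0.25, 1)) {
    for (norm in c(FALSE, TRUE)) {
      model <- train_cnb(fm, labels, smoothing = alpha,
                         weight_normalization = norm)
      oracle <- cnb_oracle_weights(as.matrix(fm), labels, alpha, norm)
      expect_equal(model$log_weights, oracle, tolerance = 1e-12)
    }
  }
  # 4-doc, 3-feature fixture
  m4 <- matrix(c(1, 0, 2, 0,
                 0, 1, 1, 3,
                 2, 2, 0, 1), nrow = 4,
               dimnames = list(paste0("d", 1:4), c("x", "y", "z")))
  fm4 <- feature_matrix(Matrix::Matrix(m4, sparse = TRUE), "tf")
  labels4 <- c("include", "include", "exclude", "exclude")
  model4 <- train_cnb(fm4, labels4, smoothing = 0.5)
  expect_equal(model4$log_weights,
               cnb_oracle_weights(m4, labels4, 0.5), tolerance = 1e-12)
})

test_that("training contracts: symmetry, normalization, input checks", {
  fm <- two_doc_fixture()
  labels <- c("include", "exclude")
  # perfectly symmetric classes give permuted weight rows
  sym <- feature_matrix(Matrix::Matrix(
    matrix(c(2, 0, 0, 2), nrow = 2,
           dimnames = list(c("d1", "d2"), c("fa", "fb"))), sparse = TRUE),
    "tf")
  model <- train_cnb(sym, labels, smoothing = 1)
  expect_equal(unname(model$log_weights["include", c("fa", "fb")]),
               unname(model$log_weights["exclude", c("fb", "fa")]),
               tolerance = 1e-12)
  # weight normalization makes each row's absolute sum 1
  norm <- train_cnb(fm, labels, smoothing = 1, weight_normalization = TRUE)
  expect_equal(unname(rowSums(abs(norm$log_weights))), c(1, 1),
               tolerance = 1e-12)
  expect_error(train_cnb(fm, c("include", "include")), "both classes")
  expect_error(train_cnb(fm, labels, smoothing = 0), "positive")
})

test_that("training is invariant to document order", {
  cp <- separable_corpus(n = 60, seed = 21)
  fm <- build_alphabetic(cp)
  model1 <- train_cnb(fm, cp$label, smoothing = 0.5)
  perm <- rev(seq_len(nrow(cp)))
  fm2 <- fm
  fm2$matrix <- fm$matrix[perm, ]
  model2 <- train_cnb(fm2, cp$label[perm], smoothing = 0.5)
  expect_equal(model1$log_weights, model2$log_weights, tolerance = 1e-12)
})

test_that("large smoothing flattens class differences toward uniform", {
  fm <- two_doc_fixture()
  labels <- c("include", "exclude")
  model <- train_cnb(fm, labels, smoothing = 1e9)
  spread <- max(abs(model$log_weights["include", ] -
                      model$log_weights["exclude", ]))
  expect_lt(spread, 1e-8)
  expect_equal(unname(model$log_weights[1, 1]), log(1 / 2), tolerance = 1e-4)
})

test_that("prediction follows the negative-complement-score rule", {
  fm <- two_doc_fixture()
  labels <- c("include", "exclude")
  model <- train_cnb(fm, labels, smoothing = 1)
  preds <- predict_cnb(model, fm)
  # hand-trace: d1 carries only fa, which dominates the exclude
  # complement, so -score favors include
  expect_equal(preds$label, c("include", "exclude"))
  expect_equal(preds$score_include,
               -as.numeric(as.matrix(fm) %*% model$log_weights["include", ]),
               tolerance = 1e-12)
  # softmax confidences sum to one and track the decision
  expect_equal(preds$conf_include + preds$conf_exclude, c(1, 1))
  expect_gt(preds$conf_include[1], 0.5)
})

test_that("zero vectors fall back to the majority class, flagged", {
  fm <- two_doc_fixture()
  model <- train_cnb(fm, c("include", "exclude"), smoothing = 1)
  zero <- feature_matrix(
    Matrix::Matrix(matrix(0, 1, 2, dimnames = list("z", c("fa", "fb"))),
                   sparse = TRUE), "tf")
  p <- predict_cnb(model, zero)
  expect_equal(p$label, "exclude")  # equal priors -> exclude
  expect_true(p$low_confidence)
})

test_that("scaling a document never flips the decision", {
  cp <- separable_corpus(n = 60, seed = 22)
  fm <- build_alphabetic(cp)
  model <- train_cnb(fm, cp$label, smoothing = 0.5)
  p1 <- predict_cnb(model, fm)
  fm_scaled <- fm
  fm_scaled$matrix <- fm$matrix * 7
  p2 <- predict_cnb(model, fm_scaled)
  expect_equal(p2$label, p1$label)
  nonzero <- Matrix::rowSums(abs(fm$matrix)) > 0
  expect_equal((p2$score_include - p2$score_exclude)[nonzero],
               7 * (p1$score_include - p1$score_exclude)[nonzero],
               tolerance = 1e-9)
})

test_that("models round-trip through JSON", {
  fm <- two_doc_fixture()
  model <- train_cnb(fm, c("include", "exclude"), smoothing = 0.25,
                     weight_normalization = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_cnb(model, path)
  back <- read_cnb(path)
  expect_equal(back$log_weights, model$log_weights, tolerance = 1e-12)
  expect_equal(back$smoothing, model$smoothing)
  expect_equal(back$weight_normalization, model$weight_normalization)
  # tidy/glance interfaces
  td <- tidy(model)
  expect_equal(nrow(td), 4L)
  expect_equal(glance(model)$n_features, 2L)
})
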