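# Complement naive Bayes for imbalanced two-class screening data.
# Class parameters are estimated from the complement of each class's
# documents, which stabilizes the minority (include) class.

#' Train a complement naive Bayes classifier
#'
#' For class `c` and feature `i`,
#' `w_ci = log( (N_notc_i + alpha) / (N_notc + alpha * V) )`,
#' where `N_notc_i` is the total weight of feature `i` over documents
#' *not* in class `c`, `N_notc` the total weight over those documents,
#' and `V` the number of features. Real-valued tf-idf weights are used
#' directly in the complement sums. With `weight_normalization = TRUE`
#' each class's weight vector is divided by the sum of its absolute
#' values (the weight-normalized variant).
#'
#' @param x A `feature_matrix` of nonnegative weights.
#' @param labels Character vector over `include`/`exclude`, aligned with
#'   the documents.
#' @param smoothing Additive smoothing `alpha > 0` (default 1).
#' @param weight_normalization Normalize each class's weight vector
#'   (default `FALSE`).
#' @return A `cnb_model` object.
#' @export
train_cnb <- function(x, labels, smoothing = 1,
                      weight_normalization = FALSE) {
  stopifnot(inherits(x, "feature_matrix"))
  if (smoothing <= 0) abort("smoothing must be positive")
  labels <- as.character(labels)
  if (length(labels) != nrow(x$matrix)) {
    abort("labels must align with the documents of the matrix")
  }
  classes <- c("include", "exclude")
  present <- intersect(classes, unique(labels))
  if (length(present) < 2L) abort("training data must contain both classes")

  mat <- x$matrix
  V <- ncol(mat)
  if (V == 0L) abort("feature matrix has no columns")
  log_weights <- matrix(0, nrow = 2L, ncol = V,
                        dimnames = list(classes, colnames(mat)))
  for (cls in classes) {
    comp <- labels != cls
    n_ci <- Matrix::colSums(mat[comp, , drop = FALSE])
    n_c <- sum(n_ci)
    w <- log((n_ci + smoothing) / (n_c + smoothing * V))
    if (weight_normalization) w <- w / sum(abs(w))
    log_weights[cls, ] <- as.numeric(w)
  }
  priors <- c(include = mean(labels == "include"),
              exclude = mean(labels == "exclude"))
  structure(list(
    classes = classes,
    log_weights = log_weights,
    smoothing = smoothing,
    weight_normalization = weight_normalization,
    feature_names = colnames(mat),
    priors = priors
  ), class = "cnb_model")
}

#' @exportS3Method base::print
print.cnb_model <- function(x, ...) {
  cat(sprintf(
    "<cnb_model> %d features, smoothing = %g, weight_normalization = %s\n",
    length(x$feature_names), x$smoothing, x$weight_normalization))
  invisible(x)
}

#' Predict screening labels with a complement naive Bayes model
#'
#' The complement decision rule scores each class by
#' `score(c) = -sum_i f_i * w_ci` and predicts the argmax; ties go to
#' `exclude` (the majority class). Confidences are the softmax of the
#' scores. Documents with an all-zero feature vector fall back to the
#' higher class prior and are flagged low-confidence.
#'
#' @param model A `cnb_model`.
#' @param newdata A `feature_matrix` (features outside the model's
#'   space are ignored; missing model features count as zero).
#' @return A tibble with columns `id`, `label`, `score_include`,
#'   `score_exclude`, `conf_include`, `conf_exclude`, `low_confidence`.
#' @export
predict_cnb <- function(model, newdata) {
  stopifnot(inherits(model, "cnb_model"))
  mat <- if (inherits(newdata, "feature_matrix")) newdata$matrix else
    Matrix::Matrix(newdata, sparse = TRUE)
  common <- intersect(colnames(mat), model$feature_names)
  aligned <- Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0),
    dims = c(nrow(mat), length(model$feature_names)),
    dimnames = list(rownames(mat), model$feature_names))
  aligned <- methods::as(aligned, "CsparseMatrix")
  if (length(common)) {
    aligned[, common] <- mat[, common, drop = FALSE]
  }
  scores <- -as.matrix(aligned %*% t(model$log_weights))
  colnames(scores) <- model$classes

  empty <- Matrix::rowSums(abs(aligned)) == 0
  label <- ifelse(scores[, "include"] > scores[, "exclude"],
                  "include", "exclude")
  if (any(empty)) {
    # ties (equal priors) go to exclude, the majority class
    fallback <- if (model$priors[["include"]] > model$priors[["exclude"]])
      "include" else "exclude"
    label[empty] <- fallback
  }
  # softmax confidences
  mx <- pmax(scores[, 1L], scores[, 2L])
  e1 <- exp(scores[, "include"] - mx)
  e2 <- exp(scores[, "exclude"] - mx)
  tibble::tibble(
    id = rownames(aligned) %||% as.character(seq_len(nrow(aligned))),
    label = unname(label),
    score_include = unname(scores[, "include"]),
    score_exclude = unname(scores[, "exclude"]),
    conf_include = unname(e1 / (e1 + e2)),
    conf_exclude = unname(e2 / (e1 + e2)),
    low_confidence = unname(empty)
  )
}

#' @export
tidy.cnb_model <- function(x, ...) {
  tibble::tibble(
    feature = rep(x$feature_names, each = 2L),
    class = rep(x$classes, times = length(x$feature_names)),
    log_weight = as.numeric(x$log_weights[, x$feature_names, drop = FALSE])
  ) |>
    dplyr::arrange(.data$feature, .data$class)
}

#' @export
glance.cnb_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names),
    smoothing = x$smoothing,
    weight_normalization = x$weight_normalization,
    prior_include = unname(x$priors["include"])
  )
}

#' Save or load a complement naive Bayes model as JSON
#'
#' @param model A `cnb_model`.
#' @param path File path.
#' @return `write_cnb()` returns `path` invisibly; `read_cnb()` a
#'   `cnb_model`.
#' @export
write_cnb <- function(model, path) {
  jsonlite::write_json(list(
    classes = model$classes,
    feature_names = model$feature_names,
    log_weights = as.data.frame(t(model$log_weights)),
    smoothing = model$smoothing,
    weight_normalization = model$weight_normalization,
    priors = as.list(model$priors)
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cnb
#' @export
read_cnb <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lw <- t(as.matrix(obj$log_weights))
  dimnames(lw) <- list(obj$classes, obj$feature_names)
  structure(list(
    classes = obj$classes,
    log_weights = lw,
    smoothing = obj$smoothing,
    weight_normalization = obj$weight_normalization,
    feature_names = obj$feature_names,
    priors = unlist(obj$priors)
  ), class = "cnb_model")
}
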