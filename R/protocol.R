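# The study-design engine: stratified half splits, feature-set
# builders with held-out projection, F3-driven grid optimization and
# the two-reviewer A|B / B|A protocol.

.FEATURE_SETS <- c("alphabetic", "alphanumeric", "indexing", "concepts",
                   "topics")

# evaluate code under a local RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

.derive_seed <- function(seed, ...) {
  h <- as.double(seed)
  for (k in c(...)) h <- (h * 69091 + as.double(k)) %% 2147483647
  as.integer(h)
}

#' Stratified random half split of a labeled corpus
#'
#' Splits a corpus into halves A and B, stratifying by label so the
#' eligible percentage is preserved: within each class the two halves
#' differ by at most one citation, and overall by at most one. Which
#' half receives the odd citation of an odd-sized class is random.
#'
#' @param x A labeled corpus (both classes with at least 2 members).
#' @param seed Integer seed; the same seed reproduces the split.
#' @return A list with corpora `A` and `B`.
#' @export
stratified_half_split <- function(x, seed = 1L) {
  counts <- table(factor(x$label, levels = c("include", "exclude")))
  if (any(counts < 2L)) {
    abort("each class needs at least 2 citations to split")
  }
  .with_seed(seed, {
    in_A <- logical(nrow(x))
    classes <- c("include", "exclude")
    # odd classes alternate which half receives the extra citation so
    # the overall sizes also differ by at most one
    extra_to_A <- runif(1) < 0.5
    for (cls in classes) {
      idx <- which(x$label == cls)
      idx <- sample(idx)
      n <- length(idx)
      kA <- n %/% 2L
      if (n %% 2L == 1L) {
        if (extra_to_A) kA <- kA + 1L
        extra_to_A <- !extra_to_A
      }
      in_A[idx[seq_len(kA)]] <- TRUE
    }
    A <- x[in_A, ]
    B <- x[!in_A, ]
    list(A = validate_corpus(new_corpus(A, review_id(x))),
         B = validate_corpus(new_corpus(B, review_id(x))))
  })
}

#' Fit a feature-set builder on a training corpus
#'
#' Builds one of the five feature sets on the training documents and
#' returns, alongside the training matrix, a projection function that
#' maps held-out documents into the *training* feature space (training
#' vocabulary and idf; training topic-word counts and class medoids for
#' the topic set). This keeps every A|B test independent.
#'
#' @param train A labeled training corpus.
#' @param set One of `"alphabetic"`, `"alphanumeric"`, `"indexing"`,
#'   `"concepts"`, `"topics"`.
#' @param lexicon Concept lexicon tibble (required for `"concepts"`).
#' @param topics Options for the topic set: list with either a fixed
#'   `T`, or `candidates` for [select_T()]; optional `iterations`,
#'   `samples_per_T`, `burnin`, `thin`.
#' @param seed Integer seed (topic fitting).
#' @return A `featurizer`: list with `train` (the training
#'   `feature_matrix`) and `project(corpus)`.
#' @export
fit_features <- function(train, set = .FEATURE_SETS, lexicon = NULL,
                         topics = list(), seed = 1L) {
  set <- match.arg(set)
  docs <- compose_documents(train)
  out <- switch(set,
    alphabetic = {
      fm <- build_alphabetic(train)
      vocab <- feature_names(fm)
      n_train <- nrow(train)
      df <- fm$df[vocab]
      list(train = fm, project = function(newdata) {
        toks <- .alphabetic_tokens(compose_documents(newdata))
        counts <- .count_matrix(toks, newdata$id, vocab = vocab)
        tfidf(feature_matrix(counts, "tf"), df = df, n_docs = n_train)
      })
    },
    alphanumeric = {
      fm <- build_alphanumeric(train)
      vocab <- feature_names(fm)
      n_train <- nrow(train)
      df <- fm$df[vocab]
      list(train = fm, project = function(newdata) {
        toks <- .alphanumeric_tokens(compose_documents(newdata))
        counts <- .count_matrix(toks, newdata$id, vocab = vocab)
        tfidf(feature_matrix(counts, "tf"), df = df, n_docs = n_train)
      })
    },
    indexing = {
      fm <- extract_indexing(train)
      vocab <- feature_names(fm)
      n_train <- nrow(train)
      df <- fm$df[vocab]
      list(train = fm, project = function(newdata) {
        toks <- purrr::map(newdata$indexing, .indexing_features)
        counts <- .count_matrix(toks, newdata$id, vocab = vocab)
        tfidf(feature_matrix(counts, "tf"), df = df, n_docs = n_train)
      })
    },
    concepts = {
      if (is.null(lexicon)) abort("the concepts set needs a lexicon")
      fm <- match_concepts(train, lexicon)
      cols <- feature_names(fm)
      list(train = fm, project = function(newdata) {
        match_concepts(newdata, lexicon, keep_concepts = cols)
      })
    },
    topics = {
      iters <- topics$iterations %||% 200L
      toks <- .alphanumeric_tokens(docs)
      T_use <- topics$T
      if (is.null(T_use)) {
        cand <- topics$candidates %||% c(25L, 50L, 100L)
        sel <- select_T(toks, cand,
                        samples_per_T = topics$samples_per_T %||% 5L,
                        seed = .derive_seed(seed, 11L),
                        burnin = topics$burnin %||% 200L,
                        thin = topics$thin %||% 10L)
        T_use <- sel$best_T
      }
      model <- gibbs_lda(toks, T_use, iterations = iters,
                         seed = .derive_seed(seed, 13L),
                         doc_ids = train$id)
      fm <- topic_feature_matrix(model, labels = train$label)
      medoids <- attr(fm, "medoids")
      list(train = fm, project = function(newdata) {
        toks_new <- .alphanumeric_tokens(compose_documents(newdata))
        dt <- infer_topics(model, toks_new,
                           seed = .derive_seed(seed, 17L),
                           doc_ids = newdata$id)
        topic_feature_matrix(model, doc_topic = dt, medoids = medoids)
      })
    }
  )
  structure(c(out, list(set = set)), class = "featurizer")
}

# align a projected matrix to the columns of a (possibly IG-filtered)
# training matrix
.align_columns <- function(fm, cols) {
  out <- fm
  out$matrix <- fm$matrix[, cols, drop = FALSE]
  out
}

#' Grid specification for complement naive Bayes optimization
#'
#' All combinations of the normalization and smoothing settings; within
#' each cell the optimizer runs `cv_repeats` stratified
#' `cv_folds`-fold cross-validations, so the default 2 x 5 grid with
#' 5 x 2-fold CV performs exactly 100 train/validate iterations.
#'
#' @param normalization_values Logical settings for weight
#'   normalization.
#' @param smoothing_values Additive smoothing settings.
#' @param cv_repeats,cv_folds Cross-validation design (default 5 x 2).
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(normalization_values = c(TRUE, FALSE),
                      smoothing_values = c(0.001, 0.250, 0.500, 0.750, 1.0),
                      cv_repeats = 5L, cv_folds = 2L) {
  structure(list(
    normalization_values = normalization_values,
    smoothing_values = smoothing_values,
    cv_repeats = as.integer(cv_repeats),
    cv_folds = as.integer(cv_folds)
  ), class = "grid_spec")
}

# stratified fold assignment: per class, shuffled ids dealt round-robin
.stratified_folds <- function(labels, k, seed) {
  .with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Optimize complement naive Bayes parameters on a training half
#'
#' For every cell of the grid (a normalization/smoothing pair), runs
#' `cv_repeats` repetitions of stratified `cv_folds`-fold
#' cross-validation on the training corpus and scores the cell by the
#' unweighted mean F3 over its validation folds. Features are rebuilt
#' on each CV-training fold and held-out folds are projected into that
#' space, so the information-gain filter never sees validation labels.
#'
#' @param train A labeled training corpus.
#' @param set Feature set name (see [fit_features()]).
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @param ig_threshold Information-gain threshold in bits (default
#'   0.001); `NULL` disables filtering.
#' @param lexicon,topics Passed to [fit_features()].
#' @return A list with `best` (one-row tibble: `normalization`,
#'   `smoothing`, `mean_f3`), `cells` (per-cell scores) and
#'   `n_iterations` (total train/validate runs).
#' @export
grid_optimize <- function(train, set = "alphabetic", grid = grid_spec(),
                          seed = 1L, ig_threshold = 0.001,
                          lexicon = NULL, topics = list()) {
  cells <- tidyr::expand_grid(
    normalization = grid$normalization_values,
    smoothing = grid$smoothing_values
  )
  fold_scores <- vector("list", grid$cv_repeats * grid$cv_folds)
  n_iter <- 0L
  slot <- 0L
  for (rep_i in seq_len(grid$cv_repeats)) {
    folds <- .stratified_folds(train$label, grid$cv_folds,
                               .derive_seed(seed, 101L, rep_i))
    # stratification keeps both classes in every fold; re-deal if a
    # degenerate draw still produced a single-class fold
    tries <- 0L
    while (any(vapply(seq_len(grid$cv_folds), function(f)
      length(unique(train$label[folds == f])) < 2L, logical(1))) &&
      tries < 10L) {
      tries <- tries + 1L
      folds <- .stratified_folds(train$label, grid$cv_folds,
                                 .derive_seed(seed, 101L, rep_i, tries))
    }
    for (f in seq_len(grid$cv_folds)) {
      cv_train <- train[folds != f, ]
      cv_valid <- train[folds == f, ]
      cv_train <- new_corpus(cv_train, review_id(train))
      cv_valid <- new_corpus(cv_valid, review_id(train))
      fz <- fit_features(cv_train, set, lexicon = lexicon, topics = topics,
                         seed = .derive_seed(seed, 211L, rep_i, f))
      fm_train <- fz$train
      if (!is.null(ig_threshold)) {
        fm_train <- information_gain_filter(fm_train, cv_train$label,
                                            ig_threshold)
      }
      fm_valid <- .align_columns(fz$project(cv_valid),
                                 feature_names(fm_train))
      slot <- slot + 1L
      fold_scores[[slot]] <- purrr::pmap_dfr(cells, function(normalization,
                                                             smoothing) {
        model <- train_cnb(fm_train, cv_train$label,
                           smoothing = smoothing,
                           weight_normalization = normalization)
        preds <- predict_cnb(model, fm_valid)
        res <- evaluate_predictions(preds$label, cv_valid$label)
        tibble::tibble(normalization = normalization, smoothing = smoothing,
                       rep = rep_i, fold = f, f3 = res$f3)
      })
      n_iter <- n_iter + nrow(cells)
    }
  }
  all_scores <- dplyr::bind_rows(fold_scores)
  cell_scores <- all_scores |>
    dplyr::group_by(.data$normalization, .data$smoothing) |>
    dplyr::summarise(mean_f3 = mean(.data$f3), .groups = "drop")
  best <- cell_scores |>
    dplyr::arrange(dplyr::desc(.data$mean_f3)) |>
    dplyr::slice(1L)
  list(best = best, cells = cell_scores, n_iterations = n_iter)
}

#' Run the two-reviewer A|B protocol for one feature set
#'
#' Splits the labeled corpus into stratified halves A and B, then runs
#' two independent tests: `A|B` (optimize and train on B, test on A)
#' and `B|A` (optimize and train on A, test on B). Each direction
#' performs its own grid optimization on its training half; features
#' are built on the training half and held-out citations are projected
#' into that space. Reported metrics are the per-test values and their
#' mean; misclassified citations correspond to discordant decisions
#' between the simulated reviewers.
#'
#' @inheritParams grid_optimize
#' @param x A labeled corpus.
#' @return An `ab_result`: tibble with rows `A|B`, `B|A` and `mean`,
#'   carrying confusion counts, recall, precision, F3, classification
#'   error and second-pass RSB; attributes record the chosen parameters
#'   and baselines.
#' @export
ab_protocol <- function(x, set = "alphabetic", grid = grid_spec(),
                        seed = 1L, ig_threshold = 0.001,
                        lexicon = NULL, topics = list()) {
  halves <- stratified_half_split(x, .derive_seed(seed, 3L))
  run_direction <- function(train, test, name, dir_seed) {
    opt <- grid_optimize(train, set, grid = grid, seed = dir_seed,
                         ig_threshold = ig_threshold, lexicon = lexicon,
                         topics = topics)
    fz <- fit_features(train, set, lexicon = lexicon, topics = topics,
                       seed = .derive_seed(dir_seed, 5L))
    fm_train <- fz$train
    if (!is.null(ig_threshold)) {
      fm_train <- information_gain_filter(fm_train, train$label, ig_threshold)
    }
    model <- train_cnb(fm_train, train$label,
                       smoothing = opt$best$smoothing,
                       weight_normalization = opt$best$normalization)
    fm_test <- .align_columns(fz$project(test), feature_names(fm_train))
    preds <- predict_cnb(model, fm_test)
    res <- evaluate_predictions(preds$label, test$label)
    res$test <- name
    res$normalization <- opt$best$normalization
    res$smoothing <- opt$best$smoothing
    res$n_grid_iterations <- opt$n_iterations
    res$baseline_f3 <- baseline_f3(eligible_fraction(test))
    res
  }
  # A|B: model trained on B, tested on A
  r_ab <- run_direction(halves$B, halves$A, "A|B", .derive_seed(seed, 23L))
  r_ba <- run_direction(halves$A, halves$B, "B|A", .derive_seed(seed, 29L))
  both <- dplyr::bind_rows(r_ab, r_ba)
  mean_row <- both |>
    dplyr::summarise(dplyr::across(
      c("tp", "fp", "tn", "fn", "n", "recall", "precision", "f3",
        "classification_error", "rsb_second_pass", "baseline_f3"), mean))
  mean_row$test <- "mean"
  out <- dplyr::bind_rows(both, mean_row) |>
    dplyr::relocate("test")
  out$feature_set <- set
  out$review <- review_id(x)
  structure(out, class = c("ab_result", class(out)), seed = seed)
}

#' @export
glance.ab_result <- function(x, ...) {
  m <- x[x$test == "mean", ]
  tibble::tibble(
    review = m$review, feature_set = m$feature_set,
    mean_f3 = m$f3, mean_recall = m$recall, mean_precision = m$precision,
    mean_classification_error = m$classification_error,
    rsb_second_pass = m$rsb_second_pass, baseline_f3 = m$baseline_f3
  )
}
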