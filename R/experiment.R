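# End-to-end experiment orchestration: run every selected feature set
# through the A|B protocol, persist metric tables with full provenance,
# and compare feature sets across reviews by Friedman ranks.

#' Declare an end-to-end screening experiment
#'
#' @param corpus A labeled [corpus], or a path to a JSONL corpus.
#' @param feature_sets Subset of
#'   `c("alphabetic", "alphanumeric", "indexing", "concepts", "topics")`.
#' @param lexicon A lexicon tibble or TSV path (required iff
#'   `"concepts"` is selected).
#' @param topics Topic-model options (see [fit_features()]).
#' @param grid A [grid_spec()].
#' @param ig_threshold Information-gain threshold in bits.
#' @param seed Integer seed recorded in all outputs.
#' @param output_dir Optional directory for metric tables and the run
#'   manifest.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(corpus, feature_sets = "alphabetic",
                              lexicon = NULL, topics = list(),
                              grid = grid_spec(), ig_threshold = 0.001,
                              seed = 1L, output_dir = NULL) {
  bad <- setdiff(feature_sets, .FEATURE_SETS)
  if (length(bad)) {
    abort(paste0("unknown feature sets: ", paste(bad, collapse = ", ")))
  }
  if ("concepts" %in% feature_sets && is.null(lexicon)) {
    abort("the concepts feature set requires a lexicon")
  }
  structure(list(
    corpus = corpus, feature_sets = feature_sets, lexicon = lexicon,
    topics = topics, grid = grid, ig_threshold = ig_threshold,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "experiment_config")
}

.config_hash <- function(config) {
  keys <- config[setdiff(names(config), c("corpus", "output_dir"))]
  .stable_hash(paste(deparse(keys), collapse = ""))
}

#' Run a screening experiment end to end
#'
#' For each selected feature set: build features, filter by information
#' gain, split into stratified halves, grid-optimize the classifier per
#' direction, run the A|B and B|A independent tests and collect
#' per-test and mean metrics (2 independent tests per feature set).
#' When `output_dir` is set, writes `metrics.csv` and a `manifest.json`
#' recording the seed, parameters and config hash.
#'
#' @param config An [experiment_config()].
#' @return A tibble of results: one row per feature set and test
#'   (`A|B`, `B|A`, `mean`) with confusion counts and metric
#'   percentages.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  x <- config$corpus
  if (is.character(x)) x <- read_corpus_jsonl(x)
  if (!all(x$label %in% c("include", "exclude"))) {
    abort("experiment corpus must be fully labeled (include/exclude)")
  }
  lexicon <- config$lexicon
  if (is.character(lexicon)) lexicon <- read_lexicon(lexicon)

  results <- purrr::map(config$feature_sets, function(set) {
    res <- tryCatch(
      ab_protocol(x, set = set, grid = config$grid, seed = config$seed,
                  ig_threshold = config$ig_threshold, lexicon = lexicon,
                  topics = config$topics),
      error = function(e) {
        abort(sprintf("feature set '%s' failed: %s", set,
                      conditionMessage(e)))
      })
    tibble::as_tibble(res)
  })
  out <- dplyr::bind_rows(results) |>
    dplyr::relocate("review", "feature_set", "test")
  out$seed <- config$seed
  out$config_hash <- .config_hash(config)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(config$output_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      review = review_id(x),
      n_citations = nrow(x),
      eligible_fraction = eligible_fraction(x),
      feature_sets = config$feature_sets,
      grid = list(normalization = config$grid$normalization_values,
                  smoothing = config$grid$smoothing_values,
                  cv_repeats = config$grid$cv_repeats,
                  cv_folds = config$grid$cv_folds),
      ig_threshold = config$ig_threshold,
      seed = config$seed,
      config_hash = .config_hash(config)
    ), file.path(config$output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Compare feature sets across reviews by Friedman ranks
#'
#' Takes mean-performance tables from two or more reviews (the
#' `test == "mean"` rows of [run_experiment()] output, or any tibble
#' with columns `review`, `feature_set` and the metrics) and computes
#' one tie-corrected Friedman rank analysis per metric: F3, recall and
#' precision (higher is better) and classification error (lower is
#' better).
#'
#' @param reports A tibble, or list of tibbles, with columns `review`,
#'   `feature_set`, `f3`, `recall`, `precision`,
#'   `classification_error`. Every review must cover the same feature
#'   sets.
#' @return A named list of [friedman_ranks()] `rank_table`s:
#'   `f3`, `recall`, `precision`, `classification_error`.
#' @export
compare_feature_sets <- function(reports) {
  if (is.data.frame(reports)) reports <- list(reports)
  tbl <- dplyr::bind_rows(reports)
  if ("test" %in% names(tbl)) tbl <- tbl[tbl$test %in% "mean", ]
  needed <- c("review", "feature_set", "f3", "recall", "precision",
              "classification_error")
  missing <- setdiff(needed, names(tbl))
  if (length(missing)) {
    abort(paste0("reports lack columns: ", paste(missing, collapse = ", ")))
  }
  sets_by_review <- tapply(tbl$feature_set, tbl$review,
                           function(s) paste(sort(s), collapse = "|"))
  if (length(unique(sets_by_review)) != 1L) {
    abort("reviews cover different feature-set columns")
  }
  if (length(unique(tbl$review)) < 2L) {
    abort("need at least two reviews to rank across")
  }
  to_matrix <- function(metric) {
    wide <- tidyr::pivot_wider(tbl[, c("review", "feature_set", metric)],
                               names_from = "feature_set",
                               values_from = dplyr::all_of(metric))
    m <- as.matrix(wide[, -1L, drop = FALSE])
    rownames(m) <- wide$review
    m
  }
  list(
    f3 = friedman_ranks(to_matrix("f3"), "higher_better"),
    recall = friedman_ranks(to_matrix("recall"), "higher_better"),
    precision = friedman_ranks(to_matrix("precision"), "higher_better"),
    classification_error = friedman_ranks(to_matrix("classification_error"),
                                          "lower_better")
  )
}
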