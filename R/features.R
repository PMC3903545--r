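# Feature matrices: sparse document-by-feature tables of weights, plus
# the builders for the alphabetic, alphanumeric+, indexing and
# review-concept feature sets, tf-idf weighting and the information-gain
# filter.

#' Construct a feature matrix
#'
#' A thin S3 wrapper around a sparse document-by-feature matrix carrying
#' the weighting scheme used (`"tf"`, `"tfidf"` or `"topic"`) and, for
#' schemes that need it at projection time, the training document
#' frequencies.
#'
#' @param mat A base or `Matrix` sparse matrix with document ids as row
#'   names and feature names as column names.
#' @param scheme Weighting scheme label.
#' @param df Optional named integer vector of training document
#'   frequencies per feature.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(mat, scheme = c("tf", "tfidf", "topic"),
                           df = NULL) {
  scheme <- match.arg(scheme)
  mat <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (anyDuplicated(colnames(mat))) abort("feature names must be unique")
  structure(list(matrix = mat, scheme = scheme, df = df),
            class = "feature_matrix")
}

#' @exportS3Method base::print
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d docs x %d features, scheme = %s\n",
              nrow(x$matrix), ncol(x$matrix), x$scheme))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$matrix)

#' Accessors for feature matrices
#' @param x A `feature_matrix`.
#' @return `doc_ids()` the document ids; `feature_names()` the feature
#'   names.
#' @export
doc_ids <- function(x) rownames(x$matrix)

#' @rdname doc_ids
#' @export
feature_names <- function(x) colnames(x$matrix)

#' @exportS3Method base::as.matrix
as.matrix.feature_matrix <- function(x, ...) as.matrix(x$matrix)

# build a sparse count matrix from a list of token vectors; column order
# is the sorted vocabulary so identical corpora give identical matrices
.count_matrix <- function(token_lists, doc_ids, vocab = NULL) {
  if (is.null(vocab)) {
    vocab <- sort(unique(unlist(token_lists, use.names = FALSE)))
  }
  lens <- lengths(token_lists)
  all_tokens <- unlist(token_lists, use.names = FALSE)
  j <- match(all_tokens, vocab)
  keep <- !is.na(j)
  i <- rep.int(seq_along(token_lists), lens)[keep]
  m <- Matrix::sparseMatrix(
    i = i, j = j[keep], x = 1,
    dims = c(length(token_lists), length(vocab)),
    dimnames = list(doc_ids, vocab)
  )
  methods::as(m, "CsparseMatrix")
}

.doc_freq <- function(mat) {
  setNames(Matrix::colSums(mat > 0), colnames(mat))
}

#' Apply tf-idf weighting to a count matrix
#'
#' `weight(d, t) = tf(d, t) * log10(N / df(t))`, where `N` is the number
#' of documents and `df(t)` the number of documents containing feature
#' `t`. When `df` is supplied (projection of held-out documents into a
#' training space) the training `N` and `df` are used instead.
#'
#' @param x A `feature_matrix` with raw counts (`scheme = "tf"`).
#' @param df Optional named training document frequencies.
#' @param n_docs Optional training document count accompanying `df`.
#' @return A `feature_matrix` with `scheme = "tfidf"`.
#' @export
tfidf <- function(x, df = NULL, n_docs = NULL) {
  stopifnot(inherits(x, "feature_matrix"))
  if (x$scheme != "tf") abort("tfidf() expects a raw-count matrix")
  mat <- x$matrix
  if (is.null(df)) {
    df <- .doc_freq(mat)
    n_docs <- nrow(mat)
  }
  idf <- log10(n_docs / pmax(df[colnames(mat)], 1))
  idf[!is.finite(idf)] <- 0
  out <- mat %*% Matrix::Diagonal(x = as.numeric(idf))
  dimnames(out) <- dimnames(mat)
  feature_matrix(out, "tfidf", df = df)
}

# drop all-zero columns (pruned vocabulary)
.drop_empty_cols <- function(mat) {
  keep <- Matrix::colSums(abs(mat)) > 0
  mat[, keep, drop = FALSE]
}

.alphabetic_tokens <- function(docs) {
  body <- tokenize_alphabetic(docs$text)
  if (!is.list(body)) body <- list(body)
  title_tok <- tokenize_alphabetic(docs$title)
  if (!is.list(title_tok)) title_tok <- list(title_tok)
  purrr::map2(body, title_tok, ~ c(.x, title_bigrams(.y)))
}

.alphanumeric_tokens <- function(docs) {
  body_alpha <- tokenize_alphabetic(docs$text, stem = FALSE)
  if (!is.list(body_alpha)) body_alpha <- list(body_alpha)
  body_alnum <- tokenize_alphanumeric(docs$text)
  if (!is.list(body_alnum)) body_alnum <- list(body_alnum)
  title_tok <- tokenize_alphanumeric(docs$title)
  if (!is.list(title_tok)) title_tok <- list(title_tok)
  journal <- ifelse(nzchar(docs$journal),
                    gsub("\\s+", "_", tolower(trimws(docs$journal))), NA)
  purrr::pmap(list(body_alpha, body_alnum, title_tok, journal),
              function(a, b, t, j) {
    # tokens shared between the two tokenizers (plain words) are kept
    # once, from the alphabetic pass; the alphanumeric pass contributes
    # only tokens with internal digits or punctuation
    c(a, b[grepl("[^a-z]", b)], title_bigrams(t), if (!is.na(j)) j)
  })
}

#' Build the alphabetic feature set
#'
#' Porter-stemmed unigrams from the composed documents (title written
#' twice) plus underscore-joined bigrams from the single title. Features
#' occurring in fewer than `min_df` citations are pruned; weights are
#' tf-idf.
#'
#' @param x A corpus.
#' @param min_df Minimum document frequency (default 3).
#' @return A `feature_matrix` with `scheme = "tfidf"`.
#' @export
build_alphabetic <- function(x, min_df = 3L) {
  if (nrow(x) < min_df) {
    abort(sprintf("corpus has %d documents; pruning at df >= %d is undefined",
                  nrow(x), min_df))
  }
  docs <- compose_documents(x)
  counts <- .count_matrix(.alphabetic_tokens(docs), docs$id)
  df <- .doc_freq(counts)
  counts <- counts[, df >= min_df, drop = FALSE]
  tfidf(feature_matrix(counts, "tf"))
}

#' Build the alphanumeric+ feature set
#'
#' The union of unstemmed alphabetic tokens, tokens with embedded
#' numbers or punctuation (`h3n2`, `case-control`, `2004-2005`), title
#' bigrams and one journal-name feature per citation (whitespace
#' replaced by underscores). No document-frequency pruning; tf-idf
#' weights.
#'
#' @param x A corpus.
#' @return A `feature_matrix` with `scheme = "tfidf"`.
#' @export
build_alphanumeric <- function(x) {
  docs <- compose_documents(x)
  counts <- .count_matrix(.alphanumeric_tokens(docs), docs$id)
  tfidf(feature_matrix(counts, "tf"))
}

# indexing terms -> features: "Descriptor/qualifier1/qualifier2" yields
# the descriptor (major-topic '*' kept as printed) and each qualifier
.indexing_features <- function(terms) {
  if (!length(terms)) return(character(0))
  unlist(lapply(terms, function(term) {
    parts <- trimws(strsplit(term, "/", fixed = TRUE)[[1L]])
    parts[nzchar(parts)]
  }), use.names = FALSE)
}

#' Build the indexing-term feature set
#'
#' One feature per distinct controlled-vocabulary term
#' (MeSH/Emtree-style). Terms of the form `Descriptor/qualifier` are
#' split so both the descriptor and the qualifier become features;
#' major-topic asterisks are preserved as printed. Weights are tf-idf.
#'
#' @param x A corpus.
#' @return A `feature_matrix` with `scheme = "tfidf"`.
#' @export
extract_indexing <- function(x) {
  tokens <- purrr::map(x$indexing, .indexing_features)
  counts <- .count_matrix(tokens, x$id)
  tfidf(feature_matrix(counts, "tf"))
}

#' Read a concept lexicon
#'
#' Tab-separated file with two columns: surface term and concept name.
#' Matching is case-insensitive, so terms are stored lowercase.
#'
#' @param path File path.
#' @return A tibble with columns `term` and `concept`.
#' @export
read_lexicon <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           quote = "", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) abort("lexicon must have two tab-separated columns")
  lex <- tibble::tibble(term = tolower(trimws(raw[[1L]])),
                        concept = trimws(raw[[2L]]))
  lex[nzchar(lex$term), ]
}

# longest non-overlapping case-insensitive matching of lexicon terms in
# one line; returns concept names, one per accepted match
.match_line <- function(line, lex_terms, lex_concepts) {
  occupied <- rep(FALSE, nchar(line))
  hits <- character(0)
  ord <- order(nchar(lex_terms), decreasing = TRUE)
  for (k in ord) {
    pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                              lex_terms[k]), "\\b")
    m <- gregexpr(pat, line, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    lens <- attr(m, "match.length")
    for (j in seq_along(m)) {
      span <- m[j]:(m[j] + lens[j] - 1L)
      if (!any(occupied[span])) {
        occupied[span] <- TRUE
        hits <- c(hits, lex_concepts[k])
      }
    }
  }
  hits
}

#' Build the review-concept feature set by lexicon matching
#'
#' Documents are split on lines; within each line, surface terms from
#' the lexicon are matched case-insensitively with a longest-match,
#' non-overlapping rule (so `influenza vaccination` beats `vaccination`
#' on the same span). Weights are concept term frequencies; concepts
#' never matched are pruned.
#'
#' @param x A corpus.
#' @param lexicon A tibble from [read_lexicon()] (columns `term`,
#'   `concept`).
#' @param keep_concepts Optional character vector fixing the concept
#'   columns (used when projecting held-out documents into a training
#'   feature space).
#' @return A `feature_matrix` with `scheme = "tf"` (concept counts).
#' @export
match_concepts <- function(x, lexicon, keep_concepts = NULL) {
  if (is.null(lexicon) || !nrow(lexicon)) abort("concept lexicon is empty")
  docs <- compose_documents(x)
  lex_terms <- tolower(lexicon$term)
  lex_concepts <- lexicon$concept
  hits <- purrr::map(docs$text, function(text) {
    lines <- tolower(strsplit(text, "\n", fixed = TRUE)[[1L]])
    unlist(lapply(lines[nzchar(lines)], .match_line,
                  lex_terms = lex_terms, lex_concepts = lex_concepts),
           use.names = FALSE)
  })
  vocab <- if (is.null(keep_concepts)) sort(unique(lex_concepts)) else keep_concepts
  counts <- .count_matrix(hits, docs$id, vocab = vocab)
  if (is.null(keep_concepts)) counts <- .drop_empty_cols(counts)
  feature_matrix(counts, "tf")
}

#' Information gain of each feature for the include/exclude label
#'
#' Mutual information, in bits, between a feature's presence (weight
#' greater than zero) and the class label:
#' `IG(t) = H(label) - H(label | t present/absent)`.
#'
#' @param x A `feature_matrix`.
#' @param labels Character vector over `include`/`exclude`, aligned with
#'   the documents of `x`.
#' @return A named numeric vector of information gains, in column order.
#' @export
information_gain <- function(x, labels) {
  stopifnot(inherits(x, "feature_matrix"))
  if (length(labels) != nrow(x$matrix)) {
    abort("labels must align with the documents of the matrix")
  }
  if (length(unique(labels)) < 2L) {
    abort("information gain needs both classes present")
  }
  pos <- labels == "include"
  n <- length(labels)
  n1 <- sum(pos)
  present <- x$matrix > 0
  np <- Matrix::colSums(present)              # docs with feature
  np1 <- Matrix::colSums(present[pos, , drop = FALSE])  # with feature, include
  na_ <- n - np
  na1 <- n1 - np1

  h <- function(k, m) {
    # entropy (bits) of a two-class split of m docs with k positives
    p <- k / m
    q <- 1 - p
    out <- numeric(length(k))
    nz <- m > 0
    t1 <- ifelse(p > 0, -p * log2(p), 0)
    t2 <- ifelse(q > 0, -q * log2(q), 0)
    out[nz] <- (t1 + t2)[nz]
    out
  }
  h_label <- h(n1, n)
  h_cond <- (np / n) * h(np1, pmax(np, 1)) + (na_ / n) * h(na1, pmax(na_, 1))
  ig <- h_label - h_cond
  ig[ig < 0] <- 0  # clip tiny negative rounding
  setNames(as.numeric(ig), colnames(x$matrix))
}

#' Filter features by information gain
#'
#' Removes columns whose information gain for the label is below
#' `threshold` bits, preserving column order. The filter is idempotent.
#'
#' @inheritParams information_gain
#' @param threshold Minimum information gain in bits (default 0.001).
#' @return The filtered `feature_matrix`.
#' @export
information_gain_filter <- function(x, labels, threshold = 0.001) {
  ig <- information_gain(x, labels)
  keep <- ig >= threshold
  out <- x
  out$matrix <- x$matrix[, keep, drop = FALSE]
  if (!is.null(out$df)) out$df <- out$df[colnames(out$matrix)]
  out
}

#' Write or read a sparse feature matrix as text triplets
#'
#' Plain-text interchange: a tab-separated file of
#' `doc_id, feature, weight` triplets with a `#scheme=` header line.
#'
#' @param x A `feature_matrix`.
#' @param path File path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns a `feature_matrix`.
#' @export
write_feature_matrix <- function(x, path) {
  trip <- Matrix::summary(x$matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#scheme=", x$scheme), con)
  writeLines(paste0("#docs=", paste(rownames(x$matrix), collapse = "\t")), con)
  writeLines(paste0("#features=", paste(colnames(x$matrix), collapse = "\t")), con)
  if (nrow(trip)) {
    writeLines(sprintf("%s\t%s\t%.10g",
                       rownames(x$matrix)[trip$i],
                       colnames(x$matrix)[trip$j], trip$x), con)
  }
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  scheme <- sub("^#scheme=", "", lines[1L])
  docs <- strsplit(sub("^#docs=", "", lines[2L]), "\t", fixed = TRUE)[[1L]]
  feats <- strsplit(sub("^#features=", "", lines[3L]), "\t", fixed = TRUE)[[1L]]
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    i <- match(vapply(parts, `[[`, "", 1L), docs)
    j <- match(vapply(parts, `[[`, "", 2L), feats)
    v <- as.numeric(vapply(parts, `[[`, "", 3L))
  } else {
    i <- j <- integer(0); v <- numeric(0)
  }
  m <- Matrix::sparseMatrix(i = i, j = j, x = v,
                            dims = c(length(docs), length(feats)),
                            dimnames = list(docs, feats))
  feature_matrix(m, scheme)
}
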