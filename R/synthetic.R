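# Synthetic labeled citation corpora and LDA corpora with known
# structure, so every pipeline stage is testable without downloads.
# Defaults emulate the shape of real screening datasets: a few percent
# of citations eligible, Zipf-distributed vocabulary, a fraction of
# abstracts missing.

#' Configuration for the synthetic screening-corpus generator
#'
#' @param n_docs Number of citations.
#' @param eligible_rate Fraction provisionally eligible (strictly
#'   between 0 and 0.5); 0.058 is the median eligible rate of typical
#'   screening datasets.
#' @param vocab_size Background vocabulary size.
#' @param n_discriminative_terms Number of planted class-discriminative
#'   terms.
#' @param effect Odds multiplier for discriminative terms in include
#'   documents (1 = no signal).
#' @param missing_abstract_rate Fraction of abstracts blanked (default
#'   0.10, inside the 4-24 percent range seen in real screening data).
#' @param indexing_vocab Controlled-vocabulary terms to draw indexing
#'   from.
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_docs = 2000L, eligible_rate = 0.058,
                             vocab_size = 2000L,
                             n_discriminative_terms = 25L,
                             effect = 20,
                             missing_abstract_rate = 0.10,
                             indexing_vocab = NULL,
                             seed = 1L) {
  if (eligible_rate <= 0 || eligible_rate >= 0.5) {
    abort("eligible_rate must be in (0, 0.5)")
  }
  if (effect < 1) abort("effect must be at least 1")
  if (missing_abstract_rate < 0 || missing_abstract_rate > 1) {
    abort("missing_abstract_rate must be in [0, 1]")
  }
  if (n_discriminative_terms > vocab_size) {
    abort("vocabulary smaller than the discriminative term set")
  }
  if (is.null(indexing_vocab)) {
    indexing_vocab <- sprintf("Descriptor %02d", 1:20)
  }
  structure(list(
    n_docs = as.integer(n_docs), eligible_rate = eligible_rate,
    vocab_size = as.integer(vocab_size),
    n_discriminative_terms = as.integer(n_discriminative_terms),
    effect = effect, missing_abstract_rate = missing_abstract_rate,
    indexing_vocab = indexing_vocab, seed = as.integer(seed)
  ), class = "generator_config")
}

# deterministic pronounceable pseudo-words (three CV syllables, 6
# letters) so both tokenizers -- including the alphabetic one, which
# splits on digits -- see the full vocabulary
.syn_vocab <- function(n) {
  cons <- c("b", "c", "d", "f", "g", "h", "j", "k", "l", "m", "n", "p",
            "q", "r", "s", "t", "v", "w", "x", "z")
  vow <- c("a", "e", "i", "o", "u")
  syll <- function(i) paste0(cons[(i %% 20L) + 1L],
                             vow[((i %/% 20L) %% 5L) + 1L])
  idx <- seq_len(n) - 1L
  paste0(syll(idx %% 100L), syll((idx %/% 100L) %% 100L),
         syll(idx %/% 10000L))
}

.SYN_JOURNALS <- c(
  "Journal of Synthetic Evidence", "Archives of Simulated Medicine",
  "Annals of Generated Research", "Synthetic Reviews Quarterly"
)

#' Generate a labeled synthetic screening corpus
#'
#' Titles (5-15 tokens) and abstracts (50-250 tokens) are drawn from a
#' Zipf-distributed background multinomial over words `w0001`,
#' `w0002`, ...; in include documents the planted discriminative terms
#' have their sampling odds multiplied by `effect`. Indexing terms are
#' drawn from `indexing_vocab` with class-dependent rates, abstracts
#' are blanked at `missing_abstract_rate`, and the include count is
#' exactly `round(eligible_rate * n_docs)`. The planted terms are
#' recorded in the `ground_truth` attribute.
#'
#' @param config A [generator_config()].
#' @return A labeled [corpus] with a `ground_truth` attribute (list
#'   with `discriminative_terms`).
#' @export
generate_screening_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  .with_seed(config$seed, {
    V <- config$vocab_size
    vocab <- .syn_vocab(V)
    base_p <- (1 / seq_len(V))  # Zipf exponent 1
    base_p <- base_p / sum(base_p)
    # plant the discriminative terms in the mid-frequency range so they
    # are common enough to survive df pruning
    disc_idx <- seq(from = max(2L, V %/% 20L), by = 3L,
                    length.out = config$n_discriminative_terms)
    disc_idx <- disc_idx[disc_idx <= V]
    disc_terms <- vocab[disc_idx]
    inc_p <- base_p
    inc_p[disc_idx] <- inc_p[disc_idx] * config$effect
    inc_p <- inc_p / sum(inc_p)

    n <- config$n_docs
    n_inc <- as.integer(round(config$eligible_rate * n))
    labels <- rep("exclude", n)
    labels[sample.int(n, n_inc)] <- "include"

    draw_tokens <- function(len, p) vocab[sample.int(V, len, replace = TRUE,
                                                     prob = p)]
    title_len <- sample(5:15, n, replace = TRUE)
    abs_len <- sample(50:250, n, replace = TRUE)
    titles <- character(n)
    abstracts <- character(n)
    indexing <- vector("list", n)
    inc_idx_rate <- 0.35
    exc_idx_rate <- 0.15
    n_index_vocab <- length(config$indexing_vocab)
    for (i in seq_len(n)) {
      p <- if (labels[i] == "include") inc_p else base_p
      titles[i] <- paste(draw_tokens(title_len[i], p), collapse = " ")
      abstracts[i] <- paste(draw_tokens(abs_len[i], p), collapse = " ")
      rate <- if (labels[i] == "include") inc_idx_rate else exc_idx_rate
      keep <- runif(n_index_vocab) < rate
      indexing[[i]] <- config$indexing_vocab[keep]
    }
    blank <- runif(n) < config$missing_abstract_rate
    abstracts[blank] <- ""
    out <- corpus(
      id = sprintf("syn%05d", seq_len(n)),
      title = titles,
      abstract = abstracts,
      journal = sample(.SYN_JOURNALS, n, replace = TRUE),
      indexing = indexing,
      label = labels,
      review_id = "synthetic"
    )
    attr(out, "ground_truth") <- list(discriminative_terms = disc_terms)
    out
  })
}

#' Generate a corpus from the LDA generative process
#'
#' Standard LDA generation: topic-word distributions drawn from
#' `Dirichlet(beta)`, per-document topic mixtures from
#' `Dirichlet(alpha)`, tokens by sampling a topic then a word. Returns
#' the ground-truth distributions for recovery checks.
#'
#' @param T_true Number of topics (at least 1).
#' @param n_docs,doc_len Corpus dimensions.
#' @param alpha,beta Dirichlet hyperparameters (defaults `50/T_true`
#'   and 0.1, the fitting defaults).
#' @param vocab_size Vocabulary size.
#' @param seed Integer seed.
#' @return A list: `docs` (list of token vectors), `topic_word` (the
#'   true T x V distributions), `doc_topic` (true mixtures), `vocab`.
#' @export
generate_lda_corpus <- function(T_true, n_docs = 200L, doc_len = 100L,
                                alpha = 50 / T_true, beta = 0.1,
                                vocab_size = 100L, seed = 1L) {
  if (T_true < 1L) abort("T_true must be at least 1")
  .with_seed(seed, {
    V <- vocab_size
    vocab <- sprintf("w%04d", seq_len(V))
    rdirichlet <- function(k, a) {
      g <- matrix(rgamma(k * length(a), shape = a), nrow = k, byrow = TRUE)
      g / rowSums(g)
    }
    topic_word <- rdirichlet(T_true, rep(beta, V))
    doc_topic <- rdirichlet(n_docs, rep(alpha, T_true))
    docs <- vector("list", n_docs)
    for (d in seq_len(n_docs)) {
      z <- sample.int(T_true, doc_len, replace = TRUE,
                      prob = doc_topic[d, ])
      nz <- tabulate(z, T_true)
      w <- integer(0)
      for (t in which(nz > 0L)) {
        counts <- rmultinom(1L, nz[t], topic_word[t, ])[, 1L]
        w <- c(w, rep.int(which(counts > 0L), counts[counts > 0L]))
      }
      docs[[d]] <- vocab[sample(w)]  # shuffle token order within the doc
    }
    list(docs = docs, topic_word = topic_word, doc_topic = doc_topic,
         vocab = vocab)
  })
}
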