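# LDA topic features: collapsed Gibbs fitting, harmonic-mean selection
# of the topic count, class medoids and symmetric KL-divergence features.

#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Latent Dirichlet Allocation over tokenized documents with symmetric
#' Dirichlet priors: document-topic hyperparameter `alpha = 50/T` and
#' topic-word hyperparameter `beta = 0.1` by default. Each Gibbs update
#' samples a token's topic from
#' `P(z_i = t | z_-i, w) ~ (n_{t,w_i} + beta) / (n_t + V beta) * (n_{d,t} + alpha)`,
#' and the reported document-topic distributions are
#' `(n_{d,t} + alpha) / (n_d + T alpha)`.
#'
#' @param docs List of character vectors, one tokenized document each
#'   (alphanumeric+ tokens in the screening pipeline).
#' @param T Number of topics (at least 1).
#' @param iterations Gibbs sweeps after which the state is read out.
#' @param seed Integer seed; fixed seed gives bit-identical assignments.
#' @param alpha,beta Dirichlet hyperparameters.
#' @param vocab Optional fixed vocabulary (tokens outside it are
#'   dropped); defaults to the sorted corpus vocabulary.
#' @param doc_ids Optional document ids.
#' @return A `topic_model` object: topic counts, hyperparameters,
#'   `topic_word` count matrix, `doc_topic` probability matrix, token
#'   assignments `z` and the seed.
#' @export
gibbs_lda <- function(docs, T, iterations = 200, seed = 1L,
                      alpha = 50 / T, beta = 0.1, vocab = NULL,
                      doc_ids = NULL) {
  if (T < 1L) abort("T must be at least 1")
  if (is.null(doc_ids)) doc_ids <- as.character(seq_along(docs))
  if (is.null(vocab)) vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  ids <- lapply(docs, function(tok) {
    m <- match(tok, vocab)
    as.integer(m[!is.na(m)] - 1L)
  })
  empty <- lengths(ids) == 0L
  if (any(empty)) {
    warn(sprintf("%d empty document(s) skipped in LDA fit", sum(empty)))
  }
  total_tokens <- sum(lengths(ids))
  if (total_tokens > 0L && T > total_tokens) {
    abort("T exceeds the total token count")
  }
  fit <- cpp_gibbs_lda(ids[!empty], length(vocab), as.integer(T),
                       alpha, beta, as.integer(iterations), 0L, 1L,
                       as.integer(seed))
  ndk <- matrix(0L, nrow = length(docs), ncol = T)
  ndk[!empty, ] <- fit$doc_topic_counts
  nd <- rowSums(ndk)
  doc_topic <- (ndk + alpha) / (nd + T * alpha)
  dimnames(doc_topic) <- list(doc_ids, .topic_names(T))
  z <- vector("list", length(docs))
  z[!empty] <- lapply(fit$z, function(v) v + 1L)
  structure(list(
    T = as.integer(T), alpha = alpha, beta = beta, vocab = vocab,
    topic_word = fit$topic_word, topic_totals = fit$topic_totals,
    doc_topic = doc_topic, z = z, doc_ids = doc_ids,
    seed = as.integer(seed), iterations = as.integer(iterations)
  ), class = "topic_model")
}

.topic_names <- function(T) sprintf("topic_%05d", seq_len(T))

#' @exportS3Method base::print
print.topic_model <- function(x, ...) {
  cat(sprintf("<topic_model> T = %d, V = %d, %d docs (alpha = %.4g, beta = %.3g)\n",
              x$T, length(x$vocab), nrow(x$doc_topic), x$alpha, x$beta))
  invisible(x)
}

#' Log-likelihood of the words given the topic assignments
#'
#' `log P(w | z, T)`, the product over topics of Dirichlet-multinomial
#' terms:
#' `sum_t [ log G(V b) - V log G(b) + sum_v log G(n_tv + b) - log G(n_t + V b) ]`
#' with `G` the gamma function. This is the quantity whose harmonic mean
#' over posterior samples estimates `P(w | T)`.
#'
#' @param model A `topic_model`.
#' @return The log-likelihood (0 for an empty corpus).
#' @export
log_p_w_given_zT <- function(model) {
  nkw <- model$topic_word
  V <- ncol(nkw)
  if (V == 0L || sum(nkw) == 0L) return(0)
  beta <- model$beta
  nk <- rowSums(nkw)
  sum(lgamma(V * beta) - V * lgamma(beta) +
        rowSums(lgamma(nkw + beta)) - lgamma(nk + V * beta))
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Select the number of topics by harmonic-mean likelihood
#'
#' For each candidate `T`, draws post-burn-in Gibbs samples of the
#' assignments and approximates the marginal likelihood by the harmonic
#' mean of the per-sample likelihoods:
#' `log P(w|T) ~ log S - logsumexp_s( -log P(w | z_s, T) )`.
#' The best `T` maximizes this estimate.
#'
#' @param docs List of tokenized documents.
#' @param candidate_Ts Integer vector of at least two candidate topic
#'   counts (a repeated candidate is scored once per occurrence).
#' @param samples_per_T Number of post-burn-in samples (at least 2).
#' @param seed Integer seed.
#' @param burnin Burn-in sweeps before sampling (default 200).
#' @param thin Sweeps between retained samples (default 10).
#' @param beta Topic-word hyperparameter; `alpha` is `50/T` per
#'   candidate.
#' @return A list with `best_T` and a tibble `scores` (columns `T`,
#'   `log_p_w`, `max_sample_loglik`, `n_samples`).
#' @export
select_T <- function(docs, candidate_Ts, samples_per_T = 5L, seed = 1L,
                     burnin = 200L, thin = 10L, beta = 0.1) {
  if (length(candidate_Ts) < 2L) abort("need at least two candidate T values")
  if (samples_per_T < 2L) abort("samples_per_T must be at least 2")
  vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  ids <- lapply(docs, function(tok) {
    m <- match(tok, vocab)
    as.integer(m[!is.na(m)] - 1L)
  })
  ids <- ids[lengths(ids) > 0L]
  scores <- purrr::map_dfr(seq_along(candidate_Ts), function(k) {
    T <- as.integer(candidate_Ts[k])
    sub_seed <- (as.integer(seed) + 7919L * T) %% .Machine$integer.max
    fit <- cpp_gibbs_lda(ids, length(vocab), T, 50 / T, beta,
                         as.integer(burnin), as.integer(samples_per_T),
                         as.integer(thin), sub_seed)
    ll <- fit$sample_loglik
    tibble::tibble(
      T = T,
      log_p_w = log(length(ll)) - .logsumexp(-ll),
      max_sample_loglik = max(ll),
      n_samples = length(ll)
    )
  })
  list(best_T = scores$T[which.max(scores$log_p_w)], scores = scores)
}

#' Per-class medoid of document-topic distributions
#'
#' The per-topic median across the class's documents, smoothed by a
#' small epsilon and renormalized to sum to one (medians of
#' distributions need not themselves sum to one).
#'
#' @param doc_topic Matrix of document-topic probabilities.
#' @param labels Character vector aligned with the rows.
#' @param class The class to summarize (`"include"` or `"exclude"`).
#' @param eps Smoothing constant (default 1e-10).
#' @return A probability vector over topics with class attribute
#'   recorded.
#' @export
class_medoid <- function(doc_topic, labels, class, eps = 1e-10) {
  rows <- labels == class
  if (!any(rows)) abort(sprintf("no documents labeled %s", class))
  med <- apply(doc_topic[rows, , drop = FALSE], 2L, median)
  med <- med + eps
  med <- med / sum(med)
  structure(med, class_label = class)
}

#' Symmetric Kullback-Leibler divergence
#'
#' The mean of the two directed divergences,
#' `0.5 * (KL(p || q) + KL(q || p))`, with logs base 2 by default. Both
#' inputs must be strictly positive (epsilon-smoothed upstream).
#'
#' @param p,q Probability vectors of equal length.
#' @param base Logarithm base (default 2).
#' @return A nonnegative divergence; 0 iff `p == q`.
#' @export
symmetric_kl <- function(p, q, base = 2) {
  if (length(p) != length(q)) abort("p and q must have the same length")
  lg <- function(x) log(x, base = base)
  0.5 * (sum(p * lg(p / q)) + sum(q * lg(q / p)))
}

#' Infer document-topic distributions for held-out documents
#'
#' Gibbs sampling of the new documents' token assignments with the
#' trained topic-word counts held fixed, then the usual smoothed
#' read-out of document-topic probabilities.
#'
#' @param model A fitted `topic_model`.
#' @param docs List of tokenized held-out documents.
#' @param iterations Sampling sweeps (default 50).
#' @param seed Integer seed.
#' @param doc_ids Optional document ids.
#' @return A document-topic probability matrix.
#' @export
infer_topics <- function(model, docs, iterations = 50L, seed = 1L,
                         doc_ids = NULL) {
  if (is.null(doc_ids)) doc_ids <- as.character(seq_along(docs))
  ids <- lapply(docs, function(tok) {
    m <- match(tok, model$vocab)
    as.integer(m[!is.na(m)] - 1L)
  })
  ndk <- cpp_infer_heldout(ids, length(model$vocab), model$topic_word,
                           model$topic_totals, model$alpha, model$beta,
                           as.integer(iterations), as.integer(seed))
  nd <- rowSums(ndk)
  out <- (ndk + model$alpha) / (nd + model$T * model$alpha)
  dimnames(out) <- list(doc_ids, .topic_names(model$T))
  out
}

#' Topic-probability plus divergence feature matrix
#'
#' Per document: the `T` topic probabilities and two symmetric
#' KL-divergence features, the distances to the include-class and
#' exclude-class medoids (`include_divergence`, `exclude_divergence`),
#' for `T + 2` features in total.
#'
#' @param model A fitted `topic_model`.
#' @param labels Labels (`include`/`exclude`) aligned with the model's
#'   training documents; used to compute the class medoids.
#' @param doc_topic Optional document-topic matrix to featurize (e.g.
#'   held-out documents from [infer_topics()]); defaults to the model's
#'   training distributions.
#' @param medoids Optional precomputed list with elements `include` and
#'   `exclude` (training medoids reused for test documents).
#' @param eps Smoothing constant applied before divergence computation.
#' @return A `feature_matrix` with `scheme = "topic"`.
#' @export
topic_feature_matrix <- function(model, labels = NULL, doc_topic = NULL,
                                 medoids = NULL, eps = 1e-10) {
  if (is.null(doc_topic)) doc_topic <- model$doc_topic
  if (is.null(medoids)) {
    if (is.null(labels)) abort("labels are required to compute class medoids")
    if (!all(c("include", "exclude") %in% labels)) {
      abort("training corpus must contain both include and exclude documents")
    }
    medoids <- list(
      include = class_medoid(model$doc_topic, labels, "include", eps),
      exclude = class_medoid(model$doc_topic, labels, "exclude", eps)
    )
  }
  smooth <- function(p) {
    p <- p + eps
    p / sum(p)
  }
  div <- t(apply(doc_topic, 1L, function(p) {
    p <- smooth(p)
    c(symmetric_kl(p, medoids$include), symmetric_kl(p, medoids$exclude))
  }))
  out <- cbind(doc_topic, div)
  colnames(out) <- c(.topic_names(model$T),
                     "include_divergence", "exclude_divergence")
  fm <- feature_matrix(out, "topic")
  attr(fm, "medoids") <- medoids
  fm
}
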