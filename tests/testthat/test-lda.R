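test_that("two disjoint vocabularies separate cleanly into two topics", {
  set.seed(101)
  docs <- c(
    replicate(20, sample(c("apple", "banana", "cherry", "grape"), 30,
                         replace = TRUE), simplify = FALSE),
    replicate(20, sample(c("nickel", "cobalt", "copper", "iron"), 30,
                         replace = TRUE), simplify = FALSE)
  )
  model <- gibbs_lda(docs, T = 2, iterations = 100, seed = 42)
  # purity: dominant topic within each vocabulary block
  top_a <- apply(model$doc_topic[1:20, ], 1, which.max)
  top_b <- apply(model$doc_topic[21:40, ], 1, which.max)
  purity <- (max(table(factor(top_a, 1:2))) +
               max(table(factor(top_b, 1:2)))) / 40
  expect_gt(purity, 0.9)
  expect_true(all(abs(rowSums(model$doc_topic) - 1) < 1e-9))
  # token conservation
  expect_equal(sum(model$topic_word), sum(lengths(docs)))
})

test_that("degenerate single-topic model puts all mass on one topic", {
  docs <- list(c("a", "b"), c("b", "c"))
  model <- gibbs_lda(docs, T = 1, iterations = 10, seed = 1)
  expect_true(all(model$doc_topic == 1))
})

test_that("a fixed seed reproduces assignments bit for bit", {
  set.seed(102)
  docs <- replicate(10, sample(letters[1:6], 20, replace = TRUE),
                    simplify = FALSE)
  m1 <- gibbs_lda(docs, T = 3, iterations = 50, seed = 7)
  m2 <- gibbs_lda(docs, T = 3, iterations = 50, seed = 7)
  expect_identical(m1$z, m2$z)
  expect_identical(m1$topic_word, m2$topic_word)
  m3 <- gibbs_lda(docs, T = 3, iterations = 50, seed = 8)
  expect_false(identical(m1$z, m3$z))
})

# direct evaluation of log P(w|z,T) from raw counts, independent of the
# package's implementation
loglik_oracle <- function(model) {
  K <- model$T
  V <- length(model$vocab)
  beta <- model$beta
  total <- 0
  for (k in seq_len(K)) {
    nkv <- model$topic_word[k, ]
    total <- total + lgamma(V * beta) - V * lgamma(beta)
    for (v in seq_len(V)) total <- total + lgamma(nkv[v] + beta)
    total <- total - lgamma(sum(nkv) + V * beta)
  }
  total
}

test_that("corpus likelihood matches a brute-force gamma-product oracle", {
  # empty corpus
  empty <- gibbs_lda(list(), T = 1, iterations = 1, seed = 1,
                     vocab = character(0)) |> suppressWarnings()
  expect_equal(log_p_w_given_zT(empty), 0)
  # scalar case: one token, one topic, V = 1
  one <- gibbs_lda(list("w"), T = 1, iterations = 5, seed = 1)
  expect_equal(log_p_w_given_zT(one),
               log(gamma(0.1)) - log(gamma(0.1)) +
                 log(gamma(1 + 0.1)) - log(gamma(1 + 0.1)) + 0,
               tolerance = 1e-12)
  # small corpus vs the explicit product of Dirichlet-multinomial terms
  docs <- list(c("a", "b", "c"), c("c", "d"), c("e", "a", "a"))
  model <- gibbs_lda(docs, T = 2, iterations = 30, seed = 3)
  expect_equal(log_p_w_given_zT(model), loglik_oracle(model),
               tolerance = 1e-10)
})

test_that("harmonic-mean scores are finite, seed-stable, below max sample", {
  gen <- generate_lda_corpus(T_true = 3, n_docs = 40, doc_len = 40,
                             vocab_size = 30, seed = 9)
  sel1 <- select_T(gen$docs, c(2, 3, 8), samples_per_T = 3, seed = 5,
                   burnin = 30, thin = 5)
  sel2 <- select_T(gen$docs, c(2, 3, 8), samples_per_T = 3, seed = 5,
                   burnin = 30, thin = 5)
  expect_equal(sel1$scores, sel2$scores)
  expect_true(all(is.finite(sel1$scores$log_p_w)))
  expect_true(all(sel1$scores$log_p_w <= sel1$scores$max_sample_loglik))
  # repeating a candidate reproduces its score exactly
  sel3 <- select_T(gen$docs, c(3, 3), samples_per_T = 3, seed = 5,
                   burnin = 30, thin = 5)
  expect_equal(sel3$scores$log_p_w[1], sel3$scores$log_p_w[2])
})

test_that("class medoids are renormalized per-topic medians", {
  # one document: medoid is that distribution
  one <- matrix(c(0.3, 0.7), nrow = 1)
  m1 <- class_medoid(one, "include", "include")
  expect_equal(as.numeric(m1), c(0.3, 0.7), tolerance = 1e-9)
  # two documents: elementwise medians then renormalize
  two <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  m2 <- class_medoid(two, c("include", "include"), "include")
  expect_equal(as.numeric(m2), c(0.5, 0.5), tolerance = 1e-9)
  # three documents: the middle value per topic
  three <- rbind(c(0.1, 0.9), c(0.5, 0.5), c(0.4, 0.6))
  m3 <- class_medoid(three, rep("include", 3), "include")
  mid <- c(0.4, 0.6)
  expect_equal(as.numeric(m3), mid / sum(mid), tolerance = 1e-8)
  expect_error(class_medoid(three, rep("include", 3), "exclude"),
               "no documents")
})

test_that("symmetric KL divergence is a premetric with hand-checkable values", {
  p <- c(0.9, 0.1); q <- c(0.5, 0.5)
  expect_equal(symmetric_kl(p, p), 0)
  expect_equal(symmetric_kl(p, q), symmetric_kl(q, p))
  hand <- 0.5 * ((0.9 * log2(0.9 / 0.5) + 0.1 * log2(0.1 / 0.5)) +
                   (0.5 * log2(0.5 / 0.9) + 0.5 * log2(0.5 / 0.1)))
  expect_equal(symmetric_kl(p, q), hand, tolerance = 1e-12)
  expect_gt(symmetric_kl(p, q), 0)
  expect_error(symmetric_kl(p, c(1)), "length")
})

test_that("topic feature matrices have T + 2 columns with zero self-divergence", {
  set.seed(103)
  docs <- replicate(12, sample(letters[1:8], 25, replace = TRUE),
                    simplify = FALSE)
  labels <- rep(c("include", "exclude"), each = 6)
  model <- gibbs_lda(docs, T = 4, iterations = 40, seed = 2)
  fm <- topic_feature_matrix(model, labels)
  expect_equal(ncol(fm), 4 + 2)
  expect_equal(tail(feature_names(fm), 2),
               c("include_divergence", "exclude_divergence"))
  # a document sitting exactly on the include medoid has zero divergence
  medoids <- attr(fm, "medoids")
  self <- matrix(medoids$include, nrow = 1,
                 dimnames = list("self", NULL))
  fm_self <- topic_feature_matrix(model, doc_topic = self, medoids = medoids)
  expect_lt(as.matrix(fm_self)[1, "include_divergence"], 1e-6)
  expect_error(topic_feature_matrix(model, labels = rep("include", 12)),
               "both include and exclude")
})

test_that("held-out inference yields valid distributions in the trained space", {
  set.seed(104)
  docs <- replicate(16, sample(letters[1:8], 25, replace = TRUE),
                    simplify = FALSE)
  model <- gibbs_lda(docs[1:10], T = 3, iterations = 40, seed = 2)
  dt <- infer_topics(model, docs[11:16], iterations = 25, seed = 4)
  expect_equal(dim(dt), c(6L, 3L))
  expect_true(all(abs(rowSums(dt) - 1) < 1e-9))
  expect_true(all(dt > 0))
})
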