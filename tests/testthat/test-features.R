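make_corpus_from_titles <- function(titles, ...) {
  corpus(id = as.character(seq_along(titles)), title = titles, ...)
}

test_that("alphabetic builder prunes by document frequency", {
  # "malaria" in 2 of 5 docs -> pruned; "vaccine" in all 5 -> kept with
  # idf 0; "influenza" in 4 -> kept
  titles <- c("vaccine influenza", "vaccine influenza", "vaccine influenza",
              "vaccine influenza malaria", "vaccine malaria")
  fm <- build_alphabetic(make_corpus_from_titles(titles))
  expect_false("malaria" %in% feature_names(fm))
  expect_true("vaccin" %in% feature_names(fm))
  expect_true(all(as.matrix(fm)[, "vaccin"] == 0))  # idf = log10(5/5) = 0
  expect_true("influenza" %in% feature_names(fm))
  expect_equal(unname(fm$df[["influenza"]]), 4)
  expect_error(build_alphabetic(make_corpus_from_titles(c("one", "two"))),
               "undefined")
})

test_that("alphanumeric builder keeps singletons and adds journal features", {
  cp <- corpus(
    id = c("1", "2"),
    title = c("An h3n2 case-control study", "Vaccines in 2004–2005"),
    journal = c("New England Journal of Medicine", "")
  )
  fm <- build_alphanumeric(cp)
  expect_true(all(c("h3n2", "case-control", "2004-2005",
                    "new_england_journal_of_medicine") %in%
                    feature_names(fm)))
  # df = 1 features retained (no pruning)
  expect_true("h3n2" %in% feature_names(fm))
  empty <- corpus(character(0), character(0))
  expect_equal(dim(build_alphanumeric(empty)), c(0L, 0L))
})

test_that("indexing features split descriptors and qualifiers", {
  cp <- corpus(
    id = c("1", "2", "3"),
    title = c("t one", "t two", "t three"),
    indexing = list(c("Influenza A virus/(Antigens, Viral)", "*Aged"),
                    c("Case-Control Studies"),
                    c("Case-Control Studies", "Case-Control Studies"))
  )
  fm <- extract_indexing(cp)
  expect_true(all(c("Influenza A virus", "(Antigens, Viral)", "*Aged",
                    "Case-Control Studies") %in% feature_names(fm)))
  expect_equal(unname(fm$df[["Case-Control Studies"]]), 2)
  # citation with no indexing gives a zero row
  cp2 <- corpus(id = c("1", "2"), title = c("a b c", "d e f"),
                indexing = list(c("Aged"), character(0)))
  fm2 <- extract_indexing(cp2)
  expect_equal(sum(as.matrix(fm2)[2, ]), 0)
})

test_that("concept matching is longest-match, non-overlapping, per line", {
  lex <- tiny_lexicon()
  cp <- corpus(id = "1",
               title = "a neutral screening title",
               abstract = "the elderly population of this region")
  fm <- match_concepts(cp, lex)
  m <- as.matrix(fm)
  expect_equal(unname(m[1, "Elderly_population_group"]), 1)
  # "influenza vaccination" wins its span; the later bare "vaccination"
  # still matches separately
  cp2 <- corpus(id = "1", title = "a neutral screening title",
                abstract = "influenza vaccination and more vaccination")
  m2 <- as.matrix(match_concepts(cp2, lex))
  expect_equal(unname(m2[1, "Influenza_vaccination"]), 1)
  expect_equal(unname(m2[1, "Vaccination"]), 1)
  # concepts in the title count twice: composed documents overweight it
  cp3 <- corpus(id = "1", title = "malaria rapid testing")
  m3 <- as.matrix(match_concepts(cp3, lex))
  expect_equal(unname(m3[1, "Malaria"]), 2)
  # concepts never matched are pruned
  expect_false("Malaria" %in% colnames(m))
  # no matches anywhere -> all columns pruned
  none <- match_concepts(corpus(id = "1", title = "nothing relevant"), lex)
  expect_equal(ncol(none), 0L)
  expect_error(match_concepts(cp, tiny_lexicon()[0, ]), "empty")
})

test_that("tf-idf uses log10(N/df) with raw term frequency", {
  # N = 10, df = 1, tf = 2 -> weight 2; term in every doc -> weight 0
  toks <- c(list(c("rare", "rare", "common")),
            replicate(9, "common", simplify = FALSE))
  counts <- screenburden:::.count_matrix(toks, as.character(1:10))
  fm <- tfidf(feature_matrix(counts, "tf"))
  m <- as.matrix(fm)
  expect_equal(unname(m[1, "rare"]), 2 * log10(10))
  expect_true(all(m[, "common"] == 0))
  # N = 4, df = 2, tf = 1 -> log10(2)
  toks2 <- list("a", "a", "b", "b")
  fm2 <- tfidf(feature_matrix(
    screenburden:::.count_matrix(toks2, as.character(1:4)), "tf"))
  expect_equal(unname(as.matrix(fm2)[1, "a"]), log10(2), tolerance = 1e-12)
  expect_true(all(as.matrix(fm2) >= 0))
})

# independent entropy oracle for a presence/absence split
ig_oracle <- function(present_inc, present_exc, n_inc, n_exc) {
  n <- n_inc + n_exc
  h <- function(k, m) {
    if (m == 0) return(0)
    p <- k / m
    sum(vapply(c(p, 1 - p), function(q) if (q > 0) -q * log2(q) else 0,
               numeric(1)))
  }
  np <- present_inc + present_exc
  na <- n - np
  h(n_inc, n) - (np / n) * h(present_inc, np) - (na / n) * h(n_inc - present_inc, na)
}

test_that("information gain matches a brute-force entropy computation", {
  # perfectly informative feature, balanced classes -> exactly 1 bit
  toks <- list("f", "f", "g", "g")
  labels <- c("include", "include", "exclude", "exclude")
  fm <- feature_matrix(screenburden:::.count_matrix(toks, as.character(1:4)),
                       "tf")
  ig <- information_gain(fm, labels)
  expect_equal(unname(ig[["f"]]), 1)
  filtered <- information_gain_filter(fm, labels, 0.001)
  expect_true("f" %in% feature_names(filtered))

  # label-independent feature (one include, one exclude) -> IG 0, removed
  toks2 <- list(c("x", "f"), "x", c("y", "f"), "y")
  fm2 <- feature_matrix(screenburden:::.count_matrix(toks2, as.character(1:4)),
                        "tf")
  ig2 <- information_gain(fm2, labels)
  expect_equal(unname(ig2[["f"]]), 0)
  expect_false("f" %in% feature_names(information_gain_filter(fm2, labels)))

  # exhaustive check over all 2x2 presence tables at small size
  n_inc <- 3; n_exc <- 5
  for (pi in 0:n_inc) {
    for (pe in 0:n_exc) {
      labels8 <- c(rep("include", n_inc), rep("exclude", n_exc))
      present <- c(rep(1, pi), rep(0, n_inc - pi),
                   rep(1, pe), rep(0, n_exc - pe))
      m <- Matrix::Matrix(matrix(present, ncol = 1,
                                 dimnames = list(as.character(1:8), "t")),
                          sparse = TRUE)
      ig_val <- information_gain(feature_matrix(m, "tf"), labels8)
      expect_equal(unname(ig_val[["t"]]), ig_oracle(pi, pe, n_inc, n_exc),
                   tolerance = 1e-12)
    }
  }
})

test_that("information-gain filter is idempotent, bounded, order-preserving", {
  cp <- separable_corpus(n = 80, seed = 3)
  fm <- build_alphabetic(cp)
  ig <- information_gain(fm, cp$label)
  h_label <- -sum(vapply(table(cp$label) / nrow(cp),
                         function(p) p * log2(p), numeric(1)))
  expect_true(all(ig >= 0 & ig <= h_label + 1e-12))
  once <- information_gain_filter(fm, cp$label, 0.01)
  twice <- information_gain_filter(once, cp$label, 0.01)
  expect_equal(feature_names(twice), feature_names(once))
  expect_true(all(feature_names(once) %in% feature_names(fm)))
  # column order preserved
  expect_equal(feature_names(once),
               intersect(feature_names(fm), feature_names(once)))
  expect_error(information_gain(fm, rep("include", nrow(cp))), "both classes")
})

test_that("feature building is deterministic and writers round-trip", {
  cp <- tiny_labeled_corpus()
  a <- build_alphanumeric(cp)
  b <- build_alphanumeric(cp)
  expect_equal(feature_names(a), feature_names(b))
  expect_equal(as.matrix(a), as.matrix(b))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(a, path)
  back <- read_feature_matrix(path)
  expect_equal(feature_names(back), feature_names(a))
  expect_equal(as.matrix(back), as.matrix(a), tolerance = 1e-9)
  expect_equal(back$scheme, a$scheme)
})

test_that("alphabetic vocabulary is stems of observed tokens only", {
  cp <- separable_corpus(n = 60, seed = 5)
  docs <- compose_documents(cp)
  unstemmed <- unique(unlist(tokenize_alphabetic(docs$text, stem = FALSE)))
  legal <- c(stem_porter(unstemmed),
             unlist(lapply(tokenize_alphabetic(docs$title), title_bigrams)))
  fm <- build_alphabetic(cp)
  expect_true(all(feature_names(fm) %in% legal))
})
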