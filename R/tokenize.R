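# Tokenizers for the two lexical feature sets. Both lowercase, drop stop
# words, then apply the 3-100 character token-length window (measured
# before stemming).

.TOKEN_MIN <- 3L
.TOKEN_MAX <- 100L

.length_ok <- function(tokens) {
  n <- nchar(tokens)
  tokens[n >= .TOKEN_MIN & n <= .TOKEN_MAX]
}

#' Alphabetic tokenization with Porter stemming
#'
#' Lowercases, splits on every non-alphabetic character and whitespace,
#' deletes stop words, keeps tokens of 3-100 characters, then Porter
#' stems the survivors. With `stem = FALSE` the same pipeline returns
#' the unstemmed tokens (used inside the alphanumeric+ set).
#'
#' @param text Character vector; each element is tokenized separately.
#' @param stem Apply the Porter stemmer (default `TRUE`).
#' @param stopwords Character vector of stop words.
#' @return A list of token vectors, one per element of `text` (a plain
#'   character vector when `text` has length one).
#' @export
#' @examples
#' tokenize_alphabetic("Vaccination and vaccines for the elderly")
tokenize_alphabetic <- function(text, stem = TRUE,
                                stopwords = stop_words_en()) {
  pieces <- strsplit(tolower(text), "[^a-z]+")
  out <- lapply(pieces, function(tok) {
    tok <- tok[nzchar(tok)]
    tok <- tok[!(tok %in% stopwords)]
    .length_ok(tok)
  })
  if (stem) {
    # stem once across the whole input so the per-word work is shared
    flat <- stem_porter(unlist(out, use.names = FALSE))
    out <- utils::relist(flat, out)
  }
  if (length(out) == 1L) out[[1L]] else out
}

#' Alphanumeric tokenization preserving internal digits and punctuation
#'
#' Lowercases, replaces em and en dashes with hyphens, splits on
#' whitespace, strips leading and trailing punctuation from each token
#' but keeps internal punctuation and digits (so `h3n2`,
#' `a/sydney/05/97`, `case-control` and `2004-2005` survive intact).
#' Plain alphabetic stop words are dropped; no stemming. Token length
#' window 3-100 characters.
#'
#' @inheritParams tokenize_alphabetic
#' @return A list of token vectors (a character vector for length-one
#'   input).
#' @export
#' @examples
#' tokenize_alphanumeric("A case-control study of H3N2 in 2004–2005")
tokenize_alphanumeric <- function(text, stopwords = stop_words_en()) {
  txt <- tolower(text)
  txt <- gsub("[–—]", "-", txt)
  pieces <- strsplit(txt, "\\s+")
  out <- lapply(pieces, function(tok) {
    tok <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", tok)
    tok <- tok[nzchar(tok)]
    plain <- !grepl("[^a-z]", tok)
    tok <- tok[!(plain & tok %in% stopwords)]
    .length_ok(tok)
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Adjacent-pair bigrams from title tokens
#'
#' Joins adjacent token pairs with an underscore, the convention used to
#' overweight title information (e.g. `influenza_vaccin`).
#'
#' @param tokens Character vector of tokens from one title, already
#'   normalized by the owning feature set's tokenizer.
#' @return Character vector of bigram features (empty for titles of
#'   fewer than two tokens).
#' @export
#' @examples
#' title_bigrams(c("influenza", "vaccin"))
title_bigrams <- function(tokens) {
  n <- length(tokens)
  if (n < 2L) return(character(0))
  paste(tokens[-n], tokens[-1L], sep = "_")
}
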