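# Porter suffix-stripping stemmer (the 1980 algorithm with the author's
# later published corrections, e.g. logi -> log). Operates on lowercase
# words; stem_porter() memoises over unique tokens so corpus-scale calls
# only stem the vocabulary.

# consonant/vowel map: TRUE where the letter acts as a consonant.
# y is a consonant at position 1 or after a vowel.
.porter_cons <- function(chars) {
  n <- length(chars)
  if (!n) return(logical(0))
  cons <- !(chars %in% c("a", "e", "i", "o", "u"))
  for (i in seq_len(n)) {
    if (chars[i] == "y") {
      cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
    }
  }
  cons
}

# m = number of VC sequences in the form [C](VC)^m[V]
.porter_m_str <- function(word) {
  chars <- strsplit(word, "", fixed = TRUE)[[1L]]
  cons <- .porter_cons(chars)
  if (!length(cons)) return(0L)
  runs <- rle(cons)$values
  m <- 0L
  for (i in seq_along(runs)[-1L]) {
    if (runs[i] && !runs[i - 1L]) m <- m + 1L
  }
  m
}

.has_vowel <- function(word) {
  chars <- strsplit(word, "", fixed = TRUE)[[1L]]
  any(!.porter_cons(chars))
}

.ends_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1L]]
  chars[n] == chars[n - 1L] && .porter_cons(chars)[n]
}

# *o: word ends cvc where the final c is not w, x or y
.ends_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1L]]
  cons <- .porter_cons(chars)
  cons[n] && !cons[n - 1L] && cons[n - 2L] &&
    !(chars[n] %in% c("w", "x", "y"))
}

.chop <- function(word, k) substr(word, 1L, nchar(word) - k)

.ends_with <- function(word, suffix) {
  ns <- nchar(suffix)
  nw <- nchar(word)
  nw > ns && substr(word, nw - ns + 1L, nw) == suffix
}

# steps 2 and 3: longest matching suffix decides the rule; its m>0
# condition is then tested on the stem and a failure ends the step.
.porter_map_step <- function(word, suffixes, replacements) {
  ord <- order(nchar(suffixes), decreasing = TRUE)
  for (k in ord) {
    if (.ends_with(word, suffixes[k])) {
      stem <- .chop(word, nchar(suffixes[k]))
      if (.porter_m_str(stem) > 0L) {
        return(paste0(stem, replacements[k]))
      }
      return(word)
    }
  }
  word
}

# step 4 (m > 1); the "ion" rule additionally requires the stem to end s/t
.porter_step4 <- function(word) {
  sufs <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
            "ion", "ism", "ate", "iti", "ous", "ive", "ize", "al", "er",
            "ic", "ou")
  for (s in sufs[order(nchar(sufs), decreasing = TRUE)]) {
    if (.ends_with(word, s)) {
      stem <- .chop(word, nchar(s))
      if (.porter_m_str(stem) > 1L) {
        if (s == "ion") {
          last <- substr(stem, nchar(stem), nchar(stem))
          if (!(last %in% c("s", "t"))) return(word)
        }
        return(stem)
      }
      return(word)
    }
  }
  word
}

.porter_word <- function(word) {
  if (nchar(word) <= 2L) return(word)
  w <- word

  # step 1a: plurals
  if (.ends_with(w, "sses")) {
    w <- .chop(w, 2L)
  } else if (.ends_with(w, "ies")) {
    w <- paste0(.chop(w, 3L), "i")
  } else if (!.ends_with(w, "ss") && .ends_with(w, "s")) {
    w <- .chop(w, 1L)
  }

  # step 1b: -ed / -ing
  if (.ends_with(w, "eed")) {
    if (.porter_m_str(.chop(w, 3L)) > 0L) w <- .chop(w, 1L)
  } else {
    stripped <- FALSE
    if (.ends_with(w, "ed") && .has_vowel(.chop(w, 2L))) {
      w <- .chop(w, 2L)
      stripped <- TRUE
    } else if (.ends_with(w, "ing") && .has_vowel(.chop(w, 3L))) {
      w <- .chop(w, 3L)
      stripped <- TRUE
    }
    if (stripped) {
      if (.ends_with(w, "at") || .ends_with(w, "bl") || .ends_with(w, "iz")) {
        w <- paste0(w, "e")
      } else if (.ends_double_cons(w) &&
                 !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
        w <- .chop(w, 1L)
      } else if (.porter_m_str(w) == 1L && .ends_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c: terminal y -> i when the stem has a vowel
  if (.ends_with(w, "y") && .has_vowel(.chop(w, 1L))) {
    w <- paste0(.chop(w, 1L), "i")
  }

  # step 2
  w <- .porter_map_step(
    w,
    c("ational", "tional", "enci", "anci", "izer", "bli", "alli", "entli",
      "eli", "ousli", "ization", "ation", "ator", "alism", "iveness",
      "fulness", "ousness", "aliti", "iviti", "biliti", "logi"),
    c("ate", "tion", "ence", "ance", "ize", "ble", "al", "ent",
      "e", "ous", "ize", "ate", "ate", "al", "ive",
      "ful", "ous", "al", "ive", "ble", "log")
  )

  # step 3
  w <- .porter_map_step(
    w,
    c("icate", "ative", "alize", "iciti", "ical", "ful", "ness"),
    c("ic", "", "al", "ic", "ic", "", "")
  )

  # step 4
  w <- .porter_step4(w)

  # step 5a: drop a final e
  if (.ends_with(w, "e")) {
    stem <- .chop(w, 1L)
    m <- .porter_m_str(stem)
    if (m > 1L || (m == 1L && !.ends_cvc(stem))) w <- stem
  }

  # step 5b: -ll -> -l when m > 1
  if (.porter_m_str(w) > 1L && .ends_double_cons(w) && .ends_with(w, "l")) {
    w <- .chop(w, 1L)
  }
  w
}

#' Porter-stem a vector of lowercase tokens
#'
#' Suffix-stripping normalization so that morphological variants map to a
#' common stem, e.g. `vaccination` and `vaccines` both map to `vaccin`.
#' Tokens are expected to be lowercase alphabetic strings.
#'
#' @param tokens Character vector of tokens.
#' @return Character vector of stems, same length as `tokens`.
#' @export
#' @examples
#' stem_porter(c("vaccination", "vaccines", "elderly", "epidemiology"))
stem_porter <- function(tokens) {
  if (!length(tokens)) return(character(0))
  uniq <- unique(tokens)
  stems <- vapply(uniq, .porter_word, character(1), USE.NAMES = FALSE)
  stems[match(tokens, uniq)]
}
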