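# Citation corpora: tibble-backed containers plus readers for MEDLINE
# nbib, RIS and a JSONL dialect. One row per citation with columns
# id, title, abstract, journal, indexing (list of character), label.

.label_levels <- c("include", "exclude", "unknown")

#' Construct a citation corpus
#'
#' A corpus is a tibble with one row per bibliographic citation and
#' columns `id`, `title`, `abstract`, `journal`, `indexing` (a list
#' column of controlled-vocabulary terms) and `label` (one of
#' `"include"`, `"exclude"`, `"unknown"`). The review it came from is
#' carried in the `review_id` attribute.
#'
#' @param id,title Character vectors; ids must be unique and titles
#'   non-empty.
#' @param abstract,journal Character vectors (may be empty strings).
#' @param indexing List of character vectors of indexing terms.
#' @param label Character vector over `include`/`exclude`/`unknown`.
#' @param review_id Single string naming the review.
#' @return A `corpus` tibble.
#' @export
#' @examples
#' corpus(id = c("1", "2"), title = c("Flu vaccines", "Malaria tests"))
corpus <- function(id, title, abstract = "", journal = "",
                   indexing = list(character(0)),
                   label = "unknown", review_id = "review") {
  n <- length(id)
  tbl <- tibble::tibble(
    id = as.character(id),
    title = as.character(title),
    abstract = rep_len(as.character(abstract), n),
    journal = rep_len(as.character(journal), n),
    indexing = rep_len(as.list(indexing), n),
    label = rep_len(as.character(label), n)
  )
  validate_corpus(new_corpus(tbl, review_id))
}

new_corpus <- function(tbl, review_id = "review") {
  stopifnot(is.data.frame(tbl))
  tbl <- tibble::as_tibble(tbl)
  class(tbl) <- c("corpus", class(tbl))
  attr(tbl, "review_id") <- review_id
  tbl
}

validate_corpus <- function(x) {
  needed <- c("id", "title", "abstract", "journal", "indexing", "label")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    abort(paste0("corpus is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(x$id)) {
    dup <- unique(x$id[duplicated(x$id)])
    abort(paste0("duplicate citation ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (nrow(x) && any(!nzchar(x$title))) {
    abort("every citation must have a non-empty title")
  }
  bad <- setdiff(unique(x$label), .label_levels)
  if (length(bad)) {
    abort(paste0("invalid labels: ", paste(bad, collapse = ", ")))
  }
  x
}

#' @exportS3Method base::print
print.corpus <- function(x, ...) {
  cat("<corpus> review: ", attr(x, "review_id") %||% "?",
      " (", nrow(x), " citations)\n", sep = "")
  if (any(x$label != "unknown")) {
    cat(sprintf("  include: %d  exclude: %d  eligible: %.1f%%\n",
                sum(x$label == "include"), sum(x$label == "exclude"),
                100 * eligible_fraction(x)))
  }
  NextMethod()
}

#' Review identifier of a corpus
#' @param x A corpus.
#' @return The review id string.
#' @export
review_id <- function(x) attr(x, "review_id") %||% "review"

# stable non-cryptographic hash for citations lacking an explicit id
.stable_hash <- function(x) {
  vapply(x, function(s) {
    h <- 5381
    for (v in utf8ToInt(enc2utf8(s))) h <- (h * 33 + v) %% 2147483647
    sprintf("h%08x", as.integer(h))
  }, character(1), USE.NAMES = FALSE)
}

# id precedence: explicit record key (PMID/accession/DOI), else a stable
# hash of title + journal
.resolve_ids <- function(explicit, title, journal) {
  out <- explicit
  need <- is.na(out) | !nzchar(out)
  if (any(need)) {
    out[need] <- .stable_hash(paste0(title[need], "\r", journal[need]))
  }
  out
}

.collapse_lines <- function(x) paste(x, collapse = " ")

#' Read a MEDLINE nbib file
#'
#' Parses the MEDLINE tag-dash-value dialect (continuation lines are
#' indented). Field mapping: `TI` to title, `AB` to abstract, `JT` to
#' journal, `MH`/`OT` to indexing terms (major-topic asterisks are
#' preserved), `PMID` to the citation id. Labels start as `"unknown"`.
#'
#' @param path Path to an nbib file, or a character vector of lines.
#' @param review_id Review name stored on the corpus.
#' @return A [corpus] tibble.
#' @export
read_medline <- function(path, review_id = "review") {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  recs <- list()
  cur <- NULL
  tag <- NULL
  flush <- function(cur) if (!is.null(cur) && length(cur$fields)) c(recs, list(cur)) else recs
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) {
      recs <- flush(cur)
      cur <- NULL
      tag <- NULL
      next
    }
    if (grepl("^\\s+", line)) {
      # continuation of the previous tag
      if (is.null(tag)) {
        abort(sprintf("malformed nbib line %d: continuation without a tag", i))
      }
      k <- length(cur$fields[[tag]])
      cur$fields[[tag]][k] <- paste(cur$fields[[tag]][k], trimws(line))
      next
    }
    m <- regmatches(line, regexec("^([A-Z][A-Z0-9]{0,3})\\s*- (.*)$", line))[[1]]
    if (!length(m)) {
      abort(sprintf("malformed nbib tag line %d: %s", i, line))
    }
    tag <- m[2]
    if (tag == "PMID" && !is.null(cur) && "PMID" %in% names(cur$fields)) {
      # a new record starting without a blank separator
      recs <- flush(cur)
      cur <- NULL
    }
    if (is.null(cur)) cur <- list(fields = list())
    cur$fields[[tag]] <- c(cur$fields[[tag]], m[3])
  }
  recs <- flush(cur)
  .records_to_corpus(recs, review_id,
    id_tags = "PMID", title_tags = "TI", abstract_tags = "AB",
    journal_tags = "JT", indexing_tags = c("MH", "OT"))
}

#' Read an RIS file
#'
#' Parses RIS `TY ... ER` blocks. Field mapping: `TI`/`T1` to title,
#' `AB`/`N2` to abstract, `JO`/`JF` to journal, `KW` to indexing terms,
#' `AN`/`DO`/`ID` to the citation id.
#'
#' @inheritParams read_medline
#' @return A [corpus] tibble.
#' @export
read_ris <- function(path, review_id = "review") {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  recs <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    m <- regmatches(line, regexec("^([A-Z][A-Z0-9])\\s{2}- ?(.*)$", line))[[1]]
    if (!length(m)) {
      # continuation line: append to the last tag seen
      if (is.null(cur) || !length(cur$fields)) {
        abort(sprintf("malformed RIS line %d: %s", i, line))
      }
      tag <- cur$last
      k <- length(cur$fields[[tag]])
      cur$fields[[tag]][k] <- paste(cur$fields[[tag]][k], trimws(line))
      next
    }
    tag <- m[2]
    val <- m[3]
    if (tag == "TY") {
      if (!is.null(cur)) abort(sprintf("RIS block before line %d not closed by ER", i))
      cur <- list(fields = list(), last = tag)
    }
    if (is.null(cur)) abort(sprintf("RIS line %d outside a TY block", i))
    if (tag == "ER") {
      recs <- c(recs, list(cur))
      cur <- NULL
      next
    }
    cur$fields[[tag]] <- c(cur$fields[[tag]], val)
    cur$last <- tag
  }
  if (!is.null(cur)) abort("RIS stream ended inside a block without ER")
  .records_to_corpus(recs, review_id,
    id_tags = c("AN", "DO", "ID"), title_tags = c("TI", "T1"),
    abstract_tags = c("AB", "N2"), journal_tags = c("JO", "JF"),
    indexing_tags = "KW")
}

.records_to_corpus <- function(recs, review_id, id_tags, title_tags,
                               abstract_tags, journal_tags, indexing_tags) {
  if (!length(recs)) {
    return(new_corpus(tibble::tibble(
      id = character(0), title = character(0), abstract = character(0),
      journal = character(0), indexing = list(), label = character(0)
    ), review_id))
  }
  first_of <- function(fields, tags) {
    for (t in tags) if (!is.null(fields[[t]])) return(.collapse_lines(fields[[t]]))
    ""
  }
  rows <- purrr::map(recs, function(r) {
    title <- first_of(r$fields, title_tags)
    if (!nzchar(title)) return(NULL)
    idx <- unlist(lapply(indexing_tags, function(t) r$fields[[t]]),
                  use.names = FALSE)
    list(
      explicit_id = first_of(r$fields, id_tags),
      title = title,
      abstract = first_of(r$fields, abstract_tags),
      journal = first_of(r$fields, journal_tags),
      indexing = if (is.null(idx)) character(0) else idx
    )
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warn(sprintf("skipped %d record(s) without a title", dropped))
  }
  rows <- purrr::compact(rows)
  if (!length(rows)) {
    return(new_corpus(tibble::tibble(
      id = character(0), title = character(0), abstract = character(0),
      journal = character(0), indexing = list(), label = character(0)
    ), review_id))
  }
  tbl <- tibble::tibble(
    id = .resolve_ids(
      purrr::map_chr(rows, "explicit_id"),
      purrr::map_chr(rows, "title"),
      purrr::map_chr(rows, "journal")
    ),
    title = purrr::map_chr(rows, "title"),
    abstract = purrr::map_chr(rows, "abstract"),
    journal = purrr::map_chr(rows, "journal"),
    indexing = purrr::map(rows, "indexing"),
    label = "unknown"
  )
  validate_corpus(new_corpus(tbl, review_id))
}

#' Read or write the JSONL corpus dialect
#'
#' One JSON object per line with keys `id`, `title`, `abstract`,
#' `journal`, `indexing` (array) and `label`. Round-trips a corpus
#' exactly.
#'
#' @param path File path.
#' @param review_id Review name stored on the corpus.
#' @return `read_corpus_jsonl()` returns a [corpus]; `write_corpus_jsonl()`
#'   returns `path` invisibly.
#' @export
read_corpus_jsonl <- function(path, review_id = "review") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(corpus(character(0), character(0), review_id = review_id))
  }
  objs <- purrr::map(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  tbl <- tibble::tibble(
    id = purrr::map_chr(objs, "id"),
    title = purrr::map_chr(objs, "title"),
    abstract = purrr::map_chr(objs, ~ .x$abstract %||% ""),
    journal = purrr::map_chr(objs, ~ .x$journal %||% ""),
    indexing = purrr::map(objs, ~ as.character(.x$indexing %||% character(0))),
    label = purrr::map_chr(objs, ~ .x$label %||% "unknown")
  )
  validate_corpus(new_corpus(tbl, review_id))
}

#' @param x A corpus to write.
#' @rdname read_corpus_jsonl
#' @export
write_corpus_jsonl <- function(x, path) {
  lines <- purrr::pmap_chr(
    list(x$id, x$title, x$abstract, x$journal, x$indexing, x$label),
    function(id, title, abstract, journal, indexing, label) {
      jsonlite::toJSON(
        list(id = id, title = title, abstract = abstract,
             journal = journal, indexing = as.character(indexing),
             label = label),
        auto_unbox = TRUE
      )
    }
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a label file of provisionally included citation ids
#'
#' Plain text, one id per line; blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @return Character vector of ids.
#' @export
read_include_ids <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Label a corpus from a set of included citation ids
#'
#' Citations whose id appears in `include_ids` are labeled `include`;
#' every other citation is labeled `exclude`, mirroring consensus
#' screening judgments inferred from published flow charts.
#'
#' @param x A corpus.
#' @param include_ids Character vector of ids; must all exist in `x`.
#' @return The corpus with updated labels.
#' @export
assign_labels <- function(x, include_ids) {
  include_ids <- as.character(include_ids)
  unknown <- setdiff(include_ids, x$id)
  if (length(unknown)) {
    abort(paste0("include ids not present in corpus: ",
                 paste(head(unknown, 10), collapse = ", ")))
  }
  x$label <- ifelse(x$id %in% include_ids, "include", "exclude")
  x
}

#' Fraction of labeled citations judged eligible
#'
#' @param x A labeled corpus.
#' @return `include / (include + exclude)`, or `NaN` when nothing is
#'   labeled.
#' @export
eligible_fraction <- function(x) {
  n_inc <- sum(x$label == "include")
  n_exc <- sum(x$label == "exclude")
  n_inc / (n_inc + n_exc)
}

#' Compose citations into field-structured documents
#'
#' Builds the text each feature extractor consumes. The title is written
#' twice to overweight it relative to the abstract and metadata; fields
#' stay individually addressable so that, e.g., title bigrams can be
#' computed from the single title and concept matching can split on
#' lines.
#'
#' @param x A corpus.
#' @return A tibble with columns `id`, `title`, `abstract`, `journal`,
#'   `indexing` and `text`, where `text` is the full composed document
#'   (duplicated title, abstract, journal, indexing terms; one field per
#'   line).
#' @export
compose_documents <- function(x) {
  tibble::tibble(
    id = x$id,
    title = x$title,
    abstract = x$abstract,
    journal = x$journal,
    indexing = x$indexing,
    text = purrr::pmap_chr(
      list(x$title, x$abstract, x$journal, x$indexing),
      function(title, abstract, journal, indexing) {
        paste(c(title, title, abstract, journal, indexing), collapse = "\n")
      }
    )
  )
}

#' @rdname compose_documents
#' @param citation A single-row corpus or a list with the citation fields.
#' @return `compose_document()` returns the composed text for one citation.
#' @export
compose_document <- function(citation) {
  if (is.data.frame(citation)) {
    stopifnot(nrow(citation) == 1L)
    return(compose_documents(citation)$text)
  }
  paste(c(citation$title, citation$title, citation$abstract %||% "",
          citation$journal %||% "",
          as.character(citation$indexing %||% character(0))),
        collapse = "\n")
}
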