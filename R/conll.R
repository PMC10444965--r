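#' Read a CoNLL-BIO corpus
#'
#' Reads a two-column CoNLL file (token TAB tag, blank line between sentences,
#' UTF-8) into a tidy corpus tibble with one row per token. [write_conll()] is
#' its exact inverse.
#'
#' @param path Path to a CoNLL-BIO file.
#' @param validate Check BIO legality of every sentence (default `TRUE`).
#' @return A tibble with columns `sentence_id` (integer), `token` (character)
#'   and `tag` (character).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".conll")
#' writeLines(c("aniridia\tB-Disease", "", "was\tO"), tf)
#' read_conll(tf)
read_conll <- function(path, validate = TRUE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  blank <- !nzchar(trimws(lines))
  sent_id <- cumsum(blank) + 1L
  keep <- !blank
  if (!any(keep)) {
    return(tibble(sentence_id = integer(), token = character(), tag = character()))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    abort(sprintf("malformed CoNLL line %d in %s: expected 'token\\ttag'",
                  which(keep)[bad[1]], path))
  }
  out <- tibble(
    sentence_id = match(sent_id[keep], unique(sent_id[keep])),
    token = vapply(parts, `[`, "", 1),
    tag = vapply(parts, `[`, "", 2)
  )
  if (validate) validate_bio(out)
  out
}

#' Write a corpus tibble as CoNLL-BIO
#'
#' @param corpus A corpus tibble (`sentence_id`, `token`, `tag`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(corpus, path) {
  check_corpus(corpus)
  sents <- corpus_sentences(corpus)
  blocks <- vapply(sents, function(s) {
    paste(paste(s$tokens, s$tags, sep = "\t"), collapse = "\n")
  }, "")
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}

check_corpus <- function(corpus) {
  need <- c("sentence_id", "token", "tag")
  if (!is.data.frame(corpus) || !all(need %in% names(corpus))) {
    abort("corpus must be a data frame with columns sentence_id, token, tag")
  }
  invisible(corpus)
}

#' Validate BIO tag legality of a corpus
#'
#' Every tag must be `O` or `B-T`/`I-T`, and every `I-T` must continue a run of
#' the same type `T`.
#'
#' @param corpus A corpus tibble.
#' @return The corpus, invisibly; aborts on the first violation.
#' @export
validate_bio <- function(corpus) {
  check_corpus(corpus)
  for (s in corpus_sentences(corpus)) {
    ok <- legal_bio(s$tags)
    if (!isTRUE(ok)) {
      abort(sprintf("illegal BIO sequence in sentence %d: %s", s$sentence_id, ok))
    }
  }
  invisible(corpus)
}

# TRUE, or a character message describing the first violation.
legal_bio <- function(tags) {
  prev <- "O"
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (t == "O") { prev <- t; next }
    if (!grepl("^[BI]-.+$", t)) return(sprintf("unknown tag '%s' at position %d", t, i))
    if (startsWith(t, "I-")) {
      type <- substring(t, 3)
      if (!(prev %in% c(paste0("B-", type), paste0("I-", type)))) {
        return(sprintf("orphan '%s' at position %d", t, i))
      }
    }
    prev <- t
  }
  TRUE
}

# Internal sentence representation: list(sentence_id, tokens, tags).
corpus_sentences <- function(corpus) {
  check_corpus(corpus)
  ids <- unique(corpus$sentence_id)
  lapply(ids, function(id) {
    rows <- corpus$sentence_id == id
    list(sentence_id = id, tokens = corpus$token[rows], tags = corpus$tag[rows])
  })
}

sentences_corpus <- function(sentences) {
  if (!length(sentences)) {
    return(tibble(sentence_id = integer(), token = character(), tag = character()))
  }
  dplyr::bind_rows(lapply(seq_along(sentences), function(i) {
    s <- sentences[[i]]
    tibble(sentence_id = i, token = s$tokens, tag = s$tags)
  }))
}

# Entity types present in a corpus, sorted.
corpus_types <- function(corpus) {
  tags <- corpus$tag[corpus$tag != "O"]
  sort(unique(substring(tags, 3)))
}

# Gold entity surfaces per type, from B-runs.
gold_surfaces <- function(corpus) {
  out <- list()
  for (s in corpus_sentences(corpus)) {
    sp <- decode_bio(s$tags)
    if (!nrow(sp)) next
    for (j in seq_len(nrow(sp))) {
      surf <- paste(s$tokens[(sp$start[j] + 1):sp$end[j]], collapse = " ")
      out[[length(out) + 1L]] <- tibble(type = sp$type[j], surface = surf)
    }
  }
  if (!length(out)) return(tibble(type = character(), surface = character()))
  dplyr::distinct(dplyr::bind_rows(out))
}
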