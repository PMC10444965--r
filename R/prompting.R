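#' Build an entity-type question prompt
#'
#' Renders the question template `"can you detect {T} entity like {E1}, {E2} ?"`
#' with two example entities drawn (without replacement, seeded) from the
#' support set's gold surfaces of that type. If only one surface exists it
#' fills both slots.
#'
#' @param entity_type Entity-type label (e.g. `"Disease"`).
#' @param support_entities Character vector of gold entity surfaces of this
#'   type from the support set.
#' @param seed Integer seed.
#' @param template Template string with `{T}`, `{E1}`, `{E2}` slots.
#' @return A `fewner_prompt`: list with `entity_type`, `example_entities`,
#'   `text`.
#' @export
build_prompt <- function(entity_type, support_entities, seed = 1L,
                         template = "can you detect {T} entity like {E1}, {E2} ?") {
  if (!length(support_entities)) {
    abort(paste0("no support entities available for type ", entity_type))
  }
  ex <- if (length(support_entities) == 1L) {
    rep(support_entities, 2L)
  } else {
    with_seed(seed, sample_vec(support_entities, 2L))
  }
  text <- template
  text <- gsub("{T}", entity_type, text, fixed = TRUE)
  text <- gsub("{E1}", ex[1], text, fixed = TRUE)
  text <- gsub("{E2}", ex[2], text, fixed = TRUE)
  structure(list(entity_type = entity_type, example_entities = ex, text = text),
            class = "fewner_prompt")
}

#' Build a label-conditional prompt
#'
#' The minimal alternative prompt style: just `"The {T}."` with no example
#' entities.
#'
#' @param entity_type Entity-type label.
#' @return A `fewner_prompt` with empty `example_entities`.
#' @export
build_label_prompt <- function(entity_type) {
  if (!is.character(entity_type) || length(entity_type) != 1 || !nzchar(entity_type)) {
    abort("entity_type must be a non-empty string")
  }
  structure(list(entity_type = entity_type, example_entities = character(),
                 text = paste0("The ", entity_type, ".")),
            class = "fewner_prompt")
}

#' @export
print.fewner_prompt <- function(x, ...) {
  cat(sprintf("<prompt [%s]> %s\n", x$entity_type, x$text))
  invisible(x)
}

#' Tokenizers for sub-word segmentation
#'
#' A tokenizer is a list with `tokenize_word(word) -> character` plus the
#' special tokens `cls` and `sep`. `whitespace_tokenizer()` keeps each word as
#' a single piece. `chunk_tokenizer(max_chars)` splits words longer than
#' `max_chars` into fixed-size chunks, marking continuations with a `##`
#' prefix — a deliberately simple stand-in for WordPiece that exercises the
#' sub-token alignment contract.
#'
#' @param max_chars Maximum characters per piece for the chunk tokenizer.
#' @return A tokenizer object.
#' @export
whitespace_tokenizer <- function() {
  structure(list(
    tokenize_word = function(word) tolower(word),
    cls = "[CLS]", sep = "[SEP]"
  ), class = "fewner_tokenizer")
}

#' @rdname whitespace_tokenizer
#' @export
chunk_tokenizer <- function(max_chars = 4) {
  structure(list(
    tokenize_word = function(word) {
      w <- tolower(word)
      if (nchar(w) <= max_chars) return(w)
      starts <- seq(1, nchar(w), by = max_chars)
      pieces <- substring(w, starts, pmin(starts + max_chars - 1, nchar(w)))
      c(pieces[1], paste0("##", pieces[-1]))
    },
    cls = "[CLS]", sep = "[SEP]"
  ), class = "fewner_tokenizer")
}

#' Assemble the question-answering model input
#'
#' Concatenates `[CLS] X [SEP] Qprompt [SEP]` at sub-token level, recording
#' which piece positions belong to the sentence and to the prompt, and mapping
#' each sentence piece back to its source word. When the sentence has gold
#' tags, the gold label of a word attaches to its first sub-token; continuation
#' sub-tokens receive the ignore marker `NA`. The prompt is never truncated;
#' an over-long sentence is truncated (whole words) with a warning.
#'
#' @param sentence A one-sentence corpus tibble or `list(tokens, tags)`.
#' @param prompt A `fewner_prompt`.
#' @param tokenizer A tokenizer object (default [whitespace_tokenizer()]).
#' @param max_pieces Encoder position limit for the full input.
#' @return A `fewner_input`: list with `pieces`, `sequence_region`,
#'   `prompt_region` (integer index vectors into `pieces`), `word_alignment`
#'   (source word index per sequence piece) and `piece_labels` (BIO tag or
#'   `NA` per sequence piece).
#' @export
assemble_input <- function(sentence, prompt, tokenizer = whitespace_tokenizer(),
                           max_pieces = 128) {
  s <- as_sentence(sentence)
  if (!length(s$tokens)) abort("sentence is empty")
  if (!inherits(prompt, "fewner_prompt") || !nzchar(prompt$text)) {
    abort("prompt must be a fewner_prompt with non-empty text")
  }
  tok_words <- function(words) {
    pieces <- lapply(words, tokenizer$tokenize_word)
    list(pieces = unlist(pieces, use.names = FALSE),
         word_of = rep(seq_along(words), lengths(pieces)),
         first = unlist(lapply(lengths(pieces), function(k) c(TRUE, rep(FALSE, k - 1L)))))
  }
  xt <- tok_words(s$tokens)
  prompt_words <- strsplit(trimws(prompt$text), "\\s+")[[1]]
  pt <- tok_words(prompt_words)

  budget <- max_pieces - length(pt$pieces) - 3L # CLS + 2 SEP are reserved
  if (budget < 1L) abort("prompt alone exceeds the encoder position limit")
  if (length(xt$pieces) > budget) {
    word_pieces <- tabulate(xt$word_of, nbins = length(s$tokens))
    fits <- which(cumsum(word_pieces) <= budget)
    if (!length(fits)) abort("first word alone exceeds the encoder position limit")
    keep_words <- max(fits)
    warn(sprintf("sentence truncated from %d to %d words to fit %d pieces",
                 length(s$tokens), keep_words, max_pieces))
    s$tokens <- s$tokens[seq_len(keep_words)]
    s$tags <- s$tags[seq_len(keep_words)]
    xt <- tok_words(s$tokens)
  }

  nx <- length(xt$pieces); np <- length(pt$pieces)
  pieces <- c(tokenizer$cls, xt$pieces, tokenizer$sep, pt$pieces, tokenizer$sep)
  seq_region <- seq.int(2L, 1L + nx)
  prompt_region <- seq.int(3L + nx, 2L + nx + np)
  piece_labels <- ifelse(xt$first, s$tags[xt$word_of], NA_character_)
  structure(list(
    pieces = pieces,
    sequence_region = seq_region,
    prompt_region = prompt_region,
    word_alignment = xt$word_of,
    piece_labels = piece_labels,
    n_words = length(s$tokens)
  ), class = "fewner_input")
}

#' Project gold labels onto a single entity type
#'
#' A question about one entity type must only be supervised by that type:
#' `B-`/`I-` tags of any other type are mapped to `O`; tags of `entity_type`
#' and `O` pass through.
#'
#' @param sentence A one-sentence corpus tibble, `list(tokens, tags)`, or a
#'   bare character vector of tags.
#' @param entity_type The queried type.
#' @param types The configured type set (for validation); defaults to the
#'   types present plus `entity_type`.
#' @return Character vector of projected BIO tags.
#' @export
project_labels <- function(sentence, entity_type, types = NULL) {
  tags <- if (is.character(sentence)) sentence else as_sentence(sentence)$tags
  if (!is.null(types) && !entity_type %in% types) {
    abort(paste0("unknown entity type: ", entity_type))
  }
  keep <- tags %in% c("O", paste0("B-", entity_type), paste0("I-", entity_type))
  ifelse(keep, tags, "O")
}
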