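#' Replace a candidate span by a neighbour concept
#'
#' Splices the neighbour's whitespace tokens into the sentence in place of the
#' matched span and adjusts BIO labels: an entity candidate keeps its gold type
#' (labels become `B-T I-T ...`), a non-entity candidate gets all-`O` labels.
#' Tokens and labels outside the span are untouched.
#'
#' @param sentence A one-sentence corpus tibble or `list(tokens, tags)`.
#' @param match One row of [match_candidates()] output (or an equivalent list
#'   with `start`, `end`, `is_entity`, `gold_type`).
#' @param neighbor Replacement concept surface string.
#' @return A `list(tokens, tags)` sentence.
#' @export
#' @examples
#' s <- list(tokens = c("severe", "myalgias"), tags = c("O", "B-Disease"))
#' m <- list(start = 1L, end = 2L, is_entity = TRUE, gold_type = "Disease")
#' replace_span(s, m, "neuromuscular pain")
replace_span <- function(sentence, match, neighbor) {
  s <- as_sentence(sentence)
  n <- length(s$tokens)
  match <- as.list(match)
  if (!(match$start >= 0 && match$start < match$end && match$end <= n)) {
    abort("match span out of range")
  }
  new_tokens <- strsplit(trimws(neighbor), "\\s+")[[1]]
  if (!length(new_tokens) || !nzchar(neighbor)) abort("neighbor string is empty")
  new_tags <- if (isTRUE(match$is_entity)) {
    c(paste0("B-", match$gold_type),
      rep(paste0("I-", match$gold_type), length(new_tokens) - 1L))
  } else {
    rep("O", length(new_tokens))
  }
  pre <- seq_len(match$start)
  post <- if (match$end < n) (match$end + 1L):n else integer()
  list(
    tokens = c(s$tokens[pre], new_tokens, s$tokens[post]),
    tags = c(s$tags[pre], new_tags, s$tags[post])
  )
}

#' Generate augmented instances for one sentence
#'
#' Knowledge-guided instance generation: candidate concepts are matched against
#' the graph, a relation-filtered sub-graph is built around each (semantic-type
#' gating applies to non-entity candidates only), and instances are formed by
#' choosing, per candidate, either to keep it or to substitute one neighbour —
#' excluding the all-keep choice, so every instance differs from the source in
#' at least one span. When the combinations exceed `n_max` a seeded sample
#' without replacement is drawn; output is deterministic given
#' `(sentence, kg, n_max, seed)`.
#'
#' @param sentence A one-sentence corpus tibble or `list(tokens, tags)`.
#' @param kg A `fewner_kg`.
#' @param n_max Per-sentence instance cap (default 9).
#' @param seed Integer seed.
#' @param max_len Maximum concept length for the matcher.
#' @param source_index Bookkeeping index of the source sentence.
#' @return List of instances; each is a list with `sentence`
#'   (`list(tokens, tags)`), `source_index`, and `replacements` (tibble with
#'   `start`, `end`, `original`, `neighbor`, `relation`).
#' @export
generate_instances <- function(sentence, kg, n_max = 9, seed = 1L, max_len = 6,
                               source_index = 1L) {
  if (!is_count(n_max)) abort("n_max must be a count >= 0")
  if (n_max == 0) return(list())
  s <- as_sentence(sentence)
  cands <- match_candidates(s, kg, max_len = max_len)
  if (!nrow(cands)) return(list())
  subs <- lapply(seq_len(nrow(cands)), function(i) {
    build_subgraph(kg, cands$concept[i],
                   require_semtype_overlap = !cands$is_entity[i])
  })
  ks <- vapply(subs, `[[`, 0L, "k")
  keep <- ks > 0
  cands <- cands[keep, , drop = FALSE]
  subs <- subs[keep]
  ks <- ks[keep]
  if (!nrow(cands)) return(list())

  total <- prod(ks + 1) - 1 # all keep/replace combinations minus all-keep
  choice_sets <- if (total <= max(n_max, 4096)) {
    picks <- enumerate_choices(ks)
    if (length(picks) > n_max) {
      with_seed(seed, picks[sort(sample.int(length(picks), n_max))])
    } else picks
  } else {
    sample_choices(ks, n_max, seed)
  }

  lapply(choice_sets, function(choice) {
    inst <- s
    reps <- list()
    for (i in rev(seq_along(choice))) { # right-to-left keeps earlier spans valid
      ci <- choice[i]
      if (ci == 0L) next
      nb <- subs[[i]]$neighbors[ci, ]
      m <- cands[i, ]
      inst <- replace_span(inst, m, nb$target)
      reps[[length(reps) + 1L]] <- tibble(
        start = m$start, end = m$end,
        original = paste(s$tokens[(m$start + 1):m$end], collapse = " "),
        neighbor = nb$target, relation = nb$relation
      )
    }
    list(sentence = inst, source_index = source_index,
         replacements = dplyr::bind_rows(rev(reps)))
  })
}

# All per-candidate choice vectors (0 = keep, j = j-th neighbour), excluding
# all-keep, in mixed-radix order.
enumerate_choices <- function(ks) {
  grids <- lapply(ks, function(k) 0:k)
  grid <- expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(ks)), drop = FALSE]
  picks <- lapply(seq_len(nrow(grid)), function(r) as.integer(grid[r, ]))
  Filter(function(p) any(p > 0L), picks)
}

# Rejection-sample n distinct non-all-keep choice vectors (huge combination
# spaces only).
sample_choices <- function(ks, n, seed) {
  with_seed(seed, {
    seen <- character()
    out <- list()
    guard <- 0L
    while (length(out) < n && guard < 100L * n) {
      guard <- guard + 1L
      p <- vapply(ks, function(k) sample.int(k + 1L, 1L) - 1L, 0L)
      if (!any(p > 0L)) next
      key <- paste(p, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- p
    }
    out
  })
}

#' Augment a corpus by knowledge-guided instance generation
#'
#' Applies [generate_instances()] to every sentence and returns the original
#' sentences followed by all generated instances. Per-sentence seeds are
#' derived deterministically from `seed` and the sentence index, so the result
#' is stable across runs and insensitive to how other sentences augment.
#'
#' @param corpus A corpus tibble.
#' @param kg A `fewner_kg`.
#' @param n_max Per-sentence instance cap (default 9, the standard cap).
#' @param seed Integer master seed.
#' @param max_len Maximum concept length for the matcher.
#' @return A corpus tibble with renumbered `sentence_id` and two extra columns:
#'   `source_id` (originating sentence) and `augmented` (logical).
#' @export
augment_corpus <- function(corpus, kg, n_max = 9, seed = 1L, max_len = 6) {
  check_corpus(corpus)
  sents <- corpus_sentences(corpus)
  if (!length(sents)) abort("corpus is empty")
  out <- list()
  meta <- list()
  for (i in seq_along(sents)) {
    out[[length(out) + 1L]] <- sents[[i]]
    meta[[length(meta) + 1L]] <- c(source = i, aug = 0L)
  }
  for (i in seq_along(sents)) {
    inst <- generate_instances(sents[[i]], kg, n_max = n_max,
                               seed = derive_seed(seed, i), max_len = max_len,
                               source_index = i)
    for (a in inst) {
      out[[length(out) + 1L]] <- a$sentence
      meta[[length(meta) + 1L]] <- c(source = i, aug = 1L)
    }
  }
  df <- sentences_corpus(out)
  m <- do.call(rbind, meta)
  df$source_id <- m[df$sentence_id, "source"]
  df$augmented <- m[df$sentence_id, "aug"] == 1L
  df
}
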