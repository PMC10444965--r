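#' Relation whitelist for knowledge sub-graphs
#'
#' The six UMLS Metathesaurus relation codes retained when building a knowledge
#' sub-graph: synonym (SY), similar (RL), broader (RB), related-possibly-
#' synonymous (RQ), parent (PAR) and child (CHD). Only these preserve enough
#' semantic consistency for a neighbour to stand in for the original concept
#' in context.
#' @export
KG_RELATIONS <- c("CHD", "PAR", "RB", "RL", "RQ", "SY")

#' Construct a knowledge graph
#'
#' A knowledge graph is an edge table over concept surface strings plus a
#' semantic-type map. Edges are deduplicated and relation codes upper-cased.
#'
#' @param edges A data frame with character columns `head`, `relation`, `tail`.
#' @param semtypes Named list mapping concepts to character vectors of semantic
#'   types; concepts absent from the list get an empty set.
#' @return An object of class `fewner_kg`: list with `nodes` (character),
#'   `edges` (tibble) and `semtypes` (named list, total over nodes).
#' @export
kg_new <- function(edges, semtypes = list()) {
  edges <- as_tibble(edges)
  if (!all(c("head", "relation", "tail") %in% names(edges))) {
    abort("edges needs columns head, relation, tail")
  }
  edges <- edges %>%
    mutate(relation = toupper(.data$relation)) %>%
    distinct(.data$head, .data$relation, .data$tail)
  if (nrow(edges) && any(!nzchar(edges$relation))) {
    abort("relation codes must be non-empty")
  }
  nodes <- sort(unique(c(edges$head, edges$tail, names(semtypes))))
  st <- stats::setNames(vector("list", length(nodes)), nodes)
  for (n in nodes) st[[n]] <- sort(unique(as.character(semtypes[[n]] %||% character())))
  structure(list(nodes = nodes, edges = edges, semtypes = st), class = "fewner_kg")
}

#' @export
print.fewner_kg <- function(x, ...) {
  cat(sprintf("<knowledge graph: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Load a knowledge graph from a KG-TSV file
#'
#' One edge per line, five tab-separated columns: head, relation, tail,
#' head semantic types (comma-joined, may be empty), tail semantic types.
#' Lines starting with `#` are comments. Duplicate edges are dropped and
#' relation codes upper-cased.
#'
#' @param path Path to a KG-TSV file.
#' @return A `fewner_kg` object.
#' @export
load_kg <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (!length(idx)) return(kg_new(tibble(head = character(), relation = character(),
                                         tail = character())))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  # trailing empty fields are dropped by strsplit; pad to 5
  parts <- lapply(parts, function(p) c(p, rep("", 5 - length(p)))[1:5])
  nf <- vapply(strsplit(lines[idx], "\t", fixed = TRUE), length, 0L)
  bad <- which(nf > 5 | nf < 3)
  if (length(bad)) {
    abort(sprintf("KG-TSV format error at line %d of %s: expected 5 tab-separated columns, got %d",
                  idx[bad[1]], path, nf[bad[1]]))
  }
  m <- do.call(rbind, parts)
  empty <- !nzchar(m[, 1]) | !nzchar(m[, 2]) | !nzchar(m[, 3])
  if (any(empty)) {
    abort(sprintf("KG-TSV parse error at line %d of %s: empty head/relation/tail",
                  idx[which(empty)[1]], path))
  }
  split_st <- function(x) {
    y <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    y[nzchar(y)]
  }
  semtypes <- list()
  for (i in seq_len(nrow(m))) {
    semtypes[[m[i, 1]]] <- union(semtypes[[m[i, 1]]] %||% character(), split_st(m[i, 4]))
    semtypes[[m[i, 3]]] <- union(semtypes[[m[i, 3]]] %||% character(), split_st(m[i, 5]))
  }
  kg_new(tibble(head = m[, 1], relation = m[, 2], tail = m[, 3]), semtypes)
}

#' Write a knowledge graph as KG-TSV
#' @param kg A `fewner_kg`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kg <- function(kg, path) {
  st <- function(n) paste(kg$semtypes[[n]], collapse = ",")
  lines <- vapply(seq_len(nrow(kg$edges)), function(i) {
    e <- kg$edges[i, ]
    paste(e$head, e$relation, e$tail, st(e$head), st(e$tail), sep = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Match candidate concepts in a sentence
#'
#' Dictionary matcher standing in for a concept tagger such as MetaMap: a
#' case-insensitive, longest-match-first, left-to-right scan of the sentence
#' tokens against the whitespace-tokenized surface forms of the knowledge-graph
#' nodes. Matches are non-overlapping and sorted by start. Each match is
#' annotated with whether its span coincides exactly with a gold entity span;
#' candidates that partially overlap a gold entity are dropped so replacement
#' can never corrupt labels.
#'
#' @param sentence A one-sentence corpus tibble, or a list with `tokens` and
#'   `tags` character vectors.
#' @param kg A `fewner_kg`.
#' @param max_len Maximum concept length in tokens (default 6).
#' @return Tibble with columns `start`, `end` (0-based, half-open token
#'   indices), `concept` (the matched KG node string), `is_entity` (logical)
#'   and `gold_type` (character, `NA` for non-entities).
#' @export
match_candidates <- function(sentence, kg, max_len = 6) {
  s <- as_sentence(sentence)
  if (!length(s$tokens)) abort("sentence is empty")
  if (!is_count(max_len, 1L)) abort("max_len must be >= 1")
  node_key <- tolower(kg$nodes)
  node_len <- lengths(strsplit(node_key, " ", fixed = TRUE))
  lut <- stats::setNames(kg$nodes, node_key)
  toks <- tolower(s$tokens)
  n <- length(toks)
  gold <- decode_bio(s$tags)
  res <- list()
  i <- 1L
  while (i <= n) {
    hit <- NULL
    for (len in seq.int(min(max_len, n - i + 1L), 1L)) {
      phrase <- paste(toks[i:(i + len - 1L)], collapse = " ")
      if (!is.na(lut[phrase])) {
        hit <- list(start = i - 1L, end = i - 1L + len, concept = unname(lut[phrase]))
        break
      }
    }
    if (is.null(hit)) { i <- i + 1L; next }
    res[[length(res) + 1L]] <- hit
    i <- i + (hit$end - hit$start)
  }
  if (!length(res)) {
    return(tibble(start = integer(), end = integer(), concept = character(),
                  is_entity = logical(), gold_type = character()))
  }
  out <- tibble(
    start = vapply(res, `[[`, 0L, "start"),
    end = vapply(res, `[[`, 0L, "end"),
    concept = vapply(res, `[[`, "", "concept")
  )
  exact <- rep(NA_character_, nrow(out))
  partial <- rep(FALSE, nrow(out))
  if (nrow(gold)) {
    for (j in seq_len(nrow(out))) {
      same <- gold$start == out$start[j] & gold$end == out$end[j]
      if (any(same)) {
        exact[j] <- gold$type[which(same)[1]]
      } else if (any(gold$start < out$end[j] & out$start[j] < gold$end)) {
        partial[j] <- TRUE
      }
    }
  }
  out$is_entity <- !is.na(exact)
  out$gold_type <- exact
  out[!partial, , drop = FALSE]
}

#' Build the knowledge sub-graph around a concept
#'
#' Collects all edges incident to `center` whose relation code is one of
#' [KG_RELATIONS], taking the non-center endpoint as the neighbour. Neighbours
#' are returned in deterministic order (relation code, then target,
#' lexicographic).
#'
#' @param kg A `fewner_kg`.
#' @param center A concept in `kg$nodes`.
#' @param require_semtype_overlap If `TRUE`, keep only neighbours sharing at
#'   least one semantic type with the center. Used for non-entity candidates,
#'   where the semantic types act as type nodes guarding the replacement.
#' @return List of class `fewner_subgraph`: `center`, `neighbors` (tibble with
#'   `relation`, `target`) and `k` (neighbour count).
#' @export
build_subgraph <- function(kg, center, require_semtype_overlap = FALSE) {
  if (!center %in% kg$nodes) abort(paste0("concept not in graph: ", center))
  e <- kg$edges
  inc <- e$head == center | e$tail == center
  e <- e[inc & e$relation %in% KG_RELATIONS, , drop = FALSE]
  target <- ifelse(e$head == center, e$tail, e$head)
  keep <- target != center
  nb <- tibble(relation = e$relation[keep], target = target[keep]) %>% distinct()
  if (require_semtype_overlap && nrow(nb)) {
    cst <- kg$semtypes[[center]]
    keep2 <- vapply(nb$target, function(t) length(intersect(cst, kg$semtypes[[t]])) > 0,
                    logical(1))
    nb <- nb[keep2, , drop = FALSE]
  }
  nb <- nb %>% arrange(.data$relation, .data$target)
  structure(list(center = center, neighbors = nb, k = nrow(nb)),
            class = "fewner_subgraph")
}

#' @export
print.fewner_subgraph <- function(x, ...) {
  cat(sprintf("<sub-graph around '%s': %d neighbours>\n", x$center, x$k))
  if (x$k) print(x$neighbors)
  invisible(x)
}

# Accept either a one-sentence corpus tibble or a list(tokens, tags).
as_sentence <- function(sentence) {
  if (is.data.frame(sentence)) {
    check_corpus(sentence)
    if (length(unique(sentence$sentence_id)) > 1) {
      abort("expected a single sentence; got several sentence_id values")
    }
    list(tokens = sentence$token, tags = sentence$tag)
  } else if (is.list(sentence) && !is.null(sentence$tokens)) {
    if (is.null(sentence$tags)) sentence$tags <- rep("O", length(sentence$tokens))
    sentence[c("tokens", "tags")]
  } else {
    abort("sentence must be a corpus tibble or a list(tokens, tags)")
  }
}
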