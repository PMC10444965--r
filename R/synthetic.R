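#' Configuration for the synthetic corpus and knowledge-graph generators
#'
#' The generators emulate the shape of a BIO-annotated biomedical corpus and a
#' Metathesaurus extract at desk scale: sentences of 5-15 filler tokens,
#' entity surfaces of 1-3 tokens inserted at a per-sentence rate, and a star
#' of relation-typed neighbours around every distinct entity surface.
#'
#' @param n_sentences Number of sentences.
#' @param entity_types Entity-type labels.
#' @param entities_per_type Distinct entity surfaces per type.
#' @param vocab_size Filler vocabulary size.
#' @param entity_rate Probability that a sentence carries an entity.
#' @param kg_neighbors_per_entity Whitelisted neighbours per entity surface
#'   (0 allowed, to exercise the no-neighbour path).
#' @param disallowed_rate Fraction of additional edges carrying a relation
#'   outside the whitelist, to exercise relation filtering.
#' @param n_filler_concepts Filler tokens also present in the graph as
#'   non-entity concepts (replaced with label `O`).
#' @param seed Integer seed; generation is deterministic per seed.
#' @return A list of class `fewner_synth_config`.
#' @export
synth_config <- function(n_sentences = 40, entity_types = "Disease",
                         entities_per_type = 8, vocab_size = 50,
                         entity_rate = 0.8, kg_neighbors_per_entity = 3,
                         disallowed_rate = 0.25, n_filler_concepts = 5,
                         seed = 1L) {
  stopifnot(n_sentences >= 1, entities_per_type >= 1, vocab_size >= 1,
            entity_rate > 0, entity_rate <= 1, kg_neighbors_per_entity >= 0)
  structure(as.list(environment()), class = "fewner_synth_config")
}

synth_surfaces <- function(config) {
  out <- list()
  for (ty in config$entity_types) {
    stem <- tolower(gsub("[^A-Za-z]", "", ty))
    for (i in seq_len(config$entities_per_type)) {
      len <- 1L + (i %% 3L) # 1-3 tokens, spread deterministically
      out[[length(out) + 1L]] <- tibble(
        type = ty,
        surface = paste(paste0(stem, i, letters[seq_len(len)]), collapse = " ")
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Generate a synthetic BIO corpus
#'
#' @param config A [synth_config()].
#' @return A corpus tibble; every configured entity type occurs at least once
#'   and all sentences carry legal BIO labels.
#' @export
make_toy_corpus <- function(config = synth_config()) {
  if (length(config$entity_types) > config$n_sentences) {
    abort("more entity types than sentences: coverage is impossible")
  }
  filler <- sprintf("w%03d", seq_len(config$vocab_size))
  surf <- synth_surfaces(config)
  sents <- with_seed(config$seed, {
    out <- vector("list", config$n_sentences)
    for (i in seq_len(config$n_sentences)) {
      n <- sample(5:15, 1)
      tokens <- sample(filler, n, replace = TRUE)
      tags <- rep("O", n)
      if (stats::runif(1) <= config$entity_rate) {
        row <- surf[sample.int(nrow(surf), 1), ]
        ins <- insert_entity(tokens, tags, row$surface, row$type)
        tokens <- ins$tokens; tags <- ins$tags
      }
      out[[i]] <- list(tokens = tokens, tags = tags)
    }
    # coverage pass: every type must be realized somewhere
    for (ty in config$entity_types) {
      present <- any(vapply(out, function(s) any(startsWith(s$tags, "B-") &
                                                   substring(s$tags, 3) == ty),
                            logical(1)))
      if (!present) {
        i <- sample.int(config$n_sentences, 1)
        row <- surf[surf$type == ty, ][sample.int(sum(surf$type == ty), 1), ]
        ins <- insert_entity(out[[i]]$tokens, out[[i]]$tags, row$surface, ty)
        out[[i]] <- list(tokens = ins$tokens, tags = ins$tags)
      }
    }
    out
  })
  sentences_corpus(sents)
}

insert_entity <- function(tokens, tags, surface, type) {
  etoks <- strsplit(surface, " ", fixed = TRUE)[[1]]
  etags <- c(paste0("B-", type), rep(paste0("I-", type), length(etoks) - 1L))
  pos <- sample.int(length(tokens) + 1L, 1) - 1L # insert after `pos` tokens
  list(tokens = append(tokens, etoks, after = pos),
       tags = append(tags, etags, after = pos))
}

#' Generate a synthetic knowledge graph for a corpus
#'
#' Every distinct gold entity surface becomes a concept with
#' `kg_neighbors_per_entity` whitelisted-relation neighbours, plus a
#' `disallowed_rate` fraction of extra edges with relation `RO` (exercising the
#' six-relation filter) and a few filler-token concepts standing in for
#' non-entity candidates. Semantic types are assigned consistently per concept
#' family, so the semantic-type gate lets family neighbours through.
#'
#' @param corpus A corpus tibble with at least one entity.
#' @param config A [synth_config()].
#' @return A `fewner_kg`.
#' @export
make_toy_kg <- function(corpus, config = synth_config()) {
  surf <- gold_surfaces(corpus)
  if (!nrow(surf)) abort("corpus has no entities")
  filler_tokens <- corpus$token[corpus$tag == "O"]
  filler_concepts <- utils::head(sort(unique(filler_tokens)), config$n_filler_concepts)
  with_seed(derive_seed(config$seed, 31L), {
    edges <- list()
    semtypes <- list()
    add_family <- function(center, family_st, n_nb) {
      semtypes[[center]] <<- union(semtypes[[center]] %||% character(), family_st)
      if (n_nb > 0) {
        for (j in seq_len(n_nb)) {
          nb <- paste(center, "variant", j)
          rel <- sample_vec(KG_RELATIONS, 1L)
          edges[[length(edges) + 1L]] <<- tibble(head = center, relation = rel,
                                                 tail = nb)
          semtypes[[nb]] <<- family_st
        }
      }
      n_bad <- round(config$disallowed_rate * n_nb)
      if (n_bad > 0) {
        for (j in seq_len(n_bad)) {
          nb <- paste(center, "excluded", j)
          edges[[length(edges) + 1L]] <<- tibble(head = center, relation = "RO",
                                                 tail = nb)
          semtypes[[nb]] <<- family_st
        }
      }
    }
    for (i in seq_len(nrow(surf))) {
      add_family(surf$surface[i], paste0("T_", surf$type[i]),
                 config$kg_neighbors_per_entity)
    }
    for (f in filler_concepts) {
      add_family(f, "T_context", max(1L, config$kg_neighbors_per_entity))
    }
    e <- if (length(edges)) dplyr::bind_rows(edges) else {
      tibble(head = character(), relation = character(), tail = character())
    }
    kg_new(e, semtypes)
  })
}

#' Packaged worked-example corpus and knowledge graph
#'
#' A four-sentence disease corpus with the classic substitution examples —
#' "aniridia" (whose child concept is "aniridia of left eye" and parent
#' "congenital anterior segment disorders"), "alkaptonuria" (synonymous with
#' "alkaptonuric ochronosis"), "myalgias" (synonymous with "neuromuscular
#' pain"), and "hypertension" next to the non-entity concept "intracellular" —
#' together with a miniature UMLS-style knowledge graph containing exactly
#' those neighbourhoods. Ships as plain-text files under `inst/extdata` and is
#' read back through the package's own parsers.
#'
#' @return List with `corpus` (tibble) and `kg` (`fewner_kg`).
#' @export
demo_fixture <- function() {
  corpus <- read_conll(system.file("extdata", "toy_corpus.conll",
                                   package = "fewner", mustWork = TRUE))
  kg <- load_kg(system.file("extdata", "toy_kg.tsv",
                            package = "fewner", mustWork = TRUE))
  list(corpus = corpus, kg = kg)
}
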