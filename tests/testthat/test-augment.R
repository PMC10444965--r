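test_that("entity replacement rewrites the span and its BIO labels", {
  s <- sent(c("severe", "myalgias", "today"), c("O", "B-Disease", "O"))
  m <- list(start = 1L, end = 2L, is_entity = TRUE, gold_type = "Disease")
  out <- replace_span(s, m, "neuromuscular pain")
  expect_equal(out$tokens, c("severe", "neuromuscular", "pain", "today"))
  expect_equal(out$tags, c("O", "B-Disease", "I-Disease", "O"))

  s2 <- sent("aniridia", "B-Disease")
  out2 <- replace_span(s2, list(start = 0L, end = 1L, is_entity = TRUE,
                                gold_type = "Disease"), "aniridia of left eye")
  expect_equal(out2$tokens, c("aniridia", "of", "left", "eye"))
  expect_equal(out2$tags, c("B-Disease", "I-Disease", "I-Disease", "I-Disease"))
})

test_that("non-entity replacement assigns O to every new token", {
  s <- sent(c("increased", "intracellular", "calcium"))
  out <- replace_span(s, list(start = 1L, end = 2L, is_entity = FALSE,
                              gold_type = NA), "intracellular space")
  expect_equal(out$tokens, c("increased", "intracellular", "space", "calcium"))
  expect_equal(out$tags, rep("O", 4))
})

test_that("empty neighbour strings are rejected", {
  s <- sent("aniridia", "B-Disease")
  m <- list(start = 0L, end = 1L, is_entity = TRUE, gold_type = "Disease")
  expect_error(replace_span(s, m, ""), "empty")
})

test_that("instance generation enumerates keep-or-replace combinations", {
  # one entity candidate with exactly two whitelisted neighbours
  kg <- kg_new(tibble::tibble(
    head = "aniridia", relation = c("PAR", "CHD", "RO"),
    tail = c("congenital anterior segment disorders", "aniridia of left eye",
             "excluded concept")
  ))
  s <- sent(c("cases", "of", "aniridia"), c("O", "O", "B-Disease"))
  inst <- generate_instances(s, kg, n_max = 9, seed = 3)
  expect_length(inst, 2)
  surfaces <- sapply(inst, function(a) paste(a$sentence$tokens, collapse = " "))
  expect_setequal(surfaces, c("cases of congenital anterior segment disorders",
                              "cases of aniridia of left eye"))
  expect_true(all(sapply(inst, function(a) nrow(a$replacements) >= 1)))
})

test_that("n_max caps and n_max = 0 silences generation", {
  kg <- toy_kg()
  s <- sent(c("aniridia", "with", "hypertension"),
            c("B-Disease", "O", "B-Disease"))
  expect_length(generate_instances(s, kg, n_max = 0, seed = 1), 0)
  # 2 and 2 whitelisted neighbours -> 3*3 - 1 = 8 combinations
  expect_length(generate_instances(s, kg, n_max = 9, seed = 1), 8)
  expect_length(generate_instances(s, kg, n_max = 5, seed = 1), 5)
})

test_that("multi-span instances replace entity and non-entity candidates together", {
  kg <- toy_kg()
  s <- sent(c("hypertension", "alters", "intracellular", "calcium"),
            c("B-Disease", "O", "O", "O"))
  inst <- generate_instances(s, kg, n_max = 9, seed = 2)
  # 2 neighbours for hypertension, 1 for intracellular: 3*2-1 = 5 combinations
  expect_length(inst, 5)
  both <- Filter(function(a) nrow(a$replacements) == 2, inst)
  expect_true(length(both) >= 1)
  for (a in inst) {
    expect_true(isTRUE(legal_bio_tags(a$sentence$tags)))
  }
})

test_that("corpus augmentation appends instances after the originals", {
  kg <- toy_kg()
  corpus <- dplyr::bind_rows(
    tibble::tibble(sentence_id = 1L, token = c("severe", "myalgias"),
                   tag = c("O", "B-Disease")),
    tibble::tibble(sentence_id = 2L, token = c("no", "match"), tag = c("O", "O"))
  )
  aug <- augment_corpus(corpus, kg, n_max = 9, seed = 1)
  # 2 originals + 1 instance (myalgias -> neuromuscular pain)
  expect_equal(length(unique(aug$sentence_id)), 3)
  expect_equal(aug$token[aug$sentence_id == 1], corpus$token[corpus$sentence_id == 1])
  expect_false(any(aug$augmented[aug$sentence_id <= 2]))
  expect_true(all(aug$augmented[aug$sentence_id == 3]))
  expect_equal(aug$source_id[aug$sentence_id == 3][1], 1L)
})

test_that("a corpus with no KG matches augments to itself", {
  corpus <- tibble::tibble(sentence_id = 1L, token = c("plain", "words"),
                           tag = c("O", "O"))
  aug <- augment_corpus(corpus, toy_kg(), n_max = 9, seed = 1)
  expect_equal(aug$token, corpus$token)
  expect_equal(aug$tag, corpus$tag)
})

test_that("augmentation invariants hold on a synthetic corpus", {
  cfg <- synth_config(n_sentences = 60, entity_rate = 0.9, seed = 8)
  corpus <- make_toy_corpus(cfg)
  kg <- make_toy_kg(corpus, cfg)
  sents <- split(corpus, corpus$sentence_id)
  for (i in seq_along(sents)) {
    src <- list(tokens = sents[[i]]$token, tags = sents[[i]]$tag)
    inst <- generate_instances(src, kg, n_max = 9, seed = 100 + i)
    expect_lte(length(inst), 9)
    for (a in inst) {
      expect_length(a$sentence$tags, length(a$sentence$tokens))
      expect_true(legal_bio_tags(a$sentence$tags))
      expect_true(all(a$replacements$relation %in% KG_RELATIONS))
      expect_gte(nrow(a$replacements), 1)
      # context preservation: rebuilding from the source via the recorded
      # replacements reproduces the instance exactly
      rebuilt <- src
      reps <- a$replacements[order(-a$replacements$start), ]
      gold <- decode_bio(src$tags)
      for (j in seq_len(nrow(reps))) {
        hit <- gold$start == reps$start[j] & gold$end == reps$end[j]
        rebuilt <- replace_span(rebuilt, list(
          start = reps$start[j], end = reps$end[j],
          is_entity = any(hit),
          gold_type = if (any(hit)) gold$type[which(hit)[1]] else NA
        ), reps$neighbor[j])
      }
      expect_identical(rebuilt$tokens, a$sentence$tokens)
      expect_identical(rebuilt$tags, a$sentence$tags)
      # type preservation: the multiset of entity types is unchanged when only
      # entities are replaced; non-entity replacements never add entities
      src_types <- sort(decode_bio(src$tags)$type)
      inst_types <- sort(decode_bio(a$sentence$tags)$type)
      expect_identical(inst_types, src_types)
    }
  }
})

test_that("augmentation is deterministic in the seed", {
  cfg <- synth_config(n_sentences = 15, seed = 4)
  corpus <- make_toy_corpus(cfg)
  kg <- make_toy_kg(corpus, cfg)
  a1 <- augment_corpus(corpus, kg, n_max = 9, seed = 77)
  a2 <- augment_corpus(corpus, kg, n_max = 9, seed = 77)
  expect_identical(a1, a2)

  # when combinations exceed the cap, the sampled subset depends on the seed
  kg2 <- kg_new(tibble::tibble(
    head = rep(c("alpha", "beta"), each = 4), relation = "SY",
    tail = paste(rep(c("alpha", "beta"), each = 4), "nb", rep(1:4, 2))
  ))
  s <- sent(c("alpha", "and", "beta"), c("B-D", "O", "B-D"))
  surf <- function(x) sort(sapply(x, function(a) paste(a$sentence$tokens,
                                                       collapse = " ")))
  i1 <- generate_instances(s, kg2, n_max = 9, seed = 1) # 24 combinations
  i2 <- generate_instances(s, kg2, n_max = 9, seed = 2)
  expect_length(i1, 9)
  expect_identical(surf(i1),
                   surf(generate_instances(s, kg2, n_max = 9, seed = 1)))
  expect_false(identical(surf(i1), surf(i2)))
})
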