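test_that("load_kg parses KG-TSV, dedups edges and upper-cases relations", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# comment",
    "aniridia\tpar\tcongenital anterior segment disorders\tT047\tT047",
    "aniridia\tCHD\taniridia of left eye\tT047\tT047",
    "aniridia\tCHD\taniridia of left eye\tT047\tT047"
  ), tf)
  kg <- load_kg(tf)
  expect_equal(length(kg$nodes), 3)
  expect_equal(nrow(kg$edges), 2)
  expect_setequal(kg$edges$relation, c("PAR", "CHD"))
  expect_equal(kg$semtypes[["aniridia"]], "T047")
})

test_that("load_kg on an empty file gives an empty graph", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), tf)
  kg <- load_kg(tf)
  expect_equal(length(kg$nodes), 0)
  expect_equal(nrow(kg$edges), 0)
})

test_that("load_kg reports malformed lines by number", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tSY\tb\t\t", "too\tfew"), tf)
  expect_error(load_kg(tf), "line 2")
})

test_that("write_kg round-trips through load_kg", {
  kg <- toy_kg()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_kg(kg, tf)
  back <- load_kg(tf)
  expect_equal(back$nodes, kg$nodes)
  expect_equal(dplyr::arrange(back$edges, head, relation, tail),
               dplyr::arrange(kg$edges, head, relation, tail))
  expect_equal(back$semtypes, kg$semtypes)
})

test_that("matcher finds entity and non-entity candidates case-insensitively", {
  kg <- toy_kg()
  s <- sent(c("Hypertension", "was", "reported"), c("B-Disease", "O", "O"))
  m <- match_candidates(s, kg)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 1L)
  expect_true(m$is_entity)
  expect_equal(m$gold_type, "Disease")

  s2 <- sent(c("increased", "intracellular", "calcium"))
  m2 <- match_candidates(s2, kg)
  expect_equal(m2$concept, "intracellular")
  expect_false(m2$is_entity)
  expect_true(is.na(m2$gold_type))
})

test_that("matcher returns empty for sentences with no KG tokens", {
  m <- match_candidates(sent(c("no", "graph", "words")), toy_kg())
  expect_equal(nrow(m), 0)
})

test_that("longest match wins over a shorter prefix concept", {
  kg <- kg_new(tibble::tibble(
    head = c("copper", "copper toxicosis"), relation = "SY",
    tail = c("cu", "copper storage disease")
  ))
  m <- match_candidates(sent(c("copper", "toxicosis", "locus")), kg)
  expect_equal(nrow(m), 1)
  expect_equal(m$concept, "copper toxicosis")
  expect_equal(c(m$start, m$end), c(0L, 2L))
})

test_that("candidates partially overlapping a gold entity are dropped", {
  kg <- kg_new(tibble::tibble(head = "copper", relation = "SY", tail = "cu"))
  s <- sent(c("copper", "toxicosis"), c("B-Disease", "I-Disease"))
  expect_equal(nrow(match_candidates(s, kg)), 0)
})

test_that("matches are disjoint and sorted across random sentences", {
  kg <- toy_kg()
  vocab <- c("hypertension", "aniridia", "intracellular", "filler", "words", "more")
  set.seed(41)
  for (rep in 1:25) {
    toks <- sample(vocab, sample(3:12, 1), replace = TRUE)
    m <- match_candidates(sent(toks), kg)
    if (nrow(m) < 2) next
    expect_true(all(diff(m$start) > 0))
    expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
  }
})

test_that("sub-graph keeps only the six whitelisted relations", {
  sg <- build_subgraph(toy_kg(), "aniridia")
  expect_equal(sg$k, 2)
  expect_false("RO" %in% sg$neighbors$relation)
  expect_true(all(sg$neighbors$relation %in% KG_RELATIONS))
  # deterministic lexicographic order: relation then target
  expect_equal(sg$neighbors$relation, c("CHD", "PAR"))
  expect_equal(sg$neighbors$target[1], "aniridia of left eye")
})

test_that("sub-graph of an isolated concept is empty and unknown centers error", {
  kg <- kg_new(tibble::tibble(head = "a", relation = "SY", tail = "b"),
               semtypes = list(c = "T1"))
  expect_equal(build_subgraph(kg, "c")$k, 0)
  expect_error(build_subgraph(kg, "zzz"), "not in graph")
})

test_that("semantic-type gating filters neighbours without shared types", {
  kg <- kg_new(
    tibble::tibble(head = c("x", "x"), relation = "SY", tail = c("y", "z")),
    semtypes = list(x = "T1", y = "T1", z = "T2")
  )
  expect_equal(build_subgraph(kg, "x")$k, 2)
  gated <- build_subgraph(kg, "x", require_semtype_overlap = TRUE)
  expect_equal(gated$neighbors$target, "y")
})

test_that("sub-graph construction is deterministic and whitelist-safe on random graphs", {
  set.seed(7)
  rels <- c(KG_RELATIONS, "RO", "AQ", "SIB")
  for (rep in 1:20) {
    nodes <- paste0("c", 1:8)
    e <- tibble::tibble(
      head = sample(nodes, 15, replace = TRUE),
      relation = sample(rels, 15, replace = TRUE),
      tail = sample(nodes, 15, replace = TRUE)
    )
    kg <- kg_new(e[e$head != e$tail, ])
    for (ctr in kg$nodes) {
      sg1 <- build_subgraph(kg, ctr)
      sg2 <- build_subgraph(kg, ctr)
      expect_identical(sg1$neighbors, sg2$neighbors)
      expect_true(all(sg1$neighbors$relation %in% KG_RELATIONS))
      expect_false(ctr %in% sg1$neighbors$target)
      expect_equal(sg1$k, nrow(sg1$neighbors))
    }
  }
})
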