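#' Sample a K-shot support set
#'
#' Sentence-level downsampling with entity-type coverage: first one sentence is
#' drawn per entity type (uniformly among sentences containing it), then the
#' set is filled uniformly without replacement up to `k` sentences. The dev and
#' test corpora are never touched; evaluation runs on the full test set.
#'
#' @param corpus Training corpus tibble.
#' @param k Number of sentences to sample (`k >= length(types)`).
#' @param types Entity types that must each occur in at least one sampled
#'   sentence; defaults to the types present in the corpus.
#' @param seed Integer seed; the draw is deterministic in
#'   `(corpus order, k, seed)`.
#' @return A `fewner_support`: corpus tibble of the sampled sentences
#'   (renumbered) with attributes `k`, `seed` and `source_ids`.
#' @export
sample_support <- function(corpus, k, types = NULL, seed = 1L) {
  check_corpus(corpus)
  sents <- corpus_sentences(corpus)
  if (is.null(types)) types <- corpus_types(corpus)
  if (!is_count(k, 1L)) abort("k must be a count >= 1")
  if (k > length(sents)) abort(sprintf("k = %d exceeds corpus size %d", k, length(sents)))
  if (k < length(types)) abort("k must be at least the number of entity types")
  has_type <- lapply(sents, function(s) unique(decode_bio(s$tags)$type))
  for (ty in types) {
    if (!any(vapply(has_type, function(h) ty %in% h, logical(1)))) {
      abort(paste0("entity type absent from corpus: ", ty))
    }
  }
  chosen <- with_seed(seed, {
    picked <- integer()
    for (ty in sort(types)) {
      if (any(vapply(picked, function(i) ty %in% has_type[[i]], logical(1)))) next
      pool <- setdiff(which(vapply(has_type, function(h) ty %in% h, logical(1))),
                      picked)
      picked <- c(picked, sample_vec(pool, 1L))
    }
    fill <- setdiff(seq_along(sents), picked)
    if (length(picked) < k) picked <- c(picked, sample_vec(fill, k - length(picked)))
    sort(picked)
  })
  out <- sentences_corpus(sents[chosen])
  attr(out, "k") <- as.integer(k)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "source_ids") <- chosen
  class(out) <- c("fewner_support", class(out))
  out
}

#' Repeated K-shot sampling over seeds
#'
#' One support set per seed (default five seeds), mirroring the protocol of
#' repeated downsampling with different random seeds and reporting mean and
#' standard deviation across the runs.
#'
#' @inheritParams sample_support
#' @param seeds Integer vector of seeds.
#' @return List of `fewner_support` tibbles, one per seed.
#' @export
repeated_samples <- function(corpus, k, types = NULL, seeds = 1:5) {
  if (!length(seeds)) abort("seeds must be non-empty")
  if (anyDuplicated(seeds)) warn("duplicate seeds: identical support sets will be drawn")
  lapply(seeds, function(s) sample_support(corpus, k, types, seed = s))
}

#' Write a support set with its manifest
#'
#' Writes the support sentences as CoNLL-BIO next to a JSON manifest recording
#' the seed, k and a checksum of the source corpus, sufficient to reproduce the
#' draw.
#'
#' @param support A `fewner_support`.
#' @param path Output CoNLL path; the manifest is written to
#'   `paste0(path, ".manifest.json")`.
#' @param source_path Optional path of the source corpus to checksum.
#' @return `path`, invisibly.
#' @export
write_support <- function(support, path, source_path = NULL) {
  write_conll(support, path)
  manifest <- list(
    k = attr(support, "k"), seed = attr(support, "seed"),
    source_ids = attr(support, "source_ids"),
    source_checksum = if (!is.null(source_path)) {
      unname(tools::md5sum(source_path))
    } else NULL,
    written = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}
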