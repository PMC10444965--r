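#' Decode a BIO tag sequence into typed entity spans
#'
#' Maximal `B-T (I-T)*` runs become spans. An `I-T` that does not continue a
#' same-type run is repaired as `B-T` (the conlleval-compatible dialect); `O`
#' breaks runs. Spans use 0-based, half-open token indices.
#'
#' @param tags Character vector of BIO tags.
#' @param repair_orphan_i Treat an orphan `I-T` as `B-T` (default) instead of
#'   raising an error.
#' @return Tibble with columns `start`, `end`, `type`.
#' @export
#' @examples
#' decode_bio(c("B-Disease", "I-Disease", "O", "B-Disease"))
decode_bio <- function(tags, repair_orphan_i = TRUE) {
  bad <- tags != "O" & !grepl("^[BI]-.+$", tags)
  if (any(bad)) abort(sprintf("unknown BIO tag '%s'", tags[which(bad)[1]]))
  starts <- integer(); ends <- integer(); types <- character()
  cur_type <- NA_character_; cur_start <- NA_integer_
  close_run <- function(i) {
    if (!is.na(cur_type)) {
      starts[[length(starts) + 1L]] <<- cur_start
      ends[[length(ends) + 1L]] <<- i - 1L
      types[[length(types) + 1L]] <<- cur_type
    }
    cur_type <<- NA_character_
  }
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (t == "O") { close_run(i); next }
    type <- substring(t, 3)
    if (startsWith(t, "B-")) {
      close_run(i)
      cur_type <- type; cur_start <- i - 1L
    } else { # I-
      if (!is.na(cur_type) && cur_type == type) next
      if (!repair_orphan_i) abort(sprintf("orphan '%s' at position %d", t, i))
      close_run(i)
      cur_type <- type; cur_start <- i - 1L
    }
  }
  close_run(length(tags) + 1L)
  tibble(start = starts, end = ends, type = types)
}

#' Encode typed spans as a BIO tag sequence
#'
#' Inverse of [decode_bio()] for non-overlapping span sets.
#'
#' @param spans Tibble with `start`, `end`, `type` (0-based, half-open).
#' @param n Sentence length in tokens.
#' @return Character vector of `n` BIO tags.
#' @export
encode_bio <- function(spans, n) {
  tags <- rep("O", n)
  if (!nrow(spans)) return(tags)
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i] + 1L; e <- spans$end[i]
    tags[s] <- paste0("B-", spans$type[i])
    if (e > s) tags[(s + 1L):e] <- paste0("I-", spans$type[i])
  }
  tags
}

#' Merge per-type span predictions
#'
#' Each entity-type prompt view yields its own span list; the merged prediction
#' is their union, with overlapping spans of different types resolved by higher
#' mean token probability, ties broken towards the longer span, then the
#' earlier start.
#'
#' @param per_type_spans Named list (by entity type) of tibbles with `start`,
#'   `end` and optionally `mean_prob`.
#' @return Tibble with `start`, `end`, `type`, `mean_prob`, sorted by start.
#' @export
merge_predictions <- function(per_type_spans) {
  all <- purrr::imap(per_type_spans, function(sp, ty) {
    sp <- as_tibble(sp)
    if (!nrow(sp)) return(tibble(start = integer(), end = integer(),
                                 type = character(), mean_prob = double()))
    if (is.null(sp$mean_prob)) sp$mean_prob <- 1
    sp$type <- ty
    sp[, c("start", "end", "type", "mean_prob")]
  }) %>% dplyr::bind_rows()
  if (!nrow(all)) return(all)
  # preference order: prob desc, length desc, start asc
  ord <- order(-all$mean_prob, -(all$end - all$start), all$start)
  all <- all[ord, ]
  kept <- all[0, ]
  for (i in seq_len(nrow(all))) {
    cand <- all[i, ]
    if (!nrow(kept) || !any(kept$start < cand$end & cand$start < kept$end)) {
      kept <- dplyr::bind_rows(kept, cand)
    }
  }
  kept %>% arrange(.data$start, .data$end)
}

#' Entity-level micro-averaged precision, recall and F1
#'
#' A predicted span is a true positive iff its `(start, end, type)` triple
#' exactly matches a gold span. Counts are pooled over all sentences before
#' computing percentages; zero denominators give 0.
#'
#' @param gold,pred Lists (one element per sentence) of span tibbles with
#'   `start`, `end`, `type`.
#' @return One-row tibble: `precision`, `recall`, `f1` (percent), `tp`, `fp`,
#'   `fn`.
#' @export
micro_prf <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    abort("gold and pred must have the same number of sentences")
  }
  tp <- fp <- fn <- 0L
  key <- function(sp) if (nrow(sp)) paste(sp$start, sp$end, sp$type) else character()
  for (i in seq_along(gold)) {
    g <- key(as_tibble(gold[[i]])); p <- key(as_tibble(pred[[i]]))
    m <- sum(!is.na(match(p, g)))
    tp <- tp + m
    fp <- fp + length(p) - m
    fn <- fn + length(g) - m
  }
  prf_from_counts(tp, fp, fn)
}

prf_from_counts <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble(precision = p, recall = r, f1 = f, tp = tp, fp = fp, fn = fn)
}

#' Aggregate metrics across seeded runs
#'
#' Arithmetic mean and sample (n-1) standard deviation of precision, recall and
#' F1 across runs; a single run gets standard deviation 0 by convention.
#'
#' @param metrics A tibble of per-run metrics (rows = runs) as returned by
#'   [micro_prf()], or a list of such one-row tibbles.
#' @return One-row tibble: `n_runs`, `mean_f1`, `sd_f1`, `mean_precision`,
#'   `sd_precision`, `mean_recall`, `sd_recall`.
#' @export
aggregate_runs <- function(metrics) {
  if (is.list(metrics) && !is.data.frame(metrics)) {
    metrics <- dplyr::bind_rows(metrics)
  }
  if (!nrow(metrics)) abort("no runs to aggregate")
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  tibble(
    n_runs = nrow(metrics),
    mean_f1 = mean(metrics$f1), sd_f1 = sd0(metrics$f1),
    mean_precision = mean(metrics$precision), sd_precision = sd0(metrics$precision),
    mean_recall = mean(metrics$recall), sd_recall = sd0(metrics$recall)
  )
}
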