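# Shared fixtures, built in code.

toy_kg <- function() {
  kg_new(
    tibble::tribble(
      ~head,          ~relation, ~tail,
      "hypertension", "SY",      "hypertensive disease",
      "hypertension", "PAR",     "vascular diseases",
      "aniridia",     "PAR",     "congenital anterior segment disorders",
      "aniridia",     "CHD",     "aniridia of left eye",
      "aniridia",     "RO",      "pax6 related phenotype", # outside whitelist
      "myalgias",     "SY",      "neuromuscular pain",
      "intracellular", "SY",     "intracellular space"
    ),
    semtypes = list(
      "hypertension" = "T047", "hypertensive disease" = "T047",
      "vascular diseases" = "T047",
      "aniridia" = "T047", "congenital anterior segment disorders" = "T047",
      "aniridia of left eye" = "T047", "pax6 related phenotype" = "T047",
      "myalgias" = "T184", "neuromuscular pain" = "T184",
      "intracellular" = "T082", "intracellular space" = "T082"
    )
  )
}

sent <- function(tokens, tags = NULL) {
  if (is.null(tags)) tags <- rep("O", length(tokens))
  list(tokens = tokens, tags = tags)
}

one_sentence_corpus <- function(tokens, tags) {
  tibble::tibble(sentence_id = 1L, token = tokens, tag = tags)
}

# Independent loop-based evaluation of the Jensen-Shannon bound: one pair at a
# time, naive softplus, no matrix batching. Deliberately distinct from the
# package's vectorized path.
mi_oracle <- function(Hp, He, Hc, disc, span_groups = NULL) {
  sp <- function(x) log(1 + exp(x))
  score1 <- function(a, b) {
    z <- c(a, b, a * b)
    h <- numeric(ncol(disc$Dw1))
    for (j in seq_len(ncol(disc$Dw1))) {
      h[j] <- tanh(sum(z * disc$Dw1[, j]) + disc$Db1[1, j])
    }
    sum(h * disc$Dw2[, 1]) + disc$Db2[1, 1]
  }
  p <- numeric(ncol(Hp))
  for (j in seq_len(ncol(Hp))) p[j] <- mean(Hp[, j])
  neg <- numeric(nrow(Hc))
  for (i in seq_len(nrow(Hc))) neg[i] <- sp(score1(p, Hc[i, ]))
  if (nrow(He) == 0) return(-mean(neg))
  if (is.null(span_groups)) span_groups <- as.list(seq_len(nrow(He)))
  pos <- numeric(length(span_groups))
  for (i in seq_along(span_groups)) {
    u <- colMeans(He[span_groups[[i]], , drop = FALSE])
    pos[i] <- -sp(-score1(p, u))
  }
  mean(pos) - mean(neg)
}

# All-pairs exact-match scorer, independent of micro_prf's key-based matching.
prf_oracle <- function(gold, pred) {
  tp <- 0L; n_gold <- 0L; n_pred <- 0L
  for (i in seq_along(gold)) {
    g <- gold[[i]]; p <- pred[[i]]
    n_gold <- n_gold + nrow(g); n_pred <- n_pred + nrow(p)
    used <- rep(FALSE, nrow(g))
    for (a in seq_len(nrow(p))) {
      for (b in seq_len(nrow(g))) {
        if (!used[b] && p$start[a] == g$start[b] && p$end[a] == g$end[b] &&
            p$type[a] == g$type[b]) {
          tp <- tp + 1L; used[b] <- TRUE; break
        }
      }
    }
  }
  prec <- if (n_pred) 100 * tp / n_pred else 0
  rec <- if (n_gold) 100 * tp / n_gold else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}

random_span_set <- function(n_sent = 5, max_len = 12) {
  lapply(seq_len(n_sent), function(i) {
    n <- sample(0:3, 1)
    if (n == 0) {
      return(tibble::tibble(start = integer(), end = integer(), type = character()))
    }
    starts <- sort(sample(0:(max_len - 2), n))
    tibble::tibble(
      start = starts,
      end = pmin(starts + sample(1:2, n, replace = TRUE), max_len),
      type = sample(c("Disease", "Gene"), n, replace = TRUE)
    )
  })
}

random_disc <- function(d, hidden = 4) {
  list(Dw1 = matrix(rnorm(3 * d * hidden, sd = 0.5), 3 * d, hidden),
       Db1 = matrix(rnorm(hidden, sd = 0.2), 1, hidden),
       Dw2 = matrix(rnorm(hidden, sd = 0.5), hidden, 1),
       Db2 = matrix(rnorm(1, sd = 0.2), 1, 1))
}

legal_bio_tags <- function(tags) {
  df <- tibble::tibble(sentence_id = 1L, token = as.character(seq_along(tags)),
                       tag = tags)
  tryCatch({ validate_bio(df); TRUE }, error = function(e) FALSE)
}
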