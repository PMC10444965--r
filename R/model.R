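#' Configuration for a few-shot NER run
#'
#' Collects every tunable of the pipeline with its default. Defaults follow the
#' standard protocol for this framework: at most 9 generated instances per
#' sentence, 20 training epochs, loss weight `lambda = 0.5`, five resampling
#' seeds, and a question-style prompt.
#'
#' @param entity_types Character vector of entity-type labels.
#' @param d Encoder width (hidden dimension).
#' @param layers Number of self-attention blocks in the desk-scale encoder.
#' @param hidden Feed-forward / head hidden width.
#' @param disc_hidden Hidden width of the MI discriminator.
#' @param epochs Training epochs.
#' @param lambda Weight of the cross-entropy term in the joint loss, in `[0,1]`.
#' @param n_max Per-sentence augmentation cap.
#' @param k Support-set size in sentences.
#' @param seeds Integer seeds for repeated downsampling.
#' @param lr Peak AdamW learning rate.
#' @param warmup_frac Fraction of steps under linear warmup before linear decay.
#' @param weight_decay Decoupled weight decay.
#' @param batch_size Views per optimizer step.
#' @param max_pieces Encoder position limit.
#' @param prompt_style `"question"` or `"label"`.
#' @param tokenizer A tokenizer object (see [whitespace_tokenizer()]).
#' @param use_pcl Compute the prompt contrastive term (`FALSE` gives the plain
#'   cross-entropy code path).
#' @param seed Master seed for parameter init, prompt example draws and
#'   shuffling.
#' @return A list of class `fewner_config`.
#' @export
fewner_config <- function(entity_types = "Disease", d = 64, layers = 2,
                          hidden = 64, disc_hidden = 32, epochs = 20,
                          lambda = 0.5, n_max = 9, k = 5, seeds = 1:5,
                          lr = 0.01, warmup_frac = 0.1, weight_decay = 0.01,
                          batch_size = 2, max_pieces = 128,
                          prompt_style = c("question", "label"),
                          tokenizer = whitespace_tokenizer(),
                          use_pcl = TRUE, seed = 1L) {
  if (!(is.numeric(lambda) && lambda >= 0 && lambda <= 1)) {
    abort("lambda must be in [0, 1]")
  }
  if (!is_count(k, 1L)) abort("k must be a count >= 1")
  structure(list(
    entity_types = entity_types, d = d, layers = layers, hidden = hidden,
    disc_hidden = disc_hidden, epochs = epochs, lambda = lambda, n_max = n_max,
    k = k, seeds = as.integer(seeds), lr = lr, warmup_frac = warmup_frac,
    weight_decay = weight_decay, batch_size = batch_size,
    max_pieces = max_pieces, prompt_style = match.arg(prompt_style),
    tokenizer = tokenizer, use_pcl = use_pcl, seed = as.integer(seed)
  ), class = "fewner_config")
}

# --- parameters --------------------------------------------------------------

rnorm_mat <- function(r, c, sd) matrix(stats::rnorm(r * c, sd = sd), r, c)

xavier <- function(r, c) rnorm_mat(r, c, sqrt(2 / (r + c)))

init_params <- function(vocab_size, cfg, seed) {
  d <- cfg$d; h <- cfg$hidden
  with_seed(seed, {
    ps <- list(
      emb = rnorm_mat(vocab_size, d, 0.05),
      pos = rnorm_mat(cfg$max_pieces, d, 0.05)
    )
    for (l in seq_len(cfg$layers)) {
      ps[[paste0("Wq", l)]] <- xavier(d, d)
      ps[[paste0("Wk", l)]] <- xavier(d, d)
      ps[[paste0("Wv", l)]] <- xavier(d, d)
      ps[[paste0("Wo", l)]] <- xavier(d, d) * 0.5 # damp residual branch at init
      ps[[paste0("F1", l)]] <- xavier(d, h)
      ps[[paste0("f1", l)]] <- matrix(0, 1, h)
      ps[[paste0("F2", l)]] <- xavier(h, d) * 0.5
      ps[[paste0("f2", l)]] <- matrix(0, 1, d)
    }
    ps$Hw1 <- xavier(d, h); ps$Hb1 <- matrix(0, 1, h)
    ps$Hw2 <- xavier(h, 3); ps$Hb2 <- matrix(0, 1, 3)
    dd <- disc_init(d, cfg$disc_hidden, init = "normal", seed = derive_seed(seed, 99L))
    ps[names(dd)] <- dd
    ps
  })
}

#' Initialize an MI discriminator
#'
#' The discriminator scores a (prompt vector, feature vector) pair by a small
#' MLP on the concatenation `[a; b; a*b]` with one tanh hidden layer. Zero
#' initialization makes the scorer identically zero, which is the closed-form
#' reference point of the Jensen-Shannon bound (both softplus terms equal
#' `log 2`).
#'
#' @param d Feature dimension.
#' @param hidden Hidden width.
#' @param init `"zero"` or `"normal"`.
#' @param seed Seed for normal init.
#' @return Named list of parameter matrices `Dw1`, `Db1`, `Dw2`, `Db2`.
#' @export
disc_init <- function(d, hidden = 32, init = c("zero", "normal"), seed = 1L) {
  init <- match.arg(init)
  if (init == "zero") {
    list(Dw1 = matrix(0, 3 * d, hidden), Db1 = matrix(0, 1, hidden),
         Dw2 = matrix(0, hidden, 1), Db2 = matrix(0, 1, 1))
  } else {
    with_seed(seed, list(
      Dw1 = xavier(3 * d, hidden), Db1 = matrix(0, 1, hidden),
      Dw2 = xavier(hidden, 1), Db2 = matrix(0, 1, 1)
    ))
  }
}

# Numeric discriminator scores for a batch of feature rows against one prompt
# vector. p: length-d vector; U: k x d matrix. Returns length-k vector.
disc_score <- function(disc, p, U) {
  U <- as_mat(U)
  P <- matrix(p, nrow(U), length(p), byrow = TRUE)
  Z <- cbind(P, U, P * U)
  H <- tanh(sweep(Z %*% disc$Dw1, 2, as.vector(disc$Db1), "+"))
  as.vector(H %*% disc$Dw2 + as.vector(disc$Db2))
}

# --- vocabulary --------------------------------------------------------------

build_vocab <- function(piece_lists) {
  pieces <- sort(unique(unlist(piece_lists, use.names = FALSE)))
  c("[UNK]", pieces)
}

piece_ids <- function(pieces, vocab) {
  ids <- match(pieces, vocab)
  ids[is.na(ids)] <- 1L
  ids
}

# --- encoder forward (tape) --------------------------------------------------

# psn: list of ad_param nodes; ids: integer piece ids. Returns node H
# (pieces x d) after `layers` blocks of single-head self-attention + FFN with
# residual connections (no layer norm; the desk-scale encoder is shallow enough
# without it).
encoder_forward <- function(psn, ids, cfg) {
  H <- ad_add(ad_rows(psn$emb, ids), ad_rows(psn$pos, seq_along(ids)))
  for (l in seq_len(cfg$layers)) {
    Q <- ad_mm(H, psn[[paste0("Wq", l)]])
    K <- ad_mm(H, psn[[paste0("Wk", l)]])
    V <- ad_mm(H, psn[[paste0("Wv", l)]])
    A <- ad_rowsoftmax(ad_scale(ad_mm_nt(Q, K), 1 / sqrt(cfg$d)))
    H <- ad_add(H, ad_mm(ad_mm(A, V), psn[[paste0("Wo", l)]]))
    FF <- ad_affine(ad_relu(ad_affine(H, psn[[paste0("F1", l)]],
                                      psn[[paste0("f1", l)]])),
                    psn[[paste0("F2", l)]], psn[[paste0("f2", l)]])
    H <- ad_add(H, FF)
  }
  H
}

head_logits <- function(psn, Hx) {
  ad_affine(ad_tanh(ad_affine(Hx, psn$Hw1, psn$Hb1)), psn$Hw2, psn$Hb2)
}

#' Encode a model input into sequence and prompt representations
#'
#' Runs the trained (or freshly initialized) encoder over the assembled
#' `[CLS] X [SEP] Q [SEP]` pieces and returns the final-layer contextual
#' representations of the sentence (`Hx`, n x d) and of the prompt (`Hp`,
#' m x d); special tokens are excluded from both.
#'
#' @param input A `fewner_input` from [assemble_input()].
#' @param model A fitted `fewner_model`, or any list with `params`, `vocab`
#'   and `config`.
#' @return List with numeric matrices `Hx` and `Hp`.
#' @export
encode <- function(input, model) {
  if (!length(input$sequence_region)) abort("empty sequence region")
  psn <- lapply(model$params, ad_param)
  ids <- piece_ids(input$pieces, model$vocab)
  H <- encoder_forward(psn, ids, model$config)
  list(Hx = H$value[input$sequence_region, , drop = FALSE],
       Hp = H$value[input$prompt_region, , drop = FALSE])
}

# --- classification head (numeric surface) -----------------------------------

#' BIO classification probabilities for a sequence representation
#'
#' Applies the classification head — an affine transform followed by a one-
#' hidden-layer MLP and a row softmax — to each sub-token representation,
#' yielding a probability distribution over the per-prompt tag set
#' `{O, B, I}` (3 tags for a single queried type).
#'
#' @param Hx Numeric n x d matrix of sequence representations.
#' @param head Named list with `Hw1` (d x h), `Hb1` (1 x h), `Hw2` (h x L),
#'   `Hb2` (1 x L).
#' @return n x L matrix; every row is non-negative and sums to 1.
#' @export
classify <- function(Hx, head) {
  Hx <- as_mat(Hx)
  A <- tanh(sweep(Hx %*% head$Hw1, 2, as.vector(head$Hb1), "+"))
  Z <- sweep(A %*% head$Hw2, 2, as.vector(head$Hb2), "+")
  if (any(!is.finite(Z))) abort("non-finite logits in classification head")
  Zs <- Z - apply(Z, 1, max)
  E <- exp(Zs)
  E / rowSums(E)
}

# --- positive / negative feature split ---------------------------------------

#' Split sequence features into entity (positive) and context (negative) rows
#'
#' Uses the position mask implied by the gold spans of the queried type: a
#' sub-token is positive iff its source word lies inside any gold span
#' (continuation sub-tokens follow their word); all other sequence sub-tokens
#' are negative context.
#'
#' @param Hx Numeric n x d sequence representation.
#' @param gold_spans Tibble of word-level spans (`start`, `end`, 0-based
#'   half-open) of the queried type.
#' @param alignment Integer vector: source word index of each sequence
#'   sub-token (1-based words).
#' @return List of class `fewner_split`: `He` (e x d), `Hc` (c x d), `e`, `c`,
#'   and `span_groups` — for each gold span, the row indices of `He` pooled for
#'   that span.
#' @export
split_by_mask <- function(Hx, gold_spans, alignment) {
  Hx <- as_mat(Hx)
  n <- nrow(Hx)
  if (length(alignment) != n) abort("alignment must cover every sequence row")
  pos_idx <- integer()
  span_groups <- list()
  if (nrow(gold_spans)) {
    for (i in seq_len(nrow(gold_spans))) {
      words <- (gold_spans$start[i] + 1L):gold_spans$end[i]
      rows <- which(alignment %in% words)
      if (!length(rows)) next
      span_groups[[length(span_groups) + 1L]] <-
        seq.int(length(pos_idx) + 1L, length(pos_idx) + length(rows))
      pos_idx <- c(pos_idx, rows)
    }
  }
  neg_idx <- setdiff(seq_len(n), pos_idx)
  structure(list(
    He = Hx[pos_idx, , drop = FALSE], Hc = Hx[neg_idx, , drop = FALSE],
    e = length(pos_idx), c = length(neg_idx),
    pos_idx = pos_idx, neg_idx = neg_idx, span_groups = span_groups
  ), class = "fewner_split")
}

# --- Jensen-Shannon MI lower bound -------------------------------------------

#' Jensen-Shannon mutual-information lower bound
#'
#' Estimates a lower bound on the mutual information between the question
#' prompt and the entity answer:
#' `I = E_pos[-sp(-T(p, u))] - E_neg[sp(T(p, v))]`,
#' where `sp` is the softplus, `T` the discriminator, `p` the mean-pooled
#' prompt vector, positive units `u` are mean-pooled per gold entity span and
#' negative units `v` are individual context rows. Both terms are non-positive
#' contributions, so the bound is always `<= 0`, with maximum 0 at perfect
#' discrimination. When there are no positives (`e = 0`) only the negative
#' term is returned.
#'
#' @param Hp Numeric m x d prompt representation.
#' @param He Numeric e x d positive rows (entity sub-tokens).
#' @param Hc Numeric c x d negative rows (context sub-tokens), `c >= 1`.
#' @param disc Discriminator parameters from [disc_init()].
#' @param span_groups List of row-index vectors of `He` to pool per entity
#'   span; defaults to one span per row.
#' @return A single numeric value.
#' @export
mi_lower_bound <- function(Hp, He, Hc, disc, span_groups = NULL) {
  Hp <- as_mat(Hp); He <- as_mat(He); Hc <- as_mat(Hc)
  e <- nrow(He); cc <- nrow(Hc)
  if (e == 0 && cc == 0) abort("nothing to contrast: no positives and no negatives")
  if (cc == 0) abort("at least one negative row is required")
  p <- colMeans(Hp)
  neg_term <- mean(softplus_num(disc_score(disc, p, Hc)))
  if (e == 0) return(-neg_term)
  if (is.null(span_groups)) span_groups <- as.list(seq_len(e))
  U <- do.call(rbind, lapply(span_groups, function(g) colMeans(He[g, , drop = FALSE])))
  pos_term <- mean(-softplus_num(-disc_score(disc, p, U)))
  pos_term - neg_term
}

#' Fit the MI discriminator on fixed features
#'
#' Maximizes the Jensen-Shannon lower bound with respect to the discriminator
#' parameters only, holding the prompt and feature representations fixed.
#' Mainly a diagnostic: on separable features (positives near the prompt
#' vector, negatives far) the bound rises above its initial value, while on
#' independently paired features it cannot.
#'
#' @param Hp,He,Hc,span_groups As in [mi_lower_bound()].
#' @param disc Initial discriminator parameters.
#' @param steps Gradient-ascent steps.
#' @param lr Learning rate (plain Adam, no weight decay).
#' @return List with `disc` (updated parameters) and `trajectory` (the bound
#'   after each step).
#' @export
fit_discriminator <- function(Hp, He, Hc, disc, span_groups = NULL,
                              steps = 50, lr = 0.05) {
  Hp <- as_mat(Hp); He <- as_mat(He); Hc <- as_mat(Hc)
  if (is.null(span_groups)) span_groups <- as.list(seq_len(nrow(He)))
  p <- matrix(colMeans(Hp), 1)
  U <- do.call(rbind, lapply(span_groups, function(g) {
    colMeans(He[g, , drop = FALSE])
  }))
  opt <- adamw_new(disc, lr, 0, warmup_steps = 1L, total_steps = steps * 2L)
  traj <- numeric(steps)
  for (t in seq_len(steps)) {
    psn <- lapply(disc, ad_param)
    pbar <- ad_const(p)
    pos <- mi_side_node(psn, pbar, ad_const(U), positive = TRUE)
    neg <- mi_side_node(psn, pbar, ad_const(Hc), positive = FALSE)
    bound <- ad_sub(pos, neg)
    loss <- ad_neg(bound)
    ad_backward(loss)
    st <- adamw_step(opt, disc, lapply(psn, function(n) n$grad))
    opt <- st$opt; disc <- st$params
    traj[t] <- bound$value
  }
  list(disc = disc, trajectory = traj)
}

#' Prompt contrastive loss over a batch
#'
#' The negated batch mean of the Jensen-Shannon MI lower-bound terms. Since
#' each term is `<= 0` the loss is `>= 0`; minimizing it maximizes the bound.
#'
#' @param batch_terms Numeric vector of per-sentence MI lower-bound values.
#' @return A single non-negative numeric value.
#' @export
prompt_contrastive_loss <- function(batch_terms) {
  if (!length(batch_terms)) abort("empty batch")
  -mean(batch_terms)
}

#' Token-level cross-entropy loss
#'
#' Mean negative log-probability of the gold tags over non-ignored positions.
#'
#' @param probs n x L probability matrix from [classify()].
#' @param gold Integer vector of gold tag indices (1-based columns of `probs`),
#'   with `NA` marking ignored positions (sub-token continuations).
#' @return A single non-negative numeric value.
#' @export
cross_entropy_loss <- function(probs, gold) {
  probs <- as_mat(probs)
  if (length(gold) != nrow(probs)) abort("probs and gold lengths differ")
  keep <- which(!is.na(gold))
  if (!length(keep)) abort("all positions ignored")
  -mean(log(probs[cbind(keep, gold[keep])]))
}

#' Joint training objective
#'
#' `Lfinal = lambda * Lce + (1 - lambda) * Lpcl`.
#'
#' @param Lce Cross-entropy loss.
#' @param Lpcl Prompt contrastive loss.
#' @param lambda Weight in `[0, 1]` (default 0.5).
#' @return One-row tibble (`Lce`, `Lpcl`, `lambda`, `Lfinal`) of class
#'   `fewner_loss`.
#' @export
joint_loss <- function(Lce, Lpcl, lambda = 0.5) {
  if (!(is.numeric(lambda) && length(lambda) == 1 && lambda >= 0 && lambda <= 1)) {
    abort("lambda must be in [0, 1]")
  }
  out <- tibble(Lce = Lce, Lpcl = Lpcl, lambda = lambda,
                Lfinal = lambda * Lce + (1 - lambda) * Lpcl)
  class(out) <- c("fewner_loss", class(out))
  out
}

# Map projected BIO tags of one type onto head column ids: O=1, B=2, I=3.
tags_to_ids <- function(tags, entity_type) {
  ids <- match(tags, c("O", paste0("B-", entity_type), paste0("I-", entity_type)))
  if (any(is.na(ids) & !is.na(tags))) {
    abort("tags must be projected to the queried type before id mapping")
  }
  ids
}
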