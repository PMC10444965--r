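# One (sentence, prompt) view: the assembled input, target tag ids per piece,
# and the positive/negative piece split for the queried type.
prepare_view <- function(sentence, type, prompt, cfg) {
  input <- assemble_input(sentence, prompt, cfg$tokenizer, cfg$max_pieces)
  proj <- project_labels(input$piece_labels[!is.na(input$piece_labels)], type)
  # piece-level targets: first sub-token gets the projected word tag, rest NA
  targets <- rep(NA_integer_, length(input$word_alignment))
  first <- !is.na(input$piece_labels)
  targets[first] <- tags_to_ids(proj, type)
  word_tags <- proj # one per kept word
  gold_spans <- decode_bio(word_tags)
  split <- split_by_mask(matrix(0, length(input$word_alignment), 1),
                         gold_spans, input$word_alignment)
  list(input = input, targets = targets, type = type,
       gold_spans = gold_spans,
       pos_idx = split$pos_idx, neg_idx = split$neg_idx,
       span_groups = split$span_groups)
}

# Tape loss terms for one view. Returns list(ce = node, mi = node or NULL).
view_loss_nodes <- function(psn, view, vocab, cfg) {
  ids <- piece_ids(view$input$pieces, vocab)
  H <- encoder_forward(psn, ids, cfg)
  Hx <- ad_rows(H, view$input$sequence_region)
  Hp <- ad_rows(H, view$input$prompt_region)
  logits <- head_logits(psn, Hx)
  if (any(!is.finite(logits$value))) abort("non-finite logits during training")
  ce <- ad_cross_entropy(logits, view$targets)
  mi <- NULL
  if (cfg$use_pcl && length(view$neg_idx) >= 1) {
    pbar <- ad_mean_rows(Hp, seq_along(view$input$prompt_region))
    neg <- mi_side_node(psn, pbar, ad_rows(Hx, view$neg_idx), positive = FALSE)
    if (length(view$span_groups)) {
      units <- lapply(view$span_groups, function(g) {
        ad_mean_rows(Hx, view$pos_idx[g])
      })
      pos <- mi_side_node(psn, pbar, ad_rbind(units), positive = TRUE)
      mi <- ad_sub(pos, neg)
    } else {
      mi <- ad_neg(neg) # no entities: only the negative term
    }
  }
  list(ce = ce, mi = mi)
}

# Tape version of one side of the JS bound. positive: mean(-sp(-T)) returned
# WITHOUT its sign flip (caller composes pos - neg); here we return
# mean(-sp(-T)) for positive=TRUE and mean(sp(T)) for positive=FALSE.
mi_side_node <- function(psn, pbar, U, positive) {
  k <- nrow(U$value)
  P <- ad_rep_rows(pbar, k)
  Z <- ad_cbind(P, U, ad_mul(P, U))
  s <- ad_affine(ad_tanh(ad_affine(Z, psn$Dw1, psn$Db1)), psn$Dw2, psn$Db2)
  if (positive) ad_neg(ad_mean_all(ad_softplus(ad_neg(s))))
  else ad_mean_all(ad_softplus(s))
}

ad_mean_list <- function(nodes) {
  ad_scale(Reduce(ad_add, nodes), 1 / length(nodes))
}

# --- AdamW with linear warmup-decay ------------------------------------------

adamw_new <- function(params, lr, weight_decay, warmup_steps, total_steps,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(
    m = lapply(params, function(p) p * 0), v = lapply(params, function(p) p * 0),
    t = 0L, lr = lr, wd = weight_decay, b1 = beta1, b2 = beta2, eps = eps,
    warmup = max(1L, warmup_steps), total = max(2L, total_steps)
  )
}

adamw_lr <- function(opt) {
  t <- opt$t
  if (t <= opt$warmup) return(opt$lr * t / opt$warmup)
  frac <- (opt$total - t) / max(1L, opt$total - opt$warmup)
  opt$lr * max(0, frac)
}

adamw_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  lr_t <- adamw_lr(opt)
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- params[[nm]] * 0
    opt$m[[nm]] <- opt$b1 * opt$m[[nm]] + (1 - opt$b1) * g
    opt$v[[nm]] <- opt$b2 * opt$v[[nm]] + (1 - opt$b2) * g^2
    mhat <- opt$m[[nm]] / (1 - opt$b1^opt$t)
    vhat <- opt$v[[nm]] / (1 - opt$b2^opt$t)
    decay <- if (nm %in% c("emb", "pos") || nrow(params[[nm]]) == 1) 0 else opt$wd
    params[[nm]] <- params[[nm]] - lr_t * (mhat / (sqrt(vhat) + opt$eps) +
                                             decay * params[[nm]])
  }
  list(opt = opt, params = params)
}

# --- training ----------------------------------------------------------------

#' Train the prompt-based few-shot NER model
#'
#' Trains the desk-scale encoder, BIO classification head and MI discriminator
#' jointly on a (typically augmented) support corpus. For every
#' (sentence, entity-type prompt) view the loss is
#' `lambda * Lce + (1 - lambda) * Lpcl`, optimized by AdamW under a linear
#' warmup-decay schedule. All randomness is derived from `config$seed`. The
#' state with the best dev F1 (training F1 when `dev` is `NULL`) is retained.
#'
#' @param support Support corpus tibble (already augmented, if desired).
#' @param dev Optional dev corpus tibble for model selection.
#' @param config A [fewner_config()].
#' @return A `fewner_model`: list with `params` (best state), `final_params`,
#'   `vocab`, `config`, `prompts`, and `metrics` (per-epoch tibble with losses,
#'   mean MI bound and F1 scores).
#' @export
train_model <- function(support, dev = NULL, config = fewner_config()) {
  check_corpus(support)
  cfg <- config
  sents <- corpus_sentences(support)
  if (!length(sents)) abort("support corpus is empty")

  surfaces <- gold_surfaces(support)
  prompts <- list()
  for (i in seq_along(cfg$entity_types)) {
    ty <- cfg$entity_types[i]
    pool <- surfaces$surface[surfaces$type == ty]
    prompts[[ty]] <- if (cfg$prompt_style == "label" || !length(pool)) {
      build_label_prompt(ty)
    } else {
      build_prompt(ty, pool, seed = derive_seed(cfg$seed, 1000L + i))
    }
  }

  views <- list()
  for (s in sents) {
    for (ty in cfg$entity_types) {
      views[[length(views) + 1L]] <- prepare_view(s, ty, prompts[[ty]], cfg)
    }
  }

  vocab <- build_vocab(c(lapply(views, function(v) v$input$pieces)))
  params <- init_params(length(vocab), cfg, seed = derive_seed(cfg$seed, 7L))

  model <- structure(list(params = params, final_params = params, vocab = vocab,
                          config = cfg, prompts = prompts,
                          metrics = tibble()), class = "fewner_model")
  if (cfg$epochs == 0) return(model)

  steps_per_epoch <- ceiling(length(views) / cfg$batch_size)
  total_steps <- steps_per_epoch * cfg$epochs
  opt <- adamw_new(params, cfg$lr, cfg$weight_decay,
                   warmup_steps = ceiling(cfg$warmup_frac * total_steps),
                   total_steps = total_steps)

  best_f1 <- -Inf
  best_params <- params
  logs <- list()
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 2000L + epoch),
                     sample.int(length(views)))
    ep_ce <- ep_pcl <- ep_final <- c()
    ep_mi <- c()
    for (b in seq_len(steps_per_epoch)) {
      take <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size,
                                                       length(views))]
      psn <- lapply(params, ad_param)
      terms <- lapply(views[take], function(v) view_loss_nodes(psn, v, vocab, cfg))
      ce_nodes <- lapply(terms, `[[`, "ce")
      mi_nodes <- Filter(Negate(is.null), lapply(terms, `[[`, "mi"))
      Lce <- ad_mean_list(ce_nodes)
      if (length(mi_nodes)) {
        Lpcl <- ad_neg(ad_mean_list(mi_nodes))
        Lfinal <- ad_add(ad_scale(Lce, cfg$lambda), ad_scale(Lpcl, 1 - cfg$lambda))
      } else {
        Lpcl <- NULL
        Lfinal <- ad_scale(Lce, if (cfg$use_pcl) cfg$lambda else 1)
      }
      if (!is.finite(Lfinal$value)) {
        abort(sprintf("training diverged at epoch %d step %d (non-finite loss)",
                      epoch, b))
      }
      ad_backward(Lfinal)
      grads <- lapply(psn, function(n) n$grad)
      st <- adamw_step(opt, params, grads)
      opt <- st$opt; params <- st$params
      ep_ce <- c(ep_ce, Lce$value)
      ep_pcl <- c(ep_pcl, if (is.null(Lpcl)) NA_real_ else Lpcl$value)
      ep_final <- c(ep_final, Lfinal$value)
      ep_mi <- c(ep_mi, vapply(mi_nodes, function(n) as.numeric(n$value), 0))
    }
    model$params <- params
    train_f1 <- evaluate_model(model, support)$f1
    dev_f1 <- if (is.null(dev)) NA_real_ else evaluate_model(model, dev)$f1
    select_f1 <- if (is.null(dev)) train_f1 else dev_f1
    if (select_f1 >= best_f1) { # >= keeps the latest best under plateaus
      best_f1 <- select_f1
      best_params <- params
    }
    logs[[epoch]] <- tibble(
      epoch = epoch, loss = mean(ep_final), ce = mean(ep_ce),
      pcl = mean(ep_pcl, na.rm = TRUE),
      mean_mi = if (length(ep_mi)) mean(ep_mi) else NA_real_,
      train_f1 = train_f1, dev_f1 = dev_f1
    )
  }
  model$params <- best_params
  model$final_params <- params
  model$metrics <- dplyr::bind_rows(logs)
  model
}

#' @export
print.fewner_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<fewner model: %d parameters, vocab %d, %d epoch(s) trained>\n",
              np, length(x$vocab), nrow(x$metrics)))
  invisible(x)
}

# Mean MI lower bound of a model over the views of a corpus (diagnostic).
mean_mi_bound <- function(model, corpus) {
  cfg <- model$config
  disc <- model$params[c("Dw1", "Db1", "Dw2", "Db2")]
  vals <- c()
  for (s in corpus_sentences(corpus)) {
    for (ty in cfg$entity_types) {
      v <- prepare_view(s, ty, model$prompts[[ty]], cfg)
      enc <- encode(v$input, model)
      sp <- split_by_mask(enc$Hx, v$gold_spans, v$input$word_alignment)
      if (sp$c == 0) next
      vals <- c(vals, mi_lower_bound(enc$Hp, sp$He, sp$Hc, disc, sp$span_groups))
    }
  }
  mean(vals)
}

# --- prediction --------------------------------------------------------------

#' Predict entity spans on a corpus
#'
#' Runs one prompt view per configured entity type over each sentence, decodes
#' the per-view BIO predictions (taken at the first sub-token of each word)
#' into spans, and merges the per-type span lists.
#'
#' @param object A fitted `fewner_model`.
#' @param corpus A corpus tibble (tags are ignored for prediction).
#' @param ... Unused.
#' @return Tibble with `sentence_id`, `start`, `end`, `type`, `mean_prob`.
#' @export
predict.fewner_model <- function(object, corpus, ...) {
  check_corpus(corpus)
  cfg <- object$config
  head <- object$params[c("Hw1", "Hb1", "Hw2", "Hb2")]
  sents <- corpus_sentences(corpus)
  out <- list()
  for (i in seq_along(sents)) {
    s <- sents[[i]]
    per_type <- list()
    for (ty in cfg$entity_types) {
      v <- prepare_view(s, ty, object$prompts[[ty]], cfg)
      enc <- encode(v$input, object)
      probs <- classify(enc$Hx, head)
      first <- !is.na(v$input$piece_labels)
      wp <- probs[first, , drop = FALSE]
      tag_id <- max.col(wp)
      tags <- c("O", paste0("B-", ty), paste0("I-", ty))[tag_id]
      spans <- decode_bio(tags)
      if (nrow(spans)) {
        spans$mean_prob <- vapply(seq_len(nrow(spans)), function(j) {
          rows <- (spans$start[j] + 1):spans$end[j]
          mean(wp[cbind(rows, tag_id[rows])])
        }, 0)
      }
      per_type[[ty]] <- spans
    }
    merged <- merge_predictions(per_type)
    if (nrow(merged)) {
      merged$sentence_id <- s$sentence_id
      out[[length(out) + 1L]] <- merged
    }
  }
  if (!length(out)) {
    return(tibble(sentence_id = integer(), start = integer(), end = integer(),
                  type = character(), mean_prob = double()))
  }
  dplyr::bind_rows(out)[, c("sentence_id", "start", "end", "type", "mean_prob")]
}

#' Evaluate a model on a gold corpus
#'
#' @param model A fitted `fewner_model`.
#' @param corpus Gold corpus tibble.
#' @return One-row metrics tibble from [micro_prf()].
#' @export
evaluate_model <- function(model, corpus) {
  sents <- corpus_sentences(corpus)
  pred <- predict(model, corpus)
  gold <- lapply(sents, function(s) decode_bio(s$tags))
  pred_by <- lapply(sents, function(s) {
    p <- pred[pred$sentence_id == s$sentence_id, c("start", "end", "type")]
    p
  })
  micro_prf(gold, pred_by)
}
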