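test_that("classification rows are probability vectors", {
  set.seed(2)
  d <- 8
  head <- list(Hw1 = matrix(rnorm(d * 6), d, 6), Hb1 = matrix(rnorm(6), 1),
               Hw2 = matrix(rnorm(18), 6, 3), Hb2 = matrix(rnorm(3), 1))
  P <- classify(matrix(rnorm(5 * d), 5, d), head)
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-6)
  expect_true(all(P >= 0))
})

test_that("a zero-weight head yields uniform class probabilities", {
  d <- 4
  head <- list(Hw1 = matrix(0, d, 3), Hb1 = matrix(0, 1, 3),
               Hw2 = matrix(0, 3, 3), Hb2 = matrix(0, 1, 3))
  P <- classify(matrix(rnorm(8), 2, d), head)
  expect_equal(P, matrix(1 / 3, 2, 3), tolerance = 1e-12)
})

test_that("classification matches an independent softmax computation", {
  Hx <- matrix(c(0.5, -1), 1, 2)
  head <- list(Hw1 = matrix(c(1, 0, 0, 1, 1, -1), 2, 3),
               Hb1 = matrix(c(0.1, 0, -0.2), 1),
               Hw2 = matrix(c(1, 0, 0, 0, 1, 0, -1, 0.5, 2), 3, 3),
               Hb2 = matrix(c(0, 0.3, 0), 1))
  # brute-force arithmetic with scalar loops
  a <- numeric(3)
  for (j in 1:3) a[j] <- tanh(sum(Hx * head$Hw1[, j]) + head$Hb1[1, j])
  z <- numeric(3)
  for (j in 1:3) z[j] <- sum(a * head$Hw2[, j]) + head$Hb2[1, j]
  expected <- exp(z) / sum(exp(z))
  expect_equal(as.vector(classify(Hx, head)), expected, tolerance = 1e-6)
})

test_that("non-finite hidden states are surfaced, not clipped", {
  d <- 2
  head <- list(Hw1 = matrix(Inf, d, 2), Hb1 = matrix(0, 1, 2),
               Hw2 = matrix(1, 2, 3), Hb2 = matrix(NaN, 1, 3))
  expect_error(classify(matrix(1, 1, d), head), "non-finite")
})

test_that("position-mask split separates entity and context sub-tokens", {
  # 5 words, words 3-4 are one gold span, each word split into 2 sub-tokens
  alignment <- rep(1:5, each = 2)
  Hx <- matrix(seq_len(10 * 3), 10, 3)
  spans <- tibble::tibble(start = 2L, end = 4L, type = "Disease")
  sp <- split_by_mask(Hx, spans, alignment)
  expect_equal(sp$e, 4)
  expect_equal(sp$c, 6)
  expect_equal(sp$He, Hx[5:8, ])
  expect_length(sp$span_groups, 1)
  expect_equal(sp$span_groups[[1]], 1:4)
  # no entities
  sp0 <- split_by_mask(Hx, spans[0, ], alignment)
  expect_equal(sp0$e, 0)
  expect_equal(sp0$c, 10)
  # span covering the whole sentence
  spall <- split_by_mask(Hx, tibble::tibble(start = 0L, end = 5L, type = "D"),
                         alignment)
  expect_equal(spall$c, 0)
})

test_that("zero-initialized scorer gives the closed-form bound -2 log 2", {
  set.seed(9)
  d0 <- disc_init(6, 8, init = "zero")
  val <- mi_lower_bound(matrix(rnorm(12), 2, 6), matrix(rnorm(6), 1, 6),
                        matrix(rnorm(18), 3, 6), d0)
  expect_equal(val, -2 * log(2), tolerance = 1e-9)
})

test_that("hand-built scorer with scores +1/-1 matches hand arithmetic", {
  # d = 1, hidden = 1: score = tanh(u) / tanh(1), so +1 for u=1, -1 for u=-1
  disc <- list(Dw1 = matrix(c(0, 1, 0), 3, 1), Db1 = matrix(0, 1, 1),
               Dw2 = matrix(1 / tanh(1), 1, 1), Db2 = matrix(0, 1, 1))
  val <- mi_lower_bound(Hp = matrix(0, 1, 1), He = matrix(1, 1, 1),
                        Hc = matrix(-1, 1, 1), disc = disc)
  expect_equal(val, -2 * log(1 + exp(-1)), tolerance = 1e-9)
})

test_that("with no positives only the negative term is returned", {
  d0 <- disc_init(3, 4, init = "zero")
  val <- mi_lower_bound(matrix(0, 1, 3), matrix(0, 0, 3), matrix(1, 1, 3), d0)
  expect_equal(val, -log(2), tolerance = 1e-12)
  expect_error(mi_lower_bound(matrix(0, 1, 3), matrix(0, 0, 3),
                              matrix(0, 0, 3), d0), "nothing to contrast")
})

test_that("the bound is never positive and matches the loop oracle", {
  set.seed(21)
  for (rep in 1:25) {
    d <- sample(2:6, 1)
    m <- sample(1:4, 1); e <- sample(0:4, 1); cc <- sample(1:5, 1)
    Hp <- matrix(rnorm(m * d, sd = 2), m, d)
    He <- matrix(rnorm(max(e, 1) * d, sd = 2), max(e, 1), d)[seq_len(e), , drop = FALSE]
    Hc <- matrix(rnorm(cc * d, sd = 2), cc, d)
    disc <- random_disc(d)
    groups <- if (e > 1 && runif(1) < 0.5) {
      split(seq_len(e), sample(1:2, e, replace = TRUE))
    } else NULL
    if (!is.null(groups)) groups <- Filter(length, groups)
    got <- mi_lower_bound(Hp, He, Hc, disc, span_groups = groups)
    expect_lte(got, 0)
    expect_equal(got, mi_oracle(Hp, He, Hc, disc, span_groups = groups),
                 tolerance = 1e-6)
  }
})

test_that("prompt contrastive loss is the negated batch mean", {
  expect_equal(prompt_contrastive_loss(-2 * log(2)), 2 * log(2), tolerance = 1e-12)
  expect_equal(prompt_contrastive_loss(c(-1, -3)), 2)
  expect_error(prompt_contrastive_loss(numeric()), "empty")
  # composition with the zero-scorer closed form
  d0 <- disc_init(2, 2, init = "zero")
  terms <- replicate(4, mi_lower_bound(matrix(0, 1, 2), matrix(1, 1, 2),
                                       matrix(1, 1, 2), d0))
  expect_equal(prompt_contrastive_loss(terms), 2 * log(2), tolerance = 1e-9)
})

test_that("cross-entropy hits its closed forms and a brute-force case", {
  perfect <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(cross_entropy_loss(perfect, c(1L, 2L)), 0)
  uniform <- matrix(1 / 3, 4, 3)
  expect_equal(cross_entropy_loss(uniform, c(1L, 3L, NA, 2L)), log(3),
               tolerance = 1e-12)
  probs <- rbind(c(0.7, 0.2, 0.1), c(0.25, 0.5, 0.25))
  expect_equal(cross_entropy_loss(probs, c(1L, 2L)),
               -(log(0.7) + log(0.5)) / 2, tolerance = 1e-6)
  expect_error(cross_entropy_loss(probs, c(NA, NA)), "ignored")
})

test_that("joint loss is the lambda mixture with validation", {
  expect_equal(joint_loss(2, 7, lambda = 1)$Lfinal, 2)
  expect_equal(joint_loss(2, 4, lambda = 0.5)$Lfinal, 3)
  expect_equal(joint_loss(1, 1)$lambda, 0.5) # default
  expect_error(joint_loss(1, 1, lambda = 1.2), "lambda")
  lb <- joint_loss(1.5, 0.25, lambda = 0.3)
  expect_equal(lb$Lfinal, 0.3 * 1.5 + 0.7 * 0.25, tolerance = 1e-12)
})

test_that("training the discriminator on separable features raises the bound", {
  set.seed(33)
  d <- 8
  p <- rnorm(d)
  Hp <- rbind(p, p + rnorm(d, sd = 0.01))
  He <- t(replicate(6, p + rnorm(d, sd = 0.05)))
  Hc <- t(replicate(10, -p + rnorm(d, sd = 0.5)))
  disc <- disc_init(d, 16, init = "normal", seed = 5)
  before <- mi_lower_bound(Hp, He, Hc, disc)
  fit <- fit_discriminator(Hp, He, Hc, disc, steps = 80, lr = 0.05)
  after <- mi_lower_bound(Hp, He, Hc, fit$disc)
  expect_gt(after, before)
  expect_gt(after, -2 * log(2)) # strictly better than the uninformed scorer
})

test_that("independent pairings yield no spurious mutual information", {
  set.seed(44)
  d <- 6
  draw <- function() list(
    Hp = matrix(rnorm(2 * d), 2, d),
    He = matrix(rnorm(4 * d), 4, d),
    Hc = matrix(rnorm(6 * d), 6, d)
  )
  disc <- disc_init(d, 8, init = "normal", seed = 2)
  eval_fresh <- function(dd) mean(replicate(30, {
    x <- draw()
    mi_lower_bound(x$Hp, x$He, x$Hc, dd)
  }))
  before <- eval_fresh(disc)
  # train under genuinely independent pairings: a fresh draw at every step,
  # so there is no dependence structure to pick up
  for (t in 1:60) {
    x <- draw()
    disc <- fit_discriminator(x$Hp, x$He, x$Hc, disc, steps = 1, lr = 0.05)$disc
  }
  after <- eval_fresh(disc)
  expect_lt(abs(after - before), 0.3)
  expect_lte(after, 0)
})

test_that("joint loss gradients reach both the head and the discriminator", {
  fw <- get("view_loss_nodes", envir = asNamespace("fewner"))
  prep <- get("prepare_view", envir = asNamespace("fewner"))
  cfg <- fewner_config(entity_types = "Disease", d = 8, hidden = 8,
                       disc_hidden = 4, max_pieces = 32, seed = 3)
  s <- sent(c("aniridia", "was", "found"), c("B-Disease", "O", "O"))
  view <- prep(s, "Disease", build_label_prompt("Disease"), cfg)
  vocab <- get("build_vocab", envir = asNamespace("fewner"))(list(view$input$pieces))
  params <- get("init_params", envir = asNamespace("fewner"))(length(vocab), cfg, 3L)
  psn <- lapply(params, get("ad_param", envir = asNamespace("fewner")))
  terms <- fw(psn, view, vocab, cfg)
  lam <- 0.5
  Lfinal <- fewner:::ad_add(fewner:::ad_scale(terms$ce, lam),
                            fewner:::ad_scale(fewner:::ad_neg(terms$mi), 1 - lam))
  fewner:::ad_backward(Lfinal)
  expect_gt(max(abs(psn$Hw2$grad)), 0)  # classification head
  expect_gt(max(abs(psn$Dw2$grad)), 0)  # discriminator
  expect_gt(max(abs(psn$emb$grad)), 0)  # encoder
})
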