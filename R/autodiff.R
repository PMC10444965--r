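# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every value on the tape is a matrix (scalars are 1x1). Nodes are environments
# carrying the forward value, their parents and a backward closure; backward()
# walks nodes in reverse creation order and accumulates gradients. This is the
# numerical core behind the trainable encoder, classification head and MI
# discriminator; it is gradient-checked against central finite differences in
# the test suite.

the <- new.env(parent = emptyenv())
the$ad_counter <- 0L

ad_node <- function(value, parents = list(), backfn = NULL) {
  # force parents (and thus their recursive construction) before taking an id,
  # so ids are a valid topological order despite R's lazy argument evaluation
  force(parents)
  force(value)
  the$ad_counter <- the$ad_counter + 1L
  e <- new.env(parent = emptyenv())
  e$id <- the$ad_counter
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  class(e) <- "ad_node"
  e
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1)
}

#' @noRd
ad_const <- function(x) ad_node(as_mat(x))

ad_param <- function(x) ad_node(as_mat(x))

ad_value <- function(n) n$value

# Reverse pass. `root` must be scalar (1x1).
ad_backward <- function(root) {
  stopifnot(length(root$value) == 1)
  nodes <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  for (n in nodes) n$grad <- NULL
  root$grad <- matrix(1, 1, 1)
  ord <- order(vapply(nodes, function(n) n$id, 0L), decreasing = TRUE)
  for (n in nodes[ord]) {
    if (is.null(n$backfn) || is.null(n$grad)) next
    gs <- n$backfn(n$grad)
    for (i in seq_along(n$parents)) {
      g <- gs[[i]]
      if (is.null(g)) next
      p <- n$parents[[i]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

# --- primitive ops -----------------------------------------------------------

ad_mm <- function(a, b) {
  ad_node(a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

# a %*% t(b)
ad_mm_nt <- function(a, b) {
  ad_node(a$value %*% t(b$value), list(a, b), function(g) {
    list(g %*% b$value, t(g) %*% a$value)
  })
}

ad_add <- function(a, b) {
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  ad_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

# add a 1 x k row vector to every row
ad_add_vec <- function(a, v) {
  ad_node(sweep(a$value, 2, as.vector(v$value), "+"), list(a, v), function(g) {
    list(g, matrix(colSums(g), 1))
  })
}

ad_mul <- function(a, b) {
  ad_node(a$value * b$value, list(a, b), function(g) {
    list(g * b$value, g * a$value)
  })
}

ad_scale <- function(a, s) {
  ad_node(a$value * s, list(a), function(g) list(g * s))
}

ad_tanh <- function(a) {
  v <- tanh(a$value)
  ad_node(v, list(a), function(g) list(g * (1 - v^2)))
}

ad_relu <- function(a) {
  v <- pmax(a$value, 0)
  ad_node(v, list(a), function(g) list(g * (a$value > 0)))
}

# log(1 + exp(x)), branch-stable at large |x|
softplus_num <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

ad_softplus <- function(a) {
  v <- softplus_num(a$value)
  ad_node(v, list(a), function(g) list(g * stats::plogis(a$value)))
}

ad_rowsoftmax <- function(a) {
  z <- a$value - apply(a$value, 1, max)
  e <- exp(z)
  v <- e / rowSums(e)
  ad_node(v, list(a), function(g) {
    list(v * (g - rowSums(g * v)))
  })
}

ad_rows <- function(a, idx) {
  ad_node(a$value[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$value), ncol(a$value))
    for (j in seq_along(idx)) out[idx[j], ] <- out[idx[j], ] + g[j, ]
    list(out)
  })
}

# mean of a row subset -> 1 x d
ad_mean_rows <- function(a, idx) {
  k <- length(idx)
  ad_node(matrix(colMeans(a$value[idx, , drop = FALSE]), 1), list(a), function(g) {
    out <- matrix(0, nrow(a$value), ncol(a$value))
    for (j in idx) out[j, ] <- out[j, ] + as.vector(g) / k
    list(out)
  })
}

# replicate a 1 x d row k times
ad_rep_rows <- function(a, k) {
  ad_node(matrix(a$value, k, ncol(a$value), byrow = TRUE), list(a), function(g) {
    list(matrix(colSums(g), 1))
  })
}

ad_cbind <- function(...) {
  args <- list(...)
  widths <- vapply(args, function(n) ncol(n$value), 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(do.call(cbind, lapply(args, ad_value)), args, function(g) {
    lapply(seq_along(args), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

ad_rbind <- function(nodes) {
  heights <- vapply(nodes, function(n) nrow(n$value), 0L)
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  ad_node(do.call(rbind, lapply(nodes, ad_value)), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

ad_mean_all <- function(a) {
  n <- length(a$value)
  ad_node(matrix(mean(a$value), 1, 1), list(a), function(g) {
    list(matrix(as.numeric(g) / n, nrow(a$value), ncol(a$value)))
  })
}

ad_sum_all <- function(a) {
  ad_node(matrix(sum(a$value), 1, 1), list(a), function(g) {
    list(matrix(as.numeric(g), nrow(a$value), ncol(a$value)))
  })
}

ad_neg <- function(a) ad_scale(a, -1)

ad_affine <- function(x, W, b) ad_add_vec(ad_mm(x, W), b)

# Mean negative log softmax probability of target classes; rows with NA target
# are ignored. logits: n x L node; targets: integer vector length n.
ad_cross_entropy <- function(logits, targets) {
  keep <- which(!is.na(targets))
  if (!length(keep)) abort("all positions are ignored; no cross-entropy signal")
  z <- logits$value
  zs <- z - apply(z, 1, max)
  logZ <- log(rowSums(exp(zs)))
  logp <- zs - logZ
  picked <- logp[cbind(keep, targets[keep])]
  val <- -mean(picked)
  ad_node(matrix(val, 1, 1), list(logits), function(g) {
    p <- exp(logp)
    d <- matrix(0, nrow(z), ncol(z))
    d[keep, ] <- p[keep, , drop = FALSE] / length(keep)
    d[cbind(keep, targets[keep])] <- d[cbind(keep, targets[keep])] - 1 / length(keep)
    list(d * as.numeric(g))
  })
}
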