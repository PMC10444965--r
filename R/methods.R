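#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-epoch training metrics
#'
#' @param x A `fewner_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `loss`, `ce`, `pcl`,
#'   `mean_mi`, `train_f1`, `dev_f1`.
#' @method tidy fewner_model
#' @export
tidy.fewner_model <- function(x, ...) {
  as_tibble(x$metrics)
}

#' One-row model summary
#'
#' @param x A `fewner_model`.
#' @param ... Unused.
#' @return Tibble with parameter count, vocabulary size, epochs trained, final
#'   loss and best F1 scores.
#' @method glance fewner_model
#' @export
glance.fewner_model <- function(x, ...) {
  m <- x$metrics
  tibble(
    n_params = sum(vapply(x$params, length, 0L)),
    vocab_size = length(x$vocab),
    epochs = nrow(m),
    final_loss = if (nrow(m)) m$loss[nrow(m)] else NA_real_,
    best_train_f1 = if (nrow(m)) max(m$train_f1) else NA_real_,
    best_dev_f1 = if (nrow(m) && !all(is.na(m$dev_f1))) {
      max(m$dev_f1, na.rm = TRUE)
    } else NA_real_,
    lambda = x$config$lambda
  )
}

#' Tidy per-seed run metrics
#'
#' @param x A `fewner_report`.
#' @param ... Unused.
#' @return Tibble of per-seed precision/recall/F1 and counts.
#' @method tidy fewner_report
#' @export
tidy.fewner_report <- function(x, ...) {
  as_tibble(x$per_seed)
}

#' One-row run summary (mean and sd across seeds)
#'
#' @param x A `fewner_report`.
#' @param ... Unused.
#' @return One-row tibble from [aggregate_runs()] plus `k`.
#' @method glance fewner_report
#' @export
glance.fewner_report <- function(x, ...) {
  out <- x$summary
  if (nrow(out)) out$k <- x$config$k
  out
}

#' Training-curve plot for a fitted model
#'
#' Loss components and entity-level F1 per epoch.
#'
#' @param object A `fewner_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fewner_model
#' @export
autoplot.fewner_model <- function(object, ...) {
  m <- tidy(object)
  if (!nrow(m)) abort("model has no training metrics (epochs = 0?)")
  long <- m %>%
    tidyr::pivot_longer(c("loss", "ce", "pcl", "train_f1", "dev_f1"),
                        names_to = "metric", values_to = "value") %>%
    dplyr::filter(!is.na(.data$value)) %>%
    mutate(panel = ifelse(.data$metric %in% c("train_f1", "dev_f1"),
                          "F1 (%)", "loss"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-seed F1 plot for a protocol run
#'
#' Per-seed F1 points with the mean and one standard deviation band.
#'
#' @param object A `fewner_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fewner_report
#' @export
autoplot.fewner_report <- function(object, ...) {
  d <- tidy(object) %>% dplyr::filter(.data$status == "ok")
  if (!nrow(d)) abort("no successful seeds to plot")
  s <- object$summary
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$seed), y = .data$f1)) +
    ggplot2::geom_hline(yintercept = s$mean_f1, linetype = 2) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = s$mean_f1 - s$sd_f1, ymax = s$mean_f1 + s$sd_f1,
                      alpha = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "seed", y = "entity-level F1 (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
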