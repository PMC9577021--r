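#' Plot a precision-recall curve
#'
#' @param object A `psgn_pr` tibble from [pr_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psgn_pr <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      title = "Precision-recall curve",
      subtitle = paste0("area = ", signif(attr(object, "area"), 4))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a jackknife curve
#'
#' @param object A `psgn_jackknife` tibble from [jackknife_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psgn_jackknife <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank,
                                       y = .data$true_positives)) +
    ggplot2::geom_step(color = "#b2182b") +
    ggplot2::labs(x = "Proteins ranked", y = "True essential proteins",
                  title = "Jackknife curve") +
    ggplot2::theme_minimal()
}

#' Plot vote frequencies from the classifier pipeline
#'
#' Histogram of positive-vote counts, split by true label, with the
#' candidate threshold marked.
#'
#' @param object A `psgn_freq` tibble from [frequency_pipeline()].
#' @param threshold Candidate cutoff to mark (default from the stored
#'   configuration).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psgn_freq <- function(object, threshold = NULL, ...) {
  if (is.null(threshold)) {
    cfg <- attr(object, "config")
    threshold <- if (!is.null(cfg)) cfg$frequency_threshold else 8
  }
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    class = factor(ifelse(.data$label == 1, "essential", "non-essential"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$positive_count,
                                   fill = .data$class)) +
    ggplot2::geom_histogram(binwidth = 1, position = "dodge",
                            boundary = -0.5) +
    ggplot2::geom_vline(xintercept = threshold + 0.5, linetype = "dashed") +
    ggplot2::labs(x = "Positive votes", y = "Proteins",
                  title = "Frequency voting", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot precision at the standard top-k cutoffs for several methods
#'
#' @param data A tibble with columns `method`, `k`, `precision` (e.g. built
#'   from [precision_at_k()] per method).
#' @return A ggplot object.
#' @export
plot_precision_at_k <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$k, y = .data$precision,
                                     color = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Top k", y = "Precision", color = NULL,
                  title = "Precision at top-k cutoffs") +
    ggplot2::theme_minimal()
}

#' Plot the training loss trace of a fitted bidirectional LSTM
#'
#' @param object A `psgn_bilstm` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psgn_bilstm <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$loss_trace),
                       loss = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "#4d9221") +
    ggplot2::labs(x = "Epoch", y = "Weighted cross-entropy",
                  title = "BiLSTM training loss") +
    ggplot2::theme_minimal()
}
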