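#' Shannon entropy of a label vector
#'
#' `-sum(p * log2(p))` over the observed classes, in bits, with the
#' convention `0 * log(0) = 0`.
#'
#' @param labels A non-empty categorical vector.
#' @return Entropy in bits.
#' @examples
#' entropy(c(1, 1, 0, 0)) # 1 bit
#' @export
entropy <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) {
    abort("`labels` must be non-empty.", class = "graftann_data_error")
  }
  p <- as.numeric(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Discretize a feature for entropy computations
#'
#' Continuous features are cut into equal-frequency bins (default 10) at the
#' unique empirical quantiles; categorical features and numerics with at
#' most `bins` distinct values are used as-is. Missing values form their own
#' category.
#'
#' @param x A feature vector.
#' @param bins Number of equal-frequency bins for continuous features.
#' @return A character vector of discrete values.
#' @export
discretize_feature <- function(x, bins = 10) {
  if (is.numeric(x) && length(unique(x[!is.na(x)])) > bins) {
    brk <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                           na.rm = TRUE, names = FALSE))
    if (length(brk) < 2L) {
      out <- rep("bin1", length(x))
    } else {
      out <- as.character(cut(x, breaks = brk, include.lowest = TRUE))
    }
  } else {
    out <- as.character(x)
  }
  out[is.na(out)] <- "(missing)"
  out
}

#' Information gain of a feature about the class labels
#'
#' The reduction in label entropy achieved by partitioning the records on
#' the feature's (discretized) values:
#' `IG = H(labels) - sum_v (n_v / n) * H(labels | feature = v)`, in bits.
#' A constant feature has gain 0; a feature identical to the labels has gain
#' `H(labels)`. Gains are non-negative up to floating-point round-off
#' (tiny negatives are clipped to zero).
#'
#' @param feature A feature vector, same length as `labels`.
#' @param labels The class labels.
#' @param bins Equal-frequency bin count for continuous features.
#' @return Information gain in bits.
#' @examples
#' information_gain(c("A", "A", "B", "B"), c(1, 1, 1, 0))
#' @export
information_gain <- function(feature, labels, bins = 10) {
  if (length(feature) != length(labels)) {
    abort("`feature` and `labels` must have equal length.",
          class = "graftann_data_error")
  }
  v <- discretize_feature(feature, bins = bins)
  n <- length(labels)
  h <- entropy(labels)
  cond <- sum(vapply(split(labels, v), function(y) length(y) / n * entropy(y),
                     numeric(1)))
  max(h - cond, 0)
}

#' Rank features by information gain
#'
#' @param data A data frame of candidate features (one column per feature).
#' @param labels Class labels, one per row of `data`.
#' @param bins Equal-frequency bin count for continuous features.
#' @return A tibble `(feature, gain)` sorted by descending gain, with class
#'   `feature_ranking` for plotting.
#' @export
feature_ranking <- function(data, labels, bins = 10) {
  gains <- vapply(data, information_gain, numeric(1),
                  labels = labels, bins = bins)
  out <- tibble(feature = names(gains), gain = unname(gains)) |>
    dplyr::arrange(dplyr::desc(.data$gain))
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Information-gain bar chart
#'
#' @param object A [feature_ranking()] tibble.
#' @param top_n Show at most this many features (default 30).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.feature_ranking <- function(object, top_n = 30, ...) {
  df <- head(as_tibble(object), top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature, .data$gain),
                                   y = .data$gain)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Information gain (bits)")
}
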