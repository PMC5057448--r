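#' Plot decoded category traces with true-presence shading
#'
#' One panel per category: the decoded probability over time in blue with
#' shaded spans where the category was actually present — the standard
#' visual check that high probabilities align with actual appearances.
#'
#' @param object A `decoded_matrix` from [decode()].
#' @param labels Optional validation [label_timecourse()] for the shading.
#' @param categories Categories to show (default: up to 4).
#' @param ... Unused.
#' @method autoplot decoded_matrix
#' @return A ggplot object.
#' @export
autoplot.decoded_matrix <- function(object, labels = NULL, categories = NULL, ...) {
  if (is.null(categories)) categories <- utils::head(object$categories, 4)
  df <- tibble::tibble(
    tr = rep(seq_len(nrow(object$values)) - 1L, length(categories)),
    category = rep(categories, each = nrow(object$values)),
    probability = as.vector(object$values[, categories])
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tr, y = .data$probability))
  if (!is.null(labels)) {
    shade <- purrr::map_dfr(categories, function(cat_id) {
      y <- labels$values[, cat_id]
      r <- rle(as.integer(y))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values == 1L
      tibble::tibble(category = cat_id, xmin = starts[keep] - 1L,
                     xmax = ends[keep] - 1L)
    })
    if (nrow(shade) > 0) {
      p <- p + ggplot2::geom_rect(
        data = shade,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
        ymin = -Inf, ymax = Inf, fill = "grey80", inherit.aes = FALSE
      )
    }
  }
  p +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~category, ncol = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "TR", y = "decoded probability") +
    ggplot2::theme_minimal()
}

#' Plot the per-timepoint log likelihood ratio trace
#'
#' LLR above zero means the decoder beats prior guessing at that TR;
#' significant TRs (permutation test) are highlighted.
#'
#' @param llr A tibble from [timepoint_llr()] or [llr_shuffle_null()].
#' @return A ggplot object.
#' @export
plot_llr_trace <- function(llr) {
  p <- ggplot2::ggplot(llr, ggplot2::aes(x = .data$tr, y = .data$llr)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "TR", y = "log likelihood ratio vs prior") +
    ggplot2::theme_minimal()
  if ("significant" %in% names(llr) && any(llr$significant)) {
    p <- p + ggplot2::geom_point(
      data = llr[llr$significant, ],
      color = "firebrick", size = 0.8
    )
  }
  p
}

#' Plot per-category AUC against the occurrence count
#'
#' @param ev The tibble from [evaluate_categories()].
#' @return A ggplot object.
#' @export
plot_category_auc <- function(ev) {
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$n_pos, y = .data$auc,
                                   color = .data$q_reject)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                name = "FDR significant") +
    ggplot2::labs(x = "validation positives", y = "AUC") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
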