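#' Score-rank plot of a drug score table
#'
#' Drugs ordered by Z-score, with known drugs and repositioning candidates
#' highlighted and the significance threshold drawn as a horizontal line.
#'
#' @param object A [score_drugs()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot drug_score_table
#' @export
autoplot.drug_score_table <- function(object, ...) {
  thr <- attr(object, "p_threshold") %||% 0.001
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    rank = dplyr::row_number(dplyr::desc(.data$z)),
    status = dplyr::case_when(
      .data$known ~ "known drug",
      .data$candidate ~ "novel candidate",
      TRUE ~ "background"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$z,
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_hline(yintercept = stats::qnorm(thr, lower.tail = FALSE),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(
      "background" = "grey65", "known drug" = "#1b9e77",
      "novel candidate" = "#d95f02"
    )) +
    ggplot2::labs(x = "drug rank", y = "Z-score", colour = NULL,
                  title = "Propagation scores by drug rank",
                  subtitle = sprintf("dashed line: p = %g (one-sided Gaussian)", thr)) +
    ggplot2::theme_minimal()
}

#' Distribution of propagated scores by node kind
#'
#' @param object A [propagate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot propagation_result
#' @export
autoplot.propagation_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score,
                                   fill = factor(.data$label))) +
    ggplot2::geom_histogram(bins = 40, position = "identity", alpha = 0.7) +
    ggplot2::facet_wrap(~ .data$kind, scales = "free") +
    ggplot2::scale_fill_manual(values = c("0" = "grey60", "1" = "#d95f02"),
                               name = "initial label") +
    ggplot2::labs(x = "propagated score", y = "nodes",
                  title = sprintf("Label propagation (alpha = %g)", object$alpha)) +
    ggplot2::theme_minimal()
}

#' Enrichment volcano plot
#'
#' Enrichment score against -log10 nominal p for one dataset's pathways.
#'
#' @param result An [enrich_dataset()] tibble.
#' @param p_threshold Significance line (default 0.01).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(result, p_threshold = 0.01) {
  ggplot2::ggplot(result, ggplot2::aes(x = .data$es, y = -log10(.data$p),
                                       colour = .data$p < p_threshold)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d95f02", `FALSE` = "grey65"),
                                 name = sprintf("p < %g", p_threshold)) +
    ggplot2::labs(x = "enrichment score", y = expression(-log[10](p)),
                  title = "Pathway enrichment") +
    ggplot2::theme_minimal()
}
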