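# ggplot2 displays for rankings and score breakdowns

#' Plot an entity ranking
#'
#' Horizontal bar chart of aggregate entity scores, colored by priority
#' group, best entity on top.
#'
#' @param object An `entrank_ranking` from [search_entities()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot entrank_ranking
#' @export
autoplot.entrank_ranking <- function(object, ...) {
  df <- tidy(object)
  df$name <- stats::reorder(df$name, df$score)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$name,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "aggregate entity score", y = NULL, fill = "group",
                  title = format_query(attr(object, "query"))) +
    ggplot2::theme_minimal()
}

#' Plot the per-document score components for a query
#'
#' Shows, for the top contributing documents, the four multiplicative
#' components (term match, entity-number penalty, journal reputation,
#' recency) side by side on a log scale; useful for understanding why a
#' document dominates a ranking.
#'
#' @param index An `entrank_index`.
#' @param query An `entrank_query` or query string.
#' @param weights,as_of Passed to [document_score()].
#' @param top_n How many documents (by combined score) to display.
#' @return A ggplot object.
#' @export
plot_score_components <- function(index, query, weights = score_weights(),
                                  as_of = NULL, top_n = 10) {
  comp <- document_score(index, query, weights = weights, as_of = as_of)
  comp <- utils::head(dplyr::arrange(comp, dplyr::desc(.data$score)), top_n)
  long <- tidyr::pivot_longer(
    dplyr::select(comp, "doc_id", `term match` = "term_score",
                  `entity number` = "entity_number",
                  reputation = "reputation", recency = "recency"),
    -"doc_id", names_to = "component", values_to = "value")
  long$doc_id <- factor(long$doc_id, levels = rev(comp$doc_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$doc_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~component, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = "component value", y = NULL) +
    ggplot2::theme_minimal()
}
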