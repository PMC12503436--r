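#' Plot strict-match metrics per type
#'
#' Grouped bars of precision, recall and F1 per type; the pooled `ALL`
#' row is drawn first.
#'
#' @param object A `ke_metrics` tibble from [evaluate_extraction()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ke_metrics <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(
      dplyr::all_of(c("precision", "recall", "f1")),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::mutate(
      type = factor(.data$type, levels = unique(object$type)),
      metric = factor(.data$metric, levels = c("precision", "recall", "f1"))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = 100 * .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "score (%)", fill = NULL,
      title = sprintf(
        "Strict-match %s extraction metrics (%s average)",
        attr(object, "level"), attr(object, "average")
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an entity-type confusion matrix
#'
#' Heatmap of gold type vs predicted type; counts are log1p-scaled for
#' fill so the dominant diagonal does not wash out rare confusions.
#'
#' @param object A `ke_confusion` tibble from [entity_confusion()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ke_confusion <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(
      gold_type = factor(.data$gold_type, levels = entity_types()),
      pred_type = factor(.data$pred_type, levels = entity_types())
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred_type, y = .data$gold_type,
                                   fill = log1p(.data$n))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      data = df[df$n > 0, ], ggplot2::aes(label = .data$n), size = 3
    ) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      x = "predicted type", y = "gold type", fill = "log(1+n)",
      title = "Entity type confusion"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot reward components for one sample
#'
#' @param object A `reward_breakdown` from [total_reward()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reward_breakdown <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(component = factor(.data$component, levels = .data$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue", na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "score",
      title = sprintf("Reward breakdown for %s", object$doc_id)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
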