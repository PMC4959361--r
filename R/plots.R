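#' @importFrom ggplot2 autoplot ggplot aes
#' @export
ggplot2::autoplot

#' Plot the score profile of a ranked list
#'
#' Column chart of scores for the top documents, in rank order.
#'
#' @param object A `ranked_list`.
#' @param top_n How many top documents to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ranked_list <- function(object, top_n = 20L, ...) {
  d <- utils::head(as_tibble(object), top_n)
  ggplot(d, aes(x = stats::reorder(.data$doc_id, .data$rank),
                y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL,
                  y = if (identical(attr(object, "scoring"), "rbo")) {
                    "RBO similarity"
                  } else {
                    "A-TF-IDF score"
                  },
                  title = sprintf("Top %d documents", nrow(d))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a k-profile's weighted-interest spectrum
#'
#' @param object A `k_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.k_profile <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = stats::reorder(.data$concept, .data$rank),
                y = .data$interest_w)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "weighted interest",
                  title = sprintf("k-profile (k = %d)", attr(object, "k")),
                  subtitle = "dashed line: independence baseline") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-round retrieval metrics of a simulated user
#'
#' Line plot of AP@10 / AP@20 across feedback rounds.
#'
#' @param object A `user_simulation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.user_simulation <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("ap10", "ap20"), names_to = "metric",
                        values_to = "ap")
  ggplot(d, aes(x = .data$round, y = .data$ap, colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(d$round)) +
    ggplot2::labs(x = "round (0 = initial search)", y = "average precision",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
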