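#' @importFrom ggplot2 ggplot aes geom_segment geom_point geom_tile geom_text
#'   geom_errorbar labs scale_fill_gradient theme_minimal
NULL

#' Plot a classification table
#'
#' Horizontal bars of each category's heterozygote-count interval,
#' annotated with its probability of correct classification.
#'
#' @param object A [classification_table()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot classification_table
#' @export
autoplot.classification_table <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$k_lo), ]
  df$category <- factor(df$category, levels = rev(object$category))
  ggplot(df, aes(y = .data$category)) +
    geom_segment(aes(x = .data$k_lo - 0.4, xend = .data$k_hi + 0.4,
                     yend = .data$category), linewidth = 3, colour = "steelblue") +
    geom_text(aes(x = .data$k_hi + 1.2,
                  label = sprintf("%.3f", .data$prob_correct)),
              hjust = 0, size = 3) +
    labs(x = "heterozygous markers (k)", y = NULL,
         title = sprintf("ML classification intervals, n = %d markers (%s)",
                         attr(object, "n"), attr(object, "scenario")),
         subtitle = "labels: probability of correct classification") +
    theme_minimal()
}

#' Plot an assignment confusion matrix
#'
#' @param object A [confusion_matrix()].
#' @param ... Ignored.
#' @return A ggplot heatmap, true category by assigned category.
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"true",
                              names_to = "assigned", values_to = "n")
  cats <- setdiff(names(object), "true")
  long$true <- factor(long$true, levels = rev(cats))
  long$assigned <- factor(long$assigned, levels = cats)
  ggplot(long, aes(x = .data$assigned, y = .data$true, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = ifelse(.data$n > 0, .data$n, "")), size = 3) +
    scale_fill_gradient(low = "white", high = "firebrick") +
    labs(x = "assigned category", y = "true category",
         title = paste0("Assignment confusion matrix (", attr(object, "method"), ")")) +
    theme_minimal()
}

#' Plot hybrid-index estimates
#'
#' Individuals ordered by estimated q with profile-likelihood intervals;
#' the expected gradient runs from pure B (q = 0) through F1 (q = 0.5) to
#' pure A (q = 1).
#'
#' @param estimates Output of [estimate_hybrid_index()].
#' @return A ggplot.
#' @export
plot_hybrid_index <- function(estimates) {
  df <- estimates[order(estimates$q), ]
  df$rank <- seq_len(nrow(df))
  ggplot(df, aes(x = .data$rank, y = .data$q, colour = .data$label)) +
    geom_errorbar(aes(ymin = .data$lower, ymax = .data$upper),
                  width = 0, alpha = 0.5) +
    geom_point(size = 1) +
    labs(x = "individual (ordered by q)",
         y = "hybrid index q (ancestry from population A)",
         colour = "category") +
    theme_minimal()
}
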