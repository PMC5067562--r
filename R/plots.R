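#' Plot total scores by subgroup
#'
#' Boxplots of total scores per rank-ordered subgroup with individual
#' subjects overlaid — the standard view of the performance gradient
#' across subgroups.
#'
#' @param object A [subgroup_assignment][stratify_cohort].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot subgroup_assignment
#' @export
autoplot.subgroup_assignment <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$subgroup <- factor(dat$subgroup)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$subgroup, y = .data$total,
                                    fill = .data$subgroup)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 0.6, alpha = 0.5) +
    ggplot2::labs(x = "subgroup (rank-ordered by mean total)",
                  y = "total score") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise effect-size grid
#'
#' Tile heatmap of Cohen's d for every subgroup pair, annotated with the
#' effect size and an asterisk for Bonferroni-significant cells.
#'
#' @param grid An [effect_grid][effect_size_grid].
#' @return A ggplot object.
#' @export
plot_effect_grid <- function(grid) {
  stopifnot(inherits(grid, "effect_grid"))
  dat <- tibble::as_tibble(grid)
  dat$label <- ifelse(dat$untestable, "n/a",
                      sprintf("%.2f%s", dat$cohens_d,
                              ifelse(dat$significant %in% TRUE, "*", "")))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$subgroup_b),
                                    y = factor(.data$subgroup_a),
                                    fill = .data$cohens_d)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  na.value = "grey85") +
    ggplot2::labs(x = "subgroup (B)", y = "subgroup (A)",
                  fill = "Cohen's d") +
    ggplot2::theme_minimal()
}

#' Item-difficulty profile lines
#'
#' Percent-correct per item for each subgroup, items ordered by overall
#' difficulty so the profiles read left (hardest) to right (easiest).
#'
#' @param profile A [difficulty_profile][item_difficulty].
#' @return A ggplot object.
#' @export
plot_difficulty_profiles <- function(profile) {
  stopifnot(inherits(profile, "difficulty_profile"))
  dat <- tibble::as_tibble(profile)
  item_order <- dat |>
    dplyr::group_by(.data$item) |>
    dplyr::summarise(overall = mean(.data$pct_correct), .groups = "drop") |>
    dplyr::arrange(.data$overall)
  dat$item <- factor(dat$item, levels = item_order$item)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$item, y = .data$pct_correct,
                                    colour = factor(.data$subgroup),
                                    group = factor(.data$subgroup))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "item (ordered by overall difficulty)",
                  y = "% correct", colour = "subgroup") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Heatmap of a cross-cohort dissimilarity matrix
#'
#' Subjects ordered by cohort and subgroup rank; block boundaries outline
#' each (cohort, subgroup) run so within- versus between-subgroup
#' similarity is visible at a glance.
#'
#' @param x A [cross_cohort_dissimilarity()] result.
#' @return A ggplot object.
#' @export
plot_dissimilarity_matrix <- function(x) {
  stopifnot(inherits(x, "cross_cohort_dissimilarity"))
  n <- nrow(x$d)
  dat <- tibble::tibble(
    row = rep(seq_len(n), times = n),
    col = rep(seq_len(n), each = n),
    value = as.vector(x$d)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$col, y = .data$row,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::geom_rect(
      data = x$blocks,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                   ymin = .data$start - 0.5, ymax = .data$end + 0.5),
      inherit.aes = FALSE, fill = NA, colour = "black", linewidth = 0.3
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Hamming\ndistance") +
    ggplot2::theme_minimal()
}

#' Null distribution of a permutation test
#'
#' Histogram of the permuted-label accuracies with the observed accuracy
#' marked.
#'
#' @param object A [permutation_result][permutation_test].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot permutation_result
#' @export
autoplot.permutation_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$null_accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "#B2182B",
                        linewidth = 1) +
    ggplot2::labs(
      x = "classification accuracy under permuted labels",
      y = "count",
      subtitle = sprintf("observed %.3f, p = %.4g", object$observed,
                         object$p_value)
    ) +
    ggplot2::theme_minimal()
}
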