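#' @import ggplot2
NULL

#' Sequence-aggregation heatmap
#'
#' Position-by-substitution heatmap of solubility scores: blue for
#' aggregation-promoting substitutions, red for solubilising ones, dots at
#' each position's wild-type residue, and grey for unmeasured cells.
#'
#' @param mat A [score_matrix()] (or a `score_table`, converted
#'   internally).
#' @return A ggplot object.
#' @export
plot_score_heatmap <- function(mat) {
  if (inherits(mat, "data.frame")) mat <- score_matrix(mat)
  long <- matrix_to_tibble(mat) |>
    mutate(mut_aa = factor(.data$mut_aa, levels = rev(colnames(mat))))
  ggplot(long, aes(x = .data$position, y = .data$mut_aa, fill = .data$score)) +
    geom_tile(color = "grey85", linewidth = 0.1) +
    geom_point(data = filter(long, .data$is_wt), size = 0.6, shape = 16) +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         midpoint = 0, na.value = "grey92",
                         name = "solubility\nscore") +
    scale_x_continuous(breaks = seq(0, nrow(mat), by = 5), expand = c(0, 0)) +
    labs(x = "position", y = "mutant amino acid") +
    theme_minimal(base_size = 10) +
    theme(panel.grid = element_blank())
}

#' Per-position mean score profile
#'
#' Mean solubility score along the sequence for all, hydrophobic and polar
#' substitutions — the one-dimensional summary of the aggregation map.
#'
#' @param summaries Tibble from [position_summaries()].
#' @return A ggplot object.
#' @export
plot_position_profile <- function(summaries) {
  long <- summaries |>
    select("position", all = "mean_all", hydrophobic = "mean_hydrophobic",
           polar = "mean_polar") |>
    pivot_longer(-"position", names_to = "substitutions", values_to = "mean_score")
  ggplot(long, aes(x = .data$position, y = .data$mean_score,
                   color = .data$substitutions)) +
    geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    geom_line() +
    labs(x = "position", y = "mean solubility score") +
    theme_minimal(base_size = 10)
}

#' Replicate-against-replicate slope scatter
#'
#' @param scores A `score_table` from [score_variants()].
#' @param reps Length-2 integer vector: which replicates to plot.
#' @return A ggplot object annotated with the Pearson correlation.
#' @export
plot_replicate_scatter <- function(scores, reps = c(1, 2)) {
  a <- paste0("slope_rep", reps[1]); b <- paste0("slope_rep", reps[2])
  if (!all(c(a, b) %in% names(scores))) abort("requested replicates not present.")
  dat <- scores |> filter(.data$class != "WT", is.finite(.data[[a]]), is.finite(.data[[b]]))
  r <- stats::cor(dat[[a]], dat[[b]])
  ggplot(dat, aes(x = .data[[a]], y = .data[[b]])) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey60") +
    labs(x = paste("replicate", reps[1], "slope"),
         y = paste("replicate", reps[2], "slope"),
         subtitle = sprintf("Pearson R = %.2f (n = %d)", r, nrow(dat))) +
    theme_minimal(base_size = 10)
}

#' Score distributions of synonymous and missense variants
#'
#' Density of missense scores over the synonymous null, with the WT-like
#' interval marked — the classification picture.
#'
#' @param classified Output of [classify_variants()].
#' @return A ggplot object.
#' @export
plot_classification <- function(classified) {
  bounds <- attr(classified, "bounds")
  dat <- classified |>
    filter(.data$class %in% c("missense", "synonymous"), !is.na(.data$score))
  p <- ggplot(dat, aes(x = .data$score, fill = .data$class)) +
    geom_density(alpha = 0.4, color = NA) +
    labs(x = "solubility score", y = "density") +
    theme_minimal(base_size = 10)
  if (!is.null(bounds)) {
    p <- p + geom_vline(xintercept = bounds, linetype = 2, color = "grey40")
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.score_table <- function(object, ...) plot_score_heatmap(object)
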