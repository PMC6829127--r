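#' Read a deposited per-variant score table
#'
#' Loads a previously published / deposited score table (TSV with columns
#' `position`, `wt_aa`, `mut_aa`, `class`, `score`; extra columns are kept)
#' into the same shape [score_variants()] produces, so downstream
#' classification, mapping and comparison functions apply unchanged.
#'
#' @param path TSV path.
#' @return A `score_table` tibble.
#' @export
read_deposited_scores <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    position = readr::col_integer(), wt_aa = readr::col_character(),
    mut_aa = readr::col_character(), class = readr::col_character(),
    score = readr::col_double(), .default = readr::col_guess()
  ))
  if (!"variant" %in% names(x)) {
    x <- mutate(x, variant = variant_id(.data$wt_aa, .data$position, .data$mut_aa),
                .before = 1L)
  }
  class(x) <- c("score_table", class(x))
  x
}

#' Summary report for a score table under fixed classification cutoffs
#'
#' Applies published WT-like cutoffs to a score table and collects the
#' headline numbers of a scan in one row: missense class counts, score
#' range and central tendency, the median score of selected substitutions,
#' and optionally the mean score over a set of positions (e.g. the
#' top-solubility cluster).
#'
#' @param scores A `score_table` (computed or deposited).
#' @param bounds WT-like interval `c(lower, upper)`, inclusive.
#' @param median_of Residues whose per-substitution median score to report.
#' @param cluster_positions Optional integer positions over which to
#'   report the mean missense score.
#' @return One-row tibble: `n_scored`, `min`, `max`, `mean`, `median`,
#'   `n_aggregation_prone`, `n_wt_like`, `n_soluble`, one `median_<aa>`
#'   column per requested residue, and `cluster_mean` when positions are
#'   given.
#' @export
score_report <- function(scores, bounds = c(-0.26, 0.39),
                         median_of = c("D", "P", "W", "F"),
                         cluster_positions = NULL) {
  mis <- filter(scores, .data$class == "missense", !is.na(.data$score))
  cls <- classify_variants(mis, bounds = bounds)
  counts <- cls |> count(.data$solubility_class, .drop = FALSE)
  n_of <- function(lbl) sum(counts$n[counts$solubility_class == lbl])
  out <- tibble(
    n_scored = nrow(mis),
    min = min(mis$score), max = max(mis$score),
    mean = mean(mis$score), median = stats::median(mis$score),
    n_aggregation_prone = n_of("more_aggregation_prone"),
    n_wt_like = n_of("WT_like"),
    n_soluble = n_of("more_soluble")
  )
  for (aa in median_of) {
    out[[paste0("median_", aa)]] <-
      stats::median(mis$score[mis$mut_aa == aa], na.rm = TRUE)
  }
  if (!is.null(cluster_positions)) {
    out$cluster_mean <- mean(mis$score[mis$position %in% cluster_positions])
  }
  out
}
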