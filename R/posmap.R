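AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residues treated as hydrophobic throughout the package. Alanine is a
# member but is reported separately where noted, since small alanine often
# behaves unlike the bulky hydrophobics in aggregation data.
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W", "C")

.KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Kyte-Doolittle hydrophobicity of amino acids
#'
#' @param aa One-letter residue codes.
#' @return Numeric hydropathy index values (positive = hydrophobic).
#' @examples
#' hydrophobicity(c("I", "D"))
#' @export
hydrophobicity <- function(aa) unname(.KYTE_DOOLITTLE[aa])

#' Build the position-by-substitution score matrix
#'
#' Arranges amino-acid-level scores as a dense matrix with ORF positions
#' as rows and mutant residues as columns — the sequence-aggregation map.
#' The cell at a position's own wild-type residue is not a substitution
#' and is `NA` with the `"wt"` mask set; cells never measured are `NA`
#' with the `"missing"` mask set.
#'
#' @param scores A `score_table` tibble (aa-level missense rows are used).
#' @param n_positions Number of ORF codons (default: max position seen).
#' @param include_stop Add a `*` column for nonsense variants.
#' @return Numeric matrix (positions x residues) with attributes `wt_aa`
#'   (character vector per position), `wt` and `missing` (logical masks).
#' @export
score_matrix <- function(scores, n_positions = NULL, include_stop = FALSE) {
  rows <- scores |>
    filter(.data$class %in% c("missense", if (include_stop) "nonsense"),
           .data$position >= 1L)
  dup <- rows |> count(.data$position, .data$mut_aa) |> filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0("duplicate (position, mut_aa) rows, e.g. position ",
                 dup$position[1], " ", dup$mut_aa[1],
                 "; aggregate scores to amino-acid level first."))
  }
  if (is.null(n_positions)) n_positions <- max(rows$position)
  cols <- c(AA_ORDER, if (include_stop) "*")
  mat <- matrix(NA_real_, n_positions, length(cols),
                dimnames = list(seq_len(n_positions), cols))
  mat[cbind(rows$position, match(rows$mut_aa, cols))] <- rows$score
  wt_aa <- rep(NA_character_, n_positions)
  seen <- rows |> distinct(.data$position, .data$wt_aa)
  wt_aa[seen$position] <- seen$wt_aa
  wt_mask <- matrix(FALSE, n_positions, length(cols), dimnames = dimnames(mat))
  has_wt <- which(!is.na(wt_aa) & wt_aa %in% cols)
  wt_mask[cbind(has_wt, match(wt_aa[has_wt], cols))] <- TRUE
  missing_mask <- is.na(mat) & !wt_mask
  attr(mat, "wt_aa") <- wt_aa
  attr(mat, "wt") <- wt_mask
  attr(mat, "missing") <- missing_mask
  mat
}

#' Long (tidy) form of a score matrix
#'
#' @param mat Matrix from [score_matrix()].
#' @return Tibble: `position`, `mut_aa`, `score`, `is_wt`, `is_missing`.
#' @export
matrix_to_tibble <- function(mat) {
  wt <- attr(mat, "wt"); miss <- attr(mat, "missing")
  expand_grid(position = as.integer(rownames(mat)), mut_aa = colnames(mat)) |>
    mutate(score = mat[cbind(.data$position, match(.data$mut_aa, colnames(mat)))],
           is_wt = wt[cbind(.data$position, match(.data$mut_aa, colnames(mat)))],
           is_missing = miss[cbind(.data$position, match(.data$mut_aa, colnames(mat)))])
}

#' Per-position score summaries
#'
#' Mean solubility score at each position over all measured substitutions,
#' and separately over hydrophobic substitutions (A, V, L, I, M, F, W, C),
#' hydrophobic substitutions excluding alanine, and polar (non-hydrophobic)
#' substitutions. WT cells are never substitutions and are excluded.
#'
#' @param mat Matrix from [score_matrix()].
#' @return Tibble: `position`, `wt_aa`, `n_measured`, `mean_all`,
#'   `mean_hydrophobic`, `mean_hydrophobic_no_A`, `mean_polar`.
#' @export
position_summaries <- function(mat) {
  long <- matrix_to_tibble(mat) |> filter(!.data$is_wt, .data$mut_aa != "*")
  long |>
    group_by(.data$position) |>
    summarise(
      n_measured = sum(!is.na(.data$score)),
      mean_all = mean(.data$score, na.rm = TRUE),
      mean_hydrophobic = mean(.data$score[.data$mut_aa %in% HYDROPHOBIC_AA], na.rm = TRUE),
      mean_hydrophobic_no_A = mean(
        .data$score[.data$mut_aa %in% setdiff(HYDROPHOBIC_AA, "A")], na.rm = TRUE),
      mean_polar = mean(.data$score[!.data$mut_aa %in% HYDROPHOBIC_AA], na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(wt_aa = attr(mat, "wt_aa")[.data$position], .after = "position")
}

#' Per-amino-acid score summaries
#'
#' Median and mean score of each mutant residue across all positions where
#' it was measured (missing and WT cells excluded). Solubilising residues
#' (aspartate, proline) show high medians; aggregation-promoting residues
#' (tryptophan, phenylalanine) low ones.
#'
#' @param mat Matrix from [score_matrix()].
#' @return Tibble: `mut_aa`, `hydrophobic`, `n`, `median`, `mean`.
#' @export
aa_summaries <- function(mat) {
  matrix_to_tibble(mat) |>
    filter(!.data$is_wt) |>
    group_by(.data$mut_aa) |>
    summarise(
      hydrophobic = .data$mut_aa[1] %in% HYDROPHOBIC_AA,
      n = sum(!is.na(.data$score)),
      median = stats::median(.data$score, na.rm = TRUE),
      mean = mean(.data$score, na.rm = TRUE),
      .groups = "drop"
    )
}

.impute_rowmean <- function(mat) {
  out <- mat
  rm <- rowMeans(mat, na.rm = TRUE)
  idx <- which(is.na(out), arr.ind = TRUE)
  if (nrow(idx)) out[idx] <- rm[idx[, 1]]
  out
}

#' Hierarchically cluster score-matrix vectors
#'
#' Agglomerative clustering of position score vectors (rows; the default)
#' or mutant-residue vectors (columns), with the dendrogram cut at `k`
#' clusters. Missing values (including WT cells) are imputed by the
#' vector's own mean for the distance computation only. Cluster ids are
#' relabelled 1..k in order of first appearance along the axis, so the
#' assignment is deterministic and permutation-invariant up to label
#' names.
#'
#' @param mat Matrix from [score_matrix()].
#' @param k Number of clusters (default 6 for positions).
#' @param axis `"position"` (rows) or `"aa"` (columns).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param metric Distance metric for [stats::dist()] (default
#'   `"euclidean"`).
#' @param max_missing Maximum tolerated fraction of missing cells per
#'   vector.
#' @return A `cluster_assignment` tibble: `item` (position number or
#'   residue), `cluster`; attributes `k`, `axis`, `linkage`, `metric`,
#'   `hclust` (the tree).
#' @export
hcluster_scores <- function(mat, k = 6L, axis = c("position", "aa"),
                            linkage = "average", metric = "euclidean",
                            max_missing = 0.5) {
  axis <- match.arg(axis)
  m <- if (axis == "position") mat else t(mat)
  m <- m[rownames(m) != "*", colnames(m) != "*", drop = FALSE]  # stop rows/cols never cluster
  frac_na <- rowMeans(is.na(m))
  if (any(frac_na > max_missing)) {
    abort(paste0("vectors with > ", 100 * max_missing, "% missing cells: ",
                 paste(rownames(m)[frac_na > max_missing], collapse = ", ")))
  }
  if (k > nrow(m)) abort("`k` exceeds the number of vectors.")
  mi <- .impute_rowmean(m)
  d <- stats::dist(mi, method = metric)
  if (all(d == 0)) abort("all vectors identical; clustering is degenerate.")
  hc <- stats::hclust(d, method = linkage)
  raw <- stats::cutree(hc, k = k)
  relab <- match(raw, unique(raw))  # 1..k by first appearance
  out <- tibble(item = rownames(m), cluster = relab)
  if (axis == "position") out$item <- as.integer(out$item)
  attr(out, "k") <- k; attr(out, "axis") <- axis
  attr(out, "linkage") <- linkage; attr(out, "metric") <- metric
  attr(out, "hclust") <- hc
  class(out) <- c("cluster_assignment", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.cluster_assignment <- function(x, ...) {
  tibble(item = x$item, cluster = x$cluster)
}

#' @exportS3Method generics::glance
glance.cluster_assignment <- function(x, ...) {
  tibble(k = attr(x, "k"), axis = attr(x, "axis"),
         linkage = attr(x, "linkage"), metric = attr(x, "metric"),
         n_items = nrow(x), n_nonempty = dplyr::n_distinct(x$cluster))
}

# maximal runs of consecutive integers
contiguous_segments <- function(positions) {
  p <- sort(unique(positions))
  if (length(p) == 0L) return(tibble(start = integer(), end = integer()))
  grp <- cumsum(c(1L, diff(p) != 1L))
  tibble(start = tapply(p, grp, min), end = tapply(p, grp, max)) |>
    mutate(across(everything(), as.integer))
}

#' Call buried beta-strand candidate positions from a position clustering
#'
#' In an aggregation scan, positions where substitutions most increase
#' solubility are the ones whose wild-type side chains the fibril core
#' depends on — candidate buried beta-strands. The cluster with the
#' highest mean solubility score (over measured substitution cells) is
#' selected; its positions are reported individually and as maximal
#' contiguous segments. A tie between cluster means is reported with a
#' warning and all tied clusters are returned.
#'
#' @param assignment A position `cluster_assignment` from
#'   [hcluster_scores()].
#' @param mat The [score_matrix()] the clustering was computed from.
#' @return A `strand_call` list: `cluster` (selected id(s)), `positions`,
#'   `segments` (tibble `start`, `end`, 1-based inclusive),
#'   `cluster_means` (tibble `cluster`, `mean_score`, `n_positions`).
#' @export
call_buried_strands <- function(assignment, mat) {
  if (attr(assignment, "axis") != "position") abort("need a position clustering.")
  long <- matrix_to_tibble(mat) |> filter(!.data$is_wt, .data$mut_aa != "*")
  means <- assignment |>
    left_join(long, by = c(item = "position")) |>
    group_by(.data$cluster) |>
    summarise(mean_score = mean(.data$score, na.rm = TRUE),
              n_positions = dplyr::n_distinct(.data$item), .groups = "drop")
  top <- max(means$mean_score)
  if (!is.finite(top)) abort("cluster means undefined (no measured cells).")
  sel <- means$cluster[abs(means$mean_score - top) < 1e-12]
  if (length(sel) > 1L) {
    warn(paste0("tie between cluster means; reporting clusters ",
                paste(sel, collapse = ", "), "."))
  }
  pos <- sort(assignment$item[assignment$cluster %in% sel])
  structure(
    list(cluster = sel, positions = pos,
         segments = contiguous_segments(pos), cluster_means = means),
    class = "strand_call"
  )
}

#' @export
print.strand_call <- function(x, ...) {
  segs <- paste(ifelse(x$segments$start == x$segments$end,
                       x$segments$start,
                       paste0(x$segments$start, "-", x$segments$end)),
                collapse = ", ")
  cat("<strand_call> cluster ", paste(x$cluster, collapse = "+"),
      " (", length(x$positions), " positions): ", segs, "\n", sep = "")
  invisible(x)
}
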