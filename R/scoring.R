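#' Aggregate codon-level counts to scoring units
#'
#' Missense and nonsense variants are aggregated to the amino-acid level by
#' summing the counts of every codon encoding the same substitution (the
#' scan's unit of interpretation); synonymous variants necessarily stay at
#' codon level (each synonymous codon is its own variant), and the WT entry
#' is kept as is. `level = "codon"` keeps everything codon-level.
#'
#' @param counts Count-table tibble (simulated or from [count_reads()]).
#' @param level `"aa"` (default) or `"codon"`.
#' @return Count tibble with a `variant` label column (e.g. `"F19D"`,
#'   synonymous `"F19F.TTC"`, and `"WT"`).
#' @export
aggregate_counts <- function(counts, level = c("aa", "codon")) {
  level <- match.arg(level)
  if (level == "aa") {
    counts <- counts |>
      mutate(mut_codon = dplyr::if_else(.data$class %in% c("missense", "nonsense"),
                                        NA_character_, .data$mut_codon)) |>
      group_by(across(all_of(c("position", "wt_aa", "mut_aa", "mut_codon", "class",
                               "replicate", "timepoint", "time_h")))) |>
      summarise(count = sum(.data$count), .groups = "drop")
  }
  counts |>
    mutate(variant = dplyr::if_else(
      .data$class == "WT", "WT",
      variant_id(.data$wt_aa, .data$position, .data$mut_aa, .data$mut_codon, .data$class)
    ))
}

#' WT-normalized log2 frequency ratios with regression weights
#'
#' For each variant, replicate and timepoint computes
#' `m_v(t) = log2((c_v(t) + p) / (c_wt(t) + p))` with pseudocount `p`
#' applied uniformly to all counts (so the WT trajectory is identically
#' zero). Because variant and WT counts share each sample's sequencing
#' depth, the mapped-read totals cancel in the ratio; they are retained
#' only for QC. Each observation also gets the inverse delta-method
#' variance of the log ratio under Poisson counts,
#' `w = 1 / (1/(c_v + p) + 1/(c_wt + p))`, used as the weight in the
#' slope regression.
#'
#' @param counts Aggregated count tibble from [aggregate_counts()] (must
#'   contain a `variant` column and one `"WT"` variant per sample).
#' @param pseudocount Pseudocount `p` added to every count (default 0.5).
#' @return Tibble with `variant`, key columns, `replicate`, `timepoint`,
#'   `time_h`, `count`, `wt_count`, `m` and `w`.
#' @examples
#' # c_v(t) = 2 c_wt(t) gives m = 1 at p = 0
#' @export
normalized_log_ratios <- function(counts, pseudocount = 0.5) {
  if (!"variant" %in% names(counts)) counts <- aggregate_counts(counts)
  wt <- counts |>
    filter(.data$class == "WT") |>
    select("replicate", "timepoint", wt_count = "count")
  if (nrow(wt) == 0L) abort("no WT entry found; WT normalization impossible.")
  if (pseudocount == 0 && any(wt$wt_count == 0)) {
    abort("WT count is zero at some timepoint and pseudocount is 0.")
  }
  counts |>
    left_join(wt, by = c("replicate", "timepoint")) |>
    mutate(
      m = log2((.data$count + pseudocount) / (.data$wt_count + pseudocount)),
      w = 1 / (1 / (.data$count + pseudocount) + 1 / (.data$wt_count + pseudocount))
    )
}

#' Weighted least-squares slope of a trajectory
#'
#' Fits `m = a + b x` minimizing `sum(w * (m - a - b x)^2)` in closed form
#' (weighted normal equations) and returns the slope with its standard
#' error, `se(b) = sqrt((sum(w e^2)/(n - 2)) / Sxx_w)`. With equal weights
#' this reduces to ordinary least squares.
#'
#' @param m Response values (log2 normalized ratios).
#' @param x Regression abscissa (sampling times in hours, or indices).
#' @param w Positive weights (default equal).
#' @return One-row tibble: `slope`, `se`, `intercept`, `n`. A degenerate
#'   design (all weight mass at one abscissa) yields `NA` slope with a
#'   warning.
#' @examples
#' wls_slope(c(0, 1, 2), c(0, 2, 4))$slope  # 0.5
#' @export
wls_slope <- function(m, x, w = rep(1, length(m))) {
  ok <- is.finite(m) & is.finite(x) & is.finite(w) & w > 0
  m <- m[ok]; x <- x[ok]; w <- w[ok]
  n <- length(m)
  if (n < 2L) {
    warn("fewer than 2 usable timepoints; slope undefined.")
    return(tibble(slope = NA_real_, se = NA_real_, intercept = NA_real_, n = n))
  }
  W <- sum(w)
  xb <- sum(w * x) / W
  mb <- sum(w * m) / W
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= 0 || !is.finite(sxx)) {
    warn("degenerate weighted design (no abscissa spread); slope undefined.")
    return(tibble(slope = NA_real_, se = NA_real_, intercept = NA_real_, n = n))
  }
  b <- sum(w * (x - xb) * (m - mb)) / sxx
  a <- mb - b * xb
  se <- if (n > 2L) sqrt(sum(w * (m - a - b * x)^2) / (n - 2L) / sxx) else NA_real_
  tibble(slope = b, se = se, intercept = a, n = n)
}

#' Score variant solubility from a selection count table
#'
#' The three-step solubility score: (1) per-sample WT-normalized log2
#' frequency ratios ([normalized_log_ratios()]); (2) a weighted
#' least-squares regression of each variant's ratios against sampling time
#' within each replicate ([wls_slope()]); (3) the per-replicate slopes
#' averaged into the final score. Because the ratios are on a log2 scale,
#' the slope is the score: log2 units per hour (or per timepoint index).
#' Scores above 0 mean more soluble than wild-type, below 0 more
#' aggregation-prone; WT scores exactly 0 by construction. A variant with
#' zero reads across all timepoints of a replicate gets an `NA` slope for
#' that replicate; one with no reads anywhere gets an `NA` score
#' (unmeasured).
#'
#' @param counts Count-table tibble (codon-level; aggregated internally).
#' @param pseudocount Pseudocount for [normalized_log_ratios()].
#' @param x_axis `"hours"` (regress against sampling time, default) or
#'   `"index"` (against timepoint rank). Scores rescale linearly between
#'   the two; classification is unaffected.
#' @param level Aggregation level, see [aggregate_counts()].
#' @param weighted Use inverse-variance weights (default) or equal weights.
#' @return A `score_table` tibble: `variant`, `position`, `wt_aa`,
#'   `mut_aa`, `mut_codon`, `class`, `score`, `se`, `n_reps`,
#'   `n_timepoints_used`, and one `slope_rep<k>` column per replicate.
#' @examples
#' lib <- enumerate_nnk_library(ab42_reference())
#' eff <- true_effect_map(lib, seed = 1)
#' des <- selection_design(depth = 2e4, seed = 1)
#' scores <- simulate_trajectories(eff, des) |> score_variants()
#' @export
score_variants <- function(counts, pseudocount = 0.5,
                           x_axis = c("hours", "index"),
                           level = c("aa", "codon"), weighted = TRUE) {
  x_axis <- match.arg(x_axis)
  level <- match.arg(level)
  ratios <- counts |>
    aggregate_counts(level = level) |>
    normalized_log_ratios(pseudocount = pseudocount) |>
    mutate(x = if (x_axis == "hours") .data$time_h else as.numeric(.data$timepoint))

  per_rep <- ratios |>
    group_by(across(all_of(c("variant", "position", "wt_aa", "mut_aa",
                             "mut_codon", "class", "replicate")))) |>
    summarise(
      measured = sum(.data$count) > 0 || .data$class[1] == "WT",
      fit = list(wls_slope(.data$m, .data$x,
                           if (weighted) .data$w else rep(1, length(.data$m)))),
      .groups = "drop"
    ) |>
    tidyr::unnest("fit") |>
    mutate(slope = dplyr::if_else(.data$measured, .data$slope, NA_real_))

  combined <- per_rep |>
    group_by(across(all_of(c("variant", "position", "wt_aa", "mut_aa",
                             "mut_codon", "class")))) |>
    summarise(
      score = if (all(is.na(.data$slope))) NA_real_ else mean(.data$slope, na.rm = TRUE),
      se = .combine_se(.data$slope, .data$se),
      n_reps = sum(!is.na(.data$slope)),
      n_timepoints_used = as.integer(max(.data$n)),
      .groups = "drop"
    )

  wide <- per_rep |>
    select("variant", "replicate", "slope") |>
    pivot_wider(names_from = "replicate", values_from = "slope",
                names_prefix = "slope_rep")

  out <- combined |>
    left_join(wide, by = "variant") |>
    arrange(.data$class != "WT", .data$position, .data$mut_aa, .data$mut_codon)
  class(out) <- c("score_table", class(out))
  out
}

.combine_se <- function(slopes, ses) {
  k <- sum(!is.na(slopes))
  if (k == 0L) return(NA_real_)
  if (k == 1L) return(ses[!is.na(slopes)][1])
  stats::sd(slopes, na.rm = TRUE) / sqrt(k)
}

#' Pairwise replicate correlation of per-replicate slopes
#'
#' Pearson correlation between each pair of replicates' slopes across all
#' variants with a defined slope in both (the standard reproducibility
#' diagnostic for a scan; well-powered scans show R around 0.8-0.9).
#'
#' @param scores A `score_table` from [score_variants()].
#' @param include_wt Keep the WT row (slope 0 in every replicate)?
#'   Default drops it.
#' @return Tibble: `rep_a`, `rep_b`, `r`, `n`.
#' @export
replicate_correlation <- function(scores, include_wt = FALSE) {
  if (!include_wt) scores <- filter(scores, .data$class != "WT")
  repcols <- grep("^slope_rep", names(scores), value = TRUE)
  if (length(repcols) < 2L) abort("need at least 2 replicates.")
  pairs <- utils::combn(repcols, 2, simplify = FALSE)
  bind_rows(lapply(pairs, function(p) {
    a <- scores[[p[1]]]; b <- scores[[p[2]]]
    ok <- is.finite(a) & is.finite(b)
    tibble(rep_a = sub("slope_rep", "", p[1]), rep_b = sub("slope_rep", "", p[2]),
           r = stats::cor(a[ok], b[ok]), n = sum(ok))
  }))
}

#' Doubling rate from two optical-density readings
#'
#' `(log10(od2 / od1) / log10(2)) / dt`: the number of culture doublings
#' per unit time between two OD measurements.
#'
#' @param od1,od2 Optical densities at the first and second reading (> 0).
#' @param dt Elapsed time between readings (> 0), in the output's time unit.
#' @return Doublings per unit time (vectorized).
#' @examples
#' doublings_per_time(0.1, 0.2, 1)  # 1
#' doublings_per_time(0.1, 0.8, 6)  # 0.5
#' @export
doublings_per_time <- function(od1, od2, dt) {
  if (any(od1 <= 0) || any(od2 <= 0)) abort("optical densities must be positive.")
  if (any(dt <= 0)) abort("`dt` must be positive.")
  (log10(od2 / od1) / log10(2)) / dt
}
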