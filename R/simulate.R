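#' Describe a timed selection experiment
#'
#' Captures the sampling design of a growth-based selection: sampling times,
#' replicate count, sequencing depth per sample, and the read-simulation
#' error model. Defaults mirror a 40-hour methotrexate selection sampled at
#' the input and five later ODs, sequenced in three replicates.
#'
#' @param timepoints Sampling times in hours, strictly increasing. The first
#'   entry is the input (t = 0) library.
#' @param replicates Number of biological replicates.
#' @param depth Read pairs sampled per timepoint per replicate.
#' @param seed Integer seed governing all simulator randomness.
#' @param error_rate Per-base substitution probability for simulated reads.
#' @param q_good,q_bad Phred qualities emitted for correct and erroneous
#'   bases respectively (two-level quality model).
#' @param r_wt Wild-type growth rate, per hour.
#' @param beta Selection-coefficient scaling: a variant with true solubility
#'   effect `s` grows at rate `r_wt + beta * s` (per hour).
#' @return An object of class `selection_design` (a named list).
#' @examples
#' selection_design(depth = 1e4, seed = 7)
#' @export
selection_design <- function(timepoints = c(0, 28, 31.5, 35, 38, 40),
                             replicates = 3L, depth = 1e5L, seed = 1L,
                             error_rate = 0, q_good = 37L, q_bad = 11L,
                             r_wt = 0.16, beta = 0.05) {
  if (any(diff(timepoints) <= 0)) abort("`timepoints` must be strictly increasing.")
  if (depth <= 0) abort("`depth` must be positive.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  if (error_rate < 0 || error_rate >= 1) abort("`error_rate` must be in [0, 1).")
  structure(
    list(timepoints = as.numeric(timepoints), replicates = as.integer(replicates),
         depth = as.integer(depth), seed = as.integer(seed),
         error_rate = error_rate, q_good = as.integer(q_good),
         q_bad = as.integer(q_bad), r_wt = r_wt, beta = beta),
    class = "selection_design"
  )
}

#' @export
print.selection_design <- function(x, ...) {
  cat("<selection_design> ", length(x$timepoints), " timepoints (",
      paste(x$timepoints, collapse = ", "), " h), ", x$replicates,
      " replicates, depth ", format(x$depth, big.mark = ","), "\n", sep = "")
  cat("  r_wt = ", x$r_wt, "/h, beta = ", x$beta, "/h per unit effect, ",
      "error_rate = ", x$error_rate, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Assign ground-truth solubility effects to a variant library
#'
#' Builds the simulator's ground truth: one true solubility effect `s` per
#' library variant. Wild-type and synonymous variants have `s = 0` by
#' definition (codon changes that preserve the residue do not change the
#' peptide); nonsense variants default to 0 as well. Missense effects are
#' drawn from a normal distribution centred slightly above zero with a
#' spread chosen to produce a realistic mix of aggregation-promoting,
#' neutral and solubilising substitutions; all codons encoding the same
#' amino-acid change share one effect.
#'
#' @param library Codon-level library tibble from [enumerate_nnk_library()].
#' @param s Optional tibble with columns `position`, `mut_aa`, `s` giving
#'   explicit missense/nonsense effects; unmatched variants get 0.
#' @param s_mean,s_sd Parameters of the default missense effect
#'   distribution (unitless solubility effect).
#' @param s_nonsense Effect assigned to nonsense (stop) variants.
#' @param seed Seed for the effect draw.
#' @return An `effect_map` tibble: the library plus a numeric `s` column.
#' @examples
#' lib <- enumerate_nnk_library(ab42_reference())
#' eff <- true_effect_map(lib, seed = 1)
#' all(eff$s[eff$class %in% c("WT", "synonymous")] == 0)
#' @export
true_effect_map <- function(library, s = NULL, s_mean = 0.1, s_sd = 0.6,
                            s_nonsense = 0, seed = 1L) {
  stopifnot(all(c("position", "mut_aa", "class") %in% names(library)))
  aa_key <- library |>
    filter(.data$class == "missense") |>
    distinct(.data$position, .data$mut_aa)
  if (is.null(s)) {
    withr_seed <- function(code) { # local RNG scope
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed); code
    }
    aa_key$s <- withr_seed(stats::rnorm(nrow(aa_key), s_mean, s_sd))
  } else {
    aa_key <- aa_key |>
      left_join(select(s, "position", "mut_aa", "s"), by = c("position", "mut_aa")) |>
      mutate(s = dplyr::coalesce(.data$s, 0))
  }
  out <- library |>
    left_join(aa_key, by = c("position", "mut_aa")) |>
    mutate(s = dplyr::case_when(
      class %in% c("WT", "synonymous") ~ 0,
      class == "nonsense" ~ s_nonsense,
      TRUE ~ .data$s
    ))
  class(out) <- c("effect_map", class(out))
  out
}

# deterministic abundance of each variant at time t (exponential growth)
.abundance <- function(f0, r, t) f0 * exp(r * t)

#' Expected (noise-free) variant frequencies and counts over a selection
#'
#' Deterministic counterpart of [simulate_trajectories()]: returns the
#' expected count `depth * f_v(t)` under pure exponential competition, with
#' no multinomial sampling. Useful for analytic checks: the slope of
#' `log2(f_v / f_wt)` against time in hours is exactly
#' `beta * s_v / ln(2)`.
#'
#' @inheritParams simulate_trajectories
#' @return A count-table tibble with a numeric (non-integer) `count` column.
#' @export
expected_trajectories <- function(effects, design, initial_freqs = NULL,
                                  wt_fraction = 0.05) {
  .trajectories(effects, design, initial_freqs, sample_counts = FALSE,
                wt_fraction = wt_fraction)
}

# WT starts at wt_fraction; everything else shares the rest uniformly
.default_initial_freqs <- function(class, wt_fraction) {
  nv <- length(class)
  is_wt <- class == "WT"
  if (!any(is_wt) || wt_fraction <= 0) return(rep(1 / nv, nv))
  f <- rep((1 - wt_fraction) / (nv - sum(is_wt)), nv)
  f[is_wt] <- wt_fraction / sum(is_wt)
  f
}

#' Simulate read counts for a timed selection experiment
#'
#' Each variant grows exponentially at rate `r_wt + beta * s_v`; at each
#' sampling time the culture's variant frequencies are the normalized
#' abundances, and sequencing draws `depth` reads multinomially from those
#' frequencies, independently per timepoint and replicate. Counts per
#' timepoint/replicate therefore sum exactly to `depth`. Replicates share
#' the ground truth and differ only in their sampling randomness; the whole
#' simulation is reproducible from `design$seed`.
#'
#' @param effects An `effect_map` from [true_effect_map()].
#' @param design A [selection_design()].
#' @param initial_freqs Optional numeric vector of starting frequencies
#'   (one per effect-map row, summing to 1). By default the WT entry
#'   starts at `wt_fraction` — pooled single-codon mutagenesis libraries
#'   retain a sizeable unmutated-template fraction, and the WT-normalized
#'   scoring assumes the denominator is deeply measured — and the
#'   remaining mass is uniform over the variants.
#' @param wt_fraction Starting frequency of the WT entry when
#'   `initial_freqs` is not given (default 0.05). Ignored if the effect
#'   map has no WT row.
#' @return A count-table tibble with columns `position`, `wt_codon`,
#'   `wt_aa`, `mut_codon`, `mut_aa`, `class`, `replicate`, `timepoint`
#'   (1-based index), `time_h` and `count`.
#' @examples
#' lib <- enumerate_nnk_library(ab42_reference())
#' eff <- true_effect_map(lib, seed = 1)
#' des <- selection_design(depth = 1e4, seed = 1)
#' counts <- simulate_trajectories(eff, des)
#' @export
simulate_trajectories <- function(effects, design, initial_freqs = NULL,
                                  wt_fraction = 0.05) {
  .trajectories(effects, design, initial_freqs, sample_counts = TRUE,
                wt_fraction = wt_fraction)
}

.trajectories <- function(effects, design, initial_freqs, sample_counts,
                          wt_fraction = 0.05) {
  stopifnot(inherits(design, "selection_design"))
  if (!"s" %in% names(effects)) abort("`effects` must carry an `s` column (see true_effect_map()).")
  nv <- nrow(effects)
  if (is.null(initial_freqs)) {
    initial_freqs <- .default_initial_freqs(effects$class, wt_fraction)
  }
  if (length(initial_freqs) != nv) abort("`initial_freqs` must have one entry per variant.")
  if (abs(sum(initial_freqs) - 1) > 1e-8) abort("`initial_freqs` must sum to 1.")
  r <- design$r_wt + design$beta * effects$s
  key <- select(effects, any_of(c("position", "wt_codon", "wt_aa",
                                  "mut_codon", "mut_aa", "class")))
  if (sample_counts) set.seed(design$seed)
  grid <- expand_grid(replicate = seq_len(design$replicates),
                      timepoint = seq_along(design$timepoints))
  rows <- pmap(grid, function(replicate, timepoint) {
    t <- design$timepoints[timepoint]
    a <- .abundance(initial_freqs, r, t)
    p <- a / sum(a)
    cnt <- if (sample_counts) {
      as.numeric(stats::rmultinom(1, design$depth, p))
    } else {
      design$depth * p
    }
    mutate(key, replicate = replicate, timepoint = timepoint,
           time_h = t, count = cnt)
  })
  out <- bind_rows(rows)
  class(out) <- c("count_table", class(out))
  out
}

#' @importFrom dplyr any_of
NULL
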