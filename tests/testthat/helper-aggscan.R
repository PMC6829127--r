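# Shared fixtures and independent oracles for the test suite.

# Tiny 4-codon reference with short flanks; translation MKFG.
tiny_reference <- function() {
  peptide_reference("tiny", "ATGAAATTTGGA",
                    flank5 = "ACGTAC", flank3 = "GTACGT")
}

# Independent weighted-least-squares oracle: solve the weighted normal
# equations with base linear algebra (never via the package's closed form).
wls_oracle <- function(m, x, w = rep(1, length(m))) {
  X <- cbind(1, x)
  A <- t(X) %*% (w * X)
  beta <- solve(A, t(X) %*% (w * m))
  resid <- m - X %*% beta
  s2 <- sum(w * resid^2) / (length(m) - 2)
  se <- sqrt(s2 * solve(A)[2, 2])
  list(slope = beta[2], intercept = beta[1], se = se)
}

# Brute-force (a, b) grid refinement oracle for the same objective.
wls_grid_oracle <- function(m, x, w, b_range = c(-10, 10), iter = 60) {
  obj <- function(a, b) sum(w * (m - a - b * x)^2)
  a_hat <- function(b) sum(w * (m - b * x)) / sum(w) # profile intercept
  lo <- b_range[1]; hi <- b_range[2]
  for (i in seq_len(iter)) {
    bs <- seq(lo, hi, length.out = 41)
    vals <- vapply(bs, function(b) obj(a_hat(b), b), 0)
    k <- which.min(vals)
    lo <- bs[max(1, k - 1)]; hi <- bs[min(41, k + 1)]
  }
  (lo + hi) / 2
}

# Count table for hand-specified per-timepoint (variant, WT) counts of a
# single missense variant, one replicate.
toy_count_table <- function(v_counts, wt_counts, times = seq_along(v_counts) - 1) {
  n <- length(v_counts)
  dplyr::bind_rows(
    tibble::tibble(position = 0L, wt_codon = NA, wt_aa = NA, mut_codon = NA,
                   mut_aa = NA, class = "WT", replicate = 1L,
                   timepoint = seq_len(n), time_h = times, count = wt_counts),
    tibble::tibble(position = 2L, wt_codon = "AAA", wt_aa = "K",
                   mut_codon = "GAT", mut_aa = "D", class = "missense",
                   replicate = 1L, timepoint = seq_len(n), time_h = times,
                   count = v_counts)
  )
}

# Minimal score table with given missense scores (positions 1..n).
toy_score_table <- function(scores, mut_aa = "A", wt_aa = "K",
                            class = "missense") {
  n <- length(scores)
  tibble::tibble(
    variant = paste0(wt_aa, seq_len(n), mut_aa),
    position = seq_len(n), wt_aa = wt_aa, mut_aa = mut_aa,
    mut_codon = NA_character_, class = class, score = scores
  )
}

# Score table over a full position x residue grid built from a matrix of
# values (rows = positions); wt residue chosen outside the mutant set.
grid_score_table <- function(values, wt_aa = NULL) {
  np <- nrow(values); aas <- colnames(values)
  if (is.null(wt_aa)) wt_aa <- rep("K", np)
  out <- tidyr::expand_grid(position = seq_len(np), mut_aa = aas) |>
    dplyr::mutate(
      wt_aa = wt_aa[position],
      score = values[cbind(position, match(mut_aa, aas))],
      class = "missense",
      variant = paste0(wt_aa, position, mut_aa), mut_codon = NA_character_
    ) |>
    dplyr::filter(mut_aa != wt_aa)
  out
}
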