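#' The 32 NNK degenerate codons
#'
#' NNK codons have any base at the first two positions and G or T at the
#' third (N = A/C/G/T, K = G/T). The 32 codons jointly encode all 20 amino
#' acids plus a single stop codon (TAG), which is why NNK saturation
#' mutagenesis is the standard design for single-codon libraries.
#'
#' @return Character vector of the 32 NNK codons.
#' @examples
#' length(nnk_codons())              # 32
#' table(translate_nnk()$aa)["*"]    # 1 stop codon
#' @export
nnk_codons <- function() {
  b <- c("A", "C", "G", "T")
  k <- c("G", "T")
  as.vector(t(outer(as.vector(t(outer(b, b, paste0))), k, paste0)))
}

#' @rdname nnk_codons
#' @return For `translate_nnk()`: a tibble with columns `codon` and `aa`.
#' @export
translate_nnk <- function() {
  cods <- nnk_codons()
  tibble(codon = cods, aa = translate_codons(cods))
}

#' Enumerate a single-codon NNK saturation library over a reference
#'
#' For every codon position of the reference ORF, enumerates all 32 NNK
#' codons and classifies each relative to the wild-type codon: `WT` (the
#' wild-type codon itself, when it is an NNK codon), `synonymous` (same
#' residue, different codon), `missense`, or `nonsense` (TAG). For a
#' 42-codon ORF this yields 42 x 19 = 798 distinct missense amino-acid
#' variants after amino-acid-level deduplication.
#'
#' @param ref A [peptide_reference()].
#' @param level `"codon"` (default; one row per position x NNK codon) or
#'   `"aa"` (deduplicated to one row per position x mutant amino acid,
#'   wild-type residue rows excluded, stop retained as `*`).
#' @return A tibble with columns `position`, `wt_codon`, `wt_aa`,
#'   `mut_codon` (absent for `level = "aa"`), `mut_aa` and `class`.
#' @examples
#' lib <- enumerate_nnk_library(ab42_reference())
#' nrow(lib)                                    # 42 * 32
#' sum(enumerate_nnk_library(ab42_reference(), level = "aa")$class == "missense")
#' @export
enumerate_nnk_library <- function(ref, level = c("codon", "aa")) {
  level <- match.arg(level)
  stopifnot(inherits(ref, "peptide_reference"))
  nnk <- translate_nnk()
  lib <- expand_grid(position = seq_len(ref$n_codons), nnk) |>
    rename(mut_codon = "codon", mut_aa = "aa") |>
    mutate(
      wt_codon = ref$wt_codons[.data$position],
      wt_aa = ref$wt_aa[.data$position],
      class = dplyr::case_when(
        mut_codon == wt_codon ~ "WT",
        mut_aa == "*" ~ "nonsense",
        mut_aa == wt_aa ~ "synonymous",
        TRUE ~ "missense"
      )
    ) |>
    select("position", "wt_codon", "wt_aa", "mut_codon", "mut_aa", "class")
  if (level == "aa") {
    lib <- lib |>
      filter(.data$class %in% c("missense", "nonsense")) |>
      distinct(.data$position, .data$wt_aa, .data$mut_aa, .data$class)
  }
  lib
}

#' Summarise library coverage at the amino-acid level
#'
#' Reports how many of the possible single missense amino-acid variants are
#' covered once a set of variants is masked (e.g. variants that received no
#' reads and therefore no score).
#'
#' @param ref A [peptide_reference()].
#' @param masked Optional tibble with columns `position` and `mut_aa` naming
#'   missense variants absent from the measured set.
#' @return One-row tibble: `n_possible` (19 per codon), `n_masked`,
#'   `n_covered`, `coverage_pct` (percentage, one decimal as conventionally
#'   printed).
#' @export
library_coverage <- function(ref, masked = NULL) {
  possible <- enumerate_nnk_library(ref, level = "aa") |>
    filter(.data$class == "missense")
  n_possible <- nrow(possible)
  n_masked <- 0L
  if (!is.null(masked) && nrow(masked) > 0L) {
    hit <- possible |> inner_join(
      distinct(masked, .data$position, .data$mut_aa),
      by = c("position", "mut_aa")
    )
    n_masked <- nrow(hit)
  }
  n_cov <- n_possible - n_masked
  tibble(
    n_possible = n_possible, n_masked = n_masked, n_covered = n_cov,
    coverage_pct = round(100 * n_cov / n_possible, 1)
  )
}

#' Build the simulated scan library: single-codon NNK variants plus one WT entry
#'
#' The codon-level NNK enumeration lists the wild-type codon at every
#' position where it happens to be an NNK codon; all of those entries are
#' the same molecule (the unmutated template), so for simulation and
#' counting they are collapsed into a single WT row (`position = 0`, codon
#' and residue fields `NA`) matching the convention of [count_reads()].
#'
#' @param ref A [peptide_reference()].
#' @return Tibble of library variants: one WT row followed by all
#'   non-WT-codon NNK variants.
#' @export
scan_library <- function(ref) {
  lib <- enumerate_nnk_library(ref) |> filter(.data$class != "WT")
  wt <- tibble(position = 0L, wt_codon = NA_character_, wt_aa = NA_character_,
               mut_codon = NA_character_, mut_aa = NA_character_, class = "WT")
  bind_rows(wt, lib)
}

# canonical variant label, e.g. "F19D"; synonymous carry the codon: "F19F.TTT"
variant_id <- function(wt_aa, position, mut_aa, mut_codon = NULL, class = NULL) {
  id <- paste0(wt_aa, position, mut_aa)
  if (!is.null(mut_codon) && !is.null(class)) {
    syn <- !is.na(class) & class %in% c("synonymous", "WT")
    id[syn] <- paste0(id[syn], ".", mut_codon[syn])
  }
  id
}
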