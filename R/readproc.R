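#' Read a pair of FASTQ files into sequence/quality matrices
#'
#' Internal-format loader used by the counting pipeline; exposed for QC.
#' Reads must all have the same length as the reference amplicon to be
#' usable downstream (others are rejected at filtering).
#'
#' @param r1,r2 Paths to mate FASTQ files (optionally gzipped).
#' @return List with `seq1`, `seq2` (character vectors), `qual1`, `qual2`
#'   (integer matrices or lists of integer vectors when widths differ).
#' @keywords internal
read_fastq_pair <- function(r1, r2) {
  read1 <- function(p) {
    # Biostrings warns that FASTQ metadata columns are dropped; we only
    # need sequences and qualities
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(p),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) invokeRestart("muffleWarning")
      }
    )
  }
  x1 <- read1(r1)
  x2 <- read1(r2)
  if (length(x1) != length(x2)) abort("mate files differ in read count.")
  list(
    seq1 = as.character(x1), seq2 = as.character(x2),
    qual1 = lapply(as.character(Biostrings::quality(x1)), function(s) utf8ToInt(s) - 33L),
    qual2 = lapply(as.character(Biostrings::quality(x2)), function(s) utf8ToInt(s) - 33L)
  )
}

#' Quality-filter a read pair
#'
#' A pair is accepted only if every base in both mates has a Phred score
#' strictly greater than `min_q` (default 20), neither mate contains an
#' uncalled base (N), and both mates match the expected amplicon length.
#' The filter is deliberately stringent: with two-level simulated
#' qualities it removes every read carrying an injected sequencing error.
#'
#' @param seq1,seq2 Mate sequences (character scalars).
#' @param qual1,qual2 Integer vectors of per-base Phred scores.
#' @param min_q Minimum Phred score; bases must be strictly greater.
#' @param expected_length Required read length (amplicon length); `NULL`
#'   skips the length check.
#' @return Character scalar: `"accepted"`, or a rejection reason among
#'   `"length"`, `"uncalled_base"`, `"low_quality"` (checked in that order).
#' @examples
#' filter_read_pair("ACGT", "ACGT", rep(30, 4), rep(30, 4))      # accepted
#' filter_read_pair("ACGT", "ACGT", c(20, 30, 30, 30), rep(30, 4)) # low_quality
#' @export
filter_read_pair <- function(seq1, seq2, qual1, qual2, min_q = 20L,
                             expected_length = NULL) {
  if (!is.null(expected_length) &&
      (nchar(seq1) != expected_length || nchar(seq2) != expected_length)) {
    return("length")
  }
  if (str_detect(seq1, "N") || str_detect(seq2, "N")) return("uncalled_base")
  if (any(qual1 <= min_q) || any(qual2 <= min_q)) return("low_quality")
  "accepted"
}

#' Call the variant carried by an amplicon read pair
#'
#' Overlapping mates are reconciled base-by-base: R2 is reverse-complemented
#' onto the forward strand and, at each position, the base with the higher
#' quality wins (ties go to R1). The ORF region is then compared codon by
#' codon against the reference: zero mismatched codons give WT, exactly one
#' gives a single-codon variant classified as synonymous / missense /
#' nonsense, and two or more give class `multi`.
#'
#' @param seq1 Forward-mate sequence (amplicon orientation).
#' @param seq2 Reverse-mate sequence (as sequenced, i.e. reverse complement
#'   of the amplicon).
#' @param qual1,qual2 Integer Phred vectors for each mate (read order).
#' @param ref A [peptide_reference()].
#' @return One-row tibble: `position`, `wt_codon`, `wt_aa`, `mut_codon`,
#'   `mut_aa`, `class`, `n_mismatch_codons`. WT calls have `position = 0`
#'   and codon/aa fields equal to `NA`; `multi` calls report
#'   `n_mismatch_codons` only.
#' @export
call_variant <- function(seq1, seq2, qual1, qual2, ref) {
  cons <- .consensus(seq1, seq2, qual1, qual2)
  .call_from_amplicon(cons, ref)
}

.consensus <- function(seq1, seq2, qual1, qual2) {
  s2 <- revcomp(seq2)
  q2 <- rev(qual2)
  b1 <- strsplit(seq1, "")[[1]]
  b2 <- strsplit(s2, "")[[1]]
  use2 <- q2 > qual1
  b1[use2] <- b2[use2]
  paste(b1, collapse = "")
}

.call_from_amplicon <- function(amplicon, ref) {
  orf <- substr(amplicon, nchar(ref$flank5) + 1L, nchar(ref$flank5) + nchar(ref$dna))
  cods <- str_sub(orf, 3L * seq_len(ref$n_codons) - 2L, 3L * seq_len(ref$n_codons))
  mism <- which(cods != ref$wt_codons)
  if (length(mism) == 0L) {
    return(tibble(position = 0L, wt_codon = NA_character_, wt_aa = NA_character_,
                  mut_codon = NA_character_, mut_aa = NA_character_,
                  class = "WT", n_mismatch_codons = 0L))
  }
  if (length(mism) > 1L) {
    return(tibble(position = NA_integer_, wt_codon = NA_character_,
                  wt_aa = NA_character_, mut_codon = NA_character_,
                  mut_aa = NA_character_, class = "multi",
                  n_mismatch_codons = length(mism)))
  }
  p <- mism
  mut_codon <- cods[p]
  mut_aa <- translate_codons(mut_codon)
  wt_aa <- ref$wt_aa[p]
  klass <- if (mut_aa == "*") "nonsense" else if (mut_aa == wt_aa) "synonymous" else "missense"
  tibble(position = p, wt_codon = ref$wt_codons[p], wt_aa = wt_aa,
         mut_codon = mut_codon, mut_aa = mut_aa, class = klass,
         n_mismatch_codons = 1L)
}

#' Count variants from paired FASTQ files
#'
#' Full read-processing pipeline for one or more sequencing samples:
#' quality filtering ([filter_read_pair()]), mate reconciliation and
#' codon-level variant calling ([call_variant()]), then tabulation into a
#' dense count table over the reference's single-codon NNK library plus
#' WT. Multi-codon calls are excluded from the count table but tallied in
#' the QC report; a sample whose retained reads contain no WT read is
#' flagged fatal since WT normalization is impossible downstream.
#'
#' @param files Tibble with columns `r1`, `r2`, `replicate`, `timepoint`,
#'   `time_h` — as returned by [write_fastq()].
#' @param ref A [peptide_reference()].
#' @param min_q Quality threshold passed to [filter_read_pair()].
#' @return A dense count-table tibble (every library variant present at
#'   every sample, zero counts included) with attributes `qc` (tibble of
#'   reads in / accepted / rejected-by-reason / multi per sample) and
#'   `totals` (retained mapped reads per sample).
#' @export
count_reads <- function(files, ref, min_q = 20L) {
  stopifnot(all(c("r1", "r2", "replicate", "timepoint", "time_h") %in% names(files)))
  lib <- enumerate_nnk_library(ref) |> filter(.data$class != "WT")
  wt_row <- tibble(position = 0L, wt_codon = NA_character_, wt_aa = NA_character_,
                   mut_codon = NA_character_, mut_aa = NA_character_, class = "WT")
  keys <- bind_rows(wt_row, lib)
  L <- nchar(ref$amplicon)

  res <- pmap(files, function(r1, r2, replicate, timepoint, time_h, ...) {
    fq <- read_fastq_pair(r1, r2)
    n_in <- length(fq$seq1)
    status <- vapply(seq_len(n_in), function(i) {
      filter_read_pair(fq$seq1[i], fq$seq2[i], fq$qual1[[i]], fq$qual2[[i]],
                       min_q = min_q, expected_length = L)
    }, "")
    keep <- which(status == "accepted")
    calls <- if (length(keep)) {
      cons <- vapply(keep, function(i) {
        .consensus(fq$seq1[i], fq$seq2[i], fq$qual1[[i]], fq$qual2[[i]])
      }, "")
      u <- unique(cons)
      ucalls <- bind_rows(lapply(u, .call_from_amplicon, ref = ref))
      ucalls[match(cons, u), ]
    } else {
      tibble(position = integer(), wt_codon = character(), wt_aa = character(),
             mut_codon = character(), mut_aa = character(), class = character(),
             n_mismatch_codons = integer())
    }
    n_multi <- sum(calls$class == "multi")
    single <- filter(calls, .data$class != "multi")
    counted <- single |>
      count(.data$position, .data$wt_codon, .data$wt_aa, .data$mut_codon,
            .data$mut_aa, .data$class, name = "count")
    dense <- keys |>
      left_join(counted, by = names(keys)) |>
      mutate(count = dplyr::coalesce(.data$count, 0L),
             replicate = replicate, timepoint = timepoint, time_h = time_h)
    qc <- tibble(
      replicate = replicate, timepoint = timepoint,
      reads_in = n_in, accepted = length(keep),
      rejected_length = sum(status == "length"),
      rejected_uncalled = sum(status == "uncalled_base"),
      rejected_quality = sum(status == "low_quality"),
      multi_codon = n_multi,
      retained = nrow(single),
      wt_reads = sum(single$class == "WT"),
      wt_missing = sum(single$class == "WT") == 0L
    )
    list(counts = dense, qc = qc)
  })

  qc <- bind_rows(map(res, "qc"))
  if (any(qc$wt_missing)) {
    bad <- qc[qc$wt_missing, , drop = FALSE]
    warn(paste0("no WT reads retained for replicate/timepoint: ",
                paste(sprintf("%d/%d", bad$replicate, bad$timepoint), collapse = ", "),
                " — WT normalization impossible for these samples."))
  }
  out <- bind_rows(map(res, "counts"))
  totals <- out |>
    group_by(.data$replicate, .data$timepoint, .data$time_h) |>
    summarise(total = sum(.data$count), .groups = "drop")
  attr(out, "qc") <- qc
  attr(out, "totals") <- totals
  class(out) <- c("count_table", class(out))
  out
}
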