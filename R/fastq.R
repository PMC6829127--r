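# variant amplicon sequence: reference amplicon with codon `position`
# replaced by `mut_codon`
variant_amplicon <- function(ref, position, mut_codon) {
  out <- rep(ref$amplicon, length(position))
  mut <- !is.na(mut_codon) & position >= 1L  # WT rows keep the template
  start <- nchar(ref$flank5) + 3L * (position - 1L) + 1L
  if (any(mut)) {
    for (i in which(mut)) substr(out[i], start[i], start[i] + 2L) <- mut_codon[i]
  }
  out
}

.phred_chr <- function(q) vapply(q, function(qi) rawToChar(as.raw(33L + qi)), "")

#' Write simulated paired-end FASTQ files for a selection experiment
#'
#' Expands a simulated count table into read pairs spanning the full
#' amplicon: R1 is the forward amplicon sequence, R2 its reverse
#' complement. Per-base substitution errors are injected at
#' `design$error_rate`; erroneous bases carry Phred `q_bad` and all other
#' bases `q_good`, so at the default settings every injected error is
#' removed by the standard quality filter. With `error_rate = 0` the reads
#' reproduce the variant sequences exactly. Output is deterministic given
#' `design$seed`.
#'
#' @param counts Count table from [simulate_trajectories()] (codon-level
#'   variants).
#' @param ref The [peptide_reference()] the counts were simulated from.
#' @param design The [selection_design()] (error model, qualities, seed).
#' @param dir Output directory (created if needed).
#' @param run Run name used in file names
#'   `{run}_rep{replicate}_t{timepoint}_R{1,2}.fastq[.gz]`.
#' @param compress Write gzipped FASTQ.
#' @return Tibble with one row per timepoint/replicate: `replicate`,
#'   `timepoint`, `time_h`, `n_reads`, `r1`, `r2` (file paths).
#' @export
write_fastq <- function(counts, ref, design, dir, run = "sim", compress = FALSE) {
  stopifnot(inherits(ref, "peptide_reference"), inherits(design, "selection_design"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (compress) ".fastq.gz" else ".fastq"
  L <- nchar(ref$amplicon)
  groups <- counts |>
    filter(.data$count > 0) |>
    group_by(.data$replicate, .data$timepoint, .data$time_h) |>
    tidyr::nest() |>
    ungroup() |>
    arrange(.data$replicate, .data$timepoint)
  set.seed(design$seed + 1L)  # independent of the count draw
  out <- pmap(groups, function(replicate, timepoint, time_h, data) {
    seqs <- rep(variant_amplicon(ref, data$position, data$mut_codon),
                times = data$count)
    n <- length(seqs)
    base <- file.path(dir, sprintf("%s_rep%d_t%d", run, replicate, timepoint))
    r1_path <- paste0(base, "_R1", ext)
    r2_path <- paste0(base, "_R2", ext)
    e1 <- .inject_errors(seqs, design, L, n)  # mates take independent errors
    e2 <- .inject_errors(seqs, design, L, n)
    ids <- sprintf("%s:%d:%d:%d", run, replicate, timepoint, seq_len(n))
    q1 <- Biostrings::PhredQuality(e1$quals)
    q2 <- Biostrings::PhredQuality(e2$quals)
    r1 <- Biostrings::QualityScaledDNAStringSet(
      stats::setNames(Biostrings::DNAStringSet(e1$seqs), ids), q1)
    r2seq <- Biostrings::reverseComplement(Biostrings::DNAStringSet(e2$seqs))
    r2 <- Biostrings::QualityScaledDNAStringSet(
      stats::setNames(r2seq, ids),
      Biostrings::PhredQuality(vapply(e2$quals, function(s)
        paste(rev(strsplit(s, "")[[1]]), collapse = ""), "", USE.NAMES = FALSE)))
    Biostrings::writeQualityScaledXStringSet(r1, r1_path, compress = compress)
    Biostrings::writeQualityScaledXStringSet(r2, r2_path, compress = compress)
    tibble(replicate = replicate, timepoint = timepoint, time_h = time_h,
           n_reads = n, r1 = r1_path, r2 = r2_path)
  })
  bind_rows(out)
}

# substitute random wrong bases at error_rate; erroneous bases get q_bad
.inject_errors <- function(seqs, design, L, n) {
  qual_good <- strrep(.phred_chr(design$q_good), L)
  quals <- rep(qual_good, n)
  if (design$error_rate == 0 || n == 0) return(list(seqs = seqs, quals = quals))
  n_err <- stats::rbinom(1, n * L, design$error_rate)
  if (n_err == 0) return(list(seqs = seqs, quals = quals))
  idx <- sample.int(n * L, n_err)            # flat index over all bases
  read_i <- (idx - 1L) %/% L + 1L
  pos_i <- (idx - 1L) %% L + 1L
  bases <- c("A", "C", "G", "T")
  bad_q <- .phred_chr(design$q_bad)
  for (k in seq_len(n_err)) {
    i <- read_i[k]; p <- pos_i[k]
    cur <- substr(seqs[i], p, p)
    substr(seqs[i], p, p) <- sample(setdiff(bases, cur), 1)
    substr(quals[i], p, p) <- bad_q
  }
  list(seqs = seqs, quals = quals)
}
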