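#' Oligonucleotide melting temperature
#'
#' Two-regime convention: the Wallace rule `2(A+T) + 4(G+C)` for
#' sequences shorter than 14 nt, and the GC-fraction formula
#' `64.9 + 41 (GC - 16.4) / length` otherwise. Degenerate bases are
#' rejected (the NNK codon itself is never part of a primer arm's Tm).
#'
#' @param seq Character vector of unambiguous DNA sequences.
#' @return Numeric Tm in degrees Celsius, one per sequence.
#' @examples
#' melting_temperature("AAAA")     # 8
#' melting_temperature("GGGGGG")   # 24
#' @export
melting_temperature <- function(seq) {
  seq <- toupper(seq)
  if (any(nchar(seq) == 0L)) abort("empty sequence.")
  if (any(str_detect(seq, "[^ACGT]"))) {
    abort("ambiguous bases are not allowed in Tm calculation.")
  }
  len <- nchar(seq)
  gc <- str_count(seq, "[GC]")
  at <- len - gc
  ifelse(len < 14L, 2 * at + 4 * gc, 64.9 + 41 * (gc - 16.4) / len)
}

.grow_arm <- function(context, anchor, direction, min_len, min_tm, position) {
  # grow one base at a time away from the target codon until both
  # constraints hold; anchor is the first base of the arm's inner end
  n <- nchar(context)
  len <- 0L
  repeat {
    len <- len + 1L
    if (direction == "left") {
      start <- anchor - len + 1L
      if (start < 1L) {
        abort(paste0("insufficient 5' flanking context for codon ", position, "."))
      }
      arm <- substr(context, start, anchor)
    } else {
      end <- anchor + len - 1L
      if (end > n) {
        abort(paste0("insufficient 3' flanking context for codon ", position, "."))
      }
      arm <- substr(context, anchor, end)
    }
    if (len >= min_len && melting_temperature(arm) > min_tm) return(arm)
  }
}

#' Design NNK saturation-mutagenesis primers for every codon of an ORF
#'
#' For each codon, the forward primer is a 5' homology arm, the literal
#' degenerate codon `NNK`, and a 3' extension arm; the reverse primer is
#' exactly the reverse complement of the homology arm (the in vivo
#' assembly design). Each arm is grown outward from the target codon one
#' base at a time until it is at least `min_len` nucleotides long and its
#' melting temperature exceeds `min_tm`, so every emitted arm is minimal:
#' shortening it by one base violates at least one constraint.
#'
#' @param ref A [peptide_reference()] whose flanks supply the plasmid
#'   context on both sides of the ORF.
#' @param min_len Minimum arm length in nucleotides (default 15).
#' @param min_tm Arm melting temperature must be strictly greater than
#'   this, in degrees Celsius (default 55).
#' @return Tibble with one row per codon: `position`, `wt_codon`,
#'   `forward` (homology + `"NNK"` + extension), `reverse`, `homology`,
#'   `extension`, `homology_len`, `extension_len`, `homology_tm`,
#'   `extension_tm`, `tm_method`.
#' @examples
#' primers <- design_primers(ab42_reference())
#' nrow(primers)  # 42
#' @export
design_primers <- function(ref, min_len = 15L, min_tm = 55) {
  stopifnot(inherits(ref, "peptide_reference"))
  context <- ref$amplicon
  off <- nchar(ref$flank5)
  rows <- lapply(seq_len(ref$n_codons), function(i) {
    start <- off + 3L * (i - 1L) + 1L          # first base of codon i
    hom <- .grow_arm(context, start - 1L, "left", min_len, min_tm, i)
    ext <- .grow_arm(context, start + 3L, "right", min_len, min_tm, i)
    tibble(
      position = i, wt_codon = ref$wt_codons[i],
      forward = paste0(hom, "NNK", ext),
      reverse = revcomp(hom),
      homology = hom, extension = ext,
      homology_len = nchar(hom), extension_len = nchar(ext),
      homology_tm = melting_temperature(hom),
      extension_tm = melting_temperature(ext),
      tm_method = "wallace_lt14_gcfraction"
    )
  })
  bind_rows(rows)
}

#' Write designed primers to FASTA
#'
#' @param primers Tibble from [design_primers()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_primer_fasta <- function(primers, path) {
  seqs <- c(rbind(primers$forward, primers$reverse))
  ids <- c(rbind(paste0("codon", primers$position, "_F"),
                 paste0("codon", primers$position, "_R")))
  # forward primers carry the degenerate NNK codon, so write plain FASTA
  lines <- paste0(">", ids, "\n", seqs)
  writeLines(lines, path)
  invisible(path)
}
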