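#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows distinct n across all_of rename
#'   pull count slice first row_number everything
#' @importFrom tidyr pivot_wider pivot_longer complete expand_grid replace_na
#' @importFrom purrr map map_dbl map_chr map_int map2 pmap imap walk
#' @importFrom stringr str_sub str_split str_detect str_count str_length
NULL

# standard genetic code, keyed by codon (DNA alphabet); "*" marks stop
.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

translate_codons <- function(codons) {
  unname(.genetic_code()[codons])
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Human Abeta42 coding sequence (APP cDNA codons) and its peptide.
.AB42_DNA <- paste0(
  "GATGCAGAATTCCGACATGACTCAGGATATGAAGTTCATCATCAAAAATTGGTGTTCTTT",
  "GCAGAAGATGTGGGTTCAAACAAAGGTGCAATCATTGGACTCATGGTGGGCGGTGTTGTC",
  "ATAGCG"
)
.AB42_PROTEIN <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"

# Synthetic plasmid-context flanks (balanced GC, long enough for primer arms);
# they stand in for vector sequence flanking the ORF in the amplicon.
.AB42_FLANK5 <- "ACGGATTCGCAGTCCATGGCTAGCAAGCTGGAGTACCGGTCATCGGATC"
.AB42_FLANK3 <- "GGATCCACTAGTGCTAGCCAGCTGGCGTTAGCCATGACCGGTATCCGAC"

#' Define a peptide reference for an amplicon-based mutational scan
#'
#' A peptide reference bundles the open reading frame (ORF), its translation,
#' and the flanking amplicon context used for read simulation, variant calling
#' and primer design. The default reference is the 42-codon human amyloid-beta
#' (Abeta42) coding sequence with synthetic plasmid-context flanks.
#'
#' @param name Reference name.
#' @param dna ORF nucleotide sequence; length must be divisible by 3 and free
#'   of ambiguous bases. Must not contain an internal stop codon.
#' @param flank5,flank3 Amplicon context flanking the ORF (unambiguous DNA;
#'   may be empty strings).
#' @return An object of class `peptide_reference`: a list with elements
#'   `name`, `dna`, `protein`, `flank5`, `flank3`, `n_codons`, `wt_codons`
#'   (character vector of codons), `wt_aa` (one-letter residues) and
#'   `amplicon` (flank5 + ORF + flank3).
#' @examples
#' ref <- ab42_reference()
#' ref$n_codons      # 42
#' ref$protein
#' @export
peptide_reference <- function(name, dna, flank5 = "", flank3 = "") {
  dna <- toupper(dna)
  flank5 <- toupper(flank5)
  flank3 <- toupper(flank3)
  if (nchar(dna) == 0L || nchar(dna) %% 3L != 0L) {
    abort("`dna` length must be a positive multiple of 3.")
  }
  if (any(str_detect(c(dna, flank5, flank3), "[^ACGT]"))) {
    abort("reference sequences must contain only unambiguous bases (A/C/G/T).")
  }
  n_codons <- nchar(dna) %/% 3L
  wt_codons <- str_sub(dna, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  wt_aa <- translate_codons(wt_codons)
  if (any(wt_aa == "*")) abort("`dna` contains an internal stop codon.")
  structure(
    list(
      name = name, dna = dna, protein = paste(wt_aa, collapse = ""),
      flank5 = flank5, flank3 = flank3,
      n_codons = n_codons, wt_codons = wt_codons, wt_aa = wt_aa,
      amplicon = paste0(flank5, dna, flank3)
    ),
    class = "peptide_reference"
  )
}

#' @rdname peptide_reference
#' @export
ab42_reference <- function() {
  peptide_reference("Abeta42", .AB42_DNA,
                    flank5 = .AB42_FLANK5, flank3 = .AB42_FLANK3)
}

#' @export
print.peptide_reference <- function(x, ...) {
  cat("<peptide_reference> ", x$name, "\n", sep = "")
  cat("  ORF: ", nchar(x$dna), " nt / ", x$n_codons, " codons\n", sep = "")
  cat("  protein: ", x$protein, "\n", sep = "")
  cat("  amplicon: ", nchar(x$amplicon), " nt (flanks ",
      nchar(x$flank5), " + ", nchar(x$flank3), ")\n", sep = "")
  invisible(x)
}

#' Write a peptide reference to FASTA
#'
#' Writes the amplicon (default) or bare ORF of a [peptide_reference()].
#'
#' @param ref A `peptide_reference`.
#' @param path Output FASTA path.
#' @param what `"amplicon"` or `"orf"`.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path, what = c("amplicon", "orf")) {
  what <- match.arg(what)
  seq <- if (what == "amplicon") ref$amplicon else ref$dna
  x <- Biostrings::DNAStringSet(stats::setNames(seq, ref$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
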