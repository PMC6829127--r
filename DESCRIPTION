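Package: aggscan
Title: Deep Mutational Scanning of Amyloid-Beta Aggregation by Growth Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for deep mutational scans of amyloid-beta (Abeta42)
    aggregation measured by a yeast DHFR growth selection. Simulates timed
    selection experiments over NNK saturation-mutagenesis libraries down to
    paired-end FASTQ with known ground truth; calls codon-level variants from
    quality-filtered amplicon reads; scores variant solubility as the weighted
    least-squares slope of log2 wild-type-normalized frequency ratios across
    timepoints, averaged over replicates; classifies variants against a
    synonymous-variant null distribution (+/- 2 SD); builds position-by-substitution
    score maps with hierarchical clustering and buried beta-strand candidate
    calling; quantifies concordance with in vitro ddG substitution scans and
    per-position beta-strand tracks from fibril structural models; and designs
    the NNK mutagenesis primers for an arbitrary open reading frame.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
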