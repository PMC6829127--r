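test_that("quality filtering is strict at the threshold and rejects uncalled bases", {
  q30 <- rep(30L, 4)
  expect_equal(filter_read_pair("ACGT", "ACGT", q30, q30), "accepted")
  # a single base at exactly Q20 fails the strictly-greater-than rule
  expect_equal(filter_read_pair("ACGT", "ACGT", c(20L, 30L, 30L, 30L), q30),
               "low_quality")
  expect_equal(filter_read_pair("ACGT", "ACGT", q30, c(30L, 30L, 30L, 20L)),
               "low_quality")
  expect_equal(filter_read_pair("ACGT", "ACGT", c(21L, 21L, 21L, 21L), q30),
               "accepted")
  # an N is rejected regardless of its quality
  expect_equal(filter_read_pair("ANGT", "ACGT", rep(40L, 4), q30), "uncalled_base")
  expect_equal(filter_read_pair("ACGT", "ACNT", q30, rep(40L, 4)), "uncalled_base")
  expect_equal(filter_read_pair("ACG", "ACGT", rep(30L, 3), q30,
                                expected_length = 4), "length")
})

test_that("raising the quality threshold never grows the accepted set", {
  set.seed(4)
  n <- 200
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = ""), "")
  quals <- lapply(seq_len(n), function(i) sample(15:40, 10, replace = TRUE))
  accept <- function(minq) {
    vapply(seq_len(n), function(i)
      filter_read_pair(seqs[i], seqs[i], quals[[i]], quals[[i]], min_q = minq), "") == "accepted"
  }
  prev <- accept(10)
  for (q in c(15, 20, 25, 30)) {
    cur <- accept(q)
    expect_true(all(!cur | prev))  # cur implies prev
    prev <- cur
  }
})

test_that("variant calling reconciles mates by quality and classifies codon changes", {
  ref <- tiny_reference()
  amp <- ref$amplicon
  L <- nchar(amp)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  hi <- rep(35L, L)

  wt_call <- call_variant(amp, rc(amp), hi, hi, ref)
  expect_equal(wt_call$class, "WT")
  expect_equal(wt_call$n_mismatch_codons, 0L)

  # codon 3 TTT -> GAT is a missense F>D call at position 3
  mut <- amp
  substr(mut, 6 + 7, 6 + 9) <- "GAT"
  call <- call_variant(mut, rc(mut), hi, hi, ref)
  expect_equal(call[c("position", "wt_aa", "mut_aa", "class")],
               tibble::tibble(position = 3L, wt_aa = "F", mut_aa = "D",
                              class = "missense"))

  # synonymous and nonsense codons are classified as such
  syn <- amp; substr(syn, 6 + 4, 6 + 6) <- "AAG"      # K -> K
  expect_equal(call_variant(syn, rc(syn), hi, hi, ref)$class, "synonymous")
  non <- amp; substr(non, 6 + 7, 6 + 9) <- "TAG"      # F -> stop
  expect_equal(call_variant(non, rc(non), hi, hi, ref)$class, "nonsense")

  # two mutated codons give a multi call
  two <- mut; substr(two, 6 + 10, 6 + 12) <- "CCC"
  m <- call_variant(two, rc(two), hi, hi, ref)
  expect_equal(m$class, "multi")
  expect_equal(m$n_mismatch_codons, 2L)

  # the higher-quality mate wins a disagreement; ties go to R1
  r1 <- amp
  substr(r1, 8, 8) <- "C"                  # error in R1 at base 8 (codon 1)
  lo <- hi; lo[8] <- 12L                   # low quality at the error in R1
  q2 <- rep(35L, L)
  disagree <- call_variant(r1, rc(amp), lo, q2, ref)
  expect_equal(disagree$class, "WT")       # R2's high-quality base rescues it
  tie <- call_variant(r1, rc(amp), hi, q2, ref)
  expect_equal(tie$class, "missense")      # equal quality: R1 is believed
  expect_equal(tie$position, 1L)
})

test_that("codon calls are position-local", {
  ref <- tiny_reference()
  amp <- ref$amplicon
  L <- nchar(amp); hi <- rep(35L, L)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  for (pos in 1:4) {
    mut <- amp
    start <- 6 + 3 * (pos - 1) + 1
    codon <- substr(amp, start, start + 2)
    new <- if (codon == "TGG") "TGT" else "TGG"
    substr(mut, start, start + 2) <- new
    call <- call_variant(mut, rc(mut), hi, hi, ref)
    expect_equal(call$position, pos)
    expect_equal(call$n_mismatch_codons, 1L)
  }
})

test_that("simulated FASTQ round-trips to the simulated count table", {
  ref <- tiny_reference()
  eff <- true_effect_map(scan_library(ref), seed = 6)
  des <- selection_design(timepoints = c(0, 20), depth = 400, seed = 6,
                          replicates = 2, error_rate = 0)
  cnt <- simulate_trajectories(eff, des)
  dir <- withr::local_tempdir()
  files <- write_fastq(cnt, ref, des, dir)
  expect_equal(nrow(files), 4L)
  expect_true(all(file.exists(files$r1), file.exists(files$r2)))

  back <- count_reads(files, ref)
  key <- c("position", "mut_codon", "class", "replicate", "timepoint")
  merged <- dplyr::full_join(
    dplyr::select(cnt, dplyr::all_of(key), sim = count),
    dplyr::select(back, dplyr::all_of(key), called = count),
    by = key
  )
  expect_true(all(merged$sim == merged$called))
  qc <- attr(back, "qc")
  expect_true(all(qc$accepted == des$depth))
  expect_true(all(qc$multi_codon == 0))
})

test_that("sequencing errors are quality-flagged and filtered out of counts", {
  ref <- tiny_reference()
  eff <- true_effect_map(scan_library(ref), seed = 8)
  des <- selection_design(timepoints = c(0, 20), depth = 300, seed = 8,
                          replicates = 1, error_rate = 0.01)
  cnt <- simulate_trajectories(eff, des)
  dir <- withr::local_tempdir()
  files <- write_fastq(cnt, ref, des, dir)
  back <- count_reads(files, ref)
  qc <- attr(back, "qc")
  # errors carry q_bad < min_q, so every erroneous pair is rejected, none miscalled
  expect_true(all(qc$rejected_quality > 0))
  expect_true(all(qc$multi_codon == 0))
  key <- c("position", "mut_codon", "class", "replicate", "timepoint")
  merged <- dplyr::inner_join(
    dplyr::select(cnt, dplyr::all_of(key), sim = count),
    dplyr::select(back, dplyr::all_of(key), called = count), by = key)
  expect_true(all(merged$called <= merged$sim))
})

test_that("identical seeds give byte-identical FASTQ output", {
  ref <- tiny_reference()
  eff <- true_effect_map(scan_library(ref), seed = 2)
  des <- selection_design(timepoints = c(0, 10), depth = 200, seed = 5,
                          replicates = 1, error_rate = 0.005)
  cnt <- simulate_trajectories(eff, des)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_fastq(cnt, ref, des, d1)
  f2 <- write_fastq(cnt, ref, des, d2)
  expect_identical(readLines(f1$r1[1]), readLines(f2$r1[1]))
  expect_identical(readLines(f1$r2[1]), readLines(f2$r2[1]))
})
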