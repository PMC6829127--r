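#' Run the full scan pipeline into an artifact directory
#'
#' Orchestrates simulate -> count -> score -> classify -> map -> compare
#' with one set of options, writing every intermediate table plus a
#' run manifest (resolved parameters and file checksums) into a single
#' flat directory. Deterministic given `design$seed`; each stage's output
#' is an ordinary TSV from which later stages can be re-run individually.
#'
#' @param out_dir Artifact directory (created; must not already contain a
#'   manifest unless `overwrite = TRUE`).
#' @param ref A [peptide_reference()] (default [ab42_reference()]).
#' @param design A [selection_design()].
#' @param effects Optional `effect_map`; by default drawn by
#'   [true_effect_map()] from `design$seed`.
#' @param use_fastq Route the simulation through FASTQ files and the read
#'   processor ([write_fastq()] / [count_reads()]) instead of using
#'   simulated counts directly. Slower; exercises the full path.
#' @param pseudocount,x_axis Scoring options, see [score_variants()].
#' @param k,linkage,metric Position-clustering options, see
#'   [hcluster_scores()].
#' @param ddg Optional ddG tibble ([read_ddg_table()]) for score/ddG
#'   correlations (proline and alanine).
#' @param tracks Optional strand-track tibble ([read_strand_tracks()])
#'   for per-model concordance ranking.
#' @param overwrite Allow writing into an existing run directory.
#' @return Invisibly, a named list of the pipeline's tibbles (`counts`,
#'   `scores`, `classified`, `null`, `replicate_correlation`, `matrix`,
#'   `clusters`, `strands`, optional `ddg_correlation`, `model_ranking`)
#'   plus `paths` of written files.
#' @export
run_scan <- function(out_dir, ref = ab42_reference(),
                     design = selection_design(), effects = NULL,
                     use_fastq = FALSE, pseudocount = 0.5,
                     x_axis = c("hours", "index"), k = 6L,
                     linkage = "average", metric = "euclidean",
                     ddg = NULL, tracks = NULL, overwrite = FALSE) {
  x_axis <- match.arg(x_axis)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    abort("`out_dir` already holds a run; set overwrite = TRUE to replace it.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  lib <- scan_library(ref)
  if (is.null(effects)) {
    effects <- stage("effects", true_effect_map(lib, seed = design$seed))
  }
  counts <- stage("simulate", simulate_trajectories(effects, design))
  fastq_manifest <- NULL
  if (use_fastq) {
    fq_dir <- file.path(out_dir, "fastq")
    fastq_manifest <- stage("fastq", write_fastq(counts, ref, design, fq_dir))
    counts <- stage("count", count_reads(fastq_manifest, ref))
  }
  scores <- stage("score", score_variants(counts, pseudocount = pseudocount,
                                          x_axis = x_axis))
  null <- stage("classify", fit_synonymous_null(scores))
  classified <- stage("classify", classify_variants(scores, null = null))
  repcor <- stage("score", replicate_correlation(scores))
  mat <- stage("map", score_matrix(scores, n_positions = ref$n_codons))
  clusters <- stage("map", hcluster_scores(mat, k = k, linkage = linkage,
                                           metric = metric))
  strands <- stage("map", call_buried_strands(clusters, mat))
  ddg_cor <- model_rank <- NULL
  if (!is.null(ddg)) {
    subs <- intersect(unique(ddg$sub), c("P", "A"))
    ddg_cor <- stage("compare",
                     bind_rows(lapply(subs, function(s) scan_correlation(scores, ddg, s))))
  }
  if (!is.null(tracks)) {
    model_rank <- stage("compare", rank_models(strands$positions, tracks))
  }

  paths <- c(
    effects = .write_tsv(effects, file.path(out_dir, "true_effects.tsv")),
    counts = .write_tsv(counts, file.path(out_dir, "counts.tsv")),
    scores = .write_tsv(classified, file.path(out_dir, "scores.tsv")),
    replicate_correlation = .write_tsv(repcor, file.path(out_dir, "replicate_correlation.tsv")),
    matrix = .write_tsv(matrix_to_tibble(mat), file.path(out_dir, "score_matrix.tsv")),
    clusters = .write_tsv(tidy(clusters), file.path(out_dir, "position_clusters.tsv")),
    strands = .write_tsv(strands$segments, file.path(out_dir, "strand_segments.tsv"))
  )
  if (!is.null(ddg_cor)) {
    paths["ddg_correlation"] <- .write_tsv(ddg_cor, file.path(out_dir, "ddg_correlation.tsv"))
  }
  if (!is.null(model_rank)) {
    paths["model_ranking"] <- .write_tsv(model_rank, file.path(out_dir, "model_ranking.tsv"))
  }
  qc <- attr(counts, "qc")
  if (!is.null(qc)) paths["qc"] <- .write_tsv(qc, file.path(out_dir, "qc_report.tsv"))

  manifest <- list(
    package = "aggscan",
    reference = list(name = ref$name, n_codons = ref$n_codons),
    design = unclass(design),
    options = list(pseudocount = pseudocount, x_axis = x_axis, k = k,
                   linkage = linkage, metric = metric, use_fastq = use_fastq),
    null = glance(null),
    strand_positions = strands$positions,
    files = as.list(tools::md5sum(unname(paths)))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    counts = counts, scores = scores, classified = classified, null = null,
    replicate_correlation = repcor, matrix = mat, clusters = clusters,
    strands = strands, ddg_correlation = ddg_cor, model_ranking = model_rank,
    fastq = fastq_manifest, paths = c(paths, manifest = manifest_path)
  ))
}

.write_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  path
}
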