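#' Read a per-substitution ddG table
#'
#' Tab-separated file with columns `position`, `sub` (one-letter mutant
#' residue, e.g. P or A for proline/alanine scans), `ddg` (relative fibril
#' stability change, kcal/mol scale) and `source`.
#'
#' @param path TSV path.
#' @return Tibble with those columns; errors on duplicate
#'   (position, sub, source) rows.
#' @export
read_ddg_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    position = readr::col_integer(), sub = readr::col_character(),
    ddg = readr::col_double(), source = readr::col_character()
  ))
  dup <- x |> count(.data$position, .data$sub, .data$source) |> filter(.data$n > 1)
  if (nrow(dup)) abort("duplicate (position, sub, source) rows in ddG table.")
  x
}

#' Read per-position beta-strand tracks for structural models
#'
#' Tab-separated file with columns `model`, `start`, `end` — one row per
#' strand segment, 1-based inclusive coordinates on the peptide.
#'
#' @param path TSV path.
#' @param n_positions Peptide length for bounds checking (default 42).
#' @return Tibble with `model` and `position` (one row per annotated
#'   strand position).
#' @export
read_strand_tracks <- function(path, n_positions = 42L) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    model = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer()
  ))
  if (any(x$start > x$end)) abort("strand segments must have start <= end.")
  if (any(x$start < 1L | x$end > n_positions)) {
    abort(paste0("strand positions must lie within 1..", n_positions, "."))
  }
  x |>
    mutate(position = purrr::map2(.data$start, .data$end, seq)) |>
    select("model", "position") |>
    tidyr::unnest("position") |>
    distinct()
}

#' Correlation between scan scores and an in vitro ddG substitution scan
#'
#' Coefficient of determination (R^2) of the least-squares line relating
#' the scan's solubility scores for one substitution (e.g. all proline
#' variants) to ddG values at the shared positions. Invariant to affine
#' rescaling of either variable.
#'
#' @param scores A `score_table` tibble.
#' @param ddg Tibble from [read_ddg_table()] (or with columns `position`,
#'   `sub`, `ddg`).
#' @param substitution Mutant residue to compare (e.g. `"P"` or `"A"`).
#' @return One-row tibble: `substitution`, `n`, `r_squared`, `slope`,
#'   `intercept`, plus the shared positions in attribute `"positions"`.
#' @export
scan_correlation <- function(scores, ddg, substitution) {
  sc <- scores |>
    filter(.data$class == "missense", .data$mut_aa == substitution,
           !is.na(.data$score)) |>
    select("position", "score")
  dd <- ddg |>
    filter(.data$sub == substitution) |>
    select("position", "ddg")
  joint <- inner_join(sc, dd, by = "position")
  if (nrow(joint) < 3L) abort("fewer than 3 overlapping positions.")
  fit <- stats::lm(ddg ~ score, data = joint)
  out <- tibble(substitution = substitution, n = nrow(joint),
                # R^2 of a simple least-squares line is the squared Pearson r
                r_squared = stats::cor(joint$score, joint$ddg)^2,
                slope = stats::coef(fit)[["score"]],
                intercept = stats::coef(fit)[["(Intercept)"]])
  attr(out, "positions") <- sort(joint$position)
  attr(out, "data") <- joint
  out
}

#' Concordance between a called position set and a strand track
#'
#' Set agreement between the scan's buried-strand candidate positions (A)
#' and one structural model's beta-strand positions (B): Jaccard
#' |A&B|/|A|B|, precision |A&B|/|A| and recall |A&B|/|B|.
#'
#' @param called Integer vector of called positions (non-empty).
#' @param track Integer vector of the model's strand positions.
#' @return One-row tibble: `n_called`, `n_track`, `n_shared`, `jaccard`,
#'   `precision`, `recall`. An empty track leaves recall `NA` with a
#'   warning.
#' @examples
#' track_concordance(c(1, 2, 3), c(2, 3, 4))
#' @export
track_concordance <- function(called, track) {
  called <- unique(as.integer(called)); track <- unique(as.integer(track))
  if (length(called) == 0L) abort("`called` position set is empty.")
  if (length(track) == 0L) warn("empty strand track; recall undefined.")
  shared <- length(intersect(called, track))
  uni <- length(union(called, track))
  tibble(
    n_called = length(called), n_track = length(track), n_shared = shared,
    jaccard = shared / uni,
    precision = shared / length(called),
    recall = if (length(track) == 0L) NA_real_ else shared / length(track)
  )
}

#' Rank structural models by concordance with called positions
#'
#' @param called Integer vector of called positions (e.g.
#'   `strand_call$positions`).
#' @param tracks Tibble from [read_strand_tracks()] (`model`, `position`).
#' @return Tibble with one row per model, sorted by decreasing Jaccard
#'   (ties broken by model name for order-invariance).
#' @export
rank_models <- function(called, tracks) {
  tracks |>
    group_by(.data$model) |>
    summarise(track_concordance(called, .data$position), .groups = "drop") |>
    arrange(dplyr::desc(.data$jaccard), .data$model)
}
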