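#' Fit the synonymous-variant null distribution
#'
#' Synonymous variants change the codon but not the peptide, so their
#' scores sample the scan's measurement noise around wild-type. The null
#' is summarised by the mean and sample (n-1) standard deviation of the
#' synonymous scores; variants within two standard deviations of the
#' synonymous mean are considered WT-like.
#'
#' @param scores A `score_table` tibble (uses rows with
#'   `class == "synonymous"` and non-missing score), or a numeric vector
#'   of synonymous scores.
#' @param n_sd Half-width of the WT-like interval in standard deviations
#'   (default 2).
#' @return An object of class `synonymous_null`: list with `n`, `mean`,
#'   `sd`, `median`, `n_sd`, `lower`, `upper`. Degenerate nulls
#'   (`sd == 0`) are flagged with a warning.
#' @examples
#' fit_synonymous_null(c(0.1, -0.05, 0.2, 0.0, 0.08))
#' @export
fit_synonymous_null <- function(scores, n_sd = 2) {
  x <- if (is.data.frame(scores)) {
    scores$score[scores$class == "synonymous" & !is.na(scores$score)]
  } else {
    scores[!is.na(scores)]
  }
  if (length(x) < 2L) abort("need at least 2 synonymous scores to fit a null.")
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) warn("synonymous scores are constant; null bounds are degenerate.")
  structure(
    list(n = length(x), mean = m, sd = s, median = stats::median(x), n_sd = n_sd,
         lower = m - n_sd * s, upper = m + n_sd * s),
    class = "synonymous_null"
  )
}

#' @export
print.synonymous_null <- function(x, ...) {
  cat("<synonymous_null> n = ", x$n, ", mean = ", signif(x$mean, 3),
      ", sd = ", signif(x$sd, 3), "\n  WT-like interval (+/- ", x$n_sd,
      " SD): [", signif(x$lower, 3), ", ", signif(x$upper, 3), "]\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.synonymous_null <- function(x, ...) {
  tibble(term = c("mean", "sd", "median", "lower", "upper"),
         estimate = c(x$mean, x$sd, x$median, x$lower, x$upper))
}

#' @exportS3Method generics::glance
glance.synonymous_null <- function(x, ...) {
  tibble(n = x$n, mean = x$mean, sd = x$sd, median = x$median,
         n_sd = x$n_sd, lower = x$lower, upper = x$upper)
}

#' Classify variants against the synonymous null
#'
#' Assigns each scored variant one of three classes using the WT-like
#' interval (inclusive at both ends): score below the lower bound is
#' `more_aggregation_prone`, within the bounds `WT_like`, above the upper
#' bound `more_soluble` (scores below zero denote variants more
#' aggregation-prone than wild-type). Variants without a score are
#' `unclassified`.
#'
#' @param scores A `score_table` tibble with a `score` column.
#' @param null A `synonymous_null` from [fit_synonymous_null()]; fitted
#'   from `scores` when `NULL` and no `bounds` given.
#' @param bounds Optional numeric length-2 vector `c(lower, upper)`
#'   overriding the fitted null (e.g. published cutoffs).
#' @return `scores` with an added `solubility_class` factor column; the
#'   null used is attached as attribute `"null"` (when fitted).
#' @examples
#' tbl <- tibble::tibble(class = "missense", score = c(-0.6, 0.0, 0.64))
#' classify_variants(tbl, bounds = c(-0.26, 0.39))$solubility_class
#' @export
classify_variants <- function(scores, null = NULL, bounds = NULL) {
  if (is.null(bounds)) {
    if (is.null(null)) null <- fit_synonymous_null(scores)
    bounds <- c(null$lower, null$upper)
  }
  if (length(bounds) != 2L || bounds[1] > bounds[2]) {
    abort("`bounds` must be c(lower, upper) with lower <= upper.")
  }
  out <- scores |>
    mutate(solubility_class = factor(
      dplyr::case_when(
        is.na(.data$score) ~ "unclassified",
        .data$score < bounds[1] ~ "more_aggregation_prone",
        .data$score > bounds[2] ~ "more_soluble",
        TRUE ~ "WT_like"
      ),
      levels = c("more_aggregation_prone", "WT_like", "more_soluble", "unclassified")
    ))
  attr(out, "null") <- null
  attr(out, "bounds") <- bounds
  out
}

#' Summarise classification results
#'
#' @param classified Output of [classify_variants()].
#' @param classes Which variant classes to count (default missense only,
#'   the scan's analysis set).
#' @return Tibble of counts and percentages per solubility class.
#' @export
classification_summary <- function(classified,
                                   classes = "missense") {
  x <- filter(classified, .data$class %in% classes, !is.na(.data$score))
  x |>
    count(.data$solubility_class, .drop = FALSE, name = "n") |>
    filter(.data$solubility_class != "unclassified") |>
    mutate(pct = round(100 * .data$n / sum(.data$n), 1))
}
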