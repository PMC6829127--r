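test_that("normalized log ratios follow the log2 count arithmetic", {
  # equal counts give a flat zero trajectory
  eq <- toy_count_table(c(50, 50, 50), c(50, 50, 50)) |>
    aggregate_counts() |>
    normalized_log_ratios(pseudocount = 0)
  expect_equal(eq$m[eq$class == "missense"], c(0, 0, 0))
  # doubling the WT count gives exactly one log2 unit
  dbl <- toy_count_table(c(100), c(50)) |>
    aggregate_counts() |>
    normalized_log_ratios(pseudocount = 0)
  expect_equal(dbl$m[dbl$class == "missense"], 1)
  # the worked two-timepoint example
  two <- toy_count_table(c(10, 40), c(100, 100)) |>
    aggregate_counts() |>
    normalized_log_ratios(pseudocount = 0)
  expect_equal(two$m[two$class == "missense"], c(-3.321928, -1.321928),
               tolerance = 1e-6)
  # pseudocount shifts numerator and denominator symmetrically: WT stays 0
  ps <- toy_count_table(c(10, 40), c(100, 100)) |>
    aggregate_counts() |>
    normalized_log_ratios(pseudocount = 0.5)
  expect_equal(ps$m[ps$class == "WT"], c(0, 0))
  expect_equal(ps$m[ps$class == "missense"], log2(c(10.5, 40.5) / 100.5))
})

test_that("weighted slopes reproduce exact lines and reduce to OLS", {
  # an exact line is recovered under any positive weights
  x <- c(0, 28, 31.5, 35, 38, 40)
  m <- 0.3 + 0.5 * x
  for (w in list(rep(1, 6), c(5, 1, 2, 9, 1, 3))) {
    expect_equal(wls_slope(m, x, w)$slope, 0.5, tolerance = 1e-12)
  }
  # equal weights match the ordinary least-squares closed form
  set.seed(11)
  m2 <- rnorm(6)
  ols <- sum((x - mean(x)) * (m2 - mean(m2))) / sum((x - mean(x))^2)
  expect_equal(wls_slope(m2, x)$slope, ols, tolerance = 1e-12)
  # degenerate designs are flagged, not silently fit
  expect_warning(out <- wls_slope(c(1, 2), c(3, 3)), "degenerate")
  expect_true(is.na(out$slope))
  expect_warning(out1 <- wls_slope(1, 1), "fewer than 2")
  expect_true(is.na(out1$slope))
})

test_that("weighted slopes agree with independent oracles on random instances", {
  set.seed(42)
  worst <- 0
  for (i in seq_len(1000)) {
    n <- sample(3:8, 1)
    x <- sort(rnorm(n, sd = 10))
    m <- rnorm(n, sd = 2)
    w <- rexp(n) + 0.05
    got <- wls_slope(m, x, w)
    ora <- wls_oracle(m, x, w)
    worst <- max(worst, abs(got$slope - ora$slope), abs(got$se - ora$se))
  }
  expect_lt(worst, 1e-8)
  # spot-check against lm and against brute-force profile minimization
  set.seed(7)
  x <- c(0, 28, 31.5, 35, 38, 40); m <- rnorm(6); w <- runif(6, 0.2, 3)
  fit <- lm(m ~ x, weights = w)
  got <- wls_slope(m, x, w)
  expect_equal(got$slope, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(got$se, summary(fit)$coefficients[2, 2], tolerance = 1e-8)
  expect_equal(got$slope, wls_grid_oracle(m, x, w, b_range = c(-1, 1)),
               tolerance = 1e-6)
})

test_that("log ratios and equal-weight slopes ignore per-timepoint depth rescaling", {
  cnt <- toy_count_table(c(10, 25, 60, 110), c(100, 90, 80, 70),
                         times = c(0, 10, 20, 30))
  scaled <- cnt |>
    dplyr::mutate(count = count * c(1, 7, 3, 11)[timepoint])
  # sequencing depth cancels inside each sample's variant/WT ratio (p = 0)
  m1 <- normalized_log_ratios(aggregate_counts(cnt), pseudocount = 0)
  m2 <- normalized_log_ratios(aggregate_counts(scaled), pseudocount = 0)
  expect_equal(m1$m, m2$m, tolerance = 1e-12)
  s1 <- score_variants(cnt, pseudocount = 0, weighted = FALSE)
  s2 <- score_variants(scaled, pseudocount = 0, weighted = FALSE)
  expect_equal(s1$score, s2$score, tolerance = 1e-12)
  # inverse-variance weights, by design, give deeper timepoints more say
  w1 <- score_variants(cnt, pseudocount = 0)
  w2 <- score_variants(scaled, pseudocount = 0)
  expect_false(isTRUE(all.equal(w1$score[2], w2$score[2], tolerance = 1e-6)))
})

test_that("the WT score is exactly zero and replicate slopes average into the score", {
  ref <- tiny_reference()
  eff <- true_effect_map(scan_library(ref), seed = 13)
  des <- selection_design(depth = 4000, seed = 13)
  sc <- simulate_trajectories(eff, des) |> score_variants()
  expect_identical(sc$score[sc$class == "WT"], 0)
  reps <- as.matrix(sc[, c("slope_rep1", "slope_rep2", "slope_rep3")])
  expect_equal(sc$score, rowMeans(reps), tolerance = 1e-12)
  # the explicit averaging example
  expect_equal(mean(c(0.4, 0.6, 0.5)), 0.5)
})

test_that("variants sequenced in no timepoint come out unmeasured", {
  cnt <- dplyr::bind_rows(
    toy_count_table(c(10, 20), c(100, 100), times = c(0, 10)),
    tibble::tibble(position = 3L, wt_codon = "TTT", wt_aa = "F",
                   mut_codon = "TGG", mut_aa = "W", class = "missense",
                   replicate = 1L, timepoint = 1:2, time_h = c(0, 10),
                   count = c(0, 0))
  )
  sc <- score_variants(cnt)
  w_row <- dplyr::filter(sc, mut_aa %in% "W")
  expect_true(is.na(w_row$score))
  expect_equal(w_row$n_reps, 0L)
  expect_false(is.na(dplyr::filter(sc, mut_aa %in% "D")$score))
})

test_that("amino-acid aggregation pools codon counts for the same substitution", {
  base <- tibble::tibble(
    replicate = 1L, timepoint = rep(1:2, each = 3),
    time_h = rep(c(0, 10), each = 3)
  )
  cnt <- dplyr::bind_rows(
    tibble::tibble(position = 0L, wt_codon = NA, wt_aa = NA, mut_codon = NA,
                   mut_aa = NA, class = "WT", replicate = 1L, timepoint = 1:2,
                   time_h = c(0, 10), count = c(100, 100)),
    tibble::tibble(position = 2L, wt_codon = "AAA", wt_aa = "K",
                   mut_codon = rep(c("GAT", "GAC"), 2), mut_aa = "D",
                   class = "missense",
                   replicate = 1L, timepoint = rep(1:2, each = 2),
                   time_h = rep(c(0, 10), each = 2),
                   count = c(10, 30, 20, 60))
  )
  agg <- aggregate_counts(cnt)
  d <- agg[agg$class == "missense", ]
  expect_equal(nrow(d), 2L)            # one row per timepoint
  expect_equal(sort(d$count), c(40, 80))
  codon <- aggregate_counts(cnt, level = "codon")
  expect_equal(nrow(codon[codon$class == "missense", ]), 4L)
})

test_that("replicate correlations behave like Pearson correlations should", {
  ref <- tiny_reference()
  eff <- true_effect_map(scan_library(ref), seed = 21)
  des <- selection_design(depth = 3000, seed = 21, replicates = 3)
  sc <- simulate_trajectories(eff, des) |> score_variants()
  rc <- replicate_correlation(sc)
  expect_equal(nrow(rc), 3L)
  expect_true(all(rc$r >= -1 & rc$r <= 1))
  # a replicate against itself correlates perfectly
  sc2 <- sc
  sc2$slope_rep2 <- sc2$slope_rep1
  expect_equal(replicate_correlation(sc2)$r[1], 1)
  # deeper sequencing makes replicates agree better
  des_lo <- selection_design(depth = 300, seed = 33, replicates = 2)
  des_hi <- selection_design(depth = 3e4, seed = 33, replicates = 2)
  eff2 <- true_effect_map(scan_library(ab42_reference()), seed = 33)
  r_lo <- replicate_correlation(simulate_trajectories(eff2, des_lo) |> score_variants())$r
  r_hi <- replicate_correlation(simulate_trajectories(eff2, des_hi) |> score_variants())$r
  expect_gt(r_hi, r_lo)
})

test_that("doubling rates come out of the OD logarithm formula", {
  expect_equal(doublings_per_time(0.1, 0.2, 1), 1)
  expect_equal(doublings_per_time(0.5, 0.5, 3), 0)
  expect_equal(doublings_per_time(0.1, 0.8, 6), 0.5)
  expect_equal(doublings_per_time(c(0.1, 0.2), c(0.2, 0.4), c(1, 1)), c(1, 1))
  expect_error(doublings_per_time(0, 0.2, 1), "positive")
  expect_error(doublings_per_time(0.1, 0.2, 0), "positive")
})
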