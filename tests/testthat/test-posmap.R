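test_that("the score matrix is dense, masked, and round-trips bit-exactly", {
  ref <- ab42_reference()
  eff <- true_effect_map(scan_library(ref), seed = 23)
  des <- selection_design(depth = 5e4, seed = 23)
  sc <- simulate_trajectories(eff, des) |> score_variants()
  mat <- score_matrix(sc, n_positions = 42)
  expect_equal(dim(mat), c(42L, 20L))
  # a complete simulated scan leaves no missing cells
  expect_equal(sum(attr(mat, "missing")), 0L)
  expect_equal(sum(attr(mat, "wt")), 42L)          # one WT cell per position
  expect_equal(attr(mat, "wt_aa"), strsplit(ref$protein, "")[[1]])
  # round trip: every missense score lands in its cell unchanged
  long <- matrix_to_tibble(mat) |> dplyr::filter(!is.na(score))
  back <- dplyr::inner_join(
    long, dplyr::filter(sc, class == "missense"),
    by = c("position", "mut_aa"))
  expect_identical(back$score.x, back$score.y)
  # duplicated cells are refused
  dup <- dplyr::bind_rows(sc, sc[sc$class == "missense", ][1, ])
  expect_error(score_matrix(dup), "duplicate")
})

test_that("position and residue summaries do the right arithmetic", {
  vals <- matrix(0, 3, 3, dimnames = list(NULL, c("A", "D", "W")))
  zero <- grid_score_table(vals)
  mz <- score_matrix(zero, n_positions = 3)
  expect_true(all(position_summaries(mz)$mean_all == 0))

  # shift every aspartate substitution up by one: its median leads by ~1
  vals2 <- matrix(rnorm(60, 0, 0.05), 20,
                  dimnames = list(NULL, NULL))
  dim(vals2) <- c(20, 3); colnames(vals2) <- c("A", "D", "W")
  vals2[, "D"] <- vals2[, "D"] + 1
  m2 <- score_matrix(grid_score_table(vals2), n_positions = 20)
  aa <- aa_summaries(m2)
  expect_gt(aa$median[aa$mut_aa == "D"] - max(aa$median[aa$mut_aa != "D"], na.rm = TRUE), 0.8)
  # a single-position matrix has medians equal to its row
  one <- score_matrix(grid_score_table(matrix(c(0.2, -0.4, 1),
                                              1, dimnames = list(NULL, c("A", "D", "W")))),
                      n_positions = 1)
  aa1 <- aa_summaries(one)
  expect_equal(aa1$median[match(c("A", "D", "W"), aa1$mut_aa)], c(0.2, -0.4, 1))
  # hydrophobic means exclude polar residues and vice versa
  ps <- position_summaries(m2)
  long <- matrix_to_tibble(m2) |> dplyr::filter(!is_wt)
  hyd <- long |>
    dplyr::filter(mut_aa %in% c("A", "W")) |>   # the hydrophobics among A/D/W
    dplyr::summarise(m = mean(score), .by = position) |>
    dplyr::arrange(position)
  expect_equal(ps$mean_hydrophobic, hyd$m)
  pol <- long |>
    dplyr::filter(mut_aa == "D") |>
    dplyr::arrange(position)
  expect_equal(ps$mean_polar, pol$score)
})

test_that("hierarchical clustering recovers planted blocks and stays deterministic", {
  set.seed(41)
  # two well-separated blocks of position vectors
  block <- rbind(
    matrix(rnorm(10 * 6, 5, 0.1), 10),
    matrix(rnorm(8 * 6, -5, 0.1), 8)
  )
  colnames(block) <- c("A", "D", "E", "K", "S", "W")
  tbl <- grid_score_table(block)
  mat <- score_matrix(tbl, n_positions = 18)
  cl <- hcluster_scores(mat, k = 2, max_missing = 0.9)
  expect_equal(cl$cluster, rep(c(1L, 2L), c(10, 8)))
  expect_equal(glance(cl)$n_nonempty, 2L)

  # permuting row order relabels but does not regroup
  perm <- sample(nrow(tbl))
  cl2 <- hcluster_scores(score_matrix(tbl[perm, ], n_positions = 18), k = 2, max_missing = 0.9)
  grouping <- function(x) split(x$item, x$cluster)
  expect_setequal(unname(purrr::map_chr(grouping(cl), paste, collapse = ",")),
                  unname(purrr::map_chr(grouping(cl2), paste, collapse = ",")))

  # six clusters on a 42-position simulated matrix are all non-empty
  eff <- true_effect_map(scan_library(ab42_reference()), seed = 29)
  des <- selection_design(depth = 3e4, seed = 29)
  sc <- simulate_trajectories(eff, des) |> score_variants()
  cl6 <- hcluster_scores(score_matrix(sc, n_positions = 42), k = 6)
  expect_equal(dplyr::n_distinct(cl6$cluster), 6L)
  expect_setequal(cl6$item, 1:42)

  # degenerate inputs are refused
  same <- grid_score_table(matrix(1, 5, 3, dimnames = list(NULL, c("A", "D", "W"))))
  expect_error(hcluster_scores(score_matrix(same, n_positions = 5), k = 2,
                               max_missing = 0.9), "identical")
  expect_error(hcluster_scores(mat, k = 50, max_missing = 0.9), "exceeds")
})

test_that("buried-strand calling selects the most solubilising cluster", {
  set.seed(43)
  vals <- matrix(rnorm(42 * 6, -0.3, 0.05), 42)
  colnames(vals) <- c("A", "D", "E", "K", "S", "W")
  hot <- c(10:14, 30:31)
  vals[hot, ] <- vals[hot, ] + 2          # substitutions here boost solubility
  mat <- score_matrix(grid_score_table(vals), n_positions = 42)
  cl <- hcluster_scores(mat, k = 2, max_missing = 0.9)
  call <- call_buried_strands(cl, mat)
  expect_setequal(call$positions, hot)
  expect_equal(call$segments,
               tibble::tibble(start = c(10L, 30L), end = c(14L, 31L)))
  # the call only depends on score differences, not the absolute level
  mat_shift <- mat + 5
  for (a in c("wt_aa", "wt", "missing")) attr(mat_shift, a) <- attr(mat, a)
  call2 <- call_buried_strands(hcluster_scores(mat_shift, k = 2, max_missing = 0.9), mat_shift)
  expect_equal(call2$positions, call$positions)
  # an all-equal matrix has no dominating cluster
  same <- score_matrix(grid_score_table(
    matrix(1, 6, 3, dimnames = list(NULL, c("A", "D", "W")))), n_positions = 6)
  expect_error(call_buried_strands(hcluster_scores(same, k = 2, max_missing = 0.9), same),
               "identical")
})

test_that("contiguous segments compress position sets correctly", {
  segs <- aggscan:::contiguous_segments(c(17, 18, 19, 20, 31, 32, 34, 35, 39, 41))
  expect_equal(segs$start, c(17L, 31L, 34L, 39L, 41L))
  expect_equal(segs$end, c(20L, 32L, 35L, 39L, 41L))
  expect_equal(nrow(aggscan:::contiguous_segments(integer())), 0L)
})

test_that("hydrophobicity annotation follows the Kyte-Doolittle scale", {
  expect_equal(hydrophobicity("I"), 4.5)
  expect_equal(hydrophobicity("R"), -4.5)
  expect_gt(hydrophobicity("F"), 0)
  expect_lt(hydrophobicity("D"), 0)
})
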