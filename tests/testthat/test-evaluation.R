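mk_preds <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(protein_id = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), score = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)))
}

test_that("candidate collection keeps strictly above-threshold windows", {
  track <- data.frame(protein_id = "p", start = 1:10,
                      llr = rep(0, 10), length = 13L)
  expect_equal(nrow(collect_candidates(track, 0)), 0L)
  expect_equal(nrow(collect_candidates(track, -Inf)), 10L)
  set.seed(70)
  track$llr <- stats::rnorm(10)
  got <- collect_candidates(track, 0.3)
  expect_equal(got$start, track$start[track$llr > 0.3])
  expect_equal(got$end, got$start + 12L)
})

test_that("labelling keeps one max-score representative per truth motif and per tile", {
  truth <- data.frame(protein_id = "p", start = 50L, end = 60L)
  none <- label_predictions(
    data.frame(protein_id = character(0), start = integer(0),
               end = integer(0), score = numeric(0)), truth)
  expect_equal(nrow(none$true_positives), 0L)
  expect_equal(nrow(none$false_positives), 0L)

  # two predictions overlap the truth motif: one TP (the higher), no FP
  lab <- label_predictions(mk_preds(list("p", 45, 57, 1.2), list("p", 55, 67, 3.4)),
                           truth)
  expect_equal(nrow(lab$true_positives), 1L)
  expect_equal(lab$true_positives$score, 3.4)
  expect_equal(nrow(lab$false_positives), 0L)

  # three chained non-truth predictions collapse to one FP with the max score
  lab2 <- label_predictions(
    mk_preds(list("p", 100, 112, 1.0), list("p", 110, 122, 2.0),
             list("p", 120, 132, 1.5)), truth)
  expect_equal(nrow(lab2$false_positives), 1L)
  expect_equal(lab2$false_positives$score, 2.0)

  # non-chained predictions stay separate tiles
  lab3 <- label_predictions(
    mk_preds(list("p", 100, 112, 1.0), list("p", 200, 212, 2.0)), truth)
  expect_equal(nrow(lab3$false_positives), 2L)

  expect_error(label_predictions(mk_preds(list("q", 1, 13, 1)), truth),
               "absent from the truth set")
})

test_that("one prediction may represent two overlapping truth motifs unless exclusive", {
  truth2 <- data.frame(protein_id = "p", start = c(50L, 58L), end = c(57L, 70L))
  span <- mk_preds(list("p", 55, 60, 2.0))
  lab <- label_predictions(span, truth2)
  expect_equal(nrow(lab$true_positives), 2L)
  labx <- label_predictions(span, truth2, exclusive = TRUE)
  expect_equal(nrow(labx$true_positives), 1L)
})

test_that("labelling is idempotent on its own representatives", {
  truth <- data.frame(protein_id = "p", start = c(50L, 200L), end = c(60L, 215L))
  set.seed(71)
  preds <- mk_preds(list("p", 45, 57, 1.2), list("p", 55, 67, 3.4),
                    list("p", 100, 112, 1.0), list("p", 110, 122, 2.0),
                    list("p", 205, 217, 0.7), list("p", 300, 312, 1.1))
  lab <- label_predictions(preds, truth)
  reps <- rbind(lab$true_positives[, c("protein_id", "start", "end", "score")],
                lab$false_positives)
  lab2 <- label_predictions(reps, truth)
  expect_equal(lab2$true_positives, lab$true_positives, ignore_attr = TRUE)
  expect_equal(lab2$false_positives, lab$false_positives, ignore_attr = TRUE)
})

test_that("ROC sweeps thresholds monotonically from (0, 0)", {
  truth <- data.frame(protein_id = "p", start = c(10L, 50L), end = c(20L, 60L))
  lab <- label_predictions(
    mk_preds(list("p", 12, 24, 5.0), list("p", 52, 64, 2.0),
             list("p", 100, 112, 3.0), list("p", 150, 162, 1.0)), truth)
  roc <- roc_points(lab, n_negative_residues = 1000L)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_equal(max(roc$tpr), 1)
  expect_error(roc_points(lab, 0), "negative residues")
})

test_that("a perfect separator's curve passes through (0, 1)", {
  truth <- data.frame(protein_id = "p", start = c(10L, 50L), end = c(20L, 60L))
  lab <- label_predictions(
    mk_preds(list("p", 12, 24, 9.0), list("p", 52, 64, 8.0),
             list("p", 100, 112, 1.0)), truth)
  roc <- roc_points(lab, 1000L)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_equal(roc_auc(roc), 1)
})

test_that("negative-residue and proteome-rate arithmetic match the stated protocol", {
  expect_identical(negative_residues(145512, 2989), 142523L)
  expect_equal(round(proteome_fpr(700, 5917, 495), 6), 0.000242)
  expect_equal(proteome_fpr(123, 123, 1, round_digits = NULL), 1)
  expect_equal(proteome_fpr(700, 5917, 495, round_digits = NULL),
               (700 / 5917) / 495, tolerance = 1e-12)
})

test_that("predictor comparison reproduces exhaustive Fisher enumeration", {
  expect_equal(compare_predictors(5, 5, 5, 5), 1)
  p <- compare_predictors(10, 0, 0, 10)
  expect_equal(p, bf_fisher_p(10, 0, 0, 10), tolerance = 1e-9)
  expect_equal(compare_predictors(7, 3, 2, 8), bf_fisher_p(7, 3, 2, 8),
               tolerance = 1e-9)
  expect_equal(compare_predictors(7, 3, 2, 8), compare_predictors(2, 8, 7, 3))
  expect_error(compare_predictors(0, 0, 0, 0), "all-zero")
})

test_that("average-linkage clustering matches a hand trace and is deterministic", {
  # rows at 1-D coordinates 0, 3, 8: {1,2} merge at 3, then {3} joins at
  # mean(8, 5) = 6.5
  mat <- matrix(c(0, 3, 8), ncol = 1)
  cl <- cluster_posteriors(mat)
  expect_equal(cl$height, c(3, 6.5))
  expect_equal(cl$merge[1, ], c(-1, -2))
  expect_setequal(cl$order, 1:3)
  # duplicate rows merge first at height 0
  dup <- rbind(c(1, 0), c(0, 5), c(1, 0))
  cld <- cluster_posteriors(dup)
  expect_equal(cld$height[1], 0)
  expect_equal(sort(cld$merge[1, ]), c(-3, -1))
  expect_error(cluster_posteriors(rbind(c(1, NA), c(0, 1))), "NA")
  expect_error(cluster_posteriors(matrix(1, 1, 2)), "at least 2 rows")
})

test_that("a random predictor's pooled ROC is near chance under the harness", {
  m <- synthetic_nes_model()
  labs <- list(); tot <- 0; mot <- 0
  for (seed in 1:20) {
    sim <- generate_proteome(simulation_spec(m, n_proteins = 20, seed = seed))
    set.seed(seed + 1000)
    preds <- do.call(rbind, lapply(names(sim$sequences), function(id) {
      n <- nchar(sim$sequences[[id]])
      starts <- sort(sample.int(n - 12L, max(1L, round(n / 25))))
      data.frame(protein_id = id, start = starts, end = starts + 12L,
                 score = stats::rnorm(length(starts)))
    }))
    labs[[seed]] <- label_predictions(preds, sim$truth)
    tot <- tot + sum(nchar(sim$sequences))
    mot <- mot + sum(sim$truth$end - sim$truth$start + 1)
  }
  roc <- roc_points(labs, negative_residues(tot, mot))
  expect_lt(abs(roc_auc(roc) - 0.5), 0.05)
})
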