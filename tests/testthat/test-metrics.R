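test_that("detection threshold is the interpolated upper quantile of all background windows", {
  m <- linear_model(rep(0, 16), l = 4)         # all energies 0
  bg <- make_window_bags(labeled_sequences("b", "ACGTACGT", -1L), 4)
  expect_equal(detection_threshold(m, bg, 0.001), 0)
  # energies {1..1000}: build via quantile identity directly on the helper
  expect_equal(unname(stats::quantile(1:1000, 0.999, type = 7)), 999.001)
  # monotone as q decreases
  set.seed(22)
  m2 <- linear_model(rnorm(16), l = 4)
  bg2 <- make_window_bags(random_seq_table(10, 50, -1L, "b"), 4)
  th <- vapply(c(0.05, 0.01, 0.001), function(q) detection_threshold(m2, bg2, q),
               numeric(1))
  expect_true(all(diff(th) >= 0))
})

test_that("contingency tables follow the strict inequalities", {
  set.seed(23)
  m <- linear_model(rnorm(16), l = 4)
  fg <- make_window_bags(random_seq_table(5, 30, 1L, "f"), 4)
  bg <- make_window_bags(random_seq_table(4, 30, -1L, "b"), 4)
  ef <- vapply(fg, function(b) sequence_energy(m, b)$energy, numeric(1))
  eb <- vapply(bg, function(b) sequence_energy(m, b)$energy, numeric(1))
  t1 <- contingency(m, fg, bg, min(c(ef, eb)) - 1)  # below every energy
  expect_equal(c(t1$fn, t1$fp), c(0L, 4L))
  t2 <- contingency(m, fg, bg, max(c(ef, eb)) + 1)  # above every energy
  expect_equal(c(t2$fn, t2$fp), c(5L, 0L))
  # a sequence exactly at threshold: fg counted present, bg counted absent
  t3 <- contingency(m, fg, bg, ef[1])
  expect_equal(t3$fn, sum(ef < ef[1]))
  expect_equal(t3$fp, sum(eb > ef[1]))
  # hand-enumerated mixed table
  t4 <- contingency(m, fg, bg, stats::median(c(ef, eb)))
  expect_equal(t4$tp + t4$fn, 5); expect_equal(t4$fp + t4$tn, 4)
})

test_that("classification accuracy is (tp+tn)/N", {
  expect_equal(classification_accuracy(contingency_table(10, 0, 0, 10)), 1)
  expect_equal(classification_accuracy(contingency_table(0, 10, 10, 0)), 0)
  expect_equal(classification_accuracy(contingency_table(50, 0, 10, 40)), 0.9)
})

test_that("AUC is the tie-aware pair-winning probability", {
  expect_equal(auc_score(c(2, 3), c(0, 1)), 1)
  expect_equal(auc_score(c(1, 2), c(1, 2)), 0.5)
  expect_equal(auc_score(c(1, 3), c(2, 0)), 0.75)
  set.seed(24)
  for (i in 1:50) {
    fg <- sample(1:6, sample(2:8, 1), replace = TRUE)   # many ties
    bg <- sample(1:6, sample(2:8, 1), replace = TRUE)
    expect_equal(auc_score(fg, bg), oracle_auc(fg, bg))
    expect_equal(auc_score(fg, bg) + auc_score(bg, fg), 1)
  }
})

test_that("Fisher's score matches closed forms and the summation oracle", {
  expect_equal(fisher_score(contingency_table(0, 5, 3, 2)), 0)
  expect_equal(fisher_score(contingency_table(10, 0, 0, 10)),
               log10(1 / choose(20, 10)), tolerance = 1e-12)
  expect_equal(fisher_score(contingency_table(10, 0, 0, 10)), -5.2667,
               tolerance = 1e-4)
  expect_equal(fisher_score(contingency_table(1, 1, 1, 1)), log10(5 / 6),
               tolerance = 1e-12)
  set.seed(25)
  for (i in 1:60) {
    tp <- sample(0:4, 1); fn <- sample(0:4, 1)
    fp <- sample(0:4, 1); tn <- sample(0:4, 1)
    if (tp + fn == 0 || fp + tn == 0) next
    expect_equal(fisher_score(contingency_table(tp, fn, fp, tn)),
                 oracle_fisher_log10(tp, fn, fp, tn), tolerance = 1e-9)
  }
})

test_that("MHG score matches prefix enumeration and is a rank statistic", {
  expect_equal(mhg_score(c(1, 2), c(3, 4)), 0)                  # reversed ranking
  expect_equal(mhg_score(c(3, 4), c(1, 2)), log10(1 / 6),
               tolerance = 1e-12)                               # perfect ranking
  expect_equal(mhg_score(c(3, 4), c(1, 2)), -0.778, tolerance = 1e-3)
  set.seed(26)
  for (i in 1:40) {
    fg <- sample(1:8, sample(2:6, 1), replace = TRUE)
    bg <- sample(1:8, sample(2:6, 1), replace = TRUE)
    expect_equal(mhg_score(fg, bg), oracle_mhg_log10(fg, bg), tolerance = 1e-9)
    expect_equal(mhg_score(exp(fg), exp(bg)), mhg_score(fg, bg),
                 tolerance = 1e-12)  # monotone-transform invariance
  }
})

test_that("nCC matches the formula and sign conventions", {
  seqs <- labeled_sequences("s", strrep("A", 100), 1L)
  truth <- data.frame(id = "s", start = 10, end = 30)
  expect_equal(ncc(truth, truth, seqs), 1)
  # counts (TP,TN,FP,FN) = (50,40,10,0): predictions [0,60), truth [0,50), len 100
  seqs2 <- labeled_sequences("s", strrep("A", 100), 1L)
  pred <- data.frame(id = "s", start = 0, end = 60)
  tru <- data.frame(id = "s", start = 0, end = 50)
  expect_equal(ncc(pred, tru, seqs2), 2000 / sqrt(6e6), tolerance = 1e-12)
  # disjoint complement -> negative
  pred2 <- data.frame(id = "s", start = 50, end = 100)
  expect_lt(ncc(pred2, tru, seqs2), 0)
  # degenerate marginal -> 0
  expect_equal(ncc(pred[0, ], tru, seqs2), 0)
})

test_that("sASP rewards quarter-length overlaps", {
  truth <- data.frame(id = c("a", "b"), start = c(10, 20), end = c(18, 28))
  expect_equal(sasp(truth, truth), 1)
  half <- truth[1, ]
  expect_equal(sasp(half, truth), (0.5 + 1) / 2)
  expect_equal(sasp(truth[0, ], truth), 0)
  # a 2 nt overlap meets ceiling(8/4) = 2
  shifted <- data.frame(id = "a", start = 16, end = 24)
  expect_equal(sasp(shifted, truth), (0.5 + 1) / 2)
  # a 1 nt overlap does not
  barely <- data.frame(id = "a", start = 17, end = 25)
  expect_equal(sasp(barely, truth), 0)
})

test_that("cross-validation trains on 2 folds and generalizes on the third", {
  set.seed(44)
  d <- small_planted_set(n = 24, len = 50, seed = 123)
  cfg <- discovery_config(motif_length = 8, seed_length = 8, n_seeds = 2)
  cv <- cross_validate(d$F, d$B, cfg, n_folds = 3)
  expect_equal(nrow(cv$folds), 3L)
  expect_true(all(c("train_auc", "test_auc", "train_fisher", "test_mhg")
                  %in% names(cv$folds)))
  expect_true(all(cv$folds$train_auc >= 0 & cv$folds$train_auc <= 1))
  # planted word in every foreground sequence: held-out detection works too
  expect_gt(cv$mean[["test_auc"]], 0.6)
  # training fit at least as good as held-out performance, on average
  expect_gte(cv$mean[["train_auc"]], cv$mean[["test_auc"]] - 0.05)
})

test_that("cross-validation folds are stratified with sizes differing by at most 1", {
  set.seed(27)
  f9 <- wsmd:::stratified_folds(9, 3, 1)
  expect_equal(unname(table(f9)), rep(3L, 3), ignore_attr = TRUE)
  f10 <- wsmd:::stratified_folds(10, 3, 1)
  expect_equal(sort(unname(table(f10)), decreasing = TRUE), c(4L, 3L, 3L),
               ignore_attr = TRUE)
  expect_error(wsmd:::stratified_folds(2, 3, 1), "too few")
})
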