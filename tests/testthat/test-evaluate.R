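test_that("confusion counts enumerate the four cells", {
  cm <- nm_confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_identical(unname(cm[c("TP", "TN", "FP", "FN")]), c(2L, 2L, 0L, 0L))
  cm <- nm_confusion(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_identical(unname(cm[c("TP", "TN")]), c(0L, 0L))
  cm <- nm_confusion(c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_identical(unname(cm[c("TP", "FP", "FN", "TN")]), c(1L, 1L, 1L, 1L))
  expect_error(nm_confusion(c(1, 0), 1), class = "nm_validation_error")
})

test_that("metrics reproduce the worked confusion case", {
  perfect <- nm_metrics(c(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unname(perfect[c("Sn", "Sp", "Acc", "MCC")]), c(1, 1, 1, 1))
  m <- nm_metrics(c(TP = 40, FN = 10, TN = 35, FP = 15))
  expect_equal(m[["Sn"]], 0.8)
  expect_equal(m[["Sp"]], 0.7)
  expect_equal(m[["Acc"]], 0.75)
  # direct substitution: (40*35 - 15*10) / sqrt(50*55*45*50)
  expect_equal(m[["MCC"]], 1250 / sqrt(6187500), tolerance = 1e-12)
  expect_equal(round(m[["MCC"]], 4), 0.5025)
})

test_that("metric degeneracies follow the stated conventions", {
  m <- nm_metrics(c(TP = 50, FN = 0, TN = 0, FP = 50))
  expect_equal(m[["Acc"]], 0.5)
  expect_equal(m[["Sp"]], 0)
  expect_identical(m[["MCC"]], 0)       # zero denominator convention
  m2 <- nm_metrics(c(TP = 0, FN = 0, TN = 7, FP = 3))
  expect_true(is.na(m2[["Sn"]]))        # undefined, not zero
  expect_error(nm_metrics(c(TP = 0, TN = 0, FP = 0, FN = 0)),
               class = "nm_validation_error")
})

test_that("metric bounds and MCC antisymmetry hold under fuzzing", {
  set.seed(51)
  for (i in 1:500) {
    cts <- as.integer(rpois(4, lambda = sample(c(1, 5, 50), 1)))
    names(cts) <- c("TP", "TN", "FP", "FN")
    if (sum(cts) == 0) next
    m <- nm_metrics(cts)
    expect_true(is.na(m[["Sn"]]) || (m[["Sn"]] >= 0 && m[["Sn"]] <= 1))
    expect_true(is.na(m[["Sp"]]) || (m[["Sp"]] >= 0 && m[["Sp"]] <= 1))
    expect_true(m[["Acc"]] >= 0 && m[["Acc"]] <= 1)
    expect_true(m[["MCC"]] >= -1 && m[["MCC"]] <= 1)
    # inverting predictions swaps TP<->FP and TN<->FN: MCC flips sign
    inv <- nm_metrics(c(TP = cts[["FP"]], TN = cts[["FN"]],
                        FP = cts[["TP"]], FN = cts[["TN"]]))
    expect_equal(inv[["MCC"]], -m[["MCC"]])
  }
})

test_that("AUC equals the Mann-Whitney statistic, ties averaged", {
  r <- nm_roc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1))
  expect_equal(r$auc, 0.75)
  expect_equal(nm_roc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(nm_roc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_error(nm_roc(c(1, 1), c(0.2, 0.4)), class = "nm_validation_error")
  set.seed(52)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 1)           # coarse grid forces ties
    expect_equal(nm_roc(labels, scores)$auc, o_auc(labels, scores))
  }
  # curve endpoints
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
})

test_that("stratified 80:20 split is balanced, seeded and exhaustive", {
  labels <- rep(c(0, 1), each = 50)
  sp <- nm_split(labels, seed = 5)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_identical(sum(labels[sp$test]), 10)
  expect_identical(sort(c(sp$train, sp$test)), 1:100)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(nm_split(labels, seed = 5), sp)
  expect_false(identical(nm_split(labels, seed = 6)$test, sp$test))
  expect_error(nm_split(c(0, 0, 0, 0, 1), test_frac = 0.2),
               class = "nm_validation_error")   # class with < 2 members
  expect_error(nm_split(rep(1, 10)), class = "nm_validation_error")
})

test_that("stratified 5-fold assignment balances folds to within one row", {
  labels <- rep(c(0, 1), c(52, 51))       # n = 103
  d <- separable_features(60, gap = 3, seed = 53)
  cv <- nm_kfold(d$X[1:103, ], labels, model = "decision_tree", k = 5,
                 seed = 9)
  sizes <- sort(as.integer(table(cv$assignment)), decreasing = TRUE)
  expect_identical(sizes, c(21L, 21L, 21L, 20L, 20L))
  # every row tested exactly once
  expect_identical(sort(unique(cv$assignment)), 1:5)
  expect_identical(sum(cv$folds$n), 103L)
  # class ratio preserved within one row per fold
  per_fold_pos <- tapply(labels, cv$assignment, sum)
  expect_lte(diff(range(per_fold_pos)), 1)
  expect_error(nm_kfold(d$X, d$y, k = 1), class = "nm_validation_error")
})

test_that("cross-validation of a separable problem scores highly", {
  d <- separable_features(30, gap = 4, seed = 54)
  cv <- nm_kfold(d$X, d$y, model = "bagging", k = 5, seed = 2)
  expect_identical(nrow(cv$folds), 5L)
  expect_gte(cv$mean[["Acc"]], 0.9)
})

test_that("evaluation reports render two decimals beside full precision", {
  d <- separable_features(30, gap = 2, seed = 55)
  ev <- nm_evaluate(d$X, d$y, models = c("decision_tree", "adaboost"),
                    seed = 3)
  expect_s3_class(ev, "nm_eval")
  expect_identical(nrow(ev), 2L)
  expect_identical(ev$protocol, rep("independent_80_20", 2))
  out <- withr::local_tempfile(fileext = ".tsv")
  rendered <- nm_report(ev, out)
  expect_true(file.exists(out))
  expect_match(rendered$Acc[1], "^\\d\\.\\d{2}$")
  expect_equal(rendered$Acc_full, ev$Acc)
  expect_identical(nm_report(ev)$MCC,
                   ifelse(is.na(ev$MCC), NA, sprintf("%.2f", ev$MCC)))
  bad <- ev; bad$protocol <- ""
  expect_error(nm_report(bad), class = "nm_validation_error")
  expect_error(nm_report(ev[0, ]), class = "nm_validation_error")
})
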