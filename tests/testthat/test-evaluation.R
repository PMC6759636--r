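test_that("stratified splits draw the exact per-class segment fraction", {
  tab <- toyFeatureTable(nSegPerClass = 25, classes = c("reach", "idle"))
  plan <- splitPlan(trainFraction = 0.6, nRepeats = 1, seed = 1)
  sp <- stratifiedSplit(tab, plan, 1)
  seg <- windowInfo(tab)[!duplicated(windowInfo(tab)$segment_id), ]
  for (cl in c("reach", "idle")) {
    ids <- seg$segment_id[seg$window_label == cl]
    expect_equal(sum(ids %in% sp$trainSegments), 15L)
    expect_equal(sum(ids %in% sp$testSegments), 10L)
  }
})

test_that("stratified splits are disjoint, exhaustive and leak-free", {
  tab <- toyFeatureTable(nSegPerClass = 7)
  plan <- splitPlan(nRepeats = 5, seed = 3)
  wi <- windowInfo(tab)
  for (r in 1:5) {
    sp <- stratifiedSplit(tab, plan, r)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), seq_len(ncol(tab)))
    # no segment contributes windows to both sides
    expect_length(intersect(wi$segment_id[sp$train],
                            wi$segment_id[sp$test]), 0L)
    # per-class test share within one segment of the full-table share
    seg <- wi[!duplicated(wi$segment_id), ]
    for (cl in unique(seg$window_label)) {
      nc <- sum(seg$window_label == cl)
      inTest <- sum(seg$segment_id[seg$window_label == cl] %in%
                      sp$testSegments)
      expect_lte(abs(inTest - 0.4 * nc), 1)
    }
  }
  # identical repeat index reproduces the identical split
  expect_identical(stratifiedSplit(tab, plan, 2),
                   stratifiedSplit(tab, plan, 2))
})

test_that("a class with a single segment fails with its name", {
  tab <- toyFeatureTable(nSegPerClass = 1, classes = c("reach", "idle"),
                         winPerSeg = 2)
  expect_error(stratifiedSplit(tab, splitPlan(seed = 1), 1), "reach")
})

test_that("LOSO yields one fold per subject partitioning the table", {
  tab <- toyFeatureTable(nSegPerClass = 6, nSubjects = 6)
  folds <- losoSplits(tab)
  expect_length(folds, 6L)
  wi <- windowInfo(tab)
  allTest <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(allTest, seq_len(ncol(tab)))
  expect_length(allTest, ncol(tab))
  for (f in folds)
    expect_length(unique(wi$subject_id[f$test]), 1L)
  one <- toyFeatureTable(nSubjects = 1)
  expect_error(losoSplits(one), "2 subjects")
})

test_that("PPV matches hand-computed values on the worked example", {
  cm <- confusionCounts(c("reach", "reach", "transport", "transport"),
                        c("reach", "transport", "transport", "transport"))
  pv <- ppvScores(cm)
  expect_equal(unname(pv$perClass["reach"]), 100)
  expect_equal(unname(pv$perClass["transport"]), 200 / 3)
  expect_equal(pv$overall, 75)
})

test_that("perfect classification gives PPV 100 everywhere", {
  cm <- diag(c(5L, 3L, 7L, 2L))
  dimnames(cm) <- list(primitiveClasses(), primitiveClasses())
  pv <- ppvScores(cm)
  expect_equal(unname(pv$perClass), rep(100, 4))
  expect_equal(pv$overall, 100)
})

test_that("micro-pooled overall PPV equals accuracy on random matrices", {
  set.seed(12)
  for (i in 1:20) {
    cm <- matrix(rpois(16, 5), 4, 4,
                 dimnames = list(primitiveClasses(), primitiveClasses()))
    if (sum(cm) == 0) next
    expect_equal(ppvScores(cm)$overall, 100 * sum(diag(cm)) / sum(cm))
  }
  expect_error(ppvScores(matrix(0, 2, 2)), "no observations")
})

test_that("never-predicted classes report missing PPV", {
  cm <- rbind(c(3L, 1L, 0L), c(1L, 4L, 0L), c(0L, 2L, 0L))
  dimnames(cm) <- list(c("a", "b", "c"), c("a", "b", "c"))
  pv <- ppvScores(cm)
  expect_true(is.na(pv$perClass["c"]))
})

test_that("row-percent confusion rows sum to 100 where supported", {
  cm <- rbind(c(3L, 1L), c(0L, 0L))
  dimnames(cm) <- list(c("a", "b"), c("a", "b"))
  rp <- rowPercent(cm)
  expect_equal(sum(rp["a", ]), 100)
  expect_true(all(is.na(rp["b", ])))
})

test_that("ROC reproduces the worked AUC examples", {
  s <- cbind(pos = c(0.9, 0.8, 0.4, 0.2))
  r <- rocAnalysis(cbind(s, neg = 1 - s), c("pos", "pos", "neg", "neg"))
  expect_equal(r$pos$auc, 1.0)
  expect_equal(r$pos$operatingPoint$fpr, 0)
  expect_equal(r$pos$operatingPoint$tpr, 1)
  r2 <- rocAnalysis(cbind(pos = c(0.9, 0.8, 0.4, 0.2), neg = 0),
                    c("pos", "neg", "neg", "pos"))
  expect_equal(r2$pos$auc, 0.5)
})

test_that("AUC equals the concordance-pair oracle with ties", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(8:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    truth <- sample(c("pos", "neg"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    r <- rocAnalysis(cbind(pos = scores, neg = 1 - scores), truth)
    expect_equal(r$pos$auc, bruteAUC(scores, truth == "pos"))
  }
})

test_that("ROC curves are anchored and monotone, AUC is rank-invariant", {
  set.seed(14)
  scores <- runif(50)
  truth <- ifelse(runif(50) < scores, "pos", "neg")
  r <- rocAnalysis(cbind(pos = scores, neg = 1 - scores), truth)$pos
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  r2 <- rocAnalysis(cbind(pos = exp(3 * scores), neg = 0), truth)$pos
  expect_equal(r2$auc, r$auc)
  # distance-to-corner operating point is available as an option
  r3 <- rocAnalysis(cbind(pos = scores, neg = 0), truth,
                    opCriterion = "closest")$pos
  expect_true(is.finite(r3$operatingPoint$threshold))
})

test_that("classes absent from truth are skipped with a warning", {
  s <- cbind(a = c(0.9, 0.2), b = c(0.1, 0.8), c = c(0, 0))
  expect_warning(r <- rocAnalysis(s, c("a", "b")), "absent")
  expect_named(r, c("a", "b"))
})

test_that("evaluation reaches PPV 100 on separable data and is deterministic", {
  tab <- toyFeatureTable(nSegPerClass = 6, sep = 10, seed = 2)
  plan <- splitPlan(nRepeats = 3, seed = 4)
  ev <- evaluatePrimitives(tab, c("lda", "nbc", "svm", "knn"), plan)
  for (a in names(ev))
    expect_equal(unname(overallPPV(ev[[a]])["mean"]), 100, info = a)
  ev2 <- evaluatePrimitives(tab, "lda", plan)
  expect_identical(ev$lda@repeatOverall, ev2$lda@repeatOverall)
  expect_identical(ev$lda@confusion, ev2$lda@confusion)
  # pooled confusion covers every test segment of every repeat
  nTestSeg <- sum(vapply(1:3, function(r)
    length(stratifiedSplit(tab, plan, r)$testSegments), 1L))
  expect_equal(sum(ev$lda@confusion), nTestSeg)
})

test_that("window-level evaluation is available alongside primitive level", {
  tab <- toyFeatureTable(nSegPerClass = 5, sep = 10, seed = 3)
  plan <- splitPlan(nRepeats = 2, seed = 5)
  evw <- evaluatePrimitives(tab, "lda", plan, level = "window")
  evp <- evaluatePrimitives(tab, "lda", plan, level = "primitive")
  expect_gt(sum(evw$lda@confusion), sum(evp$lda@confusion))
})

test_that("evaluation at permuted labels stays near the majority rate", {
  set.seed(15)
  tab <- toyFeatureTable(nSegPerClass = 30, winPerSeg = 2,
                         classes = c("reach", "idle"), sep = 0, seed = 6)
  ev <- evaluatePrimitives(tab, "lda", splitPlan(nRepeats = 5, seed = 7))
  nSeg <- length(unique(windowInfo(tab)$segment_id))
  se <- sqrt(0.5 * 0.5 / nSeg)
  expect_lt(abs(overallPPV(ev$lda)[["mean"]] / 100 - 0.5), 3 * se)
})

test_that("the timing harness has one row per algorithm and fraction", {
  tab <- toyFeatureTable(nSegPerClass = 10, winPerSeg = 2, p = 8)
  fr <- c(0.5, 1.0)
  tb <- timingBenchmark(tab, c("lda", "knn"), fractions = fr, seed = 1)
  expect_equal(nrow(tb), 4L)
  expect_equal(as.integer(table(tb$algorithm)), c(2L, 2L))
  expect_true(all(tb$train_seconds >= 0))
  expect_error(timingBenchmark(tab, "lda", fractions = numeric(0), seed = 1),
               "non-empty")
  expect_error(timingBenchmark(tab, "lda", fractions = c(0.5, 0.2), seed = 1),
               "increasing")
  expect_error(timingBenchmark(tab, "lda", fractions = c(0.5, 1.5), seed = 1),
               "lie in")
})
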