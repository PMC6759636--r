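# Evaluation protocols and metrics: stratified repeated holdout and
# leave-one-subject-out splitting at the primitive-segment level,
# per-class and micro-pooled overall PPV, row-percent confusion
# matrices, one-vs-all ROC/AUC with optimal operating points, and the
# train/test timing harness.

# unique segments of a feature table with their class and subject
.segmentSummary <- function(features) {
  wi <- windowInfo(features)
  idx <- !duplicated(wi$segment_id)
  data.frame(segment_id = wi$segment_id[idx], label = wi$window_label[idx],
             subject_id = wi$subject_id[idx], stringsAsFactors = FALSE)
}

#' Stratified segment-level train/test split
#'
#' Draws one stratified split of a feature table. The sampling unit is
#' the primitive segment — all windows of a segment travel together —
#' and within each class the fraction of segments assigned to training
#' is within one segment of `plan@trainFraction`. Splits are seeded
#' deterministically from the plan seed and `repeatIndex`.
#'
#' @param features A [WindowFeatureSet].
#' @param plan A [splitPlan()] with scheme `"stratified"`.
#' @param repeatIndex Which repeat (1-based) to draw.
#' @return List with `train` and `test` window index vectors and
#'   `trainSegments` / `testSegments` segment-id vectors.
#' @export
stratifiedSplit <- function(features, plan, repeatIndex = 1L) {
  stopifnot(is(features, "WindowFeatureSet"), is(plan, "SplitPlan"))
  seg <- .segmentSummary(features)
  counts <- table(seg$label)
  single <- names(counts)[counts < 2L]
  if (length(single))
    stop("class(es) with fewer than 2 segments cannot be split: ",
         paste(single, collapse = ", "))
  set.seed(deriveStageSeed(plan@seed, paste0("split", repeatIndex)))
  trainSeg <- unlist(lapply(split(seg$segment_id, seg$label), function(ids) {
    nTrain <- min(max(round(plan@trainFraction * length(ids)), 1L),
                  length(ids) - 1L)
    sample(ids, nTrain)
  }), use.names = FALSE)
  segIds <- windowInfo(features)$segment_id
  inTrain <- segIds %in% trainSeg
  list(train = which(inTrain), test = which(!inTrain),
       trainSegments = sort(trainSeg),
       testSegments = sort(setdiff(seg$segment_id, trainSeg)))
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: the fold's test set is all windows of that
#' subject, its training set everything else. The union of test folds is
#' the whole table.
#'
#' @param features A [WindowFeatureSet] with at least two subjects.
#' @return List of folds, each with `train`/`test` window indices and
#'   the held-out `subject`.
#' @export
losoSplits <- function(features) {
  wi <- windowInfo(features)
  subjects <- unique(wi$subject_id)
  if (length(subjects) < 2L)
    stop("leave-one-subject-out requires at least 2 subjects")
  lapply(subjects, function(s) {
    test <- which(wi$subject_id == s)
    list(train = which(wi$subject_id != s), test = test, subject = s)
  })
}

#' Confusion counts
#'
#' Tallies a true-class x predicted-class count matrix in canonical
#' class order.
#'
#' @param truth,pred Vectors of true and predicted labels.
#' @param classes Class order (default: canonical order of the classes
#'   present).
#' @return Integer classes x classes matrix (rows = truth).
#' @export
#' @examples
#' confusionCounts(c("reach", "reach", "transport", "transport"),
#'                 c("reach", "transport", "transport", "transport"))
confusionCounts <- function(truth, pred,
                            classes = .classLevels(c(as.character(truth),
                                                     as.character(pred)))) {
  t1 <- factor(as.character(truth), levels = classes)
  t2 <- factor(as.character(pred), levels = classes)
  unclass(table(truth = t1, predicted = t2))
}

#' Row-normalized confusion matrix
#'
#' Converts confusion counts to row percentages (each row of true-class
#' counts sums to 100). Rows with zero support are returned as `NA`.
#'
#' @param counts Confusion count matrix from [confusionCounts()].
#' @return Numeric matrix of row percentages.
#' @export
rowPercent <- function(counts) {
  rs <- rowSums(counts)
  out <- 100 * counts / ifelse(rs == 0, NA_real_, rs)
  out
}

#' Positive predictive values from a confusion matrix
#'
#' One-vs-all PPV per class, `100 * TP / (TP + FP)` with `TP` the
#' diagonal entry and `FP` the rest of the predicted-class column, plus
#' the micro-pooled overall PPV obtained by tallying all true and false
#' positives. Because every prediction is a positive for exactly one
#' class, the overall PPV equals overall accuracy. Classes never
#' predicted get `NA`.
#'
#' @param counts Confusion count matrix (rows = truth).
#' @return List with `perClass` (named numeric) and `overall` (numeric),
#'   both on the percent scale.
#' @export
#' @examples
#' cm <- confusionCounts(c("reach", "reach", "transport", "transport"),
#'                       c("reach", "transport", "transport", "transport"))
#' ppvScores(cm)
ppvScores <- function(counts) {
  if (sum(counts) == 0) stop("confusion matrix has no observations")
  tp <- diag(counts)
  predicted <- colSums(counts)
  perClass <- ifelse(predicted == 0, NA_real_, 100 * tp / predicted)
  names(perClass) <- colnames(counts)
  list(perClass = perClass, overall = 100 * sum(tp) / sum(counts))
}

#' One-vs-all ROC analysis
#'
#' Sweeps thresholds over each class's scores against all other classes
#' combined, reporting the ROC curve (anchored at (0,0) and (1,1)), the
#' trapezoidal AUC, and the optimal operating point. The operating point
#' maximizes Youden's J = TPR - FPR by default; `"closest"` instead
#' minimizes the distance to the perfect-classification corner (0, 1).
#'
#' @param scores Samples x classes score matrix (see [predictScores()]).
#' @param truth True labels, one per row of `scores`.
#' @param opCriterion `"youden"` (default) or `"closest"`.
#' @return Named list per class, each with `curve` (data frame
#'   `threshold`, `fpr`, `tpr`), `auc`, and `operatingPoint`. Classes
#'   absent from `truth` are skipped with a warning.
#' @export
#' @examples
#' s <- cbind(pos = c(.9, .8, .4, .2), neg = c(.1, .2, .6, .8))
#' rocAnalysis(s, c("pos", "pos", "neg", "neg"))$pos$auc
rocAnalysis <- function(scores, truth, opCriterion = c("youden", "closest")) {
  opCriterion <- match.arg(opCriterion)
  scores <- as.matrix(scores)
  truth <- as.character(truth)
  classes <- colnames(scores)
  if (is.null(classes)) stop("scores must have class column names")
  out <- list()
  for (cl in classes) {
    pos <- truth == cl
    if (!any(pos)) {
      warning("class '", cl, "' absent from truth; skipped")
      next
    }
    if (all(pos)) {
      warning("class '", cl, "' has no negatives; skipped")
      next
    }
    s <- scores[, cl]
    ord <- order(s, decreasing = TRUE)
    sPos <- cumsum(pos[ord])
    sNeg <- cumsum(!pos[ord])
    last <- !duplicated(s[ord][length(ord):1])[length(ord):1]
    thr <- s[ord][last]
    tpr <- c(0, sPos[last] / sum(pos))
    fpr <- c(0, sNeg[last] / sum(!pos))
    thr <- c(Inf, thr)
    auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    crit <- if (opCriterion == "youden") tpr - fpr else
      -sqrt(fpr^2 + (1 - tpr)^2)
    opt <- which.max(crit)
    out[[cl]] <- list(
      curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
      auc = auc,
      operatingPoint = list(fpr = fpr[opt], tpr = tpr[opt],
                            threshold = thr[opt])
    )
  }
  out
}

# majority vote of window predictions within each test segment; score of
# a segment is the mean of its window scores. Vote ties resolve toward
# the earliest class in canonical order.
.aggregateSegments <- function(pred, scores, segIds, winLabels, classes) {
  u <- unique(segIds)
  K <- length(classes)
  predSeg <- character(length(u))
  truthSeg <- character(length(u))
  segScores <- matrix(0, length(u), K, dimnames = list(NULL, classes))
  grp <- split(seq_along(segIds), factor(segIds, levels = u))
  for (i in seq_along(u)) {
    rows <- grp[[i]]
    votes <- tabulate(match(as.character(pred[rows]), classes), K)
    predSeg[i] <- classes[which.max(votes)]
    truthSeg[i] <- winLabels[rows[1]]
    segScores[i, ] <- colMeans(scores[rows, , drop = FALSE])
  }
  list(pred = predSeg, truth = truthSeg, scores = segScores)
}

#' @rdname evaluatePrimitives
#' @export
setClass("PrimitiveEvaluation",
  representation(algorithm = "character", classes = "character",
                 level = "character", scheme = "character",
                 repeatOverall = "numeric", repeatClass = "matrix",
                 confusion = "matrix", roc = "list"))

#' @describeIn evaluatePrimitives Overall PPV `c(mean, sd)` across
#'   repeats/folds, percent scale.
#' @param x A `PrimitiveEvaluation`.
#' @export
overallPPV <- function(x) {
  c(mean = mean(x@repeatOverall, na.rm = TRUE),
    sd = stats::sd(x@repeatOverall))
}

#' @describeIn evaluatePrimitives Per-class PPV mean and sd across
#'   repeats/folds.
#' @export
classPPV <- function(x) {
  data.frame(class = colnames(x@repeatClass),
             mean = colMeans(x@repeatClass, na.rm = TRUE),
             sd = apply(x@repeatClass, 2, stats::sd, na.rm = TRUE),
             row.names = NULL)
}

#' @describeIn evaluatePrimitives Pooled confusion counts across
#'   repeats/folds.
#' @export
pooledConfusion <- function(x) x@confusion

#' @describeIn evaluatePrimitives Pooled one-vs-all ROC results (see
#'   [rocAnalysis()]).
#' @export
rocResults <- function(x) x@roc

setMethod("show", "PrimitiveEvaluation", function(object) {
  ov <- overallPPV(object)
  cp <- classPPV(object)
  cat("PrimitiveEvaluation [", object@algorithm, ", ", object@scheme,
      ", ", object@level, " level]\n", sep = "")
  cat(sprintf("  %s: %.1f +/- %.2f%%\n", cp$class, cp$mean, cp$sd), sep = "")
  cat(sprintf("  overall PPV: %.1f +/- %.2f%%\n", ov["mean"], ov["sd"]))
})

#' Evaluate classifiers on a feature table
#'
#' Runs the evaluation protocol: for each repeat (stratified
#' segment-level 60/40 splits by default) or each leave-one-subject-out
#' fold, fits every requested algorithm on the training windows,
#' predicts labels and scores on the test windows, aggregates window
#' predictions to one label per primitive segment by majority vote
#' (`level = "primitive"`, the headline setting) or keeps window-level
#' predictions (`level = "window"`), and accumulates confusion counts.
#' Reported are per-class and overall PPV mean and (sample) sd across
#' repeats, the pooled confusion matrix, and one-vs-all ROC curves on
#' scores pooled across repeats. Feature columns are standardized with
#' training-set statistics for the scale-sensitive algorithms (KNN,
#' SVM); LDA and NBC are invariant to per-feature affine rescaling, so
#' they see the raw features. Everything is seeded from the plan.
#'
#' @param features A [WindowFeatureSet].
#' @param algorithms Character vector from
#'   `c("lda", "nbc", "svm", "knn")`.
#' @param plan A [splitPlan()].
#' @param level `"primitive"` (majority-vote per segment, default) or
#'   `"window"`.
#' @param hyperparams Named list of extra arguments per algorithm, e.g.
#'   `list(knn = list(k = 7))`.
#' @return Named list of `PrimitiveEvaluation` objects, one per
#'   algorithm.
#' @export
#' @examples
#' \donttest{
#' study <- simulateStudy(2, deskProtocol(), seed = 1, sampleRate = 60)
#' feats <- studyFeatures(study)
#' ev <- evaluatePrimitives(feats, "lda",
#'                          splitPlan(nRepeats = 3, seed = 1))
#' ev$lda
#' }
evaluatePrimitives <- function(features,
                               algorithms = c("lda", "nbc", "svm", "knn"),
                               plan, level = c("primitive", "window"),
                               hyperparams = list()) {
  stopifnot(is(features, "WindowFeatureSet"), is(plan, "SplitPlan"))
  level <- match.arg(level)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  X <- featureMatrix(features)
  wi <- windowInfo(features)
  y <- wi$window_label
  classes <- .classLevels(y)
  folds <- if (plan@scheme == "stratified") {
    lapply(seq_len(plan@nRepeats), function(r)
      stratifiedSplit(features, plan, r))
  } else {
    losoSplits(features)
  }
  nFold <- length(folds)
  acc <- lapply(algorithms, function(a) list(
    overall = numeric(nFold),
    class = matrix(NA_real_, nFold, length(classes),
                   dimnames = list(NULL, classes)),
    confusion = matrix(0L, length(classes), length(classes),
                       dimnames = list(truth = classes, predicted = classes)),
    scores = vector("list", nFold), truths = vector("list", nFold)
  ))
  names(acc) <- algorithms

  for (f in seq_len(nFold)) {
    fold <- folds[[f]]
    Xtr <- X[fold$train, , drop = FALSE]
    Xte <- X[fold$test, , drop = FALSE]
    ytr <- y[fold$train]
    segTe <- wi$segment_id[fold$test]
    yTe <- y[fold$test]
    ctr <- colMeans(Xtr)
    sdtr <- sqrt(pmax(colMeans(Xtr^2) - ctr^2, 0))
    sdtr[sdtr < 1e-12] <- 1
    for (a in algorithms) {
      scale <- a %in% c("knn", "svm")
      xtr <- if (scale) sweep(sweep(Xtr, 2, ctr), 2, sdtr, "/") else Xtr
      xte <- if (scale) sweep(sweep(Xte, 2, ctr), 2, sdtr, "/") else Xte
      hp <- hyperparams[[a]]
      model <- do.call(fitClassifier,
                       c(list(x = xtr, y = ytr, algorithm = a), hp))
      sc <- predictScores(model, xte)
      pred <- predictLabels(model, xte)
      if (level == "primitive") {
        agg <- .aggregateSegments(pred, sc, segTe, yTe, classes)
        cm <- confusionCounts(agg$truth, agg$pred, classes)
        acc[[a]]$scores[[f]] <- agg$scores
        acc[[a]]$truths[[f]] <- agg$truth
      } else {
        cm <- confusionCounts(yTe, pred, classes)
        acc[[a]]$scores[[f]] <- sc
        acc[[a]]$truths[[f]] <- yTe
      }
      pv <- ppvScores(cm)
      acc[[a]]$overall[f] <- pv$overall
      acc[[a]]$class[f, ] <- pv$perClass
      acc[[a]]$confusion <- acc[[a]]$confusion + cm
    }
  }

  out <- lapply(algorithms, function(a) {
    pooledScores <- do.call(rbind, acc[[a]]$scores)
    pooledTruth <- unlist(acc[[a]]$truths)
    roc <- rocAnalysis(pooledScores, pooledTruth)
    new("PrimitiveEvaluation", algorithm = a, classes = classes,
        level = level, scheme = plan@scheme,
        repeatOverall = acc[[a]]$overall, repeatClass = acc[[a]]$class,
        confusion = acc[[a]]$confusion, roc = roc)
  })
  names(out) <- algorithms
  out
}

#' Table of PPVs across algorithms
#'
#' Renders a list of [evaluatePrimitives()] results as one row per
#' algorithm with per-class and overall PPV (mean and sd columns).
#'
#' @param reports Named list of `PrimitiveEvaluation` objects.
#' @return Data frame, one row per algorithm.
#' @export
ppvTable <- function(reports) {
  rows <- lapply(names(reports), function(a) {
    r <- reports[[a]]
    cp <- classPPV(r)
    ov <- overallPPV(r)
    row <- data.frame(algorithm = a, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(cp))) {
      row[[paste0(cp$class[i], "_ppv")]] <- cp$mean[i]
      row[[paste0(cp$class[i], "_sd")]] <- cp$sd[i]
    }
    row$overall_ppv <- ov[["mean"]]
    row$overall_sd <- ov[["sd"]]
    row
  })
  do.call(rbind, rows)
}

#' Training and testing time benchmark
#'
#' Measures wall-clock training time and mean per-sample testing time of
#' each algorithm on nested random subsets of a feature table
#' (re-trained *de novo* at every dataset fraction). Absolute times are
#' hardware-dependent; the harness is meant for relative comparisons
#' such as scaling shape and the near-zero training cost of KNN.
#'
#' @param features A [WindowFeatureSet].
#' @param algorithms Algorithms to benchmark.
#' @param fractions Strictly increasing dataset fractions in (0, 1];
#'   default `seq(0.2, 1, 0.1)` (use `seq(0.25, 1, 0.25)` for large
#'   populations).
#' @param seed Integer seed for subset sampling (required).
#' @param testSize Number of samples timed at prediction (default 200).
#' @return `data.frame` with one row per (algorithm, fraction):
#'   `n_train`, `train_seconds`, `test_seconds_per_sample`.
#' @export
timingBenchmark <- function(features, algorithms = c("lda", "nbc", "svm", "knn"),
                            fractions = seq(0.2, 1, 0.1), seed,
                            testSize = 200L) {
  stopifnot(is(features, "WindowFeatureSet"))
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if (!length(fractions)) stop("fractions must be non-empty")
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  if (is.unsorted(fractions, strictly = TRUE))
    stop("fractions must be strictly increasing")
  if (missing(seed)) stop("timingBenchmark() requires an explicit seed")
  X <- featureMatrix(features)
  y <- windowInfo(features)$window_label
  rows <- list()
  for (fr in fractions) {
    set.seed(deriveStageSeed(seed, paste0("timing", round(fr * 100))))
    n <- max(2L, round(fr * nrow(X)))
    idx <- sample(nrow(X), n)
    teIdx <- sample(nrow(X), min(testSize, nrow(X)))
    xi <- X[idx, , drop = FALSE]   # materialized outside the clock
    yi <- y[idx]
    xt <- X[teIdx, , drop = FALSE]
    for (a in algorithms) {
      t0 <- proc.time()["elapsed"]
      model <- fitClassifier(xi, yi, a)
      trainS <- proc.time()["elapsed"] - t0
      t0 <- proc.time()["elapsed"]
      invisible(predictLabels(model, xt))
      testS <- (proc.time()["elapsed"] - t0) / length(teIdx)
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = a, fraction = fr, n_train = n,
        train_seconds = unname(trainS),
        test_seconds_per_sample = unname(testS),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
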