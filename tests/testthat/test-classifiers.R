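test_that("LDA predictions match the brute-force discriminant evaluator", {
  for (s in 1:30) {
    inst <- randomInstance(s)
    m <- fitClassifier(inst$x, inst$y, "lda")
    expect_equal(as.character(predictLabels(m, inst$xte)),
                 bruteLDAPredict(inst$x, inst$y, inst$xte))
  }
})

test_that("NBC predictions match brute-force log-posterior enumeration", {
  for (s in 31:60) {
    inst <- randomInstance(s)
    m <- fitClassifier(inst$x, inst$y, "nbc")
    expect_equal(as.character(predictLabels(m, inst$xte)),
                 bruteNBCPredict(inst$x, inst$y, inst$xte))
  }
})

test_that("1-NN predictions match exhaustive nearest-neighbor search", {
  for (s in 61:90) {
    inst <- randomInstance(s)
    m <- fitClassifier(inst$x, inst$y, "knn", k = 1L)
    expect_equal(as.character(predictLabels(m, inst$xte)),
                 bruteNN1Predict(inst$x, inst$y, inst$xte))
  }
})

test_that("NBC fitted means equal per-class sample means exactly", {
  inst <- randomInstance(101)
  m <- fitClassifier(inst$x, inst$y, "nbc")
  for (cl in m@classes)
    expect_identical(unname(m@means[cl, ]),
                     unname(colMeans(inst$x[inst$y == cl, , drop = FALSE])))
})

test_that("LDA boundary sits midway between symmetric 1-D classes", {
  set.seed(5)
  x <- matrix(c(rnorm(200, -1, sqrt(0.1)), rnorm(200, 1, sqrt(0.1))), ncol = 1)
  y <- rep(c("a", "b"), each = 200)
  m <- fitClassifier(x, y, "lda")
  grid <- matrix(seq(-0.2, 0.2, by = 0.001), ncol = 1)
  pred <- predictLabels(m, grid)
  boundary <- grid[max(which(pred == "a")), 1]
  expect_lt(abs(boundary), 0.05)
})

test_that("all four algorithms separate linearly separable classes", {
  set.seed(6)
  x <- rbind(matrix(rnorm(120, -3, 0.5), ncol = 4),
             matrix(rnorm(120, 3, 0.5), ncol = 4))
  y <- rep(c("idle", "reach"), each = 30)
  for (a in c("lda", "nbc", "svm", "knn")) {
    m <- fitClassifier(x, y, a)
    expect_equal(mean(as.character(predictLabels(m, x)) == y), 1,
                 info = a)
  }
})

test_that("accuracy on permuted labels stays at chance", {
  set.seed(7)
  n <- 300
  x <- matrix(rnorm(2 * n * 5), ncol = 5)
  xtr <- x[seq_len(n), ]; xte <- x[n + seq_len(n), ]
  ytr <- sample(rep(c("a", "b"), n / 2))  # permuted: no signal, balanced
  yte <- sample(rep(c("a", "b"), n / 2))
  pmaj <- max(table(ytr)) / n
  for (a in c("lda", "nbc", "svm", "knn")) {
    m <- fitClassifier(xtr, ytr, a)
    acc <- mean(as.character(predictLabels(m, xte)) == yte)
    expect_lt(abs(acc - pmaj), 3 * sqrt(pmaj * (1 - pmaj) / n))
  }
})

test_that("posterior score rows sum to one for lda, nbc and knn", {
  inst <- randomInstance(111)
  for (a in c("lda", "nbc", "knn")) {
    m <- fitClassifier(inst$x, inst$y, a)
    s <- predictScores(m, inst$xte)
    expect_equal(unname(rowSums(s)), rep(1, nrow(s)), tolerance = 1e-9)
    expect_equal(colnames(s), m@classes)
    pred <- as.character(predictLabels(m, inst$xte))
    if (a == "knn") {
      # vote ties break by neighbor distance, so the prediction must
      # attain (not necessarily be first among) the maximal score
      predScore <- s[cbind(seq_len(nrow(s)), match(pred, m@classes))]
      expect_equal(predScore, apply(s, 1, max))
    } else {
      expect_equal(pred, m@classes[max.col(s, ties.method = "first")])
    }
  }
})

test_that("KNN scores are neighbor-vote fractions", {
  xtr <- matrix(c(1, 2, 3, 10, 11), ncol = 1)
  ytr <- c("a", "a", "a", "b", "b")
  m <- fitClassifier(xtr, ytr, "knn", k = 5L)
  s <- predictScores(m, matrix(5, ncol = 1))
  expect_equal(unname(s[1, ]), c(0.6, 0.4))
})

test_that("KNN predictions are deterministic under ties", {
  xtr <- matrix(c(-1, -1, 1, 1), ncol = 1)
  ytr <- c("a", "b", "a", "b")
  m <- fitClassifier(xtr, ytr, "knn", k = 4L)
  p1 <- predictLabels(m, matrix(0, ncol = 1))
  for (i in 1:5)
    expect_identical(predictLabels(m, matrix(0, ncol = 1)), p1)
  # vote tied 2-2 and summed distances equal: canonical class order wins
  expect_equal(as.character(p1), "a")
})

test_that("NBC falls back to the majority prior on equal likelihoods", {
  # symmetric classes around 0; test point at 0 is equidistant in
  # likelihood, so the 0.9 prior dominates
  x <- matrix(c(-2, -1, -1.5, -2.5, -2, -1, -1.5, -2.5, -1.75,
                1.75), ncol = 1)
  y <- c(rep("big", 9), "small")
  m <- fitClassifier(x, y, "nbc")
  expect_equal(unname(m@priors), c(0.9, 0.1))
  mid <- (mean(x[y == "big"]) + mean(x[y == "small"])) / 2
  # force equal per-class variances so likelihoods cancel at the midpoint
  m@vars[] <- 1
  expect_equal(as.character(predictLabels(m, matrix(mid, ncol = 1))), "big")
})

test_that("monotone transforms of SVM scores preserve ROC/AUC", {
  set.seed(8)
  x <- rbind(matrix(rnorm(100, -1), ncol = 2),
             matrix(rnorm(100, 1), ncol = 2))
  y <- rep(c("a", "b"), each = 50)
  m <- fitClassifier(x, y, "svm")
  s <- predictScores(m, x)
  r1 <- rocAnalysis(s, y)
  s2 <- s^3                       # strictly monotone on (0, 1)
  r2 <- rocAnalysis(s2, y)
  expect_equal(r1$a$auc, r2$a$auc)
  expect_equal(r1$b$auc, r2$b$auc)
  expect_gt(r1$a$auc, 0.9)
})

test_that("training data problems are rejected", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(fitClassifier(x, rep("a", 10), "lda"), "2 classes")
  expect_error(fitClassifier(x[1, , drop = FALSE], "a", "nbc"), "2 training")
  xb <- x; xb[1] <- NA
  expect_error(fitClassifier(xb, rep(c("a", "b"), 5), "svm"), "finite")
  m <- fitClassifier(x, rep(c("a", "b"), 5), "lda")
  expect_error(predictLabels(m, matrix(0, 1, 3)), "dimension mismatch")
})

test_that("models round-trip through JSON serialization", {
  inst <- randomInstance(121)
  for (a in c("lda", "nbc", "knn", "svm")) {
    m <- fitClassifier(inst$x, inst$y, a)
    m2 <- modelFromJSON(modelToJSON(m))
    expect_identical(predictLabels(m2, inst$xte), predictLabels(m, inst$xte),
                     info = a)
    expect_equal(predictScores(m2, inst$xte), predictScores(m, inst$xte),
                 tolerance = 1e-8, info = a)
  }
  expect_error(modelFromJSON('{"format":"other"}'), "not a primsense")
})

test_that("serialization files round-trip via save/load", {
  inst <- randomInstance(131)
  m <- fitClassifier(inst$x, inst$y, "lda")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  saveClassifier(m, path)
  m2 <- loadClassifier(path)
  expect_identical(predictLabels(m2, inst$xte), predictLabels(m, inst$xte))
})
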