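# Four classification algorithms under a single fit / predictLabels /
# predictScores contract. LDA, Gaussian naive Bayes, and KNN are
# implemented from their closed forms; the RBF-kernel SVM delegates to
# libsvm (e1071), with one-vs-rest score models fitted alongside the
# multiclass machine so that ROC analysis has deterministic scores.

#' @rdname fitClassifier
#' @export
setClass("PrimitiveClassifier", representation("VIRTUAL",
  classes = "character", featureNames = "character"))

#' @rdname fitClassifier
#' @export
setClass("LDAClassifier", contains = "PrimitiveClassifier",
  representation(means = "matrix", pooledCov = "matrix", priors = "numeric",
                 lambda = "numeric", weights = "matrix", const = "numeric"))

#' @rdname fitClassifier
#' @export
setClass("NBClassifier", contains = "PrimitiveClassifier",
  representation(means = "matrix", vars = "matrix", priors = "numeric",
                 varFloor = "numeric"))

#' @rdname fitClassifier
#' @export
setClass("KNNClassifier", contains = "PrimitiveClassifier",
  representation(train = "matrix", labels = "character", k = "integer",
                 distance = "character"))

#' @rdname fitClassifier
#' @export
setClass("SVMClassifier", contains = "PrimitiveClassifier",
  representation(fit = "ANY", ovrFits = "list", cost = "numeric",
                 gamma = "numeric", train = "matrix", labels = "character"))

# canonical class ordering: primitive order when labels are primitives,
# otherwise alphabetical; fixed at fit time
.classLevels <- function(y) {
  u <- unique(as.character(y))
  if (all(u %in% primitiveClasses())) {
    primitiveClasses()[primitiveClasses() %in% u]
  } else {
    sort(u)
  }
}

.checkTrainingData <- function(x, y, checkFinite = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x) || (checkFinite && !all(is.finite(x))))
    stop("feature matrix must be numeric and finite")
  if (nrow(x) < 2L) stop("at least 2 training samples required")
  if (length(y) != nrow(x))
    stop("length of labels must equal number of rows in x")
  if (length(unique(as.character(y))) < 2L)
    stop("at least 2 classes must be present in the training labels")
  x
}

#' Fit a primitive classifier
#'
#' Trains one of the four supported algorithms on a windows x features
#' matrix. All algorithms share the same contract and are scored with
#' [predictLabels()] and [predictScores()].
#'
#' \describe{
#'   \item{`lda`}{Linear discriminant analysis via the pooled-covariance
#'     closed form: per-class means, empirical priors, and a pooled
#'     within-class covariance regularized by a small ridge
#'     `lambda * trace(S)/p * I` (default `lambda = 1e-6`).}
#'   \item{`nbc`}{Gaussian naive Bayes: per-class per-feature means and
#'     variances (with a variance floor of `1e-9 * max(var)`), empirical
#'     priors; likelihoods evaluated in log space.}
#'   \item{`knn`}{k-nearest neighbors with uniform weighting (default
#'     `k = 5`, Euclidean distance); fitting merely stores the training
#'     data, so training takes essentially no time.}
#'   \item{`svm`}{RBF-kernel support vector machine delegated to libsvm
#'     (\pkg{e1071}); defaults `cost = 1`,
#'     `gamma = 1/(p * var(x))`. One-vs-rest machines are fitted
#'     alongside the multiclass machine to provide deterministic
#'     per-class scores.}
#' }
#'
#' @param x Numeric samples x features matrix (no non-finite values).
#' @param y Class labels, one per row of `x`; at least two classes.
#' @param algorithm One of `"lda"`, `"nbc"`, `"svm"`, `"knn"`.
#' @param lambda LDA ridge coefficient.
#' @param k Neighbor count for KNN.
#' @param cost,gamma SVM regularization cost and RBF kernel width;
#'   `gamma = NULL` uses `1/(p * var(x))`.
#' @return An object inheriting from `PrimitiveClassifier`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, -1), 20), matrix(rnorm(40, 1), 20))
#' y <- rep(c("idle", "reach"), each = 20)
#' m <- fitClassifier(x, y, "lda")
#' table(predictLabels(m, x), y)
fitClassifier <- function(x, y, algorithm = c("lda", "nbc", "svm", "knn"),
                          lambda = 1e-6, k = 5L, cost = 1, gamma = NULL) {
  algorithm <- match.arg(algorithm)
  # KNN has no model computation: fitting just stores the data, and even
  # an O(np) finiteness scan would dominate its "training" time, so that
  # validation is deferred to prediction for knn
  x <- .checkTrainingData(x, y, checkFinite = algorithm != "knn")
  y <- as.character(y)
  classes <- .classLevels(y)
  fn <- colnames(x)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(x)))
  switch(algorithm,
    lda = .fitLDA(x, y, classes, fn, lambda),
    nbc = .fitNBC(x, y, classes, fn),
    knn = new("KNNClassifier", classes = classes, featureNames = fn,
              train = x, labels = y, k = as.integer(k),
              distance = "euclidean"),
    svm = .fitSVM(x, y, classes, fn, cost, gamma)
  )
}

.fitLDA <- function(x, y, classes, fn, lambda) {
  p <- ncol(x); n <- nrow(x); K <- length(classes)
  means <- matrix(0, K, p, dimnames = list(classes, fn))
  S <- matrix(0, p, p)
  nk <- numeric(K)
  for (i in seq_along(classes)) {
    xi <- x[y == classes[i], , drop = FALSE]
    nk[i] <- nrow(xi)
    means[i, ] <- colMeans(xi)
    xc <- sweep(xi, 2, means[i, ])
    S <- S + crossprod(xc)
  }
  S <- S / max(n - K, 1)
  S <- S + diag(lambda * sum(diag(S)) / p, p)
  priors <- nk / n
  w <- tryCatch(solve(S, t(means)),
                error = function(e) stop(
                  "pooled covariance is singular despite ridge ",
                  "regularization; raise lambda", call. = FALSE))
  const <- -0.5 * colSums(t(means) * w) + log(priors)
  new("LDAClassifier", classes = classes, featureNames = fn, means = means,
      pooledCov = S, priors = priors, lambda = lambda, weights = w,
      const = const)
}

.fitNBC <- function(x, y, classes, fn) {
  K <- length(classes); p <- ncol(x)
  means <- matrix(0, K, p, dimnames = list(classes, fn))
  vars <- matrix(0, K, p, dimnames = list(classes, fn))
  nk <- numeric(K)
  for (i in seq_along(classes)) {
    xi <- x[y == classes[i], , drop = FALSE]
    nk[i] <- nrow(xi)
    means[i, ] <- colMeans(xi)
    vars[i, ] <- colMeans(xi^2) - means[i, ]^2  # population variance
  }
  vars[vars < 0] <- 0
  floorv <- 1e-9 * max(vars, 1e-300)
  vars <- pmax(vars, floorv)
  new("NBClassifier", classes = classes, featureNames = fn, means = means,
      vars = vars, priors = nk / nrow(x), varFloor = floorv)
}

.fitSVM <- function(x, y, classes, fn, cost, gamma) {
  if (is.null(gamma)) {
    v <- mean(x^2) - mean(x)^2
    gamma <- if (v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  }
  yf <- factor(y, levels = classes)
  fit <- e1071::svm(x, yf, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  ovr <- lapply(classes, function(cl) {
    yb <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(x, yb, kernel = "radial", cost = cost, gamma = gamma,
               scale = FALSE)
  })
  names(ovr) <- classes
  new("SVMClassifier", classes = classes, featureNames = fn, fit = fit,
      ovrFits = ovr, cost = cost, gamma = gamma, train = x, labels = y)
}

.checkPredictMatrix <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model@featureNames))
    stop("feature dimension mismatch: model was fitted with ",
         length(model@featureNames), " features, got ", ncol(x))
  if (!all(is.finite(x))) stop("prediction input must be finite")
  x
}

.softmaxRows <- function(d) {
  m <- apply(d, 1, max)
  e <- exp(d - m)
  e / rowSums(e)
}

.argmaxLabels <- function(scores, classes) {
  factor(classes[max.col(scores, ties.method = "first")], levels = classes)
}

# --- LDA -------------------------------------------------------------------

setMethod("predictScores", "LDAClassifier", function(model, x) {
  x <- .checkPredictMatrix(model, x)
  d <- x %*% model@weights
  d <- sweep(d, 2, model@const, "+")
  s <- .softmaxRows(d)
  colnames(s) <- model@classes
  s
})

setMethod("predictLabels", "LDAClassifier", function(model, x) {
  x <- .checkPredictMatrix(model, x)
  d <- sweep(x %*% model@weights, 2, model@const, "+")
  .argmaxLabels(d, model@classes)
})

# --- NBC -------------------------------------------------------------------

.nbcLogPosterior <- function(model, x) {
  K <- length(model@classes)
  ll <- matrix(0, nrow(x), K, dimnames = list(NULL, model@classes))
  for (i in seq_len(K)) {
    m <- model@means[i, ]; v <- model@vars[i, ]
    # sum_j log N(x_j | m_j, v_j), vectorized over samples
    xc <- sweep(x, 2, m)
    ll[, i] <- -0.5 * sum(log(2 * pi * v)) -
      0.5 * drop(xc^2 %*% (1 / v)) + log(model@priors[i])
  }
  ll
}

setMethod("predictScores", "NBClassifier", function(model, x) {
  x <- .checkPredictMatrix(model, x)
  .softmaxRows(.nbcLogPosterior(model, x))
})

setMethod("predictLabels", "NBClassifier", function(model, x) {
  x <- .checkPredictMatrix(model, x)
  .argmaxLabels(.nbcLogPosterior(model, x), model@classes)
})

# --- KNN -------------------------------------------------------------------

.knnNeighbors <- function(model, x) {
  # squared Euclidean distances, test x train
  d2 <- outer(rowSums(x^2), rowSums(model@train^2), "+") -
    2 * tcrossprod(x, model@train)
  d2[d2 < 0] <- 0
  d2
}

setMethod("predictScores", "KNNClassifier", function(model, x) {
  x <- .checkPredictMatrix(model, x)
  d2 <- .knnNeighbors(model, x)
  k <- min(model@k, ncol(d2))
  K <- length(model@classes)
  s <- matrix(0, nrow(x), K, dimnames = list(NULL, model@classes))
  for (i in seq_len(nrow(x))) {
    nb <- order(d2[i, ])[seq_len(k)]   # stable order breaks distance ties
    s[i, ] <- tabulate(match(model@labels[nb], model@classes), K) / k
  }
  s
})

setMethod("predictLabels", "KNNClassifier", function(model, x) {
  x <- .checkPredictMatrix(model, x)
  d2 <- .knnNeighbors(model, x)
  k <- min(model@k, ncol(d2))
  K <- length(model@classes)
  out <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    nb <- order(d2[i, ])[seq_len(k)]
    cls <- match(model@labels[nb], model@classes)
    votes <- tabulate(cls, K)
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      # tie: smaller summed neighbor distance, then canonical class order
      sums <- vapply(top, function(j) sum(sqrt(d2[i, nb[cls == j]])),
                     numeric(1))
      top <- top[sums == min(sums)]
    }
    out[i] <- model@classes[top[1L]]
  }
  factor(out, levels = model@classes)
})

# --- SVM -------------------------------------------------------------------

setMethod("predictScores", "SVMClassifier", function(model, x) {
  x <- .checkPredictMatrix(model, x)
  s <- vapply(model@classes, function(cl) {
    dv <- attr(predict(model@ovrFits[[cl]], x, decision.values = TRUE),
               "decision.values")
    d <- dv[, 1L]
    # libsvm orients the decision value toward its first class; flip if
    # that was "neg" so that larger always means more positive
    if (identical(colnames(dv)[1L], "neg/pos")) d <- -d
    1 / (1 + exp(-d))  # monotone map of decision values to (0, 1)
  }, numeric(nrow(x)))
  s <- matrix(s, nrow = nrow(x), dimnames = list(NULL, model@classes))
  s
})

setMethod("predictLabels", "SVMClassifier", function(model, x) {
  x <- .checkPredictMatrix(model, x)
  factor(as.character(predict(model@fit, x)), levels = model@classes)
})

# --- show methods ----------------------------------------------------------

setMethod("show", "LDAClassifier", function(object) {
  cat("LDAClassifier:", length(object@classes), "classes,",
      length(object@featureNames), "features, ridge lambda",
      object@lambda, "\n")
})
setMethod("show", "NBClassifier", function(object) {
  cat("NBClassifier (Gaussian):", length(object@classes), "classes,",
      length(object@featureNames), "features\n")
})
setMethod("show", "KNNClassifier", function(object) {
  cat("KNNClassifier: k =", object@k, ", ", nrow(object@train),
      "stored samples,", length(object@featureNames), "features\n")
})
setMethod("show", "SVMClassifier", function(object) {
  cat("SVMClassifier (RBF): cost", object@cost, ", gamma",
      format(object@gamma, digits = 4), ",",
      length(object@classes), "classes\n")
})

# --- serialization ---------------------------------------------------------

#' Serialize / restore a classifier as JSON
#'
#' LDA, NBC and KNN parameters are written explicitly. For the delegated
#' SVM, the training data and hyperparameters are stored and the machine
#' is refitted on load; libsvm training is deterministic given identical
#' inputs, so the restored model reproduces the original's predictions.
#'
#' @param model A fitted `PrimitiveClassifier`.
#' @param txt JSON string produced by `modelToJSON()`.
#' @return `modelToJSON()` a JSON string; `modelFromJSON()` the restored
#'   classifier.
#' @aliases modelToJSON
#' @export
#' @examples
#' m <- fitClassifier(matrix(rnorm(20), 10), rep(c("a", "b"), 5), "nbc")
#' m2 <- modelFromJSON(modelToJSON(m))
modelFromJSON <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  if (!identical(obj$format, "primsense-model"))
    stop("not a primsense model serialization")
  major <- as.integer(strsplit(obj$version, ".", fixed = TRUE)[[1]][1])
  if (major > 1L) stop("unsupported model serialization major version: ",
                       obj$version)
  asMat <- function(m, classes, fn) {
    m <- as.matrix(m); dimnames(m) <- list(classes, fn); m
  }
  with(obj, switch(algorithm,
    lda = .fitLDAFromParams(classes, featureNames,
                            asMat(means, classes, featureNames),
                            asMat(pooledCov, NULL, NULL), priors, lambda),
    nbc = new("NBClassifier", classes = classes, featureNames = featureNames,
              means = asMat(means, classes, featureNames),
              vars = asMat(vars, classes, featureNames),
              priors = priors, varFloor = varFloor),
    knn = new("KNNClassifier", classes = classes, featureNames = featureNames,
              train = asMat(train, NULL, featureNames), labels = labels,
              k = as.integer(k), distance = distance),
    svm = fitClassifier(asMat(train, NULL, featureNames), labels,
                        "svm", cost = cost, gamma = gamma),
    stop("unknown algorithm: ", algorithm)
  ))
}

.fitLDAFromParams <- function(classes, fn, means, S, priors, lambda) {
  dimnames(S) <- NULL
  w <- solve(S, t(means))
  const <- -0.5 * colSums(t(means) * w) + log(priors)
  new("LDAClassifier", classes = classes, featureNames = fn, means = means,
      pooledCov = S, priors = priors, lambda = lambda, weights = w,
      const = const)
}

.modelJSON <- function(fields) {
  jsonlite::toJSON(c(list(format = "primsense-model", version = "1.0"),
                     fields),
                   auto_unbox = TRUE, digits = NA)
}

setMethod("modelToJSON", "LDAClassifier", function(model) {
  .modelJSON(list(algorithm = "lda", classes = model@classes,
                  featureNames = model@featureNames, means = model@means,
                  pooledCov = model@pooledCov, priors = model@priors,
                  lambda = model@lambda))
})
setMethod("modelToJSON", "NBClassifier", function(model) {
  .modelJSON(list(algorithm = "nbc", classes = model@classes,
                  featureNames = model@featureNames, means = model@means,
                  vars = model@vars, priors = model@priors,
                  varFloor = model@varFloor))
})
setMethod("modelToJSON", "KNNClassifier", function(model) {
  .modelJSON(list(algorithm = "knn", classes = model@classes,
                  featureNames = model@featureNames, train = model@train,
                  labels = model@labels, k = model@k,
                  distance = model@distance))
})
setMethod("modelToJSON", "SVMClassifier", function(model) {
  .modelJSON(list(algorithm = "svm", classes = model@classes,
                  featureNames = model@featureNames, train = model@train,
                  labels = model@labels,
                  cost = model@cost, gamma = model@gamma))
})
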