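# Exhaustive wrapper search over sensor-site subsets and sensor types.
# Every configuration is evaluated on identical split indices (the plan
# seed fully determines the folds), so between-configuration differences
# are paired rather than split noise. For the default LDA classifier the
# search uses a sufficient-statistics fast path: class means and the
# pooled within-class SSCP matrix are computed once per fold on the full
# feature set, and every site subset's discriminant is obtained from the
# corresponding submatrices — algebraically identical to fitting LDA on
# the selected columns.

#' Enumerate sensor configurations
#'
#' All non-empty subsets of the given sites, in deterministic order: by
#' subset size, then lexicographically by (sorted) site names.
#'
#' @param sites Character vector of site names (1 to 20 sites; the
#'   search is exhaustive, so larger inputs are refused).
#' @param sensorType `"imu"` or `"accelerometer"` applied to every
#'   configuration.
#' @return List of [sensorConfig()] objects of length `2^n - 1`.
#' @export
#' @examples
#' length(enumerateConfigs(c("a", "b", "c")))
enumerateConfigs <- function(sites, sensorType = c("imu", "accelerometer")) {
  sensorType <- match.arg(sensorType)
  sites <- sort(unique(as.character(sites)))
  if (!length(sites)) stop("sites must be non-empty")
  if (length(sites) > 20L)
    stop("refusing to enumerate subsets of more than 20 sites (",
         length(sites), " given); restrict the site list")
  out <- list()
  for (k in seq_along(sites)) {
    cmb <- utils::combn(sites, k, simplify = FALSE)
    out <- c(out, lapply(cmb, sensorConfig, sensorType = sensorType))
  }
  out
}

.configKey <- function(config) paste(config@sites, collapse = "+")

#' @rdname exhaustiveSearch
#' @export
setClass("SensorSearchResult",
  representation(entries = "data.frame", classifier = "character",
                 sensorType = "character", nRepeats = "integer"))

setMethod("show", "SensorSearchResult", function(object) {
  cat("SensorSearchResult:", nrow(object@entries), "configurations (",
      object@sensorType, ",", object@classifier, ")\n")
  bp <- bestPerCount(object)
  print(bp[, c("n_sites", "sites", "overall_ppv")], row.names = FALSE)
})

#' @describeIn exhaustiveSearch Best configuration per sensor count
#'   (ties broken toward the lexicographically smallest site set).
#' @param result A `SensorSearchResult`.
#' @export
bestPerCount <- function(result) {
  e <- result@entries[result@entries$status == "ok", ]
  e <- e[order(e$n_sites, -e$overall_ppv, e$sites), ]
  e[!duplicated(e$n_sites), , drop = FALSE]
}

#' Exhaustive sensor-configuration search
#'
#' Evaluates every non-empty subset of the given sites with one
#' classifier under a shared split plan, recording each configuration's
#' mean and sd overall PPV (primitive level) across repeats together
#' with per-class PPVs from the pooled confusion matrix. Identical split
#' seeds are reused across configurations, so comparisons are paired. A
#' configuration whose evaluation fails is recorded with
#' `status = "failed"` and the search continues.
#'
#' @param features A full-IMU [WindowFeatureSet].
#' @param classifier Classifier used as the search objective (default
#'   `"lda"`).
#' @param plan A [splitPlan()].
#' @param sites Sites to search over (default: all sites present).
#' @param sensorType `"imu"` or `"accelerometer"`.
#' @param method `"auto"` uses the sufficient-statistics fast path for
#'   LDA and direct per-configuration evaluation otherwise; `"direct"`
#'   forces the latter (mainly for cross-checking).
#' @return A `SensorSearchResult`.
#' @seealso [bestPerCount()], [compareSensorTypes()]
#' @export
exhaustiveSearch <- function(features, classifier = "lda", plan,
                             sites = NULL, sensorType = "imu",
                             method = c("auto", "direct")) {
  stopifnot(is(features, "WindowFeatureSet"), is(plan, "SplitPlan"))
  method <- match.arg(method)
  if (is.null(sites)) sites <- unique(featureInfo(features)$site)
  configs <- enumerateConfigs(sites, sensorType)
  classes <- .classLevels(windowInfo(features)$window_label)
  if (identical(classifier, "lda") && method == "auto") {
    entries <- .fastLDASearch(features, configs, plan, classes)
  } else {
    entries <- .directSearch(features, configs, classifier, plan, classes)
  }
  new("SensorSearchResult", entries = entries, classifier = classifier,
      sensorType = sensorType, nRepeats = plan@nRepeats)
}

.emptyEntry <- function(config, classes) {
  row <- data.frame(sites = .configKey(config),
                    n_sites = length(config@sites),
                    sensor_type = config@sensorType,
                    overall_ppv = NA_real_, ppv_sd = NA_real_,
                    status = "failed", stringsAsFactors = FALSE)
  for (cl in classes) row[[paste0("ppv_", cl)]] <- NA_real_
  row
}

.directSearch <- function(features, configs, classifier, plan, classes) {
  rows <- lapply(configs, function(cfg) {
    row <- .emptyEntry(cfg, classes)
    res <- tryCatch({
      sub <- selectChannels(features, cfg)
      ev <- evaluatePrimitives(sub, classifier, plan)[[classifier]]
      ov <- overallPPV(ev)
      pv <- ppvScores(pooledConfusion(ev))$perClass
      row$overall_ppv <- ov[["mean"]]; row$ppv_sd <- ov[["sd"]]
      for (cl in classes) row[[paste0("ppv_", cl)]] <- pv[[cl]]
      row$status <- "ok"
      row
    }, error = function(e) row)
    res
  })
  do.call(rbind, rows)
}

# sufficient statistics per fold, computed once on the full feature set
.ldaFoldStats <- function(fold, Xmat, wi, classes) {
  X <- Xmat
  Xtr <- X[fold$train, , drop = FALSE]
  ytr <- wi$window_label[fold$train]
  n <- nrow(Xtr); K <- length(classes)
  means <- matrix(0, K, ncol(X), dimnames = list(classes, colnames(X)))
  S <- matrix(0, ncol(X), ncol(X))
  nk <- numeric(K)
  for (i in seq_along(classes)) {
    xi <- Xtr[ytr == classes[i], , drop = FALSE]
    nk[i] <- nrow(xi)
    means[i, ] <- colMeans(xi)
    S <- S + crossprod(sweep(xi, 2, means[i, ]))
  }
  segTe <- wi$segment_id[fold$test]
  u <- unique(segTe)
  grp <- split(seq_along(segTe), factor(segTe, levels = u))
  truth <- wi$window_label[fold$test][!duplicated(segTe)]
  list(means = means, S = S / max(n - K, 1), priors = nk / n,
       Xte = X[fold$test, , drop = FALSE], grp = grp, truth = truth)
}

.fastLDASearch <- function(features, configs, plan, classes,
                           lambda = 1e-6) {
  X <- featureMatrix(features)
  wi <- windowInfo(features)
  fi <- featureInfo(features)
  folds <- if (plan@scheme == "stratified") {
    lapply(seq_len(plan@nRepeats), function(r)
      stratifiedSplit(features, plan, r))
  } else {
    losoSplits(features)
  }
  stats <- lapply(folds, .ldaFoldStats, Xmat = X, wi = wi, classes = classes)
  K <- length(classes)
  featIdxFor <- function(cfg) {
    keep <- fi$site %in% cfg@sites
    if (cfg@sensorType == "accelerometer") keep <- keep & fi$modality == "acc"
    which(keep)
  }
  rows <- lapply(configs, function(cfg) {
    row <- .emptyEntry(cfg, classes)
    tryCatch({
      idx <- featIdxFor(cfg)
      p <- length(idx)
      conf <- matrix(0L, K, K, dimnames = list(classes, classes))
      ov <- numeric(length(stats))
      for (f in seq_along(stats)) {
        st <- stats[[f]]
        Ssub <- st$S[idx, idx, drop = FALSE]
        Ssub <- Ssub + diag(lambda * sum(diag(Ssub)) / p, p)
        w <- solve(Ssub, t(st$means[, idx, drop = FALSE]))
        const <- -0.5 * colSums(t(st$means[, idx, drop = FALSE]) * w) +
          log(st$priors)
        d <- st$Xte[, idx, drop = FALSE] %*% w
        d <- sweep(d, 2, const, "+")
        predWin <- max.col(d, ties.method = "first")
        predSeg <- vapply(st$grp, function(rowsIdx)
          which.max(tabulate(predWin[rowsIdx], K)), integer(1))
        cm <- confusionCounts(st$truth, classes[predSeg], classes)
        conf <- conf + cm
        ov[f] <- ppvScores(cm)$overall
      }
      pv <- ppvScores(conf)$perClass
      row$overall_ppv <- mean(ov); row$ppv_sd <- stats::sd(ov)
      for (cl in classes) row[[paste0("ppv_", cl)]] <- pv[[cl]]
      row$status <- "ok"
      row
    }, error = function(e) row)
  })
  do.call(rbind, rows)
}

#' Paired IMU vs accelerometer comparison
#'
#' Evaluates each configuration twice on identical splits: once with all
#' 10 IMU channels per site and once with only the 3 acceleration
#' channels per site (accelerometry subsampled from the same sensors),
#' so the comparison isolates the sensor type.
#'
#' @param features A full-IMU [WindowFeatureSet].
#' @param configs List of [sensorConfig()] objects (sensor type is
#'   overridden per arm of the comparison).
#' @param classifier Classifier to use (default `"lda"`).
#' @param plan A [splitPlan()].
#' @return Data frame with one row per configuration: `sites`,
#'   `n_sites`, `imu_ppv`, `imu_sd`, `acc_ppv`, `acc_sd`.
#' @export
compareSensorTypes <- function(features, configs, classifier = "lda", plan) {
  stopifnot(is(features, "WindowFeatureSet"), is(plan, "SplitPlan"))
  if (is(configs, "SensorConfig")) configs <- list(configs)
  rows <- lapply(configs, function(cfg) {
    evalType <- function(type) {
      sub <- selectChannels(features, sensorConfig(cfg@sites, type))
      overallPPV(evaluatePrimitives(sub, classifier, plan)[[classifier]])
    }
    imu <- evalType("imu")
    acc <- evalType("accelerometer")
    data.frame(sites = .configKey(cfg), n_sites = length(cfg@sites),
               imu_ppv = imu[["mean"]], imu_sd = imu[["sd"]],
               acc_ppv = acc[["mean"]], acc_sd = acc[["sd"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot classification performance against sensor count
#'
#' Scatter of overall PPV versus number of sensors for every evaluated
#' configuration, with the best-per-count path drawn on top.
#'
#' @param result A `SensorSearchResult`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the best-per-count data frame.
#' @export
plotSearchResult <- function(result, ...) {
  e <- result@entries[result@entries$status == "ok", ]
  graphics::plot(jitter(e$n_sites, 0.3), e$overall_ppv,
                 col = "grey60", pch = 16, cex = 0.5,
                 xlab = "number of sensors", ylab = "overall PPV (%)", ...)
  bp <- bestPerCount(result)
  graphics::lines(bp$n_sites, bp$overall_ppv, col = "firebrick", lwd = 2)
  graphics::points(bp$n_sites, bp$overall_ppv, col = "firebrick", pch = 19)
  invisible(bp)
}
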