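# Normalization, sliding-window segmentation and the five statistical
# features (mean, sd, min, max, rms) per channel.

#' @rdname windowSpec
#' @export
setClass("WindowSpec", representation(widthS = "numeric", strideS = "numeric"))

setValidity("WindowSpec", function(object) {
  if (object@strideS <= 0 || object@strideS > object@widthS)
    "stride must satisfy 0 < stride_s <= width_s" else TRUE
})

#' Sliding-window specification
#'
#' Window width and stride in seconds (defaults 0.25 s / 0.1 s). Windows
#' are placed at `k * stride` from the start of a recording and emitted
#' only when fully inside it, so a contiguous span of `T` seconds yields
#' `floor((T - width) / stride) + 1` windows.
#'
#' @param widthS Window width in seconds (default 0.25).
#' @param strideS Stride in seconds (default 0.1); must satisfy
#'   `0 < strideS <= widthS`.
#' @return A `WindowSpec` object.
#' @export
#' @examples
#' windowSpec()
windowSpec <- function(widthS = 0.25, strideS = 0.1) {
  new("WindowSpec", widthS = widthS, strideS = strideS)
}

setMethod("show", "WindowSpec", function(object) {
  cat("WindowSpec:", object@widthS, "s windows sliding by",
      object@strideS, "s\n")
})

#' Z-score normalize a recording
#'
#' Transforms every channel to `(x - mean) / sd` using population
#' (divide-by-n) standard deviations. When `stats` is supplied (e.g.
#' computed on training data) those statistics are applied instead of
#' self-derived ones, which avoids train/test leakage; the statistics
#' actually used are always returned. A channel whose standard deviation
#' is below `1e-12` is passed through as all zeros after mean removal,
#' with a warning.
#'
#' @param rec A [SensorRecording].
#' @param stats Optional data frame with columns `channel`, `mean`, `sd`
#'   as returned by a previous call; its channel set must match `rec`.
#' @return List with elements `recording` (normalized
#'   [SensorRecording]) and `stats` (the per-channel statistics used).
#' @export
#' @examples
#' out <- simulateRecording(deskProtocol(), subjectParams(), seed = 1,
#'                          sampleRate = 60)
#' norm <- zscoreNormalize(out$recording)
#' round(colMeans(signalMatrix(norm$recording))[1:3], 12)
zscoreNormalize <- function(rec, stats = NULL) {
  stopifnot(is(rec, "SensorRecording"))
  x <- rec@signal
  ch <- colnames(x)
  if (is.null(stats)) {
    m <- colMeans(x)
    s <- sqrt(colMeans(x^2) - m^2)  # population sd
    stats <- data.frame(channel = ch, mean = m, sd = s,
                        row.names = NULL, stringsAsFactors = FALSE)
  } else {
    if (!setequal(stats$channel, ch) || length(stats$channel) != length(ch))
      stop("channel sets of 'stats' and the recording do not match")
    stats <- stats[match(ch, stats$channel), ]
  }
  degenerate <- stats$sd < 1e-12
  if (any(degenerate))
    warning(sum(degenerate), " channel(s) with near-zero sd passed ",
            "through as zeros after mean removal: ",
            paste(head(ch[degenerate], 5), collapse = ", "))
  sdUse <- ifelse(degenerate, 1, stats$sd)
  x <- sweep(x, 2, stats$mean)
  x <- sweep(x, 2, sdUse, "/")
  x[, degenerate] <- 0
  out <- rec
  out@signal <- x
  list(recording = out, stats = stats)
}

#' Cut a recording into labeled sliding windows
#'
#' Places windows of `spec@widthS` seconds every `spec@strideS` seconds
#' from the start of the recording; a window is emitted only if it lies
#' fully inside the recording. Each window is labeled by the primitive
#' segment owning the majority of its samples, ties broken toward the
#' earlier segment; windows whose samples fall entirely outside all
#' segments are dropped.
#'
#' @param rec A [SensorRecording].
#' @param labels A [segmentLabels()] object.
#' @param spec A [windowSpec()].
#' @return Data frame with one row per window: `window_start_s`,
#'   `start_index`, `n_samples`, `segment_id`, `label`.
#' @export
segmentWindows <- function(rec, labels, spec = windowSpec()) {
  stopifnot(is(rec, "SensorRecording"), is(labels, "SegmentLabels"),
            is(spec, "WindowSpec"))
  validObject(spec)
  rate <- rec@sampleRate
  total <- nrow(rec@signal)
  widthN <- max(1L, as.integer(round(spec@widthS * rate)))
  strideN <- max(1L, as.integer(round(spec@strideS * rate)))
  if (total < widthN) {
    warning("recording shorter than one window; no windows emitted")
    return(data.frame(window_start_s = numeric(0), start_index = integer(0),
                      n_samples = integer(0), segment_id = integer(0),
                      label = character(0)))
  }
  nWin <- (total - widthN) %/% strideN + 1L
  startIdx <- (seq_len(nWin) - 1L) * strideN + 1L

  seg <- labels@segments
  tsec <- (seq_len(total) - 1) / rate
  sampleSeg <- rep(NA_integer_, total)
  if (nrow(seg)) {
    j <- findInterval(tsec + 1e-9, seg$start_s)
    ok <- j >= 1L & tsec < seg$end_s[pmax(j, 1L)] - 1e-9
    sampleSeg[ok] <- j[ok]
  }

  segOf <- integer(nWin)
  for (w in seq_len(nWin)) {
    ss <- sampleSeg[startIdx[w]:(startIdx[w] + widthN - 1L)]
    ss <- ss[!is.na(ss)]
    if (!length(ss)) { segOf[w] <- NA_integer_; next }
    counts <- tabulate(ss, nbins = nrow(seg))
    segOf[w] <- which.max(counts)  # ties resolve to the earlier segment
  }
  keep <- !is.na(segOf)
  data.frame(
    window_start_s = (startIdx[keep] - 1L) / rate,
    start_index = startIdx[keep],
    n_samples = widthN,
    segment_id = seg$segment_id[segOf[keep]],
    label = seg$label[segOf[keep]],
    stringsAsFactors = FALSE
  )
}

#' Statistical features of one window
#'
#' Computes the five statistical features (mean, population standard
#' deviation, minimum, maximum, root mean square) of every channel in a
#' time x channel window.
#'
#' @param window Numeric time x channel matrix; must be non-empty and
#'   finite.
#' @return Named numeric vector of length `5 * ncol(window)`, channel-
#'   major (all five statistics of channel 1, then channel 2, ...).
#' @export
#' @examples
#' extractFeatures(cbind(a = c(3, -3)))
extractFeatures <- function(window) {
  window <- as.matrix(window)
  if (nrow(window) == 0L || ncol(window) == 0L)
    stop("window must be non-empty")
  if (!all(is.finite(window))) stop("window contains non-finite samples")
  m <- colMeans(window)
  ms <- colMeans(window^2)
  s <- sqrt(pmax(ms - m^2, 0))
  mn <- apply(window, 2, min)
  mx <- apply(window, 2, max)
  rms <- sqrt(ms)
  out <- as.vector(rbind(m, s, mn, mx, rms))
  ch <- colnames(window)
  if (is.null(ch)) ch <- paste0("ch", seq_len(ncol(window)))
  names(out) <- paste(rep(ch, each = 5), .featureStats(), sep = ".")
  out
}

#' Featurize a labeled recording
#'
#' Runs the windowing and featurization pipeline on one recording:
#' sliding windows per [segmentWindows()], then the five statistical
#' features of every channel per window. Feature rows are ordered
#' site-major (channel order of the recording, five statistics per
#' channel).
#'
#' @inheritParams segmentWindows
#' @return A [WindowFeatureSet].
#' @export
windowFeatures <- function(rec, labels, spec = windowSpec()) {
  win <- segmentWindows(rec, labels, spec)
  x <- rec@signal
  nWin <- nrow(win)
  nCh <- ncol(x)
  if (nWin == 0L) stop("no windows could be formed from the recording")
  widthN <- win$n_samples[1]
  # widthN x nWin index matrix into the sample dimension
  idx <- outer(0:(widthN - 1L), win$start_index, "+")
  feats <- matrix(0, nWin, nCh * 5L)
  for (c in seq_len(nCh)) {
    W <- matrix(x[idx, c], widthN, nWin)
    m <- colMeans(W)
    ms <- colMeans(W^2)
    mn <- W[1, ]; mx <- W[1, ]
    for (r in seq_len(widthN - 1L) + 1L) {
      mn <- pmin(mn, W[r, ]); mx <- pmax(mx, W[r, ])
    }
    j <- (c - 1L) * 5L
    feats[, j + 1L] <- m
    feats[, j + 2L] <- sqrt(pmax(ms - m^2, 0))
    feats[, j + 3L] <- mn
    feats[, j + 4L] <- mx
    feats[, j + 5L] <- sqrt(ms)
  }
  ci <- as.data.frame(rec@channelInfo)
  fi <- data.frame(
    site = rep(ci$site, each = 5L),
    modality = rep(ci$modality, each = 5L),
    axis = rep(ci$axis, each = 5L),
    stat = rep(.featureStats(), nCh),
    stringsAsFactors = FALSE
  )
  wi <- data.frame(
    subject_id = rec@subjectID,
    segment_id = win$segment_id,
    window_label = win$label,
    window_start_s = win$window_start_s,
    stringsAsFactors = FALSE
  )
  windowFeatureSet(feats, wi, fi)
}

#' Featurize a simulated study
#'
#' Full default pipeline from a [simulateStudy()] result to one combined
#' feature table: per-recording z-score normalization, sliding windows,
#' five statistical features per channel. Segment ids are offset per
#' subject so that they are globally unique.
#'
#' @param study List of `(recording, labels)` pairs from
#'   [simulateStudy()].
#' @param spec A [windowSpec()].
#' @param normalize Z-score each recording before featurization
#'   (default TRUE).
#' @return A [WindowFeatureSet] combining all subjects.
#' @export
studyFeatures <- function(study, spec = windowSpec(), normalize = TRUE) {
  offset <- 0L
  feats <- list(); infos <- list(); fi <- NULL
  for (s in study) {
    rec <- if (normalize) zscoreNormalize(s$recording)$recording else s$recording
    wfs <- windowFeatures(rec, s$labels, spec)
    wi <- windowInfo(wfs)
    wi$segment_id <- wi$segment_id + offset
    offset <- offset + max(segmentTable(s$labels)$segment_id)
    feats[[length(feats) + 1L]] <- featureMatrix(wfs)
    infos[[length(infos) + 1L]] <- wi
    if (is.null(fi)) fi <- featureInfo(wfs)
  }
  windowFeatureSet(do.call(rbind, feats), do.call(rbind, infos), fi)
}

# ---------------------------------------------------------------------------
# SensorConfig and channel selection
# ---------------------------------------------------------------------------

#' @rdname sensorConfig
#' @export
setClass("SensorConfig",
  representation(sites = "character", sensorType = "character"))

setValidity("SensorConfig", function(object) {
  msg <- NULL
  if (!length(object@sites)) msg <- c(msg, "sites must be non-empty")
  if (!object@sensorType %in% c("imu", "accelerometer"))
    msg <- c(msg, "sensorType must be 'imu' or 'accelerometer'")
  if (is.null(msg)) TRUE else msg
})

#' Sensor configuration
#'
#' A subset of body sites and a sensor type. A full IMU keeps all 10
#' channels per site (3 acc + 3 gyr + 4 quaternion); `"accelerometer"`
#' keeps only the 3 acceleration channels per site, emulating a
#' reduced-cost accelerometry system.
#'
#' @param sites Character vector of site names (stored sorted).
#' @param sensorType `"imu"` (default) or `"accelerometer"`.
#' @return A `SensorConfig` object.
#' @export
#' @examples
#' sensorConfig(c("r_hand", "sternum"), "accelerometer")
sensorConfig <- function(sites, sensorType = c("imu", "accelerometer")) {
  sensorType <- match.arg(sensorType)
  new("SensorConfig", sites = sort(unique(as.character(sites))),
      sensorType = sensorType)
}

setMethod("show", "SensorConfig", function(object) {
  cat("SensorConfig (", object@sensorType, "): ",
      paste(object@sites, collapse = " + "), "\n", sep = "")
})

#' Select feature columns for a sensor configuration
#'
#' Retains exactly the feature rows belonging to the configuration's
#' sites and sensor type (all modalities for `"imu"`, acceleration only
#' for `"accelerometer"`); window metadata is untouched. The operation
#' is idempotent.
#'
#' @param features A [WindowFeatureSet].
#' @param config A [sensorConfig()].
#' @return A [WindowFeatureSet] restricted to the configured channels.
#' @export
selectChannels <- function(features, config) {
  stopifnot(is(features, "WindowFeatureSet"), is(config, "SensorConfig"))
  validObject(config)
  fi <- featureInfo(features)
  valid <- unique(fi$site)
  unknown <- setdiff(config@sites, valid)
  if (length(unknown))
    stop("unknown site(s): ", paste(unknown, collapse = ", "),
         "; valid sites are: ", paste(sort(valid), collapse = ", "))
  keep <- fi$site %in% config@sites
  if (config@sensorType == "accelerometer") keep <- keep & fi$modality == "acc"
  new("WindowFeatureSet", features[keep, ])
}
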