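#' @import methods
#' @importFrom stats rnorm rlnorm rmultinom runif sd var predict
#' @importFrom utils head tail
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Canonical functional primitive classes
#'
#' The four upper-extremity functional primitives recognised by the
#' package, in canonical order: `reach` (move the hand into contact with
#' a target object), `transport` (convey the object), `reposition` (move
#' the empty hand proximate to the object) and `idle` (stand at the
#' ready). All labels, factors and score matrices use this order.
#'
#' @return Character vector of the four class names.
#' @export
#' @examples
#' primitiveClasses()
primitiveClasses <- function() c("reach", "transport", "reposition", "idle")

#' Sensor body sites
#'
#' The eleven body sites instrumented in the tabletop protocol: head,
#' sternum, pelvis, and bilateral scapula, upper arm, forearm and hand.
#' A full IMU at a site contributes 10 channels (3 linear accelerations,
#' 3 angular velocities, 4 quaternion components); an accelerometer
#' contributes the 3 acceleration channels only.
#'
#' @return Character vector of the 11 site names.
#' @export
#' @examples
#' sensorSites()
sensorSites <- function() {
  c("head", "sternum", "pelvis",
    "l_scap", "l_arm", "l_forearm", "l_hand",
    "r_scap", "r_arm", "r_forearm", "r_hand")
}

# channel layout of one full IMU: modality/axis pairs, site-major order
.imuChannelLayout <- function() {
  data.frame(
    modality = c(rep("acc", 3), rep("gyr", 3), rep("quat", 4)),
    axis     = c("x", "y", "z", "x", "y", "z", "w", "x", "y", "z"),
    stringsAsFactors = FALSE
  )
}

.featureStats <- function() c("mean", "sd", "min", "max", "rms")

# ---------------------------------------------------------------------------
# TaskProtocol
# ---------------------------------------------------------------------------

#' @rdname taskProtocol
#' @export
setClass("TaskProtocol",
  representation(
    nTrials = "integer",
    nTargets = "integer",
    targetDistance = "numeric",
    objects = "character",
    primitiveSequence = "character"
  )
)

setValidity("TaskProtocol", function(object) {
  msg <- NULL
  if (object@nTrials < 1L) msg <- c(msg, "nTrials must be >= 1")
  if (object@nTargets < 1L) msg <- c(msg, "nTargets must be >= 1")
  if (length(object@objects) < 1L) msg <- c(msg, "at least one object required")
  if (length(object@primitiveSequence) < 1L)
    msg <- c(msg, "primitiveSequence must be non-empty")
  bad <- setdiff(object@primitiveSequence, primitiveClasses())
  if (length(bad))
    msg <- c(msg, paste0("unknown primitive class(es): ",
                         paste(bad, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' Tabletop task protocol
#'
#' Describes the structured tabletop activity: an object is moved between
#' a centre target and `nTargets` radially arrayed targets
#' (`targetDistance` cm away), `nTrials` times per object. Each
#' centre-to-target move elicits the primitive sequence
#' `primitiveSequence` (default idle, reach, transport, reposition).
#'
#' @param nTrials Number of trials per object (default 5).
#' @param nTargets Number of radial targets (default 8).
#' @param targetDistance Target distance from centre, in cm (default 20).
#' @param objects Names of manipulated objects (default a paper roll and
#'   a can, i.e. two objects).
#' @param primitiveSequence Ordered primitive classes generated by each
#'   move.
#' @return A `TaskProtocol` object.
#' @export
#' @examples
#' taskProtocol(nTrials = 1, nTargets = 4)
taskProtocol <- function(nTrials = 5L, nTargets = 8L, targetDistance = 20,
                         objects = c("roll", "can"),
                         primitiveSequence = c("idle", "reach",
                                               "transport", "reposition")) {
  new("TaskProtocol",
      nTrials = as.integer(nTrials), nTargets = as.integer(nTargets),
      targetDistance = as.numeric(targetDistance),
      objects = as.character(objects),
      primitiveSequence = as.character(primitiveSequence))
}

#' Desk-scale task protocol
#'
#' A reduced protocol (1 trial, 6 targets, 2 objects = 48 primitives per
#' subject) intended for fast experimentation together with the 60 Hz
#' generator mode. Window and stride are specified in seconds throughout
#' the package, so results are robust to the sample-rate change.
#'
#' @return A `TaskProtocol` object.
#' @export
deskProtocol <- function() taskProtocol(nTrials = 1L, nTargets = 6L)

setMethod("show", "TaskProtocol", function(object) {
  nMoves <- object@nTrials * object@nTargets * length(object@objects)
  cat("TaskProtocol:", object@nTrials, "trial(s) x", object@nTargets,
      "targets x", length(object@objects), "object(s)\n")
  cat("  primitive sequence per move:",
      paste(object@primitiveSequence, collapse = " -> "), "\n")
  cat("  total primitives:", nMoves * length(object@primitiveSequence), "\n")
})

# ---------------------------------------------------------------------------
# SubjectParams
# ---------------------------------------------------------------------------

#' @rdname subjectParams
#' @export
setClass("SubjectParams",
  representation(
    subjectID = "character",
    movementSpeedScale = "numeric",
    noiseSd = "numeric",
    durationMeanS = "numeric",
    durationCV = "numeric",
    activeSide = "character",
    signalGain = "numeric",
    loadingJitter = "matrix"
  )
)

setValidity("SubjectParams", function(object) {
  msg <- NULL
  if (object@movementSpeedScale <= 0) msg <- c(msg, "movementSpeedScale must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@durationMeanS <= 0) msg <- c(msg, "durationMeanS must be > 0")
  if (object@durationCV < 0) msg <- c(msg, "durationCV must be >= 0")
  if (length(object@activeSide) != 1L ||
      !object@activeSide %in% c("left", "right"))
    msg <- c(msg, "activeSide must be exactly one of 'left' or 'right'")
  if (object@signalGain <= 0) msg <- c(msg, "signalGain must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Virtual subject parameters
#'
#' Parameters governing a virtual subject's kinematics: overall movement
#' speed, sensor noise level, primitive duration distribution (lognormal
#' with mean `durationMeanS` seconds and coefficient of variation
#' `durationCV`), the active (task-performing) side, a multiplicative
#' gain on all movement signal, and an optional per-site/per-component
#' loading jitter matrix expressing idiosyncratic movement style.
#'
#' @param subjectID Subject identifier.
#' @param movementSpeedScale Dimensionless speed multiplier (> 0); faster
#'   subjects produce shorter primitives.
#' @param noiseSd Standard deviation of additive Gaussian sensor noise,
#'   in channel units.
#' @param durationMeanS Mean primitive duration in seconds at unit speed.
#' @param durationCV Coefficient of variation of primitive durations.
#' @param activeSide `"left"` or `"right"`; the side performing the task.
#' @param signalGain Multiplicative gain on the movement signal (> 0).
#' @param loadingJitter Optional 7 x 3 matrix of per-site multipliers for
#'   the (horizontal, vertical, rotational) signal components; a 0 x 0
#'   matrix (the default) means no jitter.
#' @return A `SubjectParams` object.
#' @export
#' @examples
#' subjectParams("s1")
subjectParams <- function(subjectID = "s1", movementSpeedScale = 1,
                          noiseSd = 0.22, durationMeanS = 1.0,
                          durationCV = 0.25, activeSide = "right",
                          signalGain = 1,
                          loadingJitter = matrix(numeric(0), 0, 0)) {
  new("SubjectParams", subjectID = as.character(subjectID),
      movementSpeedScale = movementSpeedScale, noiseSd = noiseSd,
      durationMeanS = durationMeanS, durationCV = durationCV,
      activeSide = activeSide, signalGain = signalGain,
      loadingJitter = loadingJitter)
}

setMethod("show", "SubjectParams", function(object) {
  cat("SubjectParams '", object@subjectID, "': active side ",
      object@activeSide, ", speed x", format(object@movementSpeedScale, digits = 3),
      ", gain x", format(object@signalGain, digits = 3),
      ", noise sd ", format(object@noiseSd, digits = 3), "\n", sep = "")
})

# ---------------------------------------------------------------------------
# SensorRecording
# ---------------------------------------------------------------------------

#' @rdname SensorRecording
#' @export
setClass("SensorRecording",
  representation(
    signal = "matrix",          # time x channel
    channelInfo = "DataFrame",  # site, modality, axis per channel
    sampleRate = "numeric",
    subjectID = "character"
  )
)

setValidity("SensorRecording", function(object) {
  msg <- NULL
  ci <- object@channelInfo
  if (ncol(object@signal) != nrow(ci))
    msg <- c(msg, "signal columns must match channelInfo rows")
  if (!all(c("site", "modality", "axis") %in% colnames(ci)))
    msg <- c(msg, "channelInfo needs columns site, modality, axis")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (anyNA(object@signal))
    msg <- c(msg, "signal must not contain missing samples")
  if (nrow(ci) > 0 && anyDuplicated(paste(ci$site, ci$modality, ci$axis)))
    msg <- c(msg, "duplicate (site, modality, axis) channels")
  if (is.null(msg)) TRUE else msg
})

#' Multi-channel inertial recording
#'
#' A `SensorRecording` holds a time x channel matrix of inertial data
#' sampled at a fixed rate, with per-channel metadata (body site,
#' modality `acc`/`gyr`/`quat`, axis) and a subject identifier. Sample
#' `i` occurs at time `(i - 1) / sampleRate` seconds. Construct with
#' [sensorRecording()] or [simulateRecording()].
#'
#' @param signal Numeric time x channel matrix.
#' @param channelInfo Data frame (or `DataFrame`) with columns `site`,
#'   `modality`, `axis`, one row per signal column.
#' @param sampleRate Sampling rate in Hz.
#' @param subjectID Subject identifier.
#' @return A `SensorRecording` object.
#' @aliases SensorRecording-class SensorRecording
#' @export
sensorRecording <- function(signal, channelInfo, sampleRate, subjectID) {
  ci <- as(as.data.frame(channelInfo), "DataFrame")
  colnames(signal) <- paste(ci$site, ci$modality, ci$axis, sep = ".")
  new("SensorRecording", signal = signal, channelInfo = ci,
      sampleRate = as.numeric(sampleRate), subjectID = as.character(subjectID))
}

setMethod("show", "SensorRecording", function(object) {
  cat("SensorRecording: subject '", object@subjectID, "', ",
      nrow(object@signal), " samples x ", ncol(object@signal),
      " channels @ ", object@sampleRate, " Hz (",
      format(nrow(object@signal) / object@sampleRate, digits = 4),
      " s)\n", sep = "")
  cat("  sites:", paste(unique(object@channelInfo$site), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# SegmentLabels
# ---------------------------------------------------------------------------

#' @rdname segmentLabels
#' @export
setClass("SegmentLabels", representation(segments = "data.frame"))

setValidity("SegmentLabels", function(object) {
  s <- object@segments
  msg <- NULL
  need <- c("segment_id", "start_s", "end_s", "label")
  if (!all(need %in% colnames(s)))
    return(paste("segments needs columns", paste(need, collapse = ", ")))
  if (nrow(s)) {
    if (any(s$end_s <= s$start_s)) msg <- c(msg, "end_s must exceed start_s")
    if (is.unsorted(s$start_s)) msg <- c(msg, "segments must be sorted by start_s")
    if (nrow(s) > 1 && any(s$start_s[-1] < s$end_s[-nrow(s)] - 1e-9))
      msg <- c(msg, "segments must not overlap")
    bad <- setdiff(unique(s$label), primitiveClasses())
    if (length(bad))
      msg <- c(msg, paste("unknown primitive label(s):", paste(bad, collapse = ", ")))
    if (anyDuplicated(s$segment_id)) msg <- c(msg, "segment_id must be unique")
  }
  if (is.null(msg)) TRUE else msg
})

#' Ground-truth primitive segment labels
#'
#' Time-stamped, non-overlapping primitive intervals over a recording.
#' Each row gives a segment id, start and end time in seconds, and one
#' of the four primitive classes.
#'
#' @param segments Data frame with columns `segment_id`, `start_s`,
#'   `end_s`, `label`.
#' @return A `SegmentLabels` object.
#' @export
#' @examples
#' segmentLabels(data.frame(segment_id = 1:2, start_s = c(0, 1),
#'                          end_s = c(1, 2), label = c("idle", "reach")))
segmentLabels <- function(segments) {
  segments <- as.data.frame(segments)
  segments$segment_id <- as.integer(segments$segment_id)
  new("SegmentLabels", segments = segments)
}

#' @describeIn segmentLabels Segment table accessor.
#' @param x A `SegmentLabels` object.
#' @export
segmentTable <- function(x) x@segments

setMethod("show", "SegmentLabels", function(object) {
  s <- object@segments
  cat("SegmentLabels:", nrow(s), "segments spanning",
      if (nrow(s)) format(max(s$end_s) - min(s$start_s), digits = 4) else 0,
      "s\n")
  if (nrow(s)) print(table(factor(s$label, primitiveClasses())))
})

# ---------------------------------------------------------------------------
# WindowFeatureSet (SummarizedExperiment wrapper)
# ---------------------------------------------------------------------------

#' @rdname WindowFeatureSet
#' @export
setClass("WindowFeatureSet", contains = "SummarizedExperiment")

setValidity("WindowFeatureSet", function(object) {
  msg <- NULL
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject_id", "segment_id", "window_label", "window_start_s")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData needs", paste(need, collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("site", "modality", "axis", "stat") %in% colnames(rd)))
    msg <- c(msg, "rowData needs site, modality, axis, stat")
  if (length(SummarizedExperiment::assays(object)) &&
      !all(is.finite(SummarizedExperiment::assay(object))))
    msg <- c(msg, "feature values must all be finite")
  if ("window_label" %in% colnames(cd)) {
    bad <- setdiff(unique(cd$window_label), primitiveClasses())
    if (length(bad))
      msg <- c(msg, paste("unknown window label(s):", paste(bad, collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
})

#' Window-level feature table
#'
#' A `WindowFeatureSet` is a [SummarizedExperiment] whose columns are
#' analysis windows and whose rows are statistical features, named
#' `<site>.<modality>.<axis>.<stat>` with
#' `stat` in mean, sd, min, max, rms. Window metadata (`subject_id`,
#' `segment_id`, `window_label`, `window_start_s`) lives in `colData`;
#' feature provenance (`site`, `modality`, `axis`, `stat`) in `rowData`.
#'
#' @param features Numeric windows x features matrix (it is stored
#'   transposed, features x windows, as the assay).
#' @param windowInfo Data frame of window metadata, one row per window.
#' @param featureInfo Data frame with columns `site`, `modality`, `axis`,
#'   `stat`, one row per feature.
#' @return A `WindowFeatureSet`.
#' @aliases WindowFeatureSet-class WindowFeatureSet
#' @export
windowFeatureSet <- function(features, windowInfo, featureInfo) {
  featureInfo <- as.data.frame(featureInfo)
  fn <- paste(featureInfo$site, featureInfo$modality, featureInfo$axis,
              featureInfo$stat, sep = ".")
  assayMat <- t(features)
  rownames(assayMat) <- fn
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assayMat),
    rowData = S4Vectors::DataFrame(featureInfo, row.names = fn),
    colData = S4Vectors::DataFrame(as.data.frame(windowInfo))
  )
  new("WindowFeatureSet", se)
}

#' @describeIn WindowFeatureSet Windows x features numeric matrix.
#' @param x A `WindowFeatureSet`.
#' @export
featureMatrix <- function(x) t(SummarizedExperiment::assay(x, "features"))

#' @describeIn WindowFeatureSet Window metadata (`colData`) as a data frame.
#' @export
windowInfo <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn WindowFeatureSet Feature metadata (`rowData`) as a data frame.
#' @export
featureInfo <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' @describeIn WindowFeatureSet Window labels as a factor in canonical
#'   class order.
#' @export
windowLabels <- function(x) {
  factor(SummarizedExperiment::colData(x)$window_label,
         levels = primitiveClasses())
}

setMethod("show", "WindowFeatureSet", function(object) {
  cat("WindowFeatureSet:", ncol(object), "windows x", nrow(object),
      "features\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  subjects:", paste(unique(cd$subject_id), collapse = ", "), "\n")
  cat("  segments:", length(unique(paste(cd$subject_id, cd$segment_id))), "\n")
  print(table(factor(cd$window_label, primitiveClasses())))
})

# ---------------------------------------------------------------------------
# ClassMoments
# ---------------------------------------------------------------------------

#' @rdname classMoments
#' @export
setClass("ClassMoments",
  representation(means = "matrix", vars = "matrix",
                 proportions = "numeric", classes = "character")
)

setValidity("ClassMoments", function(object) {
  msg <- NULL
  if (!identical(dim(object@means), dim(object@vars)))
    msg <- c(msg, "means and vars must have identical dimensions")
  if (nrow(object@means) != length(object@classes))
    msg <- c(msg, "one row of moments per class required")
  if (any(object@vars < 0)) msg <- c(msg, "variances must be >= 0")
  if (length(object@proportions) != length(object@classes))
    msg <- c(msg, "one proportion per class required")
  if (abs(sum(object@proportions) - 1) > 1e-9)
    msg <- c(msg, "proportions must sum to 1 (tolerance 1e-9)")
  if (any(object@proportions < 0)) msg <- c(msg, "proportions must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Per-class feature moments
#'
#' Class-conditional feature means and variances plus class proportions,
#' used to draw moment-matched feature populations for scaling studies.
#'
#' @param means Class x feature matrix of means.
#' @param vars Class x feature matrix of variances (>= 0).
#' @param proportions Class proportions summing to 1.
#' @param classes Class names, one per row of `means`.
#' @return A `ClassMoments` object.
#' @seealso [momentsFromFeatures()], [simulateFeaturePopulation()]
#' @export
classMoments <- function(means, vars, proportions,
                         classes = rownames(means)) {
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(means)))
  new("ClassMoments", means = as.matrix(means), vars = as.matrix(vars),
      proportions = as.numeric(proportions), classes = as.character(classes))
}

setMethod("show", "ClassMoments", function(object) {
  cat("ClassMoments:", length(object@classes), "classes x",
      ncol(object@means), "features\n")
  cat("  proportions:",
      paste(sprintf("%s=%.3f", object@classes, object@proportions),
            collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# SplitPlan
# ---------------------------------------------------------------------------

#' @rdname splitPlan
#' @export
setClass("SplitPlan",
  representation(scheme = "character", trainFraction = "numeric",
                 nRepeats = "integer", seed = "integer")
)

setValidity("SplitPlan", function(object) {
  msg <- NULL
  if (!object@scheme %in% c("stratified", "loso"))
    msg <- c(msg, "scheme must be 'stratified' or 'loso'")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    msg <- c(msg, "trainFraction must lie in (0, 1)")
  if (object@nRepeats < 1L) msg <- c(msg, "nRepeats must be >= 1")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "an explicit integer seed is required")
  if (is.null(msg)) TRUE else msg
})

#' Evaluation split plan
#'
#' Describes how labeled windows are partitioned for evaluation. The
#' sampling unit is the primitive segment: all windows of a segment
#' travel together, so near-duplicate overlapping windows never leak
#' across the train/test boundary. `"stratified"` draws
#' `trainFraction` of each class's segments `nRepeats` times;
#' `"loso"` holds out each subject once.
#'
#' @param scheme `"stratified"` (repeated stratified holdout, default) or
#'   `"loso"` (leave-one-subject-out).
#' @param trainFraction Fraction of segments per class used for training
#'   (default 0.6).
#' @param nRepeats Number of stratified repeats (default 10; ignored for
#'   LOSO, where the fold count is the subject count).
#' @param seed Integer seed; required, with no silent default.
#' @return A `SplitPlan` object.
#' @export
#' @examples
#' splitPlan(seed = 1)
splitPlan <- function(scheme = c("stratified", "loso"), trainFraction = 0.6,
                      nRepeats = 10L, seed) {
  scheme <- match.arg(scheme)
  if (missing(seed)) stop("splitPlan() requires an explicit seed")
  new("SplitPlan", scheme = scheme, trainFraction = trainFraction,
      nRepeats = as.integer(nRepeats), seed = as.integer(seed))
}

setMethod("show", "SplitPlan", function(object) {
  if (object@scheme == "stratified")
    cat("SplitPlan: stratified ", object@trainFraction * 100, "/",
        (1 - object@trainFraction) * 100, " x ", object@nRepeats,
        " repeats (seed ", object@seed, ")\n", sep = "")
  else
    cat("SplitPlan: leave-one-subject-out (seed ", object@seed, ")\n",
        sep = "")
})
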