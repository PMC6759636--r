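# Synthetic tabletop-task generator. Emulates six stroke patients wearing
# 11 IMUs while moving an object between a centre target and radially
# arrayed targets. The kinematic model uses minimum-jerk acceleration
# bursts for moving primitives, a forearm "grasp rotation" angular-
# velocity burst present in reach but absent in reposition, a shared slow
# postural-sway component that correlates channels across adjacent sites
# (compensatory trunk/head motion, prominent in hemiparesis), and
# independent Gaussian sensor noise.

#' Primitive counts of the reference dataset
#'
#' Per-class functional-primitive counts of the tabletop reference
#' dataset: 810 reaches, 708 transports, 781 repositions, 582 idles
#' (2,881 in total).
#'
#' @return Named integer vector in canonical class order.
#' @export
#' @examples
#' sum(primitiveCounts())
primitiveCounts <- function() {
  c(reach = 810L, transport = 708L, reposition = 781L, idle = 582L)
}

#' Default class proportions
#'
#' Class proportions of the reference dataset, i.e.
#' [primitiveCounts()] normalized to sum to one.
#'
#' @return Named numeric 4-vector in canonical class order.
#' @export
#' @examples
#' defaultClassProportions()
defaultClassProportions <- function() {
  n <- primitiveCounts()
  n / sum(n)
}

# class-conditional kinematic codes: rows = (horizontal energy, vertical
# load, grasp rotation); moving classes share horizontal energy, the
# vertical component's sign separates transport (object lowered/loaded)
# from reach/reposition, and grasp rotation separates reach from
# reposition (the empty-hand return has no supination burst)
.classCodes <- function() {
  m <- rbind(
    horizontal = c(reach = 1, transport = 1, reposition = 1,    idle = 0),
    vertical   = c(reach = 1, transport = -1, reposition = 0.75, idle = 0),
    rotation   = c(reach = 1, transport = 0.2, reposition = 0,   idle = 0)
  )
  m
}

# per-site loadings of the three kinematic components, plus the gain of
# the shared sway process; signal decays from hand to trunk, sway is
# strongest at the trunk. Sites not listed (non-active arm) carry noise
# only.
.siteLoadings <- function(activeSide = "right") {
  pre <- if (activeSide == "right") "r_" else "l_"
  data.frame(
    site = c(paste0(pre, c("hand", "forearm", "arm", "scap")),
             "sternum", "pelvis", "head"),
    horizontal = c(1.00, 0.90, 0.75, 0.65, 0.60, 0.55, 0.50),
    vertical   = c(1.00, 0.90, 0.70, 0.65, 0.60, 0.55, 0.50),
    rotation   = c(0.85, 1.00, 0.75, 0.60, 0.55, 0.50, 0.45),
    sway       = c(0.35, 0.40, 0.50, 0.60, 1.00, 0.90, 0.80),
    stringsAsFactors = FALSE
  )
}

# minimum-jerk acceleration profile on tau in [0, 1], scaled to unit peak
.minJerkAcc <- function(tau) {
  (60 * tau - 180 * tau^2 + 120 * tau^3) / 5.7735
}

#' Simulate a labeled inertial recording
#'
#' Generates one subject's recording of the tabletop task together with
#' ground-truth segment labels. Each centre-to-target move produces the
#' protocol's primitive sequence; primitive durations are lognormal
#' (mean `durationMeanS`, CV `durationCV`, shortened for faster
#' subjects). Moving primitives carry a minimum-jerk linear-acceleration
#' burst (horizontal components along the target direction; a vertical
#' component whose sign separates transport from reach/reposition), reach
#' carries a biphasic forearm supination burst on the angular-velocity
#' channels which reposition lacks, and idle is signal-free. Quaternions
#' are obtained by integrating the clean angular velocity from the
#' identity orientation about each site's fixed rotation axis and
#' renormalizing; sensor noise is added afterwards. A shared slow sway
#' process is mixed into the acceleration channels of the active-arm,
#' trunk and head sites, producing realistic cross-channel correlation.
#' The non-active arm's four sites carry noise only.
#'
#' `separation` scales all class-dependent signal: at `separation = 0`
#' the four class-conditional distributions coincide (pure noise plus
#' sway), giving a null-calibration condition in which any classifier can
#' only reach chance accuracy.
#'
#' Identical `(protocol, subject, seed)` reproduce bit-identical output.
#'
#' @param protocol A [taskProtocol()].
#' @param subject A [subjectParams()].
#' @param seed Integer seed (required).
#' @param sampleRate Sampling rate in Hz (default 240; 60 is the
#'   desk-scale mode — window and stride are specified in seconds, so
#'   downstream results are robust to the rate).
#' @param separation Class-separability dial, >= 0 (default 1).
#' @param swaySd Standard deviation of the shared sway process, in
#'   channel units (default 0.7).
#' @param accAmp Peak horizontal/vertical acceleration amplitude
#'   (default 1).
#' @param gyroAmp Peak grasp-rotation angular velocity, rad/s
#'   (default 2).
#' @param siteSpecialization In `[0, 1]` (default 0). Fraction of each
#'   move's signal carried exclusively by one "dominant" signal site,
#'   assigned cyclically over moves; the other signal sites keep
#'   `1 - siteSpecialization` of their loading for that move. At 0 every
#'   signal site observes every move (redundant placement); towards 1
#'   each site becomes indispensable for its share of the moves, which
#'   emulates movement repertoires in which different body segments
#'   dominate different movements.
#' @return List with elements `recording` (a [SensorRecording]) and
#'   `labels` (a [segmentLabels()]).
#' @export
#' @examples
#' out <- simulateRecording(deskProtocol(), subjectParams("s1"),
#'                          seed = 7, sampleRate = 60)
#' out$recording
simulateRecording <- function(protocol, subject, seed, sampleRate = 240,
                              separation = 1, swaySd = 0.7,
                              accAmp = 1, gyroAmp = 2,
                              siteSpecialization = 0) {
  if (siteSpecialization < 0 || siteSpecialization > 1)
    stop("siteSpecialization must lie in [0, 1]")
  stopifnot(is(protocol, "TaskProtocol"), is(subject, "SubjectParams"))
  if (missing(seed)) stop("simulateRecording() requires an explicit seed")
  if (length(sampleRate) != 1L || !is.finite(sampleRate) || sampleRate <= 0)
    stop("sampleRate must be a single positive number")
  if (separation < 0) stop("separation must be >= 0")
  validObject(protocol)
  set.seed(as.integer(seed))

  classes <- primitiveClasses()
  seqPer <- protocol@primitiveSequence
  moves <- expand.grid(target = seq_len(protocol@nTargets),
                       object = seq_along(protocol@objects),
                       trial = seq_len(protocol@nTrials))
  nSeg <- nrow(moves) * length(seqPer)
  segClass <- rep(seqPer, times = nrow(moves))
  segTheta <- rep(2 * pi * (moves$target - 1) / protocol@nTargets,
                  each = length(seqPer))

  # lognormal durations, per-subject speed scaled
  s2 <- log(1 + subject@durationCV^2)
  mu <- log(subject@durationMeanS) - s2 / 2
  dur <- rlnorm(nSeg, mu, sqrt(s2)) / subject@movementSpeedScale
  ni <- pmax(as.integer(round(dur * sampleRate)), 4L)
  total <- sum(ni)
  segEnd <- cumsum(ni)
  segStart <- c(0L, segEnd[-nSeg])

  # within-segment phase tau in (0, 1), sample-midpoint convention
  pos <- seq_len(total) - rep.int(segStart, ni)
  tau <- (pos - 0.5) / rep.int(ni, ni)

  codes <- .classCodes()
  ci <- match(segClass, classes)
  mj <- .minJerkAcc(tau)
  gp <- sin(2 * pi * tau)
  S <- separation * subject@signalGain
  hx <- S * accAmp * rep.int(codes["horizontal", ci] * cos(segTheta), ni) * mj
  hy <- S * accAmp * rep.int(codes["horizontal", ci] * sin(segTheta), ni) * mj
  vz <- S * accAmp * rep.int(codes["vertical", ci], ni) * mj
  gr <- S * gyroAmp * rep.int(codes["rotation", ci], ni) * gp

  # shared slow sway (two incommensurate sinusoids, random phases)
  tsec <- (seq_len(total) - 1) / sampleRate
  phi <- runif(2, 0, 2 * pi)
  sway <- swaySd / 0.825 *
    (sin(2 * pi * 0.31 * tsec + phi[1]) +
       0.6 * sin(2 * pi * 0.73 * tsec + phi[2]))

  loads <- .siteLoadings(subject@activeSide)
  jit <- subject@loadingJitter
  if (!all(dim(jit) == c(7L, 3L))) jit <- matrix(1, 7, 3)

  # dominant signal site per move (cyclic over the 7 signal sites),
  # shared by all primitives of the move
  moveIdx <- rep(seq_len(nrow(moves)), each = length(seqPer))
  segDominant <- (moveIdx - 1L) %% nrow(loads) + 1L
  domSamp <- rep.int(segDominant, ni)

  sites <- sensorSites()
  layout <- .imuChannelLayout()
  nChanPerSite <- nrow(layout)
  sig <- matrix(0, total, length(sites) * nChanPerSite)
  axisW <- c(x = 1, y = 0.4, z = 0.2)          # fixed rotation axis
  axisU <- axisW / sqrt(sum(axisW^2))
  swayAxis <- c(x = 1, y = 0.7, z = 0.5)
  dt <- 1 / sampleRate

  for (si in seq_along(sites)) {
    site <- sites[si]
    col0 <- (si - 1) * nChanPerSite
    li <- match(site, loads$site)
    if (!is.na(li)) {
      Lh <- loads$horizontal[li] * jit[li, 1]
      Lv <- loads$vertical[li] * jit[li, 2]
      Lg <- loads$rotation[li] * jit[li, 3]
      w <- if (siteSpecialization > 0)
        (1 - siteSpecialization) + siteSpecialization * (domSamp == li)
      else 1
      sw <- loads$sway[li] * sway
      sig[, col0 + 1] <- w * Lh * hx + swayAxis["x"] * sw
      sig[, col0 + 2] <- w * Lh * hy + swayAxis["y"] * sw
      sig[, col0 + 3] <- w * Lv * vz + swayAxis["z"] * sw
      omega <- w * Lg * gr                      # scalar angular speed
      sig[, col0 + 4] <- omega * axisU["x"]
      sig[, col0 + 5] <- omega * axisU["y"]
      sig[, col0 + 6] <- omega * axisU["z"]
      # fixed-axis orientation: integrate clean angular speed, closed form
      theta <- cumsum(omega) * dt
      sig[, col0 + 7] <- cos(theta / 2)
      sig[, col0 + 8] <- sin(theta / 2) * axisU["x"]
      sig[, col0 + 9] <- sin(theta / 2) * axisU["y"]
      sig[, col0 + 10] <- sin(theta / 2) * axisU["z"]
    } else {
      sig[, col0 + 7] <- 1                      # identity quaternion
    }
  }

  # sensor noise: full noiseSd on acc/gyr, reduced on the unit-scale
  # quaternion components, added after orientation integration
  if (subject@noiseSd > 0) {
    noise <- matrix(rnorm(total * ncol(sig), 0, subject@noiseSd),
                    total, ncol(sig))
    quatCols <- as.vector(outer(7:10, (seq_along(sites) - 1) * nChanPerSite,
                                "+"))
    noise[, quatCols] <- noise[, quatCols] * 0.2
    sig <- sig + noise
  }

  channelInfo <- data.frame(
    site = rep(sites, each = nChanPerSite),
    modality = rep(layout$modality, length(sites)),
    axis = rep(layout$axis, length(sites)),
    stringsAsFactors = FALSE
  )
  rec <- sensorRecording(sig, channelInfo, sampleRate, subject@subjectID)
  labels <- segmentLabels(data.frame(
    segment_id = seq_len(nSeg),
    start_s = segStart / sampleRate,
    end_s = segEnd / sampleRate,
    label = segClass,
    stringsAsFactors = FALSE
  ))
  list(recording = rec, labels = labels)
}

#' Generate a cohort of virtual subjects
#'
#' Draws per-subject parameters around the package defaults: lognormal
#' movement speed, signal gain and per-site loading jitter. The jitter
#' and gain create between-subject differences in signal-to-noise ratio
#' and movement style, which is what makes leave-one-subject-out
#' evaluation harder than stratified splitting.
#'
#' @param n Number of subjects (default 6).
#' @param seed Integer seed (required).
#' @param noiseSd Sensor noise standard deviation shared by all subjects.
#' @param speedSd,gainSd,loadingSd Lognormal sigma of the speed scale,
#'   signal gain and per-site loading jitter. Set all three to 0 for
#'   interchangeable subjects.
#' @param activeSide Active side for every subject (the reference cohort
#'   is all right-paretic).
#' @return List of [subjectParams()] objects.
#' @export
#' @examples
#' makeStudySubjects(2, seed = 1)
makeStudySubjects <- function(n = 6L, seed, noiseSd = 0.22, speedSd = 0.12,
                              gainSd = 0.15, loadingSd = 0.45,
                              activeSide = "right") {
  if (missing(seed)) stop("makeStudySubjects() requires an explicit seed")
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    subjectParams(
      subjectID = sprintf("s%d", i),
      movementSpeedScale = rlnorm(1, 0, speedSd),
      noiseSd = noiseSd,
      activeSide = activeSide,
      signalGain = rlnorm(1, 0, gainSd),
      loadingJitter = matrix(rlnorm(21, 0, loadingSd), 7, 3)
    )
  })
}

#' Simulate a multi-subject study
#'
#' Convenience wrapper generating one recording plus labels per subject
#' of a virtual cohort.
#'
#' @param nSubjects Number of subjects (ignored when `subjects` given).
#' @param protocol A [taskProtocol()] shared by all subjects.
#' @param seed Integer seed; subject parameters and recordings are
#'   derived from it deterministically.
#' @param subjects Optional list of [subjectParams()] overriding the
#'   generated cohort.
#' @param ... Passed to [simulateRecording()] (e.g. `sampleRate`,
#'   `separation`).
#' @return List with one element per subject, each a list
#'   `(recording, labels)`.
#' @export
simulateStudy <- function(nSubjects = 6L, protocol = taskProtocol(), seed,
                          subjects = NULL, ...) {
  if (missing(seed)) stop("simulateStudy() requires an explicit seed")
  if (is.null(subjects))
    subjects <- makeStudySubjects(nSubjects, seed = deriveStageSeed(seed, "subjects"))
  lapply(seq_along(subjects), function(i) {
    simulateRecording(protocol, subjects[[i]],
                      seed = deriveStageSeed(seed, paste0("recording", i)),
                      ...)
  })
}

#' Analytic class moments of the kinematic model
#'
#' Builds a [classMoments()] object directly from the generator's
#' kinematic code and site loadings, without simulating recordings:
#' acceleration features carry the vertical load code, angular-velocity
#' and orientation features the grasp-rotation code, each scaled by the
#' site loading and `amplitude`; all variances are 1 and class
#' proportions follow [defaultClassProportions()]. Sites outside the
#' active-arm/trunk/head set have identical moments across classes, i.e.
#' exactly seven sites carry class signal. Together with
#' [simulateFeaturePopulation()] this yields arbitrarily large feature
#' tables with an exactly known information structure, the reference
#' condition for sensor-subset searches.
#'
#' @param amplitude Class-mean separation per feature in units of the
#'   feature standard deviation (default 0.15).
#' @param activeSide Side whose arm sites carry signal.
#' @return A [classMoments()] object over the full 550-feature layout.
#' @export
kinematicClassMoments <- function(amplitude = 0.15, activeSide = "right") {
  codes <- .classCodes()
  loads <- .siteLoadings(activeSide)
  classes <- primitiveClasses()
  layout <- .imuChannelLayout()
  sites <- sensorSites()
  fi <- data.frame(
    site = rep(sites, each = nrow(layout) * 5L),
    modality = rep(rep(layout$modality, each = 5L), length(sites)),
    axis = rep(rep(layout$axis, each = 5L), length(sites)),
    stat = rep(.featureStats(), nrow(layout) * length(sites)),
    stringsAsFactors = FALSE
  )
  fn <- paste(fi$site, fi$modality, fi$axis, fi$stat, sep = ".")
  means <- matrix(0, length(classes), nrow(fi),
                  dimnames = list(classes, fn))
  li <- match(fi$site, loads$site)
  for (k in seq_along(classes)) {
    cl <- classes[k]
    m <- ifelse(fi$modality == "acc",
                loads$vertical[li] * codes["vertical", cl],
                ifelse(fi$modality == "gyr",
                       loads$rotation[li] * codes["rotation", cl],
                       0.5 * loads$rotation[li] * codes["rotation", cl]))
    m[is.na(li)] <- 0
    means[k, ] <- amplitude * m
  }
  classMoments(means, matrix(1, length(classes), nrow(fi),
                             dimnames = dimnames(means)),
               unname(defaultClassProportions()), classes)
}

#' Class moments of a feature table
#'
#' Computes per-class feature means and variances and class proportions
#' from a [WindowFeatureSet], for use with
#' [simulateFeaturePopulation()].
#'
#' @param features A `WindowFeatureSet`.
#' @return A [classMoments()] object.
#' @export
momentsFromFeatures <- function(features) {
  x <- featureMatrix(features)
  y <- as.character(windowLabels(features))
  classes <- .classLevels(y)
  means <- t(vapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                    numeric(ncol(x))))
  vars <- t(vapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    colMeans(xi^2) - colMeans(xi)^2
  }, numeric(ncol(x))))
  vars[vars < 0] <- 0
  props <- as.numeric(table(factor(y, classes))) / length(y)
  classMoments(means, vars, props, classes)
}

#' Simulate a moment-matched feature population
#'
#' Draws a large labeled feature table matching the class proportions,
#' means and variances of a reference dataset: class counts come from a
#' multinomial over `moments@proportions`, then each class's feature
#' vectors are sampled from independent Gaussians with that class's
#' means and variances. Intended for training/testing-time scaling
#' studies (e.g. a 300,000-primitive population), not for classification
#' performance assessment.
#'
#' @param moments A [classMoments()] object.
#' @param n Total number of rows to draw (>= 1).
#' @param seed Integer seed (required).
#' @return A [WindowFeatureSet] whose rows are simulated primitives.
#' @export
simulateFeaturePopulation <- function(moments, n, seed) {
  stopifnot(is(moments, "ClassMoments"))
  validObject(moments)
  if (n < 1) stop("n must be >= 1")
  if (missing(seed)) stop("simulateFeaturePopulation() requires an explicit seed")
  set.seed(as.integer(seed))
  counts <- as.integer(rmultinom(1, n, moments@proportions))
  p <- ncol(moments@means)
  x <- matrix(0, n, p)
  lab <- character(n)
  at <- 0L
  for (i in seq_along(moments@classes)) {
    if (counts[i] == 0L) next
    idx <- at + seq_len(counts[i])
    z <- matrix(rnorm(counts[i] * p), counts[i], p)
    z <- sweep(z, 2, sqrt(moments@vars[i, ]), "*")
    x[idx, ] <- sweep(z, 2, moments@means[i, ], "+")
    lab[idx] <- moments@classes[i]
    at <- at + counts[i]
  }
  fn <- colnames(moments@means)
  if (is.null(fn)) fn <- paste0("f", seq_len(p))
  parts <- strsplit(fn, ".", fixed = TRUE)
  fi <- if (all(lengths(parts) == 4L)) {
    data.frame(site = vapply(parts, `[`, "", 1),
               modality = vapply(parts, `[`, "", 2),
               axis = vapply(parts, `[`, "", 3),
               stat = vapply(parts, `[`, "", 4),
               stringsAsFactors = FALSE)
  } else {
    data.frame(site = fn, modality = "na", axis = "na", stat = "na",
               stringsAsFactors = FALSE)
  }
  colnames(x) <- fn
  windowFeatureSet(
    x,
    windowInfo = data.frame(subject_id = "population",
                            segment_id = seq_len(n),
                            window_label = lab,
                            window_start_s = 0,
                            stringsAsFactors = FALSE),
    featureInfo = fi
  )
}
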