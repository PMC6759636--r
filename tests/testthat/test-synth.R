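test_that("simulateRecording is a pure function of (protocol, subject, seed)", {
  proto <- taskProtocol(nTrials = 1L, nTargets = 2L)
  a <- simulateRecording(proto, subjectParams(), seed = 7, sampleRate = 60)
  b <- simulateRecording(proto, subjectParams(), seed = 7, sampleRate = 60)
  expect_identical(a$recording@signal, b$recording@signal)
  expect_identical(segmentTable(a$labels), segmentTable(b$labels))
  c <- simulateRecording(proto, subjectParams(), seed = 8, sampleRate = 60)
  expect_false(identical(a$recording@signal, c$recording@signal))
})

test_that("default recording carries 11 sites x 10 channels", {
  out <- simulateRecording(taskProtocol(nTrials = 1L, nTargets = 1L,
                                        objects = "roll"),
                           subjectParams(), seed = 1, sampleRate = 60)
  ci <- as.data.frame(out$recording@channelInfo)
  expect_equal(ncol(out$recording@signal), 110L)
  expect_equal(as.vector(table(ci$site)), rep(10L, 11))
  expect_setequal(unique(ci$site), sensorSites())
  expect_equal(sum(ci$modality == "quat"), 4L * 11L)
})

test_that("segments follow the prescribed primitive sequence", {
  proto <- taskProtocol(nTrials = 1L, nTargets = 1L, objects = "roll",
                        primitiveSequence = c("idle", "reach", "transport",
                                              "reposition"))
  out <- simulateRecording(proto, subjectParams(), seed = 3, sampleRate = 60)
  seg <- segmentTable(out$labels)
  expect_equal(nrow(seg), 4L)
  expect_equal(seg$label, c("idle", "reach", "transport", "reposition"))
})

test_that("segments tile the recording without gaps or overlap", {
  out <- simulateRecording(deskProtocol(), subjectParams(), seed = 2,
                           sampleRate = 60)
  seg <- segmentTable(out$labels)
  expect_equal(seg$start_s[1], 0)
  expect_equal(seg$start_s[-1], seg$end_s[-nrow(seg)])
  expect_equal(max(seg$end_s) * 60, nrow(out$recording@signal))
})

test_that("quaternions are unit-norm before noise injection", {
  sub <- subjectParams(noiseSd = 0)
  out <- simulateRecording(taskProtocol(nTrials = 1L, nTargets = 2L),
                           sub, seed = 4, sampleRate = 60)
  x <- out$recording@signal
  ci <- as.data.frame(out$recording@channelInfo)
  for (site in c("r_forearm", "l_hand", "sternum")) {
    q <- x[, ci$site == site & ci$modality == "quat", drop = FALSE]
    expect_true(all(abs(sqrt(rowSums(q^2)) - 1) < 1e-6))
  }
})

test_that("separation 0 with no noise or sway leaves a silent recording", {
  out <- simulateRecording(taskProtocol(nTrials = 1L, nTargets = 2L),
                           subjectParams(noiseSd = 0), seed = 5,
                           sampleRate = 60, separation = 0, swaySd = 0)
  ci <- as.data.frame(out$recording@channelInfo)
  nonQuat <- ci$modality != "quat"
  expect_true(all(out$recording@signal[, nonQuat] == 0))
})

test_that("invalid generator arguments are rejected", {
  expect_error(simulateRecording(deskProtocol(), subjectParams(),
                                 seed = 1, sampleRate = 0), "sampleRate")
  expect_error(simulateRecording(deskProtocol(), subjectParams(),
                                 seed = 1, separation = -1), "separation")
  expect_error(simulateRecording(deskProtocol(), subjectParams()), "seed")
  expect_error(taskProtocol(nTrials = 0), "nTrials")
  expect_error(subjectParams(activeSide = "both"), "activeSide")
})

test_that("adjacent-site channels are correlated at default settings", {
  out <- simulateRecording(deskProtocol(), subjectParams(), seed = 6,
                           sampleRate = 60)
  x <- out$recording@signal
  expect_gt(cor(x[, "sternum.acc.x"], x[, "pelvis.acc.x"]), 0.3)
  expect_gt(cor(x[, "r_forearm.acc.x"], x[, "r_hand.acc.x"]), 0.3)
})

test_that("class proportions match the reference dataset composition", {
  p <- defaultClassProportions()
  expect_equal(sum(p), 1.0)
  expect_equal(names(p), primitiveClasses())
  expect_equal(unname(p["reach"]), 810 / 2881)
  expect_equal(unname(p["idle"]), 582 / 2881)
})

test_that("feature population matches multinomial counts and class moments", {
  m <- classMoments(means = rbind(reach = c(0, 2, 1), transport = c(1, 0, -1),
                                  reposition = c(-1, 1, 0), idle = c(0, 0, 0)),
                    vars = matrix(c(rep(1, 9), rep(0.25, 3)), 4, 3,
                                  byrow = TRUE),
                    proportions = unname(defaultClassProportions()),
                    classes = primitiveClasses())
  n <- 300000L
  pop <- simulateFeaturePopulation(m, n, seed = 9)
  counts <- table(factor(windowInfo(pop)$window_label, primitiveClasses()))
  p <- defaultClassProportions()
  expect_true(all(abs(counts - n * p) <= 3 * sqrt(n * p * (1 - p))))

  pop2 <- simulateFeaturePopulation(m, 10000L, seed = 10)
  x <- featureMatrix(pop2)
  lab <- windowInfo(pop2)$window_label
  for (k in seq_len(4)) {
    cl <- primitiveClasses()[k]
    xi <- x[lab == cl, , drop = FALSE]
    bound <- 4 * sqrt(m@vars[k, ]) / sqrt(nrow(xi))
    expect_true(all(abs(colMeans(xi) - m@means[k, ]) <=
                      pmax(bound, 1e-12)))
  }
})

test_that("zero-variance features are constant at their class mean", {
  m <- classMoments(means = rbind(reach = c(3, 1), idle = c(-2, 0)),
                    vars = rbind(reach = c(0, 1), idle = c(0, 1)),
                    proportions = c(0.5, 0.5), classes = c("reach", "idle"))
  pop <- simulateFeaturePopulation(m, 200, seed = 1)
  x <- featureMatrix(pop)
  lab <- windowInfo(pop)$window_label
  expect_true(all(x[lab == "reach", 1] == 3))
  expect_true(all(x[lab == "idle", 1] == -2))
})

test_that("invalid class moments are rejected", {
  expect_error(classMoments(means = rbind(a = 1, b = 2),
                            vars = rbind(a = -1, b = 1),
                            proportions = c(0.5, 0.5)),
               "variances")
  expect_error(classMoments(means = rbind(a = 1, b = 2),
                            vars = rbind(a = 1, b = 1),
                            proportions = c(0.6, 0.6)),
               "sum to 1")
})

test_that("study cohort generation is reproducible and sized", {
  s1 <- makeStudySubjects(6, seed = 42)
  s2 <- makeStudySubjects(6, seed = 42)
  expect_length(s1, 6L)
  expect_identical(vapply(s1, function(s) s@signalGain, 1),
                   vapply(s2, function(s) s@signalGain, 1))
  expect_equal(vapply(s1, function(s) s@subjectID, ""),
               paste0("s", 1:6))
})

test_that("analytic class moments put signal on exactly seven sites", {
  m <- kinematicClassMoments()
  fi <- do.call(rbind, strsplit(colnames(m@means), ".", fixed = TRUE))
  spread <- apply(m@means, 2, function(v) max(v) - min(v))
  sigSites <- sort(unique(fi[spread > 0, 1]))
  expect_equal(sigSites,
               sort(c("head", "sternum", "pelvis", "r_scap", "r_arm",
                      "r_forearm", "r_hand")))
  noise <- fi[, 1] %in% c("l_scap", "l_arm", "l_forearm", "l_hand")
  expect_true(all(m@means[, noise] == 0))
})
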