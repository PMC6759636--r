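test_that("z-score normalization uses population statistics", {
  rec <- oneChannelRecording(c(2, 4, 6))
  out <- zscoreNormalize(rec)
  expect_equal(as.vector(out$recording@signal),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(out$stats$mean, 4)
  expect_equal(out$stats$sd, sqrt(8 / 3))
})

test_that("z-score normalization is idempotent on standardized input", {
  rec <- oneChannelRecording(rnorm(50))
  once <- zscoreNormalize(rec)$recording
  twice <- zscoreNormalize(once)$recording
  expect_equal(once@signal, twice@signal, tolerance = 1e-9)
})

test_that("constant channels pass through as zeros with a warning", {
  rec <- oneChannelRecording(c(5, 5, 5))
  expect_warning(out <- zscoreNormalize(rec), "near-zero sd")
  expect_equal(as.vector(out$recording@signal), c(0, 0, 0))
})

test_that("supplied normalization statistics are applied and reproducible", {
  tr <- oneChannelRecording(c(1, 3, 5))
  te <- oneChannelRecording(c(2, 4))
  st <- zscoreNormalize(tr)$stats
  a <- zscoreNormalize(te, st)
  b <- zscoreNormalize(te, st)
  expect_identical(a$recording@signal, b$recording@signal)
  expect_equal(as.vector(a$recording@signal),
               (c(2, 4) - st$mean) / st$sd)
  bad <- st; bad$channel <- "other.acc.x"
  expect_error(zscoreNormalize(te, bad), "channel sets")
})

test_that("window counts follow floor((T - width) / stride) + 1", {
  rate <- 60
  set.seed(11)
  for (i in 1:25) {
    widthN <- sample(3:30, 1)
    strideN <- sample(seq_len(widthN), 1)
    totalN <- widthN + sample(0:300, 1)
    rec <- oneChannelRecording(rnorm(totalN), rate = rate)
    labels <- segmentLabels(data.frame(segment_id = 1L, start_s = 0,
                                       end_s = totalN / rate,
                                       label = "reach"))
    win <- segmentWindows(rec, labels,
                          windowSpec(widthN / rate, strideN / rate))
    expect_equal(nrow(win), (totalN - widthN) %/% strideN + 1L)
  }
})

test_that("1 s at 240 Hz with 0.25/0.1 windows yields 8 windows", {
  rec <- oneChannelRecording(rnorm(240), rate = 240)
  labels <- segmentLabels(data.frame(segment_id = 1L, start_s = 0,
                                     end_s = 1, label = "idle"))
  expect_equal(nrow(segmentWindows(rec, labels, windowSpec())), 8L)
})

test_that("windows take the majority segment's label, ties to the earlier", {
  rec <- oneChannelRecording(rnorm(10), rate = 10)
  spec <- windowSpec(widthS = 1.0, strideS = 1.0)
  maj <- segmentLabels(data.frame(segment_id = 1:2, start_s = c(0, 0.6),
                                  end_s = c(0.6, 1.0),
                                  label = c("reach", "transport")))
  expect_equal(segmentWindows(rec, maj, spec)$label, "reach")
  tie <- segmentLabels(data.frame(segment_id = 1:2, start_s = c(0, 0.5),
                                  end_s = c(0.5, 1.0),
                                  label = c("reach", "transport")))
  expect_equal(segmentWindows(rec, tie, spec)$label, "reach")
  uni <- segmentLabels(data.frame(segment_id = 1L, start_s = 0, end_s = 1,
                                  label = "reposition"))
  expect_equal(segmentWindows(rec, uni, spec)$label, "reposition")
})

test_that("a recording shorter than one window warns and yields nothing", {
  rec <- oneChannelRecording(rnorm(5), rate = 60)
  labels <- segmentLabels(data.frame(segment_id = 1L, start_s = 0,
                                     end_s = 5 / 60, label = "idle"))
  expect_warning(win <- segmentWindows(rec, labels, windowSpec()),
                 "shorter than one window")
  expect_equal(nrow(win), 0L)
})

test_that("the five statistical features are computed per channel", {
  f <- extractFeatures(cbind(a = c(1, 1, 1, 1)))
  expect_equal(unname(f), c(1, 0, 1, 1, 1))
  f <- extractFeatures(cbind(a = c(3, -3)))
  expect_equal(unname(f), c(0, 3, -3, 3, 3))
  f <- extractFeatures(cbind(a = c(1, 2, 3)))
  expect_equal(unname(f["a.rms"]), sqrt(14 / 3))
  two <- extractFeatures(cbind(a = c(1, 2), b = c(0, 4)))
  expect_length(two, 10L)
  expect_equal(names(two)[1:5],
               paste0("a.", c("mean", "sd", "min", "max", "rms")))
  expect_error(extractFeatures(cbind(c(1, NA))), "non-finite")
  expect_error(extractFeatures(matrix(numeric(0), 0, 1)), "non-empty")
})

test_that("windowFeatures agrees with extractFeatures on each window", {
  out <- simulateRecording(taskProtocol(1L, 1L, objects = "roll"),
                           subjectParams(), seed = 2, sampleRate = 60)
  wfs <- windowFeatures(out$recording, out$labels)
  win <- segmentWindows(out$recording, out$labels)
  x <- out$recording@signal
  for (w in c(1L, nrow(win))) {
    rows <- win$start_index[w]:(win$start_index[w] + win$n_samples[w] - 1L)
    expect_equal(unname(featureMatrix(wfs)[w, ]),
                 unname(extractFeatures(x[rows, , drop = FALSE])))
  }
  expect_equal(nrow(wfs), 550L)
})

test_that("featurization is permutation-equivariant in channels", {
  out <- simulateRecording(taskProtocol(1L, 1L, objects = "roll"),
                           subjectParams(), seed = 3, sampleRate = 60)
  rec <- out$recording
  perm <- sample(ncol(rec@signal))
  rec2 <- sensorRecording(rec@signal[, perm],
                          as.data.frame(rec@channelInfo)[perm, ],
                          rec@sampleRate, rec@subjectID)
  f1 <- featureMatrix(windowFeatures(rec, out$labels))
  f2 <- featureMatrix(windowFeatures(rec2, out$labels))
  expect_identical(f1[, colnames(f2)], f2)
})

test_that("channel selection yields the documented feature counts", {
  tab <- fullLayoutTable()
  expect_equal(nrow(tab), 550L)
  seven <- c("head", "sternum", "pelvis", "r_scap", "r_arm", "r_forearm",
             "r_hand")
  imu7 <- selectChannels(tab, sensorConfig(seven, "imu"))
  acc7 <- selectChannels(tab, sensorConfig(seven, "accelerometer"))
  expect_equal(nrow(imu7), 350L)
  expect_equal(nrow(acc7), 105L)
  full <- selectChannels(tab, sensorConfig(sensorSites(), "imu"))
  expect_equal(rownames(full), rownames(tab))
})

test_that("channel selection is idempotent and acc is a subset of imu", {
  tab <- fullLayoutTable()
  cfg <- sensorConfig(c("r_hand", "sternum"), "accelerometer")
  once <- selectChannels(tab, cfg)
  twice <- selectChannels(once, cfg)
  expect_identical(featureMatrix(once), featureMatrix(twice))
  imu <- selectChannels(tab, sensorConfig(c("r_hand", "sternum"), "imu"))
  expect_true(all(rownames(once) %in% rownames(imu)))
})

test_that("unknown sites are rejected with the valid site list", {
  tab <- fullLayoutTable()
  expect_error(selectChannels(tab, sensorConfig("wrist")),
               "unknown site.*valid sites")
})
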