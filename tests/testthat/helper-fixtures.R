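# Fixture builders shared across test files. Everything is generated in
# code; heavier shared datasets are cached per session.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- force(expr)
  .fixtureCache[[key]]
}

# random small classification instance (n <= 50, p <= 5, 2-4 classes)
randomInstance <- function(seed) {
  set.seed(seed)
  n <- sample(10:50, 1)
  p <- sample(2:5, 1)
  k <- sample(2:4, 1)
  classes <- letters[seq_len(k)]
  y <- character(0)
  while (length(unique(y)) < k) y <- sample(classes, n, replace = TRUE)
  mu <- matrix(rnorm(k * p, sd = 2), k, p)
  x <- mu[match(y, classes), , drop = FALSE] + matrix(rnorm(n * p), n, p)
  xte <- matrix(rnorm(20 * p, sd = 2), 20, p)
  list(x = x, y = y, xte = xte)
}

# single-channel recording for normalization / windowing tests
oneChannelRecording <- function(values, rate = 1, site = "s1") {
  sensorRecording(matrix(as.numeric(values), ncol = 1),
                  data.frame(site = site, modality = "acc", axis = "x"),
                  sampleRate = rate, subjectID = "t")
}

# small labeled Gaussian feature table: nSegPerClass segments per class,
# winPerSeg windows each, p features, class means sep apart on the first
# feature block
toyFeatureTable <- function(nSegPerClass = 8, winPerSeg = 3, p = 6,
                            classes = primitiveClasses(), sep = 4,
                            nSubjects = 2, seed = 1) {
  set.seed(seed)
  nSeg <- nSegPerClass * length(classes)
  segClass <- rep(classes, each = nSegPerClass)
  mu <- matrix(rnorm(length(classes) * p), length(classes), p) * sep / 2
  rows <- nSeg * winPerSeg
  segOf <- rep(seq_len(nSeg), each = winPerSeg)
  x <- mu[match(segClass[segOf], classes), , drop = FALSE] +
    matrix(rnorm(rows * p), rows, p)
  fi <- data.frame(site = rep(paste0("s", seq_len(ceiling(p / 2))),
                              each = 2)[seq_len(p)],
                   modality = "acc",
                   axis = rep(c("x", "y"), length.out = p),
                   stat = rep(c("mean", "sd"), length.out = p))
  # make (site, modality, axis, stat) unique per feature
  fi$stat <- paste0(fi$stat, seq_len(p))
  wi <- data.frame(subject_id = paste0("s", (segOf - 1) %% nSubjects + 1),
                   segment_id = segOf,
                   window_label = segClass[segOf],
                   window_start_s = (seq_len(rows) - 1) * 0.1)
  windowFeatureSet(x, wi, fi)
}

# desk-scale simulated study features (shared across tests)
deskFeatures <- function(nSubjects = 2, seed = 1) {
  cached(paste0("desk", nSubjects, "_", seed), {
    studyFeatures(simulateStudy(nSubjects, deskProtocol(), seed = seed,
                                sampleRate = 60))
  })
}

# tiny full-layout (11 sites x 10 channels x 5 stats) feature table
fullLayoutTable <- function(n = 40, seed = 1) {
  cached(paste0("layout", n, "_", seed), {
    simulateFeaturePopulation(kinematicClassMoments(), n, seed = seed)
  })
}
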