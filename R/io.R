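# Readers and writers for all on-disk artifacts (versioned CSV with a
# small comment header), the run configuration, seed derivation, and the
# end-to-end pipeline driver.

.artifactVersion <- "1.0"

.writeHeader <- function(path, kind, meta = character(0)) {
  lines <- c(sprintf("# primsense %s v%s", kind, .artifactVersion),
             sprintf("# %s", meta))
  writeLines(lines, path)
  length(lines)
}

.readHeader <- function(path, kind) {
  lines <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1)
    if (!length(l) || !startsWith(l, "#")) break
    lines <- c(lines, l)
  }
  if (!length(lines))
    stop("parse error in ", path, " (line 1): missing '# primsense ",
         kind, "' header")
  m <- regmatches(lines[1],
                  regexec("^# primsense ([a-z]+) v([0-9]+)\\.([0-9]+)", lines[1]))[[1]]
  if (length(m) < 4L || m[2] != kind)
    stop("parse error in ", path, " (line 1): not a primsense ", kind,
         " file")
  if (as.integer(m[3]) > 1L)
    stop("unsupported ", kind, " major version ", m[3], " in ", path)
  meta <- sub("^# ", "", lines[-1])
  kv <- strsplit(meta[grepl("=", meta)], "=", fixed = TRUE)
  vals <- vapply(kv, `[`, "", 2)
  names(vals) <- vapply(kv, `[`, "", 1)
  list(nLines = length(lines), meta = vals)
}

.freadBody <- function(path, skip) {
  tryCatch(
    withCallingHandlers(
      as.data.frame(data.table::fread(path, skip = skip, header = TRUE,
                                      fill = FALSE)),
      warning = function(w) {
        # fread's session-cleanup notice is not a property of this file
        if (grepl("cleaned up", conditionMessage(w)))
          invokeRestart("muffleWarning")
        else
          stop("parse error in ", path, ": ", conditionMessage(w),
               call. = FALSE)
      }),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
}

#' Read and write recordings
#'
#' Recordings are stored as wide CSV: a version header, column `time_s`,
#' then one column per channel named `<site>.<modality>.<axis>`
#' (e.g. `r_forearm.gyr.x`). The round trip is lossless for values
#' (within float text precision), channel names, sample rate and subject
#' id. Reading fails with a parse error on a missing `time_s` column, a
#' non-monotonic time column or ragged rows.
#'
#' @param rec A [SensorRecording].
#' @param path File path.
#' @return `readRecording()` a [SensorRecording];
#'   `writeRecording()` the path, invisibly.
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "SensorRecording"))
  .writeHeader(path, "recording",
               c(paste0("sample_rate=", format(rec@sampleRate, digits = 15)),
                 paste0("subject_id=", rec@subjectID)))
  df <- data.frame(time_s = (seq_len(nrow(rec@signal)) - 1) / rec@sampleRate,
                   rec@signal, check.names = FALSE)
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  hdr <- .readHeader(path, "recording")
  body <- .freadBody(path, hdr$nLines)
  if (colnames(body)[1] != "time_s")
    stop("parse error in ", path, " (line ", hdr$nLines + 1,
         "): first column must be 'time_s'")
  tm <- body$time_s
  if (length(tm) > 1 && any(diff(tm) <= 0))
    stop("parse error in ", path, " (line ",
         hdr$nLines + 1 + which(diff(tm) <= 0)[1],
         "): time column must be strictly increasing")
  ch <- colnames(body)[-1]
  parts <- strsplit(ch, ".", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("parse error in ", path, ": channel names must be ",
         "'<site>.<modality>.<axis>', got e.g. '",
         ch[which(lengths(parts) != 3L)[1]], "'")
  ci <- data.frame(site = vapply(parts, `[`, "", 1),
                   modality = vapply(parts, `[`, "", 2),
                   axis = vapply(parts, `[`, "", 3),
                   stringsAsFactors = FALSE)
  sensorRecording(as.matrix(body[, -1, drop = FALSE]), ci,
                  sampleRate = as.numeric(hdr$meta[["sample_rate"]]),
                  subjectID = hdr$meta[["subject_id"]])
}

#' Read and write segment labels
#'
#' Segment labels are stored as CSV with a version header and columns
#' `segment_id`, `start_s`, `end_s`, `label`.
#'
#' @param labels A [segmentLabels()] object.
#' @param path File path.
#' @return `readSegmentLabels()` a `SegmentLabels`;
#'   `writeSegmentLabels()` the path, invisibly.
#' @export
writeSegmentLabels <- function(labels, path) {
  stopifnot(is(labels, "SegmentLabels"))
  .writeHeader(path, "segments")
  data.table::fwrite(labels@segments, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeSegmentLabels
#' @export
readSegmentLabels <- function(path) {
  hdr <- .readHeader(path, "segments")
  segmentLabels(.freadBody(path, hdr$nLines))
}

#' Read and write feature tables
#'
#' Feature tables are stored as CSV with a version header, the four
#' metadata columns first (`subject_id`, `segment_id`, `window_label`,
#' `window_start_s`), then the feature columns in deterministic
#' site-major order.
#'
#' @param features A [WindowFeatureSet].
#' @param path File path.
#' @return `readFeatureTable()` a `WindowFeatureSet`;
#'   `writeFeatureTable()` the path, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  stopifnot(is(features, "WindowFeatureSet"))
  .writeHeader(path, "features")
  df <- cbind(windowInfo(features),
              as.data.frame(featureMatrix(features), check.names = FALSE))
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  hdr <- .readHeader(path, "features")
  body <- .freadBody(path, hdr$nLines)
  metaCols <- c("subject_id", "segment_id", "window_label", "window_start_s")
  if (!all(metaCols %in% colnames(body)))
    stop("parse error in ", path, ": missing metadata column(s) ",
         paste(setdiff(metaCols, colnames(body)), collapse = ", "))
  featCols <- setdiff(colnames(body), metaCols)
  parts <- strsplit(featCols, ".", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop("parse error in ", path, ": feature columns must be ",
         "'<site>.<modality>.<axis>.<stat>'")
  fi <- data.frame(site = vapply(parts, `[`, "", 1),
                   modality = vapply(parts, `[`, "", 2),
                   axis = vapply(parts, `[`, "", 3),
                   stat = vapply(parts, `[`, "", 4),
                   stringsAsFactors = FALSE)
  windowFeatureSet(as.matrix(body[, featCols, drop = FALSE]),
                   body[, metaCols], fi)
}

#' Save / load a classifier
#'
#' Thin file wrappers around [modelToJSON()] and [modelFromJSON()].
#'
#' @param model A fitted classifier.
#' @param path File path (JSON).
#' @return `loadClassifier()` the restored model; `saveClassifier()` the
#'   path, invisibly.
#' @export
saveClassifier <- function(model, path) {
  writeLines(modelToJSON(model), path)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
  modelFromJSON(paste(readLines(path), collapse = "\n"))
}

#' Derive a stage seed from the global seed
#'
#' Deterministically maps `(seed, stage name)` to a 31-bit integer seed
#' via a polynomial rolling hash, so that every pipeline stage is
#' independently reproducible from one global seed.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' deriveStageSeed(1, "subjects")
deriveStageSeed <- function(seed, stage) {
  if (missing(seed) || is.na(seed)) stop("an explicit seed is required")
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 10007) %% 2147483647)
}

# ---------------------------------------------------------------------------
# run configuration
# ---------------------------------------------------------------------------

.configDefaults <- function() {
  list(
    seed = NULL,                      # required, no silent default
    n_subjects = 6L,
    sample_rate = 240,
    separation = 1,
    noise_sd = 0.22,
    protocol = list(n_trials = 5L, n_targets = 8L, target_distance = 20,
                    objects = c("roll", "can"),
                    primitive_sequence = c("idle", "reach", "transport",
                                           "reposition")),
    window = list(width_s = 0.25, stride_s = 0.1),
    algorithms = c("lda", "nbc", "svm", "knn"),
    split = list(scheme = "stratified", train_fraction = 0.6,
                 n_repeats = 10L),
    search = list(enabled = FALSE, sensor_type = "imu", n_repeats = 3L),
    output_dir = ".",
    log_level = "info"
  )
}

.mergeConfig <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      .mergeConfig(defaults[[k]], user[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

#' Read a pipeline run configuration
#'
#' Loads a YAML configuration, validates it against the known schema
#' (unknown keys are rejected), fills defaults, and requires an explicit
#' `seed` — a missing seed is an error, never a silent default.
#'
#' @param path Path to a YAML file, or a named list with the same
#'   structure.
#' @return Validated configuration list with all defaults resolved.
#' @export
readRunConfig <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(user)) user <- list()
  cfg <- .mergeConfig(.configDefaults(), user)
  if (is.null(cfg$seed)) stop("configuration must set an explicit seed")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.logLevelNum <- c(debug = 0, info = 1, warning = 2, error = 3)

.log <- function(cfg, level, ...) {
  if (.logLevelNum[[level]] >= .logLevelNum[[cfg$log_level %||% "info"]])
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Chains the stages simulate -> featurize -> evaluate (-> search) from a
#' validated configuration, writing every artifact under the output
#' directory: per-subject recordings and labels, the combined feature
#' table, a PPV table mirroring the algorithms x primitives layout,
#' per-algorithm row-percent confusion matrices, a JSON report holding
#' the resolved configuration, and optionally the sensor-search entries
#' and best-per-count summary. All randomness derives from the single
#' configured seed via [deriveStageSeed()], so two runs with the same
#' configuration produce byte-identical outputs.
#'
#' @param config Configuration list or YAML path (see
#'   [readRunConfig()]).
#' @param outDir Output directory (default: `output_dir` from the
#'   configuration).
#' @return Invisibly, a list with the evaluation reports, file paths,
#'   and (if enabled) the search result.
#' @export
runPipeline <- function(config, outDir = NULL) {
  cfg <- readRunConfig(config)
  if (is.null(outDir)) outDir <- cfg$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  .log(cfg, "info", "resolved config: ",
       jsonlite::toJSON(cfg, auto_unbox = TRUE))

  proto <- taskProtocol(cfg$protocol$n_trials, cfg$protocol$n_targets,
                        cfg$protocol$target_distance, cfg$protocol$objects,
                        cfg$protocol$primitive_sequence)
  subjects <- makeStudySubjects(cfg$n_subjects,
                                seed = deriveStageSeed(cfg$seed, "subjects"),
                                noiseSd = cfg$noise_sd)
  .log(cfg, "info", "simulating ", cfg$n_subjects, " subjects at ",
       cfg$sample_rate, " Hz (seed ", cfg$seed, ")")
  study <- simulateStudy(protocol = proto, seed = cfg$seed,
                         subjects = subjects,
                         sampleRate = cfg$sample_rate,
                         separation = cfg$separation)
  paths <- list()
  for (i in seq_along(study)) {
    id <- study[[i]]$recording@subjectID
    paths[[paste0("recording_", id)]] <-
      writeRecording(study[[i]]$recording,
                     file.path(outDir, paste0("recording_", id, ".csv")))
    paths[[paste0("labels_", id)]] <-
      writeSegmentLabels(study[[i]]$labels,
                         file.path(outDir, paste0("labels_", id, ".csv")))
  }

  .log(cfg, "info", "featurizing (window ", cfg$window$width_s, " s / ",
       cfg$window$stride_s, " s)")
  feats <- studyFeatures(study, windowSpec(cfg$window$width_s,
                                           cfg$window$stride_s))
  paths$features <- writeFeatureTable(feats, file.path(outDir, "features.csv"))

  plan <- splitPlan(cfg$split$scheme, cfg$split$train_fraction,
                    cfg$split$n_repeats,
                    seed = deriveStageSeed(cfg$seed, "splits"))
  .log(cfg, "info", "evaluating: ", paste(cfg$algorithms, collapse = ", "))
  reports <- evaluatePrimitives(feats, cfg$algorithms, plan)
  tab <- ppvTable(reports)
  paths$ppv_table <- file.path(outDir, "ppv_table.csv")
  data.table::fwrite(tab, paths$ppv_table)
  for (a in names(reports)) {
    paths[[paste0("confusion_", a)]] <- file.path(
      outDir, paste0("confusion_", a, ".csv"))
    cm <- as.data.frame(rowPercent(pooledConfusion(reports[[a]])))
    data.table::fwrite(cbind(truth = rownames(cm), cm),
                       paths[[paste0("confusion_", a)]])
  }
  report <- list(
    schema = list(kind = "primsense report", version = .artifactVersion),
    config = cfg,
    ppv = tab,
    auc = lapply(reports, function(r)
      lapply(rocResults(r), function(x) x$auc))
  )

  searchRes <- NULL
  if (isTRUE(cfg$search$enabled)) {
    .log(cfg, "info", "exhaustive sensor search (",
         cfg$search$n_repeats, " repeats)")
    splan <- splitPlan("stratified", cfg$split$train_fraction,
                       cfg$search$n_repeats,
                       seed = deriveStageSeed(cfg$seed, "search"))
    searchRes <- exhaustiveSearch(feats, plan = splan,
                                  sensorType = cfg$search$sensor_type)
    paths$search <- file.path(outDir, "search.csv")
    data.table::fwrite(searchRes@entries, paths$search)
    report$best_per_count <- bestPerCount(searchRes)
  }
  paths$report <- file.path(outDir, "report.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  .log(cfg, "info", "pipeline complete: ", length(paths), " artifacts in ",
       outDir)
  invisible(list(reports = reports, search = searchRes, paths = paths,
                 config = cfg))
}
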