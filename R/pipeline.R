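.configDefaults <- function() {
  list(
    mode = "diagnose",
    seed = 1L,
    optimizer = list(populationSize = 12L, maxIterations = 15L,
                     cMax = 1, cMin = 0.01, attractionIntensity = 0.5,
                     attractionLengthScale = 1.5, useChaos = TRUE,
                     useQobl = TRUE),
    elm = list(hiddenCount = 20L, activation = "sigmoid", weightRange = 1),
    features = list(filterSeed = 1L, imageSize = 227L),
    benchmark = list(functions = c("F1", "F2", "F3", "F4", "F5"),
                     optimizers = c("goa", "agoa"), dimension = 30L,
                     nRuns = 35L, populationSize = 50L,
                     maxIterations = 100L),
    synth = list(nImages = 200L, tumorFraction = 0.5,
                 blobRadiusRange = c(12, 30), blobIntensityLift = 0.35,
                 noiseSd = 0.05),
    data = list(manifest = NULL, featuresCsv = NULL, imageDir = NULL,
                outputDir = NULL),
    trainFraction = 0.8)
}

.mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", path, "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste(path, unknown, sep = ".")),
                collapse = ", "))
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]],
                                      paste(path, key, sep = "."))
    } else {
      # single-bracket assignment keeps explicit NULL values in place
      defaults[key] <- list(user[[key]])
    }
  }
  defaults
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML experiment configuration, fills every unset key with its
#' documented default, and rejects unknown keys by name. An empty file
#' yields the all-defaults configuration.
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return A validated configuration list (class
#'   \code{"agoaelmConfig"}).
#' @export
loadExperimentConfig <- function(path = NULL) {
  user <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
  }
  cfg <- .mergeConfig(.configDefaults(), user)
  if (!cfg$mode %in% c("bench", "diagnose", "synth"))
    stop("mode must be one of: bench, diagnose, synth")
  if (cfg$trainFraction <= 0 || cfg$trainFraction >= 1)
    stop("trainFraction must lie strictly inside (0, 1)")
  structure(cfg, class = "agoaelmConfig")
}

#' Write a resolved configuration back to YAML
#'
#' @param config a configuration list from
#'   \code{\link{loadExperimentConfig}}.
#' @param path output YAML path.
#' @return The path, invisibly.
#' @export
writeExperimentConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.controlFromConfig <- function(cfg, seed, variant = NULL) {
  opt <- cfg$optimizer
  useChaos <- opt$useChaos
  useQobl <- opt$useQobl
  if (!is.null(variant)) {
    useChaos <- useQobl <- identical(variant, "agoa")
  }
  goaControl(populationSize = opt$populationSize,
             maxIterations = opt$maxIterations,
             cMax = opt$cMax, cMin = opt$cMin,
             attractionIntensity = opt$attractionIntensity,
             attractionLengthScale = opt$attractionLengthScale,
             useChaos = useChaos, useQobl = useQobl, seed = seed)
}

#' Benchmark validation experiment
#'
#' Runs the requested optimizer variants over the built-in benchmark
#' functions with the repeated-trial protocol and tabulates AVE/STD per
#' (function, optimizer). With an output directory, writes the comparison
#' table CSV, one convergence CSV for the first run of each pair, and the
#' seed bookkeeping needed to rerun bit-identically.
#'
#' @param functions benchmark names (default all five).
#' @param optimizers subset of \code{c("goa", "agoa")}.
#' @param dimension problem dimension (default 30).
#' @param nRuns repeated runs per pair (default 35, the study protocol).
#' @param populationSize,maxIterations swarm size and iteration budget
#'   (defaults 50 and 100, the study protocol).
#' @param seedBase first seed; run r uses \code{seedBase + r - 1}.
#' @param outputDir optional directory for CSV artifacts.
#' @return The comparison \code{data.frame} from
#'   \code{\link{summarizeTrials}}, with the per-run bests attached as
#'   attribute \code{"summaries"}.
#' @export
runBenchmarkValidation <- function(functions = benchmarkNames(),
                                   optimizers = c("goa", "agoa"),
                                   dimension = 30, nRuns = 35,
                                   populationSize = 50, maxIterations = 100,
                                   seedBase = 1L, outputDir = NULL) {
  optimizers <- match.arg(optimizers, c("goa", "agoa"), several.ok = TRUE)
  summaries <- list()
  for (fn in functions) {
    for (opt in optimizers) {
      ctl <- goaControl(populationSize = populationSize,
                        maxIterations = maxIterations,
                        useChaos = opt == "agoa", useQobl = opt == "agoa",
                        seed = seedBase)
      summaries[[paste(fn, opt, sep = ":")]] <-
        runTrials(fn, ctl, nRuns = nRuns, dimension = dimension,
                  seedBase = seedBase)
    }
  }
  tab <- summarizeTrials(summaries)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(outputDir, "benchmark_table.csv"),
                     row.names = FALSE)
    for (key in names(summaries)) {
      s <- summaries[[key]]
      utils::write.csv(
        data.frame(run = seq_len(s@nRuns), seed = seedBase + seq_len(s@nRuns) - 1L,
                   best_fitness = s@perRunBests),
        file.path(outputDir, paste0("runs_", gsub(":", "_", key), ".csv")),
        row.names = FALSE)
    }
    yaml::write_yaml(list(functions = functions, optimizers = optimizers,
                          dimension = dimension, nRuns = nRuns,
                          populationSize = populationSize,
                          maxIterations = maxIterations,
                          seedBase = as.integer(seedBase)),
                     file.path(outputDir, "protocol.yaml"))
  }
  attr(tab, "summaries") <- summaries
  tab
}

#' End-to-end synthetic diagnosis experiment
#'
#' The full classification pipeline on a labeled image set: preprocess
#' and extract convolutional features, split 80/20 stratified by label,
#' tune the ELM hidden layer with the amended grasshopper optimizer on
#' the training split, and report the test-set confusion metrics. A
#' plain random-weight ELM trained on the same split and seed is fitted
#' alongside as the baseline comparison. When no image manifest is
#' supplied, a synthetic image set is generated first from the
#' \code{synth} settings.
#'
#' @param config a configuration list from
#'   \code{\link{loadExperimentConfig}} (or \code{NULL} for defaults).
#' @param manifest optional manifest data.frame or CSV path (columns
#'   \code{filepath}, \code{label}); overrides \code{config$data$manifest}.
#' @param imageDir directory for resolving manifest paths, and where
#'   synthetic images are generated when no manifest exists.
#' @param outputDir optional directory; when set, the resolved config,
#'   the tuned model (JSON), test predictions CSV, and metric reports
#'   (JSON + CSV) are written there.
#' @param compareRandomElm logical; also fit the plain random-(W, b) ELM
#'   baseline on the identical split (default TRUE).
#' @return A list with \code{model}, \code{result}
#'   (\linkS4class{GoaResult}), \code{report} (test metrics),
#'   \code{baselineReport} (random ELM metrics or NULL),
#'   \code{predictions} (data.frame), and \code{split}.
#' @export
runDiagnosisExperiment <- function(config = NULL, manifest = NULL,
                                   imageDir = NULL, outputDir = NULL,
                                   compareRandomElm = TRUE) {
  if (is.null(config)) config <- loadExperimentConfig(NULL)
  seed <- as.integer(config$seed)
  if (is.null(manifest)) manifest <- config$data$manifest
  if (is.null(imageDir)) imageDir <- config$data$imageDir
  if (is.null(outputDir)) outputDir <- config$data$outputDir
  if (is.null(manifest)) {
    if (is.null(imageDir))
      imageDir <- file.path(tempdir(), sprintf("agoaelm_synth_%d", seed))
    sy <- config$synth
    generateSyntheticImages(imageDir, nImages = sy$nImages,
                            imageSize = config$features$imageSize,
                            tumorFraction = sy$tumorFraction,
                            blobRadiusRange = sy$blobRadiusRange,
                            blobIntensityLift = sy$blobIntensityLift,
                            noiseSd = sy$noiseSd, seed = seed)
    manifest <- file.path(imageDir, "manifest.csv")
  }
  if (is.character(manifest)) {
    if (is.null(imageDir)) imageDir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (length(unique(manifest$label)) < 2L)
    stop("the manifest must contain both classes")
  stack <- convStackConfig(config$features$imageSize)
  fm <- extractFeatureMatrix(manifest, baseDir = imageDir, stack = stack,
                             seed = config$features$filterSeed)
  featTab <- data.frame(idx = seq_len(nrow(fm$features)),
                        label = fm$labels)
  split <- splitManifest(featTab, trainFraction = config$trainFraction,
                         seed = seed)
  if (length(unique(split$train$label)) < 2L)
    stop("training split contains a single class; cannot optimize")
  xTrain <- fm$features[split$train$idx, , drop = FALSE]
  xTest <- fm$features[split$test$idx, , drop = FALSE]
  yTrain <- split$train$label
  yTest <- split$test$label
  ctl <- .controlFromConfig(config, seed)
  fit <- trainElmAgoa(xTrain, yTrain,
                      hiddenCount = config$elm$hiddenCount,
                      control = ctl, activation = config$elm$activation,
                      weightRange = config$elm$weightRange)
  pred <- elmPredict(fit$model, xTest)
  report <- metricReport(yTest, pred$class, positive = 1)
  baselineReport <- NULL
  if (compareRandomElm) {
    base <- elmTrain(xTrain, yTrain, hiddenCount = config$elm$hiddenCount,
                     activation = config$elm$activation,
                     weightRange = config$elm$weightRange, seed = seed)
    basePred <- elmPredict(base, xTest)
    baselineReport <- metricReport(yTest, basePred$class, positive = 1)
  }
  predictions <- data.frame(row = split$test$idx, truth = yTest,
                            predicted = pred$class,
                            scoreNegative = pred$scores[, 1],
                            scorePositive = pred$scores[, 2])
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeExperimentConfig(config, file.path(outputDir, "config.yaml"))
    writeELMModel(fit$model, file.path(outputDir, "model.json"))
    utils::write.csv(predictions, file.path(outputDir, "predictions.csv"),
                     row.names = FALSE)
    writeMetricsReport(report, file.path(outputDir, "metrics.json"))
    writeMetricsReport(report, file.path(outputDir, "metrics.csv"))
    writeConvergenceCSV(fit$result, file.path(outputDir, "convergence.csv"))
  }
  list(model = fit$model, result = fit$result, report = report,
       baselineReport = baselineReport, predictions = predictions,
       split = split)
}
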