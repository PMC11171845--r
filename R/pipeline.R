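# deterministic fan-out of the master seed into per-stage seeds (kept below
# 2^31 so they are valid R integer seeds)
stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage) %% 2147483629)
}

#' Configuration of a full calibration study
#'
#' Bundles every setting of the end-to-end workflow: data source (synthetic
#' generator config, or CSV paths), analytes, pretreatment grid, outlier
#' rule, split, cross-validation, GA/CARS settings, y-randomization size and
#' a master seed that fans out deterministically to every stochastic stage.
#'
#' @param synthetic a [syntheticConfig()] used when no file paths are given
#' @param spectraPath,referencesPath optional CSV inputs (see
#'   [readSpectra()], [readReferences()])
#' @param analytes analytes to model (subset of abts/frap/dpph)
#' @param preprocessMethods pretreatments compared by
#'   [runPretreatmentComparison()]
#' @param selectorPreprocess pretreatment used by [runSelectorComparison()]
#'   when not taken from a pretreatment-comparison winner (default `"snv"`)
#' @param splitFraction Kennard-Stone calibration fraction (default 2/3)
#' @param calibrationSize optional explicit calibration size override
#' @param maxLvs,folds cross-validation settings
#' @param ga a [gaConfig()]; its seed is overridden by the master seed
#' @param cars a [carsConfig()]; its seed is overridden by the master seed
#' @param outlierRule,varianceKept see [mahalanobisOutliers()]
#' @param nPerm y-randomization permutations per evaluation
#' @param seed master seed
#' @return list of class `studyConfig`
#' @export
studyConfig <- function(synthetic = syntheticConfig(),
                        spectraPath = NULL, referencesPath = NULL,
                        analytes = c("abts", "frap", "dpph"),
                        preprocessMethods = c("raw", "d1_sg", "msc", "snv",
                                              "smoothing"),
                        selectorPreprocess = "snv",
                        splitFraction = 2 / 3, calibrationSize = NULL,
                        maxLvs = 20L, folds = 10L,
                        ga = gaConfig(), cars = carsConfig(),
                        outlierRule = "chauvenet", varianceKept = 0.99,
                        nPerm = 25L, seed = 1L) {
  if (!length(analytes)) stop("at least one analyte is required")
  if (!length(preprocessMethods)) stop("at least one pretreatment is required")
  structure(list(synthetic = synthetic, spectraPath = spectraPath,
                 referencesPath = referencesPath, analytes = analytes,
                 preprocessMethods = preprocessMethods,
                 selectorPreprocess = selectorPreprocess,
                 splitFraction = splitFraction,
                 calibrationSize = calibrationSize,
                 maxLvs = as.integer(maxLvs), folds = as.integer(folds),
                 ga = ga, cars = cars, outlierRule = outlierRule,
                 varianceKept = varianceKept, nPerm = as.integer(nPerm),
                 seed = as.integer(seed)),
            class = "studyConfig")
}

# load or simulate the study data; outlier-screen once on the raw spectra
prepareStudyData <- function(config) {
  if (!is.null(config$spectraPath)) {
    spectra <- readSpectra(config$spectraPath)
    references <- alignReferences(spectra, readReferences(config$referencesPath))
    groundTruth <- NULL
  } else {
    syn <- config$synthetic
    syn$seed <- stageSeed(config$seed, 1L)
    sim <- simulateSpectra(syn)
    spectra <- sim$spectra
    references <- sim$references
    groundTruth <- sim$groundTruth
  }
  outliers <- mahalanobisOutliers(spectra, varianceKept = config$varianceKept,
                                  rule = config$outlierRule)
  keep <- setdiff(sampleIds(spectra), outliers@flagged)
  if (length(outliers@flagged))
    message("dropping ", length(outliers@flagged), " outlier sample(s)")
  spectra <- selectSamples(spectra, keep)
  references <- alignReferences(spectra, references)
  list(spectra = spectra, references = references, outliers = outliers,
       groundTruth = groundTruth)
}

# split on spectra pretreated with `method`; the MSC reference used here is
# the all-sample mean (x-only, unsupervised), while the modelling MSC
# reference is re-estimated on the calibration set only
splitByKennardStone <- function(spectra, method, config) {
  prep <- fitPreprocessor(preprocessorSpec(method), spectra)$spectra
  kennardStone(prep, calibrationFraction = config$splitFraction,
               calibrationSize = config$calibrationSize)
}

# train + evaluate one model cell; returns list(report, model, cv, selection)
fitCell <- function(calSpectra, calY, predSpectra, predY, method, analyte,
                    config, modelLabel, selector = NULL) {
  prepSpec <- preprocessorSpec(method)
  fitted <- fitPreprocessor(prepSpec, calSpectra)
  Xcal <- absorbance(fitted$spectra)
  selection <- NULL
  indices <- seq_len(ncol(Xcal))
  if (identical(selector, "ga")) {
    ga <- config$ga
    ga$seed <- stageSeed(config$seed, 100L + match(analyte, config$analytes))
    selection <- gaSelect(Xcal, calY, ga)
    indices <- selection@selectedIndices
  } else if (identical(selector, "cars")) {
    cars <- config$cars
    cars$seed <- stageSeed(config$seed, 200L + match(analyte, config$analytes))
    selection <- carsSelect(Xcal, calY, cars)
    indices <- selection@selectedIndices
  }
  trained <- trainPls(calSpectra, calY, preprocessor = prepSpec,
                      wavelengthIndices = indices, maxLvs = config$maxLvs,
                      folds = config$folds, analyte = analyte)
  report <- evaluateModel(trained$model, calSpectra, calY, predSpectra, predY,
                          trained$cv, nPerm = config$nPerm,
                          seed = stageSeed(config$seed, 300L),
                          modelLabel = modelLabel)
  list(report = report, model = trained$model, cv = trained$cv,
       selection = selection)
}

#' Compare spectral pretreatments with full-spectrum PLS models
#'
#' Fits a Full-PLS model per (pretreatment, analyte) cell and assembles the
#' comparison table.  The winner per analyte is the pretreatment with the
#' smallest RMSECV among those passing both validation gates (falling back
#' to the overall minimum when none pass).  A failed cell is recorded and
#' the run continues.
#'
#' @param config a [studyConfig()]
#' @param data optional pre-loaded result of the internal data step (reused
#'   by [runFullStudy()])
#' @return list with `table` (data frame of metric rows), `reports`,
#'   `winners` (named character vector per analyte) and `outliers`
#' @export
runPretreatmentComparison <- function(config = studyConfig(), data = NULL) {
  if (is.null(data)) data <- prepareStudyData(config)
  rows <- list()
  reports <- list()
  for (analyte in config$analytes) {
    yAll <- referenceValues(data$references, analyte)
    for (method in config$preprocessMethods) {
      cellId <- paste(analyte, method, sep = ".")
      res <- tryCatch({
        split <- splitByKennardStone(data$spectra, method, config)
        calS <- selectSamples(data$spectra, split@calibrationIds)
        predS <- selectSamples(data$spectra, split@predictionIds)
        fitCell(calS, yAll[split@calibrationIds], predS,
                yAll[split@predictionIds], method, analyte, config,
                modelLabel = method)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning("cell ", cellId, " failed: ", conditionMessage(res))
        rows[[cellId]] <- data.frame(analyte = analyte, model = method,
                                     failed = TRUE)
        next
      }
      reports[[cellId]] <- res$report
      rows[[cellId]] <- cbind(reportAsRow(res$report), failed = FALSE)
    }
  }
  table <- do.call(rbind, c(lapply(rows, function(r) {
    if (!"rmsecv" %in% colnames(r)) {
      out <- reportAsRow(new("EvaluationReport", analyte = r$analyte,
                             model = r$model, r2C = NA_real_, rmsec = NA_real_,
                             rmsecv = NA_real_, slopeC = NA_real_,
                             r2Rand = NA_real_, cr2P = NA_real_, r2P = NA_real_,
                             rmsep = NA_real_, slopeP = NA_real_, r2m = NA_real_,
                             nCal = 0L, nPred = 0L, nLvs = 1L, nVariables = 0L,
                             gates = c(r2m = NA, cr2p = NA)))
      cbind(out, failed = TRUE)
    } else r
  }), list(make.row.names = FALSE)))
  winners <- vapply(config$analytes, function(analyte) {
    sub <- table[table$analyte == analyte & !table$failed, , drop = FALSE]
    if (!nrow(sub)) return(NA_character_)
    ok <- sub[sub$r2_m >= 0.5 & sub$cr2_p >= 0.5, , drop = FALSE]
    if (nrow(ok)) ok$model[which.min(ok$rmsecv)]
    else sub$model[which.min(sub$rmsecv)]
  }, character(1))
  message("pretreatment winners: ",
          paste(names(winners), winners, sep = "=", collapse = ", "))
  list(table = table, reports = reports, winners = winners,
       outliers = data$outliers)
}

#' Compare Full-PLS, GA-PLS and CARS-PLS models
#'
#' For each analyte: Kennard-Stone split on the pretreated spectra, then a
#' full-spectrum model, a GA-selected model and a CARS-selected model, each
#' with cross-validated latent-variable counts and the full validation
#' battery.  The headline summary reports the percentage decrease in RMSEP
#' of CARS-PLS relative to Full-PLS per analyte.
#'
#' @param config a [studyConfig()]
#' @param preprocess pretreatment method used throughout (default: the
#'   config's `selectorPreprocess`, conventionally SNV)
#' @param data optional pre-loaded data (reused by [runFullStudy()])
#' @return list with `table`, `reports`, `selections`, `models`, `split`
#'   (per analyte) and `summary` (data frame with `rmsep_decrease_pct`)
#' @export
runSelectorComparison <- function(config = studyConfig(), preprocess = NULL,
                                  data = NULL) {
  if (is.null(data)) data <- prepareStudyData(config)
  if (is.null(preprocess)) preprocess <- config$selectorPreprocess
  reports <- list(); selections <- list(); models <- list(); splits <- list()
  rows <- list()
  labels <- c(full = "Full-PLS", ga = "GA-PLS", cars = "CARS-PLS")
  for (analyte in config$analytes) {
    yAll <- referenceValues(data$references, analyte)
    split <- splitByKennardStone(data$spectra, preprocess, config)
    splits[[analyte]] <- split
    calS <- selectSamples(data$spectra, split@calibrationIds)
    predS <- selectSamples(data$spectra, split@predictionIds)
    calY <- yAll[split@calibrationIds]
    predY <- yAll[split@predictionIds]
    for (kind in names(labels)) {
      cellId <- paste(analyte, kind, sep = ".")
      res <- tryCatch(
        fitCell(calS, calY, predS, predY, preprocess, analyte, config,
                modelLabel = labels[[kind]],
                selector = if (kind == "full") NULL else kind),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning("cell ", cellId, " failed: ", conditionMessage(res))
        next
      }
      reports[[cellId]] <- res$report
      models[[cellId]] <- res$model
      if (!is.null(res$selection)) selections[[cellId]] <- res$selection
      rows[[cellId]] <- reportAsRow(res$report)
    }
  }
  table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  summary <- do.call(rbind, lapply(config$analytes, function(analyte) {
    fullR <- reports[[paste(analyte, "full", sep = ".")]]
    carsR <- reports[[paste(analyte, "cars", sep = ".")]]
    gaR <- reports[[paste(analyte, "ga", sep = ".")]]
    data.frame(analyte = analyte,
               rmsep_full = if (is.null(fullR)) NA_real_ else fullR@rmsep,
               rmsep_ga = if (is.null(gaR)) NA_real_ else gaR@rmsep,
               rmsep_cars = if (is.null(carsR)) NA_real_ else carsR@rmsep,
               rmsep_decrease_pct = if (is.null(fullR) || is.null(carsR))
                 NA_real_ else rmsepDecrease(fullR@rmsep, carsR@rmsep))
  }))
  list(table = table, reports = reports, selections = selections,
       models = models, splits = splits, summary = summary)
}

#' Run the complete calibration study
#'
#' End-to-end orchestration: load or simulate the data, screen outliers
#' once on the raw spectra, compare pretreatments with full-spectrum models,
#' then compare Full/GA/CARS wavelength selection per analyte using each
#' analyte's winning pretreatment.  Optionally writes all reports, selected
#' wavelengths, traces and a manifest under `outputDir`.
#'
#' @param config a [studyConfig()]
#' @param outputDir optional directory for JSON/CSV outputs
#' @return list with `pretreatment`, `selectors` (per analyte), `summary`
#'   and `outliers`
#' @export
runFullStudy <- function(config = studyConfig(), outputDir = NULL) {
  data <- prepareStudyData(config)
  pre <- runPretreatmentComparison(config, data = data)
  selectors <- list(); summaries <- list()
  for (analyte in config$analytes) {
    cfgA <- config
    cfgA$analytes <- analyte
    winner <- pre$winners[[analyte]]
    if (is.na(winner)) winner <- config$selectorPreprocess
    sel <- runSelectorComparison(cfgA, preprocess = winner, data = data)
    selectors[[analyte]] <- sel
    summaries[[analyte]] <- cbind(sel$summary, pretreatment = winner)
  }
  summary <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  bundle <- list(pretreatment = pre, selectors = selectors, summary = summary,
                 outliers = data$outliers, groundTruth = data$groundTruth)
  if (!is.null(outputDir)) writeStudyOutputs(bundle, config, outputDir)
  bundle
}

# write reports, traces, selections and a manifest under outputDir
writeStudyOutputs <- function(bundle, config, outputDir) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (cellId in names(bundle$pretreatment$reports)) {
    f <- file.path(outputDir, paste0("pretreatment_", cellId, ".json"))
    writeReport(bundle$pretreatment$reports[[cellId]], f)
    files <- c(files, f)
  }
  for (analyte in names(bundle$selectors)) {
    sel <- bundle$selectors[[analyte]]
    for (cellId in names(sel$reports)) {
      f <- file.path(outputDir, paste0("selector_", cellId, ".json"))
      writeReport(sel$reports[[cellId]], f)
      files <- c(files, f)
    }
    for (cellId in names(sel$selections)) {
      s <- sel$selections[[cellId]]
      f <- file.path(outputDir, paste0("selection_", cellId, ".csv"))
      if (s@method == "cars") {
        data.table::fwrite(data.table::data.table(
          run = seq_along(s@trace$rmsecv), kept = s@trace$keptCount,
          rmsecv = s@trace$rmsecv), f)
      } else {
        data.table::fwrite(data.table::data.table(
          index = seq_along(s@trace$frequency),
          frequency = s@trace$frequency), f)
      }
      files <- c(files, f)
    }
  }
  data.table::fwrite(bundle$summary, file.path(outputDir, "summary.csv"))
  manifest <- list(format = "nirpls-study-manifest", seed = config$seed,
                   analytes = config$analytes,
                   files = basename(c(files, file.path(outputDir, "summary.csv"))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE),
             file.path(outputDir, "manifest.json"))
  invisible(outputDir)
}
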