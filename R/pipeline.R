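# End-to-end pipeline: simulate -> segment -> extract -> reduce ->
# associate -> predict -> evaluate -> select, with a manifest of every
# artifact written.

#' Pipeline configuration
#'
#' Nested parameter blocks for every stage.  The defaults carry the
#' standard analysis configuration: collinearity thresholds 0.75 (VI) and
#' 0.95 (GLCM), strong-correlation threshold 0.75, RF importance threshold
#' 0.1, RMSE-gap 0.1, 4-fold CV with 100 repetitions, selection
#' intensities 5/20/50 %, full VI registry and GLCM grid.
#'
#' @param seed global seed; every stage derives its own stream from it.
#' @param design list: nBlocks, checks, progeniesPerBlock.
#' @param traits list: nHarvests, geneticCor, specs.
#' @param render list passed to \code{\link{renderParams}} plus
#'   \code{imagingHarvest} (which harvest is flown).
#' @param reduce list: mode ("data-driven" or "preset"), thresholdVi,
#'   thresholdGlcm.
#' @param associate list: strongThreshold.
#' @param predict list: models, k, repetitions, importanceThreshold,
#'   rmseGap.
#' @param select list: intensities, traitA, traitB.
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(seed = 1L,
                           design = list(nBlocks = 5L,
                                         checks = c("S12", "Miyagui",
                                                    "Mombaca"),
                                         progeniesPerBlock = 42L),
                           traits = list(nHarvests = 4L, geneticCor = 0.8),
                           render = list(canvas = 64L, areaGain = 0.02,
                                         textureGain = 0.3,
                                         imagingHarvest = 1L),
                           reduce = list(mode = "preset", thresholdVi = 0.75,
                                         thresholdGlcm = 0.95),
                           associate = list(strongThreshold = 0.75),
                           predict = list(models = "rf", k = 4L,
                                          repetitions = 100L,
                                          importanceThreshold = 0.1,
                                          rmseGap = 0.1),
                           select = list(intensities = c(0.05, 0.2, 0.5),
                                         traitA = "LDMY",
                                         traitB = "n_pixels")) {
  cfg <- structure(list(seed = seed, design = design, traits = traits,
                        render = render, reduce = reduce,
                        associate = associate, predict = predict,
                        select = select), class = "pipelineConfig")
  validatePipelineConfig(cfg)
  cfg
}

#' @describeIn pipelineConfig validate a configuration, stopping with the
#'   name of any missing field.
#' @param config a pipeline configuration list.
#' @export
validatePipelineConfig <- function(config) {
  need <- list(c("seed"), c("design", "nBlocks"), c("design", "checks"),
               c("design", "progeniesPerBlock"), c("traits", "nHarvests"),
               c("reduce", "mode"), c("reduce", "thresholdVi"),
               c("reduce", "thresholdGlcm"),
               c("associate", "strongThreshold"),
               c("predict", "models"), c("predict", "k"),
               c("predict", "repetitions"),
               c("predict", "importanceThreshold"),
               c("select", "intensities"))
  for (path in need) {
    node <- config
    for (key in path) {
      node <- node[[key]]
      if (is.null(node))
        stop("pipeline config is missing field '",
             paste(path, collapse = "$"), "'")
    }
  }
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; missing blocks fall back to the defaults of
#'   \code{\link{pipelineConfig}}.
#' @return validated \code{pipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  base <- pipelineConfig()
  for (nm in names(usr)) {
    if (is.list(usr[[nm]]) && is.list(base[[nm]]))
      for (k in names(usr[[nm]])) base[[nm]][[k]] <- usr[[nm]][[k]]
    else base[[nm]] <- usr[[nm]]
  }
  validatePipelineConfig(base)
  base
}

#' Run the full pipeline
#'
#' Executes simulate, segment, extract, reduce, associate, predict,
#' evaluate and select; writes every intermediate artifact under
#' \code{outDir} together with the resolved configuration and a manifest
#' (files, seed, config hash).  Idempotent for a given seed.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory.
#' @param quiet suppress per-stage messages.
#' @return Invisibly, a run report: per-stage outputs and the manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run"),
                        quiet = FALSE) {
  validatePipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  note <- function(...) if (!quiet) message(sprintf(...))
  stageOut <- list()
  t0 <- Sys.time()

  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  files <- c(files, "config.json")

  # 1. simulate design + traits
  design <- makeDesign(config$design$nBlocks, config$design$checks,
                       config$design$progeniesPerBlock,
                       seed = childSeed(config$seed, 1L))
  traits <- simulateTraits(design, nHarvests = config$traits$nHarvests,
                           seed = childSeed(config$seed, 2L),
                           geneticCor = config$traits$geneticCor %||% 0.8)
  write.csv(designTable(design), file.path(outDir, "design.csv"),
            row.names = FALSE)
  write.csv(traits, file.path(outDir, "traits.csv"), row.names = FALSE)
  files <- c(files, "design.csv", "traits.csv")
  note("simulate: %d plots x %d harvests", nPlots(design),
       config$traits$nHarvests)
  stageOut$simulate <- list(nPlots = nPlots(design))

  # 2. render + segment the imaging flight
  rp <- do.call(renderParams, config$render[setdiff(names(config$render),
                                                    "imagingHarvest")])
  h0 <- config$render$imagingHarvest %||% 1L
  flight <- traits[traits$harvest == h0, ]
  plots <- lapply(seq_len(nrow(flight)), function(i) {
    img <- renderPlotImage(flight$biomass[i], flight$vigor[i], rp,
                           seed = childSeed(config$seed, 100L + i),
                           meta = list(entry = flight$entry[i],
                                       environment = design@environment,
                                       dap = h0))
    segmentPlot(img)
  })
  names(plots) <- paste0("p", flight$plot)
  note("segment: %d plots rendered and segmented", length(plots))
  stageOut$segment <- list(nImages = length(plots))

  # 3. extract + normalize
  ft <- extractFeatureTable(plots)
  ft <- minmaxNormalize(ft)
  rawCsv <- as.data.frame(t(SummarizedExperiment::assay(ft, "raw")))
  write.csv(cbind(plot = flight$plot, rawCsv),
            file.path(outDir, "features.csv"), row.names = FALSE)
  files <- c(files, "features.csv")
  note("extract: %d features x %d plots", nrow(ft), ncol(ft))
  stageOut$extract <- list(nFeatures = nrow(ft))

  # 4. reduce
  red <- if (identical(config$reduce$mode, "preset")) presetReduction(ft)
         else pruneCollinear(ft, config$reduce$thresholdVi,
                             config$reduce$thresholdGlcm)
  redCsv <- as.data.frame(t(SummarizedExperiment::assay(red, "raw")))
  write.csv(cbind(plot = flight$plot, redCsv),
            file.path(outDir, "reduced.csv"), row.names = FALSE)
  files <- c(files, "reduced.csv")
  note("reduce: %d -> %d features", nrow(ft), nrow(red))
  stageOut$reduce <- list(kept = nrow(red))

  # 5. associate with conventional traits of the imaged harvest
  traitCols <- intersect(c("CH", "GMY", "LDMY", "SDMY", "DMP", "TDMY"),
                         names(flight))
  assoc <- associationMatrix(red, flight, traitCols,
                             config$associate$strongThreshold)
  write.csv(assoc, file.path(outDir, "assoc.csv"), row.names = FALSE)
  files <- c(files, "assoc.csv")
  note("associate: %d pairs, %d strong", nrow(assoc), sum(assoc$strong))
  stageOut$associate <- list(nStrong = sum(assoc$strong))

  # 6. predict GMY from the reduced digital traits
  xm <- t(SummarizedExperiment::assay(red, "raw"))
  xm <- xm[, apply(xm, 2L, function(v) all(is.finite(v))), drop = FALSE]
  cv <- lapply(config$predict$models, function(mod)
    runRepeatedCv(xm, flight$GMY,
                  predictionConfig(mod, k = config$predict$k,
                                   repetitions = config$predict$repetitions,
                                   seed = childSeed(config$seed, 3L))))
  names(cv) <- config$predict$models
  imp <- rfFeatureImportance(xm, flight$GMY,
                             config$predict$importanceThreshold,
                             seed = childSeed(config$seed, 4L))
  cvJson <- list(metrics = lapply(cv, function(z) as.list(z$metrics)),
                 importance = as.list(imp$importance),
                 selected = imp$selected)
  jsonlite::write_json(cvJson, file.path(outDir, "cv.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, "cv.json")
  note("predict: mean r = %s",
       paste(sprintf("%s %.2f", names(cv),
                     vapply(cv, function(z) z$metrics["r"], 0)),
             collapse = ", "))
  stageOut$predict <- list(metrics = lapply(cv, `[[`, "metrics"))

  # 7. genetic evaluation: conventional model per trait + digital n_pixels
  prep <- prepareAugmented(traits, checkNames(design))
  fits <- list()
  for (tr in intersect(c("LDMY", "GMY"), names(prep)))
    fits[[tr]] <- fitConventionalModel(prep, tr)
  digi <- prepareAugmented(flight, checkNames(design))
  digi$n_pixels <- as.vector(
    SummarizedExperiment::assay(red, "raw")["n_pixels", ])
  fits$n_pixels <- fitDigitalModel(digi, "n_pixels")
  evalJson <- lapply(fits, function(f) list(
    components = as.list(varComp(f)),
    H2 = as.numeric(broadSenseH2(f,
      nHarvests = config$traits$nHarvests)),
    HC2 = tryCatch(cullisH2(f), error = function(e) NA)))
  jsonlite::write_json(evalJson, file.path(outDir, "fit.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, "fit.json")
  note("evaluate: %d mixed models fitted", length(fits))
  stageOut$evaluate <- list(H2 = vapply(evalJson, `[[`, 0, "H2"))

  # 8. selection coincidence between a conventional and a digital trait
  bvA <- blups(fits[[config$select$traitA]])
  bvB <- blups(fits[[config$select$traitB]])
  common <- intersect(names(bvA), names(bvB))
  sel <- lapply(config$select$intensities, function(ii)
    coincidenceIndex(rankGenotypes(bvA[common]),
                     rankGenotypes(bvB[common]), ii,
                     config$select$traitA, config$select$traitB))
  selJson <- lapply(sel, function(s) list(
    intensity = s@intensity, ci = s@ci,
    selectedA = s@selectedA, selectedB = s@selectedB))
  jsonlite::write_json(selJson, file.path(outDir, "selection.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, "selection.json")
  note("select: CI = %s",
       paste(sprintf("%.0f%%@%.0f%%", vapply(sel, ciValue, 0),
                     100 * config$select$intensities), collapse = ", "))
  stageOut$select <- list(ci = vapply(sel, ciValue, 0))

  manifest <- list(files = files, seed = config$seed,
                   configHash = unname(tools::md5sum(cfgPath)),
                   fileHashes = as.list(
                     tools::md5sum(file.path(outDir, files))),
                   elapsedSec = as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")),
                   stages = names(stageOut))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(stages = stageOut, manifest = manifest, outDir = outDir))
}
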