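## Orchestration: configuration, the end-to-end pipeline, and the
## filesystem entry points behind the command-line wrapper.

#' Pipeline configuration
#'
#' Bundles every tunable of the full analysis.  Serializable to and from a
#' flat YAML file with strict schema checking (unknown keys are errors, so
#' a typo in `lambda` or `diffusivity` cannot silently fall back to a
#' default).
#'
#' @slot protocol an [AcquisitionProtocol-class].
#' @slot vwt a [VWTConfig-class].
#' @slot pcaK principal components kept (default 6).
#' @slot icaK components unmixed by ICA (default 4).
#' @slot icaSkipBulk unmix components `2..icaK+1`, leaving the dominant
#'   bulk (shared background recovery) component out of the rotation
#'   (default `TRUE`).
#' @slot seed seed from which all pipeline randomness flows.
#' @slot backgroundTemp background temperature subtracted, degrees C.
#' @slot registerReference `"static"` or `"first"`.
#' @slot ratioTol pairing tolerance on the 2x reflection/vasomodulation
#'   time ratio.
#' @name PipelineConfig-class
#' @rdname PipelineConfig
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(
    protocol = "AcquisitionProtocol",
    vwt = "VWTConfig",
    pcaK = "integer",
    icaK = "integer",
    icaSkipBulk = "logical",
    seed = "integer",
    backgroundTemp = "numeric",
    registerReference = "character",
    ratioTol = "numeric"
  )
)

#' @param protocol,vwt,pcaK,icaK,icaSkipBulk,seed,backgroundTemp,registerReference,ratioTol
#'   see slot documentation.
#' @return a `PipelineConfig`.
#' @rdname PipelineConfig
#' @export
pipelineConfig <- function(protocol = acquisitionProtocol(),
                           vwt = vwtConfig(includeStaticInInversion = TRUE),
                           pcaK = 6L, icaK = 4L, icaSkipBulk = TRUE,
                           seed = 0L, backgroundTemp = 21,
                           registerReference = "static", ratioTol = 0.25) {
  new("PipelineConfig", protocol = protocol, vwt = vwt,
      pcaK = as.integer(pcaK), icaK = as.integer(icaK),
      icaSkipBulk = isTRUE(icaSkipBulk), seed = as.integer(seed),
      backgroundTemp = backgroundTemp,
      registerReference = registerReference, ratioTol = ratioTol)
}

pipelineConfigKeys <- c(
  "nDynamicFrames", "frameInterval", "includeStatic", "skinTempPostCooling",
  "skinTempBaseline", "roomTemp", "coolingDuration",
  "diffusivity", "lambda", "smoothnessOrder", "virtualSpeed",
  "useExcitationConvolution", "includeStaticInInversion", "mode",
  "pcaK", "icaK", "icaSkipBulk", "seed", "backgroundTemp",
  "registerReference", "ratioTol")

#' Read a pipeline configuration from a flat YAML file
#'
#' Every key is optional and falls back to the documented default; unknown
#' keys raise an error.
#'
#' @param path YAML file.
#' @return a [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj)) obj <- list()
  unknown <- setdiff(names(obj), pipelineConfigKeys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  g <- function(key, default) if (is.null(obj[[key]])) default else obj[[key]]
  prot <- acquisitionProtocol(
    nDynamicFrames = g("nDynamicFrames", 20L),
    frameInterval = g("frameInterval", 15),
    includeStatic = g("includeStatic", TRUE),
    skinTempPostCooling = g("skinTempPostCooling", 32.5),
    skinTempBaseline = g("skinTempBaseline", 34.5),
    roomTemp = g("roomTemp", 21),
    coolingDuration = g("coolingDuration", 300))
  vwt <- vwtConfig(
    diffusivity = g("diffusivity", 7.58e-8),
    lambda = g("lambda", 0.003),
    smoothnessOrder = g("smoothnessOrder", 2L),
    virtualSpeed = g("virtualSpeed", 1),
    useExcitationConvolution = g("useExcitationConvolution", TRUE),
    includeStaticInInversion = g("includeStaticInInversion", TRUE),
    mode = g("mode", "penalty"))
  pipelineConfig(protocol = prot, vwt = vwt,
                 pcaK = g("pcaK", 6L), icaK = g("icaK", 4L),
                 icaSkipBulk = g("icaSkipBulk", TRUE),
                 seed = g("seed", 0L),
                 backgroundTemp = g("backgroundTemp", 21),
                 registerReference = g("registerReference", "static"),
                 ratioTol = g("ratioTol", 0.25))
}

#' Run the full analysis pipeline on one masked breast
#'
#' Motion correction, background subtraction, stacking, virtual wave
#' inversion, PCA, product-preserving ICA, component classification, and
#' the vasoconstriction-deficit map, with every intermediate returned.
#'
#' @param stack a [FrameStack-class] of calibrated temperatures.
#' @param mask a [BreastMask-class] (or logical matrix).
#' @param config a [PipelineConfig-class].
#' @param register run rigid motion correction first (default `TRUE`).
#' @return a list with elements `pixelMatrix`, `excitation` (measured
#'   footprint), `kernel`, `virtual`, `pca`, `ica`, `readings` (classified
#'   component table, depths in metres), `componentImages`,
#'   `reflectionImage`, `vasomodulationImage`, `deficitMap`, `shifts`, and
#'   `log` (parameters, seeds, condition number).
#' @examples
#' \donttest{
#' v <- vesselSpec(depth = 0.009, reflectionCoeff = -1,
#'                 vasoFastAmplitude = 0.5, vasoSlowAmplitude = 0.2,
#'                 centerline = cbind(10:53, 32L), width = 3,
#'                 vasoTaper = seq(0.2, 1.8, length.out = 44))
#' stk <- renderPhantom(phantomSpec(c(64L, 64L), list(v), noiseStd = 0))
#' res <- runPipeline(stk, breastMask(matrix(TRUE, 64, 64)),
#'                    pipelineConfig())
#' subset(res$readings, !is.na(pairedWith))
#' }
#' @export
runPipeline <- function(stack, mask, config = pipelineConfig(),
                        register = TRUE) {
  shifts <- NULL
  validMask <- NULL
  if (register) {
    reg <- registerFrames(stack, config@registerReference)
    stack <- reg$stack
    shifts <- reg$shifts
    validMask <- reg$validMask
  }
  stack <- subtractBackground(stack, config@backgroundTemp)
  m <- if (is(mask, "BreastMask")) mask else breastMask(mask)
  if (!is.null(validMask))
    m <- breastMask(m@mask & validMask, m@side, m@includesSurround)
  pm <- stackToMatrix(stack, m, includeStatic = TRUE)
  excitationMeasured <- extractExcitation(pm)
  prot <- config@protocol
  excitationModel <- makeExcitation(prot, "step")
  dynTimes <- pm@columnTimes[setdiff(seq_len(ncol(pm@values)),
                                     pm@staticColumn)]
  realTimes <- if (config@vwt@useExcitationConvolution)
    dynTimes + prot@coolingDuration else dynTimes
  grid <- buildVirtualGrid()
  kernel <- buildKernel(realTimes, grid, config@vwt, excitationModel)
  vw <- vwtInvert(pm, kernel, config@vwt)
  pca <- suppressWarnings(pcaFactor(vw, config@pcaK))
  comps <- if (config@icaSkipBulk)
    1L + seq_len(min(config@icaK, pca@k - 1L))
  else seq_len(min(config@icaK, pca@k))
  ica <- icaUnmix(pca, seed = config@seed, components = comps)
  readings <- classifyComponents(componentReadings(ica, grid),
                                 stimulusSign = -1,
                                 ratioTol = config@ratioTol,
                                 config = config@vwt)
  imgs <- componentsToImages(ica, pm@pixelIndex, pm@shape)
  agg <- function(label) {
    sel <- which(readings$label == label)
    out <- matrix(0, pm@shape[1], pm@shape[2])
    for (j in sel) out <- out + abs(imgs[[j]]) * readings$amplitude[j] /
        max(abs(imgs[[j]]))
    out
  }
  reflImg <- agg("reflection")
  vasoImg <- agg("vasomodulation")
  dmap <- if (max(abs(reflImg)) > 0)
    deficitMap(reflImg, vasoImg) else reflImg
  list(
    pixelMatrix = pm, excitation = excitationMeasured, kernel = kernel,
    virtual = vw, pca = pca, ica = ica, readings = readings,
    componentImages = imgs, reflectionImage = reflImg,
    vasomodulationImage = vasoImg, deficitMap = dmap, shifts = shifts,
    log = list(
      seed = config@seed, pcaK = config@pcaK, icaK = config@icaK,
      icaComponents = comps, lambda = config@vwt@lambda,
      diffusivity = config@vwt@diffusivity,
      conditionNumber = vwtConditionNumber(kernel, config@vwt),
      nPixels = nrow(pm@values), nColumns = ncol(pm@values),
      packageVersion = as.character(utils::packageVersion("thermovasc"))
    )
  )
}

#' Persist pipeline results to a report directory
#'
#' Writes the classified readings (CSV, depths in mm), unmixed time traces
#' (CSV over virtual time), component images and deficit map (PNG with JSON
#' scale sidecars), the pixel matrix (CSV) and a JSON log.
#'
#' @param res result list from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePipelineResults <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rd <- res$readings
  rd$depthMm <- rd$depthM * 1000
  utils::write.csv(rd[, c("component", "label", "peakTime", "peakSign",
                          "amplitude", "depthMm", "pairedWith")],
                   file.path(dir, "readings.csv"), row.names = FALSE)
  traces <- data.frame(virtualTime = res$virtual@grid@points,
                       t(res$ica@timeMatrix))
  names(traces) <- c("virtualTime",
                     paste0("component", seq_len(res$ica@k)))
  utils::write.csv(traces, file.path(dir, "traces.csv"), row.names = FALSE)
  for (j in seq_along(res$componentImages))
    writeImagePNG(res$componentImages[[j]],
                  file.path(dir, sprintf("component_%02d.png", j)))
  writeImagePNG(res$deficitMap, file.path(dir, "deficit_map.png"))
  writePixelMatrixCSV(res$pixelMatrix, file.path(dir, "pixel_matrix.csv"))
  jsonlite::write_json(res$log, file.path(dir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Render a phantom scene file to disk
#'
#' Reads a phantom scene (YAML/JSON), renders it, and writes the frame
#' stack as DMR-dialect text grids plus a ground-truth JSON sidecar.
#'
#' @param specFile scene description readable by [readPhantomSpec()].
#' @param outDir output directory.
#' @param seed optional override of the scene's seed.
#' @return `outDir`, invisibly.
#' @export
cmdSimulate <- function(specFile, outDir, seed = NULL) {
  if (!file.exists(specFile))
    stop("scene file not found: ", specFile, call. = FALSE)
  spec <- readPhantomSpec(specFile)
  if (!is.null(seed)) spec@seed <- as.integer(seed)
  stack <- renderPhantom(spec)
  writeDMRFrames(stack, outDir)
  gt <- stack@meta$groundTruth
  jsonlite::write_json(
    list(seed = spec@seed,
         vessels = lapply(spec@vessels, function(v) list(
           depthMm = v@depth * 1000, reflectionCoeff = v@reflectionCoeff,
           vasoFastAmplitude = v@vasoFastAmplitude,
           vasoSlowAmplitude = v@vasoSlowAmplitude)),
         jitterShifts = gt$jitterShifts),
    file.path(outDir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Run the full pipeline from files
#'
#' Reads a frame stack (DMR text directory or multi-frame TIFF), one or two
#' mask images, and a configuration, then writes one report directory per
#' mask via [writePipelineResults()].
#'
#' @param input DMR frame directory or TIFF path.
#' @param maskFiles named character vector of mask image paths (names
#'   become report subdirectories, e.g. `c(left = "...", right = "...")`);
#'   `NULL` analyses all pixels.
#' @param outDir report directory.
#' @param config a [PipelineConfig-class].
#' @return `outDir`, invisibly.
#' @export
cmdRunAll <- function(input, maskFiles = NULL, outDir,
                      config = pipelineConfig()) {
  stack <- if (dir.exists(input)) readDMRFrames(input)
  else readFrameStackTIFF(input)
  d <- dim(stack@frames)
  masks <- if (is.null(maskFiles))
    list(all = breastMask(matrix(TRUE, d[1], d[2])))
  else {
    nm <- names(maskFiles)
    if (is.null(nm)) nm <- paste0("mask", seq_along(maskFiles))
    stats::setNames(lapply(seq_along(maskFiles), function(i)
      readMask(maskFiles[[i]],
               side = if (grepl("right", nm[i])) "right" else "left")), nm)
  }
  for (nm in names(masks)) {
    res <- runPipeline(stack, masks[[nm]], config)
    writePipelineResults(res, file.path(outDir, nm))
  }
  invisible(outDir)
}
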