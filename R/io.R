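## Readers and writers: multi-frame TIFF with JSON sidecar, DMR-dialect
## text temperature grids, mask images, CSV exports.

#' Write a frame stack as multi-frame TIFF plus JSON sidecar
#'
#' TIFF samples are stored affine-normalized to `[0, 1]` (32-bit float);
#' the scale and offset, timestamps, background-subtraction record and
#' static-frame position go to a `.json` sidecar next to the TIFF so the
#' temperatures are recovered exactly in degrees C on read.
#'
#' @param stack a [FrameStack-class].
#' @param path output TIFF path; the sidecar is written at
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @seealso [readFrameStackTIFF()], [writeDMRFrames()]
#' @export
writeFrameStackTIFF <- function(stack, path) {
  fr <- stack@frames
  hasStatic <- !is.null(stack@staticFrame)
  all3 <- if (hasStatic) {
    abind_local(fr, stack@staticFrame)
  } else fr
  lo <- min(all3); hi <- max(all3)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(all3)[3]),
                  function(i) (all3[, , i] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(
    offset = lo, scale = scale,
    timestamps = stack@timestamps,
    staticFrameLast = hasStatic,
    backgroundSubtracted = stack@meta$backgroundSubtracted
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

abind_local <- function(arr, mat) {
  d <- dim(arr)
  out <- array(0, dim = c(d[1], d[2], d[3] + 1L))
  out[, , seq_len(d[3])] <- arr
  out[, , d[3] + 1L] <- mat
  out
}

#' Read a frame stack written by [writeFrameStackTIFF()]
#'
#' @param path TIFF path with its `.json` sidecar alongside.
#' @return a [FrameStack-class].
#' @export
readFrameStackTIFF <- function(path) {
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * sc$scale + sc$offset
  staticF <- NULL
  if (isTRUE(sc$staticFrameLast)) {
    staticF <- arr[, , dim(arr)[3]]
    arr <- arr[, , -dim(arr)[3], drop = FALSE]
  }
  meta <- list()
  if (!is.null(sc$backgroundSubtracted))
    meta$backgroundSubtracted <- sc$backgroundSubtracted
  frameStack(arr, sc$timestamps, staticF, meta)
}

#' Write a frame stack as DMR-dialect text temperature grids
#'
#' One whitespace-separated text matrix of temperatures (degrees C, full
#' precision, row-major) per dynamic frame (`frame_001.txt`, ...), the
#' static frame as `static.txt`, and a `frames.json` sidecar holding the
#' timestamps.  This is the exact round-trip format.
#'
#' @param stack a [FrameStack-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDMRFrames <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack@frames)
  for (i in seq_len(d[3])) {
    utils::write.table(
      format(stack@frames[, , i], digits = 17, scientific = TRUE),
      file.path(dir, sprintf("frame_%03d.txt", i)),
      row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  if (!is.null(stack@staticFrame))
    utils::write.table(
      format(stack@staticFrame, digits = 17, scientific = TRUE),
      file.path(dir, "static.txt"),
      row.names = FALSE, col.names = FALSE, quote = FALSE)
  sidecar <- list(timestamps = stack@timestamps)
  if (is.numeric(stack@meta$backgroundSubtracted))
    sidecar$backgroundSubtracted <- stack@meta$backgroundSubtracted
  jsonlite::write_json(sidecar, file.path(dir, "frames.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a directory of DMR-dialect text temperature grids
#'
#' Reads `frame_*.txt` grids (and `static.txt` when present).  Timestamps
#' come from the `frames.json` sidecar when available, otherwise from
#' `frameInterval`.
#'
#' @param dir directory of per-frame text grids.
#' @param frameInterval fallback seconds between frames (default 15).
#' @return a [FrameStack-class].
#' @export
readDMRFrames <- function(dir, frameInterval = 15) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.txt$",
                           full.names = TRUE))
  if (!length(files)) stop("no frame_*.txt files in ", dir, call. = FALSE)
  mats <- lapply(files, function(f) as.matrix(utils::read.table(f)))
  arr <- array(0, dim = c(dim(mats[[1]]), length(mats)))
  for (i in seq_along(mats)) arr[, , i] <- mats[[i]]
  staticPath <- file.path(dir, "static.txt")
  staticF <- if (file.exists(staticPath))
    as.matrix(utils::read.table(staticPath)) else NULL
  if (!is.null(staticF)) dimnames(staticF) <- NULL
  sidecarPath <- file.path(dir, "frames.json")
  meta <- list()
  if (file.exists(sidecarPath)) {
    sc <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
    ts <- sc$timestamps
    if (is.numeric(sc$backgroundSubtracted))
      meta$backgroundSubtracted <- sc$backgroundSubtracted
  } else {
    ts <- frameInterval * seq_along(files)
  }
  frameStack(arr, ts, staticF, meta)
}

#' Read a binary mask image
#'
#' PNG or TIFF; any pixel above 0.5 (after collapsing color channels) is
#' inside the mask.
#'
#' @param path image path.
#' @param side `"left"` or `"right"`.
#' @param includesSurround whether this is the dilated display mask.
#' @return a [BreastMask-class].
#' @export
readMask <- function(path, side = "left", includesSurround = FALSE) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  breastMask(img > 0.5, side = side, includesSurround = includesSurround)
}

#' Write a binary mask as PNG
#'
#' @param mask a [BreastMask-class] or logical matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  m <- if (is(mask, "BreastMask")) mask@mask else mask
  png::writePNG(m * 1, path)
  invisible(path)
}

#' Write a pixel matrix as CSV
#'
#' Columns: pixel `row`, `col`, then one column per frame (`t<seconds>` for
#' dynamic columns, `static` for the static one).
#'
#' @param pm a [PixelMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePixelMatrixCSV <- function(pm, path) {
  cn <- ifelse(is.na(pm@columnTimes), "static",
               paste0("t", pm@columnTimes))
  df <- data.frame(row = pm@pixelIndex[, 1], col = pm@pixelIndex[, 2])
  df <- cbind(df, as.data.frame(pm@values))
  names(df) <- c("row", "col", cn)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a kernel matrix as a portable text array with JSON header
#'
#' @param kernel a [KernelMatrix-class].
#' @param path output path for the array (whitespace-separated text); the
#'   header goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
writeKernel <- function(kernel, path) {
  utils::write.table(format(kernel@W, digits = 17, scientific = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  hdr <- list(realTimes = kernel@realTimes,
              virtualTimes = kernel@grid@points,
              tMax = kernel@grid@tMax,
              stepsPerOctave = kernel@grid@stepsPerOctave,
              diffusivity = kernel@config@diffusivity,
              lambda = kernel@config@lambda,
              virtualSpeed = kernel@config@virtualSpeed,
              excitationConvolved = !is.null(kernel@excitation))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write virtual wave traces as CSV
#'
#' One row per pixel (`row`, `col`, then one column per virtual time).
#'
#' @param vw a [VirtualWaveMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeVirtualWaveCSV <- function(vw, path) {
  df <- data.frame(row = vw@pixelIndex[, 1], col = vw@pixelIndex[, 2])
  df <- cbind(df, as.data.frame(vw@values))
  names(df) <- c("row", "col", paste0("vt", seq_along(vw@grid@points)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a component image (or any numeric image) as PNG
#'
#' The image is affine-normalized to `[0, 1]`; scale and offset go to a
#' JSON sidecar.
#'
#' @param img numeric matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(img, path) {
  lo <- min(img); hi <- max(img)
  scale <- if (hi > lo) hi - lo else 1
  png::writePNG((img - lo) / scale, path)
  jsonlite::write_json(list(offset = lo, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize / read a phantom scene description
#'
#' YAML (or JSON) representation of a [PhantomSpec-class], so scenes can be
#' version-controlled and passed to the command-line `simulate` entry.
#'
#' @param spec a [PhantomSpec-class].
#' @param path output file (`.yaml`/`.yml` or `.json`).
#' @return `path` invisibly for the writer; a [PhantomSpec-class] for the
#'   reader.
#' @export
writePhantomSpec <- function(spec, path) {
  p <- spec@protocol
  obj <- list(
    imageShape = spec@imageShape,
    diffusivity = spec@diffusivity,
    noiseStd = spec@noiseStd,
    motionJitterPx = spec@motionJitterPx,
    seed = spec@seed,
    protocol = list(
      nDynamicFrames = p@nDynamicFrames, frameInterval = p@frameInterval,
      includeStatic = p@includeStatic,
      skinTempPostCooling = p@skinTempPostCooling,
      skinTempBaseline = p@skinTempBaseline,
      roomTemp = p@roomTemp, coolingDuration = p@coolingDuration),
    vessels = lapply(spec@vessels, function(v) list(
      depth = v@depth, reflectionCoeff = v@reflectionCoeff,
      vasoFastAmplitude = v@vasoFastAmplitude,
      vasoSlowAmplitude = v@vasoSlowAmplitude,
      vasoSlowDelay = v@vasoSlowDelay,
      centerline = apply(v@centerline, 1, function(r) as.list(r),
                         simplify = FALSE),
      width = v@width, vasoTaper = v@vasoTaper,
      baselineWarmth = v@baselineWarmth))
  )
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @param path the scene file to read.
#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  else yaml::read_yaml(path)
  p <- obj$protocol
  prot <- acquisitionProtocol(
    nDynamicFrames = p$nDynamicFrames, frameInterval = p$frameInterval,
    includeStatic = p$includeStatic,
    skinTempPostCooling = p$skinTempPostCooling,
    skinTempBaseline = p$skinTempBaseline,
    roomTemp = p$roomTemp, coolingDuration = p$coolingDuration)
  vessels <- lapply(obj$vessels, function(v) {
    cl <- do.call(rbind, lapply(v$centerline, function(pt)
      c(pt[[1]], pt[[2]])))
    vesselSpec(depth = v$depth, reflectionCoeff = v$reflectionCoeff,
               vasoFastAmplitude = v$vasoFastAmplitude,
               vasoSlowAmplitude = v$vasoSlowAmplitude,
               vasoSlowDelay = v$vasoSlowDelay,
               centerline = cl, width = v$width,
               vasoTaper = unlist(v$vasoTaper),
               baselineWarmth = v$baselineWarmth)
  })
  phantomSpec(imageShape = unlist(obj$imageShape), vessels = vessels,
              diffusivity = obj$diffusivity, protocol = prot,
              noiseStd = obj$noiseStd,
              motionJitterPx = obj$motionJitterPx, seed = obj$seed)
}
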