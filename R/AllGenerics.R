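## Accessor generics. Slot access from user code should go through these.

#' @name thermovasc-accessors
#' @title Accessors for thermovasc data classes
#' @description Small accessor layer over the S4 containers: frame data,
#'   timestamps, matrix values, pixel index maps, virtual time points and
#'   factorization parts.
#' @param x an object of the documented class.
#' @return the slot content named by the accessor.
NULL

#' @rdname thermovasc-accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname thermovasc-accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))
#' @rdname thermovasc-accessors
#' @export
setGeneric("staticFrame", function(x) standardGeneric("staticFrame"))
#' @rdname thermovasc-accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname thermovasc-accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname thermovasc-accessors
#' @export
setGeneric("pixelIndex", function(x) standardGeneric("pixelIndex"))
#' @rdname thermovasc-accessors
#' @export
setGeneric("columnTimes", function(x) standardGeneric("columnTimes"))
#' @rdname thermovasc-accessors
#' @export
setGeneric("virtualTimes", function(x) standardGeneric("virtualTimes"))
#' @rdname thermovasc-accessors
#' @export
setGeneric("imageMatrix", function(x) standardGeneric("imageMatrix"))
#' @rdname thermovasc-accessors
#' @export
setGeneric("timeMatrix", function(x) standardGeneric("timeMatrix"))
#' @rdname thermovasc-accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname thermovasc-accessors
#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))

#' @rdname thermovasc-accessors
setMethod("frames", "FrameStack", function(x) x@frames)
#' @rdname thermovasc-accessors
setMethod("timestamps", "FrameStack", function(x) x@timestamps)
#' @rdname thermovasc-accessors
setMethod("staticFrame", "FrameStack", function(x) x@staticFrame)
#' @rdname thermovasc-accessors
setMethod("maskMatrix", "BreastMask", function(x) x@mask)
#' @rdname thermovasc-accessors
setMethod("values", "PixelMatrix", function(x) x@values)
#' @rdname thermovasc-accessors
setMethod("values", "VirtualWaveMatrix", function(x) x@values)
#' @rdname thermovasc-accessors
setMethod("pixelIndex", "PixelMatrix", function(x) x@pixelIndex)
#' @rdname thermovasc-accessors
setMethod("pixelIndex", "VirtualWaveMatrix", function(x) x@pixelIndex)
#' @rdname thermovasc-accessors
setMethod("columnTimes", "PixelMatrix", function(x) x@columnTimes)
#' @rdname thermovasc-accessors
setMethod("virtualTimes", "VirtualTimeGrid", function(x) x@points)
#' @rdname thermovasc-accessors
setMethod("virtualTimes", "VirtualWaveMatrix", function(x) x@grid@points)
#' @rdname thermovasc-accessors
setMethod("virtualTimes", "KernelMatrix", function(x) x@grid@points)
#' @rdname thermovasc-accessors
setMethod("imageMatrix", "Factorization", function(x) x@imageMatrix)
#' @rdname thermovasc-accessors
setMethod("timeMatrix", "Factorization", function(x) x@timeMatrix)
#' @rdname thermovasc-accessors
setMethod("nComponents", "Factorization", function(x) x@k)
#' @rdname thermovasc-accessors
setMethod("kernelMatrix", "KernelMatrix", function(x) x@W)

setMethod("show", "AcquisitionProtocol", function(object) {
  cat("AcquisitionProtocol:", object@nDynamicFrames, "frames every",
      object@frameInterval, "s",
      if (object@includeStatic) "+ static frame" else "", "\n")
  cat("  cooling to", object@skinTempPostCooling, "degC over",
      object@coolingDuration, "s; baseline", object@skinTempBaseline,
      "degC; room", object@roomTemp, "degC\n")
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat("FrameStack:", d[1], "x", d[2], "pixels,", d[3], "dynamic frames",
      if (!is.null(object@staticFrame)) "+ static frame" else "", "\n")
  cat("  t =", round(min(object@timestamps), 2), "...",
      round(max(object@timestamps), 2), "s after stimulus end;",
      "range", round(min(object@frames), 2), "-",
      round(max(object@frames), 2), "degC\n")
})

setMethod("show", "PixelMatrix", function(object) {
  cat("PixelMatrix:", nrow(object@values), "pixels x",
      ncol(object@values), "columns",
      if (!is.na(object@staticColumn)) "(incl. static)" else "", "\n")
  cat("  background", object@backgroundTemp, "degC subtracted; image shape",
      object@shape[1], "x", object@shape[2], "\n")
})

setMethod("show", "VirtualTimeGrid", function(object) {
  n <- length(object@points)
  cat("VirtualTimeGrid:", n, "points,",
      format(object@points[1], digits = 4), "...",
      format(object@tMax, digits = 4),
      "(", object@stepsPerOctave, "steps/octave )\n")
})

setMethod("show", "KernelMatrix", function(object) {
  cat("KernelMatrix:", nrow(object@W), "real times x", ncol(object@W),
      "virtual times;",
      if (is.null(object@excitation)) "impulse excitation"
      else "excitation-convolved", "\n")
})

setMethod("show", "VirtualWaveMatrix", function(object) {
  cat("VirtualWaveMatrix:", nrow(object@values), "pixels x",
      ncol(object@values), "virtual times\n")
})

setMethod("show", "Factorization", function(object) {
  cat("Factorization (", object@stage, "): ", object@sourceShape[1], " x ",
      object@sourceShape[2], " = image[", nrow(object@imageMatrix), " x ",
      object@k, "] . time[", object@k, " x ", ncol(object@timeMatrix),
      "]\n", sep = "")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", object@imageShape[1], "x", object@imageShape[2],
      "pixels,", length(object@vessels), "vessel(s), noise",
      object@noiseStd, "degC, seed", object@seed, "\n")
})
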