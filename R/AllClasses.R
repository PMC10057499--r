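#' @import methods
#' @importFrom stats fft rnorm sd approx convolve coef lm
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

## ---------------------------------------------------------------------------
## Acquisition protocol
## ---------------------------------------------------------------------------

#' Acquisition protocol for a cold-stress thermography recording
#'
#' Describes the dynamic acquisition the pipeline expects: the skin is cooled
#' by forced airflow until it reaches a target surface temperature, then a
#' time-lapse of calibrated temperature images is recorded at a fixed frame
#' interval, optionally preceded by a static (pre-stimulus) frame.
#'
#' @slot nDynamicFrames number of post-stimulus frames (default 20).
#' @slot frameInterval seconds between frames (default 15).
#' @slot includeStatic whether a pre-stimulus static frame is part of the
#'   acquisition (default `TRUE`).
#' @slot skinTempPostCooling skin surface temperature at the end of cooling,
#'   degrees C (default 32.5).
#' @slot skinTempBaseline pre-stimulus skin surface temperature, degrees C
#'   (default 34.5).
#' @slot roomTemp background room temperature, degrees C (default 21).
#' @slot coolingDuration duration of the cooling stimulus in seconds
#'   (at most 300).
#' @name AcquisitionProtocol-class
#' @rdname AcquisitionProtocol
#' @exportClass AcquisitionProtocol
setClass("AcquisitionProtocol",
  representation(
    nDynamicFrames = "integer",
    frameInterval = "numeric",
    includeStatic = "logical",
    skinTempPostCooling = "numeric",
    skinTempBaseline = "numeric",
    roomTemp = "numeric",
    coolingDuration = "numeric"
  )
)

setValidity("AcquisitionProtocol", function(object) {
  msg <- character()
  if (object@nDynamicFrames < 2L)
    msg <- c(msg, "nDynamicFrames must be >= 2")
  if (object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be > 0")
  if (object@skinTempPostCooling <= object@roomTemp)
    msg <- c(msg, "skinTempPostCooling must exceed roomTemp")
  if (object@coolingDuration <= 0 || object@coolingDuration > 300)
    msg <- c(msg, "coolingDuration must be in (0, 300] seconds")
  if (object@skinTempBaseline <= object@skinTempPostCooling)
    msg <- c(msg, "skinTempBaseline must exceed skinTempPostCooling")
  if (length(msg)) msg else TRUE
})

#' @param nDynamicFrames,frameInterval,includeStatic,skinTempPostCooling,skinTempBaseline,roomTemp,coolingDuration
#'   see slot documentation.
#' @return an `AcquisitionProtocol` object.
#' @examples
#' acquisitionProtocol()                      # the default 20 x 15 s protocol
#' acquisitionProtocol(nDynamicFrames = 40L, frameInterval = 7.5)
#' @rdname AcquisitionProtocol
#' @export
acquisitionProtocol <- function(nDynamicFrames = 20L, frameInterval = 15,
                                includeStatic = TRUE,
                                skinTempPostCooling = 32.5,
                                skinTempBaseline = 34.5,
                                roomTemp = 21, coolingDuration = 300) {
  new("AcquisitionProtocol",
    nDynamicFrames = as.integer(nDynamicFrames),
    frameInterval = as.numeric(frameInterval),
    includeStatic = isTRUE(includeStatic),
    skinTempPostCooling = skinTempPostCooling,
    skinTempBaseline = skinTempBaseline,
    roomTemp = roomTemp,
    coolingDuration = coolingDuration
  )
}

#' Frame timestamps of a protocol
#'
#' Dynamic frame times in seconds measured from the end of the cooling
#' stimulus (`frameInterval`, `2*frameInterval`, ...).
#'
#' @param protocol an [AcquisitionProtocol-class] object.
#' @return numeric vector of length `nDynamicFrames`.
#' @export
protocolTimes <- function(protocol) {
  stopifnot(is(protocol, "AcquisitionProtocol"))
  protocol@frameInterval * seq_len(protocol@nDynamicFrames)
}

## ---------------------------------------------------------------------------
## Excitation profile
## ---------------------------------------------------------------------------

#' Excitation (cooling stimulus) profile
#'
#' A sampled surface stimulus trace. `times` run from stimulus onset (0);
#' `values` are in stimulus units relative to the pre-stimulus baseline, with
#' the fixed sign convention that cooling is negative.
#'
#' @slot times sample times in seconds from stimulus onset, strictly
#'   increasing, first sample at onset.
#' @slot values stimulus values (cooling negative).
#' @name ExcitationProfile-class
#' @rdname ExcitationProfile
#' @exportClass ExcitationProfile
setClass("ExcitationProfile",
  representation(times = "numeric", values = "numeric")
)

setValidity("ExcitationProfile", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(object@times) < 2L)
    msg <- c(msg, "need at least two samples")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (!all(is.finite(object@times)) || !all(is.finite(object@values)))
    msg <- c(msg, "times and values must be finite")
  if (length(msg)) msg else TRUE
})

#' @param times,values see slot documentation.
#' @return an `ExcitationProfile`.
#' @rdname ExcitationProfile
#' @export
excitationProfile <- function(times, values) {
  new("ExcitationProfile", times = as.numeric(times),
      values = as.numeric(values))
}

## ---------------------------------------------------------------------------
## Phantom scene description
## ---------------------------------------------------------------------------

#' Buried-vessel description for the diffusion phantom
#'
#' A vessel is modelled as a plane structure buried at `depth` below the skin
#' surface.  Passively it reflects the diffusing cooling front with
#' reflection coefficient `reflectionCoeff` (R = -1: constant-temperature
#' boundary such as a high-flow vessel, R = +1: insulator).  Actively it is a
#' vasomodulator: its emitted heat flux is reduced in proportion to the
#' stimulus by a fast (neural) and a delayed slow (hormonal) component.
#'
#' @slot depth vessel depth in metres (> 0).
#' @slot reflectionCoeff thermal reflection coefficient in `[-1, 1]`.
#' @slot vasoFastAmplitude dimensionless amplitude (>= 0) of the immediate
#'   neural vasomodulation component, in units of the stimulus amplitude.
#' @slot vasoSlowAmplitude amplitude (>= 0) of the delayed hormonal component.
#' @slot vasoSlowDelay delay of the hormonal component in seconds (>= 0).
#' @slot centerline integer matrix, one `(row, col)` pixel coordinate
#'   (0-based) per row, tracing the vessel across the image.
#' @slot width vessel raster width in whole pixels.
#' @slot vasoTaper per-centerline-point multiplier of the vasomodulation
#'   amplitudes (length 1 or `nrow(centerline)`); real vasomotor tone varies
#'   along a vessel, and a non-uniform taper is what makes the active and
#'   passive signatures spatially distinguishable.
#' @slot baselineWarmth steady-state warm footprint of the vessel at the
#'   surface, degrees C (>= 0); gives static frames realistic structure.
#' @name VesselSpec-class
#' @rdname VesselSpec
#' @exportClass VesselSpec
setClass("VesselSpec",
  representation(
    depth = "numeric",
    reflectionCoeff = "numeric",
    vasoFastAmplitude = "numeric",
    vasoSlowAmplitude = "numeric",
    vasoSlowDelay = "numeric",
    centerline = "matrix",
    width = "integer",
    vasoTaper = "numeric",
    baselineWarmth = "numeric"
  )
)

setValidity("VesselSpec", function(object) {
  msg <- character()
  if (object@depth <= 0) msg <- c(msg, "depth must be > 0")
  if (abs(object@reflectionCoeff) > 1)
    msg <- c(msg, "|reflectionCoeff| must be <= 1")
  if (object@vasoFastAmplitude < 0 || object@vasoSlowAmplitude < 0)
    msg <- c(msg, "vasomodulation amplitudes must be >= 0")
  if (object@vasoSlowDelay < 0) msg <- c(msg, "vasoSlowDelay must be >= 0")
  if (ncol(object@centerline) != 2L || nrow(object@centerline) < 1L)
    msg <- c(msg, "centerline must be an n x 2 (row, col) matrix")
  if (object@width < 1L) msg <- c(msg, "width must be >= 1 pixel")
  if (!length(object@vasoTaper) %in% c(1L, nrow(object@centerline)))
    msg <- c(msg, "vasoTaper must have length 1 or nrow(centerline)")
  if (any(object@vasoTaper < 0)) msg <- c(msg, "vasoTaper must be >= 0")
  if (object@baselineWarmth < 0) msg <- c(msg, "baselineWarmth must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param depth,reflectionCoeff,vasoFastAmplitude,vasoSlowAmplitude,vasoSlowDelay,centerline,width,vasoTaper,baselineWarmth
#'   see slot documentation.
#' @return a `VesselSpec`.
#' @examples
#' v <- vesselSpec(depth = 0.009, reflectionCoeff = -1,
#'                 vasoFastAmplitude = 0.5,
#'                 centerline = cbind(10:40, 25), width = 3)
#' @rdname VesselSpec
#' @export
vesselSpec <- function(depth, reflectionCoeff = -1,
                       vasoFastAmplitude = 0, vasoSlowAmplitude = 0,
                       vasoSlowDelay = 60, centerline, width = 3L,
                       vasoTaper = 1, baselineWarmth = 0) {
  centerline <- as.matrix(centerline)
  storage.mode(centerline) <- "integer"
  dimnames(centerline) <- NULL
  new("VesselSpec",
    depth = depth, reflectionCoeff = reflectionCoeff,
    vasoFastAmplitude = vasoFastAmplitude,
    vasoSlowAmplitude = vasoSlowAmplitude,
    vasoSlowDelay = vasoSlowDelay,
    centerline = centerline, width = as.integer(width),
    vasoTaper = as.numeric(vasoTaper), baselineWarmth = baselineWarmth
  )
}

#' Full synthetic-scene description
#'
#' Everything needed to render a reproducible synthetic cold-stress
#' recording: image geometry, the buried vessels, tissue diffusivity, the
#' acquisition protocol, detector noise and optional frame jitter.
#'
#' @slot imageShape integer `(rows, cols)`.
#' @slot vessels list of [VesselSpec-class] objects.
#' @slot diffusivity thermal diffusivity alpha in m^2/s (default 7.58e-8,
#'   subcutaneous fat).
#' @slot protocol an [AcquisitionProtocol-class].
#' @slot noiseStd additive Gaussian noise per pixel per frame, degrees C
#'   (default 0.2, a typical detector NETD).
#' @slot motionJitterPx max absolute integer per-frame translation, pixels.
#' @slot seed RNG seed making the render reproducible.
#' @name PhantomSpec-class
#' @rdname PhantomSpec
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    imageShape = "integer",
    vessels = "list",
    diffusivity = "numeric",
    protocol = "AcquisitionProtocol",
    noiseStd = "numeric",
    motionJitterPx = "integer",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@imageShape) != 2L || any(object@imageShape < 1L))
    msg <- c(msg, "imageShape must be positive (rows, cols)")
  if (!all(vapply(object@vessels, is, logical(1), "VesselSpec")))
    msg <- c(msg, "vessels must all be VesselSpec objects")
  if (object@diffusivity <= 0) msg <- c(msg, "diffusivity must be > 0")
  if (object@noiseStd < 0) msg <- c(msg, "noiseStd must be >= 0")
  if (object@motionJitterPx < 0L) msg <- c(msg, "motionJitterPx must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param imageShape,vessels,diffusivity,protocol,noiseStd,motionJitterPx,seed
#'   see slot documentation.
#' @return a `PhantomSpec`.
#' @rdname PhantomSpec
#' @export
phantomSpec <- function(imageShape = c(64L, 64L), vessels = list(),
                        diffusivity = 7.58e-8,
                        protocol = acquisitionProtocol(),
                        noiseStd = 0.2, motionJitterPx = 0L, seed = 1L) {
  new("PhantomSpec",
    imageShape = as.integer(imageShape), vessels = vessels,
    diffusivity = diffusivity, protocol = protocol,
    noiseStd = noiseStd, motionJitterPx = as.integer(motionJitterPx),
    seed = as.integer(seed)
  )
}

## ---------------------------------------------------------------------------
## FrameStack and masks
## ---------------------------------------------------------------------------

#' Calibrated temperature image sequence
#'
#' The raw material of the pipeline: a stack of temperature images (degrees
#' C) with timestamps in seconds measured from the end of the cooling
#' stimulus, plus an optional pre-stimulus static frame.
#'
#' @slot frames numeric array `rows x cols x nframes`.
#' @slot timestamps seconds from stimulus end, strictly increasing.
#' @slot staticFrame optional pre-stimulus image (`NULL` if absent).
#' @slot meta free-form list (protocol, background subtraction records,
#'   ground truth for phantoms, ...).
#' @name FrameStack-class
#' @rdname FrameStack
#' @exportClass FrameStack
setClass("FrameStack",
  representation(
    frames = "array",
    timestamps = "numeric",
    staticFrame = "matrixOrNULL",
    meta = "list"
  )
)

setValidity("FrameStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a rows x cols x nframes array")
  else {
    if (length(object@timestamps) != d[3])
      msg <- c(msg, "timestamps must match number of frames")
    if (!is.null(object@staticFrame) &&
        !identical(dim(object@staticFrame), d[1:2]))
      msg <- c(msg, "staticFrame shape must match frames")
  }
  if (any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (!all(is.finite(object@frames)))
    msg <- c(msg, "temperatures must be finite")
  if (length(msg)) msg else TRUE
})

#' @param frames,timestamps,staticFrame,meta see slot documentation.
#' @return a `FrameStack`.
#' @rdname FrameStack
#' @export
frameStack <- function(frames, timestamps, staticFrame = NULL, meta = list()) {
  new("FrameStack", frames = frames, timestamps = as.numeric(timestamps),
      staticFrame = staticFrame, meta = meta)
}

#' Breast segmentation mask
#'
#' A binary mask selecting the pixels of one breast (or of the breast plus
#' its surround, for display).
#'
#' @slot mask logical matrix, same shape as the frames it applies to.
#' @slot side `"left"` or `"right"`.
#' @slot includesSurround whether the mask is the dilated display variant.
#' @name BreastMask-class
#' @rdname BreastMask
#' @exportClass BreastMask
setClass("BreastMask",
  representation(mask = "matrix", side = "character",
                 includesSurround = "logical")
)

setValidity("BreastMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical")
  if (!any(object@mask)) msg <- c(msg, "mask must be non-empty")
  if (!object@side %in% c("left", "right"))
    msg <- c(msg, "side must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' @param mask,side,includesSurround see slot documentation.
#' @return a `BreastMask`.
#' @rdname BreastMask
#' @export
breastMask <- function(mask, side = "left", includesSurround = FALSE) {
  if (!is.logical(mask)) mask <- mask > 0.5
  new("BreastMask", mask = mask, side = side,
      includesSurround = isTRUE(includesSurround))
}

## ---------------------------------------------------------------------------
## Pixel-by-time matrix
## ---------------------------------------------------------------------------

#' Masked pixels-by-time matrix
#'
#' The stacked representation of a recording: one row per masked pixel, one
#' column per frame (static frame last when included), values in degrees C
#' above the subtracted background.  `pixelIndex` maps each matrix row back
#' to its `(row, col)` image coordinate so the stacking is invertible.
#'
#' @slot values numeric matrix `n_pixels x n_columns`.
#' @slot pixelIndex integer matrix `n_pixels x 2` of 1-based `(row, col)`.
#' @slot columnTimes seconds from stimulus end per dynamic column (`NA` for
#'   the static column).
#' @slot staticColumn index of the static column, or `NA`.
#' @slot backgroundTemp background temperature already subtracted, degrees C.
#' @slot shape source image shape `(rows, cols)`.
#' @name PixelMatrix-class
#' @rdname PixelMatrix
#' @exportClass PixelMatrix
setClass("PixelMatrix",
  representation(
    values = "matrix",
    pixelIndex = "matrix",
    columnTimes = "numeric",
    staticColumn = "integer",
    backgroundTemp = "numeric",
    shape = "integer"
  )
)

setValidity("PixelMatrix", function(object) {
  msg <- character()
  if (nrow(object@pixelIndex) != nrow(object@values))
    msg <- c(msg, "pixelIndex must have one row per matrix row")
  if (length(object@columnTimes) != ncol(object@values))
    msg <- c(msg, "columnTimes must have one entry per column")
  if (anyDuplicated(object@pixelIndex))
    msg <- c(msg, "pixelIndex must not contain duplicates")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Virtual time grid, VWT configuration, kernel, virtual-wave matrix
## ---------------------------------------------------------------------------

#' Logarithmic virtual-time grid
#'
#' The virtual time axis t'_i = tMax * 2^((i - N)/stepsPerOctave), i = 1..N:
#' a geometric grid ending exactly at `tMax` with an exact factor of 2 every
#' `stepsPerOctave` points.  With virtual speed c, one-way arrival at t'
#' corresponds to depth c * t'.
#'
#' @slot points virtual times in virtual seconds, strictly increasing.
#' @slot tMax last grid point.
#' @slot stepsPerOctave grid points per octave.
#' @name VirtualTimeGrid-class
#' @rdname VirtualTimeGrid
#' @exportClass VirtualTimeGrid
setClass("VirtualTimeGrid",
  representation(points = "numeric", tMax = "numeric",
                 stepsPerOctave = "integer")
)

setValidity("VirtualTimeGrid", function(object) {
  msg <- character()
  if (any(diff(object@points) <= 0))
    msg <- c(msg, "points must be strictly increasing")
  n <- length(object@points)
  if (n < 2L) msg <- c(msg, "need at least two points")
  if (abs(object@points[n] - object@tMax) > 1e-12 * object@tMax)
    msg <- c(msg, "last point must equal tMax")
  if (length(msg)) msg else TRUE
})

#' Configuration of the virtual wave transform
#'
#' @slot diffusivity thermal diffusivity alpha, m^2/s (default 7.58e-8).
#' @slot lambda regularization parameter (default 0.003), relative to the
#'   largest singular value of the kernel.
#' @slot smoothnessOrder order of the finite-difference smoothness penalty
#'   (default 2: second-derivative Tikhonov operator).
#' @slot virtualSpeed virtual wave speed c in m/s (default 1, so depth in
#'   metres equals one-way virtual time in seconds).
#' @slot useExcitationConvolution convolve kernel rows with the measured or
#'   protocol excitation (for non-impulse stimuli).
#' @slot includeStaticInInversion whether the static column takes part in the
#'   inversion (default `FALSE`; it has no post-stimulus timestamp).
#' @slot mode `"penalty"` (derivative-penalty Tikhonov, the default) or
#'   `"hermite"` (Gauss-Hermite basis projection truncated at
#'   `smoothnessOrder`).
#' @slot svdCutoff relative singular-value cutoff of the solver.
#' @name VWTConfig-class
#' @rdname VWTConfig
#' @exportClass VWTConfig
setClass("VWTConfig",
  representation(
    diffusivity = "numeric",
    lambda = "numeric",
    smoothnessOrder = "integer",
    virtualSpeed = "numeric",
    useExcitationConvolution = "logical",
    includeStaticInInversion = "logical",
    mode = "character",
    svdCutoff = "numeric"
  )
)

setValidity("VWTConfig", function(object) {
  msg <- character()
  if (object@diffusivity <= 0) msg <- c(msg, "diffusivity must be > 0")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (object@virtualSpeed <= 0) msg <- c(msg, "virtualSpeed must be > 0")
  if (object@smoothnessOrder < 0L)
    msg <- c(msg, "smoothnessOrder must be >= 0")
  if (!object@mode %in% c("penalty", "hermite"))
    msg <- c(msg, "mode must be 'penalty' or 'hermite'")
  if (length(msg)) msg else TRUE
})

#' @param diffusivity,lambda,smoothnessOrder,virtualSpeed,useExcitationConvolution,includeStaticInInversion,mode,svdCutoff
#'   see slot documentation.
#' @return a `VWTConfig`.
#' @rdname VWTConfig
#' @export
vwtConfig <- function(diffusivity = 7.58e-8, lambda = 0.003,
                      smoothnessOrder = 2L, virtualSpeed = 1,
                      useExcitationConvolution = TRUE,
                      includeStaticInInversion = FALSE,
                      mode = "penalty", svdCutoff = 1e-12) {
  new("VWTConfig",
    diffusivity = diffusivity, lambda = lambda,
    smoothnessOrder = as.integer(smoothnessOrder),
    virtualSpeed = virtualSpeed,
    useExcitationConvolution = isTRUE(useExcitationConvolution),
    includeStaticInInversion = isTRUE(includeStaticInInversion),
    mode = mode, svdCutoff = svdCutoff
  )
}

#' Diffusion-to-virtual-wave kernel matrix
#'
#' The discretized Fredholm kernel relating a virtual wave signal m(t') to
#' the observed thermal trace T(t): `T = W %*% m`.  Rows are real frame
#' times, columns virtual grid points (quadrature weights included).
#'
#' @slot W numeric matrix `n_real_times x n_virtual_times`.
#' @slot realTimes seconds from stimulus onset.
#' @slot grid the [VirtualTimeGrid-class].
#' @slot config the [VWTConfig-class] used to build the kernel.
#' @slot excitation the excitation the rows were convolved with, or `NULL`.
#' @name KernelMatrix-class
#' @rdname KernelMatrix
#' @exportClass KernelMatrix
setClass("KernelMatrix",
  representation(W = "matrix", realTimes = "numeric",
                 grid = "VirtualTimeGrid", config = "VWTConfig",
                 excitation = "ANY")
)

setValidity("KernelMatrix", function(object) {
  msg <- character()
  if (!all(is.finite(object@W))) msg <- c(msg, "kernel entries must be finite")
  if (nrow(object@W) != length(object@realTimes))
    msg <- c(msg, "one kernel row per real time")
  if (ncol(object@W) != length(object@grid@points))
    msg <- c(msg, "one kernel column per virtual time")
  if (length(msg)) msg else TRUE
})

#' Pixels-by-virtual-time matrix
#'
#' Output of the regularized virtual wave inversion: one virtual wave trace
#' per masked pixel, sharing its `pixelIndex` with the source
#' [PixelMatrix-class].
#'
#' @slot values numeric matrix `n_pixels x n_virtual_times`.
#' @slot pixelIndex as in [PixelMatrix-class].
#' @slot grid the [VirtualTimeGrid-class] of the columns.
#' @slot shape source image shape.
#' @name VirtualWaveMatrix-class
#' @rdname VirtualWaveMatrix
#' @exportClass VirtualWaveMatrix
setClass("VirtualWaveMatrix",
  representation(values = "matrix", pixelIndex = "matrix",
                 grid = "VirtualTimeGrid", shape = "integer")
)

setValidity("VirtualWaveMatrix", function(object) {
  msg <- character()
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (nrow(object@pixelIndex) != nrow(object@values))
    msg <- c(msg, "pixelIndex must have one row per pixel")
  if (ncol(object@values) != length(object@grid@points))
    msg <- c(msg, "one column per virtual time")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Factorization
## ---------------------------------------------------------------------------

#' Product-preserving image/time factorization
#'
#' A paired factorization `imageMatrix %*% timeMatrix` of a pixels-by-time
#' matrix, produced by uncentered PCA (`stage = "pca"`) and transformed by
#' ICA on the time matrix with the inverse rotation applied to the image
#' matrix (`stage = "ica"`), so the product is preserved.
#'
#' @slot imageMatrix `n_pixels x k` spatial weights.
#' @slot timeMatrix `k x n_times` temporal traces.
#' @slot k number of components.
#' @slot sourceShape dimensions `(n_pixels, n_times)` of the factored matrix.
#' @slot stage `"pca"` or `"ica"`.
#' @slot singularValues singular values of the PCA stage (carried along).
#' @name Factorization-class
#' @rdname Factorization
#' @exportClass Factorization
setClass("Factorization",
  representation(
    imageMatrix = "matrix",
    timeMatrix = "matrix",
    k = "integer",
    sourceShape = "integer",
    stage = "character",
    singularValues = "numeric"
  )
)

setValidity("Factorization", function(object) {
  msg <- character()
  if (ncol(object@imageMatrix) != object@k ||
      nrow(object@timeMatrix) != object@k)
    msg <- c(msg, "imageMatrix and timeMatrix must share k components")
  if (object@k > min(object@sourceShape))
    msg <- c(msg, "k must be <= min(source dims)")
  if (!object@stage %in% c("pca", "ica"))
    msg <- c(msg, "stage must be 'pca' or 'ica'")
  if (length(msg)) msg else TRUE
})
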