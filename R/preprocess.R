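## From raw frame sequence to the masked pixels-by-time matrix:
## motion correction, background subtraction, stacking, excitation recovery.

## integer translation of img relative to ref by windowed phase
## correlation: returns (dy, dx) such that img ~= ref translated by (dy, dx)
phaseCorrShift <- function(ref, img) {
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  w <- outer(hann(nrow(ref)), hann(ncol(ref)))
  F1 <- stats::fft((ref - mean(ref)) * w)
  F2 <- stats::fft((img - mean(img)) * w)
  R <- F1 * Conj(F2)
  den <- Mod(R)
  den[den < .Machine$double.eps] <- 1
  r <- Re(stats::fft(R / den, inverse = TRUE))
  pk <- arrayInd(which.max(r), dim(r)) - 1L
  nr <- nrow(ref); nc <- ncol(ref)
  dy <- pk[1]; dx <- pk[2]
  if (dy > nr %/% 2) dy <- dy - nr
  if (dx > nc %/% 2) dx <- dx - nc
  c(-dy, -dx)
}

#' Rigid motion correction of a frame stack
#'
#' Estimates a per-frame integer translation by phase correlation against a
#' reference frame (the static frame by default, falling back to the first
#' dynamic frame) and shifts every frame back into alignment.  Border
#' pixels exposed by shifting are marked invalid in the returned mask so
#' they can be excluded from downstream analysis masks.
#'
#' @param stack a [FrameStack-class].
#' @param reference `"static"` (default; falls back to first frame when no
#'   static frame exists) or `"first"`.
#' @return list with elements `stack` (the aligned [FrameStack-class]),
#'   `shifts` (an `nframes x 2` matrix of the `(dy, dx)` translations that
#'   were removed) and `validMask` (logical matrix of pixels untouched by
#'   border fill in every frame).
#' @export
registerFrames <- function(stack, reference = c("static", "first")) {
  reference <- match.arg(reference)
  fr <- stack@frames
  d <- dim(fr)
  ref <- if (reference == "static" && !is.null(stack@staticFrame))
    stack@staticFrame else fr[, , 1]
  degenerateRef <- sd(as.vector(ref)) < .Machine$double.eps
  shifts <- matrix(0L, d[3], 2L)
  valid <- matrix(TRUE, d[1], d[2])
  out <- fr
  for (f in seq_len(d[3])) {
    img <- fr[, , f]
    if (degenerateRef || sd(as.vector(img)) < .Machine$double.eps) {
      warning("degenerate (constant) frame; registration skipped, zero shift")
      next
    }
    s <- phaseCorrShift(ref, img)
    shifts[f, ] <- as.integer(s)
    if (any(s != 0L)) {
      out[, , f] <- shiftMatrix(img, -s[1], -s[2], fill = mean(img))
      vm <- shiftMatrix(matrix(TRUE, d[1], d[2]), -s[1], -s[2], fill = FALSE)
      valid <- valid & vm
    }
  }
  aligned <- frameStack(out, stack@timestamps, stack@staticFrame,
                        meta = c(stack@meta, list(registrationShifts = shifts)))
  list(stack = aligned, shifts = shifts, validMask = valid)
}

#' Subtract the background room temperature
#'
#' Reduces every pixel of every frame (static frame included) by a constant
#' background temperature; the amount is recorded in the stack metadata, so
#' the operation is invertible by applying it again with the negated value.
#'
#' @param stack a [FrameStack-class].
#' @param backgroundTemp degrees C to subtract (default 21).
#' @return the adjusted [FrameStack-class].
#' @export
subtractBackground <- function(stack, backgroundTemp = 21) {
  prev <- stack@meta$backgroundSubtracted
  meta <- stack@meta
  meta$backgroundSubtracted <- (if (is.null(prev)) 0 else prev) +
    backgroundTemp
  st <- stack@staticFrame
  if (!is.null(st)) st <- st - backgroundTemp
  frameStack(stack@frames - backgroundTemp, stack@timestamps, st, meta)
}

#' Stack masked frames into a pixels-by-time matrix
#'
#' Rows are the masked pixels in raster (row-major) order, columns the
#' frames in time order with the static frame last when included.  The
#' mapping back to image coordinates is retained in `pixelIndex`, making the
#' stacking invertible (see [matrixToStack()]).
#'
#' @param stack a [FrameStack-class].
#' @param mask a [BreastMask-class] (or logical matrix) of the pixels to
#'   keep.
#' @param includeStatic append the static frame as the final column
#'   (default `TRUE` when the stack has one).
#' @return a [PixelMatrix-class].
#' @export
stackToMatrix <- function(stack, mask, includeStatic = TRUE) {
  m <- if (is(mask, "BreastMask")) mask@mask else mask
  d <- dim(stack@frames)
  if (!identical(dim(m), d[1:2]))
    stop("mask shape must match the frames", call. = FALSE)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  ## row-major raster order of masked pixels
  idx <- which(t(m))
  cols0 <- (idx - 1L) %% d[2] + 1L
  rows0 <- (idx - 1L) %/% d[2] + 1L
  pixelIndex <- cbind(row = rows0, col = cols0)
  lin <- (cols0 - 1L) * d[1] + rows0
  vals <- matrix(0, nrow(pixelIndex), d[3])
  for (f in seq_len(d[3])) vals[, f] <- stack@frames[, , f][lin]
  columnTimes <- stack@timestamps
  staticCol <- NA_integer_
  if (includeStatic && !is.null(stack@staticFrame)) {
    vals <- cbind(vals, stack@staticFrame[lin])
    columnTimes <- c(columnTimes, NA_real_)
    staticCol <- ncol(vals)
  }
  bg <- stack@meta$backgroundSubtracted
  new("PixelMatrix", values = vals, pixelIndex = pixelIndex,
      columnTimes = columnTimes, staticColumn = staticCol,
      backgroundTemp = if (is.null(bg)) 0 else bg,
      shape = as.integer(d[1:2]))
}

#' Scatter a pixel matrix back into a frame stack
#'
#' Inverse of [stackToMatrix()] on the masked pixels; pixels outside the
#' mask are filled with `fill`.
#'
#' @param pm a [PixelMatrix-class].
#' @param fill value for unmasked pixels (default 0).
#' @return a [FrameStack-class].
#' @export
matrixToStack <- function(pm, fill = 0) {
  d <- pm@shape
  dynCols <- setdiff(seq_len(ncol(pm@values)), pm@staticColumn)
  nt <- length(dynCols)
  fr <- array(fill, dim = c(d[1], d[2], nt))
  lin <- (pm@pixelIndex[, 2] - 1L) * d[1] + pm@pixelIndex[, 1]
  for (j in seq_len(nt)) {
    img <- matrix(fill, d[1], d[2])
    img[lin] <- pm@values[, dynCols[j]]
    fr[, , j] <- img
  }
  staticF <- NULL
  if (!is.na(pm@staticColumn)) {
    staticF <- matrix(fill, d[1], d[2])
    staticF[lin] <- pm@values[, pm@staticColumn]
  }
  frameStack(fr, pm@columnTimes[dynCols], staticF,
             meta = list(backgroundSubtracted = pm@backgroundTemp))
}

#' Estimate the excitation footprint from masked data
#'
#' Returns the spatial-mean temperature trace over the masked pixels,
#' re-zeroed to its asymptotic (last-frame) value, so that a cooling
#' stimulus yields negative values recovering towards zero.  This is the
#' data-driven estimate of the stimulus footprint at the skin surface; times
#' are seconds from stimulus end, as in the source matrix.
#'
#' @param pm a [PixelMatrix-class] with at least one pixel.
#' @return an [ExcitationProfile-class].
#' @export
extractExcitation <- function(pm) {
  dynCols <- setdiff(seq_len(ncol(pm@values)), pm@staticColumn)
  tr <- colMeans(pm@values[, dynCols, drop = FALSE])
  excitationProfile(pm@columnTimes[dynCols], tr - tr[length(tr)])
}
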