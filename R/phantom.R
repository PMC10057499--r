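## Synthetic cold-stress scene rendering with known ground truth.

#' Rasterize a vessel onto an image grid
#'
#' Stamps an anti-aliasing-free hard mask of the vessel: a `width x width`
#' square neighborhood around every (0-based) centerline point.  Also
#' returns the per-pixel vasomodulation taper (each pixel takes the taper of
#' the centerline point that stamped it last).
#'
#' @param vessel a [VesselSpec-class].
#' @param shape integer `(rows, cols)`.
#' @return list with logical `mask` and numeric `taper` matrices.
#' @export
rasterizeVessel <- function(vessel, shape) {
  rows <- shape[1]; cols <- shape[2]
  mask <- matrix(FALSE, rows, cols)
  taper <- matrix(0, rows, cols)
  half <- (vessel@width - 1L) %/% 2L
  tpr <- rep_len(vessel@vasoTaper, nrow(vessel@centerline))
  for (i in seq_len(nrow(vessel@centerline))) {
    r0 <- vessel@centerline[i, 1] + 1L   # to 1-based
    c0 <- vessel@centerline[i, 2] + 1L
    rr <- (r0 - half):(r0 + half + (vessel@width - 1L) %% 2L)
    cc <- (c0 - half):(c0 + half + (vessel@width - 1L) %% 2L)
    if (any(rr < 1L) || any(rr > rows) || any(cc < 1L) || any(cc > cols))
      stop("vessel extends outside the image", call. = FALSE)
    mask[rr, cc] <- TRUE
    taper[rr, cc] <- tpr[i]
  }
  list(mask = mask, taper = taper)
}

## integer-shift a matrix, filling exposed borders
shiftMatrix <- function(m, dy, dx, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  srcR <- seq_len(nr) - dy; srcC <- seq_len(nc) - dx
  okR <- srcR >= 1L & srcR <= nr; okC <- srcC >= 1L & srcC <= nc
  out[okR, okC] <- m[srcR[okR], srcC[okC]]
  out
}

#' Render a synthetic dynamic thermogram with known ground truth
#'
#' Produces the frame sequence a cold-stress acquisition of the scene would
#' record.  Every pixel's dynamic trace is the vessel-free background
#' response to the cooling stimulus; pixels covered by a vessel add the
#' vessel's passive reflection echo and its active vasomodulation signature
#' (scaled by the local taper).  Seeded Gaussian detector noise, optional
#' per-frame integer motion jitter, protocol-consistent timestamps and a
#' pre-stimulus static frame complete the emulation.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [FrameStack-class]; `meta(stack)$groundTruth` records the spec,
#'   the per-frame jitter shifts actually applied, per-vessel rasters, and
#'   the excitation profile.
#' @examples
#' v <- vesselSpec(depth = 0.009, reflectionCoeff = -1,
#'                 vasoFastAmplitude = 0.5,
#'                 centerline = cbind(16:48, 32), width = 3)
#' stk <- renderPhantom(phantomSpec(c(64L, 64L), list(v), noiseStd = 0))
#' stk
#' @export
renderPhantom <- function(spec) {
  validObject(spec)
  prot <- spec@protocol
  alpha <- spec@diffusivity
  rows <- spec@imageShape[1]; cols <- spec@imageShape[2]
  npix <- rows * cols
  tRel <- protocolTimes(prot)
  tAbs <- tRel + prot@coolingDuration
  excitation <- makeExcitation(prot, "step")

  ## vessel-free background: direct semi-infinite response to the stimulus
  flux <- excitationFluxProfile(excitation, alpha)
  bg <- convolveExcitation(flux, function(t) planeSourceResponse(t, 0, alpha),
                           tAbs)

  nt <- length(tRel)
  base <- prot@skinTempBaseline
  ## traces matrix: npix x nt, start everything at baseline + background
  traces <- matrix(rep(bg, each = npix), npix, nt) + base
  warmth <- matrix(0, rows, cols)

  rasters <- vector("list", length(spec@vessels))
  for (vi in seq_along(spec@vessels)) {
    v <- spec@vessels[[vi]]
    ras <- rasterizeVessel(v, spec@imageShape)
    rasters[[vi]] <- ras
    refl <- surfaceResponse(v@depth, v@reflectionCoeff, alpha, excitation,
                            tAbs) - bg
    vaso <- vasomodulationResponse(v, alpha, excitation, tAbs)
    idx <- which(ras$mask)
    if (length(idx)) {
      traces[idx, ] <- traces[idx, , drop = FALSE] +
        rep(refl, each = length(idx)) +
        outer(ras$taper[idx], vaso)
      warmth[idx] <- warmth[idx] + v@baselineWarmth
    }
  }
  traces <- traces + as.vector(warmth)

  set.seed(spec@seed)
  framesArr <- array(traces, dim = c(rows, cols, nt))
  if (spec@noiseStd > 0)
    framesArr <- framesArr + array(rnorm(npix * nt, sd = spec@noiseStd),
                                   dim = c(rows, cols, nt))

  shifts <- matrix(0L, nt, 2L)
  if (spec@motionJitterPx > 0L) {
    j <- spec@motionJitterPx
    shifts[] <- sample(seq(-j, j), 2L * nt, replace = TRUE)
    for (f in seq_len(nt))
      framesArr[, , f] <- shiftMatrix(framesArr[, , f], shifts[f, 1],
                                      shifts[f, 2], fill = base)
  }

  staticF <- NULL
  if (prot@includeStatic) {
    staticF <- matrix(base, rows, cols) + warmth
    if (spec@noiseStd > 0)
      staticF <- staticF + matrix(rnorm(npix, sd = spec@noiseStd), rows, cols)
  }

  frameStack(framesArr, tRel, staticF,
    meta = list(groundTruth = list(
      spec = spec, jitterShifts = shifts, rasters = rasters,
      excitation = excitation, backgroundTrace = bg,
      absoluteTimes = tAbs
    ), protocol = prot))
}
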