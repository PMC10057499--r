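## Canonical demonstration scenes.  These fix the study conditions used
## throughout the documentation and the validation suite: vessels at the
## 9 mm and 13 mm depths of interest, total negative reflection (R = -1,
## constant-temperature vessel boundaries), vasomodulation amplitudes of a
## few tenths of the stimulus with a 60 s hormonal delay, and a vasomotor
## tone that varies along the vessel (taper 0.2..1.8) - the along-vessel
## variability that makes active and passive signatures spatially
## distinguishable and is itself the clinically interesting quantity.

#' Canonical phantom scenes
#'
#' Ready-made [PhantomSpec-class] scenes on a 64 x 64 grid used by the
#' package documentation and validation:
#' \describe{
#'   \item{`single9`}{one vessel at 9 mm depth (column 32), R = -1, fast
#'     vasomodulation amplitude 0.5, slow 0.2 delayed 60 s, taper
#'     0.2..1.8.}
#'   \item{`single13`}{the same vessel at 13 mm.}
#'   \item{`twoVessel`}{the 9 mm vessel (column 20) plus a 13 mm vessel
#'     (column 44, amplitudes 0.3/0.15, reversed taper).}
#'   \item{`deficit`}{the 9 mm vasomodulating vessel plus a second 9 mm
#'     vessel whose vasomodulation amplitudes are zero - the
#'     vasoconstriction-deficit scene.  Equal depths give both vessels
#'     passive echoes of equal strength, so the deficit map contrast
#'     reflects vasomotor function alone.}
#'   \item{`registration`}{two curved vessels with strong steady warm
#'     footprints: the two-dimensional image structure motion correction
#'     needs (a straight vessel is translation-invariant along its own
#'     axis).}
#' }
#'
#' @param type scene name.
#' @param noiseStd detector noise, degrees C (default 0: the noiseless
#'   variants used for method validation; 0.2 is the realistic NETD).
#' @param seed phantom seed.
#' @param motionJitterPx per-frame jitter amplitude in pixels (default 0).
#' @return a [PhantomSpec-class].
#' @examples
#' demoScene("single9")
#' demoScene("twoVessel", noiseStd = 0.2, seed = 3L)
#' @export
demoScene <- function(type = c("single9", "single13", "twoVessel",
                               "deficit", "registration"),
                      noiseStd = 0, seed = 1L, motionJitterPx = 0L) {
  type <- match.arg(type)
  rows <- 10:53
  taperUp <- seq(0.2, 1.8, length.out = length(rows))
  ## a 0.5 degC steady warm footprint gives static frames realistic vessel
  ## structure (needed by registration); the static-baseline subtraction
  ## before inversion removes it from the dynamic analysis
  mkv <- function(depth, col, fast = 0.5, slow = 0.2,
                  taper = taperUp, warmth = 0.5)
    vesselSpec(depth = depth, reflectionCoeff = -1,
               vasoFastAmplitude = fast, vasoSlowAmplitude = slow,
               vasoSlowDelay = 60, centerline = cbind(rows, col),
               width = 3L, vasoTaper = taper, baselineWarmth = warmth)
  vessels <- switch(type,
    single9 = list(mkv(0.009, 32L)),
    single13 = list(mkv(0.013, 32L)),
    twoVessel = list(mkv(0.009, 20L),
                     mkv(0.013, 44L, fast = 0.3, slow = 0.15,
                         taper = rev(taperUp))),
    ## uniform tone on the functioning vessel: the zero-vaso vessel supplies
    ## the spatial contrast that separates active from passive signatures
    deficit = list(mkv(0.009, 20L, taper = 1),
                   mkv(0.009, 44L, fast = 0, slow = 0, taper = 1)),
    registration = {
      r2 <- 8:55
      curve1 <- cbind(r2, as.integer(round(14 + 0.55 * (r2 - 8) +
                                             6 * sin((r2 - 8) / 7))))
      curve2 <- cbind(r2, as.integer(round(50 - 0.5 * (r2 - 8) +
                                             4 * cos((r2 - 8) / 5))))
      list(vesselSpec(0.009, -1, 0.5, 0.2, 60, curve1, 3L,
                      vasoTaper = seq(0.2, 1.8, length.out = nrow(curve1)),
                      baselineWarmth = 1),
           vesselSpec(0.013, -1, 0.3, 0.15, 60, curve2, 3L,
                      vasoTaper = 1, baselineWarmth = 0.8))
    }
  )
  phantomSpec(imageShape = c(64L, 64L), vessels = vessels,
              noiseStd = noiseStd, motionJitterPx = motionJitterPx,
              seed = seed)
}
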