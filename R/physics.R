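## 1-D heat-diffusion physics behind the phantom generator.
##
## Model: semi-infinite medium z >= 0 with diffusivity alpha, units chosen so
## volumetric heat capacity rho*c = 1 and conductivity k = alpha.  The cooling
## stimulus is a surface heat flux e(t) (cooling negative).  The surface
## Green's function of a plane impulse source at depth z, observed at the
## (otherwise insulated) surface, is
##     g(t, z) = exp(-z^2 / (4 alpha t)) / sqrt(pi alpha t),   t > 0.

## impulse surface response of a plane source at depth z (vector over t)
planeSourceResponse <- function(t, z, alpha) {
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  out[pos] <- exp(-z^2 / (4 * alpha * tp)) / sqrt(pi * alpha * tp)
  out
}

## evaluate an ExcitationProfile at arbitrary times; zero outside its support
excitationAt <- function(excitation, t) {
  v <- stats::approx(excitation@times, excitation@values, xout = t,
                     yleft = 0, yright = 0, rule = 2)$y
  v[t < min(excitation@times) | t > max(excitation@times)] <- 0
  v
}

## trapezoid quadrature weights for an arbitrary strictly increasing grid
trapezoidWeights <- function(x) {
  n <- length(x)
  if (n == 1L) return(1)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}

## convolve an excitation with an analytic impulse response h(t) evaluated
## as responseFun(tvec); returns the response at `times` (from onset)
convolveExcitation <- function(excitation, responseFun, times) {
  tau <- excitation@times
  w <- trapezoidWeights(tau) * excitation@values
  vapply(times, function(tj) sum(w * responseFun(tj - tau)), numeric(1))
}

#' Build a cooling excitation profile
#'
#' Samples the surface stimulus implied by an acquisition protocol, in
#' degrees C relative to the pre-stimulus baseline (cooling negative).  A
#' `"step"` is the constant value `-(skinTempBaseline -
#' skinTempPostCooling)` over the cooling window; a `"ramp"` rises linearly
#' to that value; `"measured"` passes a supplied profile through unchanged.
#'
#' @param protocol an [AcquisitionProtocol-class].
#' @param kind `"step"`, `"ramp"` or `"measured"`.
#' @param nSamples number of samples over the cooling window.
#' @param profile an [ExcitationProfile-class], required for
#'   `kind = "measured"`.
#' @return an [ExcitationProfile-class]; cooling values are negative.
#' @examples
#' e <- makeExcitation(acquisitionProtocol(), "step")
#' range(e@values)   # constant -2 degC
#' @export
makeExcitation <- function(protocol, kind = c("step", "ramp", "measured"),
                           nSamples = 256L, profile = NULL) {
  kind <- match.arg(kind)
  if (kind == "measured") {
    if (is.null(profile))
      stop("kind = 'measured' requires a profile", call. = FALSE)
    return(profile)
  }
  Tc <- protocol@coolingDuration
  dT <- protocol@skinTempBaseline - protocol@skinTempPostCooling
  tt <- seq(0, Tc, length.out = nSamples)
  vals <- switch(kind,
    step = rep(-dT, nSamples),
    ramp = -dT * tt / Tc
  )
  excitationProfile(tt, vals)
}

## Convert a degrees-C excitation profile into surface-flux units.  The
## convention: a step profile of value -dT over its support [0, Tc], applied
## as flux q = kappa * value, depresses the vessel-free surface by dT at the
## end of the window (step-flux solution T(0,t) = 2 q sqrt(t/(pi alpha))).
## The kernel normalizes the excitation to unit area, so kappa cancels in
## the inversion; it only fixes the phantom's absolute temperature scale.
excitationFluxProfile <- function(excitation, alpha) {
  Tc <- max(excitation@times) - min(excitation@times)
  kappa <- 1 / (2 * sqrt(Tc / (pi * alpha)))
  excitationProfile(excitation@times, excitation@values * kappa)
}

#' Surface temperature response over a buried reflecting boundary
#'
#' Method-of-images solution for the surface temperature perturbation of a
#' 1-D semi-infinite medium containing one plane reflector at `depth`:
#' the direct (semi-infinite) response plus image sources at effective
#' depths `2*k*depth` weighted by `R^k`, convolved with the excitation.
#' The series is truncated once a term falls below 1e-6 of the direct term.
#'
#' A constant-temperature boundary (R = -1) returns an echo of polarity
#' opposite to the stimulus; an insulator (R = +1) echoes with the stimulus
#' polarity.
#'
#' @param depth reflector depth in metres (> 0).
#' @param R thermal reflection coefficient in `[-1, 1]`.
#' @param alpha thermal diffusivity, m^2/s.
#' @param excitation an [ExcitationProfile-class] (surface flux, cooling
#'   negative).
#' @param times observation times in seconds from stimulus onset, strictly
#'   increasing.
#' @return numeric trace of surface temperature perturbation, degrees C.
#' @seealso [fdSolve1D()] for the independent finite-difference solution.
#' @export
surfaceResponse <- function(depth, R, alpha, excitation, times) {
  if (depth <= 0 || alpha <= 0)
    stop("depth and alpha must be positive", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  tmax <- max(times)
  terms <- list(function(t) planeSourceResponse(t, 0, alpha))
  if (R != 0) {
    for (k in seq_len(200L)) {
      peak <- abs(R)^k * exp(-(2 * k * depth)^2 / (4 * alpha * tmax))
      if (peak < 1e-6) break
      zk <- 2 * k * depth
      Rk <- R^k
      terms[[length(terms) + 1L]] <- local({
        zk <- zk; Rk <- Rk
        function(t) 2 * Rk * planeSourceResponse(t, zk, alpha)
      })
    }
  }
  h <- function(t) Reduce(`+`, lapply(terms, function(f) f(t)))
  convolveExcitation(excitationFluxProfile(excitation, alpha), h, times)
}

#' Surface signature of active vasomodulation
#'
#' Models a vessel as a buried plane heat source whose emitted flux is
#' reduced in proportion to the stimulus: an immediate (neural) component of
#' amplitude `vasoFastAmplitude` and a delayed (hormonal) component of
#' amplitude `vasoSlowAmplitude` lagging by `vasoSlowDelay` seconds.  The
#' flux change diffuses one way from the vessel depth to the surface, so the
#' resulting trace has the same polarity as the stimulus and a one-way
#' virtual arrival time.
#'
#' @param vessel a [VesselSpec-class].
#' @param alpha thermal diffusivity, m^2/s.
#' @param excitation an [ExcitationProfile-class].
#' @param times observation times in seconds from stimulus onset.
#' @return numeric trace of surface temperature perturbation, degrees C.
#' @export
vasomodulationResponse <- function(vessel, alpha, excitation, times) {
  fa <- vessel@vasoFastAmplitude
  fs <- vessel@vasoSlowAmplitude
  if (fa == 0 && fs == 0) return(numeric(length(times)))
  d <- vessel@depth
  g <- function(t) planeSourceResponse(t, d, alpha)
  flux <- excitationFluxProfile(excitation, alpha)
  out <- numeric(length(times))
  if (fa > 0)
    out <- out + fa * convolveExcitation(flux, g, times)
  if (fs > 0) {
    delayed <- excitationProfile(flux@times + vessel@vasoSlowDelay,
                                 flux@values)
    out <- out + fs * convolveExcitation(delayed, g, times)
  }
  out
}
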