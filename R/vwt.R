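## The virtual wave transform: kernel construction and regularized
## ill-posed inversion of pixel thermal traces into virtual wave traces.

#' Build the logarithmic virtual-time grid
#'
#' `t'_i = tMax * 2^((i - N)/stepsPerOctave)`, `i = 1..N`.
#'
#' @param N number of points (default 100).
#' @param tMax largest virtual time (default 0.025 virtual seconds; with
#'   virtual speed 1 m/s this spans depths up to 25 mm two-way 12.5 mm).
#' @param stepsPerOctave points per factor-of-two (default 20).
#' @return a [VirtualTimeGrid-class].
#' @examples
#' g <- buildVirtualGrid()
#' virtualTimes(g)[100]          # 0.025
#' virtualTimes(g)[80]           # exactly one octave below
#' @export
buildVirtualGrid <- function(N = 100L, tMax = 0.025, stepsPerOctave = 20L) {
  if (N < 2L || tMax <= 0 || stepsPerOctave < 1L)
    stop("grid parameters must be positive (N >= 2)", call. = FALSE)
  pts <- tMax * 2^((seq_len(N) - N) / stepsPerOctave)
  new("VirtualTimeGrid", points = pts, tMax = tMax,
      stepsPerOctave = as.integer(stepsPerOctave))
}

#' Build the diffusion-to-virtual-wave kernel matrix
#'
#' Discretizes the Fredholm kernel
#' `K(t, t') = (c / sqrt(pi alpha t)) * exp(-c^2 t'^2 / (4 alpha t))`
#' relating a virtual wave signal to the observed thermal trace, including
#' the trapezoid quadrature weights of the logarithmic virtual grid.  When
#' an excitation is supplied and the configuration enables it, rows are
#' additionally convolved with the excitation normalized to unit area, so
#' non-impulse (e.g. fan-cooling step) protocols map virtual arrivals to the
#' same virtual times an impulse would.
#'
#' @param realTimes observation times in seconds from stimulus onset,
#'   strictly increasing and positive.
#' @param grid a [VirtualTimeGrid-class].
#' @param config a [VWTConfig-class].
#' @param excitation optional [ExcitationProfile-class].
#' @return a [KernelMatrix-class].
#' @export
buildKernel <- function(realTimes, grid = buildVirtualGrid(),
                        config = vwtConfig(), excitation = NULL) {
  if (any(realTimes <= 0)) stop("real times must be > 0", call. = FALSE)
  if (any(diff(realTimes) <= 0))
    stop("real times must be strictly increasing", call. = FALSE)
  alpha <- config@diffusivity
  cc <- config@virtualSpeed
  tp <- grid@points
  k0 <- function(t) {
    ## matrix over (t values) x (virtual times); zero for t <= 0
    out <- matrix(0, length(t), length(tp))
    pos <- t > 0
    if (any(pos)) {
      tt <- t[pos]
      out[pos, ] <- (cc / sqrt(pi * alpha * tt)) *
        exp(-outer(1 / (4 * alpha * tt), (cc * tp)^2))
    }
    out
  }
  convolved <- !is.null(excitation) && config@useExcitationConvolution
  if (convolved) {
    tau <- excitation@times
    w <- trapezoidWeights(tau) * excitation@values
    area <- sum(w)
    if (abs(area) < .Machine$double.eps)
      stop("excitation has zero area; cannot normalize", call. = FALSE)
    w <- w / area
    W <- matrix(0, length(realTimes), length(tp))
    for (j in seq_along(realTimes))
      W[j, ] <- colSums(w * k0(realTimes[j] - tau))
  } else {
    W <- k0(realTimes)
  }
  W <- sweep(W, 2L, trapezoidWeights(tp), `*`)
  new("KernelMatrix", W = W, realTimes = as.numeric(realTimes), grid = grid,
      config = config, excitation = if (convolved) excitation else NULL)
}

## order-n difference operator on N points with zero-Dirichlet padding:
## the derivative is taken on the grid extended by one zero sample at each
## end, so boundary values are penalized too.  Without the padding, ramps at
## the grid edge have zero second derivative and the ill-posed inversion
## piles late-arriving echo energy onto the last virtual time.
diffOperator <- function(N, order) {
  if (order == 0L) return(diag(N))
  L <- diff(diag(N + 2L), differences = order)
  L[, 2:(N + 1L), drop = FALSE]
}

## Gauss-Hermite function basis over the (standardized log) virtual axis
hermiteBasis <- function(tp, order) {
  x <- scale(log(tp))[, 1] * 1.5
  B <- matrix(0, length(tp), order + 1L)
  Hprev <- rep(1, length(tp)); Hcur <- 2 * x
  for (k in 0:order) {
    H <- if (k == 0L) Hprev else if (k == 1L) Hcur else {
      Hnew <- 2 * x * Hcur - 2 * (k - 1) * Hprev
      Hprev <- Hcur; Hcur <- Hnew
      Hnew
    }
    B[, k + 1L] <- H * exp(-x^2 / 2)
  }
  B
}

## minimum-norm least squares via SVD with relative cutoff
svdSolveOperator <- function(A, cutoff) {
  sv <- svd(A)
  keep <- sv$d > cutoff * sv$d[1]
  list(P = sv$v[, keep, drop = FALSE] %*%
         (t(sv$u[, keep, drop = FALSE]) / sv$d[keep]),
       rank = sum(keep), d = sv$d)
}

#' Regularized virtual wave inversion
#'
#' Converts each pixel's thermal trace into a virtual wave trace by solving,
#' per pixel,
#' `min_m ||T - W m||^2 + (lambda * sigma1(W))^2 ||L_n m||^2`
#' where `L_n` is the order-`smoothnessOrder` finite-difference derivative
#' operator (`n = 2`: second-derivative penalty) and `sigma1(W)` the largest
#' singular value of the kernel, making `lambda` dimensionless.  The
#' augmented system is solved by SVD with a relative singular-value cutoff,
#' so the result is deterministic.  In `mode = "hermite"` the solution is
#' instead projected on a Gauss-Hermite function basis truncated at
#' `smoothnessOrder`.
#'
#' The static column never enters the inversion directly (it has no
#' post-stimulus time); with `includeStaticInInversion = TRUE` it is used as
#' a per-pixel baseline subtracted from the dynamic columns first.
#'
#' @param pm a [PixelMatrix-class] whose dynamic columns correspond, in
#'   order, to `kernel@realTimes`.
#' @param kernel a [KernelMatrix-class].
#' @param config a [VWTConfig-class]; defaults to the kernel's.
#' @return a [VirtualWaveMatrix-class].
#' @seealso [forwardApply()] for residual checks, [vwtConditionNumber()]
#'   for the conditioning of the regularized system.
#' @export
vwtInvert <- function(pm, kernel, config = kernel@config) {
  dynCols <- setdiff(seq_len(ncol(pm@values)), pm@staticColumn)
  if (length(dynCols) != nrow(kernel@W))
    stop("dynamic columns do not match kernel real times", call. = FALSE)
  dt <- pm@columnTimes[dynCols]
  if (all(is.finite(dt)) &&
      any(abs(diff(dt) - diff(kernel@realTimes)) >
            1e-6 * max(kernel@realTimes)))
    stop("frame spacing does not match kernel real times", call. = FALSE)
  Y <- pm@values[, dynCols, drop = FALSE]
  if (config@includeStaticInInversion && !is.na(pm@staticColumn))
    Y <- Y - pm@values[, pm@staticColumn]
  W <- kernel@W
  N <- ncol(W)
  if (config@mode == "hermite") {
    B <- hermiteBasis(kernel@grid@points, config@smoothnessOrder)
    sol <- svdSolveOperator(W %*% B, config@svdCutoff)
    M <- Y %*% t(B %*% sol$P)
  } else {
    s1 <- svd(W, nu = 0, nv = 0)$d[1]
    L <- diffOperator(N, config@smoothnessOrder)
    A <- rbind(W, config@lambda * s1 * L)
    sol <- svdSolveOperator(A, config@svdCutoff)
    if (config@lambda == 0 && sol$rank < N)
      warning("lambda = 0 with rank-deficient kernel; minimum-norm ",
              "pseudo-inverse solution returned")
    P1 <- sol$P[, seq_len(nrow(W)), drop = FALSE]
    M <- Y %*% t(P1)
  }
  new("VirtualWaveMatrix", values = M, pixelIndex = pm@pixelIndex,
      grid = kernel@grid, shape = pm@shape)
}

#' Condition number of the regularized inversion system
#'
#' The ratio of largest to smallest retained singular value of the
#' lambda-augmented system actually solved by [vwtInvert()] - the
#' ill-posedness surfaced as a number.
#'
#' @param kernel a [KernelMatrix-class].
#' @param config a [VWTConfig-class]; defaults to the kernel's.
#' @return numeric condition number.
#' @export
vwtConditionNumber <- function(kernel, config = kernel@config) {
  W <- kernel@W
  s1 <- svd(W, nu = 0, nv = 0)$d[1]
  L <- diffOperator(ncol(W), config@smoothnessOrder)
  d <- svd(rbind(W, config@lambda * s1 * L), nu = 0, nv = 0)$d
  keep <- d > config@svdCutoff * d[1]
  d[1] / min(d[keep])
}

#' Forward application of the kernel
#'
#' Reconstructs thermal traces from virtual wave traces (`T = W m` per
#' pixel), for residual checks and round trips.
#'
#' @param kernel a [KernelMatrix-class].
#' @param vw a [VirtualWaveMatrix-class].
#' @return numeric matrix `n_pixels x n_real_times`.
#' @export
forwardApply <- function(kernel, vw) {
  if (ncol(vw@values) != ncol(kernel@W))
    stop("virtual matrix does not match kernel grid", call. = FALSE)
  vw@values %*% t(kernel@W)
}
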