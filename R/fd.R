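## Finite-difference solution of the 1-D heat equation: the independent
## numerical oracle for the method-of-images phantom physics.

#' Finite-difference solution of 1-D heat diffusion under surface cooling
#'
#' Solves `dT/dt = alpha d2T/dz2` on `[0, depth]` (or a deep domain) with the
#' surface driven by the excitation flux and the stated deep boundary, using
#' an unconditionally stable implicit (backward Euler) finite-volume scheme.
#' Units follow the package convention (volumetric heat capacity 1,
#' conductivity `alpha`), so results are directly comparable with
#' [surfaceResponse()].
#'
#' Boundary kinds:
#' \describe{
#'   \item{`constant_temp`}{Dirichlet `T = 0` at `z = depth` (total negative
#'     reflection, R = -1).}
#'   \item{`insulated`}{zero flux at `z = depth` (total positive reflection,
#'     R = +1).}
#'   \item{`semi_infinite`}{no reflector; the domain extends to at least 10
#'     diffusion lengths and ends in a constant-temperature boundary.}
#' }
#' A partial reflector (`|R| < 1`) is modelled by giving `reflectionCoeff`:
#' the medium below `depth` gets conductivity and capacity scaled by
#' `beta = (1 - R)/(1 + R)` (same diffusivity, effusivity ratio `beta`),
#' which realizes the requested reflection coefficient at the interface.
#'
#' @param depth interface depth in metres (ignored for `semi_infinite`).
#' @param boundaryKind one of `"constant_temp"`, `"insulated"`,
#'   `"semi_infinite"`.
#' @param alpha thermal diffusivity, m^2/s.
#' @param excitation an [ExcitationProfile-class] in degrees C (converted to
#'   flux internally, as in [surfaceResponse()]).
#' @param times output times in seconds from stimulus onset.
#' @param reflectionCoeff optional partial reflection coefficient; overrides
#'   `boundaryKind` with a two-layer medium.
#' @param dz spatial step in metres (default resolves the first output
#'   time's diffusion length).
#' @param dt time step in seconds (default 0.25).
#' @return numeric surface-temperature trace at `times`, degrees C.
#' @examples
#' prot <- acquisitionProtocol(coolingDuration = 60)
#' e <- makeExcitation(prot, "step")
#' tt <- seq(15, 300, by = 15)
#' fd <- fdSolve1D(0.009, "insulated", 7.58e-8, e, tt)
#' mi <- surfaceResponse(0.009, +1, 7.58e-8, e, tt)
#' max(abs(fd - mi))    # small compared with the trace range
#' @export
fdSolve1D <- function(depth, boundaryKind = c("constant_temp", "insulated",
                                              "semi_infinite"),
                      alpha, excitation, times,
                      reflectionCoeff = NULL, dz = NULL, dt = 0.25) {
  boundaryKind <- match.arg(boundaryKind)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  tEnd <- max(times)
  deepLen <- 10 * sqrt(alpha * tEnd)   # >= 10 diffusion lengths

  twoLayer <- !is.null(reflectionCoeff) && abs(reflectionCoeff) < 1
  if (!is.null(reflectionCoeff) && !twoLayer) {
    boundaryKind <- if (reflectionCoeff <= -1) "constant_temp" else "insulated"
  }

  if (boundaryKind == "semi_infinite" && !twoLayer) {
    L <- deepLen
    farBC <- "constant_temp"   # irrelevant at this depth
  } else if (twoLayer) {
    L <- depth + deepLen
    farBC <- "constant_temp"
  } else {
    L <- depth
    farBC <- boundaryKind
  }

  if (is.null(dz)) {
    ## resolve the near-surface gradient built up during the excitation,
    ## not just the diffusion length at the first output time
    dz <- min(sqrt(alpha * tEnd) / 120,
              if (boundaryKind != "semi_infinite") depth / 50 else Inf)
  }
  n <- ceiling(L / dz) + 1L
  dz <- L / (n - 1L)

  ## per-cell material properties (rho*c = cap, conductivity = cond)
  z <- (seq_len(n) - 1L) * dz
  cond <- rep(alpha, n)
  cap <- rep(1, n)
  if (twoLayer) {
    beta <- (1 - reflectionCoeff) / (1 + reflectionCoeff)
    below <- z > depth + dz / 2
    cond[below] <- alpha * beta
    cap[below] <- beta
  }

  ## interface conductances (harmonic mean), finite volumes
  kh <- 2 / (1 / cond[-n] + 1 / cond[-1]) / dz
  vol <- cap * dz
  vol[c(1L, n)] <- cap[c(1L, n)] * dz / 2

  dirichletFar <- farBC == "constant_temp"
  nn <- if (dirichletFar) n - 1L else n

  ## assemble (V/dt + K) for backward Euler
  iidx <- c(seq_len(nn), seq_len(nn - 1L), 2:nn)
  jidx <- c(seq_len(nn), 2:nn, seq_len(nn - 1L))
  diagK <- numeric(nn)
  diagK[1L] <- kh[1L]
  if (nn > 1L) {
    upper <- seq_len(nn - 1L)
    diagK[2:nn] <- kh[upper] + c(kh[-1], 0)[upper]
    if (dirichletFar) diagK[nn] <- kh[nn - 1L] + kh[nn]
    else diagK[nn] <- kh[nn - 1L]
  }
  xval <- c(vol[seq_len(nn)] / dt + diagK, -kh[seq_len(nn - 1L)],
            -kh[seq_len(nn - 1L)])
  A <- Matrix::sparseMatrix(i = iidx, j = jidx, x = xval,
                            dims = c(nn, nn))
  fac <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A), "CsparseMatrix"))

  flux <- excitationFluxProfile(excitation, alpha)
  nsteps <- ceiling(tEnd / dt)
  Tfield <- numeric(nn)
  surf <- numeric(nsteps + 1L)
  stepT <- (0:nsteps) * dt
  qt <- excitationAt(flux, stepT)
  for (s in seq_len(nsteps)) {
    rhs <- vol[seq_len(nn)] / dt * Tfield
    rhs[1L] <- rhs[1L] + qt[s + 1L]
    Tfield <- as.numeric(Matrix::solve(fac, rhs))
    if (!all(is.finite(Tfield)))
      stop("finite-difference solution diverged (internal error)",
           call. = FALSE)
    surf[s + 1L] <- Tfield[1L]
  }
  stats::approx(stepT, surf, xout = times)$y
}
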