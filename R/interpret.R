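## Physiological reading of unmixed components: peaks, polarity
## classification, depth estimates, pairing and the deficit map.

#' Detect the dominant peak of a virtual trace
#'
#' Returns the global largest-magnitude extremum; local extrema are
#' available as secondary peaks.
#'
#' @param trace numeric virtual-time trace.
#' @param grid a [VirtualTimeGrid-class].
#' @param nSecondary how many secondary local extrema to report (default 0).
#' @return list with `peakTime`, `peakSign` (+1/-1, 0 for an all-zero
#'   trace, in which case `peakTime` is `NA`), `amplitude`, and a
#'   `secondary` data frame.
#' @export
detectPeak <- function(trace, grid, nSecondary = 0L) {
  stopifnot(all(is.finite(trace)))
  if (all(trace == 0))
    return(list(peakTime = NA_real_, peakSign = 0, amplitude = 0,
                secondary = data.frame(time = numeric(), sign = numeric(),
                                       amplitude = numeric())))
  i <- which.max(abs(trace))
  sec <- data.frame(time = numeric(), sign = numeric(),
                    amplitude = numeric())
  if (nSecondary > 0L) {
    a <- abs(trace)
    n <- length(trace)
    isLocal <- c(FALSE, a[2:(n - 1)] >= a[1:(n - 2)] &
                   a[2:(n - 1)] >= a[3:n], FALSE)
    cand <- setdiff(which(isLocal), i)
    cand <- cand[order(a[cand], decreasing = TRUE)]
    cand <- utils::head(cand, nSecondary)
    sec <- data.frame(time = grid@points[cand],
                      sign = sign(trace[cand]),
                      amplitude = abs(trace[cand]))
  }
  list(peakTime = grid@points[i], peakSign = sign(trace[i]),
       amplitude = abs(trace[i]), secondary = sec)
}

#' Read the components of a factorization
#'
#' Builds one reading per component: its dominant-peak virtual time,
#' amplitude, and physical polarity.  The polarity is the product of the
#' time-trace peak sign and the sign of the dominant image weight, so it is
#' invariant to the sign convention the unmixing applied.
#'
#' @param fact a [Factorization-class].
#' @param grid the [VirtualTimeGrid-class] of the time matrix columns.
#' @return data frame with columns `component`, `peakTime`, `peakSign`,
#'   `amplitude`.
#' @export
componentReadings <- function(fact, grid) {
  D <- fact@timeMatrix
  C <- fact@imageMatrix
  res <- lapply(seq_len(fact@k), function(j) {
    pk <- detectPeak(D[j, ], grid)
    ## energy-weighted sign over the strongest decile of pixels: robust to
    ## isolated noisy pixels and to diffuse low-level background leakage
    imgSign <- if (all(C[, j] == 0)) 0 else {
      w <- C[, j]
      top <- abs(w) >= stats::quantile(abs(w), 0.9)
      sign(sum(w[top] * abs(w[top])))
    }
    data.frame(component = j, peakTime = pk$peakTime,
               peakSign = pk$peakSign * imgSign,
               amplitude = pk$amplitude * max(abs(C[, j])))
  })
  do.call(rbind, res)
}

#' Classify components as reflection or vasomodulation and pair them
#'
#' A component whose physical polarity matches the stimulus sign is an
#' active vasomodulation response; opposite polarity marks a passive
#' thermal reflection from a constant-temperature vessel boundary.  Each
#' vasomodulation at virtual time t is paired with the nearest reflection at
#' approximately 2t (the two-way travel of the passive echo), within
#' `ratioTol` of the factor 2; every component is paired at most once.
#'
#' @param readings data frame from [componentReadings()] (columns
#'   `component`, `peakTime`, `peakSign`, `amplitude`).
#' @param stimulusSign -1 for cooling (default), +1 for heating.
#' @param ratioTol relative tolerance on the 2x time ratio (default 0.25).
#' @param config a [VWTConfig-class] supplying the virtual speed for depth
#'   estimates.
#' @return the readings with added columns `label` (`"reflection"`,
#'   `"vasomodulation"` or `"unclassified"`), `pairedWith` and `depthM`.
#' @export
classifyComponents <- function(readings, stimulusSign = -1, ratioTol = 0.25,
                               config = vwtConfig()) {
  stopifnot(nrow(readings) >= 1L)
  lab <- ifelse(readings$peakSign == 0 | is.na(readings$peakTime),
                "unclassified",
                ifelse(readings$peakSign == stimulusSign,
                       "vasomodulation", "reflection"))
  readings$label <- lab
  readings$pairedWith <- NA_integer_
  vasoIdx <- which(lab == "vasomodulation")
  reflIdx <- which(lab == "reflection")
  ## greedy nearest-ratio matching, strongest vasomodulation first
  for (vi in vasoIdx[order(-readings$amplitude[vasoIdx])]) {
    free <- reflIdx[is.na(readings$pairedWith[reflIdx])]
    if (!length(free)) break
    ratio <- readings$peakTime[free] / readings$peakTime[vi]
    ok <- abs(ratio - 2) <= 2 * ratioTol
    if (!any(ok)) next
    best <- free[ok][which.min(abs(ratio[ok] - 2))]
    readings$pairedWith[vi] <- readings$component[best]
    readings$pairedWith[best] <- readings$component[vi]
  }
  readings$depthM <- mapply(estimateDepth, readings$peakTime, lab,
                            MoreArgs = list(config = config))
  readings
}

#' Depth from a virtual arrival time
#'
#' One-way conversion `depth = c * t'` for active vasomodulation (the flux
#' change travels once, vessel to skin) and two-way `depth = c * t' / 2` for
#' passive reflection (skin to vessel and back).  Unclassified components
#' get the one-way value.
#'
#' @param peakTime virtual arrival time (> 0).
#' @param label `"vasomodulation"`, `"reflection"` or `"unclassified"`.
#' @param config a [VWTConfig-class] (virtual speed).
#' @return depth in metres (`NA` for `NA` input).
#' @export
estimateDepth <- function(peakTime, label = "vasomodulation",
                          config = vwtConfig()) {
  if (is.na(peakTime)) return(NA_real_)
  if (peakTime <= 0) stop("peakTime must be > 0", call. = FALSE)
  d <- config@virtualSpeed * peakTime
  if (identical(label, "reflection")) d / 2 else d
}

#' Vasoconstriction-deficit map
#'
#' Pixelwise `max(|reflection| - |vasomodulation|, 0)` after normalizing
#' each image by its maximum magnitude: high values mark vessels that
#' reflect the thermal front but barely constrict - the vasoconstriction
#' deficit of interest.
#'
#' @param reflectionImage,vasomodulationImage numeric matrices of equal
#'   shape (aggregated component images).
#' @return numeric matrix in `[0, 1]`.
#' @export
deficitMap <- function(reflectionImage, vasomodulationImage) {
  stopifnot(identical(dim(reflectionImage), dim(vasomodulationImage)))
  mr <- max(abs(reflectionImage))
  mv <- max(abs(vasomodulationImage))
  if (mr == 0) {
    warning("all-zero reflection image; deficit map is zero")
    return(reflectionImage * 0)
  }
  r <- abs(reflectionImage) / mr
  v <- if (mv == 0) vasomodulationImage * 0 else
    abs(vasomodulationImage) / mv
  pmax(r - v, 0)
}
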