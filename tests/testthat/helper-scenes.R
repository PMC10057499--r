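# Shared fixtures: all synthetic, built in code at test time.

defaultProtocol <- function(...) acquisitionProtocol(...)

stepExcitation <- function(protocol = defaultProtocol())
  makeExcitation(protocol, "step")

# absolute observation times (seconds from stimulus onset) of the default
# protocol: cooling 300 s, then 20 frames every 15 s
absTimes <- function(protocol = defaultProtocol())
  protocolTimes(protocol) + protocol@coolingDuration

fullMask <- function(shape = c(64L, 64L))
  breastMask(matrix(TRUE, shape[1], shape[2]))

# single-pixel PixelMatrix wrapper around a bare trace, for direct
# inversion of analytic responses
traceMatrix <- function(y, times) {
  new("PixelMatrix", values = matrix(y, 1), pixelIndex = cbind(1L, 1L),
      columnTimes = times, staticColumn = NA_integer_,
      backgroundTemp = 0, shape = c(1L, 1L))
}

# a smooth single-bump virtual trace centred at grid point i0
bumpTrace <- function(grid, i0, width = 4) {
  idx <- seq_along(virtualTimes(grid))
  exp(-(idx - i0)^2 / (2 * width^2))
}

runDemoPipeline <- function(type, noiseStd = 0, seed = 1L,
                            motionJitterPx = 0L, register = FALSE,
                            config = pipelineConfig()) {
  stk <- renderPhantom(demoScene(type, noiseStd = noiseStd, seed = seed,
                                 motionJitterPx = motionJitterPx))
  runPipeline(stk, fullMask(), config, register = register)
}
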