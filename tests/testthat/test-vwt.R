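# Virtual time grid, kernel construction, regularized inversion.

test_that("the virtual grid follows its defining sequence", {
  g <- buildVirtualGrid()
  tp <- virtualTimes(g)
  expect_identical(length(tp), 100L)
  expect_equal(tp[100], 0.025, tolerance = 1e-15)
  expect_equal(tp[80], 0.0125, tolerance = 1e-15)  # one octave below tMax
  expect_equal(tp[1], 0.025 * 2^(-99 / 20), tolerance = 1e-15)
  # exact factor of two every stepsPerOctave points
  expect_equal(tp[21:100] / tp[1:80], rep(2, 80), tolerance = 1e-12)
  expect_true(all(diff(tp) > 0))
  expect_error(buildVirtualGrid(N = 1L))
  expect_error(buildVirtualGrid(tMax = -1))
})

test_that("kernel rows integrate like the continuous kernel", {
  g <- buildVirtualGrid()
  tt <- absTimes()
  ker <- buildKernel(tt, g, vwtConfig(useExcitationConvolution = FALSE))
  # dense-quadrature oracle over the same virtual span
  alpha <- 7.58e-8
  tpDense <- seq(min(virtualTimes(g)), max(virtualTimes(g)),
                 length.out = 2e5)
  for (j in c(1, 10, 20)) {
    t <- tt[j]
    dense <- sum(exp(-tpDense^2 / (4 * alpha * t))) / sqrt(pi * alpha * t) *
      diff(tpDense[1:2])
    expect_equal(sum(kernelMatrix(ker)[j, ]), dense, tolerance = 1e-3)
  }
})

test_that("the kernel depends on c and t' only through their product", {
  tt <- absTimes()
  g1 <- buildVirtualGrid(tMax = 0.025)
  g2 <- buildVirtualGrid(tMax = 0.0125)
  k1 <- buildKernel(tt, g1, vwtConfig(virtualSpeed = 1,
                                      useExcitationConvolution = FALSE))
  k2 <- buildKernel(tt, g2, vwtConfig(virtualSpeed = 2,
                                      useExcitationConvolution = FALSE))
  expect_equal(kernelMatrix(k1), kernelMatrix(k2), tolerance = 1e-12)
})

test_that("a narrow virtual pulse forward-maps to a depth-ordered thermal peak", {
  g <- buildVirtualGrid()
  tt <- seq(15, 7200, by = 15)   # window long enough for every echo to peak
  ker <- buildKernel(tt, g, vwtConfig(useExcitationConvolution = FALSE))
  tp <- virtualTimes(g)
  peakT <- vapply(c(0.010, 0.018, 0.025), function(arrival) {
    m <- dnorm(tp, arrival, 5e-4)
    tt[which.max(kernelMatrix(ker) %*% m)]
  }, numeric(1))
  expect_true(all(diff(peakT) > 0))
})

test_that("forward-then-invert recovers a smooth virtual signal as lambda -> 0", {
  g <- buildVirtualGrid()
  tt <- absTimes()
  cfg0 <- vwtConfig(lambda = 1e-10, useExcitationConvolution = FALSE)
  ker <- buildKernel(tt, g, cfg0)
  sv <- svd(kernelMatrix(ker))
  m0 <- as.numeric(sv$v[, 1:6] %*% (sv$d[1:6] *
                                      c(0.5, -1, 0.8, 0.3, -0.4, 0.2)))
  y <- as.numeric(kernelMatrix(ker) %*% m0)
  rec <- as.numeric(values(vwtInvert(traceMatrix(y, tt), ker, cfg0)))
  expect_lt(sqrt(sum((rec - m0)^2) / sum(m0^2)), 0.05)
})

test_that("the penalty dominates as lambda grows and residuals are monotone", {
  g <- buildVirtualGrid()
  tt <- absTimes()
  e <- stepExcitation()
  y <- surfaceResponse(0.009, -1, 7.58e-8, e, tt)
  lambdas <- c(0.0003, 0.003, 0.03, 0.3, 30)
  res <- vapply(lambdas, function(l) {
    cfg <- vwtConfig(lambda = l)
    ker <- buildKernel(tt, g, cfg, e)
    m <- vwtInvert(traceMatrix(y, tt), ker, cfg)
    sqrt(sum((y - forwardApply(ker, m))^2) / sum(y^2))
  }, numeric(1))
  expect_true(all(diff(res) > 0))   # residual grows with lambda

  cfgBig <- vwtConfig(lambda = 1e6)
  kerBig <- buildKernel(tt, g, cfgBig, e)
  expect_lt(max(abs(values(vwtInvert(traceMatrix(y, tt), kerBig, cfgBig)))),
            1e-6 * max(abs(y)))    # m -> 0
})

test_that("inversion round trip on noiseless data has a small residual", {
  g <- buildVirtualGrid()
  tt <- absTimes()
  e <- stepExcitation()
  cfg <- vwtConfig()
  ker <- buildKernel(tt, g, cfg, e)
  # zero in, zero out
  vw0 <- new("VirtualWaveMatrix", values = matrix(0, 1, 100),
             pixelIndex = cbind(1L, 1L), grid = g, shape = c(1L, 1L))
  expect_true(all(forwardApply(ker, vw0) == 0))

  y <- surfaceResponse(0.009, -1, 7.58e-8, e, tt) +
    vasomodulationResponse(vesselSpec(0.009, -1, 0.5, 0.2, 60,
                                      cbind(1L, 1L), 1L), 7.58e-8, e, tt)
  m <- vwtInvert(traceMatrix(y, tt), ker, cfg)
  expect_lt(sqrt(sum((y - forwardApply(ker, m))^2) / sum(y^2)), 0.05)
})

test_that("echo arrivals land at their virtual travel times", {
  g <- buildVirtualGrid()
  tp <- virtualTimes(g)
  tt <- absTimes()
  e <- stepExcitation()
  cfg <- vwtConfig()
  ker <- buildKernel(tt, g, cfg, e)
  alpha <- 7.58e-8
  bg <- surfaceResponse(0.020, 0, alpha, e, tt)
  stepTol <- 2^(2 / 20)   # two grid steps

  # 9 mm: one-way (vasomodulation) at 0.009, two-way (reflection) at 0.018
  vaso9 <- vasomodulationResponse(vesselSpec(0.009, -1, 0.5, 0, 0,
                                             cbind(1L, 1L), 1L),
                                  alpha, e, tt)
  mv <- as.numeric(values(vwtInvert(traceMatrix(vaso9, tt), ker, cfg)))
  expect_lt(abs(log(tp[which.max(abs(mv))] / 0.009)), log(stepTol))
  expect_equal(sign(mv[which.max(abs(mv))]), -1)   # stimulus polarity

  refl9 <- surfaceResponse(0.009, -1, alpha, e, tt) - bg
  mr <- as.numeric(values(vwtInvert(traceMatrix(refl9, tt), ker, cfg)))
  expect_lt(abs(log(tp[which.max(abs(mr))] / 0.018)), log(stepTol))
  expect_equal(sign(mr[which.max(abs(mr))]), +1)   # reversed polarity

  # 13 mm: one-way arrival at 0.013
  vaso13 <- vasomodulationResponse(vesselSpec(0.013, -1, 0.5, 0, 0,
                                              cbind(1L, 1L), 1L),
                                   alpha, e, tt)
  mv13 <- as.numeric(values(vwtInvert(traceMatrix(vaso13, tt), ker, cfg)))
  expect_lt(abs(log(tp[which.max(abs(mv13))] / 0.013)), log(stepTol))
})

test_that("recovered arrival times are proportional to depth", {
  g <- buildVirtualGrid()
  tp <- virtualTimes(g)
  tt <- absTimes()
  e <- stepExcitation()
  cfg <- vwtConfig()
  ker <- buildKernel(tt, g, cfg, e)
  depths <- c(0.005, 0.009, 0.013, 0.020)
  arrivals <- vapply(depths, function(d) {
    v <- vasomodulationResponse(vesselSpec(d, -1, 0.5, 0, 0,
                                           cbind(1L, 1L), 1L),
                                7.58e-8, e, tt)
    m <- as.numeric(values(vwtInvert(traceMatrix(v, tt), ker, cfg)))
    tp[which.max(abs(m))]
  }, numeric(1))
  expect_true(all(diff(arrivals) > 0))
  fit <- lm(arrivals ~ depths)
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("inversion is deterministic and validates its inputs", {
  g <- buildVirtualGrid()
  tt <- absTimes()
  e <- stepExcitation()
  cfg <- vwtConfig()
  ker <- buildKernel(tt, g, cfg, e)
  y <- surfaceResponse(0.009, -1, 7.58e-8, e, tt)
  m1 <- values(vwtInvert(traceMatrix(y, tt), ker, cfg))
  m2 <- values(vwtInvert(traceMatrix(y, tt), ker, cfg))
  expect_identical(m1, m2)
  expect_error(vwtInvert(traceMatrix(y[1:10], tt[1:10]), ker, cfg),
               "match")
  expect_error(buildKernel(c(-5, 10), g, cfg), "> 0")
})

test_that("the Hermite-projection mode returns a low-dimensional smooth fit", {
  g <- buildVirtualGrid()
  tt <- absTimes()
  e <- stepExcitation()
  cfg <- vwtConfig(mode = "hermite", smoothnessOrder = 4L)
  ker <- buildKernel(tt, g, cfg, e)
  y <- surfaceResponse(0.009, -1, 7.58e-8, e, tt)
  m <- values(vwtInvert(traceMatrix(y, tt), ker, cfg))
  expect_true(all(is.finite(m)))
  B <- thermovasc:::hermiteBasis(virtualTimes(g), 4L)
  # solution lies in the span of the truncated basis
  proj <- B %*% solve(crossprod(B), crossprod(B, as.numeric(m)))
  expect_equal(as.numeric(m), as.numeric(proj), tolerance = 1e-8)
})

test_that("condition number of the regularized system is finite and surfaced", {
  g <- buildVirtualGrid()
  ker <- buildKernel(absTimes(), g, vwtConfig(), stepExcitation())
  cn <- vwtConditionNumber(ker)
  expect_true(is.finite(cn) && cn > 1)
  # weaker regularization worsens conditioning
  cn0 <- vwtConditionNumber(ker, vwtConfig(lambda = 1e-6))
  expect_gt(cn0, cn)
})
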