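# Phantom physics: excitation profiles, method-of-images surface response,
# vasomodulation signatures, scene rendering.

test_that("excitation profiles follow their definitions", {
  prot <- defaultProtocol()   # baseline 34.5, post-cooling 32.5
  step <- makeExcitation(prot, "step")
  expect_true(all(step@values == -2))
  expect_equal(range(step@times), c(0, 300))

  ramp <- makeExcitation(prot, "ramp")
  expect_equal(approx(ramp@times, ramp@values, xout = 150)$y, -1,
               tolerance = 1e-12)

  measured <- excitationProfile(c(0, 10, 20), c(0, -1, -2))
  expect_identical(makeExcitation(prot, "measured", profile = measured),
                   measured)
  expect_error(makeExcitation(prot, "sawtooth"))
  expect_error(makeExcitation(prot, "measured"), "profile")
})

test_that("surface response reduces to the semi-infinite solution at R = 0", {
  e <- stepExcitation()
  tt <- absTimes()
  r0 <- surfaceResponse(0.009, 0, 7.58e-8, e, tt)
  # depth must be irrelevant without a reflector
  expect_equal(r0, surfaceResponse(0.020, 0, 7.58e-8, e, tt))
  # cooling drives the surface down, monotone recovery after stimulus end
  expect_true(all(r0 < 0))
})

test_that("a constant-temperature boundary reflects with reversed polarity", {
  e <- stepExcitation()
  tt <- absTimes()
  direct <- surfaceResponse(0.009, 0, 7.58e-8, e, tt)
  for (d in c(0.005, 0.009, 0.013)) {
    reflNeg <- surfaceResponse(d, -1, 7.58e-8, e, tt) - direct
    reflPos <- surfaceResponse(d, +1, 7.58e-8, e, tt) - direct
    expect_true(all(reflNeg >= 0))   # cooling (-) stimulus, R = -1 echo +
    expect_true(all(reflPos <= 0))   # insulator echoes with stimulus sign
  }
})

test_that("reflected arrival time scales with depth squared", {
  # short cooling pulse ~ impulse: the echo peaks near (2d)^2 / (8 alpha)
  e <- makeExcitation(acquisitionProtocol(coolingDuration = 15), "step")
  tt <- seq(5, 8000, by = 5)   # long window so every echo peaks inside
  depths <- c(0.005, 0.009, 0.013, 0.020)
  peakT <- vapply(depths, function(d) {
    echo <- surfaceResponse(d, -1, 7.58e-8, e, tt) -
      surfaceResponse(d, 0, 7.58e-8, e, tt)
    tt[which.max(abs(echo))]
  }, numeric(1))
  expect_true(all(diff(peakT) > 0))
  fit <- lm(peakT ~ I(depths^2))
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("vasomodulation response has stimulus polarity and shifts with the delay", {
  e <- stepExcitation()
  tt <- absTimes()
  cl <- cbind(1L, 1L)
  off <- vesselSpec(0.009, -1, 0, 0, 60, cl, 1L)
  expect_true(all(vasomodulationResponse(off, 7.58e-8, e, tt) == 0))

  fast <- vesselSpec(0.009, -1, 0.5, 0, 0, cl, 1L)
  vf <- vasomodulationResponse(fast, 7.58e-8, e, tt)
  expect_true(all(vf <= 0))          # same polarity as the cooling stimulus

  tau <- 45
  slow <- vesselSpec(0.009, -1, 0, 0.5, tau, cl, 1L)
  vs <- vasomodulationResponse(slow, 7.58e-8, e, tt)
  vfShift <- vasomodulationResponse(fast, 7.58e-8, e, tt - tau)
  expect_equal(vs, vfShift, tolerance = 1e-10)
})

test_that("traces are causal: zero before stimulus onset", {
  e <- stepExcitation()
  tt <- c(-60, -1, 0)
  expect_true(all(abs(surfaceResponse(0.009, -1, 7.58e-8, e, tt)) < 1e-12))
  v <- vesselSpec(0.009, -1, 0.5, 0.3, 60, cbind(1L, 1L), 1L)
  expect_true(all(abs(vasomodulationResponse(v, 7.58e-8, e, tt)) < 1e-12))
})

test_that("rendering composes background and vessel responses", {
  # no vessels, no noise: every pixel identical to the background trace
  spec <- phantomSpec(c(8L, 8L), list(), noiseStd = 0)
  stk <- renderPhantom(spec)
  bg <- stk@meta$groundTruth$backgroundTrace
  base <- spec@protocol@skinTempBaseline
  for (f in seq_len(dim(frames(stk))[3]))
    expect_equal(as.vector(frames(stk)[, , f]),
                 rep(base + bg[f], 64), tolerance = 1e-12)

  # default protocol: 20 dynamic frames plus one static frame
  expect_identical(dim(frames(stk))[3], 20L)
  expect_false(is.null(staticFrame(stk)))
  expect_equal(timestamps(stk), seq(15, 300, by = 15))
})

test_that("rendering is deterministic under a fixed seed", {
  s1 <- renderPhantom(demoScene("twoVessel", noiseStd = 0.2, seed = 11L,
                                motionJitterPx = 2L))
  s2 <- renderPhantom(demoScene("twoVessel", noiseStd = 0.2, seed = 11L,
                                motionJitterPx = 2L))
  expect_identical(frames(s1), frames(s2))
  expect_identical(staticFrame(s1), staticFrame(s2))
  s3 <- renderPhantom(demoScene("twoVessel", noiseStd = 0.2, seed = 12L))
  expect_false(identical(frames(s1), frames(s3)))
})

test_that("vessels outside the image are rejected", {
  v <- vesselSpec(0.009, -1, 0, 0, 60, cbind(70L, 3L), 3L)
  expect_error(renderPhantom(phantomSpec(c(64L, 64L), list(v))), "outside")
})

test_that("invalid specs fail their validity checks", {
  expect_error(acquisitionProtocol(nDynamicFrames = 1L))
  expect_error(acquisitionProtocol(skinTempPostCooling = 20, roomTemp = 21))
  expect_error(acquisitionProtocol(coolingDuration = 400))
  expect_error(vesselSpec(depth = -1, centerline = cbind(1L, 1L)))
  expect_error(vesselSpec(0.01, reflectionCoeff = 1.5,
                          centerline = cbind(1L, 1L)))
  expect_error(vesselSpec(0.01, vasoFastAmplitude = -0.1,
                          centerline = cbind(1L, 1L)))
  expect_error(phantomSpec(noiseStd = -1))
})
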