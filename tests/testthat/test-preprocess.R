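# Motion correction, background subtraction, stacking, excitation recovery.

test_that("an aligned stack registers with zero shifts", {
  stk <- renderPhantom(demoScene("registration", noiseStd = 0.2, seed = 2L))
  reg <- registerFrames(stk)
  expect_true(all(reg$shifts == 0L))
  expect_identical(frames(reg$stack), frames(stk))
})

test_that("an injected shift is recovered exactly and undone", {
  stk <- renderPhantom(demoScene("registration", noiseStd = 0, seed = 2L))
  fr <- frames(stk)
  fr[, , 7] <- thermovasc:::shiftMatrix(fr[, , 7], 3L, -2L,
                                        fill = mean(fr[, , 7]))
  shifted <- frameStack(fr, timestamps(stk), staticFrame(stk), stk@meta)
  reg <- registerFrames(shifted)
  expect_identical(reg$shifts[7, ], c(3L, -2L))
  expect_true(all(reg$shifts[-7, ] == 0L))
  inside <- frames(stk)[10:55, 10:55, 7]
  expect_equal(frames(reg$stack)[10:55, 10:55, 7], inside,
               tolerance = 1e-12)
  expect_false(all(reg$validMask))   # exposed border marked invalid
})

test_that("a common shift of all frames and the reference cancels", {
  stk <- renderPhantom(demoScene("registration", noiseStd = 0, seed = 2L))
  fr <- frames(stk)
  for (f in seq_len(dim(fr)[3]))
    fr[, , f] <- thermovasc:::shiftMatrix(fr[, , f], 2L, 1L, fill = 34.5)
  ref <- thermovasc:::shiftMatrix(staticFrame(stk), 2L, 1L, fill = 34.5)
  shifted <- frameStack(fr, timestamps(stk), ref, stk@meta)
  expect_true(all(registerFrames(shifted)$shifts == 0L))
})

test_that("random jitter is recovered under detector noise", {
  # >= 95% exact recovery, jitter <= 5 px, noise 0.2 degC
  tot <- 0; ok <- 0
  for (s in 1:3) {
    stk <- renderPhantom(demoScene("registration", noiseStd = 0.2,
                                   seed = s, motionJitterPx = 5L))
    gt <- stk@meta$groundTruth$jitterShifts
    reg <- registerFrames(stk)
    ok <- ok + sum(rowSums(abs(reg$shifts - gt)) == 0)
    tot <- tot + nrow(gt)
  }
  expect_gte(ok / tot, 0.95)
})

test_that("degenerate frames skip registration with a warning", {
  fr <- array(1, dim = c(8, 8, 3))
  stk <- frameStack(fr, c(15, 30, 45))
  w <- capture_warnings(reg <- registerFrames(stk, "first"))
  expect_true(any(grepl("degenerate", w)))
  expect_true(all(reg$shifts == 0L))
})

test_that("background subtraction is linear and invertible", {
  stk <- renderPhantom(demoScene("single9"))
  sub <- subtractBackground(stk, 21)
  # a 32.5 degC pixel becomes 11.5
  expect_equal(max(abs((frames(stk) - 21) - frames(sub))), 0)
  expect_identical(frames(subtractBackground(stk, 0)), frames(stk))
  back <- subtractBackground(sub, -21)
  expect_equal(frames(back), frames(stk), tolerance = 1e-12)
  expect_equal(back@meta$backgroundSubtracted, 0)
})

test_that("stacking produces the 21-column matrix and is invertible", {
  stk <- subtractBackground(renderPhantom(demoScene("single9")), 21)
  pm <- stackToMatrix(stk, fullMask())
  expect_identical(ncol(values(pm)), 21L)       # 20 dynamic + 1 static
  expect_identical(pm@staticColumn, 21L)
  expect_identical(nrow(values(pm)), 64L * 64L)
  expect_false(anyDuplicated(pixelIndex(pm)) > 0)

  # single-pixel mask returns that pixel's trace
  m1 <- matrix(FALSE, 64, 64); m1[30, 32] <- TRUE
  pm1 <- stackToMatrix(stk, breastMask(m1))
  expect_identical(dim(values(pm1)), c(1L, 21L))
  expect_equal(as.numeric(values(pm1)[1, 1:20]), frames(stk)[30, 32, ])

  # round trip restores masked pixels exactly
  back <- matrixToStack(pm)
  expect_equal(frames(back), frames(stk), tolerance = 0)
  expect_equal(staticFrame(back), staticFrame(stk), tolerance = 0)

  expect_error(stackToMatrix(stk, breastMask(matrix(c(TRUE, rep(FALSE, 63)),
                                                    8, 8))), "shape")
})

test_that("empty masks are rejected at construction", {
  expect_error(breastMask(matrix(FALSE, 4, 4)), "non-empty")
})

test_that("excitation extraction recovers the stimulus footprint", {
  # all pixels share one trace -> that trace re-zeroed at its last sample
  fr <- array(rep(c(-2, -1.5, -1, -0.6), each = 16), dim = c(4, 4, 4))
  stk <- frameStack(fr, c(15, 30, 45, 60))
  ex <- extractExcitation(stackToMatrix(stk, breastMask(matrix(TRUE, 4, 4)),
                                        includeStatic = FALSE))
  expect_equal(ex@values, c(-2, -1.5, -1, -0.6) + 0.6, tolerance = 1e-12)

  # phantom: correlates > 0.99 with the noiseless surface footprint
  stk <- subtractBackground(renderPhantom(demoScene("single9")), 21)
  pm <- stackToMatrix(stk, fullMask())
  ex <- extractExcitation(pm)
  bg <- stk@meta$groundTruth$backgroundTrace
  expect_gt(cor(ex@values, bg - bg[length(bg)]), 0.99)
})

test_that("noise perturbs the excitation estimate at the expected scale", {
  clean <- renderPhantom(demoScene("single9", noiseStd = 0, seed = 3L))
  noisy <- renderPhantom(demoScene("single9", noiseStd = 0.2, seed = 3L))
  exC <- extractExcitation(stackToMatrix(clean, fullMask()))
  exN <- extractExcitation(stackToMatrix(noisy, fullMask()))
  n <- 64 * 64
  # re-zeroing adds the last frame's mean-noise, hence the factor 2 margin
  expect_lt(max(abs(exN@values - exC@values)), 5 * 0.2 / sqrt(n))
})
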