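# Uncentered PCA and product-preserving ICA.

test_that("a rank-1 matrix is reconstructed exactly by one component", {
  set.seed(1)
  X <- outer(rnorm(50), rnorm(30))
  f <- suppressWarnings(pcaFactor(X, 1))
  expect_lt(norm(X - imageMatrix(f) %*% timeMatrix(f), "F") / norm(X, "F"),
            1e-10)
})

test_that("reconstruction error is non-increasing in k", {
  set.seed(2)
  X <- matrix(rnorm(50 * 30), 50) + outer(rnorm(50), rnorm(30)) * 5
  errs <- vapply(1:6, function(k) {
    f <- pcaFactor(X, k)
    norm(X - imageMatrix(f) %*% timeMatrix(f), "F")
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("PCA is uncentered and respects its sign convention", {
  set.seed(3)
  X <- outer(runif(40, 1, 2), rep(1, 25))   # constant-in-time, all positive
  f <- suppressWarnings(pcaFactor(X, 1))
  # uncentered: the mean signal is captured, not discarded
  expect_lt(norm(X - imageMatrix(f) %*% timeMatrix(f), "F") / norm(X, "F"),
            1e-10)
  tm <- timeMatrix(f)
  expect_gt(tm[1, which.max(abs(tm[1, ]))], 0)
})

test_that("k beyond the numerical rank is clipped with a warning", {
  X <- outer(1:20, 1:10)
  expect_warning(f <- pcaFactor(X, 5), "rank")
  expect_identical(nComponents(f), 1L)
})

test_that("two vessel populations need at least two components", {
  stk <- subtractBackground(renderPhantom(demoScene("deficit")), 21)
  pm <- stackToMatrix(stk, fullMask())
  cfg <- vwtConfig(includeStaticInInversion = TRUE)
  ker <- buildKernel(absTimes(), buildVirtualGrid(), cfg, stepExcitation())
  vw <- vwtInvert(pm, ker, cfg)
  # remove the shared background trace so the spectrum reflects the two
  # vessel populations (reflector-only vs vasomodulating)
  bgRow <- which(pixelIndex(vw)[, 1] == 2 & pixelIndex(vw)[, 2] == 2)
  V <- sweep(values(vw), 2, values(vw)[bgRow, ])
  d <- svd(V, nu = 0, nv = 0)$d
  frac <- cumsum(d^2) / sum(d^2)
  expect_lt(frac[1], 0.99)
  expect_gt(frac[3], 0.99)
})

test_that("ICA separates single-peak traces mixed into both components", {
  g <- buildVirtualGrid()
  i0 <- 60   # arrival a; one octave later (2a) is 20 steps up
  s1 <- bumpTrace(g, i0)
  s2 <- bumpTrace(g, i0 + 20)
  tp <- virtualTimes(g)
  okCor <- numeric(0)
  for (seed in 1:10) {
    set.seed(100 + seed)
    A <- matrix(runif(4, 0.5, 1.5) * sample(c(-1, 1), 4, TRUE), 2, 2)
    while (abs(det(A)) < 0.3)
      A <- matrix(runif(4, 0.5, 1.5) * sample(c(-1, 1), 4, TRUE), 2, 2)
    P <- matrix(runif(80, 0, 1), 40, 2)
    V <- P %*% A %*% rbind(s1, s2)
    f <- suppressWarnings(pcaFactor(V, 2))
    u <- icaUnmix(f, kIca = 2, seed = seed)
    D <- timeMatrix(u)
    # product preservation against the PCA reconstruction
    rec <- imageMatrix(f) %*% timeMatrix(f)
    expect_lt(norm(imageMatrix(u) %*% D - rec, "F") / norm(rec, "F"), 1e-8)
    # each unmixed trace matches one source, ordered by arrival
    expect_equal(which.max(abs(D[1, ])), i0, tolerance = 2)
    expect_equal(which.max(abs(D[2, ])), i0 + 20, tolerance = 2)
    okCor <- c(okCor, abs(cor(D[1, ], s1)), abs(cor(D[2, ], s2)))
  }
  expect_gt(mean(okCor), 0.95)
})

test_that("already independent traces pass through up to permutation and scale", {
  g <- buildVirtualGrid()
  s1 <- bumpTrace(g, 40)
  s2 <- bumpTrace(g, 75)
  P <- cbind(c(rep(1, 20), rep(0, 20)), c(rep(0, 20), rep(1, 20)))
  V <- P %*% rbind(s1, s2)
  f <- suppressWarnings(pcaFactor(V, 2))
  u <- icaUnmix(f, kIca = 2, seed = 1)
  D <- timeMatrix(u)
  expect_gt(abs(cor(D[1, ], s1)), 0.99)
  expect_gt(abs(cor(D[2, ], s2)), 0.99)
  # sign convention: dominant peaks positive
  expect_gt(D[1, which.max(abs(D[1, ]))], 0)
  expect_gt(D[2, which.max(abs(D[2, ]))], 0)
})

test_that("the ICA rotation is deterministic given the seed", {
  g <- buildVirtualGrid()
  set.seed(9)
  V <- matrix(runif(40, 0, 1), 20, 2) %*%
    rbind(bumpTrace(g, 50), bumpTrace(g, 80))
  f <- suppressWarnings(pcaFactor(V, 2))
  u1 <- icaUnmix(f, kIca = 2, seed = 42)
  u2 <- icaUnmix(f, kIca = 2, seed = 42)
  expect_identical(timeMatrix(u1), timeMatrix(u2))
  expect_identical(imageMatrix(u1), imageMatrix(u2))
})

test_that("kIca is bounded by the PCA component count", {
  set.seed(17)
  X <- outer(rnorm(30), rnorm(20)) + outer(rnorm(30), rnorm(20))
  f <- suppressWarnings(pcaFactor(X, 2))
  expect_error(icaUnmix(f, kIca = 5), "components")
})

test_that("component images scatter and gather losslessly", {
  stk <- subtractBackground(renderPhantom(demoScene("single9")), 21)
  pm <- stackToMatrix(stk, fullMask())
  cfg <- vwtConfig(includeStaticInInversion = TRUE)
  ker <- buildKernel(absTimes(), buildVirtualGrid(), cfg, stepExcitation())
  vw <- vwtInvert(pm, ker, cfg)
  f <- suppressWarnings(pcaFactor(vw, 3))
  imgs <- componentsToImages(f, pixelIndex(pm), pm@shape)
  expect_length(imgs, 3L)
  lin <- (pixelIndex(pm)[, 2] - 1L) * pm@shape[1] + pixelIndex(pm)[, 1]
  for (j in 1:3)
    expect_equal(imgs[[j]][lin], imageMatrix(f)[, j], tolerance = 0)

  # single-pixel case
  f1 <- new("Factorization", imageMatrix = matrix(2.5), timeMatrix =
              matrix(1, 1, 1), k = 1L, sourceShape = c(1L, 1L),
            stage = "pca", singularValues = 2.5)
  img1 <- componentsToImages(f1, cbind(3L, 4L), c(8L, 8L))
  expect_equal(img1[[1]][3, 4], 2.5)
  expect_error(componentsToImages(f1, cbind(9L, 9L), c(8L, 8L)), "bounds")
})

test_that("the phantom's earliest unmixed component highlights the vasomodulating vessel", {
  res <- runDemoPipeline("deficit")
  rd <- res$readings
  vasoRows <- which(rd$label == "vasomodulation" & rd$peakTime > 0.004)
  expect_gte(length(vasoRows), 1L)
  j <- vasoRows[which.max(rd$amplitude[vasoRows])]
  img <- abs(res$componentImages[[j]])
  onV1 <- matrix(FALSE, 64, 64); onV1[11:54, 19:21] <- TRUE   # 9 mm vessel
  offV <- !onV1; offV[11:54, 43:45] <- FALSE
  expect_gt(mean(img[onV1]), 5 * mean(img[offV]))
})
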