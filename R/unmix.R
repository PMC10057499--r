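## Product-preserving component unmixing: uncentered PCA over images, then
## ICA over the time matrix with the inverse rotation applied to the images
## so the reconstruction (the matrix product) is unchanged.

#' Uncentered principal-component factorization
#'
#' Rank-`k` factorization of the virtual wave matrix by singular value
#' decomposition of the uncentered matrix (the mean virtual trace is
#' physical signal, not an offset, so it is not removed).  Components are
#' ordered by singular value, and each time trace's sign is fixed so its
#' largest-magnitude sample is positive (the compensating flip is applied to
#' the image weights, preserving the product).
#'
#' @param vw a [VirtualWaveMatrix-class] (or plain matrix, pixels x times).
#' @param k number of components (default 6); clipped with a warning when it
#'   exceeds the numerical rank.
#' @return a [Factorization-class] with `stage = "pca"`.
#' @export
pcaFactor <- function(vw, k = 6L) {
  X <- if (is(vw, "VirtualWaveMatrix")) vw@values else vw
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  sv <- svd(X)
  rank <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
  if (k > rank) {
    warning("k = ", k, " exceeds the numerical rank ", rank, "; clipped")
    k <- rank
  }
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  img <- sweep(U, 2L, sv$d[seq_len(k)], `*`)
  tim <- t(V)
  ## sign convention: dominant sample of each time trace positive
  for (j in seq_len(k)) {
    s <- sign(tim[j, which.max(abs(tim[j, ]))])
    if (s < 0) { tim[j, ] <- -tim[j, ]; img[, j] <- -img[, j] }
  }
  new("Factorization", imageMatrix = img, timeMatrix = tim, k = as.integer(k),
      sourceShape = as.integer(dim(X)), stage = "pca",
      singularValues = sv$d[seq_len(k)])
}

## fixed-point (log-cosh negentropy) symmetric ICA on the rows of X.
## Returns the unmixing matrix applied to the centered, whitened rows.
fastICARotation <- function(X, seed, maxit = 1000L, tol = 1e-8) {
  k <- nrow(X)
  Xc <- X - rowMeans(X)
  n <- ncol(X)
  C <- Xc %*% t(Xc) / n
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, max(eg$values) * 1e-12)
  K <- diag(1 / sqrt(ev), k) %*% t(eg$vectors)      # whitening
  Z <- K %*% Xc
  set.seed(seed)
  W <- matrix(rnorm(k * k), k, k)
  sym <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym(W)
  for (it in seq_len(maxit)) {
    WX <- W %*% Z
    G <- tanh(WX)
    gp <- rowMeans(1 - G^2)
    W1 <- G %*% t(Z) / n - diag(gp, k) %*% W
    W1 <- sym(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) return(list(rotation = W %*% K, converged = TRUE))
  }
  list(rotation = W %*% K, converged = FALSE)
}

#' Unmix components by temporal independence
#'
#' Takes the top `kIca` principal components and finds the invertible
#' transform `U` that maximizes the temporal independence of
#' `D = U %*% timeMatrix` (fixed-point negentropy ICA with log-cosh
#' contrast), applying `U^{-1}` to the image matrix so the product - the
#' reconstruction of the data - is preserved exactly.  Components are
#' returned in order of ascending dominant-peak virtual time with each
#' trace's dominant peak positive.
#'
#' @param fact a [Factorization-class] with `stage = "pca"`.
#' @param kIca number of components to unmix (default 4, at most `fact@k`).
#' @param seed RNG seed of the ICA initialization (default 0).  The fit is
#'   restarted from `restarts` incremented seeds and the converged solution
#'   with the largest log-cosh negentropy is kept (deterministic given
#'   `seed`); if no restart converges an error is raised.
#' @param restarts number of restarts (default 5).
#' @param components which PCA components to unmix (default the top `kIca`
#'   by singular value).  A dominant bulk component - the shared background
#'   recovery every pixel exhibits - is best left out of the rotation (see
#'   [runPipeline()], which unmixes components `2..kIca+1` for that reason).
#' @return a [Factorization-class] with `stage = "ica"` whose product equals
#'   the selected components' reconstruction.
#' @export
icaUnmix <- function(fact, kIca = 4L, seed = 0L, components = NULL,
                     restarts = 5L) {
  if (is.null(components)) {
    if (kIca > fact@k)
      stop("kIca must be <= the number of PCA components", call. = FALSE)
    components <- seq_len(kIca)
  }
  kIca <- length(components)
  if (any(components > fact@k) || any(components < 1L))
    stop("components must index PCA components", call. = FALSE)
  if (kIca < 1L) stop("kIca must be >= 1", call. = FALSE)
  Tm <- fact@timeMatrix[components, , drop = FALSE]
  Im <- fact@imageMatrix[, components, drop = FALSE]
  rot <- NULL
  bestJ <- -Inf
  gaussRef <- 0.3745693   # E[log cosh(nu)], nu standard normal
  for (attempt in seq_len(restarts) - 1L) {
    r <- fastICARotation(Tm, seed = seed + attempt)
    if (!r$converged) next
    Dc <- r$rotation %*% (Tm - rowMeans(Tm))
    Dc <- Dc / sqrt(rowMeans(Dc^2))
    J <- sum((rowMeans(log(cosh(Dc))) - gaussRef)^2)
    if (J > bestJ) { bestJ <- J; rot <- r$rotation }
  }
  if (is.null(rot))
    stop("ICA did not converge after ", restarts, " seed retries",
         call. = FALSE)
  D <- rot %*% Tm
  C <- Im %*% solve(rot)
  ## deterministic order and sign: ascending dominant-peak time, peak +
  peakIdx <- apply(abs(D), 1L, which.max)
  ord <- order(peakIdx)
  D <- D[ord, , drop = FALSE]
  C <- C[, ord, drop = FALSE]
  for (j in seq_len(kIca)) {
    s <- sign(D[j, which.max(abs(D[j, ]))])
    if (s < 0) { D[j, ] <- -D[j, ]; C[, j] <- -C[, j] }
  }
  new("Factorization", imageMatrix = C, timeMatrix = D,
      k = as.integer(kIca), sourceShape = fact@sourceShape, stage = "ica",
      singularValues = fact@singularValues[components])
}

#' Scatter component weights back into images
#'
#' Each column of the image matrix is placed back at its pixel's image
#' coordinates; pixels outside the mask are `fill` (0 by default, or the
#' corresponding values of `surroundData` for display context).
#'
#' @param fact a [Factorization-class].
#' @param pixelIndex `n_pixels x 2` matrix of 1-based `(row, col)`.
#' @param shape image `(rows, cols)`.
#' @param surroundData optional [PixelMatrix-class] covering surrounding
#'   pixels for display; its pixels receive 0-weighted context (kept `NA`
#'   outside both masks).
#' @param fill background fill value (default 0).
#' @return list of numeric matrices, one per component.
#' @export
componentsToImages <- function(fact, pixelIndex, shape, surroundData = NULL,
                               fill = 0) {
  if (nrow(pixelIndex) != nrow(fact@imageMatrix))
    stop("pixelIndex does not match the factorization", call. = FALSE)
  if (any(pixelIndex[, 1] < 1L) || any(pixelIndex[, 1] > shape[1]) ||
      any(pixelIndex[, 2] < 1L) || any(pixelIndex[, 2] > shape[2]))
    stop("pixel index out of bounds", call. = FALSE)
  lin <- (pixelIndex[, 2] - 1L) * shape[1] + pixelIndex[, 1]
  lapply(seq_len(fact@k), function(j) {
    img <- matrix(fill, shape[1], shape[2])
    if (!is.null(surroundData)) {
      slin <- (surroundData@pixelIndex[, 2] - 1L) * shape[1] +
        surroundData@pixelIndex[, 1]
      img[slin] <- 0
    }
    img[lin] <- fact@imageMatrix[, j]
    img
  })
}
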