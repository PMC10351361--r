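# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream, restoring the caller's state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# World coordinates (mm) of voxel centers along each axis.
voxelAxes <- function(gridShape, spacingMm, originMm = c(0, 0, 0)) {
  lapply(1:3, function(a) originMm[a] + (seq_len(gridShape[a]) - 0.5) * spacingMm[a])
}

# Full coordinate arrays (as vectors in array order) for the in-plane axes.
voxelCoordArrays <- function(gridShape, spacingMm, originMm = c(0, 0, 0)) {
  ax <- voxelAxes(gridShape, spacingMm, originMm)
  nx <- gridShape[1]; ny <- gridShape[2]; nz <- gridShape[3]
  list(
    x = rep(ax[[1]], times = ny * nz),
    y = rep(rep(ax[[2]], each = nx), times = nz),
    z = rep(ax[[3]], each = nx * ny)
  )
}

# Vectorized trilinear interpolation of a 3D array at world points (mm).
# `pts` is an n x 3 matrix. Points outside the grid return `outside`.
# Degenerates to bilinear when the grid has a single slice.
trilinearSample <- function(arr, pts, spacingMm, originMm = c(0, 0, 0),
                            outside = 0) {
  dm <- dim(arr)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  # continuous voxel index (1-based, voxel centers at integers)
  fx <- (pts[, 1] - originMm[1]) / spacingMm[1] + 0.5
  fy <- (pts[, 2] - originMm[2]) / spacingMm[2] + 0.5
  fz <- if (nz == 1L) rep(1, nrow(pts)) else
    (pts[, 3] - originMm[3]) / spacingMm[3] + 0.5
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
  if (nz == 1L) { k0 <- rep(1, length(fx)); wz <- rep(0, length(fx)) }
  out <- rep(outside, nrow(pts))
  ok <- i0 >= 0 & i0 <= nx & j0 >= 0 & j0 <= ny &
    (nz == 1L | (k0 >= 0 & k0 <= nz))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  wxo <- wx[ok]; wyo <- wy[ok]; wzo <- wz[ok]
  at <- function(i, j, k) {
    v <- rep(0, length(i))
    inb <- i >= 1 & i <= nx & j >= 1 & j <= ny & k >= 1 & k <= nz
    if (any(inb))
      v[inb] <- arr[cbind(i[inb], j[inb], k[inb])]
    v
  }
  acc <-
    at(i0,     j0,     k0)     * (1 - wxo) * (1 - wyo) * (1 - wzo) +
    at(i0 + 1, j0,     k0)     * wxo       * (1 - wyo) * (1 - wzo) +
    at(i0,     j0 + 1, k0)     * (1 - wxo) * wyo       * (1 - wzo) +
    at(i0 + 1, j0 + 1, k0)     * wxo       * wyo       * (1 - wzo)
  if (nz > 1L) {
    acc <- acc +
      at(i0,     j0,     k0 + 1) * (1 - wxo) * (1 - wyo) * wzo +
      at(i0 + 1, j0,     k0 + 1) * wxo       * (1 - wyo) * wzo +
      at(i0,     j0 + 1, k0 + 1) * (1 - wxo) * wyo       * wzo +
      at(i0 + 1, j0 + 1, k0 + 1) * wxo       * wyo       * wzo
  }
  out[ok] <- acc
  out
}

# Sparse bilinear sampling operator: rows sample `pts` (n x 2, world mm in a
# 2D plane) from a grid with given axis coordinate vectors. Out-of-grid points
# get empty rows (i.e. sample as 0).
bilinearOperator <- function(pts, axX, axY) {
  nx <- length(axX); ny <- length(axY)
  hx <- axX[2] - axX[1]; hy <- axY[2] - axY[1]
  fx <- (pts[, 1] - axX[1]) / hx + 1
  fy <- (pts[, 2] - axY[1]) / hy + 1
  i0 <- floor(fx); j0 <- floor(fy)
  wx <- fx - i0; wy <- fy - j0
  n <- nrow(pts)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  add <- function(i, j, w) {
    inb <- i >= 1 & i <= nx & j >= 1 & j <= ny & w > 0
    if (any(inb)) {
      rows <<- c(rows, which(inb))
      cols <<- c(cols, (j[inb] - 1L) * nx + i[inb])
      vals <<- c(vals, w[inb])
    }
  }
  add(i0,      j0,      (1 - wx) * (1 - wy))
  add(i0 + 1L, j0,      wx * (1 - wy))
  add(i0,      j0 + 1L, (1 - wx) * wy)
  add(i0 + 1L, j0 + 1L, wx * wy)
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, nx * ny))
}

assertDoseGrid <- function(dose, gridShape = NULL) {
  stopifnot(is.numeric(dose))
  if (any(!is.finite(dose))) stop("dose grid contains non-finite values")
  if (any(dose < 0)) stop("dose grid contains negative values")
  if (!is.null(gridShape) && !identical(dim(dose), as.integer(gridShape)))
    stop("dose grid shape does not match phantom grid")
  invisible(TRUE)
}

maskVolumeVoxels <- function(mask) sum(mask)
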