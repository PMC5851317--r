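# Geometric projection triples (pixel-driven linear interpolation).
# Returns rows (bin index within angle block), cols (voxel), weights and,
# when needed, the signed position of each voxel along the LOR direction.
.geomTriples <- function(nx, ny, voxelSize, nAngles, nRadial, binWidth,
                         withTOF = FALSE) {
  co <- .voxelCoords(nx, ny, voxelSize)
  X <- as.vector(matrix(co$x, nx, ny))
  Y <- as.vector(matrix(co$y, nx, ny, byrow = TRUE))
  nVox <- nx * ny
  rowsL <- list(); colsL <- list(); wL <- list(); posL <- list()
  for (a in seq_len(nAngles)) {
    th <- (a - 1) * pi / nAngles
    r <- X * cos(th) + Y * sin(th)
    u <- r / binWidth + (nRadial + 1) / 2
    k0 <- floor(u)
    fr <- u - k0
    pos <- -X * sin(th) + Y * cos(th)
    base <- (a - 1L) * nRadial
    keep0 <- k0 >= 1 & k0 <= nRadial
    keep1 <- k0 + 1 >= 1 & k0 + 1 <= nRadial
    rowsL[[a]] <- c(base + k0[keep0], base + k0[keep1] + 1L)
    colsL[[a]] <- c(which(keep0), which(keep1))
    wL[[a]] <- voxelSize * c((1 - fr)[keep0], fr[keep1])
    if (withTOF) posL[[a]] <- c(pos[keep0], pos[keep1])
  }
  list(rows = unlist(rowsL), cols = unlist(colsL), w = unlist(wL),
       pos = if (withTOF) unlist(posL) else NULL, nVox = nVox)
}

# banded symmetric Gaussian convolution matrix (zero padding)
.gaussBand <- function(n, sigmaBins) {
  K <- max(1L, ceiling(4 * sigmaBins))
  k <- exp(-((-K:K)^2) / (2 * sigmaBins^2))
  k <- k / sum(k)
  B <- matrix(0, n, n)
  for (off in -K:K) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1 & j <= n
    B[cbind(i[ok], j[ok])] <- k[off + K + 1L]
  }
  B
}

#' Build the factored system operator
#'
#' Assembles the parallel-beam system response: a sparse geometric
#' projection matrix (pixel-driven linear interpolation; projections
#' approximate line integrals in mm), per-LOR attenuation factors
#' \eqn{\exp(-\int \mu\, dl)} computed by projecting the attenuation map,
#' per-LOR normalization efficiencies, an optional sinogram-space radial
#' Gaussian PSF, and optional TOF binning (a Gaussian kernel over position
#' along each LOR, discretized to bins; per-contribution bin weights sum to
#' one so the TOF sinogram marginalizes exactly to the non-TOF one).
#'
#' @param muMap attenuation map (matrix `nx x ny`, 1/cm), or `NULL` for
#'   no attenuation.
#' @param nx,ny,voxelSize image grid (voxels, mm). Taken from `muMap` when
#'   it is supplied.
#' @param nAngles projection angles, uniform over `[0, pi)`.
#' @param nRadial radial bins (default `nx`); `binWidth` defaults to the
#'   voxel size.
#' @param tof `NULL` or `list(nBins, binWidth, fwhm)` in mm along the LOR
#'   (defaults 13 bins x 30 mm, kernel FWHM 80 mm when enabled via
#'   `tof = TRUE`).
#' @param psf `NULL`/0 or the radial PSF FWHM in mm (a `list(fwhm=)` is
#'   also accepted).
#' @param normalization scalar or per-LOR vector of detector efficiencies.
#' @return a [SystemOperator-class].
#' @export
buildSystemOperator <- function(muMap = NULL, nx = NULL, ny = NULL,
                                voxelSize = 2, nAngles = 180L,
                                nRadial = NULL, binWidth = NULL,
                                tof = NULL, psf = NULL, normalization = 1) {
  if (!is.null(muMap)) {
    if (any(muMap < 0)) stop("invalid input: negative attenuation coefficients")
    nx <- nrow(muMap); ny <- ncol(muMap)
  }
  stopifnot(!is.null(nx), !is.null(ny))
  if (is.null(nRadial)) nRadial <- nx
  if (is.null(binWidth)) binWidth <- voxelSize
  nAngles <- as.integer(nAngles); nRadial <- as.integer(nRadial)

  if (isTRUE(tof)) tof <- list(nBins = 13L, binWidth = 30, fwhm = 80)
  nTOF <- if (is.null(tof)) 1L else as.integer(tof$nBins)
  if (is.numeric(psf)) psf <- if (psf > 0) list(fwhm = psf) else NULL
  psfFWHM <- if (is.null(psf)) 0 else psf$fwhm

  tri <- .geomTriples(nx, ny, voxelSize, nAngles, nRadial, binWidth,
                      withTOF = nTOF > 1L)
  nLOR <- nRadial * nAngles
  Ggeom <- Matrix::sparseMatrix(i = tri$rows, j = tri$cols, x = tri$w,
                                dims = c(nLOR, tri$nVox))

  att <- rep(1, nLOR)
  if (!is.null(muMap)) {
    li <- as.vector(Ggeom %*% as.vector(muMap)) / 10  # mm * (1/cm) -> unitless
    att <- exp(-li)
  }
  norm <- rep(normalization, length.out = nLOR)
  if (any(norm <= 0)) stop("normalization factors must be > 0")

  if (nTOF > 1L) {
    sig <- tof$fwhm / (2 * sqrt(2 * log(2)))
    centers <- (seq_len(nTOF) - (nTOF + 1) / 2) * tof$binWidth
    W <- exp(-outer(tri$pos, centers, "-")^2 / (2 * sig^2))
    W <- W / rowSums(W)
    keep <- W > 1e-12
    W <- W * keep
    W <- W / rowSums(W)
    nz <- which(keep, arr.ind = TRUE)
    G <- Matrix::sparseMatrix(
      i = tri$rows[nz[, 1]] + (nz[, 2] - 1L) * nLOR,
      j = tri$cols[nz[, 1]],
      x = tri$w[nz[, 1]] * W[nz],
      dims = c(nLOR * nTOF, tri$nVox))
  } else G <- Ggeom

  kern <- if (psfFWHM > 0)
    .gaussBand(nRadial, psfFWHM / (2 * sqrt(2 * log(2))) / binWidth)
  else NULL

  new("SystemOperator", nx = as.integer(nx), ny = as.integer(ny),
      voxelSize = voxelSize, nAngles = nAngles, nRadial = nRadial,
      binWidth = binWidth, G = G, attenuation = att, normalization = norm,
      psfFWHM = psfFWHM, psfKernel = kern, nTOF = nTOF,
      tofBinWidth = if (nTOF > 1L) tof$binWidth else 0,
      tofFWHM = if (nTOF > 1L) tof$fwhm else 0)
}

# copy of an operator with a different PSF setting (shares the sparse G)
.setPSF <- function(op, fwhm) {
  new("SystemOperator", nx = op@nx, ny = op@ny, voxelSize = op@voxelSize,
      nAngles = op@nAngles, nRadial = op@nRadial, binWidth = op@binWidth,
      G = op@G, attenuation = op@attenuation,
      normalization = op@normalization,
      psfFWHM = if (fwhm > 0) fwhm else 0,
      psfKernel = if (fwhm > 0)
        .gaussBand(op@nRadial, fwhm / (2 * sqrt(2 * log(2))) / op@binWidth)
      else NULL,
      nTOF = op@nTOF, tofBinWidth = op@tofBinWidth, tofFWHM = op@tofFWHM)
}

# radial PSF blur of a flattened sinogram vector (self-adjoint)
.psfBlur <- function(op, y) {
  if (is.null(op@psfKernel)) return(y)
  dim(y) <- c(op@nRadial, length(y) / op@nRadial)
  as.vector(op@psfKernel %*% y)
}

#' Forward projection
#'
#' Applies the full factored operator: geometric projection (with TOF
#' binning if enabled), attenuation, radial PSF blur, then normalization.
#' Linear in the image; nonnegative images give nonnegative sinograms.
#'
#' @param image matrix `nx x ny` (or a vector of length `nx*ny`).
#' @param op a [SystemOperator-class].
#' @return sinogram array `nRadial x nAngles x nTOF`.
#' @export
forwardProject <- function(image, op) {
  stopifnot(is(op, "SystemOperator"))
  f <- as.vector(image)
  if (length(f) != op@nx * op@ny) stop("image does not match operator grid")
  if (any(!is.finite(f))) stop("image must be finite")
  attF <- rep(op@attenuation, op@nTOF)
  y <- as.vector(op@G %*% f) * attF
  y <- .psfBlur(op, y) * rep(op@normalization, op@nTOF)
  array(y, dim = c(op@nRadial, op@nAngles, op@nTOF))
}

#' Back projection (exact adjoint of [forwardProject()])
#'
#' @param sino sinogram array `nRadial x nAngles x nTOF` (or flattened).
#' @param op a [SystemOperator-class].
#' @return image matrix `nx x ny`.
#' @export
backProject <- function(sino, op) {
  stopifnot(is(op, "SystemOperator"))
  y <- as.vector(sino)
  if (length(y) != op@nRadial * op@nAngles * op@nTOF)
    stop("sinogram does not match operator shape")
  attF <- rep(op@attenuation, op@nTOF)
  z <- .psfBlur(op, y * rep(op@normalization, op@nTOF)) * attF
  matrix(as.vector(Matrix::crossprod(op@G, z)), op@nx, op@ny)
}

#' Partition projection angles into interleaved subsets
#'
#' Subset `q` (1-based) contains the angle indices congruent to `q` modulo
#' `nSubsets`, so subsets are evenly distributed over the angular range and
#' their sizes differ by at most one.
#'
#' @param nAngles total number of angles.
#' @param nSubsets number of subsets (1 = MLEM).
#' @return list of integer vectors (disjoint, exhaustive).
#' @export
makeSubsets <- function(nAngles, nSubsets) {
  nAngles <- as.integer(nAngles); nSubsets <- as.integer(nSubsets)
  if (nSubsets < 1L || nSubsets > nAngles)
    stop("invalid parameter: need 1 <= nSubsets <= nAngles")
  lapply(seq_len(nSubsets), function(q) seq.int(q, nAngles, by = nSubsets))
}

#' Simulate Poisson emission counts with randoms and scatter
#'
#' The randoms expectation is uniform at `randomsFraction x mean(trues)`;
#' the scatter expectation is a heavily radially smoothed copy of the
#' trues (Gaussian FWHM 50 mm) rescaled so its total equals
#' `scatterFraction x sum(trues)`. Prompts are drawn as
#' `Poisson(trues + randoms + scatter)`, reproducibly for a given seed.
#'
#' @param trues expected true-coincidence sinogram (array, as produced by
#'   [forwardProject()] and scaled to counts).
#' @param op the [SystemOperator-class] (provides the radial bin width).
#' @param randomsFraction,scatterFraction nonnegative background fractions.
#' @param seed integer RNG seed (uses the global RNG stream when `NULL`).
#' @param frameIndex frame label carried in the result.
#' @return a [SinogramSet-class].
#' @export
simulateCounts <- function(trues, op, randomsFraction = 0.1,
                           scatterFraction = 0.15, seed = NULL,
                           frameIndex = 1L) {
  if (randomsFraction < 0 || scatterFraction < 0)
    stop("invalid parameter: background fractions must be >= 0")
  if (any(trues < 0)) stop("expected trues must be >= 0")
  dims <- dim(trues)
  r <- array(randomsFraction * mean(trues), dim = dims)
  s <- array(0, dim = dims)
  if (scatterFraction > 0 && sum(trues) > 0) {
    B <- .gaussBand(op@nRadial, 50 / (2 * sqrt(2 * log(2))) / op@binWidth)
    sm <- trues
    dim(sm) <- c(op@nRadial, length(sm) / op@nRadial)
    sm <- B %*% sm
    s <- array(as.vector(sm), dim = dims)
    s <- s * (scatterFraction * sum(trues) / sum(s))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- array(rpois(length(trues), as.vector(trues + r + s)), dim = dims)
  new("SinogramSet", prompts = p, randoms = r, scatter = s,
      frameIndex = as.integer(frameIndex))
}
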