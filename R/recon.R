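#' Reconstruction configuration constructor
#'
#' Defaults mirror the clinical protocol studied here: OSEM with 20
#' iterations x 10 subsets (EM-equivalent 200) and a 6.5 mm post-filter;
#' TOF and TPSF with 10 x 10 (EM-equivalent 100) and a 5.0 mm post-filter;
#' FBP with a Hann-apodized ramp.
#'
#' @param method "FBP", "OSEM", "TOF" or "TPSF".
#' @param nIterations,nSubsets iteration/subset counts (iterative methods).
#' @param postfilterFWHM image-space Gaussian post-filter FWHM (mm).
#' @param fbpApodization "ramp" or "hann".
#' @return a [ReconConfig-class].
#' @export
reconConfig <- function(method = c("OSEM", "FBP", "TOF", "TPSF"),
                        nIterations = NULL, nSubsets = 10L,
                        postfilterFWHM = NULL,
                        fbpApodization = "hann") {
  method <- match.arg(method)
  if (is.null(nIterations))
    nIterations <- switch(method, OSEM = 20L, TOF = 10L, TPSF = 10L, FBP = 1L)
  if (is.null(postfilterFWHM))
    postfilterFWHM <- switch(method, OSEM = 6.5, TOF = 5, TPSF = 5, FBP = 0)
  new("ReconConfig", method = method, nIterations = as.integer(nIterations),
      nSubsets = as.integer(nSubsets), postfilterFWHM = postfilterFWHM,
      fbpApodization = fbpApodization)
}

# per-subset projection structures (rows keep radial-major order so the
# radial PSF blur applies unchanged)
.osemSetup <- function(op, nSubsets) {
  subsets <- makeSubsets(op@nAngles, nSubsets)
  nLOR <- op@nRadial * op@nAngles
  attF <- rep(op@attenuation, op@nTOF)
  normF <- rep(op@normalization, op@nTOF)
  lapply(subsets, function(ang) {
    lorRows <- as.vector(vapply(ang, function(a)
      (a - 1L) * op@nRadial + seq_len(op@nRadial), integer(op@nRadial)))
    rows <- as.vector(outer(lorRows, (seq_len(op@nTOF) - 1L) * nLOR, "+"))
    list(rows = rows, G = op@G[rows, , drop = FALSE],
         att = attF[rows], norm = normF[rows])
  })
}

.subBlur <- function(op, y) {
  if (is.null(op@psfKernel)) return(y)
  dim(y) <- c(op@nRadial, length(y) / op@nRadial)
  as.vector(op@psfKernel %*% y)
}

.fprojSub <- function(op, sub, f) {
  .subBlur(op, as.vector(sub$G %*% f) * sub$att) * sub$norm
}

.bprojSub <- function(op, sub, y) {
  as.vector(Matrix::crossprod(sub$G, .subBlur(op, y * sub$norm) * sub$att))
}

# core ordinary-Poisson OSEM loop over prepared subsets
.osemRun <- function(op, setup, p, r, s, nIterations, initial,
                     snapshots = FALSE, epsilon = 1e-12) {
  f <- as.vector(initial)
  sens <- lapply(setup, function(sub) .bprojSub(op, sub, rep(1, length(sub$rows))))
  snaps <- if (snapshots) vector("list", nIterations) else list()
  nGuard <- 0L
  for (k in seq_len(nIterations)) {
    for (q in seq_along(setup)) {
      sub <- setup[[q]]
      yh <- .fprojSub(op, sub, f) + r[sub$rows] + s[sub$rows]
      pq <- p[sub$rows]
      nGuard <- nGuard + sum(yh <= epsilon & pq > 0)
      ratio <- pq / pmax(yh, epsilon)
      bp <- .bprojSub(op, sub, ratio)
      sq <- sens[[q]]
      f <- ifelse(sq > epsilon, f * bp / sq, 0)
    }
    if (snapshots) snaps[[k]] <- matrix(f, op@nx, op@ny)
  }
  if (nGuard > 0)
    message(sprintf("OSEM: epsilon-floored %d zero-model bins with counts",
                    nGuard))
  list(image = matrix(f, op@nx, op@ny), snapshots = snaps)
}

#' Ordinary-Poisson OSEM reconstruction
#'
#' Iterates the multiplicative ordered-subsets update
#' \deqn{f_j^{k,q+1} = \frac{f_j^{k,q}}{\sum_{i \in S_q} A_{ij}}
#'   \sum_{i \in S_q} A_{ij} \frac{p_i}{\sum_l A_{il} f_l^{k,q} + r_i + s_i}}
#' cycling subsets sequentially within each iteration. Randoms and scatter
#' expectations enter the denominator of the forward model (they are never
#' subtracted from the data), so every iterate is nonnegative. Bins whose
#' modelled denominator underflows are floored at `epsilon` and reported;
#' voxels with zero sensitivity are frozen at 0.
#'
#' @param data a [SinogramSet-class] matching the operator's binning.
#' @param op a [SystemOperator-class].
#' @param config a [ReconConfig-class] with an iterative `method`.
#' @param initial starting image (> 0; default uniform 1).
#' @param snapshots keep the image after every full iteration (for
#'   convergence analysis).
#' @param epsilon denominator/sensitivity floor.
#' @return a [ReconResult-class] (image in raw data units; see
#'   [toActivityConcentration()]).
#' @export
osemReconstruct <- function(data, op, config, initial = NULL,
                            snapshots = FALSE, epsilon = 1e-12) {
  stopifnot(is(data, "SinogramSet"), is(op, "SystemOperator"),
            is(config, "ReconConfig"))
  if (config@method == "FBP") stop("use fbpReconstruct for FBP")
  if (config@method %in% c("TOF", "TPSF") && op@nTOF <= 1L)
    stop(config@method, " requires a TOF-enabled operator")
  if (config@method == "TPSF" && op@psfFWHM <= 0)
    stop("TPSF requires a PSF-enabled operator")
  expected <- c(op@nRadial, op@nAngles, op@nTOF)
  if (!identical(dim(data@prompts), as.integer(expected)))
    stop("sinogram shape does not match operator")
  if (is.null(initial)) initial <- rep(1, op@nx * op@ny)
  if (any(initial < 0)) stop("initial image must be >= 0")
  setup <- .osemSetup(op, config@nSubsets)
  out <- .osemRun(op, setup, as.vector(data@prompts), as.vector(data@randoms),
                  as.vector(data@scatter), config@nIterations, initial,
                  snapshots = snapshots, epsilon = epsilon)
  new("ReconResult", image = out$image, config = config,
      snapshots = out$snapshots)
}

# discrete Ram-Lak kernel filtering of an (nRadial x nAngles) sinogram
.rampFilter <- function(P, binWidth, apodization = "ramp") {
  nRad <- nrow(P)
  L <- 2^ceiling(log2(2 * nRad))
  h <- numeric(L)
  h[1] <- 1 / (4 * binWidth^2)
  nOdd <- seq(1, nRad, by = 2)
  h[1 + nOdd] <- -1 / (pi^2 * nOdd^2 * binWidth^2)
  h[L + 1 - nOdd] <- -1 / (pi^2 * nOdd^2 * binWidth^2)
  Hf <- Re(fft(h))
  if (apodization == "hann") {
    m <- 0:(L - 1)
    fr <- pmin(m, L - m) / (L * binWidth)
    Hf <- Hf * 0.5 * (1 + cos(pi * fr / (1 / (2 * binWidth))))
  }
  Ppad <- rbind(P, matrix(0, L - nRad, ncol(P)))
  Q <- Re(stats::mvfft(stats::mvfft(Ppad) * Hf, inverse = TRUE)) / L
  Q[seq_len(nRad), , drop = FALSE] * binWidth
}

#' Filtered backprojection reconstruction
#'
#' Precorrects the data (`(p - r - s) / (attenuation x normalization)`,
#' after summing TOF bins if present), ramp-filters each angular profile
#' (optionally Hann-apodized), and backprojects geometrically. The result
#' is linear in the prompts and may contain negative values.
#'
#' @param data a [SinogramSet-class].
#' @param op the [SystemOperator-class] describing the geometry.
#' @param config a [ReconConfig-class] with `method = "FBP"`.
#' @return a [ReconResult-class].
#' @export
fbpReconstruct <- function(data, op, config = reconConfig("FBP")) {
  stopifnot(is(data, "SinogramSet"), is(op, "SystemOperator"))
  sum3 <- function(a) {
    if (length(dim(a)) == 3L && dim(a)[3] > 1L) rowSums(a, dims = 2L)
    else matrix(a, op@nRadial, op@nAngles)
  }
  pre <- (sum3(data@prompts) - sum3(data@randoms) - sum3(data@scatter)) /
    matrix(op@attenuation * op@normalization, op@nRadial, op@nAngles)
  Q <- .rampFilter(pre, op@binWidth, config@fbpApodization)
  yv <- rep(as.vector(Q), op@nTOF)  # TOF rows of G marginalize to geometry
  img <- matrix(as.vector(Matrix::crossprod(op@G, yv)), op@nx, op@ny)
  img <- img * pi / (op@nAngles * op@voxelSize)
  new("ReconResult", image = img, config = config, snapshots = list())
}

#' Reconstruct (method dispatch)
#'
#' @param data a [SinogramSet-class].
#' @param op a [SystemOperator-class].
#' @param config a [ReconConfig-class]; FBP routes to [fbpReconstruct()],
#'   everything else to [osemReconstruct()].
#' @param ... passed to the backend.
#' @return a [ReconResult-class].
#' @export
reconstruct <- function(data, op, config, ...) {
  if (config@method == "FBP") fbpReconstruct(data, op, config)
  else osemReconstruct(data, op, config, ...)
}

# 1D symmetric-padding Gaussian convolution along matrix rows
.conv1dSym <- function(M, sigmaVox) {
  K <- max(1L, ceiling(4 * sigmaVox))
  k <- exp(-((-K:K)^2) / (2 * sigmaVox^2))
  k <- k / sum(k)
  n <- nrow(M)
  idx <- c(rev(seq_len(min(K, n))), seq_len(n),
           rev(seq_len(n))[seq_len(min(K, n))])
  if (K > n) stop("post-filter kernel wider than image")
  P <- M[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(M))
  for (off in 0:(2 * K)) out <- out + k[off + 1] * P[off + seq_len(n), , drop = FALSE]
  out
}

#' Gaussian post-filter
#'
#' Separable image-space Gaussian smoothing with the stated FWHM
#' (\eqn{\sigma = FWHM / 2.3548} mm, converted to voxels). Half-sample
#' symmetric (edge-mirror) boundary handling makes the filter conserve the
#' image sum exactly and map uniform images to themselves; `fwhm = 0`
#' returns the input unchanged.
#'
#' @param image matrix.
#' @param fwhm filter FWHM in mm (>= 0).
#' @param voxelSize voxel edge in mm.
#' @return filtered matrix.
#' @export
postFilter <- function(image, fwhm, voxelSize = 2) {
  if (fwhm < 0) stop("invalid parameter: fwhm must be >= 0")
  if (fwhm == 0) return(image)
  sig <- fwhm / (2 * sqrt(2 * log(2))) / voxelSize
  t(.conv1dSym(t(.conv1dSym(image, sig)), sig))
}

#' Convert a reconstructed frame to decay-corrected activity concentration
#'
#' Divides by the frame duration, the calibration scale, and the
#' frame-averaged decay factor
#' \eqn{\frac{1}{\Delta}\int e^{-\lambda t} dt} over the frame
#' (\eqn{\lambda = \ln 2 / T_{1/2}}), referencing all frames back to
#' injection time.
#'
#' @param image reconstructed frame (matrix, raw data units) or a
#'   [ReconResult-class].
#' @param start,duration frame start and duration (seconds).
#' @param halfLife isotope half-life (minutes).
#' @param calibration scale from activity x time to data units
#'   (counts * mL / (kBq mm s) in this simulation chain; default 1).
#' @return matrix in kBq/mL, decay-corrected to injection.
#' @export
toActivityConcentration <- function(image, start, duration, halfLife = 20,
                                    calibration = 1) {
  if (halfLife <= 0) stop("invalid parameter: halfLife must be > 0")
  if (duration <= 0) stop("invalid parameter: duration must be > 0")
  if (is(image, "ReconResult")) image <- image@image
  image / (duration * calibration * frameDecayFactor(start, duration, halfLife))
}

#' Reconstruct a full dynamic series
#'
#' Applies one reconstruction configuration to every frame, converts to
#' decay-corrected activity concentration, and post-filters the final
#' images (snapshots, kept for convergence analysis, stay unfiltered so
#' the convergence of the raw algorithm is measured).
#'
#' @param sinos list of [SinogramSet-class], one per schedule frame.
#' @param op the [SystemOperator-class].
#' @param config a [ReconConfig-class].
#' @param sched the [FrameSchedule-class].
#' @param halfLife isotope half-life (minutes).
#' @param calibration counts calibration (see [toActivityConcentration()]).
#' @param snapshots when TRUE also return a series per full iteration.
#' @return a [DynamicImageSeries-class], or (with `snapshots`) a list with
#'   elements `series` and `byLevel` (list of series, one per iteration).
#' @export
reconDynamicSeries <- function(sinos, op, config, sched, halfLife = 20,
                               calibration = 1, snapshots = FALSE) {
  nF <- nFrames(sched)
  stopifnot(length(sinos) == nF)
  st <- frameStarts(sched); du <- frameDurations(sched)
  data <- array(0, dim = c(op@nx, op@ny, nF))
  snapData <- if (snapshots && config@method != "FBP")
    lapply(seq_len(config@nIterations),
           function(i) array(0, dim = c(op@nx, op@ny, nF)))
  else NULL
  for (f in seq_len(nF)) {
    res <- reconstruct(sinos[[f]], op, config,
                       snapshots = isTRUE(snapshots) && config@method != "FBP")
    img <- toActivityConcentration(res@image, st[f], du[f], halfLife,
                                   calibration)
    data[, , f] <- postFilter(img, config@postfilterFWHM, op@voxelSize)
    if (!is.null(snapData))
      for (k in seq_along(res@snapshots))
        snapData[[k]][, , f] <- toActivityConcentration(
          res@snapshots[[k]], st[f], du[f], halfLife, calibration)
  }
  mk <- function(arr) new("DynamicImageSeries", data = arr, schedule = sched,
                          voxelSize = op@voxelSize, decayCorrected = TRUE,
                          halfLife = halfLife)
  if (is.null(snapData)) return(mk(data))
  list(series = mk(data), byLevel = lapply(snapData, mk))
}
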