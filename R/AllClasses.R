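#' @import methods
#' @importFrom Matrix sparseMatrix t crossprod
#' @importFrom stats rpois rnorm runif lm coef cor t.test sd median approx
#'   convolve fft setNames qnorm quantile
#' @importFrom utils write.csv read.csv
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Dynamic frame schedule
#'
#' Ordered, contiguous list of dynamic-frame start times and durations
#' defining the acquisition protocol. Time origin (0 s) is the injection.
#'
#' @slot start numeric vector of frame start times (seconds).
#' @slot duration numeric vector of frame durations (seconds).
#' @slot injectionTime injection time on the schedule clock (seconds);
#'   fixed at 0 by the constructor.
#'
#' @seealso [buildFrameSchedule()]
#' @export
setClass("FrameSchedule",
  representation(start = "numeric", duration = "numeric",
                 injectionTime = "numeric"))

setValidity("FrameSchedule", function(object) {
  msg <- character(0)
  n <- length(object@start)
  if (n == 0L) msg <- c(msg, "schedule must contain at least one frame")
  if (length(object@duration) != n)
    msg <- c(msg, "start and duration lengths differ")
  if (n > 0 && any(object@duration <= 0))
    msg <- c(msg, "all frame durations must be > 0")
  if (n > 0 && abs(object@start[1]) > 1e-9)
    msg <- c(msg, "first frame must start at 0")
  if (n > 1) {
    gap <- object@start[-1] - (object@start[-n] + object@duration[-n])
    if (any(abs(gap) > 1e-6))
      msg <- c(msg, "frames must be contiguous and non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' 2D cardiac phantom specification
#'
#' Geometry, attenuation and regional kinetics of a single-slice cardiac
#' phantom: left-/right-ventricular blood pools (discs), a myocardial
#' annulus, and a soft-tissue background disc. Later regions overwrite
#' earlier ones when rasterized; the constructor orders them
#' background < RV < LV < myocardium so annulus boundaries are deterministic.
#'
#' @slot nx,ny integer grid dimensions (voxels).
#' @slot voxelSize voxel edge length (mm).
#' @slot regions list of region descriptors. Each region is a list with
#'   `name`, `type` ("disc" or "annulus"), `center` (mm, relative to grid
#'   center), `radius` (mm; for an annulus `c(inner, outer)`), `mu`
#'   (attenuation, 1/cm), and `kinetics` (either
#'   `list(type = "blood", shift = seconds)` or
#'   `list(type = "tissue", K1 = , k2 = )` with rates in 1/min).
#'
#' @seealso [cardiacPhantom()], [rasterizePhantom()], [makeDynamicTruth()]
#' @export
setClass("PhantomSpec",
  representation(nx = "integer", ny = "integer", voxelSize = "numeric",
                 regions = "list"))

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (object@nx < 2L || object@ny < 2L) msg <- c(msg, "grid must be >= 2x2")
  if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be > 0")
  if (!length(object@regions)) msg <- c(msg, "at least one region required")
  for (r in object@regions) {
    if (any(r$radius <= 0))
      msg <- c(msg, sprintf("region '%s': radii must be > 0", r$name))
    if (identical(r$type, "annulus") && r$radius[2] <= r$radius[1])
      msg <- c(msg, sprintf("region '%s': outer radius must exceed inner",
                            r$name))
    if (r$mu < 0) msg <- c(msg, sprintf("region '%s': mu must be >= 0", r$name))
  }
  if (length(msg)) msg else TRUE
})

#' Parametric arterial input function
#'
#' Analytic whole-blood input curve driving the phantom kinetics. Two
#' models are available: the Feng four-exponential bolus model
#' \eqn{C_P(t) = (A_1 t - A_2 - A_3) e^{\lambda_1 t} + A_2 e^{\lambda_2 t}
#' + A_3 e^{\lambda_3 t}} and a gamma variate
#' \eqn{A t^{\alpha} e^{-t/\beta}}, both shifted by `delay` and zero
#' before it. Units are kBq/mL; time inside the model is minutes.
#'
#' @slot model "feng" or "gamma_variate".
#' @slot parameters named numeric model coefficients (`A1`, `A2`, `A3`,
#'   `lambda1..3` for Feng; `A`, `alpha`, `beta` for the gamma variate).
#' @slot delay arrival delay in seconds.
#'
#' @seealso [inputFunction()], [evaluateInputFunction()]
#' @export
setClass("InputFunction",
  representation(model = "character", parameters = "numeric",
                 delay = "numeric"))

#' Dynamic image series
#'
#' Per-frame activity-concentration images (kBq/mL) on a fixed grid,
#' together with the frame schedule, a decay-correction flag, and the
#' isotope half-life.
#'
#' @slot data numeric array `nx x ny x nFrames`.
#' @slot schedule the [FrameSchedule-class] the frames were binned on.
#' @slot voxelSize voxel edge length (mm).
#' @slot decayCorrected logical; `TRUE` once values are referenced back to
#'   injection time.
#' @slot halfLife isotope half-life in minutes (20 for carbon-11 here).
#'
#' @export
setClass("DynamicImageSeries",
  representation(data = "array", schedule = "FrameSchedule",
                 voxelSize = "numeric", decayCorrected = "logical",
                 halfLife = "numeric"))

setValidity("DynamicImageSeries", function(object) {
  msg <- character(0)
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3D array (nx, ny, frame)")
  else if (d[3] != length(object@schedule@start))
    msg <- c(msg, "number of images must equal number of schedule frames")
  if (any(!is.finite(object@data))) msg <- c(msg, "all values must be finite")
  if (object@halfLife <= 0) msg <- c(msg, "halfLife must be > 0")
  if (length(msg)) msg else TRUE
})

#' Factored tomographic system operator
#'
#' Parallel-beam system response factored as
#' normalization x (radial PSF blur) x attenuation x geometric projection,
#' with optional time-of-flight (TOF) binning. The geometric part is a
#' sparse matrix built by pixel-driven linear interpolation (each voxel
#' center projected onto the radial axis, weight split between the two
#' nearest bins, scaled by the voxel size so projections approximate
#' line integrals in mm). TOF distributes each voxel's contribution over
#' TOF bins with a Gaussian positional kernel whose per-voxel weights sum
#' to one, so summing over TOF bins reproduces the non-TOF sinogram.
#' Forward and back projection are exact adjoints by construction.
#'
#' @slot nx,ny,voxelSize image grid.
#' @slot nAngles,nRadial,binWidth sinogram geometry (angles uniform over
#'   `[0, pi)`; radial bin width in mm).
#' @slot G sparse geometric (+TOF) matrix, `nBins x nVoxels`.
#' @slot attenuation per-bin multiplicative attenuation factors in (0, 1].
#' @slot normalization per-bin detector efficiencies (> 0).
#' @slot psfFWHM sinogram-space radial PSF FWHM in mm (0 = disabled).
#' @slot psfKernel banded radial convolution matrix (or NULL).
#' @slot nTOF number of TOF bins (1 = TOF disabled).
#' @slot tofBinWidth,tofFWHM TOF bin width and kernel FWHM along the LOR (mm).
#'
#' @seealso [buildSystemOperator()], [forwardProject()], [backProject()]
#' @export
setClass("SystemOperator",
  representation(nx = "integer", ny = "integer", voxelSize = "numeric",
                 nAngles = "integer", nRadial = "integer",
                 binWidth = "numeric", G = "ANY",
                 attenuation = "numeric", normalization = "numeric",
                 psfFWHM = "numeric", psfKernel = "matrixOrNULL",
                 nTOF = "integer", tofBinWidth = "numeric",
                 tofFWHM = "numeric"))

setValidity("SystemOperator", function(object) {
  msg <- character(0)
  if (any(object@attenuation <= 0 | object@attenuation > 1 + 1e-12))
    msg <- c(msg, "attenuation factors must lie in (0, 1]")
  if (any(object@normalization <= 0))
    msg <- c(msg, "normalization factors must be > 0")
  if (length(msg)) msg else TRUE
})

#' Measured emission data for one frame
#'
#' Prompt coincidence counts with the expectations of the additive randoms
#' and scatter backgrounds, on the (radial, angle[, TOF]) binning of the
#' operator that produced them. In the ordinary-Poisson formulation the
#' backgrounds enter the reconstruction forward model; they are never
#' subtracted from the iterative data.
#'
#' @slot prompts,randoms,scatter numeric arrays of identical shape
#'   (`nRadial x nAngles x nTOF`); prompts are nonnegative counts,
#'   randoms/scatter nonnegative expectations.
#' @slot frameIndex integer frame index within the dynamic series.
#'
#' @export
setClass("SinogramSet",
  representation(prompts = "array", randoms = "array", scatter = "array",
                 frameIndex = "integer"))

setValidity("SinogramSet", function(object) {
  msg <- character(0)
  if (!identical(dim(object@prompts), dim(object@randoms)) ||
      !identical(dim(object@prompts), dim(object@scatter)))
    msg <- c(msg, "prompts, randoms and scatter must share one shape")
  if (any(object@prompts < 0) || any(!is.finite(object@prompts)))
    msg <- c(msg, "prompts must be finite and >= 0")
  if (any(object@randoms < 0) || any(object@scatter < 0))
    msg <- c(msg, "randoms and scatter expectations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Reconstruction configuration
#'
#' @slot method one of "FBP", "OSEM", "TOF", "TPSF". "TOF" is OSEM on
#'   TOF-binned data; "TPSF" additionally requires a PSF-enabled operator.
#' @slot nIterations number of full iterations (each cycles all subsets).
#' @slot nSubsets number of angular subsets.
#' @slot postfilterFWHM image-space Gaussian post-filter FWHM (mm); 0 = none.
#' @slot fbpApodization "ramp" or "hann".
#'
#' The EM-equivalent iteration count (the common convergence axis across
#' subset choices) is `nIterations * nSubsets`; see [emEquivalent()].
#'
#' @seealso [reconConfig()]
#' @export
setClass("ReconConfig",
  representation(method = "character", nIterations = "integer",
                 nSubsets = "integer", postfilterFWHM = "numeric",
                 fbpApodization = "character"))

setValidity("ReconConfig", function(object) {
  msg <- character(0)
  if (!object@method %in% c("FBP", "OSEM", "TOF", "TPSF"))
    msg <- c(msg, "method must be one of FBP, OSEM, TOF, TPSF")
  if (object@method != "FBP" && object@nIterations < 1L)
    msg <- c(msg, "iterative methods need nIterations >= 1")
  if (object@nSubsets < 1L) msg <- c(msg, "nSubsets must be >= 1")
  if (object@postfilterFWHM < 0) msg <- c(msg, "postfilterFWHM must be >= 0")
  if (!object@fbpApodization %in% c("ramp", "hann"))
    msg <- c(msg, "fbpApodization must be 'ramp' or 'hann'")
  if (length(msg)) msg else TRUE
})

#' Reconstruction result
#'
#' @slot image reconstructed image (matrix `nx x ny`). Iterative images are
#'   nonnegative everywhere; FBP images may legitimately contain negative
#'   values (the algorithm is linear).
#' @slot config the [ReconConfig-class] used.
#' @slot snapshots optional list of per-full-iteration images for
#'   convergence analysis (empty unless requested).
#'
#' @export
setClass("ReconResult",
  representation(image = "matrix", config = "ReconConfig",
                 snapshots = "list"))

#' Kinetic fit result
#'
#' One-tissue-compartment fit with dual (LV + RV) spillover correction.
#'
#' @slot params named numeric: `K1` (mL/min/mL), `k2` (1/min), `v_lv`,
#'   `v_rv` (unitless spillover fractions).
#' @slot covariance parameter covariance estimate (4x4) or a 0x0 matrix if
#'   unavailable.
#' @slot rss weighted residual sum of squares.
#' @slot weights per-frame weights used.
#' @slot converged logical convergence flag.
#' @slot nEval number of model-function evaluations across starts.
#' @slot fitted fitted model TAC (frame values).
#'
#' @seealso [fit1TCM()]
#' @export
setClass("KineticFit",
  representation(params = "numeric", covariance = "matrix", rss = "numeric",
                 weights = "numeric", converged = "logical",
                 nEval = "integer", fitted = "numeric"))

setValidity("KineticFit", function(object) {
  msg <- character(0)
  p <- object@params
  if (!all(c("K1", "k2", "v_lv", "v_rv") %in% names(p)))
    msg <- c(msg, "params must contain K1, k2, v_lv, v_rv")
  else {
    if (p[["K1"]] < 0 || p[["k2"]] < 0) msg <- c(msg, "K1, k2 must be >= 0")
    if (p[["v_lv"]] + p[["v_rv"]] > 1 + 1e-9)
      msg <- c(msg, "v_lv + v_rv must be <= 1")
  }
  if (!is.finite(object@rss)) msg <- c(msg, "rss must be finite")
  if (length(msg)) msg else TRUE
})
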