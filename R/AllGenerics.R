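#' Number of frames in a schedule or series
#' @param x a [FrameSchedule-class] or [DynamicImageSeries-class].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame start times (seconds)
#' @param x a [FrameSchedule-class] or [DynamicImageSeries-class].
#' @return numeric vector.
#' @export
setGeneric("frameStarts", function(x) standardGeneric("frameStarts"))

#' Frame durations (seconds)
#' @param x a [FrameSchedule-class] or [DynamicImageSeries-class].
#' @return numeric vector.
#' @export
setGeneric("frameDurations", function(x) standardGeneric("frameDurations"))

#' Frame mid-times (seconds)
#' @param x a [FrameSchedule-class] or [DynamicImageSeries-class].
#' @return numeric vector of `start + duration/2`.
#' @export
setGeneric("frameMids", function(x) standardGeneric("frameMids"))

#' Total scheduled duration (seconds)
#' @param x a [FrameSchedule-class] or [DynamicImageSeries-class].
#' @return total duration in seconds.
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))

setMethod("nFrames", "FrameSchedule", function(x) length(x@start))
setMethod("frameStarts", "FrameSchedule", function(x) x@start)
setMethod("frameDurations", "FrameSchedule", function(x) x@duration)
setMethod("frameMids", "FrameSchedule", function(x) x@start + x@duration / 2)
setMethod("totalDuration", "FrameSchedule", function(x) sum(x@duration))

setMethod("nFrames", "DynamicImageSeries", function(x) nFrames(x@schedule))
setMethod("frameStarts", "DynamicImageSeries", function(x) frameStarts(x@schedule))
setMethod("frameDurations", "DynamicImageSeries",
          function(x) frameDurations(x@schedule))
setMethod("frameMids", "DynamicImageSeries", function(x) frameMids(x@schedule))
setMethod("totalDuration", "DynamicImageSeries",
          function(x) totalDuration(x@schedule))

#' Extract the schedule of a dynamic series
#' @param x a [DynamicImageSeries-class].
#' @return the [FrameSchedule-class].
#' @export
schedule <- function(x) {
  stopifnot(is(x, "DynamicImageSeries"))
  x@schedule
}

#' Extract one frame image from a dynamic series
#' @param x a [DynamicImageSeries-class].
#' @param i frame index.
#' @return matrix `nx x ny`.
#' @export
frameImage <- function(x, i) {
  stopifnot(is(x, "DynamicImageSeries"))
  x@data[, , i]
}

#' Reconstructed image of a ReconResult
#' @param x a [ReconResult-class].
#' @return matrix.
#' @export
reconImage <- function(x) {
  stopifnot(is(x, "ReconResult"))
  x@image
}

#' Per-iteration snapshots of a ReconResult
#' @param x a [ReconResult-class].
#' @return list of matrices (possibly empty).
#' @export
reconSnapshots <- function(x) {
  stopifnot(is(x, "ReconResult"))
  x@snapshots
}

#' Fitted kinetic parameters
#' @param x a [KineticFit-class].
#' @return named numeric vector `K1, k2, v_lv, v_rv`.
#' @export
fitParams <- function(x) {
  stopifnot(is(x, "KineticFit"))
  x@params
}

#' EM-equivalent iteration count
#'
#' Puts OSEM runs with different subset counts on a common convergence
#' axis: the product of full iterations and subsets.
#'
#' @param config a [ReconConfig-class] (or anything with `nIterations` and
#'   `nSubsets` slots).
#' @return integer `nIterations * nSubsets`.
#' @export
emEquivalent <- function(config) {
  as.integer(config@nIterations) * as.integer(config@nSubsets)
}

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, %.0f s total (%.1f min)\n",
              length(object@start), sum(object@duration),
              sum(object@duration) / 60))
  d <- rle(object@duration)
  cat("  blocks:",
      paste(sprintf("%d x %gs", d$lengths, d$values), collapse = ", "), "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d grid, %.3g mm voxels\n",
              object@nx, object@ny, object@voxelSize))
  for (r in object@regions)
    cat(sprintf("  %-12s %-8s mu=%.3g/cm %s\n", r$name, r$type, r$mu,
                if (identical(r$kinetics$type, "blood")) "blood"
                else sprintf("K1=%.3g k2=%.3g /min",
                             r$kinetics$K1, r$kinetics$k2)))
})

setMethod("show", "DynamicImageSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "DynamicImageSeries: %d x %d x %d frames, voxel %.3g mm, %s\n",
    d[1], d[2], d[3], object@voxelSize,
    if (object@decayCorrected) "decay-corrected" else "not decay-corrected"))
})

setMethod("show", "SystemOperator", function(object) {
  cat(sprintf(
    "SystemOperator: %d x %d image, %d angles x %d radial bins (%.3g mm)\n",
    object@nx, object@ny, object@nAngles, object@nRadial, object@binWidth))
  if (object@nTOF > 1L)
    cat(sprintf("  TOF: %d bins x %.3g mm, kernel FWHM %.3g mm\n",
                object@nTOF, object@tofBinWidth, object@tofFWHM))
  if (object@psfFWHM > 0)
    cat(sprintf("  PSF: radial Gaussian FWHM %.3g mm\n", object@psfFWHM))
})

setMethod("show", "SinogramSet", function(object) {
  d <- dim(object@prompts)
  cat(sprintf(
    "SinogramSet frame %d: %d x %d x %d bins, %.3g prompts (%.3g randoms, %.3g scatter expected)\n",
    object@frameIndex, d[1], d[2], d[3], sum(object@prompts),
    sum(object@randoms), sum(object@scatter)))
})

setMethod("show", "ReconConfig", function(object) {
  if (object@method == "FBP")
    cat(sprintf("ReconConfig: FBP (%s apodization), post-filter %.2g mm\n",
                object@fbpApodization, object@postfilterFWHM))
  else
    cat(sprintf(
      "ReconConfig: %s, %d it x %d subsets (EM-equivalent %d), post-filter %.2g mm\n",
      object@method, object@nIterations, object@nSubsets,
      emEquivalent(object), object@postfilterFWHM))
})

setMethod("show", "ReconResult", function(object) {
  cat(sprintf("ReconResult (%s): %d x %d image, range [%.3g, %.3g]",
              object@config@method, nrow(object@image), ncol(object@image),
              min(object@image), max(object@image)))
  if (length(object@snapshots))
    cat(sprintf(", %d snapshots", length(object@snapshots)))
  cat("\n")
})

setMethod("show", "KineticFit", function(object) {
  p <- object@params
  cat(sprintf(
    "KineticFit: K1=%.4g mL/min/mL, k2=%.4g /min, v_lv=%.3g, v_rv=%.3g (rss=%.4g, %s)\n",
    p[["K1"]], p[["k2"]], p[["v_lv"]], p[["v_rv"]], object@rss,
    if (object@converged) "converged" else "NOT converged"))
})
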