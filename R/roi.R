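#' Circular ROI voxel mask
#'
#' A voxel is included iff its center lies strictly inside the circle
#' (the 2D section of the spherical ROI); the test is deterministic and no
#' partial-volume weighting is applied to boundary voxels.
#'
#' @param center ROI center `c(x, y)` in mm (grid centered at 0).
#' @param diameter ROI diameter in mm (> 0).
#' @param nx,ny,voxelSize image grid.
#' @return logical matrix `nx x ny`.
#' @export
makeRoiMask <- function(center, diameter, nx, ny, voxelSize) {
  if (diameter <= 0) stop("diameter must be > 0")
  half <- c(nx, ny) * voxelSize / 2
  if (any(abs(center) > half)) stop("ROI center outside grid")
  co <- .voxelCoords(nx, ny, voxelSize)
  X <- matrix(co$x, nx, ny)
  Y <- matrix(co$y, nx, ny, byrow = TRUE)
  m <- (X - center[1])^2 + (Y - center[2])^2 < (diameter / 2)^2
  if (!any(m)) stop("empty mask: ROI covers no voxel center")
  m
}

#' Cardiac ROI set for a phantom
#'
#' Reproduces the clinical ROI scheme on the phantom geometry: four 5 mm
#' myocardial ROIs evenly distributed along the myocardial wall (placed at
#' the mid-annulus radius, at 45/135/225/315 degrees to stay clear of the
#' RV contact point), one 10 mm ROI at the LV blood-pool center and one
#' 10 mm ROI at the RV blood-pool center.
#'
#' @param spec a [PhantomSpec-class] containing regions named
#'   "myocardium", "lv_blood" and "rv_blood".
#' @param myoDiameter,bloodDiameter ROI diameters in mm.
#' @return list with logical masks: `myo` (list of four), `lv`, `rv`.
#' @export
cardiacROISet <- function(spec, myoDiameter = 5, bloodDiameter = 10) {
  reg <- function(nm) {
    i <- which(vapply(spec@regions, `[[`, character(1), "name") == nm)
    if (!length(i)) stop("phantom lacks region '", nm, "'")
    spec@regions[[i[1]]]
  }
  myo <- reg("myocardium"); lv <- reg("lv_blood"); rv <- reg("rv_blood")
  rMid <- mean(myo$radius)
  ang <- (c(45, 135, 225, 315)) * pi / 180
  myoMasks <- lapply(ang, function(a)
    makeRoiMask(myo$center + rMid * c(cos(a), sin(a)), myoDiameter,
                spec@nx, spec@ny, spec@voxelSize))
  names(myoMasks) <- paste0("myo", 1:4)
  list(myo = myoMasks,
       lv = makeRoiMask(lv$center, bloodDiameter, spec@nx, spec@ny,
                        spec@voxelSize),
       rv = makeRoiMask(rv$center, bloodDiameter, spec@nx, spec@ny,
                        spec@voxelSize))
}

#' Extract a time-activity curve
#'
#' Per-frame mean over the union of the supplied masks: passing the four
#' myocardial ROIs averages them by voxel pooling (equal to the mean of
#' per-ROI means when the ROIs have equal voxel counts).
#'
#' @param series a [DynamicImageSeries-class].
#' @param masks a logical matrix or a list of logical matrices. ROIs are
#'   fixed across frames by default.
#' @param offsets optional per-frame ROI displacement table (data frame or
#'   matrix with one row per frame, columns `dx`, `dy`, in voxels) for
#'   motion experiments: the mask is shifted rigidly before extraction,
#'   voxels shifted off-grid are dropped.
#' @return data.frame with `time_min` (frame mid-times), `duration_min`
#'   and `value` (kBq/mL).
#' @export
extractTAC <- function(series, masks, offsets = NULL) {
  stopifnot(is(series, "DynamicImageSeries"))
  if (is.list(masks)) masks <- Reduce(`|`, masks)
  if (!any(masks)) stop("empty mask union")
  d <- dim(series@data)
  if (!identical(dim(masks), d[1:2])) stop("mask does not match series grid")
  if (!is.null(offsets) && nrow(offsets) != d[3])
    stop("offsets must have one row per frame")
  shift <- function(m, dx, dy) {
    idx <- which(m, arr.ind = TRUE)
    idx[, 1] <- idx[, 1] + round(dx)
    idx[, 2] <- idx[, 2] + round(dy)
    idx <- idx[idx[, 1] >= 1 & idx[, 1] <= d[1] &
                 idx[, 2] >= 1 & idx[, 2] <= d[2], , drop = FALSE]
    if (!nrow(idx)) stop("ROI shifted entirely off the grid")
    out <- matrix(FALSE, d[1], d[2])
    out[idx] <- TRUE
    out
  }
  vals <- vapply(seq_len(d[3]), function(f) {
    m <- if (is.null(offsets)) masks
    else shift(masks, offsets[f, "dx"], offsets[f, "dy"])
    mean(series@data[, , f][m])
  }, numeric(1))
  data.frame(time_min = frameMids(series) / 60,
             duration_min = frameDurations(series) / 60,
             value = vals)
}

#' ROI image-quality statistics (CV and contrast)
#'
#' \deqn{CV = \frac{\mathrm{signal\ SD}}{\mathrm{signal\ mean}}, \qquad
#'   contrast = \frac{\mathrm{signal\ mean} - \mathrm{background\ mean}}
#'   {\mathrm{background\ mean}}.}
#' The signal SD is the population (divide-by-n) standard deviation over
#' the signal voxels.
#'
#' @param image matrix.
#' @param signalMask,backgroundMask logical masks (nonempty).
#' @return list with `signal_mean`, `signal_sd`, `background_mean`, `cv`,
#'   `contrast`.
#' @export
roiStatistics <- function(image, signalMask, backgroundMask) {
  if (!any(signalMask) || !any(backgroundMask)) stop("masks must be nonempty")
  sv <- image[signalMask]
  sm <- mean(sv)
  ssd <- sqrt(mean((sv - sm)^2))
  bm <- mean(image[backgroundMask])
  if (abs(bm) < 1e-300) stop("contrast undefined: zero background mean")
  if (abs(sm) < 1e-300) stop("cv undefined: zero signal mean")
  list(signal_mean = sm, signal_sd = ssd, background_mean = bm,
       cv = ssd / sm, contrast = (sm - bm) / bm)
}

#' Standardized uptake value at selected time points
#'
#' \eqn{SUV_{mean}(t) = C(t) / (dose / weight)} with the concentration of
#' the frame containing `t` (kBq/mL), the injected dose in MBq and the
#' body weight in g (tissue density 1 g/mL assumed), so SUV is unitless.
#'
#' @param tac a TAC data frame from [extractTAC()].
#' @param dose injected dose (MBq, > 0).
#' @param weight body weight (g, > 0).
#' @param timePoints minutes post injection (default 2, 5, 10 and 30 min,
#'   sampling high, moderate and low activity).
#' @return data.frame with `time_min`, `concentration` and `suv`.
#' @export
computeSUV <- function(tac, dose, weight, timePoints = c(2, 5, 10, 30)) {
  if (dose <= 0 || weight <= 0) stop("dose and weight must be > 0")
  start <- tac$time_min - tac$duration_min / 2
  end <- tac$time_min + tac$duration_min / 2
  conc <- vapply(timePoints, function(t) {
    i <- which(t >= start - 1e-9 & t < end + 1e-9)
    if (!length(i)) stop(sprintf("time point %g min outside the scan", t))
    tac$value[i[1]]
  }, numeric(1))
  data.frame(time_min = timePoints, concentration = conc,
             suv = conc / (dose * 1000 / weight))
}

#' CV/contrast convergence across iterations
#'
#' One [roiStatistics()] row per reconstruction snapshot, indexed by the
#' EM-equivalent iteration (snapshot level x subsets).
#'
#' @param snapshots list of images (one per full iteration, ascending).
#' @param signalMask,backgroundMask logical masks.
#' @param nSubsets subsets used by the reconstruction.
#' @return data.frame with `em_equivalent`, `cv`, `contrast`,
#'   `signal_mean`, `background_mean`.
#' @export
convergenceCurve <- function(snapshots, signalMask, backgroundMask, nSubsets) {
  rows <- lapply(seq_along(snapshots), function(i) {
    st <- roiStatistics(snapshots[[i]], signalMask, backgroundMask)
    data.frame(em_equivalent = i * nSubsets, cv = st$cv,
               contrast = st$contrast, signal_mean = st$signal_mean,
               background_mean = st$background_mean)
  })
  do.call(rbind, rows)
}
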