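#' Build a dynamic frame schedule from protocol blocks
#'
#' Frames are contiguous by construction: each block contributes `count`
#' frames of `duration` seconds, and the first frame starts at 0 s
#' (injection). The clinical carbon-11 acetate protocol used throughout the
#' package is 15 x 10 s, 15 x 30 s, 16 x 60 s and 7 x 120 s: 53 frames over
#' 40 minutes.
#'
#' @param blocks list of `c(count, duration_seconds)` pairs (or a 2-column
#'   matrix, one row per block).
#' @return a [FrameSchedule-class].
#' @examples
#' sched <- buildFrameSchedule(list(c(15, 10), c(15, 30), c(16, 60), c(7, 120)))
#' nFrames(sched)          # 53
#' totalDuration(sched)    # 2400 s
#' @export
buildFrameSchedule <- function(blocks) {
  if (is.matrix(blocks)) blocks <- asplit(blocks, 1)
  if (!length(blocks)) stop("invalid protocol: empty block list")
  counts <- vapply(blocks, function(b) b[[1]], numeric(1))
  durs <- vapply(blocks, function(b) b[[2]], numeric(1))
  if (any(counts < 1) || any(counts != round(counts)))
    stop("invalid protocol: block counts must be integers >= 1")
  if (any(durs <= 0)) stop("invalid protocol: durations must be > 0")
  duration <- rep(durs, times = counts)
  start <- cumsum(c(0, duration[-length(duration)]))
  new("FrameSchedule", start = start, duration = duration, injectionTime = 0)
}

#' Construct a parametric arterial input function
#'
#' @param model "feng" (four-exponential bolus, the default),
#'   "gamma_variate", or "constant" (a flat curve, mainly for testing decay
#'   and frame-averaging behavior in isolation).
#' @param parameters named coefficients. Feng: `A1` (kBq/mL/min), `A2`, `A3`
#'   (kBq/mL), `lambda1`, `lambda2`, `lambda3` (1/min, all <= 0). Gamma
#'   variate: `A` (kBq/mL/min^alpha), `alpha` (> 0), `beta` (min).
#'   Constant: `value` (kBq/mL, >= 0).
#'   `NULL` selects defaults producing a realistic ~100 kBq/mL bolus peak.
#' @param delay tracer arrival delay in seconds (curve is 0 before it).
#' @return an [InputFunction-class].
#' @export
inputFunction <- function(model = c("feng", "gamma_variate", "constant"),
                          parameters = NULL, delay = 10) {
  model <- match.arg(model)
  if (!is.null(parameters)) parameters <- unlist(parameters)  # config lists
  if (is.null(parameters)) {
    parameters <- switch(model,
      feng = c(A1 = 851.1225, A2 = 21.8798, A3 = 20.8113,
               lambda1 = -4.133859, lambda2 = -0.01043449,
               lambda3 = -0.1190996),
      gamma_variate = c(A = 300, alpha = 1.5, beta = 0.25),
      constant = c(value = 50))
  }
  if (model == "constant") {
    if (!"value" %in% names(parameters) || parameters[["value"]] < 0)
      stop("invalid parameters: constant model needs value >= 0")
    return(new("InputFunction", model = model,
               parameters = parameters["value"], delay = delay))
  }
  if (model == "feng") {
    need <- c("A1", "A2", "A3", "lambda1", "lambda2", "lambda3")
    if (!all(need %in% names(parameters)))
      stop("feng model requires coefficients ", paste(need, collapse = ", "))
    if (any(parameters[c("A1", "A2", "A3")] < 0))
      stop("invalid parameters: negative feng amplitudes imply negative activity")
    if (any(parameters[c("lambda1", "lambda2", "lambda3")] > 0))
      stop("invalid parameters: feng exponents must be <= 0")
  } else {
    need <- c("A", "alpha", "beta")
    if (!all(need %in% names(parameters)))
      stop("gamma_variate model requires coefficients ",
           paste(need, collapse = ", "))
    if (any(parameters <= 0))
      stop("invalid parameters: gamma-variate coefficients must be > 0")
  }
  if (delay < 0) stop("delay must be >= 0")
  new("InputFunction", model = model,
      parameters = parameters[need], delay = delay)
}

#' Evaluate an input function
#'
#' Returns the whole-blood activity concentration at the requested times.
#' The curve is identically zero before the arrival delay and continuous in
#' time (both models vanish at onset).
#'
#' @param input an [InputFunction-class].
#' @param times evaluation times in seconds (nonnegative, sorted).
#' @return numeric vector of activities (kBq/mL), same length as `times`.
#' @export
evaluateInputFunction <- function(input, times) {
  stopifnot(is(input, "InputFunction"))
  if (any(times < -1e-9)) stop("times must be >= 0")
  tm <- (times - input@delay) / 60  # minutes post-arrival
  out <- numeric(length(times))
  # bolus models vanish continuously at onset; the constant model holds its
  # value from the delay onwards
  pos <- if (input@model == "constant") tm >= 0 else tm > 0
  if (any(pos)) {
    p <- input@parameters
    tp <- tm[pos]
    out[pos] <- if (input@model == "constant") {
      p[["value"]]
    } else if (input@model == "feng") {
      (p[["A1"]] * tp - p[["A2"]] - p[["A3"]]) * exp(p[["lambda1"]] * tp) +
        p[["A2"]] * exp(p[["lambda2"]] * tp) +
        p[["A3"]] * exp(p[["lambda3"]] * tp)
    } else {
      p[["A"]] * tp^p[["alpha"]] * exp(-tp / p[["beta"]])
    }
    out[pos] <- pmax(out[pos], 0)
  }
  out
}

#' Default 2D cardiac phantom
#'
#' Single-slice cross-section with a soft-tissue background disc, RV blood
#' pool, LV blood pool and a myocardial annulus around the LV. Anatomical
#' dimensions (in mm, before `scale`) are: body radius 100, LV disc radius
#' 16 centered at (-14, 0), myocardial annulus 16-26 mm around the LV
#' center, RV disc radius 14 centered at (26, 0). All regions use
#' water-equivalent attenuation (0.096 1/cm at 511 keV). Blood pools follow
#' the input function (the RV leads the LV by `rvLead` seconds, mimicking
#' right-heart transit); the myocardium follows a 1-tissue-compartment model
#' with uptake `K1` and washout `k2`; the background has low uptake.
#'
#' @param nx,ny grid size in voxels.
#' @param voxelSize voxel edge (mm).
#' @param scale multiplies every anatomical dimension; use < 1 to fit the
#'   heart into small grids.
#' @param K1,k2 myocardial kinetic parameters (1/min).
#' @param rvLead RV pre-delay (seconds).
#' @return a [PhantomSpec-class].
#' @export
cardiacPhantom <- function(nx = 128L, ny = nx, voxelSize = 2, scale = 1,
                           K1 = 0.8, k2 = 0.25, rvLead = 4) {
  s <- scale
  regions <- list(
    list(name = "background", type = "disc", center = c(0, 0) * s,
         radius = 100 * s, mu = 0.096,
         kinetics = list(type = "tissue", K1 = 0.1, k2 = 0.2)),
    list(name = "rv_blood", type = "disc", center = c(26, 0) * s,
         radius = 14 * s, mu = 0.096,
         kinetics = list(type = "blood", shift = rvLead)),
    list(name = "lv_blood", type = "disc", center = c(-14, 0) * s,
         radius = 16 * s, mu = 0.096,
         kinetics = list(type = "blood", shift = 0)),
    list(name = "myocardium", type = "annulus", center = c(-14, 0) * s,
         radius = c(16, 26) * s, mu = 0.096,
         kinetics = list(type = "tissue", K1 = K1, k2 = k2)))
  new("PhantomSpec", nx = as.integer(nx), ny = as.integer(ny),
      voxelSize = voxelSize, regions = regions)
}

#' Construct a phantom from explicit regions
#'
#' @param nx,ny grid size (voxels); `voxelSize` in mm.
#' @param regions list of region descriptors (see [PhantomSpec-class]).
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(nx, ny, voxelSize, regions) {
  new("PhantomSpec", nx = as.integer(nx), ny = as.integer(ny),
      voxelSize = voxelSize, regions = regions)
}

# voxel-center coordinates (mm, grid centered at 0)
.voxelCoords <- function(nx, ny, voxelSize) {
  list(x = (seq_len(nx) - (nx + 1) / 2) * voxelSize,
       y = (seq_len(ny) - (ny + 1) / 2) * voxelSize)
}

#' Rasterize a phantom to a label image and attenuation map
#'
#' Voxels are assigned by a center-in-region test; later regions overwrite
#' earlier ones (the constructor orders background < RV < LV < myocardium,
#' so the annulus wins at shared boundaries). Voxels covered by no region
#' get label 0 with zero attenuation and zero activity. Regions extending
#' beyond the grid are clipped with a warning.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with `labels` (integer matrix, 0 = outside all regions),
#'   `mu` (matrix, 1/cm) and `names` (region names by label index).
#' @export
rasterizePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  co <- .voxelCoords(spec@nx, spec@ny, spec@voxelSize)
  X <- matrix(co$x, spec@nx, spec@ny)
  Y <- matrix(co$y, spec@nx, spec@ny, byrow = TRUE)
  labels <- matrix(0L, spec@nx, spec@ny)
  mu <- matrix(0, spec@nx, spec@ny)
  half <- c(spec@nx, spec@ny) * spec@voxelSize / 2
  for (i in seq_along(spec@regions)) {
    r <- spec@regions[[i]]
    rmax <- max(r$radius)
    if (any(abs(r$center) + rmax > half))
      warning(sprintf("region '%s' extends beyond the grid; clipped", r$name))
    d2 <- (X - r$center[1])^2 + (Y - r$center[2])^2
    inside <- if (identical(r$type, "annulus"))
      d2 >= r$radius[1]^2 & d2 < r$radius[2]^2
    else d2 < r$radius^2
    labels[inside] <- i
    mu[inside] <- r$mu
  }
  list(labels = labels, mu = mu,
       names = vapply(spec@regions, `[[`, character(1), "name"))
}

#' Decay constant, instantaneous decay and frame-averaged decay
#'
#' `decayCorrectionFactor` returns the instantaneous correction
#' \eqn{2^{t/T_{1/2}}} referencing an activity measured at time `t` back to
#' injection (it equals 2 at one half-life, 20 min for carbon-11 here).
#' `frameDecayFactor` is the frame-averaged decay
#' \eqn{\frac{1}{\Delta}\int_{t_0}^{t_0+\Delta} e^{-\lambda t}\,dt}
#' used to decay-correct frame data.
#'
#' @param t time post injection (minutes).
#' @param halfLife isotope half-life (minutes).
#' @param start,duration frame start and duration in seconds.
#' @return numeric factor(s).
#' @export
decayCorrectionFactor <- function(t, halfLife = 20) {
  if (halfLife <= 0) stop("halfLife must be > 0")
  2^(t / halfLife)
}

#' @rdname decayCorrectionFactor
#' @export
frameDecayFactor <- function(start, duration, halfLife = 20) {
  if (halfLife <= 0) stop("halfLife must be > 0")
  if (any(duration <= 0)) stop("duration must be > 0")
  lam <- log(2) / (halfLife * 60)  # 1/s
  exp(-lam * start) * (-expm1(-lam * duration)) / (lam * duration)
}

# decay-corrected regional activity curve (kBq/mL) at times (seconds)
.regionCurve <- function(kin, input, timesSec) {
  if (identical(kin$type, "blood")) {
    evaluateInputFunction(input, timesSec + kin$shift)
  } else {
    tMin <- timesSec / 60
    fine <- seq(0, max(tMin) + 1e-9, by = 0.1 / 60)  # 0.1 s input sampling
    cp <- evaluateInputFunction(input, fine * 60)
    solve1TCM(kin$K1, kin$k2, fine, cp, tMin)
  }
}

#' Generate the ground-truth dynamic image series
#'
#' Regional true activity follows the input function (blood pools, the RV
#' optionally leading) or the 1-tissue-compartment solution driven by it
#' (tissue regions). Physical decay multiplies every curve by
#' \eqn{e^{-\lambda t}} (decay-corrected kinetics are generated first, so
#' the decay-corrected curves satisfy the model with the nominal `k2`).
#' Each frame holds the time-average of the decaying activity over
#' `[start, start + duration]`, computed by composite Simpson integration
#' at 0.5 s resolution. The output is flagged NOT decay-corrected when
#' decay is enabled.
#'
#' @param spec a [PhantomSpec-class] with kinetics for every region.
#' @param input an [InputFunction-class].
#' @param schedule a [FrameSchedule-class].
#' @param decay apply physical decay (default TRUE).
#' @param halfLife isotope half-life in minutes (default 20, carbon-11).
#' @return a [DynamicImageSeries-class] (kBq/mL).
#' @export
makeDynamicTruth <- function(spec, input, schedule, decay = TRUE,
                             halfLife = 20) {
  stopifnot(is(spec, "PhantomSpec"), is(input, "InputFunction"),
            is(schedule, "FrameSchedule"))
  for (r in spec@regions)
    if (is.null(r$kinetics))
      stop(sprintf("configuration error: region '%s' has no kinetics", r$name))
  ras <- rasterizePhantom(spec)
  nF <- nFrames(schedule)
  st <- frameStarts(schedule); du <- frameDurations(schedule)

  # Simpson nodes per frame at <= 0.5 s spacing (even interval count)
  nodes <- lapply(seq_len(nF), function(f) {
    nInt <- max(2L, 2L * ceiling(du[f] / 1))  # intervals of <= 0.5 s
    seq(st[f], st[f] + du[f], length.out = nInt + 1L)
  })
  allT <- unlist(nodes)
  dk <- if (decay) 2^(-(allT / 60) / halfLife) else rep(1, length(allT))

  simpson <- function(vals, f) {
    n <- length(vals)
    w <- c(1, rep(c(4, 2), length.out = n - 2L), 1)
    w[n] <- 1
    h <- (nodes[[f]][2] - nodes[[f]][1])
    sum(w * vals) * h / 3 / du[f]
  }
  idx <- split(seq_along(allT), rep(seq_len(nF), lengths(nodes)))

  data <- array(0, dim = c(spec@nx, spec@ny, nF))
  for (i in seq_along(spec@regions)) {
    mask <- ras$labels == i
    if (!any(mask)) next
    curve <- .regionCurve(spec@regions[[i]]$kinetics, input, allT) * dk
    fv <- vapply(seq_len(nF), function(f) simpson(curve[idx[[f]]], f),
                 numeric(1))
    for (f in seq_len(nF)) data[, , f][mask] <- fv[f]
  }
  new("DynamicImageSeries", data = data, schedule = schedule,
      voxelSize = spec@voxelSize, decayCorrected = !decay,
      halfLife = halfLife)
}
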