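#' Convergence study: CV/contrast and kinetic parameters vs EM-equivalent
#' iterations
#'
#' Runs the package's reference convergence analysis on a seeded phantom
#' instance: (i) the 30 s mid-scan frame (frame 21) is reconstructed with
#' OSEM, TOF and (optionally) TPSF at 10 subsets, keeping every full
#' iteration, and the myocardium-vs-LV-blood CV and contrast are tabulated
#' against EM-equivalent iterations; (ii) the full 53-frame dynamic scan is
#' reconstructed with TOF at every snapshot level and the spillover-
#' corrected kinetic fit is repeated per level.
#'
#' The default instance uses a 96 x 96 grid of 2 mm voxels with the phantom
#' at scale 0.9 (body about 180 mm across, so the 80 mm TOF kernel provides
#' clinically representative localization gain), 72 angles, and a count
#' calibration giving on the order of 2e7 prompts in the 30 s mid-scan
#' frame — count statistics at the upper clinical range, so that algorithmic
#' convergence rather than counting noise dominates the kinetic-parameter
#' trajectory (the clinical analysis likewise pools the entire frames to
#' minimize noise effects).
#'
#' @param seed integer seed controlling all Poisson noise.
#' @param nx,voxelSize,scale,nAngles phantom/operator geometry.
#' @param countScale calibration (counts * mL / (kBq mm s)).
#' @param nIterations full iterations (snapshots at each).
#' @param nSubsets angular subsets.
#' @param withTPSF include the TPSF contrast curve.
#' @param verbose log progress to stderr.
#' @return list with `contrast` (data.frame: method, em_equivalent, cv,
#'   contrast), `kinetics` (data.frame from [kineticConvergence()], TOF),
#'   and `instance` (the geometry/count settings used).
#' @export
convergenceStudy <- function(seed = 1L, nx = 96L, voxelSize = 2, scale = 0.9,
                             nAngles = 72L, countScale = 0.2,
                             nIterations = 20L, nSubsets = 10L,
                             withTPSF = FALSE, verbose = FALSE) {
  logmsg <- function(...) if (verbose) message(sprintf(...))
  spec <- cardiacPhantom(nx = nx, voxelSize = voxelSize, scale = scale)
  ras <- rasterizePhantom(spec)
  sched <- buildFrameSchedule(list(c(15, 10), c(15, 30), c(16, 60), c(7, 120)))
  inp <- inputFunction()
  truth <- makeDynamicTruth(spec, inp, sched)
  # detector blur (PSF) is always in the simulated data; only the TPSF
  # reconstruction models it
  opSim <- buildSystemOperator(muMap = ras$mu, voxelSize = voxelSize,
                               nAngles = nAngles, tof = TRUE, psf = 4)
  opT <- .setPSF(opSim, 0)
  opP <- buildSystemOperator(muMap = ras$mu, voxelSize = voxelSize,
                             nAngles = nAngles)
  du <- frameDurations(sched)
  logmsg("simulating %d frames", nFrames(sched))
  sinos <- lapply(seq_len(nFrames(sched)), function(f) {
    trues <- forwardProject(truth@data[, , f], opSim) * du[f] * countScale
    simulateCounts(trues, opSim, randomsFraction = 0.1,
                   scatterFraction = 0.15,
                   seed = .subjectSeed(seed, f), frameIndex = f)
  })
  rois <- cardiacROISet(spec)
  myoM <- Reduce(`|`, rois$myo)

  # (i) frame-21 contrast/CV convergence
  f21 <- 21L
  curves <- list()
  runCurve <- function(method, op, sino) {
    res <- osemReconstruct(sino, op,
                           reconConfig(method, nIterations = nIterations,
                                       nSubsets = nSubsets,
                                       postfilterFWHM = 0),
                           snapshots = TRUE)
    cc <- convergenceCurve(reconSnapshots(res), myoM, rois$lv, nSubsets)
    cbind(method = method, cc)
  }
  curves$OSEM <- runCurve("OSEM", opP, .marginalizeTOF(sinos[[f21]]))
  curves$TOF <- runCurve("TOF", opT, sinos[[f21]])
  if (withTPSF) curves$TPSF <- runCurve("TPSF", opSim, sinos[[f21]])
  logmsg("frame-21 contrast curves done")

  # (ii) dynamic TOF reconstruction with per-iteration kinetic fits
  out <- reconDynamicSeries(sinos, opT,
                            reconConfig("TOF", nIterations = nIterations,
                                        nSubsets = nSubsets,
                                        postfilterFWHM = 5),
                            sched, calibration = countScale, snapshots = TRUE)
  logmsg("dynamic TOF reconstruction done")
  kin <- kineticConvergence(out$byLevel, rois$myo, rois$lv, rois$rv, nSubsets)
  logmsg("kinetic convergence done")
  list(contrast = do.call(rbind, c(curves, make.row.names = FALSE)),
       kinetics = kin,
       instance = list(nx = nx, voxelSize = voxelSize, scale = scale,
                       nAngles = nAngles, countScale = countScale,
                       seed = seed, truthK1 = 0.8, truthk2 = 0.25))
}

#' Type-I error calibration of the pairwise comparison tests
#'
#' Simulates null cohorts (methods differing only by independent
#' measurement noise; see [simulateCohortFits()]), applies the paired
#' t-test to every method pair, and returns the overall fraction of
#' significant results at alpha = 0.05 together with the binomial 95%
#' acceptance band at `nCohorts` trials. The band is applied at the cohort
#' level because the six pairwise tests within a cohort share samples; the
#' variance of a cohort's average rejection indicator is bounded by the
#' Bernoulli variance, so the cohort-level binomial band is conservative.
#'
#' @param nCohorts number of independent null cohorts.
#' @param nSubjects subjects per cohort.
#' @param noiseCV per-method measurement noise.
#' @param parameter which simulated parameter to test.
#' @param seed RNG seed.
#' @return list with `rate`, `nTests`, `nCohorts`, `band` (length-2).
#' @export
typeICalibration <- function(nCohorts = 200L, nSubjects = 24L,
                             noiseCV = 0.05, parameter = "K1", seed = 1L) {
  sig <- 0L; tot <- 0L
  for (cohort in seq_len(nCohorts)) {
    fits <- simulateCohortFits(
      nSubjects = nSubjects, noiseCV = noiseCV,
      seed = (as.numeric(seed) * 100003 + cohort) %% 2147483647)
    d <- fits[fits$parameter == parameter, ]
    wide <- tapply(d$value, list(d$subject, d$method), mean)
    for (pr in utils::combn(colnames(wide), 2, simplify = FALSE)) {
      tt <- pairedTests(wide[, pr[1]], wide[, pr[2]])
      sig <- sig + as.integer(tt$p_value[tt$variant == "paired_t"] < 0.05)
      tot <- tot + 1L
    }
  }
  band <- 0.05 + c(-1, 1) * qnorm(0.975) * sqrt(0.05 * 0.95 / nCohorts)
  list(rate = sig / tot, nTests = tot, nCohorts = nCohorts, band = band)
}
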