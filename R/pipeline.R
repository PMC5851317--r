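#' Default experiment configuration
#'
#' One plain list holding every stage's settings: phantom geometry and
#' kinetics, input function, frame schedule blocks, projection system
#' (angles, TOF, PSF, count calibration, background fractions),
#' per-method reconstruction settings, ROI diameters, kinetic-fit options,
#' cohort distributions, dose and body weight (the protocol does not fix a
#' weight, so it is an explicit required field), and the master seed.
#' Serializable to JSON/YAML via [writeExperimentConfig()].
#'
#' @param nx,voxelSize,scale phantom grid and anatomical scale (see
#'   [cardiacPhantom()]).
#' @param nAngles projection angles.
#' @param seed master seed.
#' @return nested configuration list.
#' @export
defaultExperimentConfig <- function(nx = 128L, voxelSize = 2, scale = 1,
                                    nAngles = 180L, seed = 1L) {
  list(
    phantom = list(nx = nx, ny = nx, voxelSize = voxelSize, scale = scale,
                   K1 = 0.8, k2 = 0.25, rvLead = 4),
    input = list(model = "feng", delay = 10),
    schedule_blocks = list(c(15, 10), c(15, 30), c(16, 60), c(7, 120)),
    halfLife = 20,
    projection = list(nAngles = nAngles,
                      tof = list(nBins = 13L, binWidth = 30, fwhm = 80),
                      psfFWHM = 4, countScale = 0.002,
                      randomsFraction = 0.1, scatterFraction = 0.15),
    recon = list(
      FBP = list(fbpApodization = "hann", postfilterFWHM = 0),
      OSEM = list(nIterations = 20L, nSubsets = 10L, postfilterFWHM = 6.5),
      TOF = list(nIterations = 10L, nSubsets = 10L, postfilterFWHM = 5),
      TPSF = list(nIterations = 10L, nSubsets = 10L, postfilterFWHM = 5)),
    methods = c("FBP", "OSEM", "TOF", "TPSF"),
    rois = list(myoDiameter = 5, bloodDiameter = 10),
    kinetics = list(weights = "duration"),
    suv_times = c(2, 5, 10, 30),
    dose_MBq = 740, weight_g = 70000,
    cohort = list(nSubjects = 24,
                  K1 = list(mean = 0.8, sd = 0.15),
                  k2 = list(mean = 0.25, sd = 0.06)),
    seed = as.integer(seed))
}

#' Read / write an experiment configuration
#'
#' Format chosen by extension: `.json` via jsonlite, `.yaml`/`.yml` via
#' yaml. A round-tripped configuration reloads to an equivalent experiment.
#'
#' @param path file path.
#' @param config configuration list.
#' @return the configuration list (read) or `path` invisibly (write).
#' @export
readExperimentConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json")
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  else yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("configuration must contain a seed")
  if (!is.null(cfg$methods) &&
      !all(cfg$methods %in% c("FBP", "OSEM", "TOF", "TPSF")))
    stop("methods must be a subset of FBP, OSEM, TOF, TPSF")
  # JSON arrays of blocks arrive as a matrix or list of vectors
  if (is.matrix(cfg$schedule_blocks))
    cfg$schedule_blocks <- asplit(cfg$schedule_blocks, 1)
  cfg
}

#' @rdname readExperimentConfig
#' @export
writeExperimentConfig <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json")
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(config, path)
  invisible(path)
}

#' Write / read a dynamic image series (NIfTI + frame-timing CSV)
#'
#' The image data go to `<prefix>.nii.gz` with frames along the last axis
#' and the voxel size in the header; the frame timing goes to
#' `<prefix>_frames.csv` with columns `frame_index`, `start_s`,
#' `duration_s`.
#'
#' @param series a [DynamicImageSeries-class].
#' @param prefix output path prefix.
#' @param niftiPath,csvPath input paths for reading.
#' @param decayCorrected,halfLife metadata not carried by NIfTI.
#' @return file paths (write) or a [DynamicImageSeries-class] (read).
#' @export
writeDynamicSeries <- function(series, prefix) {
  stopifnot(is(series, "DynamicImageSeries"))
  nii <- RNifti::asNifti(series@data)
  RNifti::pixdim(nii) <- c(series@voxelSize, series@voxelSize, 1)
  pnii <- paste0(prefix, ".nii.gz")
  pcsv <- paste0(prefix, "_frames.csv")
  RNifti::writeNifti(nii, pnii)
  write.csv(data.frame(frame_index = seq_len(nFrames(series)),
                       start_s = frameStarts(series),
                       duration_s = frameDurations(series)),
            pcsv, row.names = FALSE)
  invisible(c(nifti = pnii, frames = pcsv))
}

#' @rdname writeDynamicSeries
#' @export
readDynamicSeries <- function(niftiPath, csvPath, decayCorrected = TRUE,
                              halfLife = 20) {
  img <- RNifti::readNifti(niftiPath)
  fr <- read.csv(csvPath)
  dur <- fr$duration_s
  sched <- new("FrameSchedule", start = fr$start_s, duration = dur,
               injectionTime = 0)
  vx <- RNifti::pixdim(img)[1]
  new("DynamicImageSeries", data = array(as.numeric(img), dim = dim(img)),
      schedule = sched, voxelSize = vx, decayCorrected = decayCorrected,
      halfLife = halfLife)
}

# deterministic per-subject seed derived from the master seed; subjects
# keep their seeds when the cohort grows
.subjectSeed <- function(masterSeed, subjectIndex) {
  as.integer((as.numeric(masterSeed) * 7919 + subjectIndex * 104729) %%
               2147483647)
}

# instantiate phantom, input, schedule, operator and ROI set from a config
.buildExperiment <- function(config) {
  ph <- config$phantom
  spec <- cardiacPhantom(nx = ph$nx, ny = ph$ny %||% ph$nx,
                         voxelSize = ph$voxelSize, scale = ph$scale %||% 1,
                         K1 = ph$K1, k2 = ph$k2, rvLead = ph$rvLead %||% 4)
  input <- inputFunction(model = config$input$model %||% "feng",
                         parameters = config$input$parameters,
                         delay = config$input$delay %||% 10)
  sched <- buildFrameSchedule(config$schedule_blocks)
  ras <- rasterizePhantom(spec)
  pj <- config$projection
  needTOF <- any(config$methods %in% c("TOF", "TPSF"))
  psfFWHM <- pj$psfFWHM %||% 0
  # detector blur is part of the physics, so the simulating operator always
  # carries the PSF; reconstruction operators model it only for TPSF
  opSim <- buildSystemOperator(muMap = ras$mu, voxelSize = spec@voxelSize,
                               nAngles = pj$nAngles,
                               tof = if (needTOF) pj$tof else NULL,
                               psf = psfFWHM)
  opTPSF <- opSim
  opTOF <- if (needTOF) .setPSF(opSim, 0) else NULL
  opPlain <- if (needTOF)
    buildSystemOperator(muMap = ras$mu, voxelSize = spec@voxelSize,
                        nAngles = pj$nAngles, tof = NULL, psf = NULL)
  else .setPSF(opSim, 0)
  rois <- cardiacROISet(spec, config$rois$myoDiameter %||% 5,
                        config$rois$bloodDiameter %||% 10)
  list(spec = spec, input = input, sched = sched, opSim = opSim,
       opTPSF = opTPSF, opTOF = opTOF, opPlain = opPlain, rois = rois)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# simulate the measured sinograms of one subject's dynamic scan
.simulateScan <- function(exper, config, seed) {
  pj <- config$projection
  truth <- makeDynamicTruth(exper$spec, exper$input, exper$sched,
                            decay = TRUE, halfLife = config$halfLife)
  st <- frameStarts(exper$sched); du <- frameDurations(exper$sched)
  needTOF <- any(config$methods %in% c("TOF", "TPSF"))
  sinosTOF <- vector("list", nFrames(exper$sched))
  sinosPlain <- vector("list", nFrames(exper$sched))
  for (f in seq_len(nFrames(exper$sched))) {
    op <- exper$opSim
    trues <- forwardProject(truth@data[, , f], op) * du[f] * pj$countScale
    sino <- simulateCounts(trues, op, pj$randomsFraction, pj$scatterFraction,
                           seed = .subjectSeed(seed, f), frameIndex = f)
    sinosTOF[[f]] <- sino
    sinosPlain[[f]] <- if (needTOF) .marginalizeTOF(sino) else sino
  }
  list(truth = truth, sinosTOF = sinosTOF, sinosPlain = sinosPlain)
}

# sum a TOF SinogramSet over its TOF bins (for non-TOF reconstructions)
.marginalizeTOF <- function(sino) {
  m3 <- function(a) {
    out <- rowSums(a, dims = 2L)
    array(out, dim = c(dim(a)[1:2], 1L))
  }
  new("SinogramSet", prompts = m3(sino@prompts), randoms = m3(sino@randoms),
      scatter = m3(sino@scatter), frameIndex = sino@frameIndex)
}

#' Run one simulated subject through the full chain
#'
#' Phantom truth (subject-specific myocardial kinetics drawn from the
#' cohort distributions), per-frame sinograms with Poisson noise, one
#' reconstruction per configured method, TAC extraction, SUV at the
#' configured time points, and the spillover-corrected kinetic fit.
#' Deterministic given `(config, seed)`.
#'
#' @param config configuration list (see [defaultExperimentConfig()]).
#' @param seed subject seed.
#' @param outDir optional directory: reconstructed series are written as
#'   NIfTI + frame CSV and fits/TACs/SUVs as CSV.
#' @param verbose log stages to stderr.
#' @return list with `truthParams`, `fits` (data.frame: method, K1, k2,
#'   v_lv, v_rv, rss, converged), `suvs` (long data.frame), `tacs` (list by
#'   method), `series` (list of [DynamicImageSeries-class] by method).
#' @export
runSubject <- function(config, seed = config$seed, outDir = NULL,
                       verbose = FALSE) {
  logmsg <- function(...) if (verbose) message(sprintf(...))
  set.seed(.subjectSeed(seed, 0L))
  cfgS <- config
  cfgS$phantom$K1 <- max(rnorm(1, config$cohort$K1$mean, config$cohort$K1$sd),
                         0.05)
  cfgS$phantom$k2 <- max(rnorm(1, config$cohort$k2$mean, config$cohort$k2$sd),
                         0.02)
  logmsg("subject truth: K1=%.3f k2=%.3f", cfgS$phantom$K1, cfgS$phantom$k2)
  exper <- .buildExperiment(cfgS)
  scan <- .simulateScan(exper, cfgS, seed)
  logmsg("simulated %d frames", nFrames(exper$sched))

  fits <- list(); suvs <- list(); tacs <- list(); series <- list()
  for (m in cfgS$methods) {
    rc <- cfgS$recon[[m]]
    cfgR <- reconConfig(m, nIterations = rc$nIterations,
                        nSubsets = rc$nSubsets %||% 10L,
                        postfilterFWHM = rc$postfilterFWHM,
                        fbpApodization = rc$fbpApodization %||% "hann")
    tofMethod <- m %in% c("TOF", "TPSF")
    op <- switch(m, TOF = exper$opTOF, TPSF = exper$opTPSF, exper$opPlain)
    sinos <- if (tofMethod) scan$sinosTOF else scan$sinosPlain
    ser <- reconDynamicSeries(sinos, op, cfgR, exper$sched,
                              halfLife = cfgS$halfLife,
                              calibration = cfgS$projection$countScale)
    logmsg("reconstructed %s (EM-equivalent %d)", m,
           if (m == "FBP") 0L else emEquivalent(cfgR))
    myoT <- extractTAC(ser, exper$rois$myo)
    lvT <- extractTAC(ser, exper$rois$lv)
    rvT <- extractTAC(ser, exper$rois$rv)
    fit <- fit1TCM(myoT, lvT, rvT, exper$sched,
                   weights = cfgS$kinetics$weights %||% "duration")
    p <- fitParams(fit)
    fits[[m]] <- data.frame(method = m, K1 = p[["K1"]], k2 = p[["k2"]],
                            v_lv = p[["v_lv"]], v_rv = p[["v_rv"]],
                            rss = fit@rss, converged = fit@converged)
    sv <- computeSUV(myoT, cfgS$dose_MBq, cfgS$weight_g, cfgS$suv_times)
    sv$method <- m
    suvs[[m]] <- sv
    tacs[[m]] <- list(myo = myoT, lv = lvT, rv = rvT)
    series[[m]] <- ser
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      writeDynamicSeries(ser, file.path(outDir, paste0("recon_", m)))
      write.csv(cbind(frame = seq_len(nrow(myoT)), myo = myoT$value,
                      lv = lvT$value, rv = rvT$value,
                      t_min = myoT$time_min,
                      duration_min = myoT$duration_min),
                file.path(outDir, paste0("tac_", m, ".csv")),
                row.names = FALSE)
    }
  }
  fitsDf <- do.call(rbind, c(fits, make.row.names = FALSE))
  suvDf <- do.call(rbind, c(suvs, make.row.names = FALSE))
  if (!is.null(outDir)) {
    write.csv(fitsDf, file.path(outDir, "fits.csv"), row.names = FALSE)
    write.csv(suvDf, file.path(outDir, "suv.csv"), row.names = FALSE)
  }
  list(truthParams = c(K1 = cfgS$phantom$K1, k2 = cfgS$phantom$k2),
       fits = fitsDf, suvs = suvDf, tacs = tacs, series = series)
}

#' Run a simulated cohort and compare reconstruction methods
#'
#' Iterates [runSubject()] with deterministic per-subject seeds derived
#' from the master seed and aggregates all kinetic parameters and SUVs into
#' the pairwise [methodComparisonReport()]. Per-subject failures are
#' logged and skipped; the run aborts only if every subject fails.
#'
#' @param config configuration list; `config$cohort$nSubjects >= 2`.
#' @param outDir optional output directory for the report CSV/JSON.
#' @param verbose log progress.
#' @return list with `report` (see [methodComparisonReport()]) and `fits`
#'   (the long per-subject table).
#' @export
runCohort <- function(config, outDir = NULL, verbose = FALSE) {
  nS <- config$cohort$nSubjects
  if (is.null(nS) || nS < 2) stop("cohort needs nSubjects >= 2")
  rows <- list()
  for (i in seq_len(nS)) {
    res <- tryCatch(runSubject(config, seed = .subjectSeed(config$seed, i),
                               verbose = verbose),
                    error = function(e) {
                      warning(sprintf("subject %d failed: %s", i,
                                      conditionMessage(e)))
                      NULL
                    })
    if (is.null(res)) next
    kin <- res$fits
    long <- rbind(
      data.frame(subject = i, method = kin$method, parameter = "K1",
                 value = kin$K1),
      data.frame(subject = i, method = kin$method, parameter = "k2",
                 value = kin$k2),
      data.frame(subject = i, method = res$suvs$method,
                 parameter = paste0("SUV_", res$suvs$time_min, "min"),
                 value = res$suvs$suv))
    rows[[i]] <- long
  }
  if (!length(rows)) stop("all subjects failed")
  fits <- do.call(rbind, c(rows, make.row.names = FALSE))
  report <- methodComparisonReport(fits)
  if (!is.null(outDir)) writeComparisonReport(report, outDir)
  list(report = report, fits = fits)
}

#' Write / read a sinogram set (NIfTI arrays + JSON header)
#'
#' Prompts, randoms and scatter go to `<prefix>_{prompts,randoms,scatter}.nii.gz`
#' (layout: radial x angle x TOF bin, i.e. angle-major with radial fastest
#' and TOF last); the geometry goes to `<prefix>_header.json`.
#'
#' @param sino a [SinogramSet-class].
#' @param op the [SystemOperator-class] that produced it (geometry metadata).
#' @param prefix output path prefix.
#' @return file paths (write) or a [SinogramSet-class] (read).
#' @export
writeSinogramSet <- function(sino, op, prefix) {
  stopifnot(is(sino, "SinogramSet"))
  paths <- paste0(prefix, c("_prompts.nii.gz", "_randoms.nii.gz",
                            "_scatter.nii.gz", "_header.json"))
  RNifti::writeNifti(RNifti::asNifti(sino@prompts), paths[1])
  RNifti::writeNifti(RNifti::asNifti(sino@randoms), paths[2])
  RNifti::writeNifti(RNifti::asNifti(sino@scatter), paths[3])
  jsonlite::write_json(
    list(frame_index = sino@frameIndex, n_radial = op@nRadial,
         n_angles = op@nAngles, bin_width_mm = op@binWidth,
         n_tof = op@nTOF, tof_bin_width_mm = op@tofBinWidth,
         tof_fwhm_mm = op@tofFWHM, layout = "radial,angle,tof"),
    paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname writeSinogramSet
#' @export
readSinogramSet <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, "_header.json"),
                             simplifyVector = TRUE)
  rd <- function(part) {
    a <- RNifti::readNifti(paste0(prefix, "_", part, ".nii.gz"))
    array(as.numeric(a), dim = c(hdr$n_radial, hdr$n_angles, hdr$n_tof))
  }
  new("SinogramSet", prompts = rd("prompts"), randoms = rd("randoms"),
      scatter = rd("scatter"), frameIndex = as.integer(hdr$frame_index))
}

#' Quantification-only path for externally supplied image series
#'
#' Accepts a dynamic image series (e.g. read from NIfTI + frame CSV via
#' [readDynamicSeries()]), ROI masks, and the dose/weight, and returns
#' TACs, SUVs and the kinetic fit without running the simulator.
#'
#' @param series a [DynamicImageSeries-class] (decay-corrected kBq/mL).
#' @param myoMasks,lvMask,rvMask ROI masks (see [makeRoiMask()]).
#' @param dose injected dose (MBq); `weight` body weight (g).
#' @param suvTimes SUV sampling times (minutes).
#' @param ... passed to [fit1TCM()].
#' @return list with `tacs`, `suv`, `fit`.
#' @export
quantifySeries <- function(series, myoMasks, lvMask, rvMask, dose, weight,
                           suvTimes = c(2, 5, 10, 30), ...) {
  myoT <- extractTAC(series, myoMasks)
  lvT <- extractTAC(series, lvMask)
  rvT <- extractTAC(series, rvMask)
  fit <- fit1TCM(myoT, lvT, rvT, schedule(series), ...)
  list(tacs = list(myo = myoT, lv = lvT, rv = rvT),
       suv = computeSUV(myoT, dose, weight, suvTimes),
       fit = fit)
}
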