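# shared builders for small deterministic fixtures

clinicalSchedule <- function() {
  buildFrameSchedule(list(c(15, 10), c(15, 30), c(16, 60), c(7, 120)))
}

# small square phantom-free operator
tinyOperator <- function(nx = 16, nAngles = 24, voxelSize = 2, mu = NULL,
                         tof = NULL, psf = NULL) {
  buildSystemOperator(muMap = mu, nx = nx, ny = nx, voxelSize = voxelSize,
                      nAngles = nAngles, tof = tof, psf = psf)
}

# a SinogramSet whose prompts equal an exact expectation (no Poisson draw)
expectationSinogram <- function(trues, randoms = NULL, scatter = NULL) {
  d <- dim(trues)
  if (is.null(randoms)) randoms <- array(0, d)
  if (is.null(scatter)) scatter <- array(0, d)
  new("SinogramSet", prompts = trues + randoms + scatter, randoms = randoms,
      scatter = scatter, frameIndex = 1L)
}

# centered disc image
discImage <- function(nx, voxelSize, radius, value = 1) {
  co <- (seq_len(nx) - (nx + 1) / 2) * voxelSize
  X <- matrix(co, nx, nx)
  Y <- t(X)
  img <- matrix(0, nx, nx)
  img[X^2 + Y^2 < radius^2] <- value
  img
}

# frame-averaged curve of an input function (independent fine trapezoid)
frameAveragedInput <- function(input, sched, shift = 0, nSub = 40) {
  vapply(seq_len(nFrames(sched)), function(f) {
    tt <- seq(frameStarts(sched)[f],
              frameStarts(sched)[f] + frameDurations(sched)[f],
              length.out = nSub + 1)
    v <- evaluateInputFunction(input, tt + shift)
    mean((v[-1] + v[-length(v)]) / 2)
  }, numeric(1))
}

bloodTac <- function(input, sched, shift = 0) {
  data.frame(time_min = frameMids(sched) / 60,
             duration_min = frameDurations(sched) / 60,
             value = frameAveragedInput(input, sched, shift))
}
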