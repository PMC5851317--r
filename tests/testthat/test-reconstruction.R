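test_that("OSEM update collapses to p/A on a one-voxel, one-bin system", {
  op <- buildSystemOperator(nx = 1, ny = 1, voxelSize = 1, nAngles = 1,
                            nRadial = 1)
  expect_equal(as.vector(forwardProject(matrix(1, 1, 1), op)), 1)
  sino <- expectationSinogram(array(5, c(1, 1, 1)))
  res <- osemReconstruct(sino, op, reconConfig("OSEM", nIterations = 1L,
                                               nSubsets = 1L,
                                               postfilterFWHM = 0))
  expect_equal(reconImage(res)[1, 1], 5, tolerance = 1e-12)
})

test_that("zero counts drive the image to zero in one full iteration", {
  op <- tinyOperator(nx = 16, nAngles = 24)
  sino <- expectationSinogram(array(0, c(16, 24, 1)))
  res <- osemReconstruct(sino, op, reconConfig("OSEM", nIterations = 1L,
                                               nSubsets = 4L,
                                               postfilterFWHM = 0))
  expect_true(all(reconImage(res) == 0))
})

test_that("consistent data are a fixed point of the OSEM update", {
  mu <- discImage(16, 2, 12, 0.096)
  op <- buildSystemOperator(muMap = mu, voxelSize = 2, nAngles = 24)
  f0 <- discImage(16, 2, 10, 2) + 0.5
  trues <- forwardProject(f0, op)
  r <- array(0.3, dim(trues)); s <- array(0.2, dim(trues))
  sino <- expectationSinogram(trues, r, s)
  res <- osemReconstruct(sino, op, reconConfig("OSEM", nIterations = 2L,
                                               nSubsets = 4L,
                                               postfilterFWHM = 0),
                         initial = f0)
  expect_lt(max(abs(reconImage(res) - f0) / f0), 1e-10)
})

test_that("iterates are nonnegative and conserve counts under MLEM", {
  op <- tinyOperator(nx = 16, nAngles = 24)
  truth <- discImage(16, 2, 10, 3)
  trues <- forwardProject(truth, op)
  sino <- simulateCounts(trues * 5, op, 0.2, 0.2, seed = 21)
  res <- osemReconstruct(sino, op, reconConfig("OSEM", nIterations = 10L,
                                               nSubsets = 6L,
                                               postfilterFWHM = 0),
                         snapshots = TRUE)
  for (sn in reconSnapshots(res)) expect_true(all(sn >= 0))

  # MLEM with r = s = 0: sensitivity-weighted image total equals counts
  sino0 <- new("SinogramSet", prompts = sino@prompts,
               randoms = array(0, dim(sino@prompts)),
               scatter = array(0, dim(sino@prompts)), frameIndex = 1L)
  sens <- backProject(array(1, dim(sino@prompts)), op)
  f <- matrix(1, 16, 16)
  for (k in 1:3) {
    res1 <- osemReconstruct(sino0, op,
                            reconConfig("OSEM", nIterations = 1L,
                                        nSubsets = 1L, postfilterFWHM = 0),
                            initial = f)
    f <- reconImage(res1)
    expect_lt(abs(sum(sens * f) - sum(sino0@prompts)) / sum(sino0@prompts),
              1e-6)
  }
})

test_that("one-subset OSEM equals an independently coded MLEM", {
  mu <- discImage(16, 2, 12, 0.096)
  op <- buildSystemOperator(muMap = mu, voxelSize = 2, nAngles = 24, psf = 3)
  truth <- discImage(16, 2, 10, 2)
  sino <- simulateCounts(forwardProject(truth, op) * 20, op, 0.1, 0.1,
                         seed = 8)
  res <- osemReconstruct(sino, op, reconConfig("OSEM", nIterations = 5L,
                                               nSubsets = 1L,
                                               postfilterFWHM = 0))
  # oracle: plain MLEM via the public full-operator projectors
  f <- rep(1, 256)
  sens <- as.vector(backProject(array(1, dim(sino@prompts)), op))
  p <- as.vector(sino@prompts)
  rs <- as.vector(sino@randoms + sino@scatter)
  for (k in 1:5) {
    yh <- as.vector(forwardProject(matrix(f, 16, 16), op)) + rs
    bp <- as.vector(backProject(array(p / pmax(yh, 1e-12),
                                      dim(sino@prompts)), op))
    f <- ifelse(sens > 1e-12, f * bp / sens, 0)
  }
  expect_lt(max(abs(as.vector(reconImage(res)) - f)), 1e-10)
})

test_that("MLEM recovers a noiseless phantom", {
  set.seed(2)
  truth <- matrix(0, 16, 16)
  truth[5:12, 5:12] <- 1; truth[7:10, 7:10] <- 3
  op <- tinyOperator(nx = 16, nAngles = 24)
  sino <- expectationSinogram(forwardProject(truth, op))
  res <- osemReconstruct(sino, op, reconConfig("OSEM", nIterations = 500L,
                                               nSubsets = 1L,
                                               postfilterFWHM = 0))
  nrmse <- sqrt(mean((reconImage(res) - truth)^2)) / diff(range(truth))
  expect_lt(nrmse, 0.05)
})

test_that("method/operator requirements are enforced", {
  op <- tinyOperator(nx = 16, nAngles = 24)
  sino <- expectationSinogram(array(1, c(16, 24, 1)))
  expect_error(osemReconstruct(sino, op, reconConfig("TOF")), "TOF")
  opT <- tinyOperator(nx = 16, nAngles = 24,
                      tof = list(nBins = 5, binWidth = 40, fwhm = 80))
  sinoT <- expectationSinogram(array(1, c(16, 24, 5)))
  expect_error(osemReconstruct(sinoT, opT, reconConfig("TPSF")), "PSF")
  expect_error(osemReconstruct(sino, opT, reconConfig("OSEM")), "shape")
})

test_that("FBP is linear and zero on background-only data", {
  op <- tinyOperator(nx = 32, nAngles = 48)
  r <- array(2, c(32, 48, 1)); s <- array(1, c(32, 48, 1))
  sino <- new("SinogramSet", prompts = r + s, randoms = r, scatter = s,
              frameIndex = 1L)
  res <- fbpReconstruct(sino, op)
  expect_lt(max(abs(reconImage(res))), 1e-8)

  set.seed(6)
  p1 <- array(runif(32 * 48), c(32, 48, 1))
  p2 <- array(runif(32 * 48), c(32, 48, 1))
  z <- array(0, c(32, 48, 1))
  fb <- function(p) reconImage(fbpReconstruct(
    new("SinogramSet", prompts = p, randoms = z, scatter = z,
        frameIndex = 1L), op))
  lhs <- fb(3 * p1 + 2 * p2)
  rhs <- 3 * fb(p1) + 2 * fb(p2)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-10)
})

test_that("FBP recovers the mean of a uniform disc within 5%", {
  op <- tinyOperator(nx = 64, nAngles = 180)
  disc <- discImage(64, 2, 30, 2)
  sino <- expectationSinogram(forwardProject(disc, op))
  for (apo in c("ramp", "hann")) {
    res <- fbpReconstruct(sino, op, reconConfig("FBP", fbpApodization = apo))
    inner <- discImage(64, 2, 24, 1) > 0
    expect_lt(abs(mean(reconImage(res)[inner]) - 2) / 2, 0.05)
  }
})

test_that("FBP on TOF data sums the TOF bins first", {
  mu <- discImage(16, 2, 12, 0.096)
  opT <- buildSystemOperator(muMap = mu, voxelSize = 2, nAngles = 24,
                             tof = list(nBins = 5, binWidth = 40, fwhm = 80))
  op0 <- buildSystemOperator(muMap = mu, voxelSize = 2, nAngles = 24)
  truth <- discImage(16, 2, 8, 2)
  yT <- forwardProject(truth, opT)
  resT <- fbpReconstruct(expectationSinogram(yT), opT)
  res0 <- fbpReconstruct(expectationSinogram(forwardProject(truth, op0)), op0)
  expect_equal(reconImage(resT), reconImage(res0), tolerance = 1e-8)
})

test_that("post-filter matches the sampled Gaussian and conserves mass", {
  img <- matrix(rnorm(33 * 33) + 5, 33, 33)
  expect_identical(postFilter(img, 0, 2), img)

  d <- matrix(0, 33, 33); d[17, 17] <- 1
  pf <- postFilter(d, 5, 2)
  sig <- 5 / (2 * sqrt(2 * log(2))) / 2
  k <- exp(-((-16:16)^2) / (2 * sig^2)); k <- k / sum(k)
  expect_lt(max(abs(pf - outer(k, k))) / max(pf), 1e-6)

  u <- matrix(3, 20, 20)
  expect_equal(postFilter(u, 6.5, 2), u, tolerance = 1e-12)
  expect_lt(abs(sum(postFilter(img, 6.5, 2)) - sum(img)) / abs(sum(img)),
            1e-12)
  expect_error(postFilter(img, -1, 2), "invalid")
})

test_that("activity conversion applies the frame-averaged decay correction", {
  img <- matrix(1, 4, 4)
  # 20 min frame from injection: average decay (1 - e^-ln2)/ln2 ~ 0.7213
  out <- toActivityConcentration(img, 0, 1200, halfLife = 20)
  expect_equal(out[1, 1], 1 / 1200 / ((1 - exp(-log(2))) / log(2)),
               tolerance = 1e-12)
  # short frame centered at one half-life: correction ~ 2
  out2 <- toActivityConcentration(img, 1200 - 0.05, 0.1, halfLife = 20)
  expect_equal(out2[1, 1] * 0.1, 2, tolerance = 1e-4)
  # infinitesimal frame at t = 0: no decay correction
  out3 <- toActivityConcentration(img, 0, 1e-4, halfLife = 20)
  expect_equal(out3[1, 1] * 1e-4, 1, tolerance = 1e-6)
  expect_error(toActivityConcentration(img, 0, 10, halfLife = -1), "invalid")
})

test_that("EM-equivalent bookkeeping follows iterations x subsets", {
  expect_equal(emEquivalent(reconConfig("OSEM")), 200L)
  expect_equal(emEquivalent(reconConfig("TOF")), 100L)
  expect_equal(emEquivalent(reconConfig("TPSF")), 100L)
  expect_equal(emEquivalent(reconConfig("OSEM", nIterations = 3L,
                                        nSubsets = 7L)), 21L)
})
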