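test_that("ROI masks follow the center-in-circle rule", {
  # diameter below voxel size, centered on a voxel center: exactly 1 voxel
  co <- (1:32 - 16.5) * 2
  m1 <- makeRoiMask(c(co[10], co[20]), 1.5, 32, 32, 2)
  expect_equal(sum(m1), 1L)
  expect_true(m1[10, 20])

  # 10 mm circle in 2 mm voxels: close to pi * 25 / 4 voxels
  m2 <- makeRoiMask(c(0, 0), 10, 32, 32, 2)
  expect_lt(abs(sum(m2) - pi * 25 / 4) / (pi * 25 / 4), 0.20)

  m3 <- makeRoiMask(c(-20, 0), 10, 32, 32, 2)
  m4 <- makeRoiMask(c(20, 0), 10, 32, 32, 2)
  expect_false(any(m3 & m4))
  expect_error(makeRoiMask(c(500, 0), 10, 32, 32, 2), "outside")
  expect_error(makeRoiMask(c(0, 0), -2, 32, 32, 2), "diameter")
})

test_that("TAC extraction pools voxels and is linear", {
  sched <- buildFrameSchedule(list(c(3, 10)))
  arr <- array(5, c(8, 8, 3))
  ser <- new("DynamicImageSeries", data = arr, schedule = sched,
             voxelSize = 2, decayCorrected = TRUE, halfLife = 20)
  m <- matrix(FALSE, 8, 8); m[3, 3] <- TRUE; m[4, 4] <- TRUE
  expect_equal(extractTAC(ser, m)$value, rep(5, 3))

  arr2 <- arr; arr2[3, 3, ] <- 1; arr2[4, 4, ] <- 3
  ser2 <- new("DynamicImageSeries", data = arr2, schedule = sched,
              voxelSize = 2, decayCorrected = TRUE, halfLife = 20)
  expect_equal(extractTAC(ser2, m)$value, rep(2, 3))
  expect_equal(extractTAC(ser2, m)$time_min, c(5, 15, 25) / 60)

  # linearity in the image series
  serSum <- new("DynamicImageSeries", data = arr + arr2, schedule = sched,
                voxelSize = 2, decayCorrected = TRUE, halfLife = 20)
  expect_equal(extractTAC(ser, m)$value + extractTAC(ser2, m)$value,
               extractTAC(serSum, m)$value)
  expect_error(extractTAC(ser, matrix(FALSE, 8, 8)), "empty")
})

test_that("myocardial TAC from phantom truth matches the generating curve", {
  spec <- cardiacPhantom(nx = 96, voxelSize = 2, scale = 0.9)
  sched <- buildFrameSchedule(list(c(5, 10), c(3, 30), c(2, 60)))
  inp <- inputFunction()
  truth <- makeDynamicTruth(spec, inp, sched)
  rois <- cardiacROISet(spec)
  ras <- rasterizePhantom(spec)
  myoLabel <- which(ras$names == "myocardium")
  # ROI purity: every pooled voxel lies inside the annulus
  pooled <- Reduce(`|`, rois$myo)
  expect_true(all(ras$labels[pooled] == myoLabel))
  # extraction equals the region's generated frame values exactly
  tac <- extractTAC(truth, rois$myo)
  regionVals <- vapply(seq_len(nFrames(sched)), function(f) {
    v <- unique(frameImage(truth, f)[ras$labels == myoLabel])
    expect_length(v, 1L)
    v
  }, numeric(1))
  expect_lt(max(abs(tac$value - regionVals)) / max(regionVals), 1e-6)
  # and matches an independent integration of the generating kinetics
  tg <- seq(0, totalDuration(sched), by = 0.05) / 60
  cp <- evaluateInputFunction(inp, tg * 60)
  cm <- solve1TCM(0.8, 0.25, tg, cp, tg) * 2^(-tg / 20)
  ind <- vapply(seq_len(nFrames(sched)), function(f) {
    sel <- tg * 60 >= frameStarts(sched)[f] &
      tg * 60 <= frameStarts(sched)[f] + frameDurations(sched)[f]
    mean(cm[sel])
  }, numeric(1))
  expect_lt(max(abs(tac$value - ind)) / max(ind), 1e-3)
})

test_that("pooled myocardial average equals mean of per-ROI means", {
  # heart centered on the (even) grid so the four ROIs are exact mirror
  # images of each other and share one voxel count
  spec <- phantomSpec(96, 96, 2, list(
    list(name = "lv_blood", type = "disc", center = c(0, 0), radius = 16,
         mu = 0.096, kinetics = list(type = "blood", shift = 0)),
    list(name = "rv_blood", type = "disc", center = c(34, 0), radius = 8,
         mu = 0.096, kinetics = list(type = "blood", shift = 4)),
    list(name = "myocardium", type = "annulus", center = c(0, 0),
         radius = c(16, 26), mu = 0.096,
         kinetics = list(type = "tissue", K1 = 0.8, k2 = 0.25))))
  rois <- cardiacROISet(spec)
  sizes <- vapply(rois$myo, sum, integer(1))
  expect_true(all(sizes == sizes[1]))  # symmetric phantom, equal ROIs
  set.seed(9)
  img <- matrix(runif(96 * 96), 96, 96)
  arr <- array(img, c(96, 96, 1))
  ser <- new("DynamicImageSeries", data = arr,
             schedule = buildFrameSchedule(list(c(1, 10))),
             voxelSize = 2, decayCorrected = TRUE, halfLife = 20)
  pooledMean <- extractTAC(ser, rois$myo)$value
  perRoi <- vapply(rois$myo, function(m) mean(img[m]), numeric(1))
  expect_equal(pooledMean, mean(perRoi), tolerance = 1e-12)
})

test_that("CV and contrast follow their defining identities", {
  img <- matrix(100, 4, 4)
  sMask <- matrix(FALSE, 4, 4); sMask[1, 1:2] <- TRUE
  bMask <- matrix(FALSE, 4, 4); bMask[4, 4] <- TRUE
  st <- roiStatistics(img, sMask, bMask)
  expect_equal(st$cv, 0); expect_equal(st$contrast, 0)

  img[1, 1] <- 80; img[1, 2] <- 120
  st2 <- roiStatistics(img, sMask, bMask)
  expect_equal(st2$signal_mean, 100)
  expect_equal(st2$signal_sd, 20)  # population SD
  expect_equal(st2$cv, 0.2)

  img[4, 4] <- 100; img[1, 1] <- 150; img[1, 2] <- 150
  st3 <- roiStatistics(img, sMask, bMask)
  expect_equal(st3$contrast, 0.5)

  # re-verified against independent mean/SD computation
  set.seed(12)
  imgR <- matrix(rnorm(16, 50, 5), 4, 4)
  stR <- roiStatistics(imgR, sMask, bMask)
  sv <- imgR[sMask]
  expect_equal(stR$cv, sqrt(sum((sv - mean(sv))^2) / length(sv)) / mean(sv))
  expect_equal(stR$contrast,
               (mean(sv) - imgR[4, 4]) / imgR[4, 4])

  imgZ <- matrix(0, 4, 4)
  expect_error(roiStatistics(imgZ, sMask, bMask), "undefined")
})

test_that("SUV normalizes concentration by dose per body weight", {
  sched <- buildFrameSchedule(list(c(4, 600)))
  tac <- data.frame(time_min = frameMids(sched) / 60,
                    duration_min = frameDurations(sched) / 60,
                    value = c(10, 8, 4, 2))
  suv <- computeSUV(tac, dose = 740, weight = 74000, timePoints = c(2, 15))
  expect_equal(suv$suv, c(10, 8) / (740 * 1000 / 74000))
  expect_equal(suv$suv[1], 1)

  expect_equal(computeSUV(tac, 740, 2 * 74000, 2)$suv, 2)  # weight doubles SUV
  tac0 <- tac; tac0$value <- 0
  expect_equal(computeSUV(tac0, 740, 74000, 2)$suv, 0)
  # invariance under simultaneous scaling of concentration and dose/weight
  tac2 <- tac; tac2$value <- 3 * tac$value
  expect_equal(computeSUV(tac2, 3 * 740, 74000, 2)$suv,
               computeSUV(tac, 740, 74000, 2)$suv)
  expect_error(computeSUV(tac, 740, 74000, 90), "outside")
  expect_error(computeSUV(tac, -1, 74000, 2), "dose")
})

test_that("convergence curves index snapshots by EM-equivalent iteration", {
  img <- matrix(2, 8, 8); img[3, 3] <- 4
  sMask <- matrix(FALSE, 8, 8); sMask[3, 3:4] <- TRUE
  bMask <- matrix(FALSE, 8, 8); bMask[6, 6] <- TRUE
  snaps <- rep(list(img), 20)
  cc <- convergenceCurve(snaps, sMask, bMask, 10L)
  expect_equal(cc$em_equivalent, seq(10, 200, by = 10))
  expect_true(all(cc$cv == cc$cv[1]))
  expect_true(all(cc$contrast == cc$contrast[1]))
})
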