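test_that("frame schedule builder reproduces protocols exactly", {
  sched <- clinicalSchedule()
  expect_equal(nFrames(sched), 53L)
  expect_equal(totalDuration(sched), 2400)

  one <- buildFrameSchedule(list(c(1, 10)))
  expect_equal(frameStarts(one), 0)
  expect_equal(frameDurations(one), 10)

  two <- buildFrameSchedule(list(c(2, 5), c(1, 10)))
  expect_equal(frameStarts(two), c(0, 5, 10))

  # contiguity holds for arbitrary block structures
  set.seed(7)
  for (i in 1:10) {
    blocks <- lapply(seq_len(sample(1:5, 1)),
                     function(j) c(sample(1:6, 1), sample(c(5, 10, 30, 60), 1)))
    s <- buildFrameSchedule(blocks)
    expect_equal(nFrames(s), sum(vapply(blocks, `[[`, numeric(1), 1)))
    if (nFrames(s) > 1)
      expect_equal(frameStarts(s)[-1],
                   (frameStarts(s) + frameDurations(s))[-nFrames(s)])
  }

  expect_error(buildFrameSchedule(list()), "empty")
  expect_error(buildFrameSchedule(list(c(0, 10))), "counts")
  expect_error(buildFrameSchedule(list(c(2, -1))), "durations")
})

test_that("input functions are zero before arrival and continuous at onset", {
  for (mod in c("feng", "gamma_variate")) {
    inp <- inputFunction(mod, delay = 15)
    expect_equal(evaluateInputFunction(inp, c(0, 5, 14.9)), rep(0, 3))
    # continuity: both models vanish at onset
    expect_lt(evaluateInputFunction(inp, 15 + 1e-4), 0.01)
    expect_true(all(evaluateInputFunction(inp, seq(0, 2400, by = 5)) >= 0))
  }
})

test_that("feng model matches independent term-by-term evaluation", {
  inp <- inputFunction("feng", delay = 0)
  p <- inp@parameters
  tm <- 60 / 60  # 60 s in minutes
  oracle <- (p[["A1"]] * tm - p[["A2"]] - p[["A3"]]) * exp(p[["lambda1"]] * tm) +
    p[["A2"]] * exp(p[["lambda2"]] * tm) + p[["A3"]] * exp(p[["lambda3"]] * tm)
  expect_equal(evaluateInputFunction(inp, 60), unname(oracle), tolerance = 1e-12)
})

test_that("invalid input-function coefficients are rejected", {
  expect_error(inputFunction("feng", c(A1 = -1, A2 = 1, A3 = 1, lambda1 = -1,
                                       lambda2 = -1, lambda3 = -1)),
               "negative")
  expect_error(inputFunction("gamma_variate", c(A = 1, alpha = -2, beta = 1)),
               "invalid")
  expect_error(inputFunction("feng", delay = -5), "delay")
})

test_that("phantom rasterization labels voxels deterministically", {
  # background only: uniform label
  bg <- phantomSpec(32, 32, 2, list(
    list(name = "all", type = "disc", center = c(0, 0), radius = 1000,
         mu = 0.096, kinetics = list(type = "blood", shift = 0))))
  expect_warning(ras <- rasterizePhantom(bg), "clipped")
  expect_true(all(ras$labels == 1L))
  expect_true(all(ras$mu == 0.096))

  # disc voxel count close to its area
  spec <- phantomSpec(64, 64, 2, list(
    list(name = "lv", type = "disc", center = c(0, 0), radius = 10,
         mu = 0.01, kinetics = list(type = "blood", shift = 0))))
  ras <- rasterizePhantom(spec)
  n <- sum(ras$labels == 1L)
  expect_lt(abs(n - pi * (10 / 2)^2) / (pi * 25), 0.10)
  expect_true(all(ras$mu[ras$labels == 1L] == 0.01))

  # later regions overwrite earlier ones: myocardium last wins
  spec2 <- cardiacPhantom(nx = 96, voxelSize = 2, scale = 0.9)
  ras2 <- rasterizePhantom(spec2)
  nm <- ras2$names
  expect_identical(nm[length(nm)], "myocardium")
  myoLabel <- which(nm == "myocardium")
  lvLabel <- which(nm == "lv_blood")
  expect_gt(sum(ras2$labels == myoLabel), 0)
  # annulus voxels are never labelled LV even though LV disc is interior
  lvC <- spec2@regions[[lvLabel]]$center
  co <- (seq_len(96) - 48.5) * 2
  X <- matrix(co, 96, 96); Y <- t(X)
  d2 <- (X - lvC[1])^2 + (Y - lvC[2])^2
  ann <- spec2@regions[[myoLabel]]$radius
  inAnn <- d2 >= ann[1]^2 & d2 < ann[2]^2
  expect_true(all(ras2$labels[inAnn] == myoLabel))
})

test_that("dynamic truth reproduces degenerate and constant cases", {
  sched <- buildFrameSchedule(list(c(3, 10), c(2, 30)))
  spec <- phantomSpec(16, 16, 2, list(
    list(name = "blood", type = "disc", center = c(0, 0), radius = 10,
         mu = 0, kinetics = list(type = "blood", shift = 0))))

  zero <- inputFunction("constant", c(value = 0), delay = 0)
  tz <- makeDynamicTruth(spec, zero, sched)
  expect_true(all(tz@data == 0))

  cst <- inputFunction("constant", c(value = 7), delay = 0)
  tc <- makeDynamicTruth(spec, cst, sched, decay = FALSE)
  ras <- rasterizePhantom(spec)
  for (f in seq_len(nFrames(sched)))
    expect_equal(unique(frameImage(tc, f)[ras$labels == 1L]), 7)
  # with decay disabled the series needs no further decay referencing
  expect_true(tc@decayCorrected)
})

test_that("decay halves a kinetically frozen region after one half-life", {
  # frame centered at one half-life (20 min), short duration
  sched <- buildFrameSchedule(list(c(1, 1195), c(1, 10), c(1, 100)))
  spec <- phantomSpec(8, 8, 2, list(
    list(name = "blood", type = "disc", center = c(0, 0), radius = 8,
         mu = 0, kinetics = list(type = "blood", shift = 0))))
  cst <- inputFunction("constant", c(value = 10), delay = 0)
  tr <- makeDynamicTruth(spec, cst, sched, decay = TRUE, halfLife = 20)
  v <- frameImage(tr, 2)[4, 4]
  expect_lt(abs(v - 5) / 5, 0.01)
})

test_that("truth generation is linear in input amplitude", {
  sched <- buildFrameSchedule(list(c(4, 10), c(2, 60)))
  spec <- cardiacPhantom(nx = 32, voxelSize = 2, scale = 0.3)
  p <- inputFunction()@parameters
  inp1 <- inputFunction("feng", p, delay = 10)
  p2 <- p; p2[c("A1", "A2", "A3")] <- 2 * p2[c("A1", "A2", "A3")]
  inp2 <- inputFunction("feng", p2, delay = 10)
  t1 <- makeDynamicTruth(spec, inp1, sched)
  t2 <- makeDynamicTruth(spec, inp2, sched)
  expect_equal(t2@data, 2 * t1@data, tolerance = 1e-10)
})

test_that("frame averages converge to instantaneous values as duration -> 0", {
  spec <- phantomSpec(8, 8, 2, list(
    list(name = "blood", type = "disc", center = c(0, 0), radius = 8,
         mu = 0, kinetics = list(type = "blood", shift = 0))))
  inp <- inputFunction("gamma_variate", delay = 0)
  # short frame late on the (smooth) downslope
  sched <- new("FrameSchedule", start = c(0, 120), duration = c(120, 0.1),
               injectionTime = 0)
  tr <- makeDynamicTruth(spec, inp, sched, decay = FALSE)
  inst <- evaluateInputFunction(inp, 120.05)
  expect_lt(abs(frameImage(tr, 2)[4, 4] - inst) / inst, 1e-3)
})

test_that("tissue truth matches an independent ODE integration", {
  testthat::skip_if_not_installed("deSolve")
  sched <- buildFrameSchedule(list(c(5, 10), c(3, 30), c(2, 60)))
  spec <- phantomSpec(8, 8, 2, list(
    list(name = "myo", type = "disc", center = c(0, 0), radius = 8,
         mu = 0, kinetics = list(type = "tissue", K1 = 0.8, k2 = 0.2))))
  inp <- inputFunction("gamma_variate", delay = 5)
  tr <- makeDynamicTruth(spec, inp, sched, decay = TRUE, halfLife = 20)

  # oracle: stiff ODE solve on a 0.1 s grid, decayed, frame-averaged
  tg <- seq(0, totalDuration(sched), by = 0.1)
  cpg <- evaluateInputFunction(inp, tg)
  ode <- deSolve::lsoda(
    y = c(C = 0), times = tg / 60,
    func = function(t, y, parms) {
      cp <- approx(tg / 60, cpg, xout = t, rule = 2)$y
      list(0.8 * cp - 0.2 * y)
    }, rtol = 1e-9, atol = 1e-9)
  dec <- 2^(-(tg / 60) / 20)
  curve <- ode[, "C"] * dec
  fv <- vapply(seq_len(nFrames(sched)), function(f) {
    sel <- tg >= frameStarts(sched)[f] &
      tg <= frameStarts(sched)[f] + frameDurations(sched)[f]
    mean(curve[sel])
  }, numeric(1))
  got <- vapply(seq_len(nFrames(sched)), function(f) frameImage(tr, f)[4, 4],
                numeric(1))
  # tolerance dominated by the oracle's own rectangle-rule frame averaging
  expect_lt(max(abs(got - fv) / max(fv)), 5e-4)
})

test_that("missing region kinetics raise a configuration error", {
  spec <- phantomSpec(8, 8, 2, list(
    list(name = "x", type = "disc", center = c(0, 0), radius = 4, mu = 0,
         kinetics = NULL)))
  expect_error(makeDynamicTruth(spec, inputFunction(), clinicalSchedule()),
               "configuration error")
})

test_that("decay correction factor doubles at one half-life", {
  expect_equal(decayCorrectionFactor(20, halfLife = 20), 2)
  expect_equal(decayCorrectionFactor(0), 1)
  # frame-averaged decay over [0, 1200 s] at 20 min half-life
  expect_equal(frameDecayFactor(0, 1200, 20), (1 - exp(-log(2))) / log(2),
               tolerance = 1e-12)
})
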