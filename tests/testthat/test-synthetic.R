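test_that("evoked kernel is silent without drive and errors on bad input", {
  k <- new("KernelParams", peakDff = 1.5)
  t <- seq(0, 20, by = 0.02)
  expect_equal(evokedKernel("cytosol", c(5, 2, 0), k, t), numeric(length(t)))
  k0 <- new("KernelParams", peakDff = 0)
  expect_equal(evokedKernel("cytosol", c(5, 2, 50), k0, t),
               numeric(length(t)))
  expect_error(evokedKernel("nucleus", c(5, 2, 50), k, t), "compartment")
})

test_that("kernels are zero before onset and peak at the stated amplitude", {
  t <- seq(0, 60, by = 0.1)
  for (comp in c("cytosol", "er", "mito")) {
    cfg <- simConfig(comp)
    r <- evokedKernel(comp, c(5, 2, 40), cfg@kernel, t)
    expect_true(all(r[t < 5] == 0), info = comp)
  }
})

test_that("ER kernel dip equals its amplitude when the slow component is delayed", {
  k <- new("KernelParams", riseTau = 5, decayTau = 20, peakDff = 0.3,
           dipAmp = 0.1, dipTau = 0.8)
  t <- seq(0, 60, by = 0.1)  # onset on the sampling grid
  r <- evokedKernel("er", c(5, 2, 40), k, t)
  expect_equal(min(r), -0.1, tolerance = 1e-3)
  expect_gt(t[which.max(r)], 7)  # slow uptake peaks after the train
})

test_that("mito kernel matches dense oversampled evaluation and its plateau", {
  k <- new("KernelParams", riseTau = 0.4, decayTau = 1.2, peakDff = 2,
           plateauFraction = 0.4, slowTau = 30)
  stim <- c(5, 2, 80)
  fr <- 10
  t <- seq(0, 60 - 1 / fr, by = 1 / fr)
  r <- evokedKernel("mito", stim, k, t)
  # dense 1000x-oversampled evaluation as the oracle for sampled values
  tDense <- seq(0, 60, by = 1 / (fr * 1000))
  rDense <- evokedKernel("mito", stim, k, tDense)
  idx <- match(round(t * fr * 1000), round(tDense * fr * 1000))
  expect_equal(r, rDense[idx], tolerance = 1e-12)
  expect_equal(max(r), 2, tolerance = 1e-6)
  # post-decline plateau ~ plateauFraction * peak
  atPlateau <- r[which.min(abs(t - (7 + 3 * k@decayTau)))]
  expect_equal(atPlateau, 0.8, tolerance = 0.1)
})

test_that("trace without noise, minis or drive equals the bleach curve", {
  cfg <- simConfig("cytosol", genotypeScale = 0, duration = 4,
                   stim = c(1, 0.5, 50), noise = list(gaussianSd = 0),
                   seed = 1)
  sim <- simulateTrace(cfg)
  n <- length(traceValues(sim$trace))
  expect_equal(traceValues(sim$trace), 1000 * (1:n)^-0.05)
})

test_that("bleach-only trace is strictly decreasing for b < 0, constant for b = 0", {
  cfg <- simConfig("cytosol", genotypeScale = 0, duration = 4,
                   stim = c(1, 0.5, 50), noise = list(gaussianSd = 0),
                   seed = 1)
  expect_true(all(diff(traceValues(simulateTrace(cfg)$trace)) < 0))
  cfg@bleach <- c(500, 0)
  expect_equal(unique(traceValues(simulateTrace(cfg)$trace)), 500)
})

test_that("simulation is deterministic in the seed", {
  cfg <- simConfig("er", mini = list(rateHz = 0.3), seed = 42)
  s1 <- simulateTrace(cfg)
  s2 <- simulateTrace(cfg)
  expect_identical(traceValues(s1$trace), traceValues(s2$trace))
  expect_identical(miniTimes(s1$truth), miniTimes(s2$truth))
  cfg2 <- cfg; cfg2@seed <- 43L
  expect_false(identical(traceValues(simulateTrace(cfg2)$trace),
                         traceValues(s1$trace)))
})

test_that("ER preset samples at 10 frames per second", {
  cfg <- simConfig("er", duration = 12, seed = 1)
  tr <- simulateTrace(cfg)$trace
  expect_equal(frameRate(tr), 10)
  expect_equal(length(traceValues(tr)), 120)
})

test_that("ground-truth mini count matches the Poisson mean over seeds", {
  counts <- vapply(1:200, function(s) {
    cfg <- simConfig("postsynaptic", duration = 20, stim = c(0, 0, 0),
                     mini = list(rateHz = 0.5), seed = s)
    length(miniTimes(simulateTrace(cfg)$truth))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10) / sqrt(200))
  # and the recorded truth is always sorted within the recording
  cfg <- simConfig("postsynaptic", duration = 20, stim = c(0, 0, 0),
                   mini = list(rateHz = 2), seed = 7)
  tt <- miniTimes(simulateTrace(cfg)$truth)
  expect_false(is.unsorted(tt))
  expect_true(all(tt >= 0 & tt <= 20))
})

test_that("rendered bouton reproduces its generating trace up to one constant", {
  cfg <- simConfig("cytosol", duration = 2, stim = c(0.5, 0.5, 50),
                   noise = list(gaussianSd = 0), seed = 5)
  mv <- simulateMovie(cfg)
  tr <- traceValues(extractTrace(mv$movie, mv$rois[[1]]))
  gen <- traceValues(mv$boutonTraces[[1]])
  ratio <- tr / gen
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
})

test_that("movie drift ground truth is the cumulative integer drift", {
  cfg <- simConfig("cytosol", duration = 0.2, stim = c(0.05, 0.05, 50),
                   noise = list(gaussianSd = 0),
                   geometry = list(driftPxPerFrame = c(1, 0)), seed = 1)
  mv <- simulateMovie(cfg)
  expect_equal(unname(trueShifts(mv$truth)[, 1]), 0:9)
  expect_equal(unname(trueShifts(mv$truth)[, 2]), rep(0, 10))
})

test_that("bouton placement outside the image errors", {
  cfg <- simConfig("cytosol", duration = 0.1,
                   stim = c(0.02, 0.02, 50),
                   geometry = list(imageShape = c(20L, 20L),
                                   boutonRadius = 6), seed = 1)
  expect_error(simulateMovie(cfg), "inside the image")
})

test_that("two boutons with 2:1 peaks give a 2:1 max dF/F after the pipeline", {
  cfg <- simConfig("cytosol", duration = 12, stim = c(5, 2, 50),
                   noise = list(gaussianSd = 0),
                   geometry = list(nBoutons = 2L,
                                   boutonPeakScale = c(1, 0.5)),
                   seed = 3)
  mv <- simulateMovie(cfg)
  maxDffOf <- function(roi) {
    tr <- extractTrace(mv$movie, roi, stim = cfg@stim)
    analyzeTrace(tr)$features@maxDff
  }
  ratio <- maxDffOf(mv$rois[[1]]) / maxDffOf(mv$rois[[2]])
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("static pair: no puncta means no truth pixels and equal partitions", {
  cfg <- simConfig("cytosol", seed = 4,
                   geometry = list(imageShape = c(48L, 48L)))
  sp <- simulateStaticPair(cfg, nPuncta = 0)
  expect_false(any(sp$punctaTruth))
  pp <- punctaPartition(sp$marker, Roi(sp$nmjMask))
  expect_equal(pp$area_px[pp$roi_id == "puncta"], 0L)
  expect_equal(pp$mean_intensity[pp$roi_id == "whole"],
               pp$mean_intensity[pp$roi_id == "complement"])
})

test_that("static pair ratiometry against a constant reference", {
  cfg <- simConfig("cytosol", seed = 4,
                   geometry = list(imageShape = c(48L, 48L)))
  sp <- simulateStaticPair(cfg, nPuncta = 0, referenceLevel = 80)
  q <- measureIntensity(sp$marker, Roi(sp$nmjMask), sp$reference)
  expect_equal(q$relative_intensity,
               mean(sp$marker[sp$nmjMask]) / 80, tolerance = 1e-12)
})
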