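test_that("log-log fit recovers a noiseless power law exactly", {
  tr <- powerTrace(1000, -0.05, 100)
  m <- fitBleach(tr, 50)
  expect_equal(m@a, 1000, tolerance = 1e-9)
  expect_equal(m@b, -0.05, tolerance = 1e-9)
  const <- CaTrace(rep(500, 50), 10)
  mc <- fitBleach(const, 50)
  expect_equal(mc@a, 500, tolerance = 1e-12)
  expect_equal(mc@b, 0, tolerance = 1e-12)
})

test_that("bleach fit errors on short windows and non-positive values", {
  tr <- powerTrace(n = 50)
  expect_error(fitBleach(tr, 2), "at least 3")
  bad <- CaTrace(c(-1, rep(10, 20)), 10)
  expect_error(fitBleach(bad, 10), "positive")
})

test_that("fitted exponent is unbiased under Gaussian noise", {
  bs <- vapply(1:500, function(s) {
    set.seed(s)
    f <- 800 * (1:100)^-0.08 + rnorm(100, 0, 2)
    fitBleach(CaTrace(f, 10), 100)@b
  }, numeric(1))
  expect_lt(abs(mean(bs) - (-0.08)), 0.005)
})

test_that("bleach fit is scale-equivariant", {
  set.seed(5)
  f <- 900 * (1:80)^-0.06 + rnorm(80, 0, 1)
  m1 <- fitBleach(CaTrace(f, 10), 80)
  m2 <- fitBleach(CaTrace(7 * f, 10), 80)
  expect_equal(m2@a / m1@a, 7, tolerance = 1e-9)
  expect_equal(m2@b, m1@b, tolerance = 1e-9)
})

test_that("correcting a pure power-law trace yields the constant 1", {
  tr <- powerTrace(1000, -0.05, 100)
  out <- traceValues(correctBleach(tr, fitBleach(tr, 100)))
  expect_lt(max(abs(out - 1)), 1e-9)
})

test_that("bleach correction recovers a known modulation exactly", {
  n <- 200
  r <- 0.5 * sin(seq(0, 3, length.out = n))^2
  pc <- 1200 * (1:n)^-0.07
  tr <- CaTrace(pc * (1 + r), 10)
  model <- new("BleachModel", a = 1200, b = -0.07,
               fitWindow = c(0L, 49L), xOffset = 1)
  expect_equal(traceValues(correctBleach(tr, model)) - 1, r,
               tolerance = 1e-12)
})

test_that("corrected noisy baseline sits within 1% of unity", {
  cfg <- simConfig("cytosol", duration = 15, noise = list(gaussianSd = 10),
                   seed = 8)
  sim <- simulateTrace(cfg)
  corr <- correctBleach(sim$trace, fitBleach(sim$trace))
  pre <- traceValues(corr)[1:(5 * 50 - 1)]
  expect_gt(mean(pre), 0.99)
  expect_lt(mean(pre), 1.01)
})

test_that("rolling average matches the brute-force shrinking-window mean", {
  bruteForce <- function(v, w) {
    h <- (w - 1) / 2
    n <- length(v)
    vapply(seq_len(n), function(i) {
      k <- min(h, i - 1, n - i)
      mean(v[(i - k):(i + k)])
    }, numeric(1))
  }
  set.seed(31)
  for (rep in 1:100) {
    v <- rnorm(sample(10:60, 1))
    expect_equal(rollingAverage(v, 5), bruteForce(v, 5))
  }
  expect_equal(rollingAverage(c(0, 0, 5, 0, 0), 5), c(0, 5 / 3, 1, 5 / 3, 0))
  expect_equal(rollingAverage(rep(3, 10), 5), rep(3, 10))
  expect_error(rollingAverage(1:10, 4), "odd")
})

test_that("dff is corrected minus one and recovers the simulated peak", {
  flat <- CaTrace(rep(1, 10), 10)
  expect_equal(traceValues(dff(flat)), rep(0, 10))
  cfg <- simConfig("cytosol", genotypeScale = 0.7, duration = 15,
                   noise = list(gaussianSd = 0), seed = 2)
  sim <- simulateTrace(cfg)
  corr <- correctBleach(sim$trace, fitBleach(sim$trace))
  d <- dff(corr)
  expect_equal(max(traceValues(d)), truePeakDff(sim$truth),
               tolerance = 1e-6)
  expect_equal(truePeakDff(sim$truth), 0.7 * 1.5, tolerance = 1e-9)
})

test_that("evoked features reproduce piecewise-linear pulse geometry", {
  fr <- 10
  n <- 121
  t <- (0:(n - 1)) / fr
  onset <- 2
  d <- numeric(n)
  rise <- t >= onset & t <= onset + 2
  fall <- t > onset + 2 & t <= onset + 6
  d[rise] <- (t[rise] - onset) / 2
  d[fall] <- 1 - (t[fall] - onset - 2) / 4
  raw <- CaTrace(1000 * (1 + d), fr, stim = c(onset, 1, 20))
  model <- new("BleachModel", a = 1000, b = 0, fitWindow = c(0L, 19L),
               xOffset = 1)
  dTrace <- CaTrace(d, fr, stim = c(onset, 1, 20))
  f <- evokedFeatures(raw, model, dTrace, noiseBandK = 0)
  expect_equal(f@timeToPeak, 2)
  expect_equal(f@t50Recovery, 2, tolerance = 0.11)  # first sample <= 0.5
  expect_equal(f@t100Recovery, 4, tolerance = 0.11)
  expect_equal(f@maxDff, 1)
  expect_equal(f@restingF, 1000)
  expect_equal(f@deltaF, f@maxF - f@restingF)
})

test_that("a trace that never recovers reports no 100% recovery time", {
  fr <- 10
  t <- (0:99) / fr
  d <- ifelse(t >= 2, 1, 0)
  raw <- CaTrace(1000 * (1 + d), fr, stim = c(2, 1, 20))
  model <- new("BleachModel", a = 1000, b = 0, fitWindow = c(0L, 19L),
               xOffset = 1)
  f <- evokedFeatures(raw, model, CaTrace(d, fr, stim = c(2, 1, 20)))
  expect_true(is.na(f@t100Recovery))
  expect_false(is.na(f@maxDff))
  expect_error(evokedFeatures(raw, model, CaTrace(d, fr)), "stim")
})

test_that("time features are invariant to shifting the stimulation onset", {
  base <- simConfig("cytosol", duration = 15, noise = list(gaussianSd = 0),
                    seed = 3)
  shifted <- simConfig("cytosol", duration = 15, stim = c(7, 2, 50),
                       noise = list(gaussianSd = 0), seed = 3)
  f1 <- analyzeTrace(simulateTrace(base)$trace)$features
  f2 <- analyzeTrace(simulateTrace(shifted)$trace)$features
  expect_equal(f1@timeToPeak, f2@timeToPeak, tolerance = 1e-9)
  expect_equal(f1@t50Recovery, f2@t50Recovery, tolerance = 1e-9)
})

test_that("noisy evoked-feature recovery stays within tolerance", {
  errsPeak <- errsT <- numeric(60)
  for (s in 1:60) {
    cfg <- simConfig("cytosol", duration = 15,
                     noise = list(gaussianSd = 20), seed = s)
    sim <- simulateTrace(cfg)
    f <- analyzeTrace(sim$trace)$features
    errsPeak[s] <- abs(f@maxDff - truePeakDff(sim$truth)) /
      truePeakDff(sim$truth)
    tTrue <- (which.max(cleanDff(sim$truth)) - 1) / 50 - 5
    errsT[s] <- abs(f@timeToPeak - tTrue)
  }
  expect_lt(median(errsPeak), 0.05)
  expect_lte(median(errsT), 1 / 50)
})

test_that("control normalization maps the control mean to one", {
  vals <- c(2, 4, 1.5)
  groups <- c("WT", "WT", "KO")
  norm <- normalizeToControl(vals, groups, "WT")
  expect_equal(norm, c(2 / 3, 4 / 3, 0.5))
  expect_equal(unique(normalizeToControl(rep(7, 4), rep("WT", 4))), 1)
  expect_error(normalizeToControl(c(0, 0), c("WT", "WT")), "positive")
})

test_that("timecourse pair normalization pins the control range at 100", {
  wt <- CaTrace(c(-0.2, 0.1, 0.8, 0.3), 10)
  other <- CaTrace(c(0, 0.2, 0.4, 0.1), 10)
  out <- normalizeTimecoursePair(wt, other)
  expect_equal(out$scale, 100)
  expect_equal(diff(range(traceValues(out$wt))), 100)
  expect_equal(traceValues(out$other), c(0, 20, 40, 10))
  spanned <- seq(0, 100, length.out = 11)
  expect_equal(traceValues(normalizeTimecoursePair(
    CaTrace(spanned, 1), CaTrace(spanned, 1))$wt), spanned)
  expect_error(normalizeTimecoursePair(CaTrace(rep(1, 5), 1), other),
               "flat")
})

test_that("batch normalization removes a pure gain difference", {
  set.seed(41)
  wt1 <- rnorm(8, 10, 0.5); mut1 <- rnorm(8, 5, 0.3)
  gain <- 2
  vals <- c(wt1, mut1, gain * wt1, gain * mut1)
  groups <- rep(rep(c("WT", "mut"), each = 8), 2)
  batches <- rep(c("s1", "s2"), each = 16)
  norm <- batchNormalize(vals, groups, batches)
  expect_equal(norm[batches == "s1"], norm[batches == "s2"],
               tolerance = 1e-12)
  # single batch degenerates to plain control normalization
  one <- batchNormalize(vals[1:16], groups[1:16], rep("s1", 16))
  expect_equal(one, normalizeToControl(vals[1:16], groups[1:16], "WT"))
  expect_error(batchNormalize(1:3, rep("mut", 3), rep("s1", 3)), "no 'WT'")
})

test_that("simulated two-setup gain difference pools correctly", {
  co <- simulateCohort(nLarvae = 10, frequencies = 50,
                      batchGains = c(s1 = 1, s2 = 1.7), seed = 9)
  norm <- batchNormalize(co$max_dff, co$genotype, co$batch_id)
  mutMean <- mean(norm[co$genotype == "mutant"])
  expect_gt(mutMean, 0.45)
  expect_lt(mutMean, 0.55)
})
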