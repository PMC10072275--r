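#' Build a simulation configuration with compartment defaults
#'
#' Returns a [SimConfig-class] whose defaults emulate the study conditions
#' for each compartment: ER-lumen and mitochondrial recordings at 10
#' frames/s, cytosolic and postsynaptic recordings at 50 frames/s; a 5 s
#' pre-stimulation baseline followed by a 2 s stimulus train; power-law
#' photobleaching of the baseline; Gaussian read noise at 2% of baseline;
#' and evoked kinetics per compartment (fast cytosolic transient; ER
#' release dip then slow uptake overshoot; fast mitochondrial uptake with
#' a partial decline to a plateau that returns to baseline over tens of
#' seconds). `genotypeScale` multiplies evoked amplitudes (1 = wild type;
#' the mutant preset is 0.5).
#'
#' @param compartment `"cytosol"`, `"er"`, `"mito"` or `"postsynaptic"`.
#' @param genotypeScale multiplier on evoked amplitudes.
#' @param frameRate,duration acquisition rate (Hz) and length (s).
#' @param stim `c(onset_s, duration_s, frequency_hz)`.
#' @param kernel a [KernelParams-class]; compartment default when `NULL`.
#' @param bleach `c(a, b)` of the photobleach power curve.
#' @param noise list with `gaussianSd` (a.u.) and `shotNoise` (flag).
#' @param mini list with `rateHz`, `ampMean`, `ampSd` (dF/F units) and
#'   `decayTau` (s).
#' @param geometry list with `nBoutons`, `boutonRadius`, `imageShape`
#'   (`c(H, W)`), `driftPxPerFrame` (`c(dy, dx)`), `background`, and
#'   optionally `boutonPeakScale` (per-bouton multipliers on the evoked
#'   peak).
#' @param seed integer seed; all randomness in the simulators flows from it.
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig("er", seed = 1)
#' st <- simulateTrace(cfg)
#' st$trace
#' @export
simConfig <- function(compartment = c("cytosol", "er", "mito", "postsynaptic"),
                      genotypeScale = 1,
                      frameRate = NULL, duration = NULL, stim = NULL,
                      kernel = NULL, bleach = c(a = 1000, b = -0.05),
                      noise = list(), mini = list(), geometry = list(),
                      seed = 1L) {
  compartment <- match.arg(compartment)
  fast <- compartment %in% c("cytosol", "postsynaptic")
  frameRate <- frameRate %||% if (fast) 50 else 10
  duration <- duration %||% if (fast) 25 else 60
  stim <- stim %||% switch(compartment,
    cytosol = c(5, 2, 50), postsynaptic = c(5, 2, 2),
    er = c(5, 2, 40), mito = c(5, 2, 80))
  kernel <- kernel %||% switch(compartment,
    cytosol = new("KernelParams", riseTau = 2, decayTau = 2,
                  peakDff = 1.5),
    postsynaptic = new("KernelParams", riseTau = 0.5, decayTau = 1,
                       peakDff = 1),
    er = new("KernelParams", riseTau = 3, decayTau = 15, peakDff = 0.3,
             dipAmp = 0.1, dipTau = 0.8),
    mito = new("KernelParams", riseTau = 0.4, decayTau = 1.2, peakDff = 2,
               plateauFraction = 0.4, slowTau = 45))
  noise <- utils::modifyList(list(gaussianSd = 20, shotNoise = FALSE), noise)
  mini <- utils::modifyList(
    list(rateHz = 0, ampMean = 0.3, ampSd = 0.1, decayTau = 0.2), mini)
  geometry <- utils::modifyList(
    list(nBoutons = 3L, boutonRadius = 4, imageShape = c(48L, 48L),
         driftPxPerFrame = c(0, 0), background = 0,
         boutonPeakScale = NULL), geometry)
  new("SimConfig", compartment = compartment,
      genotypeScale = genotypeScale, frameRate = frameRate,
      duration = duration, stim = stim, kernel = kernel,
      bleach = as.numeric(bleach), noise = noise, mini = mini,
      geometry = geometry, seed = as.integer(seed))
}

# integral from 0 to x of exp(-s/taud) - exp(-s/taur); 0 for x < 0.
# convolving a unit boxcar with a difference-of-exponentials kernel reduces
# to differences of this primitive.
.boxConvPrimitive <- function(x, taur, taud) {
  ifelse(x <= 0, 0,
         taud * (1 - exp(-x / taud)) - taur * (1 - exp(-x / taur)))
}

# unnormalized evoked waveform: boxcar train envelope convolved with a
# difference-of-exponentials impulse response
.boxConvWave <- function(t, onset, dur, taur, taud) {
  .boxConvPrimitive(t - onset, taur, taud) -
    .boxConvPrimitive(t - onset - dur, taur, taud)
}

#' Closed-form evoked-response kernel, sampled at given times
#'
#' The dimensionless drive \eqn{r(t)} added (times the genotype scale) to
#' the baseline by [simulateTrace()]. Zero before stimulation onset and
#' identically zero when the stimulation frequency or all amplitudes are
#' zero. Shapes by compartment:
#' \describe{
#'   \item{cytosol / postsynaptic}{saturating first-order rise (time
#'     constant `riseTau`) during the train to `peakDff`, exponential
#'     decay with `decayTau` after it; the peak sits at the end of the
#'     train.}
#'   \item{er}{a negative release dip of amplitude `dipAmp` at onset
#'     decaying with `dipTau`, plus a slow positive uptake component
#'     (same convolved form with slow time constants) of amplitude
#'     `peakDff` peaking after the train ends.}
#'   \item{mito}{fast saturating rise to `peakDff` during the train, fast
#'     partial decline (time constant `decayTau`) to
#'     `plateauFraction * peakDff`, then slow return to baseline with
#'     `slowTau`.}
#' }
#'
#' @param compartment compartment name.
#' @param stim `c(onset_s, duration_s, frequency_hz)`.
#' @param params a [KernelParams-class].
#' @param times sample times in seconds.
#' @return numeric vector `r(t)` (dF/F units), same length as `times`.
#' @export
evokedKernel <- function(compartment, stim, params, times) {
  if (!compartment %in% .compartments)
    stop("unknown compartment '", compartment, "'; must be one of: ",
         paste(.compartments, collapse = ", "))
  validObject(params)
  onset <- stim[1]; dur <- stim[2]; freq <- stim[3]
  if (freq <= 0) return(numeric(length(times)))
  r <- numeric(length(times))
  if (compartment %in% c("cytosol", "postsynaptic")) {
    if (params@peakDff == 0) return(r)
    # saturating first-order rise during the train, exponential decay
    # after it; the peak sits exactly at the end of the train, where the
    # derivative changes sign discontinuously - as in recorded traces,
    # the peak time is well defined at frame resolution
    p <- params@peakDff / (1 - exp(-dur / params@riseTau))
    rise <- times >= onset & times <= onset + dur
    post <- times > onset + dur
    r[rise] <- p * (1 - exp(-(times[rise] - onset) / params@riseTau))
    r[post] <- params@peakDff *
      exp(-(times[post] - onset - dur) / params@decayTau)
  } else if (compartment == "er") {
    if (params@peakDff > 0) {
      g <- function(t) .boxConvWave(t, onset, dur, params@riseTau,
                                    params@decayTau)
      pk <- stats::optimize(g, c(onset, onset + dur + 10 * params@decayTau),
                            maximum = TRUE, tol = 1e-10)$objective
      r <- params@peakDff * g(times) / pk
    }
    dt <- times - onset
    r <- r - params@dipAmp * ifelse(dt < 0, 0, exp(-dt / params@dipTau))
  } else { # mito
    if (params@peakDff == 0) return(r)
    p <- params@peakDff / (1 - exp(-dur / params@riseTau))
    plateau <- params@plateauFraction * params@peakDff
    rise <- times >= onset & times <= onset + dur
    post <- times > onset + dur
    r[rise] <- p * (1 - exp(-(times[rise] - onset) / params@riseTau))
    te <- times[post] - (onset + dur)
    r[post] <- plateau * exp(-te / params@slowTau) +
      (params@peakDff - plateau) * exp(-te / params@decayTau)
  }
  r
}

# Poisson miniature-event train; truncated-normal amplitudes (> 0)
.drawMinis <- function(rateHz, duration, ampMean, ampSd) {
  k <- stats::rpois(1, rateHz * duration)
  times <- sort(stats::runif(k, 0, duration))
  amps <- stats::rnorm(k, ampMean, ampSd)
  while (any(amps <= 0)) {
    bad <- amps <= 0
    amps[bad] <- stats::rnorm(sum(bad), ampMean, ampSd)
  }
  list(times = times, amps = amps)
}

# superpose mini waveforms (single-frame rise, exponential decay) on the
# frame grid
.miniSignal <- function(t, times, amps, decayTau) {
  m <- numeric(length(t))
  for (k in seq_along(times)) {
    on <- t >= times[k]
    m[on] <- m[on] + amps[k] * exp(-(t[on] - times[k]) / decayTau)
  }
  m
}

#' Simulate one fluorescence trace with known ground truth
#'
#' Forward model of a single-ROI recording:
#' \deqn{F_i = a (i + 1)^b [1 + s\, r(t_i) + \sum_k m_k(t_i)] + \epsilon_i}
#' with `a, b` the photobleach power curve over the 1-based frame index,
#' `s` the genotype scale, `r` the compartment's evoked kernel
#' ([evokedKernel()]), `m_k` Poisson miniature events (instantaneous rise,
#' exponential decay, truncated-normal amplitudes) and Gaussian (plus
#' optional Poisson shot) noise. The same config, including its seed,
#' always yields identical output.
#'
#' @param cfg a [SimConfig-class].
#' @return list with `trace` (a [CaTrace-class]) and `truth`
#'   (a [SimTruth-class] recording every drawn quantity).
#' @export
simulateTrace <- function(cfg) {
  validObject(cfg)
  n <- round(cfg@duration * cfg@frameRate)
  t <- (seq_len(n) - 1) / cfg@frameRate
  r <- evokedKernel(cfg@compartment, cfg@stim, cfg@kernel, t)
  withSeed(cfg@seed, {
    mn <- .drawMinis(cfg@mini$rateHz, cfg@duration, cfg@mini$ampMean,
                     cfg@mini$ampSd)
    clean <- cfg@genotypeScale * r +
      .miniSignal(t, mn$times, mn$amps, cfg@mini$decayTau)
    bleach <- cfg@bleach[1] * (seq_len(n))^cfg@bleach[2]
    f <- bleach * (1 + clean)
    if (isTRUE(cfg@noise$shotNoise))
      f <- stats::rpois(n, pmax(f, 0))
    if (cfg@noise$gaussianSd > 0)
      f <- f + stats::rnorm(n, 0, cfg@noise$gaussianSd)
  })
  trace <- CaTrace(f, cfg@frameRate, stim = cfg@stim,
                   meta = list(compartment = cfg@compartment,
                               genotype = if (cfg@genotypeScale == 1) "WT"
                                          else "mutant",
                               genotype_scale = cfg@genotypeScale))
  truth <- new("SimTruth", kernel = cfg@kernel,
               truePeakDff = cfg@genotypeScale * max(r),
               miniTimes = mn$times, miniAmps = mn$amps,
               bleachA = cfg@bleach[1], bleachB = cfg@bleach[2],
               cleanDff = clean)
  list(trace = trace, truth = truth)
}

# disc pixel set around a centre, clipped check done by caller
.discPixels <- function(center, radius, shape) {
  rr <- seq(max(1, floor(center[1] - radius)),
            min(shape[1], ceiling(center[1] + radius)))
  cc <- seq(max(1, floor(center[2] - radius)),
            min(shape[2], ceiling(center[2] + radius)))
  g <- expand.grid(row = rr, col = cc)
  d2 <- (g$row - center[1])^2 + (g$col - center[2])^2
  as.matrix(g[d2 <= radius^2, , drop = FALSE])
}

# shift a frame by integer (dy, dx), filling vacated pixels
.shiftFrame <- function(frame, dy, dx, fill) {
  out <- matrix(fill, nrow(frame), ncol(frame))
  h <- nrow(frame); w <- ncol(frame)
  srcR <- seq_len(h) - dy; srcC <- seq_len(w) - dx
  okR <- srcR >= 1 & srcR <= h; okC <- srcC >= 1 & srcC <= w
  out[okR, okC] <- frame[srcR[okR], srcC[okC]]
  out
}

#' Simulate a bouton movie with known ground truth
#'
#' Renders `geometry$nBoutons` boutons as 2-D Gaussian intensity spots
#' whose per-frame brightness follows independent [simulateTrace()] draws,
#' adds a flat background, applies optional integer-pixel whole-field
#' drift (`geometry$driftPxPerFrame`), and adds frame noise. Returned ROIs
#' mark each bouton (disc of `boutonRadius`) at its reference (frame 1)
#' position, plus one ROI covering the whole NMJ.
#'
#' @param cfg a [SimConfig-class].
#' @return list with `movie` ([CaMovie-class]), `rois` (list of
#'   [Roi-class], boutons then the NMJ union), `truth` ([SimTruth-class];
#'   `trueShifts()` holds the per-frame (dy, dx) ground truth), and
#'   `boutonTraces` (list of clean generating [CaTrace-class]s, one per
#'   bouton).
#' @export
simulateMovie <- function(cfg) {
  validObject(cfg)
  geom <- cfg@geometry
  shape <- as.integer(geom$imageShape)
  nb <- as.integer(geom$nBoutons)
  rad <- geom$boutonRadius
  n <- round(cfg@duration * cfg@frameRate)
  margin <- ceiling(3 * rad) + 1
  if (2 * margin >= min(shape))
    stop("bouton footprints do not fit inside the image")
  centers <- cbind(
    row = round(seq(margin, shape[1] - margin, length.out = max(nb, 2)))[seq_len(nb)],
    col = round(rep(shape[2] / 2, nb)))
  pkScale <- geom$boutonPeakScale %||% rep(1, nb)
  sims <- lapply(seq_len(nb), function(k) {
    ck <- cfg
    ck@seed <- as.integer(subSeed(cfg@seed, k) %% .Machine$integer.max)
    ck@noise$gaussianSd <- 0  # noise is added at the frame level
    ck@noise$shotNoise <- FALSE
    ck@kernel@peakDff <- cfg@kernel@peakDff * pkScale[k]
    simulateTrace(ck)
  })
  sigma <- rad / 2
  profiles <- lapply(seq_len(nb), function(k) {
    if (any(centers[k, ] - 3 * rad < 1) ||
        centers[k, 1] + 3 * rad > shape[1] ||
        centers[k, 2] + 3 * rad > shape[2])
      stop("bouton footprints must lie inside the image bounds")
    px <- .discPixels(centers[k, ], 3 * rad, shape)
    w <- exp(-((px[, 1] - centers[k, 1])^2 +
               (px[, 2] - centers[k, 2])^2) / (2 * sigma^2))
    list(px = px, w = w)
  })
  drift <- geom$driftPxPerFrame
  shifts <- cbind(dy = round((seq_len(n) - 1) * drift[1]),
                  dx = round((seq_len(n) - 1) * drift[2]))
  base <- matrix(geom$background, shape[1], shape[2])
  dat <- array(0, dim = c(n, shape[1], shape[2]))
  for (i in seq_len(n)) {
    fr <- base
    for (k in seq_len(nb)) {
      p <- profiles[[k]]
      fr[p$px] <- fr[p$px] + traceValues(sims[[k]]$trace)[i] * p$w
    }
    if (shifts[i, 1] != 0 || shifts[i, 2] != 0)
      fr <- .shiftFrame(fr, shifts[i, 1], shifts[i, 2], geom$background)
    dat[i, , ] <- fr
  }
  if (cfg@noise$gaussianSd > 0)
    dat <- dat + withSeed(subSeed(cfg@seed, 997),
                          stats::rnorm(length(dat), 0, cfg@noise$gaussianSd))
  rois <- lapply(seq_len(nb), function(k)
    Roi(.discPixels(centers[k, ], rad, shape),
        id = paste0("bouton", k), kind = "bouton"))
  allPx <- unique(do.call(rbind, lapply(rois, roiMask)))
  rois <- c(rois, list(Roi(allPx, id = "nmj", kind = "nmj")))
  truth <- sims[[1]]$truth
  truth@shifts <- shifts
  truth@boutonCenters <- centers
  list(movie = CaMovie(dat, cfg@frameRate, cfg@compartment),
       rois = rois, truth = truth,
       boutonTraces = lapply(sims, `[[`, "trace"))
}

#' Simulate a static two-channel confocal image pair
#'
#' Channel 1 (marker) is a dim ER-tubule field filling an elliptical NMJ
#' mask, plus bright puncta rendered as sharp-edged discs at known
#' positions (sharp edges keep ground-truth pixel membership unambiguous).
#' Channel 2 (reference) is uniform inside the NMJ mask, emulating a
#' plasma-membrane marker. The returned truth mask records exactly the
#' puncta pixels.
#'
#' @param cfg a [SimConfig-class] (its `geometry$imageShape` and seed are
#'   used).
#' @param nPuncta number of puncta (0 allowed).
#' @param punctaAmp absolute puncta intensity (a.u.), independent of the
#'   tubule level.
#' @param tubuleLevel mean marker intensity of the non-puncta NMJ (a.u.).
#' @param tubuleSd Gaussian variation of the tubule field (a.u.).
#' @param punctaRadius puncta disc radius (px).
#' @param referenceLevel uniform reference-channel intensity inside the
#'   mask (a.u.).
#' @return list with matrices `marker` and `reference`, logical matrices
#'   `nmjMask` and `punctaTruth`, and `punctaCenters`.
#' @export
simulateStaticPair <- function(cfg, nPuncta = 5, punctaAmp = 200,
                               tubuleLevel = 10, tubuleSd = 1,
                               punctaRadius = 2, referenceLevel = 100) {
  validObject(cfg)
  shape <- as.integer(cfg@geometry$imageShape)
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  cy <- (shape[1] + 1) / 2; cx <- (shape[2] + 1) / 2
  nmj <- ((rows - cy) / (0.38 * shape[1]))^2 +
    ((cols - cx) / (0.45 * shape[2]))^2 <= 1
  marker <- matrix(0, shape[1], shape[2])
  punctaTruth <- matrix(FALSE, shape[1], shape[2])
  centers <- matrix(numeric(), 0, 2)
  withSeed(subSeed(cfg@seed, 31), {
    marker[nmj] <- pmax(tubuleLevel + stats::rnorm(sum(nmj), 0, tubuleSd), 0)
    if (nPuncta > 0) {
      inside <- which(nmj &
        ((rows - cy) / (0.30 * shape[1]))^2 +
        ((cols - cx) / (0.38 * shape[2]))^2 <= 1)
      pick <- sample(inside, nPuncta)
      centers <- cbind(row = rows[pick], col = cols[pick])
      for (k in seq_len(nPuncta)) {
        px <- .discPixels(centers[k, ], punctaRadius, shape)
        marker[px] <- punctaAmp  # puncta level independent of the tubules
        punctaTruth[px] <- TRUE
      }
    }
  })
  punctaTruth <- punctaTruth & nmj
  reference <- matrix(0, shape[1], shape[2])
  reference[nmj] <- referenceLevel
  list(marker = marker, reference = reference, nmjMask = nmj,
       punctaTruth = punctaTruth, punctaCenters = centers)
}

#' Simulate a two-genotype cohort of evoked responses through the pipeline
#'
#' Generates per-larva maximum dF/F datapoints by simulating one noisy
#' trace per larva and stimulation frequency and running the full analysis
#' (bleach fit and correction, 5-frame rolling average, dF/F, evoked
#' features). Peak amplitudes follow a saturating frequency response
#' `f / (f + f50)` and a lognormal per-larva random effect, so the output
#' has the nested genotype x frequency x larva structure the statistics
#' stage expects.
#'
#' @param nLarvae larvae per genotype.
#' @param genotypeScales named vector of evoked-amplitude multipliers.
#' @param frequencies stimulation frequencies (Hz) as the within-subject
#'   factor.
#' @param compartment compartment preset for [simConfig()].
#' @param noiseSd Gaussian noise (a.u.; default 2% of the baseline a).
#' @param larvaSd SD of the lognormal per-larva amplitude effect.
#' @param f50 half-saturation frequency (Hz) of the peak response.
#' @param batchGains optional named vector of multiplicative setup gains;
#'   larvae are split across batches.
#' @param seed integer seed.
#' @return data.frame with columns `larva_id`, `genotype`, `frequency`,
#'   `batch_id`, `max_dff`.
#' @export
simulateCohort <- function(nLarvae = 10,
                           genotypeScales = c(WT = 1, mutant = 0.5),
                           frequencies = c(10, 20, 40, 80),
                           compartment = "cytosol", noiseSd = 20,
                           larvaSd = 0.1, f50 = 20,
                           batchGains = c(setup1 = 1), seed = 1L) {
  rows <- list()
  gi <- 0L
  for (g in names(genotypeScales)) {
    gi <- gi + 1L
    for (l in seq_len(nLarvae)) {
      larva <- sprintf("%s_L%02d", g, l)
      batch <- names(batchGains)[1 + (l - 1) %% length(batchGains)]
      eff <- withSeed(subSeed(seed, gi * 1000L + l),
                      exp(stats::rnorm(1, 0, larvaSd)))
      for (f in frequencies) {
        cfg <- simConfig(compartment,
                         genotypeScale = genotypeScales[[g]],
                         duration = 15, stim = c(5, 2, f),
                         noise = list(gaussianSd = noiseSd),
                         seed = subSeed(seed, gi * 100000L + l * 100L + f))
        cfg@kernel@peakDff <- cfg@kernel@peakDff * eff * f / (f + f50)
        tr <- simulateTrace(cfg)$trace
        tr@values <- tr@values * batchGains[[batch]]
        feats <- analyzeTrace(tr)$features
        rows[[length(rows) + 1L]] <- data.frame(
          larva_id = larva, genotype = g, frequency = f,
          batch_id = batch, max_dff = feats@maxDff)
      }
    }
  }
  do.call(rbind, rows)
}
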