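#' @import methods
NULL

#' Single-ROI fluorescence time series
#'
#' `CaTrace` is the pipeline's central currency: the average fluorescence of
#' one ROI over time, together with the frame rate, an optional stimulation
#' window and free-form metadata (genotype, compartment, larva/NMJ ids).
#'
#' @slot values numeric vector of fluorescence values (a.u. for raw traces,
#'   dimensionless after bleach correction, dF/F units after [dff()]).
#' @slot frameRate frames per second (> 0).
#' @slot stim numeric of length 3, `c(onset_s, duration_s, frequency_hz)`,
#'   or length 0 when the recording is unstimulated.
#' @slot meta named list; recognised entries include `genotype`,
#'   `compartment`, `larva_id`, `nmj_id`, `batch_id`, `roi_id`, `units`.
#' @exportClass CaTrace
setClass("CaTrace",
  representation(values = "numeric", frameRate = "numeric",
                 stim = "numeric", meta = "list"),
  prototype(values = numeric(), frameRate = 1, stim = numeric(),
            meta = list()))

setValidity("CaTrace", function(object) {
  msg <- character()
  if (length(object@values) < 2L)
    msg <- c(msg, "trace must have at least 2 frames")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "trace values must be finite")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (length(object@stim) > 0L) {
    if (length(object@stim) != 3L)
      msg <- c(msg, "stim must be c(onset_s, duration_s, frequency_hz)")
    else {
      dur <- length(object@values) / object@frameRate
      if (object@stim[1] < 0 || object@stim[1] + object@stim[2] > dur)
        msg <- c(msg, "stim window must lie inside the recording")
      if (object@stim[3] < 0)
        msg <- c(msg, "stim frequency must be >= 0")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Fitted power-law photobleach model
#'
#' Holds the coefficients of the bleach-correction power curve
#' \eqn{PC(x) = a x^b} fitted to pre-stimulation fluorescence, the frame
#' window used for the fit and the domain origin (`xOffset`, so that
#' \eqn{x = i + xOffset} with `i` the 0-based frame index; the default
#' offset 1 keeps \eqn{x^b} defined at the first frame).
#'
#' @slot a positive scale (a.u.).
#' @slot b dimensionless exponent (typically <= 0 for bleaching).
#' @slot fitWindow integer of length 2, first and last 0-based frame index
#'   of the fitted pre-stimulation window.
#' @slot xOffset domain origin added to the 0-based frame index.
#' @exportClass BleachModel
setClass("BleachModel",
  representation(a = "numeric", b = "numeric", fitWindow = "integer",
                 xOffset = "numeric"),
  prototype(a = 1, b = 0, fitWindow = c(0L, 2L), xOffset = 1))

setValidity("BleachModel", function(object) {
  msg <- character()
  if (length(object@a) != 1L || !is.finite(object@a) || object@a <= 0)
    msg <- c(msg, "a must be a single positive number")
  if (length(object@b) != 1L || !is.finite(object@b))
    msg <- c(msg, "b must be a single finite number")
  if (length(object@fitWindow) != 2L ||
      diff(object@fitWindow) + 1L < 3L)
    msg <- c(msg, "fit window must span at least 3 frames")
  if (length(msg)) msg else TRUE
})

#' Scalar readouts of an evoked response
#'
#' The features extracted from one stimulated recording: resting
#' fluorescence (the fitted bleach curve evaluated immediately before
#' stimulation), maximum raw fluorescence, their difference (dF), the dF/F
#' extrema after stimulation onset, and the kinetic times (time to peak,
#' time from peak to 50% and to 100% recovery; the latter is `NA` when the
#' trace never returns to within the pre-stimulation noise band).
#'
#' @slot restingF,maxF,deltaF a.u.
#' @slot maxDff,minDffPostStim dF/F units.
#' @slot timeToPeak,t50Recovery,t100Recovery seconds; `t100Recovery` may be
#'   `NA`.
#' @exportClass EvokedFeatures
setClass("EvokedFeatures",
  representation(restingF = "numeric", maxF = "numeric", deltaF = "numeric",
                 maxDff = "numeric", minDffPostStim = "numeric",
                 timeToPeak = "numeric", t50Recovery = "numeric",
                 t100Recovery = "numeric"))

setValidity("EvokedFeatures", function(object) {
  msg <- character()
  if (is.finite(object@timeToPeak) && object@timeToPeak < 0)
    msg <- c(msg, "timeToPeak must be >= 0")
  if (is.finite(object@t50Recovery) && is.finite(object@t100Recovery) &&
      object@t50Recovery > object@t100Recovery)
    msg <- c(msg, "t50Recovery must be <= t100Recovery when both defined")
  if (abs(object@deltaF - (object@maxF - object@restingF)) >
      1e-8 * max(1, abs(object@maxF)))
    msg <- c(msg, "deltaF must equal maxF - restingF")
  if (length(msg)) msg else TRUE
})

#' Fluorescence movie (time x height x width)
#'
#' @slot data numeric array `T x H x W` of non-negative intensities (a.u.).
#' @slot frameRate frames per second.
#' @slot channelLabel character label for the imaged channel.
#' @exportClass CaMovie
setClass("CaMovie",
  representation(data = "array", frameRate = "numeric",
                 channelLabel = "character"),
  prototype(frameRate = 1, channelLabel = ""))

setValidity("CaMovie", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "movie data must be a T x H x W array")
  else if (dim(object@data)[1] < 1L)
    msg <- c(msg, "movie must contain at least one frame")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "movie values must be finite")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Region of interest
#'
#' A set of pixels, labelled by what the region outlines: the whole NMJ, a
#' bouton, a mitochondrion, a puncta region or background.
#'
#' @slot id character identifier.
#' @slot kind one of `"nmj"`, `"bouton"`, `"mitochondrion"`, `"puncta"`,
#'   `"background"`.
#' @slot mask integer matrix with columns `row`, `col` (1-based pixel
#'   coordinates).
#' @exportClass Roi
setClass("Roi",
  representation(id = "character", kind = "character", mask = "matrix"))

.roiKinds <- c("nmj", "bouton", "mitochondrion", "puncta", "background")

setValidity("Roi", function(object) {
  msg <- character()
  if (!object@kind %in% .roiKinds)
    msg <- c(msg, paste0("kind must be one of: ",
                         paste(.roiKinds, collapse = ", ")))
  if (nrow(object@mask) < 1L || ncol(object@mask) != 2L)
    msg <- c(msg, "mask must be a non-empty n x 2 matrix of (row, col)")
  if (any(object@mask < 1L))
    msg <- c(msg, "mask pixels must be 1-based positive coordinates")
  if (length(msg)) msg else TRUE
})

#' Waveform parameters for the evoked-response kernels
#'
#' @slot riseTau,decayTau seconds; fast rise/decay constants of the
#'   stimulus-driven component.
#' @slot peakDff peak amplitude in dF/F units (the positive component; for
#'   the ER kernel this is the slow uptake overshoot).
#' @slot dipAmp,dipTau ER only: amplitude (dF/F, >= 0) and decay (s) of the
#'   transient release dip at stimulation onset.
#' @slot plateauFraction,slowTau mito only: fraction of the peak retained
#'   after the fast partial decline, and the slow (> 40 s class) return
#'   time constant in seconds.
#' @exportClass KernelParams
setClass("KernelParams",
  representation(riseTau = "numeric", decayTau = "numeric",
                 peakDff = "numeric", dipAmp = "numeric", dipTau = "numeric",
                 plateauFraction = "numeric", slowTau = "numeric"),
  prototype(riseTau = 0.25, decayTau = 2, peakDff = 1.5, dipAmp = 0,
            dipTau = 1, plateauFraction = 0, slowTau = 45))

setValidity("KernelParams", function(object) {
  msg <- character()
  taus <- c(object@riseTau, object@decayTau, object@dipTau, object@slowTau)
  if (any(!is.finite(taus)) || any(taus <= 0))
    msg <- c(msg, "all time constants must be positive")
  if (object@peakDff < 0) msg <- c(msg, "peakDff must be >= 0")
  if (object@dipAmp < 0) msg <- c(msg, "dipAmp must be >= 0")
  if (object@plateauFraction < 0 || object@plateauFraction > 1)
    msg <- c(msg, "plateauFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Configuration of a synthetic recording
#'
#' Defines one simulated recording: the compartment whose kinetics to
#' emulate, the multiplier applied to evoked amplitudes (1 for wild type,
#' 0.5 for the default mutant preset), acquisition parameters, the
#' photobleach curve, noise, miniature-event statistics and (for movies)
#' the bouton geometry. Use [simConfig()] to build one with
#' compartment-appropriate defaults.
#'
#' @exportClass SimConfig
setClass("SimConfig",
  representation(compartment = "character", genotypeScale = "numeric",
                 frameRate = "numeric", duration = "numeric",
                 stim = "numeric", kernel = "KernelParams",
                 bleach = "numeric", noise = "list", mini = "list",
                 geometry = "list", seed = "integer"))

.compartments <- c("cytosol", "er", "mito", "postsynaptic")

setValidity("SimConfig", function(object) {
  msg <- character()
  if (!object@compartment %in% .compartments)
    msg <- c(msg, paste0("compartment must be one of: ",
                         paste(.compartments, collapse = ", ")))
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (length(object@stim) != 3L)
    msg <- c(msg, "stim must be c(onset_s, duration_s, frequency_hz)")
  else if (object@stim[1] < 0 ||
           object@stim[1] + object@stim[2] > object@duration)
    msg <- c(msg, "stim window must lie inside [0, duration]")
  if (length(object@bleach) != 2L || object@bleach[1] <= 0)
    msg <- c(msg, "bleach must be c(a, b) with a > 0")
  if (object@mini$rateHz < 0) msg <- c(msg, "mini rate must be >= 0")
  if (!all(is.finite(c(object@mini$ampMean, object@mini$ampSd))))
    msg <- c(msg, "mini amplitudes must be finite")
  if (object@geometry$nBoutons < 1L)
    msg <- c(msg, "geometry must place at least one bouton")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic recording
#'
#' Records every drawn quantity of a simulation so recovery tests can score
#' the analysis against it: the kernel and the realized evoked peak
#' (genotype scale already applied), miniature event times and amplitudes,
#' the bleach coefficients, per-frame drift shifts and bouton centres, and
#' the clean (noise-free, bleach-free) dF/F signal.
#'
#' @exportClass SimTruth
setClass("SimTruth",
  representation(kernel = "KernelParams", truePeakDff = "numeric",
                 miniTimes = "numeric", miniAmps = "numeric",
                 bleachA = "numeric", bleachB = "numeric",
                 shifts = "matrix", boutonCenters = "matrix",
                 cleanDff = "numeric"),
  prototype(shifts = matrix(numeric(), 0, 2),
            boutonCenters = matrix(numeric(), 0, 2)))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (is.unsorted(object@miniTimes))
    msg <- c(msg, "miniTimes must be sorted ascending")
  if (length(object@miniTimes) != length(object@miniAmps))
    msg <- c(msg, "miniTimes and miniAmps must have equal length")
  if (any(object@miniTimes < 0))
    msg <- c(msg, "miniTimes must be >= 0")
  if (length(msg)) msg else TRUE
})
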