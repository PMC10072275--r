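#' Fit the photobleach power curve to pre-stimulation fluorescence
#'
#' Fits \eqn{PC(x) = a x^b}, with \eqn{x = i + xOffset} over the 0-based
#' frame index, to the pre-stimulation frames by ordinary least squares on
#' \eqn{\log F} versus \eqn{\log x}. The closed-form log-log fit is exact
#' on a noiseless power law and fully deterministic.
#'
#' @param trace a [CaTrace-class] of raw fluorescence.
#' @param prestimEndFrame number of pre-stimulation frames to fit (the fit
#'   window is frames `0 .. prestimEndFrame - 1`, 0-based). Defaults to
#'   the last frame before the trace's stimulation onset.
#' @param xOffset domain origin; default 1 (1-based frame index), so the
#'   curve is defined at the first frame.
#' @return a [BleachModel-class].
#' @examples
#' tr <- CaTrace(1000 * (1:200)^-0.05, frameRate = 10, stim = c(5, 2, 40))
#' fitBleach(tr)
#' @export
fitBleach <- function(trace, prestimEndFrame = NULL, xOffset = 1) {
  stopifnot(is(trace, "CaTrace"))
  if (is.null(prestimEndFrame)) {
    if (!length(trace@stim))
      stop("prestimEndFrame is required when the trace has no stim metadata")
    prestimEndFrame <- floor(trace@stim[1] * trace@frameRate)
  }
  if (prestimEndFrame < 3)
    stop("need at least 3 pre-stimulation frames to fit the bleach curve")
  f <- trace@values[seq_len(prestimEndFrame)]
  if (any(f <= 0))
    stop("pre-stimulation fluorescence must be positive (log undefined)")
  x <- seq_len(prestimEndFrame) - 1 + xOffset
  fit <- stats::lm.fit(cbind(1, log(x)), log(f))
  new("BleachModel", a = exp(unname(fit$coefficients[1])),
      b = unname(fit$coefficients[2]),
      fitWindow = c(0L, as.integer(prestimEndFrame) - 1L),
      xOffset = xOffset)
}

#' Divide a trace by its fitted bleach curve
#'
#' Divides raw fluorescence over the entire time course by the fitted
#' power curve, yielding a dimensionless trace with baseline ~ 1.
#'
#' @param trace a raw [CaTrace-class].
#' @param model a [BleachModel-class] from [fitBleach()].
#' @return a corrected [CaTrace-class] (meta gains `units = "corrected"`).
#' @export
correctBleach <- function(trace, model) {
  stopifnot(is(trace, "CaTrace"), is(model, "BleachModel"))
  pc <- predictBleach(model, seq_along(trace@values) - 1)
  if (any(pc <= 0))
    stop("fitted bleach curve is non-positive over the trace domain")
  out <- trace
  out@values <- trace@values / pc
  out@meta$units <- "corrected"
  out
}

#' Centered rolling average
#'
#' Centered moving mean with an odd window; at the edges the window
#' shrinks symmetrically so no padding values are invented.
#'
#' @param trace a [CaTrace-class] (or bare numeric vector).
#' @param windowFrames odd window length in frames; default 5.
#' @return same type as the input, smoothed.
#' @export
rollingAverage <- function(trace, windowFrames = 5L) {
  if (windowFrames < 1 || windowFrames %% 2 == 0)
    stop("window must be an odd positive number of frames")
  v <- if (is(trace, "CaTrace")) trace@values else trace
  n <- length(v)
  half <- (windowFrames - 1) %/% 2
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  k <- pmin(half, i - 1L, n - i)
  sm <- (cs[i + k + 1] - cs[i - k]) / (2 * k + 1)
  if (is(trace, "CaTrace")) { trace@values <- sm; trace } else sm
}

#' dF/F from a bleach-corrected trace
#'
#' With the baseline divided out (so corrected baseline ~ 1), the
#' fractional fluorescence change is simply `corrected - 1`.
#'
#' @param corrected a bleach-corrected [CaTrace-class].
#' @return a [CaTrace-class] in dF/F units.
#' @export
dff <- function(corrected) {
  stopifnot(is(corrected, "CaTrace"))
  out <- corrected
  out@values <- corrected@values - 1
  out@meta$units <- "dff"
  out
}

#' Extract evoked-response features
#'
#' Computes the scalar readouts of one stimulated recording:
#' \itemize{
#'   \item `restingF` - the fitted power curve evaluated at the last
#'     pre-stimulation frame (immediate pre-stimulation value);
#'   \item `maxF` - maximum raw fluorescence; `deltaF = maxF - restingF`;
#'   \item `maxDff` - maximum dF/F at/after stimulation onset;
#'   \item `minDffPostStim` - minimum dF/F in a fixed window after onset
#'     (default onset to onset + 2 s; the ER release dip);
#'   \item `timeToPeak` - seconds from onset to the dF/F peak;
#'   \item `t50Recovery` - seconds from the peak to the first sample at or
#'     below half the peak;
#'   \item `t100Recovery` - seconds from the peak to the first sample back
#'     within `noiseBandK` pre-stimulation SDs of baseline (`NA` if never
#'     reached within the recording).
#' }
#'
#' @param raw the raw [CaTrace-class] (for `maxF`).
#' @param model the [BleachModel-class] (for `restingF`).
#' @param dffTrace the (smoothed) dF/F [CaTrace-class]; must carry stim
#'   metadata.
#' @param noiseBandK multiplier on the pre-stimulation dF/F SD defining
#'   the 100%-recovery band; default 1.
#' @param minDffWindow seconds after onset searched for the minimum.
#' @return an [EvokedFeatures-class].
#' @export
evokedFeatures <- function(raw, model, dffTrace, noiseBandK = 1,
                           minDffWindow = 2) {
  stopifnot(is(raw, "CaTrace"), is(model, "BleachModel"),
            is(dffTrace, "CaTrace"))
  if (!length(dffTrace@stim))
    stop("stim metadata is required to extract evoked features")
  fr <- dffTrace@frameRate
  onset <- dffTrace@stim[1]
  onsetIdx <- floor(onset * fr) + 1L  # first frame at/after onset
  v <- dffTrace@values
  n <- length(v)
  t <- traceTimes(dffTrace)

  restingF <- predictBleach(model, onsetIdx - 2L)  # last pre-stim frame
  maxF <- max(raw@values)

  post <- onsetIdx:n
  peakIdx <- post[which.max(v[post])]
  maxDff <- v[peakIdx]
  winEnd <- min(n, floor((onset + minDffWindow) * fr) + 1L)
  minDff <- min(v[onsetIdx:winEnd])
  timeToPeak <- t[peakIdx] - onset

  after <- if (peakIdx < n) (peakIdx + 1L):n else integer()
  half <- after[v[after] <= maxDff / 2]
  t50 <- if (length(half)) t[half[1]] - t[peakIdx] else NA_real_
  sigma0 <- stats::sd(v[seq_len(max(onsetIdx - 1L, 2L))])
  band <- after[v[after] <= noiseBandK * sigma0]
  t100 <- if (length(band)) t[band[1]] - t[peakIdx] else NA_real_
  if (!is.na(t50) && !is.na(t100) && t100 < t50) t50 <- t100

  new("EvokedFeatures", restingF = restingF, maxF = maxF,
      deltaF = maxF - restingF, maxDff = maxDff, minDffPostStim = minDff,
      timeToPeak = timeToPeak, t50Recovery = t50, t100Recovery = t100)
}

#' Run the standard trace pipeline on one raw trace
#'
#' Convenience wrapper chaining [fitBleach()], [correctBleach()],
#' [rollingAverage()] (5 frames), [dff()] and [evokedFeatures()].
#'
#' @param trace raw [CaTrace-class] with stim metadata.
#' @param prestimEndFrame,smoothWindow,noiseBandK,minDffWindow passed on.
#' @return list with `model`, `corrected`, `dffTrace`, `features`.
#' @export
analyzeTrace <- function(trace, prestimEndFrame = NULL, smoothWindow = 5L,
                         noiseBandK = 1, minDffWindow = 2) {
  model <- fitBleach(trace, prestimEndFrame)
  corrected <- correctBleach(trace, model)
  smoothed <- rollingAverage(corrected, smoothWindow)
  d <- dff(smoothed)
  feats <- evokedFeatures(trace, model, d, noiseBandK = noiseBandK,
                          minDffWindow = minDffWindow)
  list(model = model, corrected = corrected, dffTrace = d,
       features = feats)
}

#' Normalize feature values to a control-group mean
#'
#' Divides every value by the mean of the control group, so the control
#' mean maps to 1 and other groups are expressed in control units.
#'
#' @param values numeric feature values (one per larva).
#' @param groups group labels, same length.
#' @param controlLabel label of the control group.
#' @return numeric vector of normalized values.
#' @export
normalizeToControl <- function(values, groups, controlLabel = "WT") {
  ctrl <- values[groups == controlLabel]
  if (!length(ctrl)) stop("control group '", controlLabel, "' is empty")
  m <- mean(ctrl)
  if (!is.finite(m) || m <= 0)
    stop("control-group mean must be positive for normalization")
  values / m
}

#' Normalize a pair of mean time courses to the control range
#'
#' Scales both traces by the single factor
#' `100 / (max(control) - min(control))`, so the control trace's
#' max-minus-min equals exactly 100 and the other trace is expressed on
#' the same scale.
#'
#' @param wtMean,otherMean mean dF/F [CaTrace-class]s (or numeric).
#' @return list of the two scaled traces, plus the `scale` used.
#' @export
normalizeTimecoursePair <- function(wtMean, otherMean) {
  wv <- if (is(wtMean, "CaTrace")) wtMean@values else wtMean
  rng <- max(wv) - min(wv)
  if (rng <= 0) stop("control trace is flat; range normalization undefined")
  sc <- 100 / rng
  scaleBy <- function(x) {
    if (is(x, "CaTrace")) { x@values <- x@values * sc; x } else x * sc
  }
  list(wt = scaleBy(wtMean), other = scaleBy(otherMean), scale = sc)
}

#' Normalize across acquisition batches via each batch's control mean
#'
#' Within each batch, divides all values by that batch's control-group
#' mean, removing multiplicative setup differences (e.g. two microscope
#' gains) so batches can be pooled.
#'
#' @param values numeric feature values.
#' @param groups genotype labels.
#' @param batches batch labels.
#' @param controlLabel control genotype present in every batch.
#' @return numeric vector of normalized values.
#' @export
batchNormalize <- function(values, groups, batches, controlLabel = "WT") {
  out <- numeric(length(values))
  for (b in unique(batches)) {
    sel <- batches == b
    ctrl <- values[sel & groups == controlLabel]
    if (!length(ctrl))
      stop("batch '", b, "' has no '", controlLabel, "' datapoints")
    out[sel] <- values[sel] / mean(ctrl)
  }
  out
}
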