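#' Detect miniature (spontaneous) transients in a resting dF/F trace
#'
#' Candidate events are local maxima of the median-centred dF/F trace
#' exceeding `thresholdSigma` times a robust noise SD. The noise SD is
#' the smaller of a lower-tail MAD (minis are positive-going, so negative
#' excursions stay event-free at moderate rates) and a first-difference
#' MAD (event rises and decays occupy few difference frames even when
#' events blanket the trace), so the estimate resists contamination by
#' the events themselves across event rates. Several checks
#' separate events from noise while keeping close pairs apart:
#' \itemize{
#'   \item baseline amplitude - the peak must clear the threshold
#'     measured against a median local baseline taken just before its
#'     rise. A genuine event adds its full amplitude on top of whatever
#'     level the trace sat at (so events riding a larger event's decay
#'     tail still pass), while noise ripples born of a brief dip do not,
#'     because the median baseline is robust to the dip;
#'   \item sharp rise - the trace must climb at least the threshold
#'     within two frames going into the event: minis rise much faster
#'     than they decay, noise ripples and slow drifts do not;
#'   \item smoothed corroboration - a centred rolling average of
#'     `smoothWindow` frames must also cross threshold at its own scale
#'     near the peak, which rejects single-sample noise spikes (real
#'     events persist for several frames);
#'   \item separation - peaks closer than `minSeparation` are merged
#'     unless the trace dips between them by at least half the
#'     threshold or a fresh full-threshold one-frame rise (the later
#'     event's own onset) lies between them, so the separation acts as
#'     a duplicate guard rather than a hard dead time.
#' }
#' Each accepted event is finally located at the steepest-rise frame of
#' the raw trace nearby (the rise is far sharper than frame-to-frame
#' noise, pinning the event time at the sampling resolution) and its
#' amplitude read from the raw trace. Median-centring makes detection
#' invariant to adding a constant; positive scaling scales amplitudes and
#' leaves event times unchanged.
#'
#' @param dffTrace a resting (unstimulated) [CaTrace-class] in dF/F units.
#' @param thresholdSigma detection threshold in robust SDs; default 3.
#' @param minSeparation minimum separation between events, seconds.
#' @param smoothWindow odd number of frames of the corroboration
#'   smoothing; 1 disables that check.
#' @return data.frame with columns `time_s`, `amplitude_dff`, `frame`,
#'   `roi_id` (one row per event, ordered by time; zero rows when none).
#' @export
detectMinis <- function(dffTrace, thresholdSigma = 3, minSeparation = 0.2,
                        smoothWindow = 5L) {
  stopifnot(is(dffTrace, "CaTrace"))
  fr <- dffTrace@frameRate
  raw <- dffTrace@values - stats::median(dffTrace@values)
  n <- length(raw)
  if (n / fr < 1) stop("analysis window must be at least 1 s")
  # robust noise SD: the smaller of the lower-tail MAD (negative
  # excursions are event-free at moderate rates) and a first-difference
  # estimate (events occupy few difference frames even at high rates)
  lowerTailSd <- function(x) 1.4826 * stats::median(-x[x <= 0])
  sigma <- min(lowerTailSd(raw), stats::mad(diff(raw)) / sqrt(2))
  if (!is.finite(sigma)) sigma <- 0
  sm <- rollingAverage(dffTrace@values, smoothWindow)
  sm <- sm - stats::median(sm)
  sigmaSm <- sigma / sqrt(smoothWindow)
  # floor at 1e-11 dF/F: double-precision residue of the bleach division
  # can leave ~1e-15-scale ripples on an otherwise noise-free trace
  if (sigma < 1e-11) sigma <- 0
  thr <- if (sigma > 0) thresholdSigma * sigma else 1e-11
  thrSm <- if (sigmaSm > 0) thresholdSigma * sigmaSm else 1e-11
  roi <- dffTrace@meta$roi_id %||% "roi"
  empty <- data.frame(time_s = numeric(), amplitude_dff = numeric(),
                      frame = integer(), roi_id = character())
  isMax <- c(FALSE, raw[2:(n - 1)] > raw[1:(n - 2)] &
                    raw[2:(n - 1)] >= raw[3:n], FALSE)
  cand <- which(isMax & raw > thr)
  if (!length(cand)) return(empty)
  # smoothed corroboration near the peak
  half <- (smoothWindow - 1L) %/% 2L
  cand <- cand[vapply(cand, function(i)
    max(sm[max(1L, i - half - 1L):min(n, i + half + 1L)]) >= thrSm,
    logical(1))]
  if (!length(cand)) return(empty)
  cand <- cand[order(raw[cand], decreasing = TRUE)]
  minGap <- minSeparation * fr
  keep <- integer()
  for (i in cand) {
    near <- keep[abs(keep - i) < minGap]
    resolved <- !length(near) || all(vapply(near, function(j) {
      rng <- min(i, j):max(i, j)
      valley <- min(raw[rng])
      # separate events either dip between their peaks or show a fresh
      # full-threshold one-frame rise (the later event's own onset)
      raw[i] - valley >= thr / 2 ||
        (length(rng) > 1 && max(diff(raw[rng])) >= thr)
    }, logical(1)))
    if (resolved) keep <- c(keep, i)
  }
  # pin each event to the steepest-rise frame of the raw trace nearby
  # (never searching past the midpoint to a neighbouring event), then
  # apply the two shape requirements: the amplitude above a median local
  # baseline taken just before the rise must clear the threshold (a
  # genuine event adds its full amplitude on top of whatever level the
  # trace sat at; a noise ripple born of a dip does not, because the
  # median baseline is robust to the dip), and the rise itself must be
  # fast (at least half the threshold within two frames)
  keep <- sort(keep)
  orig <- keep
  amp <- numeric(length(keep))
  sharp <- logical(length(keep))
  baseW <- 5L
  for (k in seq_along(keep)) {
    i <- orig[k]
    lo <- max(2L, i - smoothWindow); hi <- min(n, i + 1L)
    if (k > 1L) lo <- max(lo, (orig[k - 1L] + i) %/% 2L + 1L)
    if (lo > hi) { lo <- hi <- i }
    j <- (lo:hi)[which.max(raw[lo:hi] - raw[(lo:hi) - 1L])]
    keep[k] <- j
    base <- stats::median(raw[max(1L, j - baseW):max(1L, j - 1L)])
    amp[k] <- raw[i] - base
    rise <- max(raw[j] - raw[j - 1L], raw[j] - raw[max(1L, j - 2L)])
    sharp[k] <- amp[k] >= thr && rise >= thr
  }
  keep <- keep[sharp]; amp <- amp[sharp]
  if (!length(keep)) return(empty)
  ord <- order(keep)
  keep <- keep[ord]; amp <- amp[ord]
  dup <- duplicated(keep)
  keep <- keep[!dup]; amp <- amp[!dup]
  data.frame(time_s = (keep - 1) / fr, amplitude_dff = amp,
             frame = keep, roi_id = roi)
}

#' Miniature-event frequency
#'
#' Number of events per second over the scoring window (the study scores
#' minis per second over a 5-s recording; counting used a 20-s interval).
#'
#' @param events data.frame from [detectMinis()] (or anything with a row
#'   per event).
#' @param windowS scoring window in seconds (> 0).
#' @return events per second.
#' @export
miniFrequency <- function(events, windowS = 5) {
  if (windowS <= 0) stop("window must be positive")
  nrow(events) / windowS
}

#' Maximum miniature amplitude over a window
#'
#' The maximum dF/F value reached within the first `windowS` seconds of
#' the trace (default 20 s, the study's counting interval).
#'
#' @param dffTrace a resting [CaTrace-class] in dF/F units.
#' @param windowS window length, seconds.
#' @return maximum dF/F within the window.
#' @export
maxMiniAmplitude <- function(dffTrace, windowS = 20) {
  stopifnot(is(dffTrace, "CaTrace"))
  nWin <- min(length(dffTrace@values),
              floor(windowS * dffTrace@frameRate))
  if (nWin < 1) stop("window does not cover any frame")
  max(dffTrace@values[seq_len(nWin)])
}

#' Match detected events to ground-truth event times
#'
#' Greedy one-to-one matching within a frame tolerance; the validation
#' harness for the detector.
#'
#' @param detected data.frame from [detectMinis()].
#' @param truthTimes ground-truth event times, seconds.
#' @param frameRate frames per second.
#' @param tolFrames matching tolerance in frames (default 1; detection at
#'   the sampling resolution). Event onsets land on the first frame at or
#'   after the true time, so tolerance is applied to that grid.
#' @return list with `recall`, `precision`, `nMatched`.
#' @export
matchMinis <- function(detected, truthTimes, frameRate, tolFrames = 1) {
  if (!length(truthTimes))
    return(list(recall = NA_real_,
                precision = if (nrow(detected)) 0 else NA_real_,
                nMatched = 0L))
  truthFrame <- ceiling(truthTimes * frameRate) + 1
  used <- rep(FALSE, nrow(detected))
  matched <- 0L
  for (tf in truthFrame) {
    d <- abs(detected$frame - tf)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tolFrames) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(recall = matched / length(truthTimes),
       precision = if (nrow(detected)) matched / nrow(detected)
                   else NA_real_,
       nMatched = matched)
}
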