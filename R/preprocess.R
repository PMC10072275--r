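# centred sliding-window minimum of width 2*h + 1 along each row,
# computed with the doubling trick in O(n log h); +Inf padding makes the
# window shrink at the edges
.slideRowExtreme <- function(m, h, maxmode = FALSE) {
  if (h < 1L) return(m)
  w <- ncol(m)
  pad <- if (maxmode) -Inf else Inf
  comb <- if (maxmode) pmax else pmin
  # pad h columns on the left so the centred window [j-h, j+h] becomes a
  # forward window of length L = 2h + 1 starting at padded column j
  L <- 2L * h + 1L
  a <- cbind(matrix(pad, nrow(m), h), m)
  wp <- ncol(a)
  shiftP <- function(x, k) {
    if (k == 0L) return(x)
    out <- matrix(pad, nrow(x), wp)
    if (k < wp) out[, 1:(wp - k)] <- x[, (k + 1):wp]
    out
  }
  len <- 1L
  while (2L * len <= L) {
    a <- comb(a, shiftP(a, len))
    len <- 2L * len
  }
  fwd <- comb(a, shiftP(a, L - len))
  fwd[, 1:w, drop = FALSE]
}

# grayscale erosion/dilation by a disc of the given radius, via the
# decomposition of the disc into horizontal chords
.discMorph <- function(img, radius, maxmode = FALSE) {
  h <- nrow(img)
  pad <- if (maxmode) -Inf else Inf
  comb <- if (maxmode) pmax else pmin
  acc <- matrix(pad, h, ncol(img))
  for (dy in -radius:radius) {
    half <- floor(sqrt(radius^2 - dy^2))
    rowmin <- .slideRowExtreme(img, half, maxmode)
    shifted <- matrix(pad, h, ncol(img))
    src <- seq_len(h) + dy
    ok <- src >= 1 & src <= h
    shifted[ok, ] <- rowmin[src[ok], ]
    acc <- comb(acc, shifted)
  }
  acc
}

#' Rolling-ball style background subtraction
#'
#' Estimates, per frame, a smooth background by grayscale morphological
#' opening (erosion then dilation) with a disc structuring element of the
#' given radius - the classic rolling-ball semantics: the background is
#' the envelope a structuring element of that radius can reach from below
#' - and subtracts it. Output is clipped at zero; frame count and shape
#' are unchanged. The default radius of 50 px matches standard practice
#' for NMJ movies.
#'
#' @param movie a [CaMovie-class].
#' @param radiusPx structuring-element radius in pixels (>= 1).
#' @return a background-subtracted [CaMovie-class].
#' @export
rollingBallSubtract <- function(movie, radiusPx = 50L) {
  stopifnot(is(movie, "CaMovie"))
  if (radiusPx < 1) stop("radius must be >= 1 pixel")
  d <- dim(movie@data)
  if (radiusPx > d[2] && radiusPx > d[3])
    stop("radius exceeds both image dimensions")
  out <- movie@data
  for (i in seq_len(d[1])) {
    fr <- movie@data[i, , ]
    bg <- .discMorph(.discMorph(fr, radiusPx, maxmode = FALSE),
                     radiusPx, maxmode = TRUE)
    out[i, , ] <- pmax(fr - bg, 0)
  }
  m <- movie
  m@data <- out
  m
}

# integer-shift cross-correlation of one frame against a masked reference,
# computed by FFT; returns the (dy, dx) maximizing the masked product
.bestShift <- function(ref, frame, maskMat, maxShift) {
  h <- nrow(ref); w <- ncol(ref)
  rm <- ref * maskMat
  # cross-correlation C(dy,dx) = sum_{y,x} rm(y,x) * frame(y+dy, x+dx)
  cc <- Re(stats::fft(Conj(stats::fft(rm)) * stats::fft(frame),
                      inverse = TRUE)) / (h * w)
  dys <- c(0:(h - 1)); dys[dys > h / 2] <- dys[dys > h / 2] - h
  dxs <- c(0:(w - 1)); dxs[dxs > w / 2] <- dxs[dxs > w / 2] - w
  ok <- outer(abs(dys) <= maxShift, abs(dxs) <= maxShift)
  cc[!ok] <- -Inf
  idx <- arrayInd(which.max(cc), dim(cc))
  c(dy = dys[idx[1]], dx = dxs[idx[2]])
}

#' Register a movie by translation against its first frame
#'
#' Translation-only stabilization: each frame is shifted by the integer
#' (dy, dx) that maximizes its cross-correlation with the reference frame
#' (frame 1), restricted to the supplied ROI. Pixels shifted in from
#' outside the frame are filled with that frame's median. A frame whose
#' best alignment still correlates poorly with the reference (flat or
#' uncorrelated content) raises an `uncorrectable_motion` error. Movies
#' with residual drift may be registered multiple times; a second pass on
#' an already-registered noiseless movie yields all-zero shifts.
#'
#' @param movie a [CaMovie-class] with >= 2 frames.
#' @param roi [Roi-class] restricting the correlation (e.g. the whole
#'   NMJ).
#' @param maxShift largest shift searched, in pixels.
#' @param minCorrelation Pearson correlation (within the ROI, after
#'   alignment) below which a frame is declared uncorrectable.
#' @return list with `movie` (registered) and `shifts` (n x 2 matrix of
#'   detected per-frame (dy, dx) displacements relative to the reference;
#'   the applied correction is their negative; row 1 is the reference and
#'   is zero).
#' @export
registerTranslation <- function(movie, roi, maxShift = 10L,
                                minCorrelation = 0.2) {
  stopifnot(is(movie, "CaMovie"), is(roi, "Roi"))
  d <- dim(movie@data)
  if (d[1] < 2) stop("registration needs at least 2 frames")
  ref <- movie@data[1, , ]
  if (stats::sd(ref) == 0)
    stop("uncorrectable_motion: reference frame is flat")
  maskMat <- matrix(0, d[2], d[3])
  maskMat[roiMask(roi)] <- 1
  out <- movie@data
  shifts <- matrix(0L, d[1], 2, dimnames = list(NULL, c("dy", "dx")))
  refRoi <- ref[roiMask(roi)]
  for (i in 2:d[1]) {
    fr <- movie@data[i, , ]
    if (stats::sd(fr) == 0)
      stop("uncorrectable_motion: frame ", i, " is flat")
    s <- .bestShift(ref, fr, maskMat, maxShift)
    aligned <- .shiftFrame(fr, -s[1], -s[2], stats::median(fr))
    alRoi <- aligned[roiMask(roi)]
    if (stats::sd(alRoi) == 0 || stats::sd(refRoi) == 0 ||
        stats::cor(refRoi, alRoi) < minCorrelation)
      stop("uncorrectable_motion: frame ", i,
           " cannot be aligned to the reference (correlation peak ambiguous)")
    out[i, , ] <- aligned
    shifts[i, ] <- as.integer(s)
  }
  m <- movie
  m@data <- out
  list(movie = m, shifts = shifts)
}

#' Extract the mean-fluorescence trace of an ROI
#'
#' The trace value at frame i is the arithmetic mean of the movie pixels
#' inside the ROI at frame i. When a list of ROIs is supplied (e.g. all
#' mitochondria of one NMJ) the combined trace is the mean of the per-ROI
#' traces.
#'
#' @param movie a [CaMovie-class].
#' @param roi an [Roi-class] or list of them.
#' @param stim optional stimulation metadata attached to the trace.
#' @return a [CaTrace-class].
#' @export
extractTrace <- function(movie, roi, stim = numeric()) {
  stopifnot(is(movie, "CaMovie"))
  if (is.list(roi)) {
    traces <- vapply(roi, function(r)
      traceValues(extractTrace(movie, r)), numeric(nFrames(movie)))
    return(CaTrace(rowMeans(traces), movie@frameRate, stim = stim,
                   meta = list(roi_id = "combined")))
  }
  stopifnot(is(roi, "Roi"))
  px <- roiMask(roi)
  if (nrow(px) == 0) stop("empty ROI")
  d <- dim(movie@data)
  if (any(px[, 1] > d[2]) || any(px[, 2] > d[3]))
    stop("ROI pixels fall outside the image bounds")
  flat <- matrix(movie@data, d[1], d[2] * d[3])
  cols <- (px[, 2] - 1L) * d[2] + px[, 1]
  CaTrace(rowMeans(flat[, cols, drop = FALSE]), movie@frameRate,
          stim = stim, meta = list(roi_id = roi@id, roi_kind = roi@kind))
}

#' Registration residual of a movie within an ROI
#'
#' Mean absolute difference of each frame to the reference frame inside
#' the ROI, normalized by the ROI mean of the reference; the quality
#' metric consumed by [qcFilter()].
#'
#' @param movie a (registered) [CaMovie-class].
#' @param roi the [Roi-class] used for registration.
#' @return a single non-negative number.
#' @export
registrationResidual <- function(movie, roi) {
  px <- roiMask(roi)
  d <- dim(movie@data)
  flat <- matrix(movie@data, d[1], d[2] * d[3])
  cols <- (px[, 2] - 1L) * d[2] + px[, 1]
  sub <- flat[, cols, drop = FALSE]
  ref <- sub[1, ]
  m <- mean(abs(ref))
  if (m == 0) return(Inf)
  mean(abs(sweep(sub, 2, ref))) / m
}

#' Quality-control filter for extracted traces
#'
#' Applies the study's discard rules: recordings whose post-registration
#' residual exceeds the threshold are discarded as uncorrectable motion
#' (or, when flagged, focus drift), and NMJs with fewer than `minRois`
#' usable ROIs (default 3, i.e. only one or two boutons/mitochondria) are
#' discarded entirely.
#'
#' @param info data.frame with columns `id`, `nmj_id`, `residual` and
#'   optionally logical `out_of_focus`.
#' @param residualThreshold maximum acceptable normalized residual.
#' @param minRois minimum usable ROIs per NMJ.
#' @return list with `kept` (ids) and `discarded` (data.frame of id,
#'   reason); the two sets are disjoint.
#' @export
qcFilter <- function(info, residualThreshold = 0.2, minRois = 3L) {
  stopifnot(all(c("id", "nmj_id", "residual") %in% names(info)))
  oof <- if ("out_of_focus" %in% names(info)) info$out_of_focus
         else rep(FALSE, nrow(info))
  reason <- rep(NA_character_, nrow(info))
  reason[info$residual > residualThreshold] <- "uncorrectable_motion"
  reason[oof] <- "out_of_focus"
  usable <- is.na(reason)
  perNmj <- tapply(usable, info$nmj_id, sum)
  few <- names(perNmj)[perNmj < minRois]
  reason[usable & info$nmj_id %in% few] <- "too_few_rois"
  discarded <- data.frame(id = info$id[!is.na(reason)],
                          reason = reason[!is.na(reason)])
  list(kept = info$id[is.na(reason)], discarded = discarded)
}
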