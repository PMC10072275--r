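#' NMJ mask from a reference (plasma-membrane marker) channel
#'
#' Manual-threshold semantics: the mask is the set of reference-channel
#' pixels at or above the threshold, and is then applied unchanged to the
#' other channels.
#'
#' @param referenceImage numeric matrix.
#' @param manualThreshold intensity threshold (a.u.).
#' @return an [Roi-class] of kind `"nmj"`.
#' @export
nmjMaskFromReference <- function(referenceImage, manualThreshold) {
  sel <- referenceImage >= manualThreshold
  if (!any(sel))
    stop("threshold ", manualThreshold, " selects no pixels (empty mask)")
  Roi(sel, id = "nmj", kind = "nmj")
}

#' Intermodes histogram threshold
#'
#' The classic Intermodes rule: iteratively smooth the intensity histogram
#' with a running mean of 3 bins until exactly two local maxima remain, at
#' bins j and k, and return the midpoint (j + k) / 2. For an image input,
#' a 256-bin histogram over the min-max intensity range is used (the 8-bit
#' convention of the source tool) and the threshold is mapped back to
#' intensity units.
#'
#' @param x numeric matrix/vector of intensities, or a histogram of counts
#'   (named or passed via `isHistogram = TRUE`).
#' @param nBins histogram bins for image input.
#' @param maxIter smoothing iteration cap; exceeding it means the
#'   histogram cannot be reduced to two modes (not bimodal) and is an
#'   error.
#' @param isHistogram interpret `x` as bin counts (bin values `0 ..
#'   length(x) - 1`); the returned threshold is then in bin units.
#' @return threshold (intensity units, or bin units for histogram input).
#' @export
intermodesThreshold <- function(x, nBins = 256L, maxIter = 10000L,
                                isHistogram = FALSE) {
  if (isHistogram) {
    h <- as.numeric(x)
    lo <- 0; step <- 1
  } else {
    v <- as.numeric(x)
    lo <- min(v); hi <- max(v)
    if (hi <= lo) stop("image has no intensity range; histogram unimodal")
    step <- (hi - lo) / (nBins - 1)
    h <- tabulate(pmin(floor((v - lo) / step) + 1L, nBins), nBins)
  }
  findPeaks <- function(h) {
    # pad so modes in the first/last bin count too
    hp <- c(-1, h, -1)
    n <- length(hp)
    which(hp[2:(n - 1)] > hp[1:(n - 2)] & hp[2:(n - 1)] > hp[3:n])
  }
  iter <- 0L
  while (length(findPeaks(h)) > 2L) {
    iter <- iter + 1L
    if (iter > maxIter)
      stop("histogram cannot be reduced to two modes (iteration cap)")
    h <- (c(h[1], h[-length(h)]) + h + c(h[-1], h[length(h)])) / 3
  }
  peaks <- findPeaks(h)
  if (length(peaks) < 2L)
    stop("histogram is not bimodal; Intermodes threshold undefined")
  # a genuinely bimodal histogram has a pronounced valley between the
  # modes; a unimodal one that merely stabilized at two ripples does not
  valley <- min(h[peaks[1]:peaks[2]])
  if (valley > 0.5 * min(h[peaks]))
    stop("histogram is not bimodal; Intermodes threshold undefined")
  mid <- mean(peaks - 1L)  # 0-based bin convention
  lo + mid * step
}

#' Measure mean intensity, area and reference ratio over an ROI
#'
#' @param markerImage numeric matrix of the marker channel.
#' @param roi an [Roi-class].
#' @param referenceImage optional matrix; when given, the relative
#'   intensity is the marker mean divided by the reference mean over the
#'   same ROI.
#' @return data.frame with `roi_id`, `mean_intensity`, `area_px`,
#'   `relative_intensity` (NA without a reference), `sum_intensity`.
#' @export
measureIntensity <- function(markerImage, roi, referenceImage = NULL) {
  stopifnot(is(roi, "Roi"))
  px <- roiMask(roi)
  if (any(px[, 1] > nrow(markerImage)) || any(px[, 2] > ncol(markerImage)))
    stop("ROI pixels fall outside the image")
  mv <- markerImage[px]
  rel <- NA_real_
  if (!is.null(referenceImage)) {
    rmean <- mean(referenceImage[px])
    if (rmean == 0) stop("reference mean over the ROI is zero")
    rel <- mean(mv) / rmean
  }
  data.frame(roi_id = roi@id, mean_intensity = mean(mv),
             area_px = nrow(px), relative_intensity = rel,
             sum_intensity = sum(mv))
}

#' Partition an NMJ into puncta and the remainder
#'
#' Applies the Intermodes threshold to the marker intensities inside the
#' NMJ ROI to delimit bright puncta, and reports mean intensity and area
#' over the whole NMJ, the puncta region, and the NMJ excluding puncta.
#' When the intensity histogram has no second mode (no puncta), a
#' degenerate result is returned with zero puncta area, so control images
#' flow through batch analyses.
#'
#' @param markerImage numeric matrix.
#' @param nmjRoi the NMJ [Roi-class].
#' @param referenceImage optional reference channel for ratiometry.
#' @return data.frame with rows `whole`, `puncta`, `complement` (puncta
#'   row has area 0 and NA means in the degenerate case), and the
#'   threshold used as attribute `"threshold"`.
#' @export
punctaPartition <- function(markerImage, nmjRoi, referenceImage = NULL) {
  stopifnot(is(nmjRoi, "Roi"))
  px <- roiMask(nmjRoi)
  vals <- markerImage[px]
  thr <- tryCatch(intermodesThreshold(vals),
                  error = function(e) NA_real_)
  inPuncta <- if (is.na(thr)) rep(FALSE, nrow(px)) else vals > thr
  mkRow <- function(id, sel) {
    if (!any(sel))
      return(data.frame(roi_id = id, mean_intensity = NA_real_,
                        area_px = 0L, relative_intensity = NA_real_,
                        sum_intensity = 0))
    measureIntensity(markerImage,
                     Roi(px[sel, , drop = FALSE], id = id,
                         kind = if (id == "puncta") "puncta" else "nmj"),
                     referenceImage)
  }
  out <- rbind(mkRow("whole", rep(TRUE, nrow(px))),
               mkRow("puncta", inPuncta),
               mkRow("complement", !inPuncta))
  attr(out, "threshold") <- thr
  out
}

#' Connected-component object sizes
#'
#' Labels foreground pixels of a binary (or label) mask with
#' 8-connectivity and returns one area per object.
#'
#' @param mask logical or numeric matrix; non-zero pixels are foreground.
#' @return integer vector of object areas in pixels (empty for an empty
#'   mask).
#' @export
objectSizes <- function(mask) {
  fg <- mask != 0
  lab <- labelConnected(fg)
  if (max(lab) == 0L) return(integer())
  as.integer(tabulate(lab[lab > 0L]))
}

#' 8-connectivity connected-component labelling
#'
#' @param fg logical matrix of foreground pixels.
#' @return integer matrix of object labels (0 = background).
#' @export
labelConnected <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0L, h, w)
  nextLab <- 0L
  idx <- which(fg)
  offs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  for (start in idx) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    lab[start] <- nextLab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((cur - 1L) %% h) + 1L
      cc <- ((cur - 1L) %/% h) + 1L
      nr <- r + offs[, 1]; nc <- cc + offs[, 2]
      ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= w
      nidx <- (nc[ok] - 1L) * h + nr[ok]
      nidx <- nidx[fg[nidx] & lab[nidx] == 0L]
      if (length(nidx)) {
        lab[nidx] <- nextLab
        queue <- c(queue, nidx)
      }
    }
  }
  lab
}

#' Maximum-intensity projection of an image stack
#'
#' @param stack numeric array `Z x H x W` (or a [CaMovie-class]).
#' @return matrix of per-pixel maxima.
#' @export
maxProjection <- function(stack) {
  if (is(stack, "CaMovie")) stack <- stack@data
  apply(stack, c(2, 3), max)
}
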