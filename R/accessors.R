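#' Construct a CaTrace
#'
#' @param values numeric fluorescence values, one per frame.
#' @param frameRate frames per second.
#' @param stim optional `c(onset_s, duration_s, frequency_hz)`.
#' @param meta named list of metadata.
#' @return A [CaTrace-class] object.
#' @examples
#' tr <- CaTrace(1000 * (1:100)^-0.05, frameRate = 10, stim = c(5, 2, 40))
#' traceTimes(tr)[1:3]
#' @export
CaTrace <- function(values, frameRate, stim = numeric(), meta = list()) {
  new("CaTrace", values = as.numeric(values),
      frameRate = as.numeric(frameRate),
      stim = as.numeric(stim), meta = meta)
}

#' Construct a CaMovie
#' @param data `T x H x W` array of intensities.
#' @param frameRate frames per second.
#' @param channelLabel channel name.
#' @export
CaMovie <- function(data, frameRate, channelLabel = "") {
  new("CaMovie", data = data, frameRate = as.numeric(frameRate),
      channelLabel = channelLabel)
}

#' Construct a Roi
#' @param mask n x 2 matrix of (row, col) pixel coordinates, or a logical
#'   matrix that is converted with [which()].
#' @param id identifier.
#' @param kind one of `"nmj"`, `"bouton"`, `"mitochondrion"`, `"puncta"`,
#'   `"background"`.
#' @export
Roi <- function(mask, id = "roi", kind = "nmj") {
  if (is.logical(mask)) mask <- which(mask, arr.ind = TRUE)
  mask <- matrix(as.integer(mask), ncol = 2,
                 dimnames = list(NULL, c("row", "col")))
  new("Roi", id = id, kind = kind, mask = mask)
}

#' @rdname CaTrace
#' @param x a `CaTrace`.
#' @export
traceValues <- function(x) x@values

#' @rdname CaTrace
#' @export
frameRate <- function(x) x@frameRate

#' @rdname CaTrace
#' @export
stimWindow <- function(x) x@stim

#' @rdname CaTrace
#' @export
traceMeta <- function(x) x@meta

#' Time of each frame, in seconds
#' @param x a `CaTrace`.
#' @return numeric vector, frame i at `(i - 1) / frameRate`.
#' @export
traceTimes <- function(x) (seq_along(x@values) - 1) / x@frameRate

#' @rdname CaMovie
#' @param x a `CaMovie`.
#' @export
movieData <- function(x) x@data

#' @rdname CaMovie
#' @export
nFrames <- function(x) dim(x@data)[1]

#' @rdname Roi
#' @param x an `Roi`.
#' @export
roiMask <- function(x) x@mask

#' @rdname Roi
#' @export
roiArea <- function(x) nrow(x@mask)

#' Evaluate a fitted bleach curve
#'
#' @param model a [BleachModel-class].
#' @param frames 0-based frame indices at which to evaluate
#'   \eqn{PC(x) = a (i + xOffset)^b}.
#' @return numeric vector of predicted fluorescence (a.u.).
#' @export
predictBleach <- function(model, frames) {
  stopifnot(is(model, "BleachModel"))
  model@a * (frames + model@xOffset)^model@b
}

#' Tabular view of evoked features
#' @param x an `EvokedFeatures`.
#' @param ... ignored.
#' @return one-row `data.frame` with the eight feature columns.
#' @export
setMethod("as.data.frame", "EvokedFeatures", function(x, ...) {
  data.frame(resting_F = x@restingF, max_F = x@maxF, delta_F = x@deltaF,
             max_dff = x@maxDff, min_dff_post_stim = x@minDffPostStim,
             time_to_peak_s = x@timeToPeak, t50_recovery_s = x@t50Recovery,
             t100_recovery_s = x@t100Recovery)
})

setMethod("show", "CaTrace", function(object) {
  cat("CaTrace:", length(object@values), "frames @",
      object@frameRate, "Hz (",
      sprintf("%.1f", length(object@values) / object@frameRate), "s )\n")
  if (length(object@stim))
    cat("  stim: onset", object@stim[1], "s, duration", object@stim[2],
        "s,", object@stim[3], "Hz\n")
  if (length(object@meta)) {
    keep <- intersect(c("genotype", "compartment", "larva_id", "nmj_id"),
                      names(object@meta))
    if (length(keep))
      cat("  meta:", paste(keep, unlist(object@meta[keep]), sep = "=",
                           collapse = ", "), "\n")
  }
})

setMethod("show", "BleachModel", function(object) {
  cat(sprintf("BleachModel: PC(x) = %.6g * x^%.6g  (fit frames %d..%d, x = frame + %g)\n",
              object@a, object@b, object@fitWindow[1], object@fitWindow[2],
              object@xOffset))
})

setMethod("show", "CaMovie", function(object) {
  d <- dim(object@data)
  cat("CaMovie:", d[1], "frames of", d[2], "x", d[3], "px @",
      object@frameRate, "Hz")
  if (nzchar(object@channelLabel)) cat(" [", object@channelLabel, "]")
  cat("\n")
})

setMethod("show", "Roi", function(object) {
  cat("Roi", object@id, "(", object@kind, "):", nrow(object@mask),
      "pixels\n")
})

setMethod("show", "EvokedFeatures", function(object) {
  cat("EvokedFeatures:\n")
  print(as.data.frame(object), row.names = FALSE)
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth: true peak dF/F", sprintf("%.4g", object@truePeakDff),
      "|", length(object@miniTimes), "minis | bleach a =",
      sprintf("%.4g", object@bleachA), "b =",
      sprintf("%.4g", object@bleachB), "\n")
})

#' @rdname SimTruth-class
#' @param x a `SimTruth`.
#' @export
truePeakDff <- function(x) x@truePeakDff

#' @rdname SimTruth-class
#' @export
miniTimes <- function(x) x@miniTimes

#' @rdname SimTruth-class
#' @export
miniAmps <- function(x) x@miniAmps

#' @rdname SimTruth-class
#' @export
trueShifts <- function(x) x@shifts

#' @rdname SimTruth-class
#' @export
cleanDff <- function(x) x@cleanDff
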