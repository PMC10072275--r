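# File formats: movies and masks as multilayer grayscale TIFF, traces as
# CSV (frame, time_s, value) with a plain-text key/value sidecar.

.sidecarPath <- function(path) paste0(path, ".meta.txt")

.writeSidecar <- function(path, kv) {
  writeLines(paste0(names(kv), "=", vapply(kv, paste, "", collapse = ",")),
             .sidecarPath(path))
}

.readSidecar <- function(path) {
  if (!file.exists(.sidecarPath(path))) return(list())
  lines <- readLines(.sidecarPath(path))
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(x) {
    v <- strsplit(x[2], ",", fixed = TRUE)[[1]]
    n <- suppressWarnings(as.numeric(v))
    if (!anyNA(n)) n else v
  })
  names(out) <- vapply(kv, `[`, "", 1)
  out
}

#' Write / read a movie as multilayer grayscale TIFF
#'
#' Intensities are stored as 32-bit float TIFF frames scaled to [0, 1];
#' the scale, frame rate and channel label live in a plain-text sidecar
#' (`<path>.meta.txt`), so the round trip restores absolute units.
#'
#' @param movie a [CaMovie-class].
#' @param path output .tif path.
#' @return `path`, invisibly.
#' @export
writeMovie <- function(movie, path) {
  stopifnot(is(movie, "CaMovie"))
  sc <- max(movie@data, 1e-12)
  frames <- lapply(seq_len(nFrames(movie)), function(i)
    movie@data[i, , ] / sc)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  .writeSidecar(path, list(frame_rate_hz = movie@frameRate, scale = sc,
                           channel = movie@channelLabel))
  invisible(path)
}

#' @rdname writeMovie
#' @param frameRate used if the sidecar is missing.
#' @export
readMovie <- function(path, frameRate = 1) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  meta <- .readSidecar(path)
  sc <- meta$scale %||% 1
  d <- dim(frames[[1]])
  dat <- array(0, c(length(frames), d[1], d[2]))
  for (i in seq_along(frames)) dat[i, , ] <- frames[[i]] * sc
  CaMovie(dat, meta$frame_rate_hz %||% frameRate,
          as.character(meta$channel %||% ""))
}

#' Write / read a label mask as 16-bit TIFF
#'
#' @param labels integer matrix (0 = background).
#' @param path output .tif path.
#' @export
writeLabelMask <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeLabelMask
#' @export
readLabelMask <- function(path) {
  round(tiff::readTIFF(path) * 65535)
}

#' Write / read a trace as CSV with a metadata sidecar
#'
#' Columns `frame` (1-based), `time_s`, `value`; frame rate, stimulation
#' window and metadata go to `<path>.meta.txt`.
#'
#' @param trace a [CaTrace-class].
#' @param path output .csv path.
#' @export
writeTraceCsv <- function(trace, path) {
  stopifnot(is(trace, "CaTrace"))
  utils::write.csv(data.frame(frame = seq_along(trace@values),
                              time_s = traceTimes(trace),
                              value = trace@values),
                   path, row.names = FALSE)
  kv <- c(list(frame_rate_hz = trace@frameRate),
          if (length(trace@stim)) list(stim = trace@stim),
          trace@meta[vapply(trace@meta, is.atomic, TRUE)])
  .writeSidecar(path, kv)
  invisible(path)
}

#' @rdname writeTraceCsv
#' @export
readTraceCsv <- function(path) {
  df <- utils::read.csv(path)
  meta <- .readSidecar(path)
  stim <- meta$stim %||% numeric()
  meta$stim <- NULL
  fr <- meta$frame_rate_hz %||% {
    if (nrow(df) > 1) 1 / diff(df$time_s[1:2]) else 1
  }
  meta$frame_rate_hz <- NULL
  CaTrace(df$value, fr, stim = stim, meta = meta)
}

#' Write a QC report as CSV
#'
#' @param report list from [qcFilter()].
#' @param path output .csv path.
#' @export
writeQcReport <- function(report, path) {
  kept <- data.frame(id = report$kept,
                     status = rep("kept", length(report$kept)),
                     reason = rep(NA_character_, length(report$kept)))
  disc <- if (nrow(report$discarded))
    data.frame(id = report$discarded$id, status = "discarded",
               reason = report$discarded$reason)
  else kept[0, ]
  utils::write.csv(rbind(kept, disc), path, row.names = FALSE)
  invisible(path)
}
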