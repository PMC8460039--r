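# Recording container: channels x samples voltage with metadata.

#' Construct a Recording
#'
#' @param voltage numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_ids character or integer channel identifiers.
#' @param good_mask logical vector, one flag per channel; `FALSE` marks
#'   channels excluded from referencing and analysis.
#' @return an object of class `lfp_recording`.
#' @export
recording <- function(voltage, fs,
                      channel_ids = paste0("ch", seq_len(nrow(voltage))),
                      good_mask = rep(TRUE, nrow(voltage))) {
  voltage <- as.matrix(voltage)
  stopifnot(is.numeric(voltage), fs > 0,
            length(channel_ids) == nrow(voltage),
            length(good_mask) == nrow(voltage))
  if (!all(is.finite(voltage))) stop("voltage contains non-finite values")
  structure(list(voltage = voltage, fs = fs,
                 channel_ids = as.character(channel_ids),
                 good_mask = as.logical(good_mask)),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels x %d samples @ %g Hz (%.1f s), %d good\n",
              nrow(x$voltage), ncol(x$voltage), x$fs,
              ncol(x$voltage) / x$fs, sum(x$good_mask)))
  invisible(x)
}

#' @export
dim.lfp_recording <- function(x) dim(x$voltage)

#' Write a Recording to a flat self-describing container
#'
#' Writes `<path>.json` (metadata: sampling rate, channel ids, good mask,
#' dimensions, dtype, byte order) alongside `<path>.f32`, the voltage
#' matrix as little-endian float32 in channel-major order.  The payload is
#' directly loadable from numpy via
#' `np.fromfile(p, '<f4').reshape(channels, samples)`.
#'
#' @param rec an `lfp_recording`.
#' @param path file stem (no extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "lfp_recording"))
  meta <- list(format = "songlfp-recording", version = 1L,
               fs = rec$fs, channels = nrow(rec$voltage),
               samples = ncol(rec$voltage),
               channel_ids = rec$channel_ids,
               good_mask = rec$good_mask,
               dtype = "float32", byte_order = "little",
               order = "channel-major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  con <- file(paste0(path, ".f32"), "wb")
  on.exit(close(con))
  # channel-major: write row by row
  writeBin(as.numeric(t(rec$voltage)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a Recording written by [write_recording()]
#' @param path file stem (no extension).
#' @return an `lfp_recording`.
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "songlfp-recording"))
    stop("not a songlfp recording container: ", path)
  n <- meta$channels * meta$samples
  con <- file(paste0(path, ".f32"), "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  recording(matrix(v, nrow = meta$channels, byrow = TRUE),
            fs = meta$fs, channel_ids = meta$channel_ids,
            good_mask = meta$good_mask)
}

#' Write a schematic audio rendering of annotated song
#'
#' Emits a 16-bit mono PCM WAV in which every vocal interval is rendered
#' as a pure tone (one fixed frequency per syllable class).  This is a
#' schematic stand-in used to exercise audio I/O, not a birdsong
#' synthesiser.
#'
#' @param ann an `annotation_set`.
#' @param path output `.wav` path.
#' @param fs audio sampling rate (default 8000 Hz).
#' @return `path`, invisibly.
#' @export
write_schematic_wav <- function(ann, path, fs = 8000) {
  ev <- vocal_events(ann)
  dur_s <- (max(ev$offset) / ann$fs) + 0.5
  n <- ceiling(dur_s * fs)
  x <- numeric(n)
  classes <- sort(unique(ev$label))
  tone <- stats::setNames(440 * 2^(seq_along(classes) / 6), classes)
  for (i in seq_len(nrow(ev))) {
    i0 <- floor(ev$onset[i] / ann$fs * fs) + 1
    i1 <- min(n, ceiling(ev$offset[i] / ann$fs * fs))
    tt <- seq.int(i0, i1)
    x[tt] <- 0.8 * sin(2 * pi * tone[[ev$label[i]]] * tt / fs)
  }
  pcm <- as.integer(round(32767 * x))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
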