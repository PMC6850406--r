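# File I/O: minimal RIFF/WAVE reader and writer (16-bit PCM and 32-bit
# float), and the TSV formats used to exchange signals, spectra and
# comodulograms between pipeline stages.

#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader supporting uncompressed PCM (8/16/24/32 bit) and
#' IEEE float (32/64 bit). Multi-channel audio is averaged to mono. Samples
#' are returned on the [-1, 1] scale.
#'
#' @param path path to a .wav file
#' @return list with \code{samples} (numeric) and \code{fs} (Hz)
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  stopIfNot(identical(riff, "RIFF"), "not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  stopIfNot(identical(wave, "WAVE"), "not a WAVE file: ", path)
  fmt <- NULL; dataRaw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audioFormat = sum(as.integer(raw[1:2]) * c(1, 256)),
        nChannels   = sum(as.integer(raw[3:4]) * c(1, 256)),
        sampleRate  = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bitsPerSample = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (id == "data") {
      dataRaw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(dataRaw)) break
  }
  stopIfNot(!is.null(fmt) && !is.null(dataRaw), "malformed WAV: ", path)
  bytes <- fmt$bitsPerSample %/% 8
  n <- length(dataRaw) %/% bytes
  x <- if (fmt$audioFormat == 3L) {
    readBin(dataRaw, "double", n, size = bytes, endian = "little")
  } else if (fmt$bitsPerSample == 8L) {
    (as.integer(dataRaw) - 128) / 128
  } else if (fmt$bitsPerSample == 24L) {
    b <- matrix(as.integer(dataRaw[seq_len(n * 3)]), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    ifelse(v >= 2^23, v - 2^24, v) / 2^23
  } else {
    readBin(dataRaw, "integer", n, size = bytes, signed = TRUE,
            endian = "little") / 2^(fmt$bitsPerSample - 1)
  }
  if (fmt$nChannels > 1L)
    x <- colMeans(matrix(x, nrow = fmt$nChannels))
  list(samples = x, fs = fmt$sampleRate)
}

#' Write a WAV file
#'
#' Writes mono 16-bit PCM. Samples are clipped to [-1, 1].
#'
#' @param samples numeric vector on the [-1, 1] scale
#' @param fs sampling rate (Hz)
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeWav <- function(samples, fs, path) {
  x <- pmax(-1, pmin(1, samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")              # PCM, mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * 2), con, 4, endian = "little")     # byte rate
  writeBin(c(2L, 16L), con, 2, endian = "little")             # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Write a signal as TSV
#'
#' Writes an \linkS4class{EnvelopeSignal} or \linkS4class{RoiTimeSeries} as a
#' two-column TSV (\code{time_s}, \code{value}).
#'
#' @param x signal object
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeSignalTSV <- function(x, path) {
  s <- samples(x)
  df <- data.frame(time_s = (seq_along(s) - 1) / samplingRate(x), value = s)
  utils::write.table(format(df, digits = 10, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a neural time series from TSV
#'
#' Reads a two-column TSV (\code{time_s}, \code{value}) written by
#' \code{\link{writeSignalTSV}}; the sampling rate is recovered from the time
#' column.
#'
#' @param path TSV path
#' @param subject,condition,roi labels for the returned object
#' @param nTrials trial count of the stored signal
#' @return a \linkS4class{RoiTimeSeries}
#' @export
readRoiTSV <- function(path, subject = "s01", condition = "unlabeled",
                       roi = "ROI", nTrials = 1) {
  df <- utils::read.delim(path)
  stopIfNot(all(c("time_s", "value") %in% names(df)),
            "expected columns time_s and value in ", path)
  fs <- 1 / stats::median(diff(df$time_s))
  roiTimeSeries(df$value, fs = round(fs, 6), subject = subject,
                condition = condition, roi = roi, nTrials = nTrials)
}

#' Write a spectrum or comodulogram as TSV
#'
#' \code{writeSpectrumTSV} writes a \linkS4class{CoherenceSpectrum} (columns
#' \code{freq_hz}, \code{coherence}) or a plain \code{freqs}/\code{power}
#' list (columns \code{freq_hz}, \code{power}).
#' \code{writeComodulogramTSV} writes a \linkS4class{Comodulogram} in long
#' format (\code{phase_hz}, \code{amp_hz}, \code{mi_bits}) with a JSON
#' sidecar (same path, extension \code{.json}) holding the labels and phase
#' source.
#'
#' @param x object to write
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeSpectrumTSV <- function(x, path) {
  df <- if (is(x, "CoherenceSpectrum"))
    data.frame(freq_hz = spectrumFreqs(x), coherence = coherenceValues(x))
  else data.frame(freq_hz = x$freqs, power = x$power)
  utils::write.table(format(df, digits = 10, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectrumTSV
#' @export
writeComodulogramTSV <- function(x, path) {
  df <- data.frame(
    phase_hz = rep(phaseFreqs(x), times = length(ampFreqs(x))),
    amp_hz = rep(ampFreqs(x), each = length(phaseFreqs(x))),
    mi_bits = as.vector(miMatrix(x)))
  utils::write.table(format(df, digits = 10, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(
    list(subject = subjectId(x), condition = conditionLabel(x),
         roi = roiLabel(x), phase_source = phaseSource(x)),
    side, auto_unbox = TRUE)
  invisible(path)
}
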