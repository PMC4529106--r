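## Readers and writers: delimited-text segments with a sidecar header,
## minimal EDF, and electrode-coordinate tables.

#' Read a segment from a delimited text matrix with a sidecar header
#'
#' The data file is a tab-separated numeric matrix, channels in rows. The
#' sidecar `<path>.meta` holds `key<TAB>value` lines with at least
#' `fs` (Hz) and optionally `labels` (comma-separated, one per channel).
#'
#' @param path path to the data file
#' @return a [Segment-class]
#' @export
readSegmentTable <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  meta <- readSidecar(paste0(path, ".meta"))
  d <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(d) <- NULL
  labels <- if (!is.null(meta$labels))
    strsplit(meta$labels, ",")[[1]] else NULL
  Segment(d, fs = as.numeric(meta$fs), labels = labels)
}

#' Write a segment as delimited text plus sidecar header
#'
#' @param segment a [Segment-class]
#' @param path output path; the sidecar goes to `<path>.meta`
#' @return `path`, invisibly
#' @export
writeSegmentTable <- function(segment, path) {
  stopifnot(is(segment, "Segment"))
  utils::write.table(sigData(segment), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  writeLines(c(paste0("fs\t", sampleRate(segment)),
               paste0("labels\t",
                      paste(channelLabels(segment), collapse = ","))),
             paste0(path, ".meta"))
  invisible(path)
}

readSidecar <- function(path) {
  if (!file.exists(path)) stop("sidecar header not found: ", path)
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(lines)], "\t")
  stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "\t")),
                  vapply(kv, `[[`, character(1), 1L))
}

edfAscii <- function(con, nchars) {
  trimws(rawToChar(readBin(con, "raw", nchars)))
}

#' Read a multichannel segment from an EDF file
#'
#' Minimal reader for the European Data Format: parses the fixed-layout
#' ASCII header and the per-signal headers, reads the 16-bit little-endian
#' data records, rescales digital to physical units, and returns the
#' signals as one segment. All signals must share one sampling rate;
#' annotation channels are not supported.
#'
#' @param path path to the EDF file
#' @param channels optional character vector of channel labels to keep
#' @return a [Segment-class]
#' @export
readSegmentEDF <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  edfAscii(con, 8L)                      # version
  edfAscii(con, 80L); edfAscii(con, 80L) # patient / recording id
  edfAscii(con, 8L); edfAscii(con, 8L)   # start date / time
  edfAscii(con, 8L)                      # header bytes
  edfAscii(con, 44L)                     # reserved
  nRec <- as.integer(edfAscii(con, 8L))
  recDur <- as.numeric(edfAscii(con, 8L))
  ns <- as.integer(edfAscii(con, 4L))
  fld <- function(w) vapply(seq_len(ns), function(i) edfAscii(con, w),
                            character(1))
  labels <- fld(16L)
  fld(80L)                               # transducer
  fld(8L)                                # physical dimension
  physMin <- as.numeric(fld(8L))
  physMax <- as.numeric(fld(8L))
  digMin <- as.numeric(fld(8L))
  digMax <- as.numeric(fld(8L))
  fld(80L)                               # prefiltering
  spr <- as.integer(fld(8L))             # samples per record
  fld(32L)                               # reserved
  if (length(unique(spr)) != 1L)
    stop("signals with differing sampling rates are not supported")
  fs <- spr[1L] / recDur
  d <- matrix(0, ns, nRec * spr[1L])
  for (r in seq_len(nRec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      gain <- (physMax[s] - physMin[s]) / (digMax[s] - digMin[s])
      d[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        (dig - digMin[s]) * gain + physMin[s]
    }
  }
  seg <- Segment(d, fs = fs, labels = labels)
  if (!is.null(channels)) seg <- subsetChannels(seg, channels)
  seg
}

#' Write a segment to a minimal EDF file
#'
#' Inverse of [readSegmentEDF()] for round-tripping and for producing
#' small test inputs: one data record per second, 16-bit quantization over
#' the observed per-channel range.
#'
#' @param segment a [Segment-class]; fs and durations must give a whole
#'   number of one-second records
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSegmentEDF <- function(segment, path) {
  stopifnot(is(segment, "Segment"))
  d <- sigData(segment)
  fs <- sampleRate(segment)
  if (abs(fs - round(fs)) > 1e-9 || ncol(d) %% round(fs) != 0L)
    stop("need an integer fs and a whole number of one-second records")
  spr <- as.integer(round(fs))
  nRec <- ncol(d) %/% spr
  ns <- nrow(d)
  # symmetric physical range, padded so the 4-significant-digit header
  # representation still covers every sample
  M <- apply(d, 1L, function(x) max(abs(x)))
  M <- ifelse(M == 0, 1, M * 1.001)
  physMin <- -M
  physMax <- M
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- formatC(as.character(x), width = -w)
    writeBin(charToRaw(paste(substr(s, 1L, w), collapse = "")), con)
  }
  pad("0", 8L); pad("synthetic", 80L); pad("synthetic", 80L)
  pad("01.01.26", 8L); pad("00.00.00", 8L)
  pad(as.character(256L + ns * 256L), 8L); pad("", 44L)
  pad(as.character(nRec), 8L); pad("1", 8L); pad(as.character(ns), 4L)
  for (l in channelLabels(segment)) pad(l, 16L)
  for (i in seq_len(ns)) pad("", 80L)
  for (i in seq_len(ns)) pad("uV", 8L)
  for (v in physMin) pad(formatC(v, digits = 4, format = "g"), 8L)
  for (v in physMax) pad(formatC(v, digits = 4, format = "g"), 8L)
  for (i in seq_len(ns)) pad("-32768", 8L)
  for (i in seq_len(ns)) pad("32767", 8L)
  for (i in seq_len(ns)) pad("", 80L)
  for (i in seq_len(ns)) pad(as.character(spr), 8L)
  for (i in seq_len(ns)) pad("", 32L)
  # re-read the truncated physical ranges so reader and writer agree
  pMin <- as.numeric(formatC(physMin, digits = 4, format = "g"))
  pMax <- as.numeric(formatC(physMax, digits = 4, format = "g"))
  for (r in seq_len(nRec)) {
    for (s in seq_len(ns)) {
      x <- d[s, ((r - 1L) * spr + 1L):(r * spr)]
      dig <- round((x - pMin[s]) / (pMax[s] - pMin[s]) * 65535 - 32768)
      writeBin(as.integer(pmax(-32768, pmin(32767, dig))), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Keep a subset of channels of a segment
#'
#' @param segment a [Segment-class]
#' @param channels labels to keep (order preserved as given)
#' @return the sub-[Segment-class]
#' @export
subsetChannels <- function(segment, channels) {
  idx <- match(channels, channelLabels(segment))
  if (anyNA(idx))
    stop("unknown channel(s): ",
         paste(channels[is.na(idx)], collapse = ", "))
  Segment(sigData(segment)[idx, , drop = FALSE], sampleRate(segment),
          channels)
}

#' Read electrode coordinates
#'
#' Tab-separated file with columns label, x, y, z and optionally lobe.
#' A header line is detected automatically.
#'
#' @param path path to the coordinates file
#' @return an [ElectrodeLayout-class]
#' @export
readElectrodeCoords <- function(path) {
  if (!file.exists(path)) stop("coordinates file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  hasHeader <- suppressWarnings(is.na(as.numeric(first[2L])))
  d <- utils::read.table(path, sep = "\t", header = hasHeader,
                         stringsAsFactors = FALSE)
  lobe <- if (ncol(d) >= 5L) as.character(d[[5L]]) else NULL
  ElectrodeLayout(as.character(d[[1L]]),
                  as.matrix(d[, 2:4]), lobe)
}
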