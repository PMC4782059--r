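# Minimal European Data Format (EDF) reader/writer. EDF stores 16-bit samples
# with per-channel physical/digital scaling in a fixed-width ASCII header; the
# subset implemented here (uniform sampling rate, 1-second data records) covers
# what containerization needs. Payloads are otherwise treated as opaque bytes.

.edf_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")  # left-justified, space padded
}

# Canonical <=8-char numeric text: round to fewer significant digits until it
# fits, so that re-encoding the parsed value reproduces identical bytes.
.edf_num_txt <- function(x, width = 8) {
  for (k in 8:1) {
    s <- formatC(signif(x, k), format = "g", digits = k, width = -1)
    if (nchar(s) <= width) return(s)
  }
  s
}

.edf_num <- function(x, width) .edf_field(.edf_num_txt(x, width), width)

#' Write a multichannel signal as an EDF file
#'
#' Samples are quantized to 16 bits with per-channel scaling chosen from the
#' observed minimum and maximum (recorded as physical min/max in the header),
#' organized into 1-second data records. The sampling rate must be a positive
#' integer; the final partial record, if any, is zero-padded.
#'
#' @param path Destination file.
#' @param data Channels-by-samples numeric matrix (amplitudes, microvolts).
#' @param samplingRate Sampling rate in Hz (positive integer).
#' @param channelLabels One label (<= 16 ASCII characters) per row of `data`.
#' @param startDateTime Optional `POSIXct` recording start; default epoch.
#' @param physicalDimension Unit string written per channel, default `"uV"`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, data, samplingRate, channelLabels,
                      startDateTime = as.POSIXct("2000-01-01 00:00:00",
                                                 tz = "UTC"),
                      physicalDimension = "uV") {
  stopifnot(is.matrix(data), nrow(data) == length(channelLabels))
  if (samplingRate <= 0 || samplingRate != round(samplingRate)) {
    stop("EDF writer requires a positive integer sampling rate")
  }
  ns <- nrow(data)
  spr <- as.integer(samplingRate)           # samples per record per channel
  nSamples <- ncol(data)
  nRecords <- as.integer(ceiling(nSamples / spr))
  if (nRecords < 1L) stop("cannot write EDF with zero samples")

  pmin <- apply(data, 1, min)
  pmax <- apply(data, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  # scale with the values as actually encoded in the ASCII header, so a
  # read/write cycle is byte-stable
  pmin <- as.numeric(vapply(pmin, .edf_num_txt, character(1)))
  pmax <- as.numeric(vapply(pmax, .edf_num_txt, character(1)))
  dmin <- -32768
  dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wr(.edf_field("0", 8))
  wr(.edf_field("X X X X", 80))                       # anonymized patient id
  wr(.edf_field("Startdate X X X X", 80))
  wr(.edf_field(format(startDateTime, "%d.%m.%y"), 8))
  wr(.edf_field(format(startDateTime, "%H.%M.%S"), 8))
  wr(.edf_field(256L * (ns + 1L), 8))
  wr(.edf_field("", 44))
  wr(.edf_field(nRecords, 8))
  wr(.edf_field("1", 8))                               # record duration (s)
  wr(.edf_field(ns, 4))
  for (l in channelLabels) wr(.edf_field(l, 16))
  for (i in seq_len(ns)) wr(.edf_field("", 80))        # transducer
  for (i in seq_len(ns)) wr(.edf_field(physicalDimension, 8))
  for (i in seq_len(ns)) wr(.edf_num(pmin[i], 8))
  for (i in seq_len(ns)) wr(.edf_num(pmax[i], 8))
  for (i in seq_len(ns)) wr(.edf_field(dmin, 8))
  for (i in seq_len(ns)) wr(.edf_field(dmax, 8))
  for (i in seq_len(ns)) wr(.edf_field("", 80))        # prefiltering
  for (i in seq_len(ns)) wr(.edf_field(spr, 8))
  for (i in seq_len(ns)) wr(.edf_field("", 32))

  # quantize whole channels at once, then interleave per record
  scale <- (dmax - dmin) / (pmax - pmin)
  total <- nRecords * spr
  dig <- matrix(0L, nrow = ns, ncol = total)
  idx <- seq_len(nSamples)
  for (i in seq_len(ns)) {
    d <- as.integer(round((data[i, ] - pmin[i]) * scale[i]) + dmin)
    d[d < dmin] <- dmin
    d[d > dmax] <- dmax
    dig[i, idx] <- d
  }
  for (r in seq_len(nRecords)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF header
#'
#' @param path EDF file path.
#' @return A list: `nRecords`, `recordDuration` (s), `nSignals`,
#'   `channelLabels`, `samplesPerRecord`, `physicalMin`, `physicalMax`,
#'   `digitalMin`, `digitalMax`, `startDate`, `startTime`.
#' @export
read_edf_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    if (length(raw) < n) stop("truncated EDF header in ", path)
    rawToChar(raw)
  }
  version <- trimws(rd(8))
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  rd(80); rd(80)
  startDate <- trimws(rd(8))
  startTime <- trimws(rd(8))
  headerBytes <- as.integer(trimws(rd(8)))
  rd(44)
  nRecords <- as.integer(trimws(rd(8)))
  recordDuration <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  if (is.na(ns) || ns < 1 || is.na(headerBytes) ||
      headerBytes != 256L * (ns + 1L)) {
    stop("corrupt EDF header in ", path)
  }
  fld <- function(width) {
    vapply(seq_len(ns), function(i) trimws(rd(width)), character(1))
  }
  labels <- fld(16)
  fld(80)
  dims <- fld(8)
  pmin <- as.numeric(fld(8))
  pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8))
  dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  list(nRecords = nRecords, recordDuration = recordDuration, nSignals = ns,
       channelLabels = labels, samplesPerRecord = spr,
       physicalDimension = dims, physicalMin = pmin, physicalMax = pmax,
       digitalMin = dmin, digitalMax = dmax,
       startDate = startDate, startTime = startTime)
}

#' Read an EDF file into a channels-by-samples matrix
#'
#' Inverts [write_edf()] up to 16-bit quantization. All channels must share
#' one samples-per-record value (uniform sampling rate).
#'
#' @param path EDF file path.
#' @return A list: `data` (channels x samples matrix in physical units),
#'   `samplingRate`, `channelLabels`, plus the header under `header`.
#' @export
read_edf <- function(path) {
  hdr <- read_edf_header(path)
  if (length(unique(hdr$samplesPerRecord)) != 1L) {
    stop("mixed per-channel sampling rates are not supported")
  }
  spr <- hdr$samplesPerRecord[1]
  ns <- hdr$nSignals
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  seek(con, 256L * (ns + 1L))
  total <- hdr$nRecords * spr
  data <- matrix(0, nrow = ns, ncol = total)
  scale <- (hdr$physicalMax - hdr$physicalMin) /
    (hdr$digitalMax - hdr$digitalMin)
  for (r in seq_len(hdr$nRecords)) {
    vals <- readBin(con, "integer", n = ns * spr, size = 2L, signed = TRUE,
                    endian = "little")
    if (length(vals) < ns * spr) stop("truncated EDF payload in ", path)
    block <- matrix(vals, nrow = spr, ncol = ns)   # channel-major blocks
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    data[, cols] <- t(block)
  }
  data <- (data - hdr$digitalMin) * scale + hdr$physicalMin
  list(data = data, samplingRate = spr / hdr$recordDuration,
       channelLabels = hdr$channelLabels, header = hdr)
}
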