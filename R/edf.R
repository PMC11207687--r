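# Minimal EDF / BDF reader and writer.
#
# EDF stores samples as 16-bit and BDF (the BioSemi variant) as 24-bit
# little-endian integers, linearly mapped between a physical and a digital
# range, in fixed-duration data records preceded by a 256-byte global header
# plus 256 bytes per channel.  Only continuous, equal-rate recordings are
# handled -- exactly what this pipeline produces and consumes.

edf_pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

#' Write a recording as EDF or BDF
#'
#' @param rec An [eeg_recording].
#' @param path Output file; extension does not matter, `format` decides.
#' @param format `"bdf"` (24-bit, BioSemi) or `"edf"` (16-bit).
#' @param physical_max Symmetric physical range in microvolts used for the
#'   integer scaling; samples outside it are clipped.
#' @param record_duration Data-record length in seconds; `rate *
#'   record_duration` must be an integer.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path, format = c("bdf", "edf"),
                      physical_max = 3000, record_duration = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  ns <- length(rec$labels)
  spr <- rec$rate * record_duration          # samples per record per channel
  if (abs(spr - round(spr)) > 1e-9) {
    stop("rate * record_duration must be an integer number of samples")
  }
  spr <- as.integer(round(spr))
  n <- ncol(rec$data)
  nrec <- n %/% spr
  if (nrec < 1L) stop("recording shorter than one data record")
  if (n %% spr != 0L) {
    warning("dropping ", n %% spr, " trailing samples that do not fill a record")
  }

  dig_max <- if (format == "bdf") 8388607L else 32767L
  con <- file(path, "wb")
  on.exit(close(con))

  version_bytes <- if (format == "bdf") {
    as.raw(c(0xff, charToRaw(edf_pad("BIOSEMI", 7))))
  } else {
    charToRaw(edf_pad("0", 8))
  }
  writeBin(version_bytes, con)
  writeChar(edf_pad("vimsnet synthetic subject", 80), con, 80, eos = NULL)
  writeChar(edf_pad("vimsnet recording", 80), con, 80, eos = NULL)
  writeChar(edf_pad("01.01.00", 8), con, 8, eos = NULL)
  writeChar(edf_pad("00.00.00", 8), con, 8, eos = NULL)
  writeChar(edf_pad(256L * (ns + 1L), 8), con, 8, eos = NULL)
  reserved <- if (format == "bdf") "24BIT" else ""
  writeChar(edf_pad(reserved, 44), con, 44, eos = NULL)
  writeChar(edf_pad(nrec, 8), con, 8, eos = NULL)
  writeChar(edf_pad(format(record_duration), 8), con, 8, eos = NULL)
  writeChar(edf_pad(ns, 4), con, 4, eos = NULL)

  field <- function(values, width) {
    for (v in values) writeChar(edf_pad(v, width), con, width, eos = NULL)
  }
  field(rec$labels, 16)                                  # labels
  field(rep("active electrode", ns), 80)                 # transducer
  field(rep("uV", ns), 8)                                # physical dimension
  field(rep(format(-physical_max), ns), 8)               # physical min
  field(rep(format(physical_max), ns), 8)                # physical max
  field(rep(format(-dig_max - 1L), ns), 8)               # digital min
  field(rep(format(dig_max), ns), 8)                     # digital max
  field(rep("", ns), 80)                                 # prefiltering
  field(rep(format(spr), ns), 8)                         # samples per record
  field(rep("", ns), 32)                                 # reserved

  scale <- (2L * dig_max + 1L) / (2 * physical_max)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    block <- rec$data[, idx, drop = FALSE]
    dig <- round(block * scale)
    dig <- pmin(pmax(dig, -dig_max - 1L), dig_max)
    dig <- as.integer(t(dig))       # channel-major within the record
    if (format == "edf") {
      writeBin(dig, con, size = 2L, endian = "little")
    } else {
      neg <- dig < 0L
      u <- ifelse(neg, dig + 16777216, dig)   # two's complement, 24 bit
      bytes <- raw(3L * length(u))
      bytes[seq(1L, length(bytes), 3L)] <- as.raw(u %% 256L)
      bytes[seq(2L, length(bytes), 3L)] <- as.raw((u %/% 256L) %% 256L)
      bytes[seq(3L, length(bytes), 3L)] <- as.raw(u %/% 65536L)
      writeBin(bytes, con)
    }
  }
  invisible(path)
}

#' Read an EDF or BDF file
#'
#' @param path File written by [write_eeg()] or any continuous equal-rate
#'   EDF/BDF recording.
#' @return An [eeg_recording] with physical-unit samples.
#' @export
read_eeg <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "raw", 1L)
  magic <- rawToChar(readBin(con, "raw", 7L))
  format <- if (first == as.raw(0xff) && magic == "BIOSEMI") "bdf" else "edf"
  txt <- function(nchars) trimws(rawToChar(readBin(con, "raw", nchars)))
  invisible(txt(80 + 80 + 8 + 8))          # patient/recording/date/time
  invisible(txt(8))                        # header length
  invisible(txt(44))
  nrec <- as.integer(txt(8))
  rec_dur <- as.numeric(txt(8))
  ns <- as.integer(txt(4))

  fields <- function(width) {
    vapply(seq_len(ns), function(i) txt(width), character(1))
  }
  labels <- fields(16)
  invisible(fields(80)); invisible(fields(8))
  phys_min <- as.numeric(fields(8)); phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8)); dig_max <- as.numeric(fields(8))
  invisible(fields(80))
  spr <- as.integer(fields(8))
  invisible(fields(32))
  if (length(unique(spr)) != 1L) stop("channels with unequal rates are not supported")
  spr <- spr[1]
  rate <- spr / rec_dur

  n_total <- nrec * spr
  data <- matrix(0, ns, n_total)
  for (r in seq_len(nrec)) {
    if (format == "edf") {
      dig <- readBin(con, "integer", ns * spr, size = 2L, signed = TRUE,
                     endian = "little")
    } else {
      bytes <- as.integer(readBin(con, "raw", 3L * ns * spr))
      u <- bytes[seq(1L, length(bytes), 3L)] +
        256 * bytes[seq(2L, length(bytes), 3L)] +
        65536 * bytes[seq(3L, length(bytes), 3L)]
      dig <- ifelse(u >= 8388608, u - 16777216, u)
    }
    block <- matrix(dig, nrow = spr, ncol = ns)   # channel-major on disk
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    data[, idx] <- t(block)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_max - gain * dig_max
  data <- data * gain + offset
  eeg_recording(data, rate, labels)
}

#' Read or write a state-timestamp sidecar
#'
#' Plain-text (tab-separated) sidecar giving, per subject, the resting-block
#' start and the oral report times of light and heavy sickness, in seconds
#' from recording onset.  Columns: `subject`, `rest_start`, `t_light`,
#' `t_heavy`.
#'
#' @param path File path.
#' @param events Data frame with the four columns above (for writing).
#' @return For `read_state_events`, the data frame.
#' @export
read_state_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "rest_start", "t_light", "t_heavy")
  if (!all(need %in% names(ev))) {
    stop("sidecar must have columns: ", paste(need, collapse = ", "))
  }
  ev
}

#' @rdname read_state_events
#' @export
write_state_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
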