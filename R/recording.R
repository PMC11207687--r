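#' Multichannel EEG recording
#'
#' Lightweight container for a channels-by-samples EEG array with its
#' sampling rate, channel labels and scalp-region assignment.  All
#' preprocessing and connectivity functions in this package consume and
#' return `eeg_recording` objects; channel order is frozen at construction
#' and preserved by every operation, so a row index means the same electrode
#' throughout a pipeline run.
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param rate Sampling rate in Hz.
#' @param labels Character vector of unique channel names, one per row.
#' @param regions Optional named character vector mapping channel name to one
#'   of `"frontal"`, `"temporal"`, `"central"`, `"parietal"`, `"occipital"`.
#'   Defaults to the BioSemi 10-20 assignment in [biosemi64_montage] for
#'   labels found there.
#' @return An `eeg_recording` object.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(4 * 100), 4), rate = 100,
#'                      labels = c("Fz", "Cz", "Pz", "Oz"))
#' rec
#' @export
eeg_recording <- function(data, rate, labels, regions = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  labels <- as.character(labels)
  if (nrow(data) != length(labels)) {
    stop("data has ", nrow(data), " rows but ", length(labels), " labels")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number")
  }
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  if (is.null(regions)) {
    regions <- stats::setNames(
      biosemi64_montage$region[match(labels, biosemi64_montage$label)], labels)
  } else {
    regions <- regions[labels]
  }
  rownames(data) <- labels
  structure(list(data = data, rate = as.numeric(rate), labels = labels,
                 regions = regions),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  cat("channels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "...", "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

# replace the sample array, keeping labels/rate metadata consistent
replace_data <- function(rec, data, rate = rec$rate) {
  rec$data <- data
  rec$rate <- rate
  rownames(rec$data) <- rec$labels
  rec
}

#' BioSemi 64-channel 10-20 montage with scalp regions
#'
#' The standard BioSemi 64-electrode layout under 10-20 naming, each channel
#' assigned to one of five scalp regions (frontal, temporal, central,
#' parietal, occipital).  [vims_channels] is the 52-channel working montage
#' obtained by dropping the twelve conventionally noisy electrodes.
#'
#' @format Data frame with columns `label` and `region`.
#' @export
biosemi64_montage <- local({
  reg <- function(labels, region) data.frame(label = labels, region = region)
  rbind(
    reg(c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
          "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"), "frontal"),
    reg(c("FT7", "FT8", "T7", "T8", "TP7", "TP8"), "temporal"),
    reg(c("FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
          "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
          "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6"), "central"),
    reg(c("P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10"),
        "parietal"),
    reg(c("PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "Iz"),
        "occipital"))
})

#' Channels excluded from the working montage
#'
#' The twelve electrodes dropped for poor signal quality, leaving the
#' 52-channel montage every connectivity matrix in this package indexes.
#' @export
excluded_channels <- c("PO4", "O2", "PO8", "P10", "TP8", "F6",
                       "Fp2", "Fpz", "POz", "P2", "P1", "PO3")

#' @rdname biosemi64_montage
#' @export
vims_channels <- biosemi64_montage[
  !biosemi64_montage$label %in% excluded_channels, , drop = FALSE]

#' Canonical EEG frequency bands
#'
#' The six analysis bands: delta 0.5-4, theta 4-8, alpha 8-14, beta 15-30,
#' gamma 30-45 and full 0.5-45 Hz.
#'
#' @param name Optional band names to select.
#' @return Data frame with columns `name`, `lo`, `hi` (Hz).
#' @examples
#' eeg_bands()
#' eeg_bands("gamma")
#' @export
eeg_bands <- function(name = NULL) {
  bands <- data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma", "full"),
    lo = c(0.5, 4, 8, 15, 30, 0.5),
    hi = c(4, 8, 14, 30, 45, 45))
  if (is.null(name)) return(bands)
  idx <- match(name, bands$name)
  if (anyNA(idx)) stop("unknown band: ", paste(name[is.na(idx)], collapse = ", "))
  bands[idx, , drop = FALSE]
}
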