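# Preprocessing chain: channel exclusion -> band-pass -> notch -> downsample
# -> average re-reference -> band decomposition.  Filters are always applied
# to whole recordings, never to 3-s segments, so segment edges carry no
# filter transients.

#' Drop named channels from a recording
#'
#' @param rec An [eeg_recording].
#' @param bad Character vector of channel names to remove (may be empty).
#' @return The recording without the named channels; survivor order is
#'   unchanged.
#' @examples
#' rec <- eeg_recording(matrix(0, 3, 10), 100, c("A", "B", "C"))
#' exclude_channels(rec, "B")$labels
#' @export
exclude_channels <- function(rec, bad) {
  stopifnot(inherits(rec, "eeg_recording"))
  bad <- as.character(bad)
  if (length(bad) == 0L) return(rec)
  unknown <- setdiff(bad, rec$labels)
  if (length(unknown)) {
    stop("channel(s) not present in recording: ",
         paste(unknown, collapse = ", "))
  }
  keep <- !(rec$labels %in% bad)
  eeg_recording(rec$data[keep, , drop = FALSE], rec$rate, rec$labels[keep],
                rec$regions[keep])
}

apply_filter <- function(rec, filt) {
  replace_data(rec, sos_filtfilt(filt, rec$data))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-4 Butterworth prototype applied forward and backward per channel
#' (zero net phase shift -- a requirement for downstream phase statistics).
#'
#' @param rec An [eeg_recording].
#' @param lo,hi Band edges in Hz; `hi` must be below Nyquist.
#' @param order Prototype order (even).
#' @return Filtered recording, same length.
#' @export
bandpass_filter <- function(rec, lo, hi, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"), lo > 0, hi > lo)
  if (hi >= rec$rate / 2) {
    stop("upper band edge ", hi, " Hz is not below the Nyquist frequency ",
         rec$rate / 2, " Hz")
  }
  apply_filter(rec, butter_sos(order, c(lo, hi), rec$rate, "pass"))
}

#' Zero-phase Butterworth band-stop (notch) filter
#'
#' Default 49-51 Hz, suppressing mains interference.
#'
#' @inheritParams bandpass_filter
#' @export
notch_filter <- function(rec, lo = 49, hi = 51, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"), lo > 0, hi > lo)
  if (hi >= rec$rate / 2) {
    stop("upper band edge ", hi, " Hz is not below the Nyquist frequency ",
         rec$rate / 2, " Hz")
  }
  apply_filter(rec, butter_sos(order, c(lo, hi), rec$rate, "stop"))
}

#' Downsample by an integer factor
#'
#' Anti-alias low-pass (zero-phase Butterworth, cutoff at 0.9 of the target
#' Nyquist) followed by decimation.  Only integer rate ratios are supported;
#' the acquisition-to-analysis step here is 2048 to 1024 Hz, factor 2.
#'
#' @param rec An [eeg_recording].
#' @param target_rate Desired rate in Hz; `rec$rate` must be an integer
#'   multiple of it.
#' @param order Anti-alias filter prototype order.
#' @return Recording at `target_rate` with `floor(n * target/rate)` samples.
#' @export
downsample <- function(rec, target_rate = 1024, order = 8L) {
  stopifnot(inherits(rec, "eeg_recording"), target_rate > 0)
  ratio <- rec$rate / target_rate
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
    stop("rate ", rec$rate, " Hz is not an integer multiple of the target ",
         target_rate, " Hz")
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(rec)
  filt <- butter_sos(order, 0.9 * target_rate / 2, rec$rate, "low")
  keep <- seq(1L, ncol(rec$data), by = ratio)
  out <- sos_filtfilt(filt, rec$data)[, keep, drop = FALSE]
  replace_data(rec, out, rate = target_rate)
}

#' Re-reference to the whole-brain average
#'
#' Subtracts the across-channel mean at every sample, so each output sample
#' vector sums to zero.  Idempotent.
#'
#' @param rec An [eeg_recording].
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  replace_data(rec, sweep(rec$data, 2L, colMeans(rec$data)))
}

#' Split a recording into frequency bands
#'
#' One zero-phase band-pass per requested band.  The `full` band (0.5-45 Hz)
#' is the same filter as the broadband preprocessing pass.
#'
#' @param rec An [eeg_recording].
#' @param bands Data frame with columns `name`, `lo`, `hi` as returned by
#'   [eeg_bands()].
#' @return Named list of band-filtered recordings.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 2048), 2), 1024, c("C3", "C4"))
#' names(band_decompose(rec, eeg_bands(c("alpha", "gamma"))))
#' @export
band_decompose <- function(rec, bands = eeg_bands()) {
  stopifnot(inherits(rec, "eeg_recording"),
            all(c("name", "lo", "hi") %in% names(bands)))
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (i in seq_len(nrow(bands))) {
    out[[i]] <- bandpass_filter(rec, bands$lo[i], bands$hi[i])
  }
  out
}

#' Artifact-removal hook
#'
#' Placeholder for ICA-based EMG/EOG artifact removal.  The synthetic data
#' this package generates carries no such artifacts, so the default method is
#' the identity; the generic exists so a real-data workflow can plug a
#' decomposition in without touching the rest of the pipeline.
#'
#' @param rec An [eeg_recording].
#' @param method Only `"none"` is implemented.
#' @export
remove_artifacts <- function(rec, method = "none") {
  stopifnot(inherits(rec, "eeg_recording"))
  method <- match.arg(method)
  rec
}

#' Standard preprocessing chain
#'
#' Channel exclusion, 0.5-45 Hz band-pass, 49-51 Hz notch, downsampling to
#' 1024 Hz and average re-referencing, in that order.
#'
#' @param rec Raw [eeg_recording].
#' @param exclude Channel names to drop (default [excluded_channels] when all
#'   are present, otherwise none).
#' @param target_rate Analysis rate in Hz.
#' @param bp Band-pass edges in Hz.
#' @param notch Notch edges in Hz.
#' @return Preprocessed recording (not yet band-decomposed).
#' @export
preprocess_recording <- function(rec, exclude = NULL, target_rate = 1024,
                                 bp = c(0.5, 45), notch = c(49, 51)) {
  if (is.null(exclude)) {
    exclude <- intersect(excluded_channels, rec$labels)
  }
  rec <- exclude_channels(rec, exclude)
  rec <- bandpass_filter(rec, bp[1], bp[2])
  rec <- notch_filter(rec, notch[1], notch[2])
  rec <- downsample(rec, target_rate)
  rec <- remove_artifacts(rec)
  rereference_average(rec)
}
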