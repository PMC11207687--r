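# State-window extraction, segmentation and instantaneous phase.

#' Locate the three VIMS state windows in a recording
#'
#' Each analysis window is exactly 60 s: `VIMS_0` is the first 60 s of the
#' resting block, `VIMS_1` straddles the light-sickness report (30 s either
#' side), and `VIMS_2` is the 60 s immediately before the heavy-sickness
#' report (the session stops at that report).
#'
#' @param rec An [eeg_recording].
#' @param rest_start Resting-block onset in seconds.
#' @param t_light,t_heavy Oral report times in seconds.
#' @param duration Window length in seconds.
#' @return A `state_windows` object: named list of `c(start, end)` sample
#'   indices (1-based, end inclusive) for `VIMS_0`, `VIMS_1`, `VIMS_2`.
#' @examples
#' rec <- eeg_recording(matrix(0, 1, 500 * 64), 64, "Cz")
#' extract_state_windows(rec, rest_start = 0, t_light = 300, t_heavy = 400)
#' @export
extract_state_windows <- function(rec, rest_start, t_light, t_heavy,
                                  duration = 60) {
  stopifnot(inherits(rec, "eeg_recording"))
  rate <- rec$rate
  n <- ncol(rec$data)
  half <- duration / 2
  spans <- list(
    VIMS_0 = c(rest_start, rest_start + duration),
    VIMS_1 = c(t_light - half, t_light + half),
    VIMS_2 = c(t_heavy - duration, t_heavy))
  win <- lapply(names(spans), function(state) {
    s <- spans[[state]]
    start <- round(s[1] * rate) + 1L
    end <- start + as.integer(round(duration * rate)) - 1L
    if (start < 1L || end > n) {
      stop("state window for ", state, " [", s[1], ", ", s[2],
           "] s falls outside the recording (0-", n / rate, " s)")
    }
    c(start = start, end = end)
  })
  names(win) <- names(spans)
  if (t_heavy - t_light < half) {
    message("VIMS_1 and VIMS_2 windows overlap (reports ",
            t_heavy - t_light, " s apart)")
  }
  structure(win, class = "state_windows", rate = rate)
}

#' Cut a window into fixed-length non-overlapping segments
#'
#' @param x Channels x samples matrix (or an [eeg_recording]).
#' @param rate Sampling rate in Hz (taken from the recording if given one).
#' @param win_len Segment length in seconds (default 3 s, giving 20 segments
#'   per 60-s state window).
#' @return List of channels x `win_len * rate` matrices in temporal order;
#'   a trailing remainder shorter than `win_len` is discarded.
#' @examples
#' segs <- segment_window(matrix(rnorm(2 * 7 * 10), 2), rate = 10, win_len = 3)
#' length(segs)   # 2: the trailing 1 s is dropped
#' @export
segment_window <- function(x, rate = NULL, win_len = 3) {
  if (inherits(x, "eeg_recording")) {
    rate <- x$rate
    x <- x$data
  }
  stopifnot(is.matrix(x), !is.null(rate), win_len > 0)
  len <- as.integer(round(win_len * rate))
  nseg <- ncol(x) %/% len
  if (nseg == 0L) return(list())
  lapply(seq_len(nseg), function(i) {
    x[, ((i - 1L) * len + 1L):(i * len), drop = FALSE]
  })
}

# analytic signal of one real vector via the frequency-domain construction
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of each channel
#'
#' Phase of the analytic (Hilbert-transform) signal, wrapped to (-pi, pi].
#' Input channels are expected to be narrowband (band-pass filtered); on a
#' broadband channel the analytic phase is still defined but not readily
#' interpretable.  The circular FFT construction leaks over roughly the
#' first and last tenth of a second, so phase should be extracted over
#' whole state windows and segmented afterwards (as [session_plv()] does)
#' rather than per 3-s segment.  An identically-zero channel has no phase;
#' it is returned as all zeros with a warning.
#'
#' @param x Channels x samples matrix or [eeg_recording].
#' @param rate Sampling rate (only used for the returned metadata).
#' @return A `phase_series` object: list with `phase` (radians, channels x
#'   samples) and `rate`.
#' @export
instantaneous_phase <- function(x, rate = NULL) {
  if (inherits(x, "eeg_recording")) {
    rate <- x$rate
    x <- x$data
  }
  stopifnot(is.matrix(x))
  zero_rows <- which(apply(x, 1L, function(r) all(r == 0)))
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  analytic <- stats::mvfft(stats::mvfft(t(x)) * h, inverse = TRUE) / n
  ph <- t(Arg(analytic))
  if (length(zero_rows)) {
    warning("channel(s) ", paste(zero_rows, collapse = ", "),
            " are identically zero; their phase is defined as 0")
    ph[zero_rows, ] <- 0
  }
  # Arg() yields [-pi, pi]; fold -pi onto +pi for the (-pi, pi] convention
  ph[ph == -pi] <- pi
  structure(list(phase = ph, rate = rate), class = "phase_series")
}
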