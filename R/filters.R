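# Zero-phase Butterworth filtering in second-order sections.
#
# Transfer-function (b, a) Butterworth designs are numerically fragile for
# the band edges EEG work needs (0.5 Hz at 1-2 kHz sampling puts poles within
# 1e-3 of the unit circle, and the expanded polynomial form pushes them
# outside in double precision).  The cascade-of-biquads form below stays
# stable for every band this package uses.

#' Design a Butterworth filter as second-order sections
#'
#' Builds an order-`n` Butterworth prototype, applies the analog band
#' transform, and maps it to the digital domain with the bilinear transform,
#' keeping the result as a cascade of biquads rather than one expanded
#' polynomial.
#'
#' @param order Prototype order; must be even (each transformed conjugate
#'   pole pair becomes one biquad).
#' @param w Corner frequency in Hz (`low`/`high`) or length-2 band edges
#'   (`pass`/`stop`).
#' @param rate Sampling rate in Hz.
#' @param type One of `"low"`, `"high"`, `"pass"`, `"stop"`.
#' @return A `butter_sos` object: list with `sos` (sections x 6 matrix of
#'   `b0 b1 b2 a0 a1 a2` rows), plus the design parameters.
#' @keywords internal
butter_sos <- function(order, w, rate, type = c("low", "high", "pass", "stop")) {
  type <- match.arg(type)
  stopifnot(order >= 2, order %% 2 == 0, rate > 0, all(w > 0))
  nyq <- rate / 2
  if (any(w >= nyq)) {
    stop("filter corner frequency (", paste(w, collapse = "-"),
         " Hz) must lie below the Nyquist frequency ", nyq, " Hz")
  }
  if (type %in% c("pass", "stop")) {
    stopifnot(length(w) == 2L, w[1] < w[2])
  } else {
    stopifnot(length(w) == 1L)
  }

  fs2 <- 2 * rate
  wa <- fs2 * tan(pi * w / rate)          # prewarped analog frequencies
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LHP poles

  if (type == "low") {
    poles <- proto * wa
    zero_b <- c(1, 2, 1)                  # zeros at z = -1
  } else if (type == "high") {
    poles <- wa / proto
    zero_b <- c(1, -2, 1)                 # zeros at z = +1
  } else {
    w0 <- sqrt(wa[1] * wa[2])
    bw <- wa[2] - wa[1]
    if (type == "pass") {
      # s -> (s^2 + w0^2) / (bw * s): each prototype pole splits in two
      disc <- sqrt((proto * bw)^2 / 4 - w0^2 + 0i)
      poles <- c(proto * bw / 2 + disc, proto * bw / 2 - disc)
      zero_b <- c(1, 0, -1)               # one zero at z = 1, one at z = -1
    } else {
      inv <- bw / proto
      disc <- sqrt(inv^2 / 4 - w0^2 + 0i)
      poles <- c(inv / 2 + disc, inv / 2 - disc)
      th0 <- 2 * atan(w0 / fs2)           # notch zeros e^{+-i th0}
      zero_b <- c(1, -2 * cos(th0), 1)
    }
  }

  zp <- (fs2 + poles) / (fs2 - poles)     # bilinear transform
  # keep one pole from each conjugate pair, ordered by |Im| for stable pairing
  zp <- zp[Im(zp) >= 0]
  zp <- zp[order(abs(Im(zp)), decreasing = TRUE)]
  nsec <- length(zp)
  sos <- matrix(0, nsec, 6)
  for (s in seq_len(nsec)) {
    p <- zp[s]
    sos[s, ] <- c(zero_b, 1, -2 * Re(p), Re(p)^2 + Im(p)^2)
  }

  # normalize overall gain at a reference frequency inside the passband
  fref <- switch(type,
    low = 0,
    stop = 0,
    high = nyq,
    pass = rate / pi * atan(sqrt(wa[1] * wa[2]) / fs2))
  zref <- exp(1i * 2 * pi * fref / rate)
  g <- prod(vapply(seq_len(nsec), function(s) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    abs(sum(b * zref^(0:-2)) / sum(a * zref^(0:-2)))
  }, numeric(1)))
  sos[1, 1:3] <- sos[1, 1:3] / g

  structure(list(sos = sos, order = order, w = w, rate = rate, type = type),
            class = "butter_sos")
}

# Single-pass cascade filtering of one signal through all sections.
sos_filter <- function(filt, x) {
  drop(sos_filter_rows(filt$sos, matrix(x, 1L)))
}

#' Zero-phase filtering through a biquad cascade
#'
#' Applies the cascade forward and backward so the net phase response is
#' zero, after padding both ends with an odd reflection long enough to absorb
#' the transient of the slowest pole (several seconds for a 0.5 Hz edge).
#'
#' @param filt A `butter_sos` design.
#' @param x Numeric vector (one channel) or channels x samples matrix; every
#'   row is filtered.
#' @return Filtered data with the input's shape.
#' @keywords internal
sos_filtfilt <- function(filt, x) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, 1L)
  n <- ncol(x)
  if (n < 4L) stop("signal too short to filter (", n, " samples)")
  lo_edge <- min(filt$w)
  pad <- min(n - 2L, as.integer(ceiling(6 * filt$rate / max(lo_edge, 1))) +
               12L * nrow(filt$sos))
  out <- sos_filtfilt_mat(filt$sos, x, pad)
  if (vec) drop(out) else out
}
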