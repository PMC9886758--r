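# FIR band-pass design and zero-phase application.
#
# Design: odd-length linear-phase FIR (Hamming window, signal::fir1), with
# the tap count chosen so the transition width is ~2 Hz at the given sampling
# rate, i.e. >= 40 dB attenuation 2 Hz outside the band edges. Applied by
# FFT-based linear convolution with the group delay removed, the symmetric
# impulse response makes the net filter zero-phase.

default_ntaps <- function(fs, transition_hz = 2) {
  # Hamming-window transition width ~ 3.3 / N (normalized frequency)
  n <- ceiling(3.3 * fs / transition_hz)
  if (n %% 2L == 0L) n <- n + 1L
  as.integer(n)
}

fir_bandpass <- function(fs, band, ntaps = NULL) {
  check_band(band, fs)
  if (is.null(ntaps)) ntaps <- default_ntaps(fs)
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  as.numeric(signal::fir1(ntaps - 1L, band / (fs / 2), type = "pass"))
}

check_band <- function(band, fs) {
  if (length(band) != 2L || !all(is.finite(band)) ||
      band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2)
    stop("band must satisfy 0 < low < high < fs/2")
  invisible(band)
}

# one epoch of a nodes x samples x epochs array, dims preserved
epoch_slab <- function(a, e) {
  m <- a[, , e, drop = FALSE]
  dim(m) <- dim(a)[1:2]
  m
}

# frequency response of the band filter on the n-point FFT grid
fir_response <- function(fs, band, nfft, ntaps = NULL) {
  h <- fir_bandpass(fs, band, ntaps)
  if (length(h) > nfft) stop("filter longer than the FFT grid")
  stats::fft(c(h, numeric(nfft - length(h))))
}

#' Zero-phase band-pass filtering of epoched series
#'
#' Filters every node and epoch with an odd-length linear-phase FIR
#' band-pass (Hamming window) applied by FFT convolution with the group
#' delay compensated, so the net response is zero-phase. The tap count
#' defaults to a ~2 Hz transition width (>= 40 dB stopband 2 Hz outside the
#' band at `fs` = 1000 Hz). Epoch padding, if present, absorbs the filter
#' edge effects and is removed later by [trim_padding()].
#'
#' @param series an `epoched_series`.
#' @param band `(low, high)` Hz; must lie strictly inside `(0, fs/2)`.
#' @param ntaps optional FIR length (forced odd).
#' @return The filtered `epoched_series`, with `band` recorded.
#' @examples
#' x <- epoched_series(matrix(sin(2 * pi * 20 * (0:999) / 250), 1), fs = 250)
#' y <- bandpass(x, c(12, 30), ntaps = 301)
#' @export
bandpass <- function(series, band, ntaps = NULL) {
  stopifnot(inherits(series, "epoched_series"))
  fs <- series$fs
  check_band(band, fs)
  h <- fir_bandpass(fs, band, ntaps)
  nt <- length(h)
  d <- dim(series$data)
  ns <- d[2]
  nfft <- stats::nextn(ns + nt - 1L, c(2, 3, 5))
  H <- stats::fft(c(h, numeric(nfft - nt)))
  delay <- (nt - 1L) %/% 2L
  out <- series$data
  for (e in seq_len(d[3])) {
    X <- t(epoch_slab(series$data, e))                 # samples x nodes
    Xp <- rbind(X, matrix(0, nfft - ns, d[1]))
    Y <- stats::mvfft(stats::mvfft(Xp) * H, inverse = TRUE) / nfft
    out[, , e] <- t(Re(Y[(delay + 1L):(delay + ns), , drop = FALSE]))
  }
  series$data <- out
  series$band <- band
  series
}

#' Instantaneous phase via the analytic signal
#'
#' Extracts the instantaneous phase of each node, sample and epoch as the
#' argument of the analytic signal `z(t) = x(t) + i H[x](t)`, computed by the
#' FFT Hilbert method per epoch. Input is assumed band-limited (by
#' convention; not checked).
#'
#' @param series an `epoched_series` with no NA values.
#' @return An object of class `phase_series`: list with `phase` (radians in
#'   `(-pi, pi]`, same dimensions as the data), `fs`, `band`, `pad_s`.
#' @export
instantaneous_phase <- function(series) {
  stopifnot(inherits(series, "epoched_series"))
  if (anyNA(series$data)) stop("NA in input series")
  d <- dim(series$data)
  ns <- d[2]
  mask <- numeric(ns)
  mask[1L] <- 1
  if (ns %% 2L == 0L) {
    mask[ns / 2L + 1L] <- 1
    if (ns > 2L) mask[2L:(ns / 2L)] <- 2
  } else {
    mask[2L:((ns + 1L) / 2L)] <- 2
  }
  ph <- array(0, d)
  for (e in seq_len(d[3])) {
    X <- t(epoch_slab(series$data, e))
    Z <- stats::mvfft(stats::mvfft(X) * mask, inverse = TRUE) / ns
    ph[, , e] <- t(Arg(Z))
  }
  structure(
    list(phase = ph, fs = series$fs, band = series$band,
         pad_s = series$pad_s),
    class = "phase_series"
  )
}

#' @export
print.phase_series <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf("phase_series: %d nodes x %d samples x %d epochs @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}
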