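#' Epoched source-space time series
#'
#' Container for per-subject source time series, `nodes x samples x epochs`.
#' Epochs may carry symmetric padding (`pad_s` seconds of real data at each
#' side) that is discarded after filtering and phase extraction, so that
#' filter and Hilbert edge artifacts never reach the analysis window.
#'
#' @param data numeric array `nodes x samples x epochs` (a matrix is treated
#'   as a single epoch).
#' @param fs sampling rate in Hz.
#' @param band optional `(low, high)` Hz label of the band the data are
#'   limited to, or `NULL` for broadband.
#' @param pad_s seconds of padding at each side of every epoch.
#' @return An object of class `epoched_series`.
#' @export
epoched_series <- function(data, fs, band = NULL, pad_s = 0) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L, fs > 0, pad_s >= 0)
  if (anyNA(data) || any(!is.finite(data)))
    stop("series contains NA or non-finite values")
  if (2 * pad_s * fs >= dim(data)[2])
    stop("padding longer than the epoch itself")
  structure(
    list(data = data, fs = fs, band = band, pad_s = pad_s),
    class = "epoched_series"
  )
}

#' @export
print.epoched_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "epoched_series: %d nodes x %d samples x %d epochs @ %g Hz%s%s\n",
    d[1], d[2], d[3], x$fs,
    if (is.null(x$band)) " (broadband)"
    else sprintf(" [%g-%g Hz]", x$band[1], x$band[2]),
    if (x$pad_s > 0) sprintf(", %g s padding/side", x$pad_s) else ""
  ))
  invisible(x)
}

#' Remove epoch padding
#'
#' Drops `pad_s` seconds from each side of every epoch of an
#' `epoched_series` or `phase_series`.
#'
#' @param x an `epoched_series` or `phase_series`.
#' @return The trimmed object with `pad_s = 0`.
#' @export
trim_padding <- function(x) {
  UseMethod("trim_padding")
}

#' @export
trim_padding.epoched_series <- function(x) {
  x$data <- trim_array(x$data, x$fs, x$pad_s)
  x$pad_s <- 0
  x
}

#' @export
trim_padding.phase_series <- function(x) {
  x$phase <- trim_array(x$phase, x$fs, x$pad_s)
  x$pad_s <- 0
  x
}

trim_array <- function(a, fs, pad_s) {
  if (pad_s == 0) return(a)
  np <- round(pad_s * fs)
  keep <- (np + 1L):(dim(a)[2] - np)
  a[, keep, , drop = FALSE]
}
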