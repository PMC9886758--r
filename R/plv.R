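#' Phase locking value of a pair of phase series
#'
#' `PLV = |(1/M) sum_m exp(i (phi_j(t_m) - phi_k(t_m)))|`: the modulus of
#' the time-averaged unit phasor of the phase difference. 1 means a perfectly
#' constant phase relation, values near zero mean no consistent relation
#' (for `n` independent uniform phase differences the expectation is
#' `sqrt(pi) / (2 sqrt(n))`).
#'
#' @param phase_j,phase_k numeric vectors of phases in radians, equal length
#'   `n >= 2`.
#' @return A scalar in `[0, 1]`.
#' @examples
#' t <- seq(0, 1, length.out = 500)
#' plv_pair(2 * pi * 10 * t, 2 * pi * 10 * t + 1.2)  # constant offset -> 1
#' @export
plv_pair <- function(phase_j, phase_k) {
  if (length(phase_j) != length(phase_k))
    stop("phase series must have equal length")
  if (length(phase_j) < 2L) stop("need at least 2 samples")
  Mod(mean(exp(1i * (phase_j - phase_k))))
}

#' Epoch-averaged PLV matrix
#'
#' Computes the PLV between every pair of nodes over the within-epoch
#' samples, then averages the per-epoch matrices arithmetically across
#' epochs for a more robust resting-state estimate. The diagonal is set to 1
#' for display; it is excluded from all strength computations.
#'
#' @param phases a `phase_series` (or a `nodes x samples x epochs` array of
#'   phases in radians) with at least 2 nodes.
#' @return Symmetric `nodes x nodes` matrix of PLV values in `[0, 1]`.
#' @export
plv_matrix <- function(phases) {
  ph <- if (inherits(phases, "phase_series")) phases$phase else phases
  if (is.matrix(ph)) ph <- array(ph, c(dim(ph), 1L))
  stopifnot(is.array(ph), length(dim(ph)) == 3L)
  d <- dim(ph)
  if (d[1] < 2L) stop("need at least 2 nodes to form pairs")
  if (d[2] < 2L) stop("need at least 2 samples per epoch")
  acc <- matrix(0, d[1], d[1])
  for (e in seq_len(d[3])) {
    U <- exp(1i * t(ph[, , e, drop = FALSE][, , 1L]))   # samples x nodes
    acc <- acc + Mod(crossprod(Conj(U), U)) / d[2]
  }
  P <- acc / d[3]
  P <- (P + t(P)) / 2          # enforce exact symmetry
  P[P > 1] <- 1                # clip numerical overshoot at 1 + eps
  diag(P) <- 1
  P
}

#' Normalized nodal strength
#'
#' Per-node mean functional connectivity: the sum of a node's links divided
#' by the number of links, `strength(j) = sum_{k != j} plv(j, k) / (N - 1)`.
#' The diagonal is excluded.
#'
#' @param plv symmetric matrix with values in `[0, 1]`, `N >= 2`.
#' @return Numeric vector of per-node strengths in `[0, 1]`.
#' @export
nodal_strength <- function(plv) {
  stopifnot(is.matrix(plv))
  n <- nrow(plv)
  if (n < 2L || ncol(plv) != n) stop("plv must be square with N >= 2")
  if (!isTRUE(all.equal(plv, t(plv), tolerance = 1e-8)))
    stop("plv must be symmetric")
  if (min(plv) < -1e-8 || max(plv) > 1 + 1e-8)
    stop("plv values must lie in [0, 1]")
  (rowSums(plv) - diag(plv)) / (n - 1)
}

#' Band-limited PLV connectivity of one subject
#'
#' Convenience wrapper running the full connectivity chain: zero-phase
#' band-pass filter, analytic-signal phase extraction, removal of the epoch
#' padding, epoch-averaged PLV matrix and normalized nodal strength.
#'
#' @param series an `epoched_series` (broadband or already band-limited).
#' @param band `(low, high)` Hz; default beta, 12-30 Hz.
#' @param ntaps optional FIR length passed to [bandpass()].
#' @return An object of class `plv_connectivity`: list with `plv`,
#'   `strength`, `band`, `fs`.
#' @export
connectivity <- function(series, band = c(12, 30), ntaps = NULL) {
  stopifnot(inherits(series, "epoched_series"))
  filt <- bandpass(series, band, ntaps = ntaps)
  ph <- trim_padding(instantaneous_phase(filt))
  P <- plv_matrix(ph)
  structure(
    list(plv = P, strength = nodal_strength(P), band = band, fs = series$fs),
    class = "plv_connectivity"
  )
}

#' @export
print.plv_connectivity <- function(x, ...) {
  cat(sprintf(
    "plv_connectivity: %d nodes [%g-%g Hz], mean strength %.3f\n",
    nrow(x$plv), x$band[1], x$band[2], mean(x$strength)
  ))
  invisible(x)
}
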