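# Independent oracles used across the suite; deliberately written with
# different algorithms than the package internals.

# Benjamini-Hochberg step-up, literal textbook form
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- (m / seq_len(m)) * p[o]
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# connected components by label propagation on the induced subgraph
# (iterate minimum-label exchange to a fixed point)
components_oracle <- function(nodes, adjacency) {
  if (!length(nodes)) return(list())
  lab <- stats::setNames(nodes, nodes)
  repeat {
    changed <- FALSE
    for (v in nodes) {
      nb <- intersect(adjacency[[v]], nodes)
      if (length(nb)) {
        m <- min(lab[as.character(c(v, nb))])
        if (m < lab[as.character(v)]) {
          lab[as.character(v)] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  unname(lapply(split(nodes, lab), sort))
}

# covariate-adjusted Spearman via explicit regression residuals on ranks
partial_spearman_oracle <- function(x, y, covariates) {
  rx <- rank(x)
  ry <- rank(y)
  RC <- apply(as.matrix(covariates), 2, rank)
  ex <- stats::residuals(stats::lm(rx ~ RC))
  ey <- stats::residuals(stats::lm(ry ~ RC))
  r <- stats::cor(ex, ey)
  df <- length(x) - 2 - ncol(as.matrix(covariates))
  tval <- r * sqrt(df / (1 - r^2))
  list(rho = r, p = 2 * stats::pt(-abs(tval), df))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small helper: a padded sinusoidal epoched series
sinusoid_series <- function(freq, fs = 1000, epoch_len = 4, pad_s = 2,
                            phase = 0, nodes = 1) {
  tt <- (seq_len(fs * (epoch_len + 2 * pad_s)) - 1) / fs
  x <- sin(2 * pi * freq * tt + phase)
  epoched_series(matrix(rep(x, nodes), nodes, byrow = TRUE), fs = fs,
                 pad_s = pad_s)
}

# analytic-signal unit phasors drawn uniformly; for null PLV checks
runif_phase <- function(n) stats::runif(n, -pi, pi)
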