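# Synthetic cohort generator.
#
# Sources are narrow-band Gaussian processes: each node (and a shared
# "driver") gets an independent complex-Gaussian spectrum shaped by the
# frequency response of the same FIR band-pass used in the connectivity
# stage, on the FFT grid of the padded epoch. This is identical in
# distribution to filtering white Gaussian noise with that FIR, and lets
# the analytic signal (hence the instantaneous phase) be synthesized
# directly as a matrix product. Nodes belonging to the planted cluster mix
# the shared driver in linearly: x = (1 - c) * noise + c * driver, so the
# within-cluster phase locking is a monotone function of the coupling c
# (c = 0: independent; c = 1: identical signals, PLV = 1).

#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort generator. Defaults emulate
#' the study conditions of a large ageing MEG cohort: a 1 cm source grid
#' with 1202 nodes in 78 regions, 4 s epochs at 1000 Hz padded by 2 s of
#' real data per side, the beta band (12-30 Hz), group sizes 261 cognitively
#' intact (CI) vs 118 mild cognitive impairment (MCI), a negative
#' connectivity-to-recall slope of paper-like magnitude (marker-behaviour
#' correlations around -0.2 to -0.3), and an APOE-carrier moderation planted
#' in the CI group only.
#'
#' @param n_nodes,n_regions,spacing source-grid geometry (see [make_grid()]).
#' @param fs sampling rate, Hz.
#' @param epoch_len analysis epoch length, seconds.
#' @param pad_s padding per side, seconds of real signal.
#' @param n_epochs epochs per subject.
#' @param band `(low, high)` Hz of the oscillatory sources.
#' @param coupling scalar in `[0, 1]`: shared-driver mixing weight used by
#'   [simulate_sources()] for a single subject.
#' @param coupling_range range from which per-subject couplings are drawn
#'   uniformly by [simulate_cohort()], so realized cluster strength varies
#'   across subjects.
#' @param cluster_nodes integer node ids of the planted phase-coupled
#'   cluster; `NULL` plants a contiguous 15-node blob at the start of the
#'   lattice order.
#' @param effect_beta slope of delayed recall on realized cluster strength
#'   (negative: hypersynchronization predicts worse recall).
#' @param b2 main effect of APOE-e4 carriage on recall.
#' @param moderation_b3 carrier-by-strength interaction slope.
#' @param moderation_groups diagnostic groups in which the interaction is
#'   planted (default CI only).
#' @param gamma_age slope of recall on (age - 68) years.
#' @param noise_sd residual SD of the recall score.
#' @param recall_intercepts per-group intercepts of the recall model.
#' @param group_sizes named vector `c(CI = , MCI = )`.
#' @param carrier_fraction probability of APOE-e4 carriage.
#' @param carrier_counts optional exact per-group carrier counts; must not
#'   exceed the group sizes.
#' @param rare_genotype_fraction fraction of subjects assigned an e2-bearing
#'   genotype; such rows are excluded from moderation fits (see
#'   [drop_rare_genotypes()]). Default 0: the cohort emulates a final sample
#'   from which rare genotypes were already excluded.
#' @param structural_lambda standardized loading (`<= 0`) of structural
#'   measures on cluster strength, emulating negative structure-function
#'   associations.
#' @param null_mode if `TRUE`, zeroes `effect_beta`, `b2` and
#'   `moderation_b3` (behaviour independent of connectivity).
#' @param ntaps optional FIR length used to shape the source spectra.
#' @param seed integer RNG seed; identical configs give byte-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_nodes = 1202, n_regions = 78, spacing = 1,
                       fs = 1000, epoch_len = 4, pad_s = 2, n_epochs = 2,
                       band = c(12, 30),
                       coupling = 0.5, coupling_range = c(0.2, 0.8),
                       cluster_nodes = NULL,
                       effect_beta = -50, b2 = -5, moderation_b3 = -30,
                       moderation_groups = "CI",
                       gamma_age = -0.4, noise_sd = 10,
                       recall_intercepts = c(CI = 65, MCI = 28),
                       group_sizes = c(CI = 261, MCI = 118),
                       carrier_fraction = 0.3, carrier_counts = NULL,
                       rare_genotype_fraction = 0,
                       structural_lambda = -0.25,
                       null_mode = FALSE,
                       ntaps = NULL, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$coupling < 0 || cfg$coupling > 1)
    stop("coupling must lie in [0, 1]")
  if (any(cfg$coupling_range < 0) || any(cfg$coupling_range > 1) ||
      cfg$coupling_range[1] > cfg$coupling_range[2])
    stop("coupling_range must be an ordered subinterval of [0, 1]")
  check_band(cfg$band, cfg$fs)
  if (any(cfg$group_sizes <= 0)) stop("group sizes must be positive")
  if (is.null(names(cfg$group_sizes))) names(cfg$group_sizes) <- c("CI", "MCI")
  if (cfg$carrier_fraction < 0 || cfg$carrier_fraction > 1)
    stop("carrier_fraction must lie in [0, 1]")
  if (!is.null(cfg$carrier_counts) &&
      any(cfg$carrier_counts > cfg$group_sizes))
    stop("carrier_counts inconsistent with group_sizes")
  if (cfg$structural_lambda > 0)
    stop("structural_lambda must be <= 0")
  if (is.null(cfg$cluster_nodes))
    cfg$cluster_nodes <- seq_len(min(15L, cfg$n_nodes))
  if (any(cfg$cluster_nodes < 1) || any(cfg$cluster_nodes > cfg$n_nodes))
    stop("cluster_nodes outside the grid")
  if (cfg$null_mode) {
    cfg$effect_beta <- 0
    cfg$b2 <- 0
    cfg$moderation_b3 <- 0
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("sim_config: %d nodes/%d regions, %g s epochs (+%g s pad) x %d ",
           "@ %g Hz, band %g-%g Hz\n  cohort: CI=%d MCI=%d, carrier ",
           "fraction %.2f; effect_beta=%g, b3=%g (%s), noise_sd=%g; seed %d\n"),
    x$n_nodes, x$n_regions, x$epoch_len, x$pad_s, x$n_epochs, x$fs,
    x$band[1], x$band[2], x$group_sizes[["CI"]], x$group_sizes[["MCI"]],
    x$carrier_fraction, x$effect_beta, x$moderation_b3,
    paste(x$moderation_groups, collapse = "+"), x$noise_sd, x$seed
  ))
  invisible(x)
}

# --- spectral machinery -----------------------------------------------------

# Basis for synthesizing band-limited sources on the padded-epoch FFT grid.
# Returns the kept positive-frequency bins, their filter amplitudes, and the
# complex exponential bases for the full padded segment and for the interior
# analysis window.
synth_basis <- function(cfg) {
  ns <- as.integer(round(cfg$fs * (cfg$epoch_len + 2 * cfg$pad_s)))
  H <- fir_response(cfg$fs, cfg$band, ns, cfg$ntaps)
  f <- (seq_len(ns) - 1) / ns * cfg$fs
  amp <- Mod(H)
  keep <- which(f > 0 & f < cfg$fs / 2 & amp > 1e-3 * max(amp))
  npad <- as.integer(round(cfg$pad_s * cfg$fs))
  interior <- (npad + 1L):(ns - npad)
  tt <- seq_len(ns) - 1L
  Efull <- exp(2i * pi * outer(tt, keep - 1L) / ns)
  list(ns = ns, keep = keep, amp = amp[keep],
       Efull = Efull, Eint = Efull[interior, , drop = FALSE],
       interior = interior)
}

# iid complex-Gaussian spectra shaped by the band filter: nbins x ncols.
# Scaled so each synthesized series has unit variance order of magnitude
# (the absolute scale is irrelevant to phase-based metrics).
draw_spectra <- function(basis, ncols) {
  nb <- length(basis$keep)
  S <- matrix(
    complex(real = stats::rnorm(nb * ncols), imaginary = stats::rnorm(nb * ncols)),
    nb, ncols
  )
  S * (basis$amp / sqrt(sum(basis$amp^2)))
}

# analytic signals (samples x nodes) for one epoch of one subject: per-node
# independent narrow-band noise, cluster nodes mixed with a shared driver.
synth_epoch_analytic <- function(basis, n_nodes, cluster, coupling,
                                 interior_only = TRUE) {
  S <- draw_spectra(basis, n_nodes + 1L)
  E <- if (interior_only) basis$Eint else basis$Efull
  Z <- E %*% S
  drv <- Z[, n_nodes + 1L]
  Z <- Z[, seq_len(n_nodes), drop = FALSE]
  if (length(cluster) && coupling > 0)
    Z[, cluster] <- (1 - coupling) * Z[, cluster, drop = FALSE] +
      coupling * drv
  Z
}

#' Simulate band-limited oscillatory sources for one subject
#'
#' Generates `nodes x samples x epochs` real time series (including the
#' epoch padding): every node carries independent narrow-band Gaussian
#' noise; nodes in `cfg$cluster_nodes` additionally mix in a shared
#' narrow-band driver with weight `cfg$coupling`, planting phase coupling.
#' The driver is redrawn per epoch and per call, so its phase is random
#' across subjects. Deterministic under `cfg$seed`.
#'
#' @param grid a `source_grid` whose node count matches `cfg$n_nodes`.
#' @param cfg a `sim_config`.
#' @return An `epoched_series` with `pad_s = cfg$pad_s`, broadband label set
#'   to the synthesis band.
#' @export
simulate_sources <- function(grid, cfg) {
  stopifnot(inherits(grid, "source_grid"), inherits(cfg, "sim_config"))
  if (nrow(grid$nodes) != cfg$n_nodes)
    stop("grid size does not match cfg$n_nodes")
  if (any(!cfg$cluster_nodes %in% grid$nodes$node))
    stop("cluster_nodes must be a subset of the grid nodes")
  set.seed(cfg$seed)
  basis <- synth_basis(cfg)
  d <- c(cfg$n_nodes, basis$ns, cfg$n_epochs)
  out <- array(0, d)
  for (e in seq_len(cfg$n_epochs)) {
    Z <- synth_epoch_analytic(basis, cfg$n_nodes, cfg$cluster_nodes,
                              cfg$coupling, interior_only = FALSE)
    out[, , e] <- t(Re(Z))
  }
  epoched_series(out, fs = cfg$fs, band = cfg$band, pad_s = cfg$pad_s)
}

# strength map and PLV of one subject from the spectral model directly
# (phases from the synthesized analytic signal on the analysis window);
# distributionally the bandpass -> Hilbert -> trim pipeline on the same
# sources, without the redundant re-filtering. With keep_series = TRUE the
# real padded series built from the very same draws is returned too.
simulate_subject_connectivity <- function(basis, cfg, coupling,
                                          keep_series = FALSE) {
  n <- cfg$n_nodes
  ni <- length(basis$interior)
  acc <- matrix(0, n, n)
  dat <- if (keep_series) array(0, c(n, basis$ns, cfg$n_epochs)) else NULL
  for (e in seq_len(cfg$n_epochs)) {
    Z <- synth_epoch_analytic(basis, n, cfg$cluster_nodes, coupling,
                              interior_only = !keep_series)
    if (keep_series) {
      dat[, , e] <- t(Re(Z))
      Z <- Z[basis$interior, , drop = FALSE]
    }
    U <- Z / Mod(Z)
    acc <- acc + Mod(t(Conj(U)) %*% U) / ni
  }
  P <- acc / cfg$n_epochs
  P <- (P + t(P)) / 2
  P[P > 1] <- 1
  diag(P) <- 1
  out <- list(plv = P, strength = (rowSums(P) - 1) / (n - 1))
  if (keep_series)
    out$series <- epoched_series(dat, fs = cfg$fs, band = cfg$band,
                                 pad_s = cfg$pad_s)
  out
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

genotype_from_carrier <- function(carrier) {
  ifelse(carrier == 1L,
         ifelse(stats::runif(length(carrier)) < 0.85, "e3e4", "e4e4"),
         "e3e3")
}

#' Simulate a full synthetic cohort with planted effects
#'
#' Draws a cohort of CI and MCI subjects with demographics emulating a large
#' ageing sample (MCI older, less educated, lower delayed recall), simulates
#' each subject's phase-coupled sources with a per-subject coupling drawn
#' from `cfg$coupling_range`, computes realized PLV connectivity and nodal
#' strength, and generates behaviour from the realized cluster strength:
#'
#' `recall = a_g + effect_beta * strength + b2 * carrier
#'           + moderation_b3 * carrier * strength (planted groups)
#'           + gamma_age * (age - 68) + noise`
#'
#' Structural measures (GM/WM/hippocampal volume, four FA tracts) load
#' negatively on standardized cluster strength with weight
#' `cfg$structural_lambda`. With `cfg$null_mode = TRUE` behaviour is
#' independent of connectivity.
#'
#' @param cfg a `sim_config`.
#' @param grid optional `source_grid`; built from the config if missing.
#' @param return_plv keep each subject's PLV matrix (needed for seed-based
#'   analyses; memory scales with `n_subjects * n_nodes^2`).
#' @param return_series keep each subject's raw padded series (large).
#' @return An object of class `sim_cohort`: list with `cohort` (data frame:
#'   `subject_id`, `group`, `age`, `education`, `apoe_genotype`, `apoe_e4`,
#'   `delayed_recall`, `coupling`, `cluster_strength`, structural columns),
#'   `strength` (subjects x nodes matrix), optional `plv`/`series` lists,
#'   `grid`, `cluster_nodes`, `config`.
#' @export
simulate_cohort <- function(cfg, grid = NULL, return_plv = FALSE,
                            return_series = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(grid)) grid <- make_grid(cfg$n_nodes, cfg$n_regions, cfg$spacing)
  if (nrow(grid$nodes) != cfg$n_nodes)
    stop("grid size does not match cfg$n_nodes")
  set.seed(cfg$seed)

  ng <- cfg$group_sizes
  n <- sum(ng)
  group <- factor(rep(names(ng), ng), levels = names(ng))
  is_mci <- group == "MCI"
  age <- numeric(n)
  edu <- numeric(n)
  age[!is_mci] <- rtrunc_norm(sum(!is_mci), 65.96, 8.48, 41, 82)
  age[is_mci] <- rtrunc_norm(sum(is_mci), 74.28, 5.26, 58, 87)
  edu[!is_mci] <- rtrunc_norm(sum(!is_mci), 14.30, 5.49, 0, 25)
  edu[is_mci] <- rtrunc_norm(sum(is_mci), 9.99, 4.33, 0, 25)

  if (is.null(cfg$carrier_counts)) {
    carrier <- stats::rbinom(n, 1L, cfg$carrier_fraction)
  } else {
    carrier <- unlist(lapply(names(ng), function(g) {
      k <- cfg$carrier_counts[[g]]
      sample(rep(c(1L, 0L), c(k, ng[[g]] - k)))
    }))
  }
  genotype <- genotype_from_carrier(carrier)
  if (cfg$rare_genotype_fraction > 0) {
    rare <- stats::runif(n) < cfg$rare_genotype_fraction
    genotype[rare] <- sample(c("e2e2", "e2e3", "e2e4"), sum(rare),
                             replace = TRUE)
    carrier[rare] <- NA_integer_
  }

  coupling <- stats::runif(n, cfg$coupling_range[1], cfg$coupling_range[2])

  basis <- synth_basis(cfg)
  strength <- matrix(NA_real_, n, cfg$n_nodes)
  plv <- if (return_plv) vector("list", n) else NULL
  series <- if (return_series) vector("list", n) else NULL
  for (i in seq_len(n)) {
    conn <- simulate_subject_connectivity(basis, cfg, coupling[i],
                                          keep_series = return_series)
    strength[i, ] <- conn$strength
    if (return_plv) plv[[i]] <- conn$plv
    if (return_series) series[[i]] <- conn$series
  }

  marker <- rowMeans(strength[, cfg$cluster_nodes, drop = FALSE])
  mod_on <- as.integer(group %in% cfg$moderation_groups)
  carrier0 <- ifelse(is.na(carrier), 0L, carrier)
  recall <- cfg$recall_intercepts[as.character(group)] +
    cfg$effect_beta * marker +
    cfg$b2 * carrier0 +
    cfg$moderation_b3 * carrier0 * marker * mod_on +
    cfg$gamma_age * (age - 68) +
    stats::rnorm(n, 0, cfg$noise_sd)

  z <- as.numeric(scale(marker))
  lam <- cfg$structural_lambda
  mix <- function(mu, sd_g) {
    mu + sd_g * (lam * z + sqrt(1 - lam^2) * stats::rnorm(n))
  }
  gm <- ifelse(is_mci, mix(533531, 51447), mix(567118, 53093))
  wm <- ifelse(is_mci, mix(398978, 56706), mix(432580, 64658))
  hip <- ifelse(is_mci, mix(6124, 805), mix(7132, 846))
  fa <- function(mu) pmin(1, pmax(0, mix(mu, 0.035)))
  cohort <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = group, age = age, education = edu,
    apoe_genotype = genotype,
    apoe_e4 = ifelse(is.na(carrier), NA_character_,
                     ifelse(carrier == 1L, "carrier", "noncarrier")),
    delayed_recall = as.numeric(recall),
    coupling = coupling,
    cluster_strength = marker,
    total_gm = gm, total_wm = wm, hippocampus = hip,
    fa_cingulum_left = fa(ifelse(is_mci, 0.39, 0.41)),
    fa_cingulum_right = fa(ifelse(is_mci, 0.39, 0.41)),
    fa_forceps_major = fa(ifelse(is_mci, 0.53, 0.55)),
    fa_forceps_minor = fa(ifelse(is_mci, 0.52, 0.54)),
    stringsAsFactors = FALSE
  )
  structure(
    list(cohort = cohort, strength = strength, plv = plv, series = series,
         grid = grid, cluster_nodes = cfg$cluster_nodes, config = cfg),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  tab <- table(x$cohort$group)
  cat(sprintf(
    "sim_cohort: %d subjects (%s), %d nodes, planted cluster of %d nodes\n",
    nrow(x$cohort), paste(names(tab), tab, sep = "=", collapse = ", "),
    ncol(x$strength), length(x$cluster_nodes)
  ))
  invisible(x)
}

#' Drop subjects with rare APOE genotypes
#'
#' Keeps only e3e3 homozygotes and e4 carriers (e3e4, e4e4); subjects with
#' e2-bearing combinations are removed before any carrier/noncarrier
#' contrast, mirroring standard practice of excluding the protective and
#' ambiguous allele combinations.
#'
#' @param cohort a cohort data frame with an `apoe_genotype` column (rows
#'   lacking it are filtered on non-missing `apoe_e4` instead).
#' @return The filtered data frame.
#' @export
drop_rare_genotypes <- function(cohort) {
  if ("apoe_genotype" %in% names(cohort))
    cohort <- cohort[cohort$apoe_genotype %in% c("e3e3", "e3e4", "e4e4"), ,
                     drop = FALSE]
  if ("apoe_e4" %in% names(cohort))
    cohort <- cohort[!is.na(cohort$apoe_e4), , drop = FALSE]
  cohort
}
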