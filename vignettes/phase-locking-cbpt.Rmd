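---
title: "Phase-locking connectivity, cluster permutation inference, and moderated memory associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-locking connectivity, cluster permutation inference, and moderated memory associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plvnet)
```

`plvnet` analyses resting-state source-space MEG: it quantifies
phase-locking functional connectivity, relates per-node connectivity
strength to a behavioural score with a cluster-based permutation test,
follows up with seed-based and structural-association analyses, and probes
genotype moderation of the connectivity–behaviour relation. This vignette
is the package's account of the methods: the models, the defaults and why,
the numerical choices, and what the synthetic-data tests do and do not
establish.

## The connectivity model

The input is an `epoched_series`: per-subject source time series of
dimension nodes × samples × epochs. The canonical geometry is a 1 cm
volumetric grid of 1202 source positions labelled by 78 cortical regions,
with 4 s epochs sampled at 1000 Hz. Epochs carry 2 s of real signal as
padding on each side; the pipeline filters and extracts phase on the padded
8 s segment and then discards the padding, so that filter and Hilbert edge
transients never touch the 4000 analysis samples.

Filtering is a zero-phase FIR band-pass (Hamming window, odd length, group
delay compensated after FFT convolution). The tap count defaults to
`3.3 * fs / 2` rounded up to odd — a ~2 Hz transition band, i.e. at least
40 dB of stopband attenuation 2 Hz outside the band edges at fs = 1000 Hz
(the Hamming window gives ~53 dB). The canonical bands are theta (4–8 Hz),
alpha (8–12), beta (12–30) and gamma (30–45); beta is the default
everywhere because it is the band where hypersynchronization-with-poorer-
memory effects concentrate.

The instantaneous phase φ_j(t) is the argument of the analytic signal
z_j(t) = x_j(t) + i·H[x_j](t), computed per epoch by the FFT Hilbert
method; the amplitude is discarded. Phase coupling between nodes j and k is
the phase locking value,

PLV(j,k) = (1/M) | Σ_{m=1}^{M} exp{ i(φ_j(t_m) − φ_k(t_m)) } |,

with the sum running over the M = 4000 within-epoch samples, and the
per-epoch matrices averaged arithmetically across epochs. PLV is 1 for a
perfectly constant phase relation and has expectation √π/(2√M) ≈ 0.014 for
M independent uniform phase differences (the Rayleigh resultant length);
note that band-limited signals decorrelate slowly, so the *empirical* null
level between independent narrow-band sources is higher (≈ 0.1 for a 18 Hz
band over 4 s) because the number of effectively independent samples is
roughly twice the bandwidth–duration product, not M. Both levels are
covered by tests.

Nodal strength is the normalized row sum, `s(j) = Σ_{k≠j} PLV(j,k)/(N−1)`,
i.e. the node's mean connectivity to the rest of the grid. The diagonal is
stored as 1 for display but excluded from every strength and seed-link
computation.

## Cluster-based permutation inference

The node statistic is a covariate-adjusted Spearman correlation between
strength and behaviour: all variables are rank-transformed (mid-ranks for
ties) and a partial Pearson correlation is computed on the ranks given the
ranked covariates, with p-values from the t distribution on
n − 2 − (number of covariates) degrees of freedom. Age is the conventional
covariate for the node-level scan.

Candidate clusters are connected components — under the 26-neighbourhood of
the cubic lattice, i.e. Euclidean distance ≤ √3 × spacing (+1e−6 slack) —
of nodes with two-sided p below `alpha_node` (default 0.001), split by the
sign of the correlation so every cluster is sign-pure. Components smaller
than 1% of the grid are discarded: `max(1, floor(0.01 N))`, which is 12
nodes on the 1202-node grid. (The floor, not the ceiling, is what
reproduces 12 from 1202 × 0.01 = 12.02.) Each cluster is scored by its
Fisher-Z mass `Σ atanh(ρ)`, the variance-stabilized sum of its member
correlations.

Family-wise calibration uses the maximum statistic: each permutation
jointly re-assigns the (behaviour, covariate) rows to the strength maps by
a uniform random permutation — preserving the behaviour–covariate
dependence while breaking any map–behaviour link, the exchangeable
structure under the null of no association — reruns the thresholding and
clustering, and records the maximum absolute cluster mass across both
signs. A cluster's p-value is the add-one estimator
`(1 + #{max null mass ≥ |observed mass|}) / (n_perm + 1)`, which can never
be exactly zero and has minimum `1/(n_perm + 1)`. A Freedman–Lane variant
(permute the rank-residuals of behaviour on the covariates) is available as
`perm_scheme = "freedman_lane"`; the joint scheme is the default because it
is exact under exchangeability and keeps the covariate distribution
intact. When `n_perm` exceeds n! the permutation distribution is enumerated
exhaustively instead (with a warning), which is also how the Monte-Carlo
p-values are validated in the tests at n = 6.

Numerical choices: permutation correlations are clipped to ±(1 − 1e−12)
before the Fisher transform, since mid-rank correlations at small n can hit
±1 exactly and an infinite mass would poison the max-statistic; observed
clusters with |ρ| = 1 are rejected with a diagnostic rather than silently
clipped, because they indicate a degenerate input. Node columns with zero
rank variance are flagged NA and never enter a cluster.

Each significant cluster yields a per-subject *marker*: the mean strength
over its member nodes, the single FC number carried into all downstream
analyses.

## Seed-based secondary analysis

To ask which connections drive a strength cluster, every node gets a
seed-link value: its mean PLV to the cluster's nodes, excluding
self-connections (seed-internal nodes average over the *other* members —
including the diagonal 1 would bias them upward; with the seed equal to the
whole grid the seed-link map reduces exactly to nodal strength, a tested
identity). The CBPT is then rerun on the seed-link maps. A secondary
cluster's marker is the mean PLV over the primary × secondary block —
the strength of that specific long-range link — rather than the plain
member mean. Secondary clusters may overlap the seed; the overlap is
reported, not forbidden.

## Associations and group contrasts

Cluster markers are correlated (Spearman) with structural measures — total
grey and white matter volume, hippocampal volume, and tract fractional
anisotropy — for the whole sample and per diagnostic group, with
Benjamini–Hochberg FDR correction applied within each marker × group family
across measures. The family definition is recorded in the output table
because it is a genuine analysis choice; a different slicing can be
obtained by filtering the table and re-adjusting. Constant or
too-small-n measures are flagged and excluded from their family rather than
silently corrected.

Group contrasts of a marker are ANCOVA-style: `marker ~ group + age +
education` by least squares, reporting the F of the group term on (1,
n − 4) degrees of freedom (identically the squared t of the group
coefficient, which the tests assert to 1e−8) and adjusted group means at
the covariate means.

## Moderated regression and the Johnson–Neyman region

The moderation model is ordinary least squares,

y = b0 + b1·x + b2·w + b3·(x·w) + γ₁·age + γ₂·education + ε,

with x the FC marker on its raw PLV scale (deliberately uncentered, so
thresholds are reported in PLV units), w the 0/1 APOE-ε4 carrier indicator,
and ΔR² = R²(full) − R²(without x·w) the interaction's incremental variance
share (identically the squared semipartial correlation of the interaction
term). Rows with genotypes outside {ε3ε3, ε4 carrier} are excluded before
any carrier contrast.

The Johnson–Neyman probe follows the orientation in which the *genotype*
effect is probed across FC values: the conditional effect θ(x) = b2 + b3·x
has Var θ(x) = V₂₂ + x²V₃₃ + 2xV₂₃, and the region of significance is
bounded by the real roots of θ(x)² = t²_crit·Var θ(x) with t_crit the
two-sided critical value on the model's residual degrees of freedom. The
quadratic is solved in closed form, each root polished by a root-finder to
ensure |t(threshold)| = t_crit to 1e−6, and the region classified by
probing between and beyond the thresholds (significant above / below /
between / outside / everywhere / nowhere). The degenerate linear case
(b3² = t²V₃₃) is handled separately. For the reverse probe the moderator is
binary, so the effect of x is simply reported at w = 0 and w = 1.
`subgroup_moderation_profile()` repeats the fit and probe per diagnostic
group and tabulates age-adjusted Spearman correlations per group × carrier
cell, the stratified descriptive profile.

## The synthetic cohort generator

No public data accompany this kind of cohort, so the generator is a
first-class module. It emulates: the grid geometry (a connected cubic
lattice with contiguous region labels), narrow-band oscillatory sources,
a phase-coupled cluster, Table-1-style demographics — 261 CI and 118 MCI by
default, MCI older (74.3 ± 5.3 vs 66.0 ± 8.5 years), less educated
(10.0 ± 4.3 vs 14.3 ± 5.5 years) and with far lower delayed recall —
structural measures with a configurable negative loading on cluster
strength, and a genotype-moderated recall slope planted in the CI group by
default.

Sources are narrow-band Gaussian processes, synthesized in the frequency
domain: each node (and one shared *driver*) receives an independent
complex-Gaussian spectrum shaped by the frequency response of the very same
FIR used by the connectivity stage, and the analytic signal is produced by
direct evaluation of the Fourier sum. This is identical in distribution to
filtering white Gaussian noise with that FIR, avoids any filter mismatch
between generator and pipeline, and gives closed-form control of the
coupling: cluster nodes mix the driver in linearly,
x = (1 − c)·noise + c·driver, so within-cluster PLV rises monotonically
from the narrow-band chance level at c = 0 to exactly 1 at c = 1 (a
Kuramoto-style dynamical model would not admit this control). A consistency
test confirms that phases taken directly from the synthesized analytic
signal agree with the explicit bandpass → Hilbert → trim pipeline on the
same draws (PLV entries within 0.05; the residual difference is the
pipeline's second filter pass re-weighting the transition band).

Behaviour is linear in the *realized* cluster strength (the mean strength
over cluster nodes actually computed from each subject's PLV), not the
nominal coupling, so parameter recovery is well-posed:

recall = a_group + effect_beta·strength + b2·carrier +
         b3·carrier·strength·[group planted] + γ·(age − 68) + noise.

Per-subject couplings are drawn uniformly from `coupling_range`
(default 0.2–0.8) so strength varies across subjects. Defaults are
paper-like: `effect_beta = −50` with `noise_sd = 10` puts the
marker–recall Spearman correlation near −0.2 to −0.3, the magnitude typical
of reported strength–recall associations; the group intercepts (65 vs 28)
reproduce the large CI/MCI recall gap.

**What the generator does not emulate:** forward/inverse MEG modelling and
volume-conduction leakage, 1/f spectra, non-Gaussian or nonstationary
dynamics, spatially smooth noise fields. Passing tests therefore establish
the *statistical* correctness of the pipeline (calibration, power against
the planted model, algebraic identities), not robustness to the leakage and
artifact structure of real source-reconstructed MEG.

## Test conditions and problem sizes

Simulation-heavy checks are sized to run comfortably on one CPU; the sizes
are the package's own choices and are stated here so they can be judged:

- CBPT family-wise error: 200 null datasets of 60 subjects × 100 nodes
  (Gaussian strength maps, independent behaviour and age), 500 permutations
  each; the familywise false-positive rate must sit in the binomial 95%
  band around 0.05 ([0.02, 0.09]).
- Planted-cluster recovery: 50 replicates of a 48-node grid with a 15-node
  coupled cluster, n = 150 subjects, one 4 s epoch per subject, 500
  permutations; a significant negative cluster with Jaccard ≥ 0.5 against
  the planted set must appear in ≥ 80% of replicates. The recovery
  configuration uses `noise_sd = 4` — chosen by power analysis (node-wise
  p < 0.001 at n = 150 needs |ρ| ≳ 0.35; the default paper-like noise of 10
  puts node correlations near 0.25, which is *not* meant to clear a 0.001
  gate) — and equal group intercepts, because the Table-1 recall gap is
  orthogonal to the planted effect and acts purely as variance inflation in
  a whole-sample scan.
- Generator null calibration: one cohort of 80 subjects × 200 nodes in null
  mode; node-wise strength–behaviour p-values must pass a
  Kolmogorov–Smirnov uniformity check.
- Moderation recovery: 100 replicates at n = 250 of the moderated linear
  model with low noise; every coefficient within 3 standard errors in
  ≥ 95%.

## Known limitations

- PLV is sensitive to source leakage; leakage-robust metrics (PLI, wPLI,
  orthogonalized amplitude coupling) are out of scope.
- The permutation scheme assumes exchangeable subjects under the null;
  family or site structure would require restricted permutations.
- The Johnson–Neyman thresholds carry no confidence bands (no bootstrap).
- Epoch padding requires 2 s of real signal around each epoch; data epoched
  without padding can be analysed (`pad_s = 0`) at the cost of filter edge
  effects inside the window.
- The FDR family for structural associations is a convention (marker ×
  group, across measures); other slicings are defensible and supported by
  re-adjusting the table.
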