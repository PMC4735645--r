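---
title: "Lagged phase coherence networks: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lagged phase coherence networks: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpcnet)
```

## The problem this package addresses

Resting-state EEG studies of disordered perception — phantom sounds
(tinnitus) being the motivating case — ask whether a patient group's
brain networks differ from controls in two complementary ways: the
*temporal structure* of each channel's signal (the 1/f spectral
exponent, which indexes how far the system sits between white-noise
randomness and Brownian rigidity) and the *topology* of the band-wise
functional connectivity graph (whether the network is drifting towards
a regular lattice or towards a random graph, away from the small-world
regime of high clustering plus short paths).

`lpcnet` implements that full analysis chain as composable functions:
preprocessing, spectral estimation, lagged-phase-coherence
connectivity, weighted graph metrics, distance relations,
cross-frequency coupling and the group statistics. Because the clinical
recordings behind such studies are rarely shareable, the package ships
a simulator whose outputs have *known* spectral exponents and *planted*
lagged couplings, and every stage is validated against that ground
truth or against an independent brute-force oracle.

## Signal model and preprocessing

A recording is a channels × samples matrix with a sampling rate and
per-channel MNI coordinates. Preprocessing band-passes to 2–44 Hz and
resamples to 128 Hz, the conventional processing rate for this family
of analyses. Both operations are frequency-domain: the band-pass is a
zero-phase spectral mask with 0.5 Hz raised-cosine skirts, and
resampling is Fourier (spectrum truncation), which doubles as an ideal
anti-alias filter. We chose these over time-domain IIR filtering
because no signal-processing toolbox is required, the operations are
exactly zero-phase, and their contracts are directly testable (a 1 Hz
tone must emerge below 10% of its input RMS; the resampled length is
`floor(n * 128 / rate)`).

Recordings are cut into 2 s non-overlapping epochs by default. Two
seconds gives 0.5 Hz spectral resolution, the coarsest grid that still
separates the delta/theta boundary at 3.5 vs 4 Hz; the band edges are
inclusive on both sides, so of the eight canonical bands only the
printed alpha1/alpha2 boundary at exactly 10 Hz is shared by two bands.

## 1/f spectral exponent

Per channel, Hann-tapered periodograms are averaged over epochs and the
exponent is fit by ordinary least squares of `log(PS)` on `log(f)`:
`log(PS) = -alpha * log(f) + beta`, reported with the sign convention
that decaying spectra have positive `alpha` (white noise 0, pink 1,
Brownian 2). The default fit range is 2–43 Hz: the conventional printed
window is 1–43 Hz, but power below the 2 Hz passband edge is filter
residue whose logarithm is numerically unstable, so the default clips
to the passband and the full window remains available by passing
`f_lo = 1`. `epoch_slopes()` provides the fit-per-epoch-then-average
variant; for log-linear spectra the two estimators agree in
expectation, and the package treats the averaged-spectrum fit as
primary because it is less variable at short epoch lengths.

Group slope comparison (`compare_slopes`) pools all channel × frequency
log-log points into one regression with a group dummy and a
group × log(f) interaction, and t-tests the interaction. Note its
resolution limit: with a single recording per group the points are not
exchangeable units and the test is anti-conservative; it is meant for
spectra averaged over group members, mirroring how such contrasts are
reported in practice.

## Lagged phase coherence

For each band, every epoch's Fourier coefficients are normalized to
unit modulus (phase-only), the outer-product coherency is averaged over
epochs and over the band's Fourier bins, and the lagged phase coherence
of a pair with coherency `rho` is

    LPC = Im(rho)^2 / (1 - Re(rho)^2).

The real part of `rho` carries the instantaneous, zero-phase-lag
component of the coupling — exactly what volume conduction through the
scalp produces — so dividing it out leaves only time-lagged
synchronization, interpretable as axonal cross-talk. Identical signals
give LPC = 0; a clean quarter-cycle lag drives LPC towards 1 (at 10 Hz
a quarter cycle is 25 ms, at 20 Hz 12.5 ms). The estimator is invariant
to amplitude scaling of either channel, which the tests pin to 1e-12.

Two variants of band bookkeeping exist in the literature: single
representative frequency versus averaging the phase-only cross-spectra
over all bins in the band. We implement the band-collapsed variant —
one `rho`, hence one LPC, per band — matching the "average Fourier
cross-spectral matrices per band" convention, and document it here
because the choice affects the effective sample size of the null.

**Significance.** Under independence, `n_epochs * n_bins * LPC` is
referred to a chi-square distribution with 1 df, Bonferroni-corrected
over the simultaneous edges (171 for 19 nodes, 3486 for 84). The exact
null variance of `Im(rho)` is 1/(2m) for m independent products, so
this scaling is conservative by roughly a factor of two (and slightly
less so under Hann-induced correlation of adjacent bins). We keep the
stated form and verify the direction that matters by Monte Carlo: on
independent-noise recordings the family-wise false-positive rate stays
at or below the nominal level. Degenerate input `Re(rho)^2 = 1`
(perfect instantaneous coherence) has no lagged component and is
defined as LPC = 0 with a warning rather than an error.

Weighted analyses run on the full matrix; `threshold_matrix()` applies
the cutoff for edge-display purposes only, since zeroing sub-threshold
edges changes every path-based metric.

## Graph metrics

All metrics follow the Brain Connectivity Toolbox conventions:

* **Node strength** — row sums of `W`; network mean is the arithmetic
  average over nodes.
* **Connection length** — `L = 1/W` elementwise, infinite for absent
  edges. The alternative `-log(w)` mapping was rejected to stay aligned
  with the toolbox convention the field reports against.
* **Functional distance** — all-pairs Dijkstra over `L` (via igraph);
  the **characteristic path length** is the mean over unordered pairs
  with finite distance, so isolated nodes shrink the averaging set
  instead of producing infinities. If no finite pair exists the CPL is
  `NA`.
* **Clustering** — the Onnela geometric-mean-of-triangles form on
  globally max-normalized weights,
  `C_i = sum_jh (w'_ij w'_jh w'_ih)^(1/3) / (k_i (k_i - 1))`, with
  `k_i` counting strictly positive neighbors (no epsilon threshold);
  `k_i < 2` scores 0, not `NaN`.
* **Local efficiency** — for each node, inverse shortest-path lengths
  among its neighbors (paths confined to the neighbor subgraph, with
  cube-root lengths), weighted by the cube-root weights to the center
  and normalized by `k_i (k_i - 1)`. This is the toolbox formula; local
  efficiency is *correlated* with clustering but not proportional to
  it, and the package implements the formula rather than any
  proportionality shortcut.

One consequence of global max normalization worth knowing: planting a
single very strong edge raises `max(W)` and therefore *lowers* every
other node's normalized clustering. This is a property of the
convention, not an artifact.

All of these are cross-checked against independent brute-force oracles
(Floyd–Warshall, explicit triple enumeration) at 1e-10 on randomized
graphs, and the lattice-versus-random sanity anchor (ring lattice has
higher clustering *and* longer paths than a degree-matched random
graph) is asserted in the suite.

## Distance relations and group statistics

Physical distance between nodes is the Euclidean distance of their MNI
coordinates. Connectivity weights and functional distances are each
regressed on physical distance over the unordered edges
(`distance_regression`), and slopes are compared between groups by the
pooled interaction t-test (`compare_regression_slopes`). Edges with
infinite functional distance are excluded and counted.

Cross-frequency coupling correlates, across edges, the functional
distances of a low band (delta, theta, alpha1, alpha2) with those of a
high band (beta1–3, gamma); group differences use the Fisher r-to-z
test with `n` equal to the number of edges finite in both bands. The
effective `n` of such edge-level correlations is a genuine modelling
choice (edges of one network are not independent observations); it is
exposed as a parameter rather than hidden.

The edgewise group map applies the Fisher z machinery to the
*connectivity weights*, which are bounded in [0, 1) and therefore
admissible arguments of `atanh`, with the group sample sizes as `n` and
Bonferroni correction over edges; the *direction* label of each
significant edge comes from the functional distance matrices (which
group's distance is longer), preserving the red/black/white semantics
of the standard figure. Applying `atanh` to unbounded distances
directly would be undefined; this bounded-weight surrogate is the
package's documented resolution of that gap.

The repeated-measures ANOVA (`group_band_anova`) treats nodes (for
strength, clustering, local efficiency) or edges as observational
units: between-subject factor group, within-subject factor band, group
main effect tested against units-within-group, interaction against the
band × unit stratum, verified against a direct sums-of-squares oracle.
Per-band simple contrasts are pooled-variance t-tests reported as
`F = t^2` with one-tailed p in the direction of the observed mean
difference, at the conventional 0.05 level. Treating nodes of a group
network as units is itself an approximation (nodes are not independent
either); it is isolated behind this one function so an analysis with
subject-level units can swap it out.

## The synthetic world

`simulation_config()`/`generate_recording()` build each channel as

1. a 1/f^alpha background, synthesized by inverse-FFT shaping of
   complex Gaussian coefficients (the target spectrum is exact in
   expectation), normalized to unit RMS;
2. for each planted coupling, a shared narrowband noise carrier —
   filtered noise rather than a sinusoid, so epoch-averaged
   cross-spectra are nondegenerate — injected into channel *i* and,
   phase-rotated by the configured lag, into channel *j*, scaled to a
   configured multiple of the background RMS;
3. independent white noise.

Defaults state the world once: 128 Hz, pink background (`alpha = 1`,
the exponent typical of spontaneous neural activity), carrier amplitude
2× background RMS for planted effects, white-noise SD 0.5, 60 s
recordings, and 20 subjects per group in the study driver — a typical
resting-state EEG group size, and the scale at which the edgewise
Fisher-z map has power to flag a strong planted edge at the
Bonferroni-corrected level. Identical configuration plus seed gives a
bit-identical recording; all study-level seeds derive deterministically
from one top-level seed.

What the generator deliberately omits: volume conduction and any
leadfield/head geometry (so zero-lag mixing must be *planted*, not
emergent), nonstationarity, artifacts, and any claim about the
physiology behind the couplings. A green recovery test therefore
establishes that the estimators do what they claim on signals with the
assumed structure — not that the pipeline is robust to real-world EEG
contamination, which is upstream artifact handling's job. Two side
effects of the stated world are worth noting because the analysis
scripts surface them: the additive white-noise floor biases fitted
exponents below the background's nominal `alpha`, and planted band
carriers add real band power, so a "connectivity-only" manipulation
also moves the group's spectral slope.

## Numerical conventions and degenerate cases

* Hann tapering spreads a bin-centered sinusoid over a 3-bin main lobe;
  the spectral concentration test asserts ≥90% of power in that lobe
  (a rectangular window would give one bin, at the price of far worse
  leakage for non-bin frequencies).
* A phase-only coefficient of exactly zero power carries no phase and
  is dropped from the coherency average (set to 0) rather than
  producing NaN.
* Matrix symmetry is enforced by averaging `W` with its transpose
  before the diagonal is zeroed, guarding against rounding asymmetry.
* CPL conventions: means are over unordered pairs; for symmetric
  matrices ordered and unordered means coincide, and the tests pin the
  unordered convention.
* All randomness flows through integer seeds; derived per-subject seeds
  stay below 2^31.

## Limitations

Source localization (the inverse problem producing region-of-interest
time series) is out of scope — ROI series are accepted as a
channels × samples input like any recording. EDF ingestion is not
provided (no EDF reader without extra dependencies); CSV/TSV plus a
JSON sidecar is the interchange format, with lossless round-trips
tested. The clinical-scale group statistics of the motivating
literature (hundreds of subjects) are not reproducible at desk scale;
the package's claims are correctness and calibration on its stated
synthetic world.
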