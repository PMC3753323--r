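---
title: "Multiscale entropy and frequency-band network analysis of epoched MEG-like recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale entropy and frequency-band network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megnets)
```

## Overview

`megnets` implements a multiscale characterization of epoched multichannel
electrophysiological recordings at three statistical levels:

* **univariate** — the Shannon wavelet entropy of every sensor's band-limited
  series, per trial;
* **bivariate** — normalized mutual information (NMI) between sensor series,
  both within a frequency band and between pairs of bands;
* **multivariate** — binary graph diagnostics of the resulting connectivity
  matrices across a sweep of network densities, compared between groups with
  functional-data-analysis (FDA) permutation tests, and over trials with a
  coefficient-of-variation (CV) analysis.

The expected experimental layout is a working-memory-style task: 6 blocks of
11 stimulus–response periods, giving 66 epochs of 1800 ms per subject,
recorded at 600 Hz and analyzed at 120 Hz (216 samples per epoch). All of
these are configurable; the defaults encode that protocol.

## The processing model

### Bands

Epochs are resampled to the analysis rate (anti-alias FIR low-pass at the
target Nyquist, zero phase, integer decimation) and decomposed with the
maximal overlap discrete wavelet transform (MODWT), an undecimated transform
whose detail series have the same length as the input. At 120 Hz the four
detail scales cover 30–60 Hz (low γ), 15–30 Hz (β), 8–15 Hz (α) and 4–8 Hz
(θ). Frequencies below 4 Hz are not analyzed: a 1.8 s epoch carries too few
cycles.

Two filter choices are supported, because the name "Daubechies 4" is used in
the literature for both the 4-tap filter with two vanishing moments
(`"d4"`, the default) and the 8-tap filter with four vanishing moments
(`"db4"`). Boundary handling is periodic (circular), which makes the energy
identity `sum_j ||W_j||^2 + ||V_J||^2 = ||x||^2` exact and keeps all detail
series exactly epoch-length; with 1.8 s epochs, boundary effects at scale 4
are non-negligible, so the convention is stated rather than hidden.

### Entropy

For one sensor, band and trial, the wavelet entropy is the Shannon entropy
of the normalized energy distribution over time points,
`p_k = w_k^2 / sum(w^2)`, in bits. It is bounded by `log2(216) ≈ 7.75` bits
(attained by constant-magnitude series), invariant under amplitude scaling,
and low when band energy is concentrated in bursts. The published analyses
this design follows defer the exact entropy formula to supplementary
material that is not machine-readable; of the plausible readings
(distribution over time, over scales, or over an amplitude histogram) we
default to the time-point energy distribution because the analysis reports
entropy *per band*, which rules out the across-scale reading, and the
time-point form is the standard relative-wavelet-energy construction. An
amplitude-histogram estimator is available behind
`entropy_profile(estimator = "histogram")`.

### Connectivity

MI is estimated with a plug-in equal-width histogram (default 8 bins per
axis for 216 samples, roughly the `sqrt(n)/2` rule; quantile binning is an
option) and normalized by the geometric mean of the marginal entropies
(Strehl–Ghosh), clipping into `[0, 1]`. No small-sample bias correction is
applied; trial ensembles (66 networks per subject and kind) are the
mitigation. Per trial this yields 4 intra-band matrices and 6 inter-band
matrices — 660 networks per subject under the default protocol.

The inter-band raw matrix `raw[i, j] = NMI(i@f1, j@f2)` is not symmetric.
Binary graph diagnostics need an undirected graph, so the stored weights are
`(raw + t(raw))/2` with the diagonal (same-sensor cross-band coupling)
zeroed, mirroring the no-self-loop convention of the intra-band networks.
The raw matrix is retained as an attribute for inspection. A bipartite
2N-node construction would be an alternative reading; the symmetrized form
is the default because it keeps every downstream diagnostic directly
comparable between intra- and inter-band networks.

### Networks and diagnostics

Weighted matrices are converted to binary graphs by cumulative thresholding:
at density (cost) κ the `floor(κ N(N-1)/2)` strongest weights become edges.
Because all densities share one edge ranking, the graphs are nested along
the default grid κ = 0.01–0.50 (step 0.01), and multiplying the weights by
any positive constant leaves every binary graph unchanged — fixed-density
comparisons are blind to group differences in mean strength. Ties are broken
lexicographically so results are reproducible even on degenerate inputs.
κ = 0 (the empty graph) is excluded from diagnostics.

Thirteen diagnostics are computed at every density: path length, clustering,
global and local efficiency, betweenness, greedy-agglomerative modularity
(seeded random tie-breaking restarts), hierarchy exponent (−slope of
`log C(k)` on `log k`), synchronizability (Laplacian eigenratio
`λ2/λmax` of the largest component; the reciprocal convention is an option),
assortativity, robustness to targeted and to random attack (area under the
largest-component curve), mean connection distance, and the physical Rent
exponent (slope of log boundary-crossing edges on log enclosed nodes over
random axis-aligned boxes in the layout's native dimensionality). The
comparison grid uses twelve of these: path length is computed and exported
but replaced by global efficiency in the grid, the two being monotone
transforms of the same distance structure on a density sweep.

Conventions for fragmented graphs (inevitable at low κ): path length
averages over connected pairs only and carries a connectedness flag; global
efficiency uses the `1/∞ = 0` convention; any diagnostic that is undefined
(assortativity on regular graphs, hierarchy with fewer than two usable
degree classes, synchronizability with a largest component under 3 nodes,
Rent with fewer than 30 usable boxes) is reported as missing, never as
zero.

Cost-efficiency collapses the global-efficiency curve to
`max_κ (E_glob(κ) − κ)`, with the smallest maximizing κ reported on ties
(to within `1e-12`, so floating-point noise cannot flip a tie).

### Group and dynamics statistics

* Subject-level entropy and strength are compared between groups with a
  two-sample permutation test on means (default 10000 permutations,
  `p = (1 + #{permuted ≥ observed}) / (n_perm + 1)`), Holm-corrected within
  each measure's four bands.
* Diagnostic-versus-cost curves are compared with an FDA permutation test:
  the statistic is the integrated absolute group-mean difference over the
  grid (a supremum statistic is selectable), with 20000 label permutations
  by default. The 120 p-values (10 network kinds × 12 diagnostics) receive a
  joint Benjamini–Hochberg correction at `q = 0.05`; uncorrected flags at
  `α = 0.05` are reported alongside.
* Both permutation tests draw their label permutations over a canonically
  sorted pool with subset size `min(nA, nB)`, which makes the p-value
  exactly invariant under exchanging the two groups at a fixed seed.
* Trial-to-trial variability uses the CV (sample SD over mean — the n−1
  denominator is a stated choice) of each diagnostic across trials, averaged
  over costs, and a classical repeated-measures ANOVA with group as the
  between-subject factor and network kind and diagnostic as within-subject
  factors. Hierarchy and assortativity are excluded from the CV analysis
  (their values sit near zero, making the CV ill-conditioned), leaving 10
  diagnostics and the familiar 1/9/9/81 degree-of-freedom layout. No
  sphericity correction is applied, matching the classical univariate
  table; the F statistics should be read accordingly.
* Erdős–Rényi `G(n, M)` ensembles with exactly `floor(κ N(N-1)/2)` edges —
  matching the fixed-density construction rather than Bernoulli `G(n, p)` —
  provide the random-graph reference curves, 66 graphs per density by
  default (one per trial network).

## The synthetic cohort generator

No recordings ship with the package; `generate_cohort()` produces two-group
cohorts with the statistical structure the analysis is designed to detect.
Per band, latent narrowband Gaussian sources (4th-order Butterworth
band-pass magnitude applied spectrally to white noise; bandwidth half the
nominal scale-band width around centers θ 6, α 10, β 20, low-γ 45 Hz) are
mixed into sensors through a loading matrix that decays with distance on
the unit-radius hemispherical layout (`exp(−d/0.4)`), scaled by the band's
`coupling_scale`; each sensor also receives an independent narrowband
source and white noise. Four knobs map onto the analysis's observables:

* `coupling_scale` (per band) raises inter-sensor NMI and hence strength;
* `regularity` (per band, `[0, 1]`) concentrates each sensor's band
  envelope (`x ← x (e/ē)^{2r}`, rescaled to its original SD so band power
  is untouched) and thereby lowers wavelet entropy;
* `xfreq_coupling` (per band pair) modulates each sensor's high-band
  amplitude by its instantaneous unit-variance low-band waveform, raising
  inter-band NMI;
* `trial_jitter` perturbs the loading matrix independently per trial,
  raising the trial-to-trial CV of network diagnostics.

Two design points deserve an explicit record. First, "regularity" is
implemented as envelope *concentration*, not compression toward the mean:
under the time-point energy entropy, a flatter envelope would *raise* H, so
compression would invert the intended knob direction; concentration is the
construction under which more regular, stereotyped signals have lower
entropy, which is the contrast the analysis is designed to detect. Second,
the cross-frequency mechanism is amplitude modulation locked to the
low-band waveform rather than to its slow envelope: in Monte-Carlo probes
the envelope-driven variant produces only even-moment dependence that the
8-bin histogram-MI estimator cannot resolve at 216 samples (the
coupled-minus-uncoupled NMI difference was indistinguishable from zero),
whereas waveform-locked modulation is detected reliably. The generator
emulates dependence structure, not MEG physics: there are no lead fields,
no axial/planar geometry, and no artifacts, so passing tests demonstrate
that the pipeline recovers designed statistical structure, not that it
reproduces any property of real brains.

Determinism: one master seed derives per-subject and per-trial streams by
fixed arithmetic, so identical configurations reproduce cohorts
bit-for-bit, independent of trial batching.

The default group presets encode the qualitative contrasts the analysis
targets — the patient-like group has 1.4× band coupling, +0.25 envelope
regularity, doubled θ–γ gain and doubled trial jitter relative to controls —
i.e. higher strength, lower entropy and stronger cross-frequency coupling.
The CV of binarized network structure responds to the jitter-to-coupling
ratio rather than to jitter alone (stronger coupling stabilizes the ranked
edge structure), so the isolated-jitter contrast, not the combined preset,
is the calibrated test of the variability knob.

## Numerical and problem-size choices

* Rent boxes are pre-sampled once per layout (`make_rent_box_cache()`);
  membership depends only on coordinates, so one box set serves every
  trial, kind and density. Small layouts need more boxes for 30 usable
  samples (≈2500 at 10 sensors, ≈1000 at 16); the default 5000 suits
  full-size arrays.
* The modularity optimizer is greedy agglomeration with 10 seeded restarts;
  on every connected graph with ≤ 5 nodes and on bridged-clique benchmarks
  it attains the exhaustive-search optimum, but on larger graphs it is, like
  all greedy community detection, a lower bound.
* Validation simulations run on reduced problems chosen to preserve the
  statistical property under test: the type-I calibration of the FDA grid
  uses 8 subjects per group, 16 sensors, 20 trials, a 4-point density grid
  and 99 permutations over 200 replicates — permutation validity (uniform
  p under exchangeability) does not depend on grid resolution or
  permutation count, only the granularity of attainable p-values does.
  Directional knob-recovery runs use 3–4 subjects per group, 10 sensors and
  6 trials over 20 seeded replicates.

## Limitations

* The histogram MI estimator is biased upward at finite samples; the
  independent-noise floor is ≈0.05–0.1 NMI at 216 samples and 8 bins.
  Analyses should compare conditions under identical estimator settings,
  as the pipeline does; absolute NMI values are estimator-dependent.
* Binary-network results depend on the density sweep; the package follows
  the cumulative-threshold construction precisely so that comparisons are
  strength-blind, but weighted-network analysis is out of scope.
* The RM-ANOVA is the classical univariate table; with 10-level
  within-subject factors, sphericity is a strong assumption
  (Greenhouse–Geisser-style corrections are not applied in the default
  layout).
* Real-data preprocessing (artifact removal, planar transformation, head
  movement control) is out of scope: the pipeline starts from "clean"
  epoched sensor data.

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(
  cohort = cohort_config(n_subjects_per_group = 6, n_sensors = 16,
                         master_seed = 1),
  kappas = seq(0.05, 0.5, 0.05),
  n_perm_fda = 499, seed = 2
)
bundle <- run_pipeline(cfg, verbose = TRUE)
write_report(bundle, "megnets_out", plots = TRUE)
bundle
```
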