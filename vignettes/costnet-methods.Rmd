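---
title: "Methods: cost-thresholded brain networks and small-world statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-thresholded brain networks and small-world statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costnet)
```

## The analysis in one paragraph

Given per-subject parcellated ROI time series (a T×N table per subject),
costnet computes the N×N Pearson correlation matrix and its Fisher
z-transform, binarizes |z| over a *cost* (network density) sweep so that
every subject's graph has exactly the same number of edges at each
threshold, computes binary graph metrics at every cost — clustering
coefficient $C_p$, characteristic path length $L_p$, global efficiency
$E_{global}$, local efficiency $E_{local}$, nodal efficiency
$E_{nodal}$ — normalizes $C_p$ and $L_p$ against ensembles of
degree-preserving rewired random networks to obtain the small-world
indices $\gamma$, $\lambda$, $\sigma$, collapses each metric-versus-cost
curve into a single area-under-the-curve (AUC) scalar, and compares
groups with nonparametric permutation tests (global metrics, region-wise
nodal efficiency, and edge-wise tests with Bonferroni or network-based
statistic correction), plus covariate-adjusted correlations between
network metrics and a behavioral variable.

## Definitions and conventions

With $D_i$ the degree of node $i$ and $E_i$ the number of edges among
its neighbors,

$$C_p = \frac{1}{N}\sum_i \frac{E_i}{D_i (D_i - 1)/2}, \qquad
  L_p = \frac{1}{N(N-1)} \sum_{i \ne j} L_{i,j},$$

$$E_{global} = \frac{1}{N(N-1)} \sum_{i \ne j} \frac{1}{L_{i,j}}, \qquad
  E_{local} = \frac{1}{N} \sum_i E_{global}(G_i), \qquad
  E_{nodal}(i) = \frac{1}{N-1} \sum_{j \ne i} \frac{1}{L_{i,j}},$$

where $L_{i,j}$ is the unweighted shortest-path length and $G_i$ the
subgraph induced by the neighbors of $i$. Numerical conventions, chosen
where the equations are silent:

* **Fragmentation.** Low-cost graphs can be disconnected, making the
  $L_p$ sum undefined. $L_p$ here averages *finite* distances only and
  carries a count of disconnected pairs; efficiency metrics use
  $1/\infty = 0$, which handles fragmentation naturally. Whether
  fragmentation occurred is always reported (`fragmented`,
  `infinite_pairs`), so a user who prefers to discard fragmented costs
  can.
* **Low-degree nodes.** Nodes with $D_i < 2$ contribute clustering 0
  (and $E_{local}$ contribution 0) but stay in the mean, so $C_p$ is
  always an N-term mean consistent with the $1/N$ prefactor.
* **Identity.** $\text{mean}_i\,E_{nodal}(i) = E_{global}$ holds to
  machine precision by construction and is asserted in the tests.
* **Thresholding.** Cost is enforced by edge *count*: the
  $E = \mathrm{round}(c \cdot N(N-1)/2)$ (round half up) edges with the
  largest $|z|$ are kept. Rank thresholding — rather than a fixed z
  cut — is what makes topology comparable across subjects with
  different overall correlation levels. The absolute value means strong
  negative correlations also become edges. Ties at the cut are broken
  lexicographically by $(i,j)$ and logged; edge sets are therefore
  nested along the grid. The default grid is the 31 densities 0.10,
  0.11, …, 0.40: network metrics become unstable below ~0.10 (severe
  fragmentation) and lose specificity above ~0.40 (near-random density).
* **Fisher transform.** $|r|$ is clamped to $1 - 10^{-15}$ before
  `atanh`; a clamp is logged, never silent.

## Null models and small-worldness

Each network is compared against `n_null` random graphs with the same
node count, edge count, and degree sequence, generated by double-edge
swaps: pick two edges $(a,b), (c,d)$, rewire to $(a,d), (c,b)$, reject
self-loops and duplicates. The default attempts `swap_factor = 10`
swaps per edge, a standard mixing heuristic (configurable; complete
graphs admit no swap and are returned unchanged with a message). Then

$$\gamma = C_p / \overline{C_p^{rand}},\quad
  \lambda = L_p / \overline{L_p^{rand}},\quad
  \sigma = \gamma / \lambda .$$

A network is reported small-world when $\gamma > 1$ and $\sigma$
exceeds a configurable threshold (default 1; 1.1 available as a
stricter criterion). Fragmented ensemble members use the same
finite-pairs $L_p$ convention as real networks — consistency over
convention-mixing. Ensemble member seeds derive from a master seed via
a counter, so parallel or reordered evaluation cannot change results.

## Permutation statistics

Group tests use the pooled-variance two-sample t statistic and an
empirical null built by re-drawing group memberships of the original
sizes; two-sided p-values use the add-one estimator
$p = (1 + \#\{|t^{perm}| \ge |t^{obs}|\})/(n_{perm}+1)$, which is valid
under exchangeability and never exactly zero. Default 5000
permutations, $\alpha = 0.05$ for global and nodal tests.

Edge-wise tests operate on the *pre-threshold* Fisher-z values (t tests
on binarized 0/1 entries would be ill-posed). The primary edge-level
threshold is $p < 0.005$. Correction is either Bonferroni or the
network-based statistic: connected components of suprathreshold edges
are calibrated against the permutation null of the maximal component
statistic (component *extent* by default, sum-of-|t| *mass* as an
option).

Brain–behavior association uses partial correlation: metric and
behavior are residualized on age and education (plus intercept), the
residuals correlated, and p taken from the t distribution with $n-4$
degrees of freedom.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
imaging data. It emulates a two-group resting-state study: group A
("nonsmoker-like", 30 subjects by default) and group B ("smoker-like",
32), N = 246 regions, T = 170 volumes at TR = 2 s. Signals are drawn
from a block-structured correlation matrix — `within_module_corr`
(default 0.35) inside each of 6 near-equal modules,
`between_module_corr` (default 0.05) elsewhere — via the symmetric
matrix square root, plus iid sensor noise with `noise_sd = 0.5`
(correlation attenuation $1/(1+\sigma^2_{noise}) = 0.8$, a realistic
fMRI signal-to-noise regime), then column-standardized. The modular
structure is what makes the resulting cost-thresholded networks
small-world: within-module edges create triangles (high $C_p$), sparse
between-module edges keep paths short.

Two planted effects drive the group analyses:

* `clustering_deficit` multiplies group B's within-module correlation
  by $1-d$, producing lower clustering-type metrics ($C_p$,
  $E_{local}$) in group B — the headline group difference.
* `duration_effect` attenuates each group-B subject's within-module
  correlation further by $1 - s \cdot \text{duration}$, with durations
  lognormal (median 4.5 y, log-sd 0.5). This plants a *negative*
  metric–duration association recoverable by the partial-correlation
  stage. The recovery analyses use $d = 0.15$ and $s = 0.02$/year,
  chosen once so the planted brain–behavior correlation is moderate
  (|r| ≈ 0.2–0.5), matching the effect-size regime such studies report.

The generator's covariance is exactly block-constant — real functional
connectivity is heterogeneous, hierarchical, and spatially embedded —
and its samples are temporally white by default (an AR(1) knob exists
but defaults off, since band-pass filtering makes residual
autocorrelation irrelevant to the expectation of Pearson r). Passing
tests on synthetic data therefore demonstrate that the *pipeline*
recovers what was planted under a known covariance; they cannot certify
behavior on real fMRI, where covariance structure, motion artifacts,
and physiological noise are richer. The generator's signals stand in
for *already band-limited* data, so analyses of synthetic cohorts can
feed them to network construction directly; applying the band-pass
anyway is harmless but halves the effective temporal degrees of
freedom (the pass band covers ~28% of the spectrum), inflating
correlation sampling noise.

## Band-pass filter

The temporal filter (0.01–0.08 Hz) is implemented as a zero-phase
frequency-domain projection: Fourier coefficients outside the band
(including DC) are zeroed. We chose the ideal rectangular filter, a
standard choice in resting-state fMRI processing, because the contract
that matters for downstream correlation estimates is the measured
frequency response: unit pass-band gain, zero-phase (no distortion of
inter-regional correlation), exact linearity and idempotence. Low-order
IIR alternatives applied forward–backward fail the unit-gain contract
well inside the pass band (a 2nd-order Butterworth passes only ~0.69 of
the amplitude at 0.07 Hz and loses ~8% of pass-band RMS on refiltering);
the projection satisfies all of it exactly, at the usual price of
spectral leakage for strictly finite signals. Nuisance regression (the
14-parameter design: six motion traces, their derivatives, white-matter
and CSF signals) is applied *before* filtering, following standard
practice.

## Reproducibility and problem sizes

Every stochastic stage takes a seed; subject, ensemble and permutation
seeds derive from one master seed by a fixed counter scheme, so a run's
configuration echo reproduces it exactly, independent of scheduling.
The test suite exercises the study design at reduced, desk-scale sizes
chosen as the package's own test conditions: oracle checks on ~100
random graphs of up to 15 nodes (exhaustive Floyd–Warshall / triangle /
neighbor-subgraph oracles, agreement to 1e-12); a 20-subject, 90-ROI,
6-module cohort with 20 rewired nulls per network for the small-world
bounds; calibration of the permutation test (500 null repetitions) and
of NBS family-wise error (200 repetitions at 30 ROIs); and a 20-seed
recovery study at the full 30+32 subject design with 90 ROIs. The same
90-ROI cohort is what `scripts/acceptance.R` recomputes.

## Known limitations

* Strictly binary, undirected networks; no weighted variants,
  betweenness, modularity, or rich-club metrics.
* The bundled 246-region atlas file is a synthetic stand-in (generic
  labels, synthetic centroid coordinates) for visualization-export
  plumbing; substitute a real parcellation table for anatomical work.
* No volume-level preprocessing: the pipeline starts from parcellated
  time series.
* Whether a real study thresholds by rank or by a per-cost z cut is
  rarely reported; rank thresholding is used here because it equates
  edge counts exactly, and ties are handled deterministically.
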