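---
title: "Static and dynamic brain networks from free-viewing fMRI: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic brain networks from free-viewing fMRI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

During natural movie viewing, interareal coupling in the macaque brain is not
static: regions change their network role as the content of the scene changes.
`fvconn` implements a complete analysis chain for this question on two kinds of
input defined over a bilateral cortical parcellation (the study scale is 184
regions, 92 per hemisphere):

* **structural networks** from diffusion-tractography streamline counts, and
* **free-viewing functional networks** from regional BOLD time series recorded
  during movie watching in a 30 s movie / 30 s darkness block design
  (300 s runs, TR 1.5 s, 200 volumes),

and asks how eigenvector-centrality hubs of the functional network sit on the
structural modular architecture, and how hub membership reconfigures across
movie scenes in time-resolved connectivity.

Because the original imaging data cannot ship with a package, `fvconn` includes
a first-class synthetic cohort generator with planted ground truth; every
stage of the pipeline is validated by recovering what was planted.

# Network construction

**Functional.** Each regional series is optionally band-limited with a maximal
overlap discrete wavelet transform (MODWT, Daubechies extremal-phase `d4`,
five levels, circular boundary), keeping detail levels 2–3. At TR 1.5 s
(sampling rate `fs = 2/3` Hz) level *j* nominally covers the octave
`(fs/2^(j+1), fs/2^j]`, so levels 2–3 span roughly 0.042–0.167 Hz, the band
where block-locked hemodynamic events live. The printed frequency labels in
the source literature (0.125–0.06, 0.06–0.03 Hz) are inconsistent with these
TR-derived octaves; the implementation derives band edges from the TR and
reports them in the output metadata rather than hard-coding labels. The MODWT
is implemented in the package (pyramid algorithm) and is validated by its
additive reconstruction identity (`sum of details + smooth == input`), its
shift covariance, and per-level variance bookkeeping.

Pairwise Pearson correlations are stored as absolute values, with two-sided
t-distribution p-values. Edges are thresholded by Benjamini–Hochberg FDR at
`q = 0.01` over the `N(N-1)/2` unique pairs (the FDR procedure is a design
choice; the threshold level is the study's). The absolute value is taken
*before* thresholding, and p-values are two-sided for consistency.
Whole-brain correction is the default; per-hemisphere correction can be had by
masking. Both the sparsified weighted matrix and its binary indicator are
returned, with the threshold recorded in the object.

**Structural.** Pairs connected by strictly more than 10 streamlines are kept
(`n > 10`, a strict inequality: a count of exactly 10 is removed) and
surviving counts are log-scaled (base 10 by default; the base is metadata, as
the source states only "logarithmically scaled"). Graph measures use the
binarized survivor network; centrality and the structure–function comparison
use the weighted forms.

# Graph characterization

* **Density** globally and per hemisphere block (intra-L, intra-R, inter).
  The edge count decomposes exactly as `E = E_L + E_R + E_inter`.
* **Degree** with its complementary CDF using the inclusive convention
  `cCDF(k) = P(deg >= k)`, so `cCDF(0) = 1`.
* **Clustering** is the Watts–Strogatz local coefficient; nodes of degree < 2
  contribute `C_i = 0` to the mean.
* **Characteristic path length** is the mean shortest-path step count over
  *reachable* ordered pairs; unreachable pairs are counted and reported
  separately rather than poisoning the mean. This is dimensionless steps; the
  source literature prints path length in mm, which conflates edge length with
  hop count — Euclidean edge lengths are reported separately by
  `edge_distance_profile()`.
* **Null networks** are Maslov–Sneppen degree-preserving rewirings
  (10 attempted swaps per edge by default, seeds recorded), used to judge
  empirical clustering.

# Modularity

The modularity of a partition `{g_i}` at resolution `gamma` is

```
Q(gamma, {g_i}) = sum_ij [A_ij - gamma * k_i k_j / (2m)] delta(g_i, g_j)
```

kept deliberately *unnormalized* (no global `1/2m`), matching the printed
form; a normalized variant is exposed. Closed-form anchors: one module at
`gamma = 1` gives `Q = 0`; all singletons give `-gamma * sum(k_i^2)/(2m)`.

Optimization is Louvain (igraph) with the resolution parameter, best of
`n_restarts` runs with a random node permutation per restart. Determinism
comes from seeding the R RNG; the package does not re-implement the greedy
sweep, so tie-breaking follows igraph's internals rather than a
lowest-label rule — partitions are validated against exhaustive search on
small cases and planted-block recovery, not against a specific tie-break.

**Multiresolution consensus.** Partitions are sampled over a resolution sweep
(default 40 log-spaced values in `[0.5, 2]`, 5 samples each), accumulated into
a co-assignment frequency matrix with exact integer bookkeeping, and
recursively clustered. A split is attempted only where some co-assignment
exceeds a familywise null threshold `alpha`: the 95th percentile of the
per-permutation *maximum* off-diagonal co-assignment obtained by permuting
each sampled partition's labels over nodes (50 permutation rounds). The
max-statistic matters: a per-entry 95th percentile would flag ~5% of null
pairs by construction and shatter unstructured graphs into spurious modules.

One honest limitation: the label-permutation null tests *consistency across
the sampled partitions*, not "structure vs a random graph". A fixed
realization of an Erdős–Rényi graph has chance communities that Louvain finds
consistently, and the consensus will report them — they are real structure of
that realization. Only an ensemble-of-graphs null could suppress them. The
test suite therefore asserts the two properties this null does deliver:
complete graphs stay a single module, and rewired modular graphs carry no
trace of their pre-rewiring blocks.

# Centrality and hubs

Eigenvector centrality solves `x_i = (1/lambda) * sum_j C_ij x_j` on the
weighted thresholded matrix (the formula's `C_ij` are thresholded
correlations; a binary mode is available). The implementation is a shifted
power iteration on `A + cI` with `c = max row sum`: the shift leaves
eigenvectors unchanged and makes the Perron eigenvalue strictly dominant,
which plain power iteration lacks on bipartite spectra (a star graph
oscillates forever without it). Convergence is to `1e-13` on the iterate;
the fixed-point residual is tested at `1e-8`. The vector is sign-fixed
non-negative and normalized to unit sum, so absolute cutoffs are N-relative:
the static hub rule is `EC > 14e-3` together with `z > 1` (z-scored across
nodes, sample sd), the dynamic per-scene rule is `c > 1e-4` with `z > 1`.
On disconnected graphs the vector concentrates on the dominant component and
zero-mass components are reported.

`rank_centrality_summary()` averages centrality across any list of
hemispheres/subjects/runs sharing one region order (the source literature is
internally inconsistent about its n — 14 hemispheres in one place, n = 20 in
another — so the operation deliberately takes an arbitrary list).

# Time-varying connectivity (MTD)

The multiplication of temporal derivatives for regions *i, j* in a window of
`w` samples is

```
MTD_ij(t) = (1/w) * sum over window of [dt_i(s) dt_j(s)] / (sigma_i sigma_j)
```

with `dt` the first difference of the series and `sigma` its standard
deviation over the *whole run* (not per window). The default window is 12
samples = 18 s at TR 1.5 s. Two numerical choices make the identities exact:
derivatives are mean-centred and `sigma` is the population (1/n) sd, so the
full-run self-coupling is exactly 1 (tested to 1e-10) and anti-phase pairs
give exactly −1. Windows are trailing (causal) with the centre reported at
the mean of the window's derivative-sample times; window alignment is not
stated in the source, so it is recorded in the output. MTD is invariant to
per-region affine rescaling `a*x + b`, `a > 0`.

Because sigma is global, a *transient* burst of shared signal inside an epoch
produces window couplings well above the background correlation level — MTD
is deliberately amplitude-sensitive. This matters for interpreting hubs: a
region engaged in many epochs accumulates derivative variance and its
per-epoch couplings deflate relative to a region engaged once. The synthetic
hub experiment works with this property rather than against it (below).

**Epoch states.** The matrices of windows whose *centre* falls in
`[onset, offset)` (half-open, seconds) are averaged per scene label;
same-label epochs pool. Hubs are detected per state on |MTD| with zero
diagonal, pairwise hub-set overlap is Jaccard, and regions that are hubs in
two or more states are flagged poly-functional.

# The synthetic cohort

`generate_parcellation()` mirrors `n_per_hemisphere` regions across the
midline and scatters each bilateral module around a spatial centroid
(rejection-sampled to stay >= 16 mm apart, sd 4 mm), so modules are
spatially contiguous and distance decay and modularity are mutually
consistent.

`generate_structural_counts()` draws Poisson counts with expectation
`base_count * exp(-d/lambda_mm)` times an interhemispheric penalty and a
within-module gain. Two choices deserve comment:

* **Mirrored-distance callosal routing.** Cross-hemisphere pairs decay with
  the distance after reflecting one region across the midline, because
  callosal fibres run predominantly homotopically. This keeps bilateral
  modules coherent while different-module interhemispheric counts stay
  sparse. It also means Euclidean-binned counts are monotone in distance
  *within* a hemisphere only — homotopic pairs are the deliberate
  long-distance exception, as in real macaque connectomes.
* **Defaults** `lambda_mm = 7`, `base_count = 300`, `within_module_gain = 20`,
  `interhemi_penalty = 0.2` give a binarized structural density near 0.3
  with intrahemispheric ≈ 0.45 vs interhemispheric ≈ 0.19 and an
  order-of-magnitude within/between-module count contrast — the regime real
  tractography shows, and strong enough that the planted modules are the
  dominant community structure.

`generate_bold()` builds each region as global latent + module latent +
HRF-convolved block regressor + white noise. The variance budget
`v = noise_sd^2/(1 - c_w)` with global share `c_b * v` and module share
`(c_w - c_b) * v` hits the correlation targets (`c_w = 0.3`, `c_b = 0.1` by
default) exactly in expectation. The HRF is the gamma variate
`h(t) = (t/tau)^a exp(-(t - a tau)/tau)` with `a = 8.6`, `tau = 0.547` s,
peak-normalized (the standard primate/human default; the source names only
"gamma variate"). The stimulus response uses the unit-peak convolved
regressor at amplitude `0.5 * noise_sd` — a moderate evoked response that
leaves null-coupling cohorts with mean |r| < 0.1.

**Epoch hubs** are an additive latent active only inside the epoch, loaded at
`hub_gain * noise_sd` (default 4) on the epoch's hubs and a quarter of that
on every other region. An additive burst — rather than a variance-preserving
correlation change — is the signal MTD is built to detect; a
variance-preserving design was tried and is essentially invisible to a
global-sigma estimator. Scene epochs sit on stimulation blocks 2–5 by
default so that every scene has full sliding-window coverage (windows cannot
centre earlier than half a window into the run). The hub-recovery experiment
averages epoch states over two runs per session, matching the study's two
scan repetitions; under these conditions planted hubs are recovered and the
shared hub flagged poly-functional in ≥ 95% of seeds.

What the generator does **not** emulate: scanner drift and physiological
noise spectra, hemodynamic variability across regions, spatial
autocorrelation within modules beyond the shared latent, subject motion, and
the long-tailed weight distributions of real tractography. Passing tests
therefore demonstrate the estimators' correctness and the pipeline's
recovery power under idealized noise, not preprocessing robustness on real
data. One visible consequence: the epoch latents touch every region, so
synthetic functional densities after FDR run higher than the sparse
free-viewing networks of real data.

# Numerical choices and degenerate inputs

* Zero-variance regions: correlation edges set to 0 (p = 1) with a warning;
  MTD couplings set to 0 with a warning.
* Coherence `C(f0) = A(f0)/sqrt(sum_band A(f)^2)` uses the demeaned series
  (detrending optional), snaps off-grid `f0` to the nearest DFT bin with a
  warning, defaults the band to ±2 bins, and returns 0 with a warning when
  the band holds no power (the 0/0 case).
* tSNR is mean over population sd; zero-variance input returns `Inf` with a
  `zero_variance` attribute.
* Matrix TSV round-trips are bit-stable (17 significant digits).
* `run_pipeline()` manifests record parameters, seeds, package version and
  output checksums but no timestamps or paths, so reruns with one seed are
  byte-identical.

# Problem sizes used in validation

The test suite and the acceptance script validate at the study's structural
scale (184 regions) for module recovery (10 seeds), at 60 regions for the
100-seed dynamic hub experiment, with 200 null replicates (30 regions,
200 volumes) for FDR control, and with 50 random instances per estimator for
oracle equivalence at sizes where exhaustive `O(N^3)` checks are cheap
(N ≤ 15). These sizes were chosen so each property is measured with
comfortable statistical margin while the whole suite stays quick to run.
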