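---
title: "Extracting dynamic functional connectivity states: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting dynamic functional connectivity states: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(dfcstates)
```

Resting-state fMRI connectivity is not static: over a scan, whole-brain
correlation structure moves through a small repertoire of recurring
patterns, usually called functional connectivity (FC) *states*. `dfcstates`
implements a complete pipeline for estimating those states from
region-of-interest (ROI) time series and comparing their temporal and
topological properties between subject groups, together with a
Markov-switching simulator that plants known states so every stage can be
validated against ground truth.

## The model and the pipeline

Each subject contributes an `L x M` matrix of ROI signals sampled every
`TR` seconds (the motivating design uses `M = 90` atlas regions and
`TR = 2` s). The pipeline has five stages.

**1. Sliding-window connectivity.** A rectangular window of `w` TRs
(configured in seconds and converted as `round(seconds / TR)`; default 30 s,
hence 15 TRs) slides in steps of `step_tr` (default 1, the maximal temporal
resolution). In each window the Pearson correlation matrix is computed and
mapped through the Fisher R-Z transform `z = ½ log((1+r)/(1−r))`, which
stabilizes the variance of correlations near ±1. Correlations within
`1e-7` of ±1 are clamped before the transform so outputs stay finite; the
diagonal (self-correlation) is set to 0 and excluded from every downstream
vector and metric. No taper is applied.

**2. Two-stage state clustering.** Windows are vectorized to their
`M(M−1)/2` upper-triangle entries and clustered with k-means under the
Manhattan (L1) distance, which discriminates better than L2 in this
high-dimensional setting. Because clustering every window of every subject
directly is redundant and expensive, stage 1 clusters only *exemplars* —
each subject's `n_exemplars = 7` windows with the largest population
variance across their FC entries (windows with crisp, strongly modular
patterns rank high) — using k-means++ seeding and 50 restarts. The stage-1
centroids then initialize a single stage-2 run over all windows of all
subjects, run to convergence. States are finally ordered by descending
centroid mean, so State 1 is always the most strongly connected pattern.

Two numerical choices deserve comment:

* *Centroid update.* With an L1 assignment rule the centroid update that
  is consonant with the objective is the coordinate-wise **median**
  (k-medians); it makes the recorded objective provably non-increasing
  across iterations, and it is what the widely used city-block k-means
  implementations do. The coordinate-wise mean — the textbook update for
  the squared-L2 objective — is available via `update = "mean"`.
* *Empty clusters* are repaired by re-seeding the empty centroid at the
  sample farthest from its current assignment, which cannot increase the
  objective; repairs are counted in the fit object.

**3. Choosing the number of states.** `elbow_select_k()` clusters the
pooled exemplars for each candidate `k` (default 2–10) and records a
clustering effectiveness index: the mean over samples of the ratio of the
sample's intra-cluster distance to its distance to the nearest other
cluster. The index falls while new clusters separate genuine structure and
rises once they begin splitting homogeneous clusters, so the chosen `k`
is the curve's minimum. We initially implemented the common alternative —
the largest second difference ("sharpest bend") of a pooled
intra/inter-distance curve — but found it unreliable when state
separations are hierarchical (one state much farther from the rest than
the others are from each other), which is exactly the geometry produced
by states ranked by mean connectivity: the curvature then splits between
the true `k` and smaller values. The per-sample ratio index identified the
planted `k` in every cohort replicate we examined while still selecting
`k = 2` for two-cluster data. The full curve is returned and plotted by
`autoplot()`, and a fixed `k` always overrides the rule.

**4. Temporal dynamics.** From each subject's window-state sequence we
compute per-state occupancy fractions, mean dwelling time (mean length of
maximal runs, in windows; multiply by `step_tr * TR` for seconds), visit
counts, and the total number of transitions. Group differences use the
classic pooled-variance two-sample t-test (Welch's form behind a flag).
Subjects who never visit a state are excluded from that state's dwell-time
test rather than zero-imputed — absence is not the same as a short visit —
and the exclusion count is reported.

**5. Graph topology and edge statistics.** Each state matrix is
thresholded at `tau = 0.3` on the Fisher-Z centroid values (entries
*strictly below* the threshold, including all negative values, are treated
as disconnected). On the binarized graph we compute degree, clustering
coefficient `2tᵢ/(kᵢ(kᵢ−1))`, breadth-first shortest paths,
characteristic path length (averaged over reachable pairs only, with the
number of excluded pairs reported), global efficiency (mean inverse
distance with `1/∞ = 0`, so it remains meaningful on disconnected
graphs), local efficiency on each node's neighbour-induced subgraph,
Louvain modularity (10 seeded restarts, best Q kept), the participation
coefficient `1 − Σ_m (k_im/kᵢ)²`, and the within-module degree z-score
(population-sd denominator; modules with zero spread give z = 0). The
nodal formulas are written for binary graphs, so binary is the default
mode; weighted degree (sum of suprathreshold weights) is reported
alongside because hub rankings are often quoted on weights.

Edge-wise group tests operate on per-subject state connectivity: a
subject's edge value for a state is the mean of their windowed Fisher-Z
matrices over the windows assigned to that state (subjects with no window
in the state are excluded and logged). Per-edge two-sample t maps feed
either Benjamini-Hochberg FDR (edge-level control) or the network-based
statistic (NBS): connected components of edges with `|t|` above a primary
threshold (default 3.0, in the range of typically reported significant
edge statistics) are assessed against the permutation null distribution of
the maximal component size under full relabeling of subjects, giving
family-wise control at component level. Permutation p-values use the
`(1 + b)/(P + 1)` estimator and are therefore never exactly zero.

## The synthetic cohort generator

`generate_cohort()` emulates preprocessed ROI time series with
piecewise-stationary covariance. Each state is a correlation matrix built
from a module partition: within-block correlations are raised by
`block_contrast = 0.3` above the state's target mean and between-block
correlations lowered so the mean off-diagonal correlation hits the target
within ±0.05 (verified at construction; matrices are repaired to positive
definiteness by doubling diagonal loading from `1e-6`, with the repair
count recorded). States after the first apply the partition to a seeded
random permutation of the regions, so any two states differ substantially
in *pattern*, not just in overall level — the defining property of
distinct connectivity states. Default mean-FC levels are
0.58/0.39/0.25/0.20, a descending four-state profile typical of published
state decompositions.

State switching is a first-order Markov chain at time-point resolution;
group differences are planted through group-specific transition matrices
(dynamics-level effects) and/or additive per-edge covariance deltas
(edge-level effects for NBS validation). Observations are zero-mean
Gaussian draws from the active state's covariance plus isotropic noise
(`noise_sd = 0.2`; mild, so the observed correlations stay within the
targeted band — heavier noise attenuates all correlations below their
nominal levels). Two stock designs are provided:

* `mci_like_cohort_spec()` — three groups of 67/48/45 subjects with
  self-transition probabilities 0.95/0.90/0.80, so the control-like group
  dwells longest and the most affected group switches most.
* `state_recovery_cohort_spec()` — three groups of 30 with a shared slow
  self-transition (default 0.98; the validation suite uses 0.99). Slow
  switching matters for *window-level* validation: with mean dwell times
  shorter than the window, most windows straddle a transition and no
  method can recover window labels (with self-transition 0.80–0.95 and
  15-TR windows, even an oracle classifier using the planted centroids
  reaches a label agreement of only ARI ≈ 0.25). At self-transition 0.99
  the oracle — and the pipeline — reach ARI ≈ 0.94.

What the generator deliberately omits: hemodynamic response convolution,
within-state temporal autocorrelation, scanner drift, motion artifacts,
and spatial atlas structure. Under the i.i.d.-within-state model, windowed
Pearson correlation is a consistent estimator of the planted state, which
is what makes clean ground-truth validation possible; real fMRI violates
these assumptions, so passing tests demonstrate the correctness of the
algorithms, not expected effect sizes on real data.

## A worked example

```{r example, fig.width = 6, fig.height = 4}
spec <- state_recovery_cohort_spec(
  n_per_group = c(NC = 6, eMCI = 6, lMCI = 6),
  n_regions = 16, n_timepoints = 120, seed = 42)
cohort <- generate_cohort(spec)

report <- run_pipeline(cohort, window_seconds = 30, k = 4,
                       n_restarts = 20, n_permutations = 200, seed = 42)
report
tidy(report$states)
glance(report)
```

```{r plots, fig.width = 7, fig.height = 5}
autoplot(report$states)
plot_state_dynamics(report$dynamics)
```

## Validation suite: what is checked, and at what size

The package's tests validate every stage against independent oracles:
the Fisher transform against its closed form; all graph indicators
against brute-force enumeration (Floyd-Warshall paths, explicit triangle
counts, induced-subgraph efficiencies) on hundreds of random graphs of up
to 8 nodes; k-medians against the exhaustive optimum on 12-sample
one-dimensional instances (where L1-optimal partitions are contiguous in
sorted order, making exhaustive search exact); state recovery, elbow
stability (20 generator seeds), bootstrap stability (20 replicates) and
window-length robustness (30–60 s) on the 90-subject, 30-region,
150-time-point recovery cohort; dynamics detection on 40-subject-per-group
fast/slow cohorts; and NBS type-I error (200 null replicates) and power
(50 replicates with a planted 6-edge star component) at 200 permutations
per replicate. Bootstrap and sweep replicates use 20 stage-1 restarts
rather than the default 50; on these well-separated cohorts results are
insensitive to the restart count, and the reduction keeps the suite quick.

## Known limitations

* The elbow index requires at least two candidate cluster numbers and
  cannot distinguish `k = 1` from `k = 2`; inspect the returned curve
  when no multi-state structure is expected.
* Dwell-time estimates are biased upward for states whose true dwell is
  shorter than the window, because windowed labels smooth fast switching.
* The NBS implementation tests two groups at a time; multi-group designs
  are handled pairwise without omnibus correction.
* Covariate adjustment (age, sex, education) is out of scope; group
  comparisons are plain two-sample tests.
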