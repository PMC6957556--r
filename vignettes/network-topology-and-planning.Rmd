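---
title: "Linking resting-state connectome topology to planning performance: methods and design"
author: "PlanTopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking resting-state connectome topology to planning performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PlanTopo)
```

# The analysis problem

PlanTopo implements a complete analysis chain relating the topology of
resting-state functional brain networks to performance on the Tower of
London (ToL) planning task. The chain is: parcellated ROI time series
(about 192 volumes at TR = 1.8 s, 194-225 nodes grouped into the
default-mode, frontoparietal, dorsal- and ventral-attention networks
plus unassigned nodes) → per-subject functional-connectivity matrices by
band-averaged wavelet coherence (0.06-0.12 Hz) → weighted graph measures
(global and per-subnetwork efficiency and clustering, within- and
between-network mean FC) → bootstrapped hierarchical regression of ToL
accuracy and reaction time on those measures, controlling age and head
motion, with BCa confidence intervals, bootstrap P values and
Benjamini-Hochberg FDR control across subnetwork tests.

Because no raw imaging data are distributed with studies of this design,
the package ships a synthetic-cohort generator whose defaults encode the
study conditions the analysis assumes. Every downstream stage is
therefore testable end to end, and the statistical machinery can be
validated by simulation (type-I error, power, interval coverage) rather
than by re-deriving unavailable empirical tables.

# The Tower of London model

Three distinct beads sit on three posts of capacities 3, 2 and 1; one
bead moves at a time, only from the top of a stack, only onto a post
with free capacity. The state space has exactly 36 configurations (six
occupancy patterns times 3! bead orders), is connected, and has graph
diameter 8; difficulty levels are the minimal move counts 1-5 computed
by breadth-first search over the full graph (all-pairs distances are
precomputed once and cached — the graph is tiny, so exactness costs
nothing). Scoring follows the task's convention: accuracy is the
percentage of trials whose answered minimum-move count is exact; mean
reaction time is computed over correct trials only. A level-restricted
variant (levels 4-5 only) supports the high-load re-analysis.

Two RT-averaging conventions exist (pool all correct trials, or average
within level first); both are implemented and pooling is the default,
since trial counts per level are balanced by construction and the two
then differ only through accuracy imbalances.

# Wavelet coherence

Connectivity is the band mean of the magnitude-squared wavelet
coherence,

$$
C_{xy}(s,t)=\frac{\left|S\!\left(W_x(s,t)\,W_y^{*}(s,t)\right)\right|^{2}}
{S\!\left(|W_x(s,t)|^{2}\right)\,S\!\left(|W_y(s,t)|^{2}\right)},
$$

with $W$ a complex Morlet continuous wavelet transform (centre
frequency $\omega_0 = 6$, computed in the frequency domain with
zero-padding) and $S$ a smoothing operator. **Smoothing is essential**:
without it the magnitude coherence is identically 1 at every point of
the scale-time plane. $S$ is a Gaussian filter in time whose standard
deviation equals the scale (so the effective averaging window tracks
the oscillation period) followed by a boxcar over one adjacent scale on
each side. The scale grid is 12 log-spaced frequencies spanning
0.04-0.18 Hz so that the 0.06-0.12 Hz averaging band is interior to the
grid.

Choices the upstream literature leaves open, resolved here as package
defaults:

* **Squared vs unsquared coherence** — the squared value is stored
  (bounded energy interpretation); `waveletSpec(squared = FALSE)`
  exposes the square root.
* **Cone of influence** — coefficients within $\sqrt{2}\,s$ (the Morlet
  e-folding time) of either record edge are excluded from band-time
  means; `coiPolicy = "keep"` retains them for short records.
* **Why not Pearson correlation** — band-restricted coherence is robust
  to broadband artefacts and confines the statistic to a frequency
  range reported to be reliable for cognitive associations; a smoothed
  coherence is also bounded in [0, 1] with a stable null level.

The null level matters for interpretation: with these smoothing windows
and 192 volumes, two *independent* white-noise series have band-mean
coherence around 0.35 (not 0), because finite smoothing windows leave
positive bias. All downstream comparisons are therefore relative
(between subjects or conditions), never against zero.

# Graph measures

The analysis is fully weighted — no threshold or binarization is
applied anywhere, which avoids an unreported free parameter and keeps
every measure a smooth function of the coherence values.

* **Global efficiency** $E = \frac{1}{n(n-1)}\sum_{i\neq j} 1/d_{ij}$,
  with shortest weighted paths $d_{ij}$ over edge lengths $1/w$
  (`lengthTransform = "neglog"` gives $-\log w$ as an alternative).
  Disconnected pairs contribute zero (this cannot occur on a complete
  coherence matrix but matters if a user thresholds one). Paths use
  Dijkstra's algorithm via igraph; the test suite validates against an
  independent Floyd-Warshall implementation.
* **Clustering** uses the Onnela geometric-mean-of-triangles form on
  weights normalized by the maximum off-diagonal entry; it is bounded
  in [0, 1] and reduces exactly to the classic
  proportion-of-neighbor-edges definition on binary graphs (validated
  against triple enumeration and an independent binary implementation).
* **Subnetwork measures** are computed on the induced subgraph: paths
  may not route through out-of-network nodes. This is the standard
  "within-network" reading; the alternative (full-graph paths
  restricted to within-network endpoints) answers a different question
  and is not implemented.
* **Within/between-network FC** are plain block means of the coherence
  matrix (diagonal excluded), six between-network values for the four
  named networks, four within-network values.

# Quality control

* **Motion.** Frame-wise displacement is the rigid-body root-mean-square
  displacement of a solid sphere of radius 80 mm under the relative
  transform between consecutive volumes,
  $\mathrm{RMS}=\sqrt{\tfrac{r^2}{5}\,\mathrm{tr}(A^{\mathsf T}A)+b^{\mathsf T}b}$
  with $A = R_\mathrm{rel}-I$ — the exact closed form of the
  point-cloud average, which the tests verify by numeric integration.
  Subjects are excluded when mean relative RMS > 0.2 mm or when more
  than 20 transitions exceed 0.25 mm (both thresholds configurable,
  defaults as printed).
* **Behavior.** |z| ≥ 2 (inclusive) on accuracy or RT, z computed once
  over the candidate pool — a single pass, no iterative re-exclusion
  (recomputing z on the reduced pool could cascade; the one-shot rule
  matches how such criteria are applied in practice). An interval of
  more than 21 days between scan and task (exclusive: 21 days is
  admissible) and missing task data are also exclusion reasons.
* **Harmonization.** Nodes with fewer than 4 signal voxels in any
  subject are dropped for all subjects; the common set is the
  order-preserving intersection. The default full-size generator
  produces 225 nodes of which 31 are planted low-signal, leaving 194
  common nodes.

# The regression machinery

For each outcome (accuracy, RT — overall or levels 4-5) and each
network measure, nested OLS blocks are fit in the fixed order age →
measure → mean relative RMS, optionally followed by sex or education as
a sensitivity block. The final model's coefficients are the headline
outputs, with the R² of every nested model reported.

Inference is by case-resampling bootstrap (whole rows, 2000 replicates
by default): resampling rows rather than residuals keeps the procedure
valid under heteroscedasticity. Confidence intervals are BCa: bias
correction $z_0$ from the fraction of replicates below the point
estimate (ties split evenly, so exact symmetry gives $z_0=0$; a
one-sided degenerate case is clamped to the value implied by half a
replicate and flagged in the result's notes), acceleration $a$ from
jackknife skewness. The bootstrap P value is defined by interval
inversion: the smallest $\alpha$, on a grid of step 0.001 floored at
$1/B$, at which the $1-\alpha$ BCa interval excludes zero. This makes
"CI excludes 0 ⇔ P < 0.05" hold by construction up to grid resolution.
Values at the floor are reported at the floor and flagged.

Simulation calibration under the generator's study conditions (n = 62):
95% BCa intervals for a Normal mean (n = 30, B = 2000) cover at ≈ 93%;
the type-I error of the integration coefficient under a null generator
is ≈ 5-6%; power for a planted standardized effect of 0.4 is ≈ 95%.
The acceptance script recomputes all three.

**Correlations** use Pearson or Spearman, chosen automatically by a
Shapiro-Wilk check (α = 0.05) on each variable — the conventional
realization of "depending on the distribution" when no test is named.

**FDR families.** Benjamini-Hochberg at q = 0.05 is applied per outcome
and per family: the 8 subnetwork topology tests form one family, the 6
between-network FC values another, the 4 within-network values a third;
the two global measures are uncorrected. Correcting all 18 subnetwork
quantities as one family is defensible but conflates measures with
different null behavior; per-family correction also matches how the
between-network results are reported with a common adjusted value.

# The synthetic cohort

What the generator emulates, and how:

* **Signals.** Each named network has a shared band-limited (0.06-0.12
  Hz) Gaussian component built by Fourier masking of white noise (not
  sinusoids, so coherence is spread realistically across the band); a
  global component mixed in with weight $\sqrt{\text{couplingBetween}}$
  produces between-network coherence. Node $=$
  $c\cdot$shared$+\sqrt{1-c^2}\cdot$noise with $c$ the product of a
  subject-level coupling (Beta(2,2) mapped to [0.35, 0.8] — the
  inter-subject topology variability no study reports a distribution
  for, so this is a documented modelling choice) and a per-network
  multiplier. Columns are standardized exactly.
* **Motion.** Random-walk six-parameter traces; step sizes are
  calibrated so severity 1 gives a mean relative RMS near 0.068 mm with
  a lognormal severity spread matching the reported 0.027-0.17 mm
  range.
* **Demographics.** Age truncated-normal 48.1 ± 13.9 on [21, 74], 46.8%
  female, Verhage education levels 3-7 with the reported frequencies,
  scan-task interval 0-21 days.
* **Behavior.** Trial-level ToL responses over a seeded balanced
  problem set (10 trials per level by default — the trial count per
  level is not standardized across task versions, so it is
  configurable). Subject-level means follow a linear model expressed in
  standardized effects: age→RT 0.5, integration→RT 0.22, age→accuracy
  −0.24 by default, with totals set to reproduce accuracy 87.7 ± 7.5%
  and RT 10.1 ± 2.1 s. Because trial scoring adds noise, measured
  spreads are slightly wider than the targets; planted effects are set
  on the latent scale.
* **Planted QC violators.** Configurable fractions of subjects violate
  each exclusion rule; they are labeled in a hidden ground-truth table
  so QC tests can assert exact recovery. When violators are planted,
  the generator guarantees exactness: compliant subjects' behavioral
  deviations are clipped at 1.5 SD of the compliant pool, trial scoring
  is made deterministic, and compliant motion traces are damped away
  from the thresholds. (Without planted violators — the analysis
  default — natural 2 SD outliers occur at the expected Gaussian rate,
  which is realistic and intended.)

What it does **not** emulate: hemodynamic response shapes,
physiological (cardiac/respiratory) noise, spatial structure within
nodes, scanner drift, or any voxel-level property. Passing tests
demonstrate the correctness and calibration of the analysis chain under
the assumed statistical structure, not robustness to every artefact of
real fMRI.

# Statistical validation strategy

The Monte Carlo checks of type-I error and power run the regression
stage on cohorts generated without time series, using the generator's
latent integration variable as the network measure. This deliberately
isolates the inferential machinery from wavelet-stage sampling
variance; the full route (time series → coherence → graph metrics →
regression) is exercised by the end-to-end emulation, where measured
global efficiency correlates > 0.9 (Spearman) with the planted coupling
— so the latent variable is an accurate stand-in at a fraction of the
cost.

Problem sizes were chosen to keep each check sharp but cheap: 2000
coverage simulations, several hundred null regressions at n = 62 with
B = 500, 100 power runs, and a 62-subject, 60-node end-to-end emulation
(the full 194-node analysis scales quadratically in nodes and runs the
same code paths).

# Numerical and degenerate-input policy

* Constant (zero-variance) series make coherence undefined: an error
  naming the offending node, never a silent NaN.
* Non-finite samples, malformed motion rows, empty harmonized node
  sets, rank-deficient designs and out-of-range P values all raise
  errors naming the offender.
* A trial subset with no correct responses leaves mean RT `NA` with a
  warning (never silently zero).
* More than 1% rank-deficient bootstrap refits aborts the bootstrap
  with diagnostics; isolated singular refits are dropped.
* All randomness flows from explicit seeds; every stage derives its
  substream from the root seed, so any stage is independently
  reproducible and a full pipeline run is bit-identical across re-runs
  (no timestamps are written into results).

# Known limitations

* The wavelet smoothing windows, COI rule and squared-coherence choice
  are conventions; absolute coherence levels (including the ≈ 0.35
  independent-noise floor) depend on them, so only relative comparisons
  are meaningful.
* Subnetwork efficiency on induced subgraphs is one of two defensible
  readings of "within-network efficiency".
* BCa P values by interval inversion are one construction of "the P
  value accompanying a BCa interval"; other software may invert
  differently near the grid floor.
* The generator's linear behavioral model and Beta coupling
  distribution are modelling choices, stated, not claims about any
  empirical cohort.
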