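# PlanTopo

Links resting-state functional brain-network topology to planning
performance on the Tower of London (ToL) task, for researchers studying
how the connectome's balance of integration and segregation relates to
executive function in healthy adults.

The analysis chain:

1. **Functional connectivity** — for every pair of parcellated ROI time
   series (≈ 192 volumes at TR = 1.8 s), the band mean over 0.06–0.12 Hz
   of the smoothed magnitude-squared wavelet coherence

   C(s,t) = |S(Wₓ W*ᵧ)|² / ( S(|Wₓ|²) · S(|Wᵧ|²) ),

   with W a complex Morlet CWT (ω₀ = 6) and S Gaussian-in-time /
   boxcar-in-scale smoothing, giving a symmetric node × node matrix in
   [0, 1].
2. **Graph measures** on the fully weighted matrix (no thresholding):
   global efficiency E = mean over pairs of 1/d(i,j) with edge length
   1/w (integration), Onnela weighted clustering Gcc (segregation), the
   same two per resting-state network (DMN, FPN, DAN, VAN) on induced
   subgraphs, and within- (4) and between-network (6) mean FC.
3. **Quality control** — rigid-body frame-wise RMS displacement over an
   80 mm sphere (exclude mean > 0.2 mm or > 20 spikes > 0.25 mm), |z| ≥ 2
   behavioral outliers, scan-task interval > 21 days, and harmonization
   to nodes with ≥ 4 signal voxels in every subject.
4. **Inference** — bootstrapped hierarchical regression (blocks: age →
   network measure → motion, optional sex/education), 2000 case
   resamples, BCa 95% CIs, bootstrap P values by interval inversion,
   standardized betas, nested-model R², and Benjamini–Hochberg FDR
   (q < 0.05) per subnetwork family.

An exact 3-bead ToL solver (36-state BFS, minimal-move problems at
difficulty levels 1–5, accuracy/RT scoring with a levels-4–5 variant)
and a synthetic-cohort generator (band-limited modular BOLD-like
signals, motion traces, demographics, and behavior with planted
standardized age and network-integration effects) make the whole chain
testable without access to raw imaging data.

## Worked example

A small end-to-end run (24 subjects, 25 nodes; the defaults emulate the
full design at 62 subjects and 60 nodes):

```r
library(PlanTopo)
cfg <- pipelineConfig(
  cohort = cohortConfig(nSubjects = 24L, nVolumes = 128L,
                        partitionSizes = c(DMN = 8L, FPN = 6L, DAN = 6L,
                                           VAN = 5L, other = 5L),
                        lowSignalNodes = 2L),
  measures = c("GE", "Gcc"), nBoot = 1000L, seed = 7L)
res <- runPipeline(cfg, "demo_results")
show(res$matrices[[1]])
show(res$regressions[["tol_rt_s.GE"]])
```

```
CoherenceMatrix: 28 nodes, band 0.06-0.12 Hz
   off-diagonal coherence: mean 0.396, range [0.184, 0.717]
Bootstrapped hierarchical regression of tol_rt_s (n = 22, 1000 replicates)
  term                           B (      SE) [  CI low,  CI high]    Beta   P_bca
  age_years                  0.043 (   0.021) [  -0.007,    0.083]   0.393   0.090
  GE                        15.882 (  12.242) [  -9.386,   42.156]   0.278   0.226
  motion_mean_rms           24.053 (  10.533) [   2.552,   41.995]   0.487   0.031
  nested-model R2: 0.128 -> 0.133 -> 0.327
```

Two of 24 subjects were excluded by QC (hence n = 22), and 2 of 30
generated nodes were dropped by voxel-count harmonization (28 common
nodes). The coherence matrix's off-diagonal mean (0.396) sits above the
independent-noise floor (≈ 0.35 at these smoothing parameters — smoothed
coherence is positively biased, so only relative comparisons are
meaningful). In the final regression block, B is the unstandardized
coefficient (seconds of RT per unit predictor), Beta the standardized
one, and the BCa interval/P value come from 1000 case resamples: at this
small n the planted positive integration→RT effect (standardized 0.22
in the generator) yields a positive but non-significant GE coefficient
(Beta = 0.278, P_bca = 0.226); at the default 62-subject scale the
acceptance script recovers it reliably. The nested R² sequence shows the
incremental variance explained by age, GE, and motion.

The result directory contains the serialized config, the cohort, a QC
report with an exclusion-flow summary, per-subject FC matrices (TSV +
JSON sidecar), the metrics table, and Table-style regression output per
outcome with raw and FDR-adjusted P values. Re-running with the same
config reproduces the tree bit-identically.

A command-line front end with `run | simulate | qc | connect | metrics
| stats` subcommands is installed at
`system.file("scripts", "pipeline.R", package = "PlanTopo")`.

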