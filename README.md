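# gastroSync

Phase synchronization between the stomach's slow myoelectrical rhythm and
the brain's BOLD signal, from concurrent electrogastrography (EGG) and
resting-state fMRI.

The stomach generates a ~0.05 Hz electrical rhythm (three cycles per
minute) measurable with cutaneous electrodes. A set of brain regions — the
"gastric network" — shows BOLD fluctuations phase-locked to it. gastroSync
is an R implementation of the full analysis chain used to map and stress-
test that coupling, for researchers who want a reproducible, offline-
testable pipeline:

* **EGG preprocessing** — resampling (5000 → 10 Hz), Welch spectra (200 s
  windows, 150 s overlap), gastric-peak detection in the normogastric band
  (0.033–0.066 Hz), channel selection, ±0.015 Hz zero-phase FIR filtering,
  and three-level quality grading with exclusion of ungradable recordings.
* **BOLD preparation** — four documented nuisance-regression variants
  (strict with/without global signal, strict + cardiac RETROICOR, minimal
  CSF-only), masked 3 mm Gaussian smoothing, voxelwise gastric-band
  filtering, and motion-based run exclusion (mean FD > group mean + 2 SD).
* **Synchrony** — the phase-locking value per voxel,

  PLV(x,y) = | (1/T) Σ_t exp(i(θx(t) − θy(t))) |,

  referenced to a circular-shift surrogate null (shifts of at least ±60 s;
  360 surrogates for a 15-min run, 210 for 10 min) through the per-voxel
  median ("PLV-delta"), plus a cross-subject surrogate variant.
* **Group inference** — paired t-maps, cluster mass at t > 2.3, max-mass
  sign-flip permutation FWE, Benjamini–Hochberg FDR, Dice overlap, and a
  hemisphere-symmetric spin test on spherical annotations.
* **Confound synchrony** — PLV of ten nuisance series with the gastric
  rhythm, shifted-EGG nulls, and the relation of confound synchrony to
  brain-wide PLV-delta under minimal versus strict preprocessing.
* **Reliability** — run-to-run correlation of summary synchrony,
  parcelwise similarity across runs, EGG-peak reliability, and functional-
  connectivity fingerprinting.
* **Synthetic cohorts** — seeded generators for EGG/BOLD/confound/PPG data
  with controllable coupling, confound contamination and subject
  stability, with ground truth stored alongside, so everything above is
  testable end to end with no downloads.

## Worked example

A six-subject synthetic cohort with a 27-voxel coupled block, run through
the whole pipeline:

```r
library(gastroSync)

cfg <- simConfig(nSubjects = 6, runsPerSubject = 1, runDurationS = 600,
                 gridShape = c(8, 8, 8), nCoupledVoxels = 27,
                 couplingPlvTarget = 0.7, couplingRange = c(1, 1),
                 seed = 111)
cohort <- genCohort(cfg, includePpg = FALSE)
bundles <- lapply(cohort$subjects, function(s) bundleFromSim(s[[1]]))
res <- runPipeline(bundles, pipelineConfig(nPerm = 1000, fwhm = 0,
                                           variant = "minimal", seed = 3))
res$group$clusters
nullLags(res$runResults[[1]]$nulls) |> length()
truth <- cohort$subjects[[1]][[1]]$truth
diceSimilarity(res$group$significantMask,
               seq_len(512) %in% truth$coupledIdx)
```

which prints

```
ClusterSet: 11 cluster(s), t > 2.3 , connectivity 26
   cluster size       mass       p_fwe
1        1   44 214.043554 0.008991009
2        2    6  20.830659 0.240759241
3        3    2   6.224316 0.767232767
4        4    1   5.646658 0.820179820
...
[1] 210
[1] 0.7605634
```

Reading this: each of the 300-volume (10-minute) runs yields 210
circular-shift surrogates; the group sign-flip test finds one large
44-voxel cluster (mass 214, family-wise p = 0.009) that overlaps the
ground-truth 27-voxel coupled block with Dice 0.76, while the scattered
small clusters are correctly non-significant.

## Data formats

EGG and PPG are tab-separated sample tables with a JSON sidecar (`fs`,
channel labels, identifiers); BOLD volumes and masks are NIfTI-1 (via
RNifti); confounds are fMRIPrep-style tab-separated tables; sphere
annotations are per-vertex tables (vertex, x, y, z, label). See
`?loadRunBundle` and `?runPipeline`.
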