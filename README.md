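# drillscore

Automated scoring of drilled-tooth outcomes from virtual dental surgery
training, for simulator developers and dental-education researchers who
need an objective stand-in for instructor ratings of root-canal access
openings.

A drilling outcome is a 3D voxel occupancy volume.  Comparing the
student's *actual* outcome with an expert-approved *ideal* outcome over
the voxels of the *initial* tooth yields the confusion counts of the
"undrilled" class — TP (correctly undrilled), TN (correctly drilled),
FP (under-drilling), FN (over-drilling).  From precision
`P = TP/(TP+FP)` and sensitivity `S = TP/(TP+FN)`, linearly rescaled by
their empirical anchors,

    P~ = (P − 0.95) / 0.05        S~ = (S − 0.2) / 0.8

the **Dentist score** flips a weighted mean of the two onto the 0–15
clinical rubric scale (0 = ideal, lower is better):

    D = (1 − (1.5·S~ + P~) / 2.5) · 15
      = 15·(32·FP·TP + 3·FN·TP + 35·FN·FP) / (4·(TP+FN)·(TP+FP))

The two forms are algebraically identical; the package implements both
and tests their agreement to 1e−9.  Alongside the metric itself the
package provides the F1 baseline and a 24-metric comparison suite,
essential-outcome selection for expert review, inter-rater agreement
statistics (Cohen's κ, ICC, IBMD, Pearson), a procedural molar phantom
plus outcome/cohort generators so everything runs on purely synthetic
data, learning-gain analytics, and NRRD/NIfTI/PLY/OBJ I/O.

## Worked example

```r
library(drillscore)

ph <- buildToothPhantom(seed = 1)      # procedural molar, 90 x 135 x 90
ph
#> ToothPhantom: grid 90 x 135 x 90, 14004 spheres, 331578 tooth voxels,
#>   49389 ideal-cavity voxels

## a student who over-drills slightly, leaves 15% of the cavity uncut,
## and has a slightly ragged technique
plan <- idealPlan(ph, overdrillExtent = 0.06, underdrillFraction = 0.15,
                  roughness = 0.01, seed = 5L)
actual <- simulateOutcome(ph, plan)

cc <- classifyOutcome(ph@occupancy, ph@idealOutcome, actual)
cc
#> ClassificationCounts: TP=237940 TN=41981 FP=7408 FN=44249 (total 331578)

componentScores(cc)
#> ComponentScores: P=0.96981 S=0.84319  rescaled Ptilde=0.39612 Stilde=0.80399

dentistScoreFromCounts(cc)
#> [1] 5.387332
f1Score(cc)
#> [1] 0.9020789
```

Reading: 44,249 voxels were drilled that should have remained (the
dominant error — sensitivity 0.843) and 7,408 that should have been
drilled remain (precision 0.970, inside its narrow empirical window).
On the expert 0–15 rubric scale the outcome scores D ≈ 5.4 — a
mediocre access opening — while the F1 baseline (0.90, higher-better)
compresses the same errors into the top tenth of its range, which is
precisely why the rescaled Dentist metric exists.

A command-line interface covering generation, scoring,
essential-outcome selection, expert-agreement validation and cohort
analysis ships as `inst/scripts/drillscore` (see `runCli()`).

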