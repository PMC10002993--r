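# dbsreco

Coordinate-level comparison of postoperative deep brain stimulation (DBS)
electrode reconstructions between localization methods — e.g. a semi-automated
toolbox reconstruction versus manual localization in a surgical planning
system — in the AC–PC stereotactic frame, together with a fully seeded
synthetic cohort generator so every stage of the analysis runs and is testable
without patient imaging data.

## Who this is for

Functional-neurosurgery and neuroimaging researchers who need to quantify how
well two electrode localization methods agree: per-axis contact coordinate
discrepancies, the relative position of the electrode with respect to the
subthalamic nucleus (STN), depth validation against intraoperative
microelectrode recording (MER), and overlap of clinically optimal contacts
with the sensorimotor (dorsolateral) STN.

## The computation

All coordinates live in the AC–PC frame with the posterior commissure (PC) as
origin and +X right-lateral, +Y anterior, +Z inferior.

**Electrode model.** A quadripolar lead (Medtronic 3389 / PINS 301 geometry:
2 mm center-to-center contact spacing, 1.5 mm contacts, 1.5 mm tip gap) is a
straight line fitted through the ventral-most contact center
p₁ = (x₁, y₁, z₁) and a second point on the bend-free cranial part of the
trajectory. Contact *i* sits at p₁ + lᵢ·û with lᵢ = 2i mm (i = 0…3), the
parametric solution of the per-coordinate distance equations
xᵢ = x₁ ± √(lᵢ² − (y₁−yᵢ)² − (z₁−zᵢ)²) (and cyclic) with the sign branch
resolved toward the cranial point; the physical tip lies 2.25 mm
(1.5 + 0.75 half-contact) ventral of the ventral contact center. The four
contact centers are averaged per hemisphere before any comparison.

**Pooling.** Bilateral cohorts are pooled per axis on coordinate magnitudes
(|x| folds the mirrored hemispheres together); left-hemisphere rows are
*printed* with every axis negative, a display convention that never touches
stored geometry. The mean discrepancy is mean(B) − mean(A) on the pooled
magnitudes.

**Statistics.** Normality is assessed by a Lilliefors-corrected
Kolmogorov–Smirnov test; two methods are compared by a paired *t*-test (normal
differences) or Wilcoxon signed-rank test; three paired conditions (two
methods + a third modality, or two tip-to-target distances + the MER-recorded
depth) by repeated-measures ANOVA with Tukey's HSD on the within-subject error
term, or by Friedman + Dunn's multiple comparison for non-normal data.

**Relative position.** At the axial level where the red nucleus (RN)
cross-section is maximal, a ray from the RN cross-section centroid through the
electrode's center point is intersected with the ventral border of the STN
(the ray's most inferior exit intersection); the electrode–border Euclidean
distance and a positional category (within / medial / lateral / anterior /
posterior) are recorded per electrode and method. Optimal contacts are tested
against the dorsolateral STN subregion by a winding-number point-in-mesh test.

**Synthetic cohort.** Ellipsoidal STN with a carved dorsolateral subregion and
spherical RN per hemisphere (exact mirror images), bilateral implants aimed at
the dorsolateral STN, and two "methods" observing each electrode's landmark
points with 1 mm per-axis noise — method B with a configurable systematic bias
(default (−0.13, −1.16, +0.59) mm in lateral/anterior/inferior terms). One
seed drives documented per-patient substreams, so growing the cohort never
perturbs earlier patients.

## Worked example

```r
library(dbsreco)

## electrode geometry: two marked points -> four contacts, average, tip
tr <- fit_trajectory(c(10, 10, 2), c(16, 13, -4))
cs <- interpolate_contacts(tr, electrode_spec("medtronic_3389"), side = "right")
cs
#> contact_set (right hemisphere, medtronic_3389):
#>            x       y       z
#> [1,] 10.0000 10.0000  2.0000
#> [2,] 11.3333 10.6667  0.6667
#> [3,] 12.6667 11.3333 -0.6667
#> [4,] 14.0000 12.0000 -2.0000
average_contacts(cs)    # per-hemisphere summary coordinate
#>  x  y  z
#> 12 11  0
tip_position(tr)        # 2.25 mm ventral of the first contact center
#> [1] 8.50 9.25 3.50

## simulate a 26-patient cohort and compare the two methods on the Y axis
cfg <- simulation_config(seed = 7)
co  <- simulate_cohort(cfg)
paired_axis_test(co$table, "y", "all")
#> Y axis (all, n = 52): leaddbs 11.33 +/- 1.06 vs surgiplan 10.08 +/- 1.16
#>   mean discrepancy -1.26 mm, paired t, p = 3.131e-07
```

The printed line reads: across 52 pooled electrodes the planning-system-like
method reconstructs contacts on average 1.26 mm less anterior than the
toolbox-like method (the injected anterior bias is −1.16 mm; the difference is
sampling noise), and the paired *t*-test calls the shift highly significant.

`run_pipeline(cfg, "out/")` executes the whole chain — contacts, relative
position at the maximum RN level, per-axis comparison table, MER distance
validation, subregion rates — and writes `coordinates.csv`, `distances.csv`,
`relative_position.csv`, `comparison.csv`, a markdown report and a
reproducibility manifest. A thin CLI wraps the same functions:

```sh
Rscript inst/cli/dbsreco run --config cfg.yaml --seed 7 --out out/
```

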