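# platefit

Quantitative assessment of how well a pre-contoured lateral distal-femur
locking plate fits a femur, on 3D triangle surface models.

Pre-contoured plates are factory-shaped to an average anatomy. When the
plate-to-bone gap is large — typically at the proximal plate tip, where the
plate's sagittal bow radius mismatches the femoral anterior bow — using the
plate as a reduction template risks valgus malalignment. `platefit` turns
"does this plate fit this bone?" into a reproducible computation:

1. **Positioning** — a rigid transform seats the plate undersurface on the
   lateral distal femur under surgical constraints: plate-bone contact
   (≤ 0.2 mm) at three zones (distal anterior, distal posterior, shaft),
   zero penetration of the undersurface into the bone, no screw in the
   intercondylar fossa, and the most proximal screw inside the
   intramedullary canal.
2. **Measurement** — plate-bone distance at every layout point is the
   shortest Euclidean distance from the point to any bone-mesh vertex.
3. **Criteria** — anatomical fit requires all three: ≤ 1 mm at the most
   anterior distal point; ≤ 2 mm at nine metaphyseal points (incl. the
   distal tip); ≤ 3 mm at anterior/centre/posterior shaft points in rows
   every 40 mm (incl. the proximal tip). 16/19/22 shaft points for
   9/11/13-hole plates.
4. **Bow radius** — the femoral anterior-bow radius of curvature (ROC) is
   the best-fit circle through the centre points of 20 axial cross-sections
   of the inner cortex over the diaphysis; the plate ROC is the best-fit
   circle to its shaft centre curve (940 mm for the default plate).
5. **Cohort statistics** — Mann-Whitney U, chi-square and Spearman tests
   with table-style summaries by ethnicity, age group and sex.

Because the clinical bone models are not publicly deposited, the package
generates parametric synthetic femora (controllable bow radius, condylar
block with a 10° medially inclined lateral facet, intercondylar notch,
analytic landmarks) and plate undersurfaces, and validates the entire
pipeline on them. See the methods vignette
(`vignettes/plate-fit-methods.Rmd`) for the model and every numerical
choice.

## Worked example

```r
library(platefit)

# a femur with a 900 mm anterior bow and an 11-hole default-bow plate
bone  <- make_femur(femur_params(r_bow = 900), id = "demo")
plate <- make_plate(plate_params(holes = 11))

measure_bone_roc(bone)
#> roc_result: radius 900.0 mm (rms residual 0.0001 mm, 20 points)

pos <- refine_position(plate, bone)
pos
#> positioning_result: converged after 34 sweeps
#>   contact zones (mm): distal_anterior=0.161, distal_posterior=0.080, shaft=0.170
#>   penetrating samples: 0; fossa clear: TRUE; screw in canal: TRUE

measure_fit(plate, bone, pos)
#> fit_report (11-hole plate): overall fit ACHIEVED
#>   criterion n_points       max      mean pass
#> 1        c1        1 0.1874070 0.1874070 TRUE
#> 2        c2        9 0.1893822 0.1360223 TRUE
#> 3        c3       19 0.5718057 0.2654867 TRUE
#>   distal tip 0.12 mm, proximal tip 0.49 mm
```

Read: the bow measurement recovers the generating 900 mm radius, the plate
seats with genuine three-zone contact (all zones under 0.2 mm, zero
penetrating samples, screws clear), and all three distance criteria pass —
a 40 mm bow mismatch against the 940 mm plate costs only ~0.5 mm at the
proximal tip. Rebuilding the bone with a stronger mismatch (say
`r_bow = 1160`) triples the proximal tip distance, the mechanism behind
proximal shaft misfit; far outside the plate's bow range the three-contact
placement itself becomes infeasible and `refine_position()` reports
`converged = FALSE`.

A full cohort run (generate → measure ROC → position → measure fit →
tables) is one call:

```r
res <- run_pipeline(run_config(seed = 1, out_dir = "run", n = 10))
```

which writes meshes, landmark sidecars, per-bone JSON fit reports, a
long-format distance CSV, four summary/statistics tables, a manifest and a
log under `run/`. A thin CLI with `run`, `generate`, `roc` and `analyze`
subcommands is installed at `inst/cli/platefit.R`.

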