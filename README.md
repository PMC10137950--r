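# hipoffset

Three-dimensional hip offset morphometry and virtual acetabular cup
implantation from CT-derived bone surface models, with a fully
ground-truthed synthetic anatomy generator.

## The problem

Preoperative planning for total hip arthroplasty (THA) hinges on the hip's
offset geometry. On an AP radiograph the **femoral offset** (FO) is the
perpendicular distance from the hip rotation centre (HRC) to the femoral
shaft axis, the **acetabular offset** (AO) is the horizontal distance from
the HRC to the vertical line through the inferior teardrop edge, and the
**global offset** is their sum, GO = AO + FO. Radiographs foreshorten the
femoral offset whenever the neck points out of the coronal plane, so 2D
planning systematically underestimates the true offset by a factor of
cos(anteversion). Measured in 3D on surface models, the femoral offset is
the distance from the femoral head centre (FHC, the centre of the sphere
fitted to the head) to its orthogonal projection on the shaft axis — the
reference point — and the **cup offset** is the distance from that
reference point to the centre of a virtual cup (CC) seated flush to the
true floor of the acetabulum, parallel to the transverse acetabular
ligament. Because seating on the true floor medialises the hip centre, the
cup offset exceeds the femoral offset by the medial wall depth: the
cup-femoral difference a surgeon must compensate on the femoral side.

`hipoffset` implements this pipeline end to end:

* least-squares (algebraic + Gauss-Newton geometric) sphere fits of the
  femoral head and acetabular socket;
* total-least-squares shaft axis through cross-section area centroids;
* ISB-style femoral and anterior-pelvic-plane (APP) coordinate frames;
* virtual cup sizing (largest available diameter under the maximal axial
  rim distance) and implantation flush to the true acetabular floor;
* femur-to-pelvis matching at the native HRC with anteversion preserved;
* simulated orthographic AP-radiograph measures (CE angle, FO, AO, GO);
* cohort statistics: Student's t, Pearson correlation, ICC(2,1), with
  broom-style `tidy()`/`glance()` and ggplot2 `autoplot()` methods.

Because no patient CTs ship with the package, a parametric generator
(`generate_femur()`, `generate_hemipelvis()`, `generate_cohort()`) builds
sphere-capped femora and hemispherical sockets with controllable head
radius, neck-shaft angle, anteversion, true offset, medial wall thickness
and CE angle, plus Gaussian surface noise — and emits the exact
constructive truth, so every stage is validated by parameter recovery.

## Worked example

```r
library(hipoffset)

# one noisy synthetic femur, measured back
f <- generate_femur(femur_params(noise_sd = 0.5, anteversion = 15, seed = 7))
measure_femur(f$mesh, landmarks = f$truth$landmarks)
#> <femur_measurement> (right)
#>   FHC (-35.50, 9.48, 150.79) mm, head radius 24.04 mm
#>   3D femoral offset 36.69 mm, anteversion 14.8 deg
f$truth$true_FO3D   # 36.77 mm: recovered to < 0.1 mm under 0.5 mm noise

# a 66-hip synthetic cohort through the whole pipeline
cohort   <- generate_cohort(n = 66, seed = 42)
measured <- measure_cohort(cohort)
stats    <- cohort_stats(measured)
stats
#> <hip_cohort_stats> 66 hips
#>   mean 3D FO 40.2 mm, mean 3D cup offset 45.4 mm (diff 5.2 mm, p = 4.14e-08)
#>   correlations:
#>     r(fo3d, cup_offset3d) = 0.959 (p = 6.77e-37)
#>     r(fo3d, body_length) = 0.610 (p = 5.35e-08)
#>     r(fo2d, fo3d) = 0.922 (p = 3.96e-28)
#>     r(fo_diff_3d_2d, femoral_anteversion) = 0.683 (p = 2.62e-10)
#>     r(cup_femoral_diff, ao2d) = 0.577 (p = 4.05e-07)
#>     ...
autoplot(stats)     # cup offset vs femoral offset, identity line, lm fit
```

The cohort means read exactly as a clinician would: the average 3D femoral
offset of the synthetic population is 40.2 mm, the virtual cup offset
45.4 mm, so seating the cup on the true floor medialises the hip centre by
about 5 mm — which tracks the 2D acetabular offset (r = 0.58), while the
3D-minus-2D femoral offset difference tracks femoral anteversion
(r = 0.68). `measure_cohort()` returns a tibble (one row per hip) that
pipes straight into `group_compare()`, `correlate()` or ggplot2.

Meshes and landmarks round-trip through standard formats: `write_stl()` /
`read_stl()` (binary or ASCII), `write_ply()` / `read_ply()`, and landmark
JSON via `read_landmarks()`. A deterministic end-to-end driver,
`run_pipeline(run_config(n = 20, seed = 1))`, serialises the measurement
table, statistics and configuration; identical seeds give byte-identical
outputs.

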