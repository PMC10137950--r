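---
title: "Measuring 3D hip offsets and simulating cup implantation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3D hip offsets and simulating cup implantation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipoffset)
```

## The measurement model

`hipoffset` measures the offset geometry of a hip from two triangulated
bone surfaces — a proximal femur and a hemipelvis — the way a CT-based
planning workstation does, and verifies every stage against synthetic
anatomy with known ground truth.

All coordinates are millimetres in a right-handed frame with +x towards
the patient's right, +y anterior and +z superior. The pelvic reference is
the anterior pelvic plane (APP) through both anterior superior iliac
spines and the pubic tubercles (`build_app_frame()`); its normal is the
anteroposterior axis and "vertical" on the simulated radiograph is its
superoinferior axis.

**Femur.** The femoral head centre (FHC) is the centre of a sphere fitted
to the head region. The region is isolated by iterative sphere-region
growing (`extract_head_surface()`): starting from a 20 mm neighbourhood of
the vertex farthest from a provisional shaft axis, a sphere is fitted and
all mesh vertices with radial residual below twice the median residual of
the region (floored at 0.25 mm so a noise-free cap is not rejected) are
re-selected, for at most 10 rounds. The fit itself
(`fit_sphere()`) solves the linearised sphere equation by least squares
and refines with Gauss-Newton on the radial residuals (relative objective
change below 1e-10 or 100 iterations). The shaft axis is the total
least-squares line through the area centroids of shaft cross-sections cut
every 5 mm perpendicular to a provisional axis
(`compute_shaft_sections()`); the provisional axis comes from a trimmed
principal-component iteration that keeps the 60% of vertices nearest the
current axis, which converges onto the tubular shaft and marks the
trimmed-away head/neck cluster as the proximal end. With more than two
sections a total-least-squares line is the natural reading of "the line
connecting the midpoints", and it is noise-robust.

The **reference point** is the orthogonal projection of the FHC onto the
shaft axis. The proximal shaft centre has no canonical level; this choice
is level-independent, makes the 3D femoral offset exactly the
point-to-line distance from the FHC to the axis, and renders the offset
segment perpendicular to the axis. **Femoral anteversion** is the
transverse-plane angle between the neck axis (reference point to FHC) and
the posterior condylar axis when condylar landmarks are supplied; the
output records which reference was used, and anteversion is `NA` without
one.

**Acetabulum.** The socket is recovered from the internal wall — vertices
whose outward normal faces the cavity. Two coincident spheres of equal
radius live there: the articular (lunate) surface and the cotyloid fossa,
recessed medially by the wall depth. Because the spheres intersect,
residuals alone cannot separate them; the package splits the internal wall
by polar angle about the estimated opening axis (the fossa is the central
cap within 48 degrees of the deep pole, the lunate the zone beyond 62
degrees) and iterates the split with the improving centre estimate. The
**true floor** is the medial pole of the fossa sphere, or of the articular
sphere when no recessed fossa is detected (wall depth zero). The **rim**
is the set of per-azimuth extremal-polar-angle lunate points; the rim
diameter is the maximum pairwise distance within the best 1 mm axial slab,
matching an axial-plane caliper measurement (and, for a near-circular rim,
the global all-pairs maximum, because some diametral chord of a tilted
circle is horizontal).

**Virtual cup.** The cup diameter is the largest available size (default
38–66 mm in 2 mm steps) not exceeding the rim diameter. Orientation uses a
fixed radiographic inclination (default 40 degrees, a conventional target;
the source procedure fixes only anteversion) and an anteversion chosen so
the face's transverse trace is parallel to the transverse acetabular
ligament. "Flush to the true floor" defaults to contact along the
mediolateral axis — the cup centre sits `diameter/2` lateral to the floor
point — because this reduces to the native centre when the wall depth is
zero and the cup fills the socket. Polar contact along the face normal is
available (`flush = "face_normal"`), but with a 40-degree face it displaces
a full-size cup far from the native centre even in a wall-less socket,
which is not what "flush" means on a planning workstation.

**Matching and offsets.** `match_hip()` translates the measured femur so
the FHC coincides with the native acetabular centre, aligns the shaft axis
with the pelvic superoinferior axis (neutral limb pose; the in-scan pose
is not knowable from the meshes alone) and rotates about the axis so the
measured anteversion is preserved in the pelvic frame. The **3D femoral
offset** is the distance between the reference point and the FHC, and the
**3D cup offset** the distance between the reference point and the cup
centre — point-to-point 3D distances, per the definition of the quantities.
An alternative reading projects the three points onto the APP coronal
plane first; that variant is reported alongside (`fo3d_coronal`,
`cup_offset3d_coronal`), but it is not the primary definition because in
the matched neutral pose it collapses onto the 2D radiographic offset
(both equal FO x cos(anteversion)), which would make the 3D measurement
redundant and the 3D-minus-2D anteversion effect vanish identically.

**Simulated radiograph.** Projection is orthographic (parallel-beam) along
the APP normal: magnification-free, so the 2D/3D identities are exact —
FO2D = FO3D x cos(anteversion) on ideal anatomy, hence FO2D <= FO3D with
equality at zero anteversion. A point-source perspective model is out of
scope; with uncalibrated magnification it would only blur the identities
the tests rely on.

## The synthetic anatomy generator

The generator is the package's study population, not a test fixture; its
defaults are the study conditions.

`generate_femur()` builds a sphere-capped head on a cylindrical neck at the
neck-shaft angle, rotated anteriorly by the anteversion, joining a tubular
shaft; the true offset is `neck_length * sin(180 - neck_shaft_angle)`.
`generate_hemipelvis()` carves a spherical socket, oriented by radiographic
inclination/anteversion, into a shell of finite thickness; the cotyloid
fossa (a 55-degree cap about the socket axis) is recessed medially by the
wall thickness, and the superior roof is extended or cut back by
root-finding (`uniroot`, tolerance well under the 0.5-degree contract)
until the projected centre-edge angle of its lateral edge equals the
requested CE angle. Surface noise is Gaussian along outward vertex
normals, default SD 0.5 mm as a surrogate for 1 mm-slice surface
reconstruction error; the acquisition literature gives slice thickness,
not a surface-error model, so an isotropic-along-normal displacement is
the simplest defensible choice.

`generate_cohort()` draws 28:38 men:women per 66 specimens. Demographics,
CE angle, femoral anteversion and the target 3D femoral offset come per
sex from the shipped reference summary (`reference_offset_table()`):
anteversion men 13.2 (SD 9.6) / women 21.2 (SD 9.9) degrees, offset 42.1
(4.8) / 38.4 (3.6) mm, CE 31.9 (5.3) / 28.1 (6.8) degrees truncated at 20
(dysplastic hips excluded). Constructive parameters the summary does not
determine use field-typical values chosen once: head radius 24 (1.2) /
21.5 (1.1) mm, neck-shaft angle 128 (5) degrees, shaft radius 14 (1) mm,
cartilage allowance 2.5 (0.3) mm, medial wall thickness 5 (1.5) mm
truncated at 1.5, socket inclination 40 (4) and anteversion 18 (5)
degrees, teardrop margin 3 (0.8) mm. Sampling is truncated-normal with
resampling (at most 100 retries; the socket orientation pair is jointly
truncated so the medial pole stays inside the fossa). The femoral offset
is drawn with correlation 0.4 to the body-length z-score, and the teardrop
offset is the socket radius plus wall thickness plus margin — the two
couplings that let the cohort reproduce the offset-versus-stature and
medialisation-versus-acetabular-offset associations structurally. All
randomness derives from one master seed; specimen-level seeds are drawn
once from it, so runs are reproducible byte for byte.

What the generator does **not** emulate: segmentation artefacts,
osteophytes or dysplastic deformity, cortical/trabecular interiors, a
non-spherical (conchoid) femoral head, fovea, labrum, or the true
irregular pelvic silhouette. Passing recovery tests on this anatomy shows
the estimators are unbiased and noise-stable on clean spherical geometry;
it does not certify performance on pathological bone.

## Numerical choices and degenerate inputs

* Sphere fits refuse fewer than 4 points and (near-)coplanar sets;
  extraction refuses regions that collapse below 50 vertices, radii
  outside 5–80 mm, clouds thinner than 5% of the radius along their
  smallest principal direction, and regions whose two halves disagree on
  the centre by more than 20% of the radius (this is what rejects a
  headless shaft tube).
* Axis fits refuse identical midpoints; two midpoints give the exact line.
* Section contours are ordered by angle (shaft sections are convex); a
  degenerate sliver falls back to the vertex mean. Oblique sections of a
  cylinder give the same centroid as orthogonal ones (the centroid of an
  ellipse is its centre), which the tests assert to 1e-6 mm.
* Angles are unsigned degrees from `atan2`, stable near 0 and 180.
* Cup sizing takes the largest size `<=` the rim diameter; a rim smaller
  than every size is an error, not a clamp.
* Statistics: Student's pooled t is the default (Welch by flag) because
  the reproduced analysis specifies Student's test; ICC defaults to
  ICC(2,1) — two-way random, absolute agreement, single measure — the
  standard form for intra/inter-rater agreement of continuous
  measurements, with ICC(1,1) and ICC(3,1) available; correlation p-values
  use the exact t transform.

## Problem sizes

The shipped tests measure 50 noisy femurs for parameter recovery (mean
absolute errors: offset < 0.5 mm, head centre < 0.3 mm, anteversion < 1
degree), 50 noisy pelves for cup-centre recovery (< 1 mm mean), one
66-specimen cohort for the sign/structure checks (cup offset > femoral
offset in every hip; r(FO3D, cup offset) > 0.8; positive anteversion and
acetabular-offset associations), and a 20-specimen end-to-end run twice
for byte-identical determinism. Meshes default to about 2,700 (femur) and
1,700 (pelvis) vertices — enough that discretisation error sits an order
of magnitude below the 0.5 mm noise floor, while a full cohort measures in
under a minute.

## Known limitations

* The pipeline starts at surface meshes; DICOM segmentation is out of
  scope.
* Anteversion needs condylar landmarks; proximal-only scans inherit the
  pelvic mediolateral reference, which the output flags.
* The fossa/lunate angular split assumes a roughly central fossa (the
  generator's 55-degree cap); a wildly eccentric fossa would need the
  split angles retuned.
* The matched pose is neutral; scanned-pose matching would require the
  original scene, which meshes alone do not carry.
* Cup inclination does not feed back into sizing or coverage; reaming,
  press-fit and impingement analysis are out of scope.
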