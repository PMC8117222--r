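---
title: "Automatic fiducial localization on 3D head scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic fiducial localization on 3D head scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiducial3d)
```

## The problem

EEG source reconstruction needs the positions of the scalp electrodes in a
head coordinate system, and that coordinate system is anchored by three
anatomical fiducials: the **nasion** (the depression between the eyes, just
above the bridge of the nose) and the **left and right preauricular
points** (just anterior to the tragus of each ear). Digitizing these by
hand — calipers, electromagnetic pens, or clicking on a rendered scan — is
slow and operator-dependent. Given a textured triangle-mesh head scan from
a commodity structured-light scanner, `fiducial3d` localizes the three
fiducials automatically and builds the CTF subject coordinate system (SCS)
from them.

The approach is dimensional reduction: instead of searching the mesh
directly, the head is *rendered* to 2D images from a ring of viewpoints,
standard 2D object detectors find facial elements (face, eyes, nose,
mouth, ears) in those images, the fiducial pixel coordinates are derived
from the detector bounding boxes by fixed geometric rules, and the pixels
are reprojected onto the mesh surface by ray casting.

## Pipeline

1. **Gravity-flip correction** (`gravity_flip()`). Structured-light
   scanners orient the Z axis along gravity, so the exported mesh is
   upside down. The correction reflects the mesh about the horizontal
   plane through its centroid and re-winds the faces. We use a reflection,
   not a 180-degree rotation: the scanner's convention is a sign flip of
   the gravity axis, and a reflection is its own inverse (which the tests
   exploit). A rotation variant can be composed by the caller if a
   particular scanner needs it.
2. **Azimuth scan** (`scan_face_elements()`). The mesh is rendered at
   1-degree steps over the full circle and the face/eye/nose/mouth
   detectors run on every view. An azimuth *succeeds* when face, both
   eyes and nose are all detected; the mouth is recorded but not
   required, because the nasion geometry below only uses the eyes and the
   nose, and requiring the mouth would only shrink the usable arc.
3. **Detection arc and best view** (`find_arcs()`,
   `select_best_view()`). Success flags form circular runs; the longest
   contiguous arc is taken as the frontal region. Inside it, each azimuth
   is scored by `(A_L + A_R) * (1 - |A_L - A_R| / (A_L + A_R))` where
   `A_L`, `A_R` are the eye-box areas: eye boxes are largest and most
   symmetric in the most frontal pose. Ties go to the smallest azimuth;
   when several arcs tie for longest, the one containing the globally
   best-scoring azimuth wins.
4. **Nasion estimate** (`nasion_intrinsic()`). With eye boxes
   `[top_1, left_1, w_1, h_1]` (subject's right eye, image left) and
   `[top_2, left_2, w_2, h_2]` (subject's left eye) and nose box
   `[top_3, left_3, w_3, h_3]`, the nasion pixel is
   row `(top_1 + top_2)/2 + (h_1 + h_2)/4` (the mean vertical center of
   the eye boxes) and column
   `((left_1 + left_2 + w_2)/2 + (left_3 + w_3/2))/2` (the mean of the
   eye-pair inner midpoint and the nose-box center). The original
   typesetting of this column rule is ambiguous; we adopted the parse
   that (i) is exactly symmetric for a mirror-symmetric face and (ii)
   keeps the estimate between the eyes and above the nose. The rejected
   parses place the point outside the face or off-frame.
5. **Lateral views and the ear ladder** (`ear_ladder_detect()`). The best
   lateral projections of the ears sit at the best frontal view plus or
   minus 87 degrees (not 90: the ear is slightly posterior on the head,
   so a small anterior offset shows the tragus region more fully). With
   our counterclockwise-from-above azimuth convention, +87 degrees shows
   the subject's left ear — a convention verified against synthetic
   ground truth in the tests. Per side, a *ladder* of ear detectors
   ordered by ascending total false-alarm rate is applied recursively
   over an 11-view window (the lateral angle plus/minus 5 degrees at
   1-degree steps, scanned center-outward): the strictest detector scans
   all views first; a view returning exactly one box wins; a view
   returning several boxes counts as a failure for that detector (the
   goal is a single confident true positive, and a multi-box answer means
   the detector's false-alarm behavior cannot be trusted in that view).
6. **Preauricular estimate** (`right_cp()`/`left_cp()`,
   `right_pp()`/`left_pp()`). The closest point (CP) of the ear box to
   the preauricular point is the midpoint of the box edge facing the
   face. The calibrated correction moves it inside the box — column at
   `left + 0.8 * width` (right ear) or `left + width/5` (left ear), row
   at `top + 0.36 * height` — equivalently a shift of 20% of the box
   width and 14% of its height from the CP, on both sides.
   `calibrate_pp_correction()` re-derives such constants from annotated
   examples by exhaustive grid search on `[0, 1]^2` minimizing the summed
   L1 pixel error (ties to the lexicographically smallest pair); the L1
   loss separates over the two fractions, which the implementation
   exploits without changing the answer.
7. **Reprojection** (`pixel_to_surface()`). Fiducial pixels (fractional:
   the estimators produce sub-pixel coordinates, which are *not* snapped)
   are mapped back to 3D by casting the orthographic ray through the
   pixel and keeping the nearest ray-triangle intersection over all
   triangles. We deliberately replaced interactive pick-on-screen
   mechanics with analytic ray casting: the geometric result is identical
   by construction and needs no GUI.
8. **SCS construction** (`build_ctf_transform()`). CTF convention:
   origin at the midpoint of the preauricular points, +x toward the
   nasion, +y toward the left preauricular point, +z up. The z sign is
   disambiguated against the gravity-corrected vertical, the only "up"
   the pipeline can rely on when the scan is tilted.

## The camera model

The renderer (`render_view()`) is an **orthographic** z-buffered
rasterizer with barycentric UV texture lookup, written in C++ for the
360-view sweeps. Orthographic rather than perspective projection is a
deliberate choice: the detector geometry of steps 4-6 is scale-invariant,
and the 2D-to-3D inverse of step 7 becomes exact (all pixel rays are
parallel), whereas a perspective camera would require a distance and
field-of-view that nothing in the method constrains. All images use
intrinsic coordinates — `(row, col)`, 1-based, row 1 at the top, pixel
centers at integers — and every public API sticks to `(row, col)` order.

Numerical details: depth ties at shared triangle edges resolve to the
smallest face index (determinism); triangles degenerate in projection are
skipped; ray-triangle intersection uses Möller-Trumbore with a symmetric
edge tolerance so a ray crossing a shared edge registers exactly one hit;
the default framing fits the mesh bounding sphere to 90% of the smaller
image dimension (default 240 x 240 pixels, about 0.8 px/mm for an adult
head, which keeps eye boxes around 20 pixels — comfortably above detector
resolution — while a full 360-view scan stays around a few seconds).

## Cascade arithmetic and the detector ladder

A boosted cascade with per-stage false-alarm rate `f`, per-stage
true-positive rate `t` and `s` stages has total false-alarm rate `f^s`
and total true-positive rate `t^s` (`cascade_total_far()`,
`cascade_total_tpr()`): more stages suppress false alarms exponentially
but also erode sensitivity. `ear_detector_design()` records the sixteen
ear-cascade designs (eight per side) that the default ladder is built
from; the ladder orders them by *computed* total FAR, which is not the
same as ordering by per-stage FAR (for the right ear, `f = 0.4, s = 12`
has a lower total FAR than `f = 0.3, s = 8`).

Detectors themselves are pluggable handles (`fd_detector()`): a function
from a rendered view and an element name to bounding boxes. The package
does not bundle trained Viola-Jones/HOG models and does not train any —
detector training is explicitly out of scope; any runtime detector can be
wrapped in a handle, and the oracle detectors below make the pipeline
fully testable without one.

## What the synthetic fixtures emulate — and what they do not

`make_synthetic_head()` builds a deterministic head-like mesh: an
ellipsoid with adult-head semi-axes (defaults 95, 75, 110 mm,
anterior-posterior / left-right / vertical), a nose protrusion (22 mm)
and ear bumps (7 mm), triangulated on a 6-degree latitude/longitude grid
(3,480 faces, mean edge about 9 mm). Landmarks are tagged grid vertices,
so ground truth lies exactly on the surface. One seed drives everything:
semi-axis scaling in a plus/minus 8% band, bump-size variation, a random
yaw (so each head faces a different direction and the arc search is
genuinely exercised), and the texture speckle. The mesh is also provided
in scanner orientation (upside down) so the pipeline's gravity flip is
exercised end to end. `degrade_head()` adds two seeded degradation
hooks — texture pixelation (the aliasing that fine clothing patterns
cause during scanning) and face-deletion holes — for robustness
experiments; both are deterministic for a fixed seed.

`make_oracle_detectors()` replaces trained detectors with
geometry-driven ones: each projects its ground-truth landmark, checks
visibility against the depth buffer, and emits a box placed so the
downstream estimator inverts it exactly at zero jitter (eye/nose boxes
invert the nasion rule; ear boxes invert the preauricular correction).
Eye and ear boxes foreshorten away from frontal, which is what gives the
best-view score its frontal peak. Optional Gaussian jitter on box
placement is derived deterministically from (seed, azimuth, element), so
detectors remain pure functions of their view.

Passing the end-to-end tests on these fixtures therefore demonstrates
that the *geometry* of the pipeline — rendering, arc logic, box algebra,
reprojection, SCS construction — is correct and self-consistent. It does
not demonstrate detector robustness on real scans: real texture, hair
occlusion, glasses, scanning artifacts and detector false alarms are
outside what the fixtures model, and the accuracy of trained cascade
models is exactly the part the oracle abstracts away.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `step` | 1 degree | azimuth scan resolution; coarser steps shrink arcs and can miss short ones |
| `lateral_offset` | 87 degrees | rotation from best frontal view to each ear view |
| `window` | 10 degrees | ear-ladder search range around the lateral angle (11 views at 1-degree steps) |
| `image_size` | 240 x 240 px | render target; drives pixel/mm scale |
| `scale` | auto | pixels per mesh unit; default fits the bounding sphere to 90% of the image |
| `vis_tol` (oracle) | 6 mm | depth-buffer agreement tolerance for landmark visibility |
| `a_col`, `b_row` | 0.8/0.2, 0.36 | preauricular correction fractions (right/left column, row) |

## Problem sizes used in the checks

The randomized suites run at sizes chosen to exercise the geometry well
while keeping a full test run comfortable on a laptop: the arc-finder
equivalence uses 1,000 random circular flag vectors (24 to 360 slots);
reprojection is checked against the brute-force all-triangle oracle on
icospheres up to 1,280 faces plus the 3,480-face synthetic head; the CTF
invariants use 100 random fiducial triples; the end-to-end battery runs
20 synthetic heads (seeds 1-20) at the full 1-degree scan.

## Known limitations

* Only the `v`/`vt`/`f` OBJ dialect (plus MTL `map_Kd`) is read — that is
  what head scanners emit; PLY/STL/GLB are out of scope.
* Coordinates are assumed millimetres but never rescaled; `units_hint`
  records the caller's belief. The downstream math is unit-agnostic.
* One UV per vertex: per-corner UV seams are collapsed (last assignment
  wins). Fine for the scanner exports and fixtures targeted here.
* No perspective camera; the orthographic model is part of the method's
  geometry (see above).
* Ears are sought independently; if one side fails its ladder the error
  names that side and the run report records the partial progress.
* Runtime cascade model files are not loaded; detectors enter through the
  handle interface.
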