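---
title: "Measuring cervical spine kinematics from surface-model registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cervical spine kinematics from surface-model registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

In vivo cervical spine kinematics can be measured without markers by
imaging a subject in a neutral posture and in end positions of functional
movements (flexion/extension, lateral bending, axial rotation), segmenting
each vertebra into a closed triangle-mesh surface model, and rigidly
registering per-vertebra models across postures. Because each vertebra is
a rigid body, the registration transform of a vertebra from neutral to an
end position *is* its motion; differences between the transforms of
adjacent vertebrae are the intervertebral (joint) motions clinicians care
about. Upright low-dose cone-beam CT makes this practical for the cervical
spine, including the atlantoaxial (C1–C2) joint that planar radiography
resolves poorly.

`spinekin` implements this measurement chain end to end on meshes:

1. **mesh I/O and deviation statistics** — STL/PLY models, signed
   point-to-surface distances, and the summary statistics used to validate
   model accuracy;
2. **rigid registration** — iterative closest point (ICP) with
   point-to-surface correspondences;
3. **anatomic frames** — per-vertebra coordinate systems from four bony
   landmarks;
4. **6-DOF kinematics** — intervertebral translations and rotations under
   clinical sign conventions;
5. **synthetic studies** — vertebra-like fixtures at typical cervical
   dimensions with ground-truth motion, so every claim above is testable
   without patient data.

## Signed deviations and what the report columns mean

For every vertex of a *moving* model, the closest point on the *target*
surface (facet interior, edge, or vertex) is found, and the Euclidean
distance is signed by the side of the nearest facet's outward normal:
positive means the moving vertex lies outside the target surface. Ties
between facets are broken toward the lowest facet index, which makes the
accelerated spatial-grid query bit-identical to an exhaustive per-facet
scan (the grid is performance-only, and the test suite asserts exact
equality).

`deviation_report()` summarizes a signed distance field as:

* `average_distance` — mean signed distance (mm); near zero for unbiased
  segmentation noise;
* `max_positive` / `max_negative` — extreme distances either side;
* `std_positive` / `std_negative` — standard deviation within the positive
  and negative subsets (an empty or singleton subset reports 0);
* `mean_absolute_deviation` — mean of |d|;
* `mean_deviation` — root mean square of d (so
  `mean_absolute_deviation <= mean_deviation <= max |extreme|` always);
* `angular_prediction_pos` / `angular_prediction_neg` — the
  angular-equivalent bounds of the extremes via the small-angle map below.

These definitions are fixed and self-consistent; published tables of this
kind do not always define their columns, so the package documents its own
semantics rather than guessing at others'.

A linear surface deviation `d` on a bone of characteristic dimension `L`
is equivalent to an angular uncertainty of about `d / L` radians.
`estimate_angular_deviation()` implements exactly this:
sub-0.1 mm mean deviations over a typical 11.9 mm vertebral height bound
the angular error of the method at roughly 0.1–0.3 degrees, which is the
scale that justifies trusting sub-degree intervertebral angles.

## Registration

`icp_register()` alternates (a) closest-point correspondence from every
moving vertex to the target *surface* and (b) the closed-form
least-squares rigid update (orthogonal Procrustes via SVD, with the
determinant correction that excludes reflections). The objective is the
RMS of correspondence distances; iteration stops when its change drops
below `tolerance` (relative, with an absolute floor of 1e-8 mm so exact
self-registration terminates) or at `max_iterations`. The trace is
monotonically non-increasing and is asserted to be so in every test
registration. The rotation is re-projected onto SO(3) at construction of
every transform, so orthonormality cannot drift.

Two documented choices:

* The alignment objective is *summed squared* distances (standard ICP),
  reported as RMS. Plain summed unsigned distances (an L1 objective) has
  no closed-form rigid update; the least-squares form is the standard
  choice and behaves identically on the sub-millimetre residuals involved
  here.
* The moving model is the neutral-posture model and the end-position model
  is the fixed target, matching the workflow in which one neutral model
  per vertebra is carried to every end position (and frame-construction
  error therefore cancels within a subject).

Initialization (`initial_align()`) is centroid translation, optionally
with principal-axes alignment that tries the four proper sign combinations
and keeps the lowest-RMS candidate. ICP is deterministic: no sampling, no
randomness. A registration that does not converge is returned flagged, not
raised, so one bad posture cannot lose a session; a grossly displaced
initialization fails loudly (high final objective / `converged = FALSE`)
rather than silently wrong.

There is no outlier trimming by default — the model pairs are same-bone,
same-subject — but `trim_quantile` exposes percentile trimming for
robustness experiments.

## Anatomic frames and 6-DOF conventions

Each vertebra's frame is built from four explicit landmarks: the most
posterior-inferior point of the vertebral body in the mid-sagittal plane
(origin), a superior reference defining "up", and the left/right
transverse-process tips. The left–right axis is primary
(`x = unit(left - right)`, positive leftward); the superior direction is
Gram–Schmidt orthonormalized against it (`y`, positive superior);
`z = x × y` (positive anterior); and the origin is projected onto the
mid-sagittal plane (through the left/right midpoint, normal `x`). The
orthonormalization order is a documented choice — the left–right pair is
the most reliably symmetric landmark pair, so it anchors the frame.
Landmarks are *inputs* (CSV/JSON); `suggest_landmarks()` offers
extreme-point heuristics for roughly axis-aligned fixtures, but manual
landmarks are authoritative on real anatomy. Frames are built once on the
neutral model and carried to end positions through the registration
transforms.

The pose of a vertebra relative to the subjacent one is
`R = R_lower' R_upper`, `t = R_lower' (o_upper - o_lower)`: translations
are expressed along the *lower* vertebra's anatomic axes. Rotations are
decomposed with an intrinsic Tait–Bryan sequence, by default y–x–z (axial
rotation, then flexion–extension, then lateral bending), mapped to
clinical angles with these signs:

| angle | motion | sign |
|---|---|---|
| alpha | flexion–extension | flexion (−) / extension (+) |
| gamma | lateral bending | left (−) / right (+) |
| beta  | axial rotation | right (−) / left (+) |

and translations x right (−) / left (+), y inferior (−) / superior (+),
z posterior (−) / anterior (+).

The sequence is configurable because no single convention is universal.
Different Tait–Bryan sequences agree to second order: the spread across
sequences scales as the square of the angles (≈0.02° at 1°, ≈0.2° at 5°),
so physiological intervertebral angles are sequence-robust; the test suite
asserts this quadratic scaling. Gimbal lock (middle angle at ±90°) is
detected and raised by name — cervical anatomy cannot reach it, so hitting
it indicates corrupted input. `intervertebral_6dof()` reports either the
absolute relative pose at a posture or, by default, the joint displacement
from neutral (`motion_from_neutral`), in which the neutral posture is
exactly zero; both are provided because published figures of this kind are
ambiguous between the two readings.

## The synthetic study and what it does (not) show

`generate_vertebra()` builds a closed, connected, star-shaped surface: a
radially displaced icosphere with an anterior body bulge, a posterior
spinous prominence, two *unequal* transverse prominences and an off-axis
superior prominence, anisotropically scaled so the bounding box equals the
built-in typical dimensions of the chosen level (C1–C7) exactly. The
unequal and off-axis prominences remove all rotational and mirror
symmetry, so registration has a unique optimum. The fixtures are stylized
test bodies, **not** anatomical atlases: they reproduce realistic size,
surface complexity, and the absence of vertex correspondence between
independently segmented models — not patient anatomy, segmentation
artifacts, or imaging physics. Passing tests therefore demonstrate the
correctness and numerical accuracy of the measurement chain, not the
clinical accuracy of any particular scanner protocol.

`perturb_mesh()` emulates an independently segmented copy of the same
bone: the surface is resampled onto a fresh, randomly rotated icosphere
connectivity by radial ray casting from the centroid (no shared vertices,
resampled vertices exactly on the original surface), then vertices are
displaced along local normals by zero-mean Gaussian noise — segmentation
error lives on the surface normal, not isotropically. The half-normal
identity E|N(0, σ)| = σ√(2/π) gives a closed-form check: σ = 0.2 mm must
produce a mean absolute deviation of ≈0.16 mm, and does.

Study conditions (the generator defaults) are: icosphere subdivision 4
(2562 vertices / 5120 faces per vertebra), remeshed copies at face-count
factor 4 (≈20k faces), noise σ = 0.2 mm — the sub-0.6 mm deviation regime
of CT-vs-CBCT model comparisons. Resolution matters because flat facets
chord the true surface: the chordal sag acts as a resolution-dependent
bias floor on registration accuracy. At these conditions the noiseless
recovery bias is ≈0.02°, an order below the 0.1° accuracy the validation
asserts; at subdivision 3 / factor 1 it would be ≈0.17°. These sizes were
fixed by measuring that bias floor before the validation suite was
frozen, and they keep a 100-registration recovery study in the
few-minute range.

`make_scenario()` builds ground-truth multi-posture motion: C7 fixed, each
joint rotation acting about the *moving* vertebra's frame origin, so the
prescribed joint angles appear with exactly zero intervertebral
translation — a clean target for end-to-end recovery. The `"ar"` preset
concentrates 30° of axial rotation at C1–C2 with a small
opposite-direction coupled lateral bend there (and small same-direction
subaxial rotation), the characteristic atlantoaxial pattern; `"fe"` and
`"lb"` distribute their primary motions across levels.

## Numerical choices, edge cases, limitations

* Closest-point queries: Ericson's region-based point-triangle algorithm;
  uniform spatial grid over facet bounding boxes with conservative
  shell-by-shell search; results identical to brute force by construction
  and by test.
* Signs at edges/vertices come from the nearest facet (lowest index on
  exact ties). At strongly concave creases a sign can flip; the deviation
  magnitudes, which all reported statistics except `average_distance`
  depend on most, are unaffected.
* Transform construction re-orthonormalizes via SVD and rejects
  reflections; compose/invert therefore cannot accumulate drift.
* Degenerate inputs fail by name: zero-area faces, disconnected meshes,
  non-manifold edges, collinear landmarks, gimbal lock, non-star-shaped
  inputs to the radial remesher.
* The remesher requires star-shaped input (true of generated fixtures,
  not of real vertebrae with foramina); it is a fixture tool, not a
  general-purpose remesher.
* Determinism: generation and perturbation derive everything from the
  spec seed through a private RNG stream (the caller's `.Random.seed` is
  restored); ICP contains no randomness; pipeline runs with a fixed
  config produce bit-identical CSVs.
* Per-subject statistics across participants, non-rigid registration,
  DICOM handling, and time-resolved motion are out of scope.
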