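# spinekin

Markerless, in vivo measurement of cervical spine kinematics from
per-vertebra surface models. Given closed triangle meshes of each vertebra
(C1–C7) segmented in a neutral posture and in end positions of functional
movement — e.g. from upright cone-beam CT — `spinekin` registers each
vertebra across postures by iterative closest point (ICP), builds
anatomic coordinate frames from bony landmarks, and reports
six-degree-of-freedom intervertebral motion, together with the signed
surface-deviation statistics used to validate model accuracy. A synthetic
vertebra generator provides ground-truth studies so the whole chain is
verifiable without patient data.

## The method in brief

For a vertebra with moving-model vertices `m_i` and a target surface `S`,
registration minimizes the summed squared closest-point distances

    E(R, t) = sum_i  d(R m_i + t, S)^2

by alternating point-to-surface correspondence with the closed-form
orthogonal-Procrustes (SVD) rigid update; the reported objective is the
RMS of correspondence distances. Per-vertebra anatomic frames (x leftward,
y superior, z anterior; origin at the posterior-inferior corner of the
vertebral body in the mid-sagittal plane) are carried through the
recovered transforms; the pose of each vertebra in its subjacent
vertebra's frame,

    R_rel = R_lower' R_upper ,  t_rel = R_lower' (o_upper - o_lower) ,

is decomposed (intrinsic y–x–z) into clinical angles: alpha = flexion(−)
/ extension(+), gamma = lateral bending left(−)/right(+), beta = axial
rotation right(−)/left(+); translations are mm along the lower vertebra's
axes. Model accuracy is summarized by signed point-to-surface deviations
(mean, extremes, subset SDs, mean absolute deviation, RMS), and a linear
deviation `d` over a bone dimension `L` maps to an angular uncertainty of
`d/L` radians — e.g. 0.02–0.06 mm over an 11.9 mm vertebral height is
roughly 0.1–0.3°.

## Worked example

```r
library(spinekin)

# simulate a study: 30 deg of axial rotation concentrated at C1-C2,
# independently remeshed models with 0.2 mm segmentation noise
dir <- tempfile()
simulate_study(dir, make_scenario("ar", postures = "left_rotation"),
               seed = 1)

cfg <- study_config(manifest = file.path(dir, "manifest.json"),
                    out_dir = file.path(dir, "out"))
kin <- run_kinematics(cfg)$kinematics
subset(kin, posture == "left_rotation",
       select = c(level_pair, tx, ty, tz, alpha, gamma, beta))
```

```
   level_pair       tx       ty       tz    alpha    gamma     beta
2       C1-C2 -0.04104 -0.01372  0.01027  0.06446 -6.00563 30.09132
4       C2-C3 -0.01942  0.02195 -0.02222 -0.10153  0.23565  2.96973
6       C3-C4  0.01250 -0.00430 -0.01234  0.01750  0.26989  3.05458
8       C4-C5  0.04024  0.01126  0.03298 -0.03186  0.33209  2.85995
10      C5-C6 -0.04787 -0.00244 -0.01579  0.03596  0.19867  2.20588
12      C6-C7  0.02479  0.00034  0.01517 -0.00672  0.21904  1.84423
```

The injected motion was 30° of atlantoaxial rotation with a −6° coupled
lateral bend there, 2–3° of same-direction rotation (with ~0.2–0.3°
coupled bend) subaxially, and exactly zero translation. Through the full
chain — independent remeshing, 0.2 mm surface noise, ICP registration,
frame transport and Euler decomposition — every joint angle is recovered
within ~0.2° and every translation within 0.05 mm. `run_validation()` produces the matching
model-accuracy table (one row of deviation statistics per level), and all
outputs (transforms JSON, accuracy and kinematics CSVs, run manifest) are
written to `cfg$out_dir`.

A command-line front end with `simulate`, `validate`, `kinematics` and
`inspect-transform` subcommands is installed at `inst/cli/spinekin.R`.

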