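---
title: "How far can CT dose drop before LV function metrics break? Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lvdose)
```

`lvdose` asks a study-design question: if the tube current of a cardiac CT
acquisition is cut from its standard level (~500 mA) to 100, 50, 25 or
10 mA, at what point do left-ventricular functional metrics derived from
automatic segmentation stop being trustworthy? The package answers it with
an *objective observer* pipeline on synthetic ventricles: phantoms whose
functional metrics are known in closed form are scanned by a simulated CT,
low-dose scans are emulated from the standard-dose data, observers segment
every volume, and each low-dose measurement is compared with the
standard-dose measurement of the same case. This vignette records the
models, the tunable parameters, the numerical choices, and the places
where the design was genuinely open.

## The phantom and its closed-form ground truth

The left ventricle is modelled as a truncated prolate-spheroid shell in a
canonical pose (long axis along $z$, apex down). The end-diastolic (ED)
endocardium and epicardium are coaxial prolate spheroids with semi-axes
$(a, a, c)$ and $(A, A, C)$; both are cut by the basal plane at height
$f\,c$ above centre ($f$ = `base_truncation_frac`, default 0.5).
End-systole (ES) scales the endocardium by `es_radial_scale` $s_r$ in-plane
and `es_long_scale` $s_\ell$ along the axis. The basal plane follows the
endocardial long axis ($h_{ES} = s_\ell f c$), so it stays at the same
material level.

Because every surface is an ellipsoid, all four metrics have closed forms.
The cavity volume of a spheroid truncated at $z \le f c$ is
$V = \pi a^2 c\,(f - f^3/3 + 2/3)$, so

* **EF** $= 100\,(1 - s_r^2 s_\ell)$ (independent of the anatomy),
* **GLS** $= 100\,(s_\ell - 1)$, with $L$ the endocardial-apex-to-basal-plane length,
* **CS** $= 100\,(s_r - 1)$ at every short-axis level (the fraction-based
  plane placement makes the longitudinal coordinate scale out),
* **WT** per level from the radial thickness
  $t(z) = A\sqrt{1-(z/C)^2} - a\sqrt{1-(z/c)^2}$ and its ES counterpart.

The ES epicardium follows one of two wall models. The default,
*volume-preserving*, solves the ES epicardial short axis so that the
myocardial shell volume is conserved — incompressible myocardium, which
guarantees physiological systolic wall thickening. *Fixed-thickness* keeps
the ED wall at apex and equator instead (and gives near-zero WT); it
exists mainly as a contrast case. `build_phantom_spec(target_ef_pct=)`
solves a one-knob contractility family ($s_\ell = 1 - 0.6(1-s_r)$,
longitudinal shortening 60% of radial — a physiological GLS/CS ratio) by
1-D root finding on the analytic EF, which is how `generate_cohort()`
spans normal to reduced function (default target EF range 35–70%).

Voxelization applies analytic inside-tests on the rotated surfaces; the HU
image maps labels through `hu_map` (background 40, myocardium 100, blood
pool 350 — a contrast-enhanced study). The image embeds the LV in a
cylindrical soft-tissue body with air outside (`body_radius_mm`, default
90% of the in-plane half-extent): a compact object inside the field of
view is what a CT scanner actually sees, and without it the projections
are truncated at every angle and filtered back-projection cannot recover
the DC term. What the phantom deliberately lacks: papillary muscles,
trabeculation, the right ventricle and atria, motion blur, and any
anatomical texture. Passing tests therefore show that the *pipeline*
measures ellipsoidal ventricles correctly at these noise levels — they do
not certify performance on clinical anatomy.

## The CT simulator

A deliberately simple parallel-beam, per-axial-slice geometry replaces the
clinical wide-coverage cone-beam system: the study's question concerns
noise level, not geometry. Defaults: 192 detectors at 1.0 mm pitch, 180
angles over [0, 180°); the study runs use 128 × 1.25 mm and 120 angles on
a 64³ grid at 2.25 mm (field of view 144 mm). Geometries below the
$n_\text{angles} \ge n_\text{det}\,\pi/2$ rule of thumb are flagged with a
warning, not an error — mild angular undersampling adds streaks that are
part of the accepted desk-scale dialect here.

HU convert to attenuation as $\mu = \mu_w(1 + \mathrm{HU}/1000)$, clamped
at zero, with $\mu_w = 0.020$/mm. The noise model inserts, per ray,

$$N = \mathrm{Poisson}(I_0 e^{-p}) + \mathcal{N}(0, \sigma_e^2), \qquad
p' = \ln(I_0/N),$$

with $I_0(\mathrm{mA}) = I_0^{ref}\,\mathrm{mA}/500$ and electronic noise
$\sigma_e = 10$ counts. Counts are floored at 0.1 before the log (photon
starvation guard). $I_0^{ref} = 3\cdot10^5$ photons/ray at 500 mA was
calibrated once against the degradation magnitudes reported for clinical
low-dose emulation: at the study conditions the rule-based observer's
myocardium Dice against its own standard-dose result is ~0.97 at 100 mA,
~0.94 at 50 mA (the anchor), ~0.89 at 25 mA, and ~0.73 at 10 mA — the
regime where functional analysis visibly starts to fail, which is the
point of including 10 mA at all. Standard-dose segmentation remains
near-perfect (Dice ~0.985 against ground truth).

Low doses are **emulated, not re-scanned**: per ray, zero-mean Gaussian
noise with variance equal to the difference of the delta-method variances
at the low and standard doses is added to the *measured* standard-dose
sinogram (whose own noise is part of the total). This paired design gives
every ladder volume identical anatomy and identical standard-dose noise —
exactly the design that lets a per-case low-dose-vs-standard-dose
comparison isolate the effect of dose. The Gaussian increment is a known
approximation: at 10 mA (hundreds of counts per ray) the Poisson
difference is not quite Gaussian, and `simulate_counts()` provides the
direct route for cross-checks; the Monte-Carlo validation keeps both
within 10% in mean and variance.

Reconstruction is per-slice FBP. The ramp filter is the discrete Ram-Lak
kernel built in the *spatial* domain and FFT'd — sampling $|f|$ directly
in frequency zeroes DC and produced a −30 to −40 HU cupping bias — then
Hann-apodized as the surrogate for a clinical "standard" kernel.
A noise-free project-then-reconstruct cycle reproduces interior HU within
a few HU (tested within ±10).

## The observers

Two observer families share one contract (`segment_volume()`):

**Rule-based** (deterministic): HU thresholds at 70 and 225 (the class
midpoints), largest 6-connected component per foreground class, and
enclosed background pockets filled by their boundary majority. It is
exact on noise-free phantoms and serves as the fully reproducible
observer for the degradation-structure experiments.

**Residual 3D U-Net**: four encoder–decoder levels, two residual blocks
per level (conv–norm–ReLU ×2 with identity shortcut; 1×1×1 projection
when channel counts change), channel doubling per level, instance
normalization, nearest-neighbour upsampling + conv in the decoder,
concatenated skips, and deep supervision — generalized-Dice losses at the
three finest decoder resolutions with weights 1/0.5/0.25 against
nearest-downsampled labels. The finest head additionally receives the raw
(HU-normalized) input as an extra channel: instance-norm features are
window-relative, and at desk-scale window sizes the skip restores the
absolute intensity cue that defines the classes. Inference is
sliding-window at the training window size (instance statistics are
window-dependent), averaging softmax over overlaps, argmax ties broken
toward the lower class index.

The generalized Dice loss follows
$\mathrm{GDL} = 1 - 2\,\frac{\sum_l w_l \sum_n r_{ln} p_{ln}}
{\sum_l w_l \sum_n (r_{ln} + p_{ln})}$, $w_l = 1/(\sum_n r_{ln} +
\epsilon)^2$. For *training*, classes absent from a patch get the largest
finite weight instead of the $1/\epsilon^2$ blow-up — the usual
stabilization; absent classes are still suppressed, with a bounded
gradient scale. The exported `generalized_dice_loss()` keeps the literal
formula.

Training is patch-based (Adam, no data augmentation), with half the
patches centred on a random foreground voxel. The clinical-scale recipe
(batch 32, 200 epochs, lr 5·10⁻⁴, patch 128×128×64, 32 base channels)
is expressible through `net_config()`/`train_recipe()`, but the package's
study runs use a desk-scale configuration: 4 base channels, 16³ patches,
batch 2, 100 epochs × 10 batches, lr 2·10⁻² with cosine decay. The
learning rate is *not* the clinical-scale one: a ~50k-step budget was scaled to ~1k
steps, and Adam's total displacement is bounded by lr × steps, so the
rate must scale up with the step-budget cut or the weights can never
reach the magnitudes that separate the classes. Training is exactly
reproducible: fixed (recipe, data) gives an identical loss curve.

The two regimes mirror the study design: the **Standard** observer trains
on standard-dose volumes only (`doses_included = "SD"`), the
**Noise-Robust** observer on standard plus all emulated low-dose volumes
of the same cases (`"all"`); the `dataset_audit` in each trained observer
records exactly which (case, dose) pairs participated.

## Views and metrics

The long axis is the principal eigenvector of the blood pool's second
central moment tensor (declared degenerate below an eigenvalue ratio of
1.2), oriented apex→base using the cavity's uncovered basal face. The
apex and base positions along the axis are then refined by extent
regression: near a rounded (apical) end the cumulative voxel count behind
depth $d$ grows as $d^2$, at a flat (basal) cut linearly, so the sorted
axial projections extrapolate to the surface with far less quantization
noise (~0.02 mm) than any single extreme voxel (~0.3 × voxel).

Five planes are resampled per volume: two long-axis views containing the
axis at azimuths 0° and 90° (the phantom is axisymmetric; the right angle
mirrors the roughly orthogonal clinical 2-CH/PLAX pair), and three
short-axis planes perpendicular to the axis at fractions 0.8/0.5/0.2 of
the apex-to-base length from the apex (the standard basal/middle/apical
levels; the exact fractions are a package choice, configurable and
logged). Labels are resampled nearest-neighbour (1 mm pixels); smooth
per-class indicator fields and fine boundary profiles are carried
alongside for sub-voxel measurement. By default, plane positions are
located from **each phase's own labels** (`plane_mode = "per-phase"`):
under longitudinal shortening, a fixed world plane cuts the ES ventricle
at a different material level (biasing apical CS by up to ~15 pp), while
per-phase fractions compare corresponding levels — which is also what
makes the fraction-defined analytic ground truth recoverable. The
`"ed-frame"` mode (reuse ED planes verbatim) remains available.

Metric conventions, all logged: Lagrangian strain, ED reference,
shortening negative. EF from blood-pool voxel counts in native
coordinates. GLS from the apex-to-basal-plane cavity extent along the
axis within each long-axis view (sub-pixel 0.5-crossings of a fine
0.2 mm axial blood profile), averaged over the two views. CS from the
endocardial perimeter traced by 360 radial rays from the blood-pool
centroid; the radius profile is regularized by a ±4° circular moving
average before the polygon length is taken — raw per-ray crossings carry
~0.1 mm voxel-grid jitter which inflates a polygon quadratically, and
asymmetrically between phases. WT along 16 equally spaced spokes from
each phase's own centroid, thickness = epicardial minus endocardial
crossing radius (profiles smoothed ±2°); spokes whose ray exits straight
into background are flagged missing, more than 4 missing is an error, and
an obliterated ES cavity reports CS = −100 with a flag. On a ten-phantom
cohort with generator labels at 0.75 mm voxels the pipeline recovers the
analytic ground truth within 1 pp for EF/GLS/CS and 2 pp for average WT
(the acceptance surface; EF errors are ~0.04 pp, GLS ~0.2 pp).

## The study and the threshold rule

`run_study()` wires the stages per case and phase: voxelize → standard
scan → emulated ladder → segment (every observer × dose) → views →
metrics; low-dose results are compared against the same observer's
standard-dose result via signed deltas (stored signed; absolute values at
aggregation) and per-phase Dice. Failures are recorded per (case,
observer, dose), never silently dropped. `aggregate_deltas()` reports
mean ± SD of Δ and |Δ| plus the 90th-percentile |Δ| (linear-interpolation
quantile, R type 7).

The narrative acceptability judgement clinicians apply is formalized as one explicit
monotone rule: the detected threshold is the lowest mA such that it *and
every higher dose* satisfies P90(|Δ|) ≤ 2.5 pp for every metric family in
the configured set — default {EF, GLS, CS}, with WT excluded by default
given its substantially higher measurement variability (includable via
configuration). This is one faithful formalization of a narrative
judgement, flagged as such in every exported manifest.

## Problem sizes and numerical choices

The package's study conditions, chosen once for desk scale and used by
the analysis scripts, the acceptance checks and the tests: parameter
recovery on 10 phantoms at 0.75 mm voxels (168³); the rule-observer
ladder on 10 phantoms at 64³/2.25 mm, 128 detectors × 1.25 mm, 120
angles, doses 500/100/50/25/10 mA; network observers trained on 6
phantoms × 2 phases × 5 doses with the desk-scale recipe above and
compared on 10 held-out phantoms at 500 vs 25 mA. Monte-Carlo noise
validation uses 10⁴ repetitions of a fixed ray. Degenerate inputs are
errors, not warnings: zero-wall phantoms, unattainable target EF,
non-rotation orientations, inverted thresholds, unsorted dose ladders,
empty blood pools.

Known limitations, beyond the phantom's geometric idealism: the Gaussian
incremental-injection approximation thins at 10 mA; parallel-beam FBP is
not a vendor reconstruction; the desk-scale U-Net is an objective
observer, not a clinical model — its absolute Dice (~0.85 myocardium on
held-out standard-dose phantoms) is far below what the clinical-scale
network reaches on real data, and only *relative* statements between its
two training regimes carry over; and kVp, BMI dependence, and effective
dose in mSv are out of scope (tube current is the only dose axis).
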