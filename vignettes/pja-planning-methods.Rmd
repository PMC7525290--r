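---
title: "Biomechanical PJA planning: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomechanical PJA planning: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pjaplan)
```

# The problem

After long posterior instrumentation and fusion for adolescent idiopathic
scoliosis, a fraction of patients develop proximal junctional kyphosis
(PJK): the proximal junctional angle (PJA) measured two years after
surgery exceeds 10 degrees and the pre-operative value by at least 10
degrees. The working hypothesis behind this package is biomechanical: an
inappropriate intra-operative change of the PJA redistributes the load of
the body weight carried above the upper instrumented vertebra (UIV), and
the resulting change of the stress state in the cephalad intervertebral
disc of the UIV drives early degeneration. `pjaplan` implements that
hypothesis as a computational pipeline — disc FEM, stress-change features,
a small neural risk model, and a one-dimensional angle optimisation — and
provides the synthetic machinery needed to test every step.

# Loading model

The contact force on the superior disc surface is the component of the
supported weight along the surface normal,

$$F = G \cos\alpha, \qquad G = w\, g\, f_{\mathrm{UIV}},$$

with $w$ the body weight (kg), $g = 9.81\,\mathrm{m/s^2}$, $\alpha$ the
PJA in degrees, and $f_{\mathrm{UIV}}$ the fraction of body weight carried
above the UIV. $f_{\mathrm{UIV}}$ defaults to 0.5 and is configurable per
UIV level; published anthropometric tables put the weight fraction above
the mid-thoracic spine near one half, and none of the package's
conclusions depend on its exact value because $F$ enters the linear model
multiplicatively. The direction of $F$ is fixed along $-z$ (normal to the
superior face); only its magnitude varies with $\alpha$. This keeps the
whole stress field an explicit linear function of $G\cos\alpha$, which the
optimiser exploits.

# Disc geometry and mesh

Patient imaging is out of scope, so the disc is idealised as an elliptic
cylinder: lateral semi-axis 20 mm, anterior–posterior semi-axis 14 mm,
height 8 mm — mid-range adult lumbar/thoracolumbar disc dimensions — with
a concentric nucleus pulposus bounded by the outer ellipse scaled by 0.6
(nucleus area fraction 0.36, within the commonly cited 30–50%). The
coordinate convention is +x = patient left, +y = anterior, +z = cephalad,
origin at the inferior-face centroid, which turns the anatomical
left/right and anterior/posterior splits into sign tests on element
centroids (ties go to the non-negative side).

The mesh is a structured polar scaffold — centre wedges plus quad rings
per axial layer — whose prisms are split into tetrahedra by cutting every
quadrilateral face along the diagonal through its smallest global node
index. Because the cut depends only on the face, neighbouring cells make
the same cut and the tetrahedralisation is conforming; orientation is
fixed by a signed-volume check. At the default resolution (4 radial rings,
16 sectors, 4 layers; 1344 elements) the meshed volume is within 2.6% of
$\pi a b h$; the error is set by the polygonal approximation of the
ellipse and shrinks with the sector count. One consequence worth knowing:
the diagonal choices are not mirror-symmetric, so properties such as
"mirrored load gives mirrored stress" hold exactly only between a mesh and
its explicitly mirrored copy, not within one mesh; the tests are written
accordingly.

# Material model and solver

Both components are linear elastic, homogeneous and isotropic (Hooke's
law): nucleus $E = 1.0$ MPa, $\nu = 0.49$; annulus fibrosus $E = 3.4$ MPa,
$\nu = 0.45$ — standard values for idealised disc models. Anisotropy,
poroelasticity and time dependence are deliberately excluded. Units are
mm–N–MPa throughout.

The solver uses 4-node constant-strain tetrahedra, assembles the global
stiffness into a sparse matrix, fixes every inferior-surface node in all
three degrees of freedom by row/column elimination (exact constraint
satisfaction, no penalty parameters), lumps the uniform traction
consistently over the superior-face triangles (area/3 per vertex) and
solves by sparse direct factorisation — the systems are a few thousand
unknowns, so iterative methods would add tolerance questions for no
benefit. Element stress is recovered from the displacement gradient via
Hooke's law and scalarised as von Mises stress. The published description
of the original workflow never names its stress scalar; von Mises is
chosen here because it is rotation-invariant and the de-facto standard for
soft-tissue FEM summaries. Verification is by construction: the uniform-
pressure patch test is exact to solver precision at $\nu = 0$ (the
constant-strain element reproduces constant-stress states exactly), and
reaction forces balance the applied load to machine precision.

# Stress-change features

Stress is summarised over eight anatomical subregions — annulus (F) or
nucleus (N) × anterior/posterior × left/right — by two statistics per
subregion: the maximum element von Mises stress and the volume-weighted
mean (volume weighting makes the average insensitive to local mesh
density). The model input is the signed difference, post-operative minus
pre-operative, of the 16 summaries, with both solves performed on the same
disc model, plus age and gender (encoded M = 0, F = 1). The signed choice
(not absolute value) lets the downstream model distinguish stress
increase from relief. The fixed feature order is
`dmax_FAL ... dmax_NPR, davg_FAL ... davg_NPR, age, gender`.

Because the problem is linear, the post-operative summaries at any angle
are the unit-load summaries times $G\cos\alpha$; `unit_stress_summary()`
therefore solves the FEM once per geometry and every downstream angle
evaluation is a vector scaling. The equality of this shortcut with a full
re-solve is asserted to 1e-6 relative in the tests (it holds to ~1e-13).

# Risk model

The classifier is a fully connected network with one hidden layer (width
8, tanh) and a sigmoid output, trained full-batch by Adam (learning rate
0.01, $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$, 2000
epochs, Xavier-uniform initialisation) on the mean squared error between
the predicted risk and the binary outcome — an L2 objective rather than
cross-entropy, honouring the originating formulation literally. None of
the architectural constants were published; the defaults here are the
smallest sensible capacity for cohorts of the published scale and all are
configurable. Features are z-standardised with training-set statistics
(stress deltas in MPa and age in years differ by orders of magnitude);
held-out cases are always transformed with the training fold's statistics,
never their own. Training is bit-reproducible given the configuration
seed, and backpropagation is verified against central finite differences
for both weight gradients and input gradients — the latter feed the angle
optimiser. Evaluation is leave-one-out cross-validation (each fold
re-standardises and re-trains) with accuracy at a 0.5 threshold — the
threshold consistent with the published per-patient outputs, where 0.556
is flagged positive and 0.401 negative — and the Mann–Whitney form of the
ROC AUC with ties counted one half, cross-checked against an independent
implementation in the tests.

# Feature ranking and sensitivity

Features are ranked by the DX discrimination score
$(\mu_1 - \mu_0)^2 / (\sigma_1^2 + \sigma_0^2)$ using sample variances and
a $10^{-12}$ denominator guard; the score is invariant to affine feature
rescaling, so ranking before or after standardisation is equivalent. The
impact of a subset is its share of the total score, in percent.
Sensitivity of a trained model follows the perturbation reading of
"output variance under a 5% input perturbation": each selected feature is
perturbed multiplicatively over an 11-point symmetric grid spanning ±5%,
and the statistic is the maximum relative change of the predicted risk
across patients and grid points. Features with exact zeros in the cohort
(gender, for instance) fall back to additive perturbation scaled by the
feature's cohort standard deviation, and are flagged.

# Optimal PJA

For a new patient the recommended post-operative PJA minimises the
predicted risk over a feasible range (default 0–45 degrees, which covers
every angle in the packaged cohort with margin). The risk curve over
$\alpha$ is evaluated through the unit-load scaling, so the optimisation
is a cheap 1-D problem: a 0.1-degree grid scan for global robustness,
followed by Adam refinement from the best grid point using the analytic
chain-rule gradient $\partial g/\partial\alpha$ through
$\Delta\sigma(\alpha)$. Angles whose risk lies within $10^{-3}$ of the
minimum are ties, resolved toward the patient's pre-operative angle —
minimising the PJA blindly is clinically unreasonable, and for flat or
near-flat risk curves the least-disruptive angle is the defensible
recommendation (a `flat` diagnostic is set). The refined optimum is never
worse than the best grid point by more than the tie tolerance, and the
whole procedure is deterministic.

# Synthetic cohorts and what they do (not) show

The original twelve-patient table is packaged verbatim as
`cohort_fixture()`, including the originally reported per-patient model
outputs and recommended angles as `reported_*` columns. Its printed
summary statistics are reproduced by the tests, with one caveat: the
published pre-operative PJA summary of the PJK group (8.4° ± 2.9°,
"between 5.2° and 9.4°") is inconsistent with the table's own PJK rows
(10.7/4.1/9.4 → mean 8.1, sd 3.5); the package follows the table. The raw
per-patient imaging is unavailable, so the published headline accuracy can
only be reproduced from the reported outputs, not re-derived from images.

`generate_cohort()` draws virtual patients inside the published cohort's
envelope — weight uniform on 32.5–71 kg, age uniform on 13–20 years,
pre-operative PJA normal (7°, 5°) truncated to [0°, 20°], intra-operative
change normal with 5° spread, two-thirds female, PJK prevalence near the
published 3/12 — assigns each a disc geometry jittered ±10% around the
default, computes true stress features through the FEM, and labels
patients by a known mechanism on one designated stress feature (default
`dmax_NAR`, the maximum-stress change in the right anterior nucleus,
echoing the kind of feature reported as highly ranked). Two structural
choices matter:

* **Independent feature noise (sd 0.35 of each feature's cohort SD).**
  With idealised, near-symmetric geometries all 16 stress features are
  almost exactly proportional to $G(\cos\alpha_{post} -
  \cos\alpha_{pre})$ across patients; a single-feature mechanism would
  then be unidentifiable in principle — every feature would discriminate
  equally. The additive noise emulates the patient-specific disc-shape
  variation that the parametric jitter cannot represent and makes the
  mechanism recoverable. Real CT-derived features would carry at least
  this much patient-level variation.
* **Separation margin.** The threshold label rule optionally enforces a
  gap (default test condition: 0.3 standardised units) around the
  decision boundary by oversampling and keeping only patients clear of
  it. Without the gap, patients arbitrarily close to the boundary bound
  the achievable held-out accuracy near 0.85 regardless of the learner;
  with it, the recovery tests check the pipeline rather than the
  boundary-point lottery.

Consequently, passing recovery tests show that the pipeline can find a
strong, separated, single-feature mechanism at n = 60 and behaves at
chance when there is none; they do not show that real PJK risk is
single-featured, separable, or learnable at n = 12.

# Numerical choices and limitations

Problem sizes were chosen to keep the full test suite fast: verification
meshes use 2 radial rings × 8 sectors × 2 layers, recovery cohorts n = 60,
and the default mesh 1344 elements; all resolutions are parameters.
Degenerate inputs are rejected early (zero-volume tetrahedra, unconstrained
systems, single-class training sets warn, empty subregions error as
under-resolution). Known limitations: linear elasticity without contact or
vertebrae, an idealised disc shape, a load direction fixed along the disc
normal, and a risk model whose capacity is intentionally tiny. The
package's claims are about the pipeline's internal correctness and
recoverability, not about clinical validity.
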