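---
title: "Voxel-wise prediction of chronic stroke lesions from acute multi-parametric MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise prediction of chronic stroke lesions from acute multi-parametric MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

In hemispheric ischemic stroke, the extent of the final infarct — read from a
T2-weighted MRI about three months after the event — is the imaging gold
standard for tissue outcome. `strokenet` implements a voxel-wise predictor of
that chronic T2WI from four co-registered acute-phase contrasts (DWI, T1WI,
T2WI, PDWI). Each voxel contributes a 4-vector of normalized acute
intensities $x \in \mathbb{R}^4$ and a continuous target $y$, the normalized
chronic T2WI intensity at the same location. The regression function is a
small multilayer perceptron

$$\hat y = g\!\left(W_3\,\phi\!\left(W_2\,\phi(W_1 \tilde x)\right)\right),$$

where $\tilde x$ appends a bias unit to each layer's input, $\phi = \tanh$ is
the bipolar sigmoid (an S-shaped activation polar between $-1$ and $1$), and
$g(a) = \tfrac{hi-lo}{2}(\tanh a + 1) + lo$ maps the output unit onto the
normalized-intensity range $[lo, hi] = [0, 3]$. The reference architecture is
$[4{+}1]:[3{+}1]:[3{+}1]:1$, 31 free parameters. Because brain-mean
normalization puts healthy parenchyma near 1 and the infarct well above it,
a continuous prediction of the chronic intensity doubles as a graded lesion
map; the binary lesion/normal labels are kept only for the
classification-style statistics (ROC, CCF).

Training is batch back-propagation on the mean squared error: the gradient
is accumulated over *all* training voxels and applied in one update per
epoch,

$$\Delta W^{(t)} = -\eta\,\nabla_W \mathrm{MSE} + \mu\,\Delta W^{(t-1)},$$

with learning rate $\eta = 0.01$ and momentum $\mu = 0$. We define the MSE
as the per-epoch **mean** (not sum) of squared residuals so the learning
rate's meaning does not depend on the number of voxels shown to the network.
The MSE, and hence the 0.06 termination error, is computed on the
normalized-T2 $[0,3]$ output scale — the natural scale of the target — not
on the $[-1,1]$ activation scale; this choice is documented because it fixes
the absolute meaning of the termination error.

## Preprocessing

* **Smoothing.** Every slice of every channel (the chronic target included)
  is smoothed with a 3×3 unity filter — each voxel replaced by the
  unweighted mean of its 3×3 neighbourhood — to blunt residual
  mis-registration. Borders use symmetric (edge-replicating) padding; zero
  padding would artificially darken brain-edge voxels.
* **Normalization.** Each channel is divided by its mean over the brain mask,
  computed once per subject over all slices (per-slice normalization would
  erase genuine inter-slice contrast). The result is gain-invariant:
  multiplying a channel by any $k > 0$ leaves the normalized data unchanged.
  The brain mask itself thresholds the smoothed acute T2WI at a configurable
  fraction (default 0.10) of the stack maximum.
* **ROIs.** The lesion ROI thresholds the normalized chronic T2WI (the
  threshold is a required configuration value — in the clinic it is a
  neurologist's judgment; on phantoms the default 1.35 is the midpoint
  between the normal and lesion class means). The contralateral-normal ROI
  reflects the lesion ROI about the midline, taken by default as the central
  image column and configurable for tilted acquisitions. Mirrored voxels
  that land back inside the lesion ROI (midline-crossing lesions, bright
  midline CSF) are removed from the normal mask with a warning. Prevalence —
  the lesion fraction of all selected voxels — is reported as an outcome,
  not imposed; an optional erosion/dilation of the normal mask can hit a
  requested prevalence within 2 points for sensitivity analyses, off by
  default.

## Cross-validation and model selection

Folds are whole patients: with $K$ subjects, each fold trains on $K-1$
subjects' voxels and tests on the held-out patient, so no voxel of a test
subject ever influences its own fold's weights. Two stopping modes exist:

* **Plateau mode** (used to *find* the termination error): every fold trains
  to the epoch cap while tracing the held-out correct classification
  fraction (CCF) — the fraction of voxels whose predicted and observed
  intensities fall in the same 0.05-wide bin. The per-epoch CCF curves are
  averaged across folds (aligned by truncation to the shortest trace), the
  plateau is estimated as the mean over the final 10% of epochs, and the
  stopping epoch is the first epoch within 10% of that plateau. The phrase
  "10% of the plateau" is ambiguous; we read it as "within 10% of the
  plateau value" and expose both fractions as knobs. We locate the plateau
  on the fold-averaged curve rather than per fold, since the averaged curve
  is what the stopping heuristic was described on. The mean of the per-fold
  training MSEs at that epoch is the **termination error**.
* **MSE mode** (the production run): each fold trains until its pre-update
  epoch MSE reaches the termination error (default 0.06).

Architecture selection fixes the first hidden layer at 3 units (smaller
first layers fail to train) and scores each candidate second-hidden-layer
size by the **AUCCF** — the span-normalized trapezoidal area under the CCF
curve of the concatenated held-out predictions — selecting the maximum with
ties broken toward the smaller network.

Pooled held-out predictions across folds yield the ROC curve (thresholds at
all midpoints between distinct scores, trapezoidal AUROC, which equals the
tie-corrected pairwise-ranking probability), the optimal operating point at
the intersection of the ROC with the descending 45° line $TPF = 1 - FPF$
(the sensitivity = specificity locus, consistent with near-equal reported
optima), and the correlation between predicted and observed chronic maps.
Because voxels within a patient are correlated, the regression of observed
on predicted uses a cluster-robust (CR0) sandwich variance — the meat is the
sum of within-cluster score outer products, with no small-sample factor —
and a $t$ reference with $G-1$ degrees of freedom for $G$ patients, the
conventional small-$G$ choice.

## The synthetic phantom cohort

No imaging data are distributed, so the generator builds what the analysis
assumes: per subject, a stack of 2D slices (default 7, ≈ 83 slices / 12
subjects) with an elliptical brain on a zero background and three tissue
classes — normal parenchyma, a one-sided ischemic lesion whose radius varies
across slices, and a bilaterally symmetric pair of CSF disks. Intensities
are class-conditional Gaussians truncated at zero, on the brain-mean ≈ 1
scale, with defaults (normal / lesion / CSF): DWI 1.0 / 1.6 / 0.4, T1WI
1.0 / 0.9 / 0.6, T2WI 1.0 / 1.3 / 1.6, PDWI 1.0 / 1.2 / 1.3, chronic T2WI
0.9 / 1.8 / 1.9, SD 0.1 throughout. These encode the qualitative physics the
method exploits — the lesion is bright and CSF dark on DWI while both are
bright on chronic T2WI — with class separations of several pooled SDs, i.e.
an idealized, clearly learnable cohort. Spatial coherence comes from box-
smoothing the noise field (half-width 1 voxel) while class boundaries stay
crisp so ROI-counting tests are exact. The chronic lesion geometry defaults
to the acute geometry; a growth/recovery factor and an integer chronic-only
mis-registration jitter are available but off by default, since no
magnitudes are reported for them. An optional two-subclass (core /
recoverable) lesion is likewise left unparameterized by default. All
randomness flows from one master seed through documented sub-seed splitting,
so cohorts are bit-reproducible.

What the phantom does **not** emulate: MR physics (no TR/TE/b-value signal
equations), partial-volume mixtures beyond what the 3×3 smoothing induces,
anatomical texture, bias fields, or non-rigid deformation. Passing the
end-to-end tests therefore shows the pipeline is correct and recovers a
learnable signal under its own assumptions — not that the clinical accuracy
figures transfer to any particular scanner or cohort.

One consequence worth knowing: smoothing the chronic channel creates
partial-volume halo voxels around the lesion and CSF that exceed the default
ROI threshold, so the default cohort's prevalence lands near 0.63 rather
than the ≈ 0.57 the class geometry alone would give. We left this alone —
prevalence is an outcome of ROI construction here, exactly as in practice.

## Numerical choices and problem sizes

* Weight initialization: uniform $[-0.5, 0.5]$, seeded; per-fold seeds are
  derived deterministically from the global seed.
* Termination checks the **pre-update** MSE each epoch; on convergence the
  pre-update weights are kept, so the reported MSE describes the returned
  model.
* `training_config()` caps training at 1000 epochs; the pipeline default
  raises the cap to 5000 so the MSE-threshold rule, not the cap, decides
  when folds stop (defaults converge in roughly 500–2100 epochs). Hitting
  the cap returns the model with a warning flag rather than an error.
* Discretization bins are half-open with the exact upper range edge assigned
  to the last bin; CCF compares bin indices (a ±window tolerance band is
  available behind a config switch, since either reading of the published
  procedure is defensible).
* ROC tie handling: thresholds sit between distinct scores, so tied scores
  traverse diagonal segments and the trapezoid gives them half weight —
  matching the rank-statistic definition to machine precision.
* Architecture-search ties break toward fewer neurons.
* Default problem sizes — 12 subjects × 7 slices of 32 × 32 voxels,
  ≈ 9,500 ROI voxels — were chosen so a full leave-one-out run completes in
  about a minute on a laptop core while leaving every class ≥ 1,000 voxels
  for distributional checks.

## A worked run

```r
library(strokenet)
report <- run_pipeline(pipeline_config(seed = 1))
report
```

With the default conditions this prints (numbers from an actual run): 12
subjects, 9,540 voxel samples at prevalence 0.631; termination error 0.0599;
pooled held-out AUROC 0.969; optimal sensitivity/specificity 0.923/0.923;
and predicted-vs-observed correlation r = 0.928 with cluster-robust
p = 9.3e-11. On real patient data the corresponding published figures are
lower (AUROC ≈ 0.89, r ≈ 0.80) — the phantom is cleaner than pathology.

## Known limitations

* The phantom's idealized class separation makes the end-to-end accuracy an
  upper bound, not a forecast, for clinical data.
* The midline is a vertical column; rotated heads need the configurable
  midline or upstream reorientation.
* Batch gradient descent at a fixed small learning rate is deliberately
  faithful and deliberately slow; no adaptive optimizers, mini-batches or
  regularization are provided because the modelled procedure uses none.
* Inter-visit registration is out of scope: inputs are assumed co-registered.
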