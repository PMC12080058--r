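---
title: "Deep normative modelling of multi-modal brain features: methods and design"
author: "normdev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep normative modelling of multi-modal brain features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Case–control analyses of neurodegeneration average over patients who differ
widely in which brain regions are affected and how far their disease has
progressed. Normative modelling inverts the logic: it learns the range of
healthy variation in imaging-derived measures, conditional on demographic
covariates, and scores each *individual* by how far they deviate from that
norm. `normdev` implements a deep multi-modal variant of this idea for
tabular ROI features — regional grey-matter volumes (T1), and fractional
anisotropy (FA) and mean diffusivity (MD) of white-matter tracts — and the
downstream statistics used to interrogate the resulting deviations in
cohorts at risk of Alzheimer-type dementia.

The workflow has three stages:

1. **Train** a disentangled multi-modal variational autoencoder (DMVAE) on
   a large healthy cohort, after removing age/sex/ICV effects.
2. **Fine-tune** all weights on a smaller control cohort from the target
   site/study, absorbing acquisition and processing differences.
3. **Score** a holdout control cohort and the clinical cohort; deviations
   are referenced to the holdout controls so that residual model misfit,
   which affects controls and patients alike, cancels.

# Confound removal

For every feature we fit, on controls only,

$$y_j = f_j(\mathrm{age}) + \beta_{j,\mathrm{sex}}\,\mathrm{sex} +
        \beta_{j,\mathrm{ICV}}\,\mathrm{ICV} + \varepsilon_j,$$

with \(f_j\) a low-rank thin-plate regression spline (basis dimension 10 by
default) whose smoothness is selected by GCV; the spline basis and the
penalized least-squares solver come from **mgcv** (`smoothCon` + `magic`).
The age spline and the linear terms are fitted jointly. Features are then
replaced by control-referenced z-scores: residuals centred and scaled by
the control cohort's residual mean and (n − 1) standard deviation. One
confound model is fitted per site — the training site's controls for the
training cohort, the target site's fine-tuning controls for everything
else — and never shared, because the covariate-to-feature mapping is
site-dependent. Ages outside the fitted range are handled by linear
extension of the spline beyond the boundary, with a warning.

The basis dimension and GCV selection are implementation defaults, not
values prescribed by the method class; both are exposed in the API.

# The model

Each modality \(m\) has its own encoder and decoder (2-layer ReLU MLPs,
hidden width 64 by default). Encoders output Gaussian posteriors over a
**shared** latent \(z_s\) (default dimension 10) and a modality-**private**
latent \(z_p^{(m)}\) (default 2). Decoders are Gaussian with a learned
per-feature log-variance. Training minimises, per modality pair
\((m, n)\), the reconstruction negative log-likelihood of \(x_m\) decoded
from \([z_s^{(n)}, z_p^{(m)}]\) — i.e. both self- and cross-modal
reconstruction through the shared code, which is what pushes cross-modal
structure into \(z_s\) and modality-specific structure into \(z_p\) —
plus \(\beta\)-weighted KL terms for every shared and private posterior
against \(\mathcal N(0, I)\). Optimisation is Adam (learning rate 1e-3,
batch 256); fine-tuning continues from the pretrained weights at 1e-4, the
usual transfer-learning ratio. \(\beta = 1\) by default with optional
linear annealing. These architecture defaults are re-implementation
choices, deliberately small enough to train in seconds on desk-scale
cohorts, and all reconfigurable.

The model is implemented directly in base R matrix operations with
hand-derived gradients (verified against numerical differentiation in the
development process) so that training is fully deterministic under a fixed
seed and thread count — "deterministic" here means reproducible on the
same hardware class, not bit-identical across BLAS implementations.

At inference no sampling is performed: the subject's shared code is the
precision-weighted (product-of-experts) combination of the per-modality
shared posterior means, and reconstructions decode posterior means. This
makes both deviation metrics deterministic.

# Deviation metrics

Let the holdout controls' shared codes have mean \(\mu_z\) and covariance
\(\Sigma_z\) (ridge-regularised by \(10^{-6}\,\mathrm{tr}(\Sigma_z)/k_s\)),
and their reconstruction residuals have per-feature mean \(\mu_r\) and sd
\(\sigma_r\). For a subject with shared code \(z\) and residual vector
\(r = x - \hat x\):

- **D_ml** \(= \sqrt{(z-\mu_z)^\top \Sigma_z^{-1} (z-\mu_z)}\), the
  Mahalanobis distance of the subject's whole-brain multi-modal latent
  representation from the healthy holdout distribution. Non-negative;
  larger is more abnormal. It uses the shared latents only: the private
  codes carry modality-specific nuisance structure by construction.
- **D_uf** \(_j = (r_j - \mu_{r,j}) / \sigma_{r,j}\), a signed per-region
  z-score. Because residuals are input minus reconstruction, volume or FA
  *loss* relative to the norm appears as negative D_uf and MD *increase*
  as positive D_uf.

Deviations are computed per subject-visit row; aggregation across visits
(baseline vs latest) is a caller-level choice exposed as `visit_policy`.

**Self-referencing correction.** A holdout subject scored against a
reference estimated partly from itself sits systematically closer to that
reference than a new subject does; at \(n = 200\), \(k_s = 10\) the
deflation in \(D_{ml}^2\) is large enough to masquerade as longitudinal
"progression" when baseline (in-reference) visits are compared with
follow-up (out-of-reference) visits. `compute_dml(exclude_self = TRUE)`
therefore scores reference members against a leave-one-subject-out
reference, and the pipeline uses this throughout. Scoring any visit of a
reference subject excludes that subject entirely, so follow-up visits are
not pulled toward the subject's own baseline.

# Outlier and network statistics

A region is an outlier for a subject when D_uf crosses 1.96 in the
disease-expected direction: below −1.96 for T1 and FA, above +1.96 for MD
(strict inequalities; 1.96 is the standard normal 2.5% tail). Outlier maps
are per-region outlier proportions within a stratum (holdout, CDR and MMSE
subgroups). For display, proportions under 0.025 are conventionally
greyed out; this floor never enters any statistic.

Cortical regions are aggregated into the seven Yeo functional networks,
and subcortical structures into medial temporal lobe
(hippocampus/amygdala), thalamus (including ventral diencephalon) and
basal ganglia. The bundled Desikan-Killiany-to-Yeo crosswalk is an
approximate majority-overlap mapping intended for the synthetic analyses;
users with a preferred crosswalk can supply their own two-column file. A
network's rate is the proportion of subjects with at least one flagged
region in the network — each subject counts once however many member
regions are flagged.

Significance comes from group-label permutation: case/control labels are
shuffled `n_perm` times (default 10,000) and the p-value is the
add-one-smoothed proportion of permuted rates that equal or exceed the
observed case rate, \(p = (1 + \#\{\text{null} \ge \text{obs}\}) /
(n_\text{perm} + 1)\). Ties count as exceeding, which is conservative and
avoids \(p = 0\). Per-region permutation p-values reuse the same draws as
the network-level test within a run, for coherence and speed. Because the
statistic is discrete, the null p-values are super-uniform rather than
exactly uniform — the test's size is at or slightly below nominal, which
the test suite checks directly. FDR control is Benjamini–Hochberg.

Remaining inference: Pearson correlations between deviations and
age-adjusted CSF biomarkers (p-tau, t-tau, abeta42, p-tau/abeta42) and
cognition, with age coefficients learnt on the super-healthy controls only
and pairwise-complete deletion (the n used is always reported); Bonferroni
threshold \(\alpha/m\) for that six-test family; Cohen's d with pooled
(n − 1) sd between holdout and ApoE ε4 strata, positive d meaning higher
D_uf than controls; Welch t-tests between strata; and paired t-tests on
baseline vs 12-month D_ml. All tests are two-sided. Pooled-sd d (rather
than a Welch-style denominator) is the conventional default; if both
groups have identical values the paired test returns t = 0 by continuity,
while a nonzero constant difference is an error.

# The synthetic cohort generator

Real multi-site imaging-genetics cohorts are access-controlled, so every
stage is validated against a generator whose ground truth is known.
Features arise from `k_shared` (default 6) Gaussian factors shared across
modalities plus `k_private` (default 2) per-modality factors, a smooth age
effect (linear drift plus a logistic acceleration after age ~62, declining
for volumes/FA, rising for MD), linear sex effects, a linear ICV effect on
volumes only, and Gaussian noise (sd 0.6 against a total feature sd of
~1). Cohorts mirror a two-site design: a large healthy training cohort,
and target-site fine-tune/holdout/at-risk cohorts offset by a per-feature
site shift (0.3 control-sd by default). At-risk subjects draw CDR and MMSE
labels (CDR 0/0.5/1 with probabilities 0.64/0.34/0.02; MMSE deficits
Poisson with CDR-dependent rate, matching a mean CDR near 0.19 and MMSE
near 28), which map to a severity scalar
\(s = (2\,\mathrm{CDR} + (30 - \mathrm{MMSE})/10)/9 \in [0, 1]\) — a
simple monotone blend of both stratification axes, anchored at 0 for a
cognitively normal subject. CSF biomarkers are drawn with severity
coupling (p-tau and t-tau rising, abeta42 falling).

Disease shifts act on a default affected set of 20 medial-temporal and
limbic-tract features (hippocampi, amygdalae, entorhinal,
parahippocampal, temporal gyri; fornix/stria terminalis and hippocampal
cingulum FA down / MD up). Each at-risk subject's shift is
`effect_size` × (severity / cohort-mean severity) in control-sd units, so
`effect_size` *is* the cohort-mean shift and shifts grow with severity.
Holdout and at-risk subjects have a second visit 12 months later sharing
the same subject factors; at-risk rows additionally progress by
`progression_rate` control-sd per visit in the affected regions.

Magnitude defaults are calibration choices of this package, not estimates
of any real cohort: `effect_size = 1` gives an early-disease-scale mean
shift, and `progression_rate = 0.75` was fixed at design time, via a
pilot power check of the generator itself, so that a 12-month follow-up
of a few hundred pairs yields a decisively detectable paired-test signal
in the at-risk arm while the holdout arm stays null — the qualitative
pattern this class of models is intended to exhibit. What passing tests
on these cohorts shows is that the pipeline recovers structure it is
pointed at; it does not certify performance on real scanners, real
site effects beyond an additive offset, non-Gaussian biology, or
missing-data patterns, none of which the generator emulates.

# Numerical choices and degenerate inputs

- Latent covariance ridge \(10^{-6}\,\mathrm{tr}/k_s\); a covariance that
  is still not positive definite (e.g. identical holdout rows) is an
  error, as is a holdout smaller than \(k_s + 3\).
- Encoder log-variances are clamped to \([-8, 8]\); non-finite training
  loss aborts with a diagnostic rather than continuing.
- Constant features are excluded (with a warning) at confound fit; a
  rank-deficient confound design is an error.
- An outlier threshold is crossed strictly; a value exactly at ±1.96 is
  not an outlier.
- Weight initialisation, minibatch order and reparameterisation noise all
  derive from explicit seeds; generation, fitting and scoring restore the
  caller's RNG state.

# Problem sizes used in validation

The bundled checks run the full pipeline at deliberately desk-scale sizes
chosen as the package's validation conditions: 500 training controls, 200
fine-tune controls, 200 holdout controls and 500 at-risk subjects with two
visits, 30-epoch pretraining and 10-epoch fine-tuning, repeated over 50
seeds for the longitudinal analysis; 2,000-permutation tests over 400
simulated null datasets for calibration; and a 2,000-subject single-site
cohort for factor-recovery checks. Fidelity improves with more epochs and
subjects; these sizes are the point at which every qualitative property
is stable.

# Known limitations

- The DMVAE trains on CPU-scale matrix algebra; it is not intended for
  cohorts of tens of thousands of subjects with voxel-level features.
- No site harmonisation beyond fine-tuning and per-site confound models
  (ComBat-style adjustment is out of scope).
- The latent deviation uses shared latents only; deviations confined to a
  single modality's private structure surface in D_uf, not D_ml.
- Deviation magnitudes are partially absorbed by the autoencoder when a
  large fraction of features deviate together (the encoder "explains"
  part of the shift); D_uf therefore under-states very widespread
  effects. This is a property of reconstruction-based normative models in
  general, mitigated here by holdout referencing.
- Two-visit longitudinal designs only; no mixed-effects trajectory
  modelling.
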