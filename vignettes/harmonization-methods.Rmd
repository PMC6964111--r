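---
title: "Dual adversarial harmonization of DTI scalar maps: models and methods"
author: "dtigan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual adversarial harmonization of DTI scalar maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dtigan)
```

## The problem

Quantitative diffusion MRI metrics — fractional anisotropy (FA) and mean
diffusivity (MD) — are reproducible only when scanner and protocol are held
fixed. Pooling cohorts across sites introduces systematic measurement
differences ("site effects") that can dwarf the biological effects of
interest, so harmonization is a prerequisite for any multi-site analysis.
dtigan removes site effects from pre-registered scalar maps using unpaired
image-to-image translation, and ships the conventional comparators and the
evaluation statistics needed to judge whether harmonization removed the site
difference *without* removing biology.

All inputs are assumed registered to one template space; the package never
resamples. Array indices are (X, Y, Z) in that space.

## The dual-GAN model

Two U-Net generators translate between the site domains,
$G_A: \text{site 1} \to \text{site 2}$ and $G_B: \text{site 2} \to
\text{site 1}$; two fully convolutional Markovian (patch) critics $D_A$,
$D_B$ judge whether an image looks like a genuine member of the target
domain. Training minimises, for the critics, the Wasserstein objective with
gradient penalty

$$ L_{adv} = \mathbb{E}[D(y)] - \mathbb{E}[D(G(x))]
   - \lambda_{gp}\,\mathbb{E}\big[(\lVert\nabla_{\hat x} D(\hat x)\rVert_2 - 1)^2\big], $$

with $\hat x$ drawn uniformly on the segment between a real and a generated
sample and $\lambda_{gp} = 10$; the generators minimise the negated
adversarial terms plus an L1 cycle-reconstruction loss

$$ L = L_{adv} + \lambda\, L_{recon}, \qquad
   L_{recon} = \lVert x - G_B(G_A(x))\rVert_1 + \lVert y - G_A(G_B(y))\rVert_1, $$

with $\lambda = 20$. The cycle term constrains the unpaired translation to a
one-to-one mapping. The L1 terms are averaged per element, so $\lambda$ is
resolution-independent.

### Architecture

* **Generators** are U-Nets: encoder convolutions of kernel 5 and stride 2
  (5×5×5 in the 3D variant), each followed by LeakyReLU (slope 0.2) and
  batch normalization; mirrored transposed convolutions decode, with encoder
  feature maps concatenated into the matching decoder level (skip
  connections). Depth and width are size-dependent defaults: depth 3 with
  base 16 channels for 64×64 inputs, depth 4 with base 32 for 128×128 —
  the smallest nets that keep a 30×30 critic patch meaningful.
* **Output head.** The final transposed convolution is linear and predicts
  an *additive residual correction* to the input; its weights start at zero,
  so an untrained generator is exactly the identity. This is a declared
  design choice (no output activation is prescribed by the underlying
  method): it makes "no site difference" the natural starting point, keeps
  early training stable, and means a model trained on identical domains has
  nothing to unlearn. Outputs are clipped to the metric range ([0, 1] for
  FA) at inference only, so training gradients are unaffected.
* **Critics** contain no batch normalization. The default 2D layer plan —
  kernels 4/4/4/3, strides 2/2/1/1 — has an analytic receptive field of
  exactly 30×30 per output unit; the 3D plan adds through-plane kernels
  3/3/3/2 at stride 1 for 30×30×8. Any custom plan is checked at build time
  by stride/kernel arithmetic and the build fails if the receptive field is
  not exactly the target; `receptiveField()` also measures it empirically
  by gradient probing. The critic's image score is the mean of its local
  score map.

### Training procedure

Critics are updated first (`criticSteps` times per generator step), then
both generators jointly, using RMSProp throughout. Three choices matter at
desk scale and are the package's own:

* **Position-matched mini-batches.** Because cohorts are registered, a 2D
  training batch draws the *same slice positions* from both sites (with
  independent random subjects). Anatomical variability between slice
  positions is much larger than any plausible site effect; matching removes
  it from the critic's real-versus-fake contrast, leaving the site
  difference as the dominant signal. Slices with white-matter coverage
  below `backgroundSlicePolicy` (1%) never enter batches, and at inference
  out-of-mask voxels are restored from the input.
* **Two-time-scale updates.** The critics' learning rate is
  `criticLrMult` times the generators'. A gradient-penalised critic is
  1-Lipschitz and must track the generators closely; if both move at the
  same speed the generators exploit stale critic directions and drift away
  from the data manifold (we observed exactly this: fake scores exceeding
  real scores with growing cycle loss). Defaults: generator learning rate
  5e-5, multiplier 4; the desk-scale validation runs documented below use
  1e-5 and 100 with `criticSteps = 2` and batch size 8.
* **Gradient-penalty double backpropagation.** The penalty's parameter
  gradient is computed exactly (almost everywhere) by backpropagating
  through the input-gradient chain; for conv + LeakyReLU critics the
  activation pattern is locally constant, so the chain is linear in the
  weights and bias gradients vanish. The implementation is verified against
  finite differences in the test suite.

Training is fully reproducible from the seed on a fixed BLAS; the loss
history (adversarial estimates, gradient penalties, reconstruction, total)
is recorded per generator update, and non-finite losses abort with the
update index.

`epochs = 300` is the default budget for full-scale runs; desk-scale
runs instead cap `maxGeneratorUpdates` (400 in the validation suite). With
more than two sites, one site is the reference and each other site is
trained pairwise against it.

## Comparator methods

* **Global-wise scaling**: one factor, the ratio of reference to target
  cohort means over the white-matter mask; exact equalization of whole-mask
  means, none of the spatial structure.
* **Voxel-wise scaling**: the same ratio per voxel; equalizes per-voxel
  group means exactly on the fitting subjects. Masked voxels with zero
  target mean pass through with factor 1 and are reported as degenerate.
* **ComBat** (voxel-level location/scale model): fitted in-package in a
  *reference-anchored* parameterisation — baseline $\alpha(v)$, covariate
  coefficients $\beta(v)$ (age, sex) and residual scale $\sigma(v)$ come
  from the reference cohort; other sites' standardized residuals give
  additive $\gamma_i(v)$ and multiplicative $\delta_i(v)$ batch parameters,
  optionally shrunk by parametric empirical Bayes (iterative updates,
  tolerance 1e-4, max 100 iterations). The reference site has
  $\gamma = 0, \delta = 1$ by construction, so "harmonize" always means
  "map onto the reference", the same convention the other methods use, and
  a model fitted on training folds can transform unseen subjects of any
  fitted site. EB can be disabled for exact-recovery analyses. The
  in-package implementation exists because fit-on-train/apply-on-test and
  an EB-off mode are required here; the test suite cross-checks it against
  the standard reference implementation and against per-voxel least-squares
  oracles. Zero-variance voxels are excluded, passed through, and listed.

All fitted models map the **target** site onto the **reference** site;
direction is stored in the model, never inferred.

## The synthetic phantom generator

No public neonatal data exist for this problem, so validation runs on
phantoms whose ground truth is known by construction:

* **Template** (`makeTemplate`): an ellipsoidal white-matter region with a
  smoothly varying baseline FA around 0.30 and elongated tube "tracts"
  along X with baseline ~0.48 — the statistical structure (coherent
  high-FA tracts inside lower-FA white matter) that tract profiling and
  masking assume, with no anatomical realism.
* **Covariates** (`covariateModel`): postmenstrual ages uniform on 38–44
  weeks and a 2:1 male:female ratio (the demographic shape of a typical
  two-site neonatal cohort: n = 42 with 28:14 at a median of ~41 weeks); a
  positive age slope of 0.01 FA/week and a +0.01 FA female offset inside
  tracts (population Cohen's d ≈ 0.35, within the reported 0.1–0.4 band);
  between-subject and voxel noise of 0.02 FA each. Sex is assigned by
  deterministic proportion (shuffled by seed) so the 28:14 ratio is exact.
* **Site effects** (`makeSiteEffect`): spatially smooth random gain/offset
  fields (seeded white noise, Gaussian-smoothed at `smoothnessMm`,
  normalized to the requested mean), an optional power nonlinearity, and
  site noise; kinds `identity`, `multiplicative`, `additive`, `nonlinear`,
  `mixed`. The transform `clip((g·x + a)^γ + ε)` is applied within tissue
  support only — site effects are measurement effects on tissue, and air
  stays zero. No generative model of real site differences is claimed; the
  field family is a declared simulation choice spanning the premise that
  site effects are spatially heterogeneous and nonlinear.

What passing tests on these phantoms show: the training loop can find and
invert a smooth, moderate (~10%) site effect while preserving planted
covariate effects, and the statistics behave as specified. What they do not
show: performance on real anatomy, realistic artifact structure, or site
effects outside the simulated family.

## Evaluation statistics

Unpaired cohorts have no subject-level ground truth, so two declared
re-interpretations are used and labelled in every report: the
**absolute-error map** is the voxel-wise |difference of group means|, and
**per-subject RMSE** is measured against the reference site's voxel-wise
group mean, summarized by the median. Cohen's d between sexes uses the
pooled (n−1) standard deviation and is computed on per-subject tract-mean
FA. Tract profiles average the metric in 100 equal bins along the tract
axis (the principal axis of the tract voxel coordinates, origin at the
smaller projected coordinate); per-location Pearson correlations against
age are flagged at p < 0.05, with zero-variance locations excluded. The
voxel-wise group test is a declared *stand-in* for skeleton-based TBSS
(which is an external tool): a per-voxel two-sample comparison with either
Benjamini–Hochberg FDR or max-statistic permutation FWER control; its
family-wise error calibration is verified by null simulation in the test
suite. Cross-validated results are combined by union: a voxel is
reported when significant in any fold.

## Cross-validation protocol

`runExperiment()` runs the standard cross-validated protocol: a per-site k-fold split
(default sixfold), per fold fit/train on training subjects of all sites,
harmonize the held-out non-reference subjects, and evaluate them against
the reference *training* group mean, so no held-out subject influences any
parameter it is scored with. Assembled over folds, every subject appears
once, transformed by a model that held it out. Reports carry per-fold and
fold-averaged summaries (fold-averaged maps are arithmetic means of
per-fold maps; the labelling records which).

## Numerical choices and degenerate inputs

FA is clipped to [0, 1] (MD to (0, 4×10⁻³] mm²/s) wherever a transform
could leave the range, with clipped-voxel counts reported. Marginally
out-of-range FA on input (|value| ≤ 1.5) is clipped with a warning;
grosser values are rejected. Degenerate voxels (zero mean for scaling, zero
variance for ComBat) pass through unchanged and are listed on the model.
Batch normalization uses batch statistics during training and running
averages (momentum 0.1) at inference. The Mann–Whitney U test enumerates
exactly for tie-free samples with both n ≤ 20 and uses the
continuity-corrected normal approximation otherwise.

## Problem sizes used in the validation suite

The shipped tests validate the full loop at desk scale: phantom cohorts of
20 subjects/site at 64×64×16 voxels with a mixed site effect shifting the
white-matter mean by ~10%; 2D-axial generators of depth 3 with base 16
channels trained for 400 generator updates (batch 8, critic steps 2,
generator learning rate 1e-5, critic multiplier 100, seed fixed); the
identity check trains the same configuration on two zero-effect cohorts
of 20 subjects/site; ComBat recovery uses 2 sites × 50 subjects at the same
volume size; statistical calibration uses 200 null repetitions. These sizes
are the package's declared validation conditions.

## Known limitations

* Phantoms lack anatomy, motion/eddy artifacts, and realistic site-effect
  physics; results on them bound optimism, not real-data performance.
* The 3D kernel variant is implemented and tested at toy scale; routine 3D
  training is substantially more expensive than slice-wise 2D.
* ComBat here is the parametric-EB variant only (no nonparametric prior,
  no longitudinal extension).
* The group test is not TBSS: no skeleton projection, no TFCE; reports are
  labelled accordingly.
* Harmonization quality is bounded by what a patch critic can sense; a site
  effect orthogonal to local image statistics (e.g., a pure global offset
  indistinguishable within every 30×30 patch) is better handled by the
  scaling/ComBat comparators, which is precisely why they ship together.
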