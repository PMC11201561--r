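---
title: "Adversarial growth prediction of lung nodules: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial growth prediction of lung nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A nodule found on a screening low-dose CT (LDCT) scan is often indeterminate:
its malignancy risk only becomes clear when a follow-up scan, typically a year
later, shows whether it grew. `nodulegp` implements a generative approach to
shortening that wait: a predictor network is trained on pairs of nodule image
patches from consecutive annual scans, and at deployment synthesizes the
expected one-year follow-up appearance ("GP-nodule") of a baseline nodule.
A downstream risk scorer applied to the synthesized patch can then stratify
risk at baseline, and reclassification statistics quantify what that buys
relative to stratifying on the baseline image alone.

The package has four coordinated parts: a synthetic nodule-growth simulator
(`generate_dataset()`), CT patch preparation (`resample_isotropic()`,
`extract_roi()`, `normalize_intensity()`), the adversarial growth predictor
(`train()`, `predict_followup()`), and the evaluation statistics
(`roc_auc()`, `delong_test()`, `nri()`, `nri_z_test()`, ...).

## The adversarial model

The unit image is a 64 x 64 patch covering a 32 mm x 32 mm region of interest
at 0.5 mm/pixel, intensities normalized to [0, 1]. Writing $X$ for a baseline
patch, $X_F$ for its real follow-up and $G_X$ for the predictor's output, the
predictor minimizes the composite synthesis loss

$$L_G = \lambda_1 L_1 + \lambda_2 L_{SSIM} + \lambda_3 L_{LP} + \lambda_4 L_A$$

with

* $L_1$: mean absolute pixel difference between $G_X$ and $X_F$ — pixel-wise
  accuracy;
* $L_{SSIM} = 1 - \mathrm{SSIM}(G_X, X_F)$: structural dissimilarity, an
  11 x 11 Gaussian-window SSIM ($\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$,
  dynamic range 1, valid windows) — structure preservation;
* $L_{LP}$: a learned perceptual distance, the mean squared difference of
  channel-normalized feature maps from a fixed two-stage convolutional
  extractor — high-level appearance;
* $L_A = -\mathbb{E}[D(G_X)]$: the Wasserstein adversarial term, pushing
  predictions toward the critic's notion of a real follow-up patch.

The critic $D$ (five 3 x 3 convolutions, leaky ReLU, 2x mean pooling after
each, global average pooling, linear head; no normalization layers, which
interact badly with a per-sample gradient penalty) outputs one unbounded
score per patch and carries the gradient penalty of the WGAN-GP family on
interpolated images $\hat x = t X_F + (1 - t) G_X$, $t \sim U(0,1)$:

$$L_D = \mathbb{E}[D(G_X)] - \mathbb{E}[D(X_F)]
      + \lambda_D\, \mathbb{E}\big[(\lVert\nabla_{\hat x} D(\hat x)\rVert_2 - 1)^2\big].$$

`discriminator_loss()` also exposes the mirrored sign convention
(`"printed"`), in which the first two expectations appear with opposite
signs; that form appears in some write-ups of the Wasserstein loss but does
not produce an adversarial game against a generator that maximizes
$\mathbb{E}[D(G_X)]$ — both players would then push the same direction — so
training uses the `"standard"` convention above. This was a genuinely open
choice and the switch documents it.

Default weights are $\lambda_1 = 100$, $\lambda_2 = 10$, $\lambda_3 = 1$,
$\lambda_4 = 1$, $\lambda_D = 10$: the usual L1-dominant weighting of
image-to-image translation, with the standard penalty weight. Optimization is
Adam; the conventional full-scale recipe (learning rate $10^{-4}$, five
critic steps per generator step) is the default of `train_config()`.

### Why the predictor head is residual

A baseline and its follow-up share almost everything: the parenchyma
background, the nodule position, attenuation character. The predictor is
therefore parameterized as an identity-plus-delta map: a U-Net style
encoder-decoder (depth 4, base 32 channels by default; instance
normalization; leaky-ReLU encoder, ReLU decoder) whose final 3 x 3
convolution predicts the *change* from baseline to follow-up; the change is
added to the input and clamped to [0, 1]. The head uses a reduced-gain
initialization (0.3 of the He scale), so the untrained network starts near
the identity map and training spends its budget on the part that matters —
where and how much the nodule grows — instead of first learning to
reproduce the background. A sigmoid head was tried and needs far more steps
to become competitive, because it must reconstruct the entire image from
features.

### Gradients

All gradients are derived and implemented in the package (R with C++
im2col/col2im kernels; BLAS matmuls). The gradient penalty requires
differentiating through the critic's own input gradient; because every critic
layer is piecewise linear, this is done exactly (almost everywhere) with a
forward-over-reverse tangent pass: with $u = \nabla_x D(\hat x)$ held fixed,
$\nabla_\theta \lVert g \rVert^2 = 2 \nabla_\theta (g^\top u)$, and
$g^\top u$ is the directional derivative of $D$ along $u$, computable by one
tangent forward pass and one reverse pass over it. Unit tests check every
gradient path against central finite differences, and the penalty against
closed forms for constant and affine-region critics.

## The synthetic simulator

Restricted screening data cannot ship with a package, so the simulator
generates baseline/follow-up pairs with the statistical structure the model
assumes:

* **Geometry**: baseline equivalent diameters 4-30 mm, log-uniform
  (screening nodules are mostly small); nodule centre offset up to 2 mm from
  the patch centre; sigmoid-edged radially smooth profile (edge scale
  0.35 mm).
* **Growth**: malignant nodules grow by volume doubling time (VDT),
  $d(t) = d_0 \cdot 2^{\Delta t / (3\,\mathrm{VDT})}$, with VDT log-uniform
  over 180-1460 days — six months to about four years, the range reported
  for screen-detected cancers. Benign nodules are exactly stable by default
  (a `benign_jitter` switch adds ±10% drift). Diameters are clipped at 30 mm
  with a metadata flag rather than an error, so slow-VDT tails remain usable.
* **Morphology**: margins smooth or spiculated (spiculation probability 0.42
  for malignant vs 0.09 for benign, following published screening-cohort
  margin tables after folding the "other" category out); attenuation solid /
  ground-glass / mixed (0.70/0.21/0.09 malignant, 0.83/0.13/0.04 benign),
  with peak intensities 0.70-0.95, 0.30-0.45, and a two-component
  core-plus-halo profile respectively.
* **Background and noise**: a correlated Gaussian field (smoothed, sd 0.03
  around level 0.15) mimics parenchyma and persists across time points (same
  anatomy); independent additive noise (sd 0.02) is redrawn per time point
  (a new scan). Discriminators trained on flat backgrounds are degenerate,
  hence the correlated field.
* **Determinism**: every nodule's draws come from a stream seeded by a
  splitmix-style hash of (master seed, subject index), so datasets are
  byte-reproducible and nodules are independent.

What the simulator does *not* emulate: real parenchymal anatomy (vessels,
fissures, pleural contact), partial-volume and reconstruction-kernel effects,
inter-scan registration error, attenuation change over time, or any
correlation between growth rate and morphology beyond the class frequencies
above. A model that passes the synthetic end-to-end checks has been shown to
*learn growth from paired images*, not to perform on clinical data.

## Patch preparation

For real volumes (NIfTI input), `resample_isotropic()` applies separable
natural cubic splines along each axis to a 0.5 mm isotropic grid — spline
order 3 is the standard reading of "spline interpolation" with no order
stated — with overshoot clamped to the input intensity range. Coordinates
are 0-based; physical coordinates map to indices by nearest rounding, and a
64 x 64 ROI spans the half-open range $[c-32, c+32)$ so the marked centre
lands at index 32. An ROI crossing the volume edge raises an error; silent
padding would fabricate tissue. Intensity normalization uses a fixed
(-1000, 400) HU lung window by default; whether per-patch or fixed-window
normalization better matches any particular cohort is a data question the
default does not settle.

## Evaluation statistics

* **AUC / DeLong**: AUC is the Mann-Whitney concordance (ties 1/2), with the
  DeLong structural-components variance; paired curves are compared with the
  DeLong test (two-sided). These are delegated to `pROC` behind the package
  interface and cross-checked in tests against an all-pairs oracle and a
  bootstrap variance estimate.
* **Hochberg**: step-up adjusted p-values via `stats::p.adjust`.
* **Stratification**: `stratify_risk()` uses a closed middle interval
  (`score < t_low` low, `t_low <= score <= t_high` medium, else high),
  matching how published threshold rules (e.g. Brock 0.0117/0.10) are
  printed. `match_subgroup_thresholds()` places thresholds at order
  statistics so subgroup sizes match a reference stratification exactly; a
  tied block straddling a boundary is absorbed into the lower group and the
  deviation reported, since no published tie rule exists to follow.
* **NRI**: event NRI = (events escalated − events de-escalated)/n_events;
  nonevent NRI = (nonevents de-escalated − nonevents escalated)/n_nonevents;
  overall NRI is their exact sum (kept in full precision, rounded half-up to
  2 decimals only for presentation). Escalation means any move to a strictly
  higher of the three ordered groups; low-to-high counts once.
* **Z-test**: each component uses the movement-proportion variance
  $SE = \sqrt{(p_{up} + p_{down} - (p_{up} - p_{down})^2)/n}$, the overall
  statistic combines the two independent component variances. Zero-movement
  components have an undefined Z and are reported as `NA`. Published
  analyses of the same tables sometimes use other variance estimators
  (details of which are not always stated), so p-values — unlike the NRI
  point values — should not be expected to agree across software.
* **Toy risk scorer**: a logistic model over four interpretable patch
  features (apparent diameter by half-maximum profile scan, mean intensity,
  peak intensity, margin spikiness as the dispersion of half-max radii
  across rays). It deliberately stands in for a full image-based risk model
  as the downstream consumer of predicted patches; its absolute AUC is not
  the object of interest — the *comparison* across baseline / predicted /
  real-follow-up inputs is.

## Packaged reference counts

`reference_reclass_tables()` ships the 3 x 3 reclassification counts of a
published 450-subject screening test set (53 cancers, 397 negatives) in
which stratifications by Lung-RADS, the Brock model, and an image-based risk
scorer (on baseline and on follow-up nodules) were reclassified by the same
scorer applied to model-predicted follow-up patches. `reproduce_table3()`
recomputes all NRI components from those counts. One internal inconsistency
in the source is preserved rather than hidden: for the Lung-RADS block the
published counts give event NRI 8/53 = 0.151 and nonevent NRI 94/397 =
0.237, whose exact sum 0.388 rounds to 0.39, while the published overall
value is 0.38; the package reports the value implied by the counts.

## Problem sizes and reproducibility

The package's own end-to-end checks run a smoke-scale profile chosen as the
default of `experiment_config()`: 64 training pairs (14 malignant, 50
benign, matching a roughly 20% positive training fraction), 32 held-out
pairs (8/24), 200 generator steps with 5 critic steps each, batch 8,
learning rate $10^{-3}$, and compact networks (depth-3, base-8 predictor;
base-8 critic; base-8 extractor). These sizes are the package's scaled
study conditions: large enough for the L1 term to fall and for predicted
malignant follow-ups to overtake the baseline in SSIM against the real
follow-up, small enough to run routinely. `full_scale = TRUE` switches to a
776/450-pair synthetic cohort with the full-size networks and the
conventional $10^{-4}$ learning rate.

Every stage derives its random stream from one master seed through an
integer hash (`derive_seed()`); experiment artifacts are stamped with a
configuration fingerprint (`config_hash()`); rerunning a configuration
reproduces every reported number exactly.

## Known limitations

* 2D, single-nodule, one-year horizon; no 3D context and no multi-interval
  forecasting.
* The perceptual extractor is a fixed randomly-initialized network, not a
  pretrained classifier: random deep features are a serviceable perceptual
  metric and keep the package self-contained, but a pretrained extractor
  would likely sharpen the perceptual term.
* The gradient penalty's parameter gradient ignores the (measure-zero)
  activation-boundary terms, as all piecewise-linear autodiff does.
* Synthetic validation shows the mechanism works; it says nothing about
  clinical performance (see the simulator's non-goals above).
* DICOM series input is not supported; convert to NIfTI first.
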