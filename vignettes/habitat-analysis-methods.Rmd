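---
title: "Tumor-habitat MRI analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-habitat MRI analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitatdx)
```

## The problem

Atypical glioblastoma (GBM) — GBM presenting with minimal or no visible
necrosis — and primary CNS lymphoma (PCNSL) can look very similar on
conventional MRI, yet their treatments differ fundamentally. `habitatdx`
implements a quantitative differential-diagnosis pipeline built on three
ideas:

1. **Tumor habitats.** Voxels inside the enhancing tumor are clustered in
   the joint (T1-CE, ADC) feature space. With three clusters the
   composition is interpretable as a high-enhancement cellular habitat
   (high T1-CE, low ADC), a low-enhancement cellular habitat (low T1-CE,
   low ADC), and a nonviable-tissue habitat (low T1-CE, high ADC). The
   voxel fractions f1, f2, f3 summarize intratumoral heterogeneity.
2. **Peritumoral edema.** The edema index
   EI = (tumor voxels + edema voxels) / tumor voxels measures edema volume
   relative to tumor volume; PCNSL, with its more extensive blood-brain
   barrier disruption, tends to higher EI.
3. **Relative ADC.** Tumor ADC statistics are normalized by the mean ADC of
   a normal-appearing reference region, giving rADCmean/max/min and
   rADCdif = rADCmax − rADCmin.

These features feed an AIC-selected logistic model (nomogram, calibration,
decision-curve analysis). A companion module quantifies vasculogenic
mimicry (VM) — tumor-cell-lined, CD34-negative/PAS-positive vessel-like
channels — from box-count sheets and regresses habitat fractions on the VM
measures, probing the histological mechanism behind the imaging phenotype.

Because the underlying patient data are not public, the package ships a
synthetic cohort and phantom generator with known ground truth; every
pipeline stage is tested against that ground truth.

## Preprocessing

Volumes are resampled to a common grid (default 1 × 1 × 3 mm) with
trilinear interpolation for intensities and nearest-neighbour for masks
(midpoint ties resolve toward the background-favouring smaller value).
Resampling preserves the physical extent under a voxel-centre convention
and is idempotent at a fixed spacing.

T1-CE intensities are then mapped to 0–255 with a **gradient-anchored
window**: the 3-D gradient magnitude is computed by central differences
within the body mask; voxels whose gradient magnitude exceeds its
within-mask mean are treated as tissue edges; the mean μ and standard
deviation σ of the *original* intensities over those edge voxels define a
window [μ − 3σ, μ + 3σ] mapped linearly to [0, 255] and clipped. Anchoring
the window at high-gradient voxels makes the mapping invariant to positive
affine rescalings of the input (the edge set and the window transform
together), which is the property a scanner-independent normalization
needs. Only a one-sentence description of the original gradient-based
windowing exists, so this concrete rule is a documented design choice of
this package, not a claimed reconstruction. A constant image has no
window and is rejected.

ADC maps are never intensity-normalized: their values carry physical units
(10⁻⁶ mm²/s) and enter the analysis only through ratios or within-tumor
standardization.

## Habitat segmentation

K-means (Lloyd's algorithm) runs per patient on the tumor voxels' 2-D
feature vectors. Choices that matter:

* **Feature scaling.** Both channels are standardized to zero mean and unit
  variance *within the tumor* before clustering. Raw ADC values are three
  orders of magnitude larger than 0–255 T1-CE values and would otherwise
  dominate the distance metric. Per-tumor standardization also matches the
  "relatively high/low" within-tumor semantics of the habitat definitions.
* **Initialization and determinism.** k-means++ seeding, 10 restarts by
  default, best within-cluster SSE wins; everything is reproducible from a
  recorded seed. Nearest-centroid ties break toward the lowest cluster
  index; an emptied cluster is re-seeded at the point farthest from its
  assigned centroid.
* **Per-patient clustering.** Whether the original analysis pooled voxels
  across patients is not stated; per-patient clustering is the default
  here because the habitat definitions are relative to each tumor's own
  intensity distribution.
* **Habitat naming.** After clustering, the cluster with the maximal ADC
  centroid becomes habitat 3; of the remaining two, the higher-T1-CE
  centroid becomes habitat 1, the other habitat 2. The fourth logical
  combination (high enhancement, high ADC) was not observed in the study
  population; if it ever arises the same rule is applied and a warning is
  recorded. Relabeling is a pure permutation — the voxel partition never
  changes.

The implementation is validated against an exhaustive-enumeration oracle
(all label assignments on instances of ≤ 8 voxels) and against noiseless
phantoms, where recovered fractions must equal the generative ones exactly.

## Imaging metrics

* **EI** uses voxel counts on the resampled grid; it depends on masks only.
* **rADC** statistics divide tumor ADC statistics by the mean ADC over a
  user-supplied reference mask. The reference tissue for the original
  ratios is not specified; contralateral normal-appearing white matter is
  the conventional choice and is what the generator emulates (mean
  850 × 10⁻⁶ mm²/s). By default the top and bottom 0.5% of tumor ADC
  voxels are excluded before taking the extrema (single-voxel extrema are
  acquisition-noise dominated); the trim is configurable and the mean is
  never trimmed.
* **Tumor diameter** is the 3-D Feret diameter: the maximal pairwise
  distance between tumor voxel centres in physical coordinates, computed
  on per-line extreme voxels so the pairwise scan stays tractable. A
  single-voxel tumor has diameter 0.

## Diagnostic model

The cohort is split 7:3 (training size ⌈0.7 n⌉, stratified by diagnosis,
largest-remainder apportionment across classes — 125 patients give 88/37).
PCNSL is coded 1. Candidates significant in univariable logistic screening
(Wald p < 0.05) enter backward elimination: at each step the term whose
removal most decreases the AIC is dropped, ties broken by the larger Wald
p, until no removal helps. Exactly collinear candidates (the synthetic
rADCdif is by construction rADCmax − rADCmin) are dropped before
elimination starts. The final model reports B, SE, OR = exp(B) with Wald
95% CIs, per-term tolerance and VIF = 1/tolerance.

The **nomogram** assigns predictor j at value x the points
100·|B_j|·(x − ref_j)/S with S = max_j |B_j|·range_j and the reference at
the lowest-risk end of the display range, so the widest-effect predictor
spans exactly 0–100 points; total points map back through the
reconstructed linear predictor, making the nomogram probability identical
to the model probability (tested to 10⁻⁶).

**Calibration** combines the Hosmer–Lemeshow deciles-of-risk test
(χ² = Σ (O − E)²/(E(1 − E/n_g)), df = bins − 2; tied predicted
probabilities are kept in one bin, which can reduce the df) with Harrell's
optimism bootstrap for the calibration slope and intercept: refit on each
resample, evaluate on the original data, subtract the mean optimism from
the apparent values (apparent slope is 1 by the logistic score equations).
Resamples that collapse to a single outcome class are skipped and counted.
Note that the df = bins − 2 reference applies to *fitted* probabilities;
a simulation that feeds the true generative probabilities to the test is
calibrated against χ²(bins) instead, so the package's null-rate check
refits the model, as the test's sampling theory requires.

**Decision-curve analysis** reports the net benefit
NB(p_t) = TP/n − (FP/n)·p_t/(1 − p_t) of treating patients with predicted
probability ≥ p_t, alongside treat-all and treat-none policies.

## VM quantification

Slides carry ten counting boxes of 550 × 500 μm (0.275 mm²). Discrete-VM
and endothelial-vessel densities are mean counts per box divided by the
box area; counts from the three observers are averaged per box before the
density step. Continuous-VM positivity is reported per patient as the
fraction of the ten areas flagged positive (a per-patient binary "any area
positive" variant is also returned, since the original group-level
positivity rates do not specify the unit).

The habitat–vasculature link is ordinary least squares of one habitat
fraction on the three VM measures, reporting standardized β (z-scored
response and predictors; t statistics equal the unstandardized ones),
adjusted R², the overall F, and the Durbin–Watson statistic
Σ(eᵢ−eᵢ₋₁)²/Σeᵢ² in input order.

## The synthetic generator

`default_config()` fixes the study conditions. Class-conditional
distributions are calibrated to the published cohort table for 61 atypical
GBM and 64 PCNSL patients:

* **Habitat fractions** are Dirichlet with means (0.395, 0.525, 0.080) for
  GBM and (0.543, 0.415, 0.042) for PCNSL; the concentrations (10.85 and
  6.93) reproduce the reported habitat-1 SDs (14.2% and 17.7%). A
  Dirichlet cannot match all three reported SDs simultaneously; habitat 1
  was chosen as the anchor because it is the headline discriminator.
* **EI** is modeled as 1 + lognormal so EI ≥ 1 holds by construction and
  the configured medians (2.008, 3.445) are exact medians of the
  transform; log-SDs (1.39, 0.95) come from the reported quartiles.
* **rADCmean** is lognormal with medians 1.201 and 0.968; per-patient
  habitat ADC means are a fixed shape (800, 900, 1800) × a patient scale
  chosen so the habitat mixture reproduces that patient's rADCmean over
  the reference ADC exactly. rADCmax/min then follow from the habitat
  means present.
* **Demographics** (age, diameter, sex, headache, midline) use the
  reported normal/lognormal/Bernoulli summaries.
* **VM couplings** are linear in (f1, f2, f3) and class with Gaussian
  noise truncated at zero: discrete-VM density rises with f1 and falls
  with f2 (group medians ≈ 1.6 vs 9.1 vessels/mm²); endothelial density
  rises with f1 with a negative class offset (group means 24.3 vs 20.4);
  continuous-VM positivity falls with f3 on the logit scale (group rates
  10% vs 30%, solved numerically to account for the spread of f3). The
  coupling magnitudes were fixed once so that the n = 19 subgroup
  regressions produce t statistics of the same order as the reported
  ones; this makes sign recovery a meaningful, reproducible property.

Phantoms realize a patient's latent values as a spherical tumor whose
voxels are partitioned into habitats by largest-remainder rounding
(concentric shells by default — habitat 1 rim, habitat 2 middle,
habitat 3 core — with a "speckled" random layout for stress-testing,
since the source describes composition, not geometry), an edema shell of
(EI − 1) × tumor volume voxels grown outward, and a cuboid reference
region whose mean ADC is exact. Habitat ADC means are re-anchored to the
*realized* voxel counts so a noiseless phantom passed through the full
pipeline returns f, EI and all rADC statistics exactly — the package's
strongest end-to-end identity.

The T1-CE background is a smooth sinusoidal texture (base 80, amplitude
50) standing in for grey/white/CSF contrast. This matters: a flat noisy
background would dominate the mean-gradient edge set, collapse the
normalization window onto the background intensity and clip distinct
habitats to a common value. Structured tissue intensity is precisely the
premise of a gradient-anchored window, so the phantom must provide it.

What the generator does **not** emulate: real anatomy (skull, ventricles,
tissue boundaries), pulse-sequence physics, bias fields, partial-volume
effects, motion, registration error, or spatially correlated noise.
Passing tests therefore demonstrate the correctness and internal
consistency of the computations under controlled conditions — not
clinical performance on real data.

## Problem sizes and numerical choices

Test and acceptance runs use sizes chosen to give stable Monte-Carlo
estimates at desk scale: 20 phantoms (≈ 40 × 40 × 20 grids at 1 × 1 × 3 mm)
for recovery checks; 100 seeded runs at n = 500 for selection recovery;
500 runs at n = 5000 for the Hosmer–Lemeshow null rate; 200 runs at the
published subgroup size n = 19 for VM sign recovery; 10⁴ patients for
generator calibration; 50 seeds at the published cohort size n = 125 for
the training-AUC coverage check. K-means convergence is assignment
stability (cap 100 iterations); logistic fits use IRLS with tolerance
10⁻⁸ and 100 iterations; coefficients with |B| > 15 on standardized-scale
predictors trigger a separation warning. Exact enumeration backs the
Mann-Whitney test up to combined n = 12 and the signed-rank test up to 15
nonzero pairs; beyond that the continuity-corrected normal approximations
with tie correction take over (agreeing with the exact tails to ≤ 0.01 and
0.02 at the cutovers).

## Known limitations

* The gradient-normalization window is one defensible reading of a
  one-sentence description; other windowing rules would change absolute
  0–255 values (but not the within-tumor clustering, which standardizes
  per tumor).
* The rADC reference region must be supplied; the package does not
  segment normal-appearing white matter.
* Habitat counts of zero produce phantoms with fewer than three distinct
  signatures, on which k = 3 clustering correctly refuses to run; real
  tumors with a truly absent habitat would need k selection, which is out
  of scope (k is a parameter, default 3).
* The VM module implements counting arithmetic and regression only;
  vessel detection on slide images is manual upstream work.
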