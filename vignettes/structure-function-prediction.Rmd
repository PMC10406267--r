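---
title: "Predicting individual task-activation maps from structural imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting individual task-activation maps from structural imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structofunc)
```

## The scientific question

Task fMRI maps where a person's brain activates during a task, but individual
z-maps are noisy and unreliable, which limits their clinical use (e.g.
presurgical mapping). An attractive alternative is to *predict* a subject's
activation maps from structural imaging alone — T1w/T2w anatomy plus diffusion
microstructure — which is faster to acquire and immune to task-performance and
neurovascular confounds. The scientific bar is not predicting the group-average
map (that needs no subject data at all) but predicting the *individual
deviations* from it: a prediction is only useful if a subject's predicted map
resembles their own actual map more than it resembles other people's maps.

`structofunc` implements that full analysis as a reusable, testable pipeline:

1. a synthetic cohort generator with a *planted* structure-to-function signal,
   so every downstream component can be validated without any data download;
2. per-shell diffusion tensor modelling producing MD and directionally-encoded
   (RGB) FA channels;
3. a residual 3D U-Net regressing activation volumes from the stacked
   structural channels, trained with a domain-weighted MSE loss;
4. permutation and per-vertex linear baselines;
5. an evaluation suite: prediction-vs-actual correlation matrices,
   Kolmogorov-Smirnov diagonal tests, lateralization-index regressions,
   ICC(3,1) test-retest reliability, and Gaussian + two-gamma mixture
   thresholding of z-maps.

## The synthetic cohort: what is emulated, and what is not

Real studies use cohorts of co-registered T1w/T2w/DWI volumes and task z-maps.
The generator emulates the *statistical structure* of such data on a small
grid (default $24^3$ voxels at 2 mm), not its visual realism:

* **Anatomy.** The brain is an ellipsoid with soft (logistic) tissue
  boundaries: subcortical core, white matter shell, cortex. Each subject
  carries a latent anatomy vector $\theta \sim N(0, I)$ (default length 6)
  that radially deforms the *internal* tissue boundaries through a fixed basis
  of low-order spherical-harmonic-like angular functions (amplitude 0.12,
  i.e. roughly one voxel of boundary displacement per unit $\theta$). The
  outer brain boundary is deliberately $\theta$-independent: the whole-brain
  mask is identical across subjects, while cortex and subcortical shapes are
  individual — this plants the "folding patterns carry the individual
  information" structure that the ablation arms probe (a cortex-mask model can
  identify subjects; a brain-mask model cannot).
* **Contrasts.** t1 and t2 are distinct affine combinations of the soft
  tissue memberships; the soft boundaries make sub-voxel deformations visible
  at coarse grids. $\theta = 0$ reproduces the population template exactly.
* **Microstructure.** White-matter voxels get prolate tensors along a
  circumferential template tract direction with axial diffusivity
  $\lambda_1 = (1.5 + 0.4\tanh\theta_1)\times 10^{-3}\,mm^2/s$
  (gray matter near-isotropic at $0.8\times10^{-3}$), so the diffusion
  channels carry genuine microstructural information about $\theta$.
  The deformation and diffusivity amplitudes are free design parameters of
  the generator; they were fixed during design, by pilot calibration, at
  values that make the planted signal learnable by a small CNN at desk-scale
  grids and cohort sizes, and are not revisited by any test.
* **Function.** Each activation map $t$ has a fixed smooth group template
  $G_t$ (one dominant focus plus secondary foci, mirror-symmetrized),
  $K = 3$ smooth nonnegative weight fields $w_{t,k}$, and an antisymmetric
  lateralization field $h_t$ (positive left, negative right). A subject's
  session map is
  $$A_{s,t}(v) = G_t(v) + \beta \sum_{k=1}^{K} w_{t,k}(v)\, f_k(\theta_s)
  + L_s h_t(v) + \varepsilon, \qquad
  \varepsilon \sim N(0, \sigma_\varepsilon^2),$$
  where the readouts
  $f_1 = \tanh\theta_1 + \tfrac12\tanh\theta_2\tanh\theta_3$,
  $f_2 = \tanh\theta_2 - \tfrac12\tanh\theta_1\tanh\theta_3$,
  $f_3 = \tanh\theta_3 + \tfrac12\tanh\theta_1\tanh\theta_2$ are bounded,
  Lipschitz, and deliberately nonlinear so that a per-vertex linear model
  cannot represent the mapping exactly while a CNN can. The fingerprint is
  multi-dimensional on purpose: with a single scalar readout, subjects whose
  readout happens to fall near zero are intrinsically unidentifiable, which
  caps the identifiability statistics at small cohort sizes no matter how
  good the predictions are; three components make near-zero fingerprints
  rare, mirroring the many independent ways real individuals deviate from a
  group template. The *same* $\theta$ drives anatomy, microstructure and
  function, so structure genuinely predicts function; the lateralization
  coefficient $L_s \sim N(0, \sigma_L^2)$ is independent of $\theta$ and
  therefore structurally unpredictable by design — it exercises the
  lateralization statistics, not the CNN.
* **Sessions and alignment.** A retest session redraws only
  $\varepsilon$. Vertex correspondence error from surface registration is
  emulated by Gaussian jitter of the per-subject vertex sampling loci;
  jitter 0 is perfect alignment. DWI noise is additive Gaussian (a documented
  simplification of Rician noise that keeps parameter-recovery oracles
  closed-form), default 0.

What the generator does **not** emulate: realistic cortical geometry or
topology (the surface template is a point set with exact left-right homologue
pairs, no mesh), BOLD time series (z-like maps are generated directly),
scanner artifacts, and registration failure modes beyond locus jitter.
Passing tests on this cohort therefore demonstrates the *statistical
machinery* end to end — not performance on real scans.

## Diffusion tensor features

Tensors are fitted per b-shell (default shells 1000/2000/3000 s/mm², six
icosahedral directions each — the exactly determined design — plus one b0
shared by all shell fits) by ordinary least squares on the log signal.
Eigenvalues are sorted descending and clamped at zero (clamp count recorded);
MD is their mean and FA the usual normalized dispersion. "Directional FA" is
the RGB-FA encoding — FA times the absolute components of the principal
eigenvector — giving 3 channels per shell; with MD this yields the 12
diffusion channels of the full 14-channel input stack (t1, t2, then per shell
MD/FAx/FAy/FAz). Voxels with any nonpositive signal are flagged and zeroed.
Input channels are z-scored over brain voxels (training stability); binary
mask channels for the ablation arms are passed through unnormalized.

## The U-Net and its training

The regressor is a pre-activation residual 3D U-Net: `depth` encoder layers
(default 3 at desk scale; 5 at full scale) of two residual blocks each
(group norm → ReLU → 3×3×3 conv, twice, identity skip with a 1×1×1 projection
where channel counts change), whole-channel dropout (rate 0.2) between the
two blocks of the first layer only, stride-2 convolutions (doubling channels)
between layers, and a mirrored decoder whose layers consume the trilinearly
upsampled previous output (1×1×1-convolved to halve channels) concatenated
with the same-depth encoder output. A final group norm and 1×1×1 convolution
produce one channel per activation map, with no output nonlinearity (z-score
regression). Choices left open by the architecture family and fixed here:
trilinear upsampling + 1×1×1 convolution rather than transposed convolution;
preferred group-norm group count 8, with each normalization using the largest
divisor of its channel count not exceeding that (so e.g. the 14-channel input
layer uses 7 groups); normalization (without ReLU) before the output
convolution; fan-in-scaled Gaussian initialization; all 3×3×3 convolutions
pad by 1.

Because no deep-learning framework is available to R in this toolchain, the
network is implemented directly: im2col-based 3D convolution and trilinear
resampling in C++ (RcppArmadillo, BLAS matrix products), normalization,
dropout, Adam and the full backward pass in R. The backward pass is verified
against central-difference numerical gradients in the test suite.

Training uses Adam (initial learning rate $10^{-3}$; desk-scale experiments
use $2\times10^{-3}$), batch size 1 volume, and the domain-weighted MSE loss:
map $m$ in domain $d$ receives weight $1/(n_{domains}\, n_{maps\in d})$, so
every *domain* — not every map — has equal influence. Augmentation draws one
scale factor per sample from Uniform(0.9, 1.1) applied to inputs *and*
targets (a shared factor preserves the structure-function relationship;
independent factors would corrupt it) and adds white noise (sd 0.05) to
inputs only. The learning rate halves when validation loss has not improved
(relative decrease $>10^{-6}$) for 20 consecutive epochs; training stops
after 50 such epochs; by default the best-validation weights are returned.
Train and validation subject ids must be disjoint (the id-level emulation of
the family-structure exclusions used with real cohorts).

One caveat matters at desk scale: with a validation split of only a few
subjects, the validation MSE is dominated by the irreducible activation
noise, and best-validation selection reliably freezes on an early lucky dip
while held-out identifiability keeps improving for tens of epochs
(we verified this by comparing checkpoints directly; enlarging the
validation split or accelerating the LR decay does not recover it).
`train_config(checkpoint = "final")` therefore trains for a fixed epoch
budget and returns the final weights; the desk-scale reference experiments
use it. At realistic cohort sizes the default best-validation rule is the
right one.

Baselines: (1) a CNN trained on derangement-permuted input/target pairings —
it can learn the group template but no individual mapping, so its
self-vs-other delta is centered at zero; (2) an independent OLS regression
with intercept per (vertex, map) on the feature channels sampled at the
template vertices (rank-deficient vertices fall back to the minimum-norm
solution and are flagged). The linear baseline's feature set is configurable
because the per-vertex OLS needs more training subjects than features + 1;
desk-scale experiments use the two anatomical channels.

## Evaluation statistics

Predicted and actual maps are sampled at the shared template vertices
(trilinear interpolation at each subject's — possibly jittered — loci) and
compared by Pearson correlation: $C_{ij}$ correlates subject $i$'s
*predicted* map with subject $j$'s *actual* map. Individual-level prediction
shows as diagonal dominance: mean(diag) − mean(off-diag) is the
self-vs-other delta. Significance uses a two-sample Kolmogorov-Smirnov test
between diagonal and off-diagonal elements, with the asymptotic Kolmogorov
p-value (Stephens' small-sample correction, effective
$n = n_1 n_2/(n_1+n_2)$); per-map tests are Bonferroni-corrected. Row/column
(double-)centering of the matrix is available to remove mean-correlation
differences between subjects.

At desk scale the all-maps matrix has as few as 6-7 diagonal entries, so the
KS test is underpowered no matter how good the predictions are. The suite
therefore also reports a pooled per-map variant: each map's correlation
matrix is z-scored against its own off-diagonal mean and sd (the pooled
analogue of row/column normalization — it removes between-map correlation
levels), then the diagonal and off-diagonal samples are pooled across maps
before the KS test. Under the null each map's diagonal is distributed like
its off-diagonal, so the standardization preserves exchangeability up to
estimation noise; its type-I behaviour is checked empirically on
$\beta = 0$ cohorts in the acceptance tests (it is in fact conservative
there). The pooled test carries the headline significance in desk-scale
experiments; both statistics are always reported. When retest data are
available the standardized samples can additionally be pooled across
independent acquisition sessions of the same subjects
(`pooled_session_ks()`): the desk-scale reference experiment evaluates its
predictions against four sessions, which multiplies the pooled sample size
fourfold without enlarging the cohort.

Other statistics follow standard forms: the lateralization index is
mean(left) − mean(right) over vertices within 10 mm (Euclidean distance in
template coordinates — the synthetic template has no mesh for geodesics) of
the predicted map's peak on the peak's hemisphere plus their homologues,
using the *same predicted peak* for predicted and actual maps, with the peak
taken as the maximum signed value (activation maps of interest are
positive-dominant; both choices are options); ICC(3,1) is the two-way mixed,
consistency, single-measurement form $(BMS - EMS)/(BMS + EMS)$ for $k = 2$
sessions, computed per vertex across subjects and averaged per map; partial
correlations residualize both vectors on an intercept plus covariate by OLS.
Deterministic models predict identically from identical structural data, so
predicted-map ICC is 1 by construction wherever between-subject variance is
positive — the synthetic counterpart of the empirical finding that predicted
maps are far more reliable than the measured ones.

The Gaussian + two-gamma mixture for z-map thresholding is fitted by EM:
a central Gaussian plus gamma components supported on $z>0$ and $-z>0$
(responsibilities are zero on the wrong-sign side; gamma M-steps use weighted
maximum likelihood with a Newton update on the shape). The gamma means are
constrained to at least 2.5 null standard deviations: the gamma components
represent genuinely activated voxels, and without the constraint the EM
solution for near-null data drifts to a local optimum where the gammas model
the Gaussian's own tails (the boundary M-step maximizes the constrained
likelihood, so monotonicity is preserved). Initialization:
$\mu = 0$, $\sigma$ = sd of the central 80% of the data, gammas
moment-matched to the tails beyond one sd, weights (0.8, 0.1, 0.1);
convergence at relative log-likelihood change $<10^{-8}$ or 500 iterations
(the log-likelihood is non-decreasing by construction and asserted in
tests). Display thresholds are the medians of the two gamma components.
All-one-sign data degenerate to a flagged two-component fit.

## Desk-scale problem sizes

The reference experiments in the tests and the acceptance script use: cohorts
of 20 subjects on $24^3$ grids (split 12 train / 2 validation / 6 test),
$\beta = 1$, $\sigma_\varepsilon = 0.5$, 240 template vertices, a depth-3,
base-8 U-Net on a $20^3$ feature stack, and a fixed 100-epoch constant-LR
budget with `checkpoint = "final"`; the ablation-ordering
comparison (cortex vs brain mask) uses $16^3$ grids and shorter training,
paired over seeds. These sizes were chosen once so that a full run completes
on one CPU core in minutes while every statistic remains well-defined;
they are small, so stochastic outcomes (a KS p-value, an ICC) carry
Monte-Carlo noise that the tests absorb with seed-fixed conditions rather
than tighter tolerances.

## Known limitations

* The synthetic anatomy is an ellipsoid phantom; none of the results here
  transfer claims about real-data performance.
* The lateralization coefficient is structurally unpredictable by design, so
  predicted-vs-actual lateralization regressions on synthetic cohorts test
  the *statistic*, not a planted lateralization-prediction capability.
* Gaussian (not Rician) DWI noise; signals are clamped at zero, which biases
  fits at very low SNR.
* The KS p-value is asymptotic; at very small matrices the exact two-sample
  distribution would differ (all intended uses pool enough elements).
* All desk-scale identifiability inference conditions on a handful of test
  subjects. The session-pooled KS multiplies measurement sessions, not
  subjects, so any cohort-level fluctuation repeats in every session and its
  calibration is conditional on the cohort draw: conservative at the
  reference conditions used in the tests, but not uniformly across cohort
  seeds. Cohort-level uncertainty only genuinely shrinks with more subjects.
* Training is single-threaded and CPU-bound; full-scale configurations
  (depth 5, base 32, $144\times160\times144$ grids, 47 maps) run through the
  same code paths but are not practical without hardware acceleration.
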