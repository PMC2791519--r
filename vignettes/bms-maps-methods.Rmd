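---
title: "Group-level Bayesian model selection maps: model, estimation and design choices"
author: "BMSmaps authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level Bayesian model selection maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BMSmaps)
```

## The inference problem

A group model-selection study provides, for each of $N$ subjects and $K$
candidate models, a log model evidence
$\log p(y_n \mid m_k)$ — in imaging practice a variational free-energy
approximation computed upstream, one whole-brain image per subject and
model. The group-level question is which model best explains the
population's data, and (voxel-wise) where. `BMSmaps` implements the two
standard answers.

**Fixed effects.** If one model is assumed to generate every subject's
data, subjects are independent replications and evidence pools
multiplicatively: the log group Bayes factor is the difference of summed
log evidences, and the posterior model probability under a uniform model
prior is the softmax of the summed log evidences
(`ffxPosterior()`; the per-voxel maximum is subtracted before
exponentiation, a standard stabilisation that changes nothing
mathematically). The two-model special case `posteriorFromBayesFactor()`
maps a Bayes factor $B$ to $B/(1+B)$; $B = 20$ gives $20/21 \approx 0.952$,
the conventional boundary of "strong" evidence.

**Random effects.** Populations are heterogeneous: different subjects may
genuinely use different models. The hierarchical model draws population
model frequencies $r \sim \mathrm{Dirichlet}(\alpha_0)$ and, per subject,
a generating model $m_n \sim \mathrm{Multinomial}(1, r)$. `rfxFit()`
inverts this model by the conjugate variational scheme: with
$\alpha_S = \sum_k \alpha_k$,

$$u_{nk} = \exp\!\big(\log p(y_n|m_k) + \Psi(\alpha_k) - \Psi(\alpha_S)\big),
\qquad g_{nk} = u_{nk} \Big/ \sum_k u_{nk},$$

$$\beta_k = \sum_n g_{nk}, \qquad \alpha = \alpha_0 + \beta,$$

iterated to convergence. Two conservation laws hold at every iteration and
are asserted throughout the test suite: each belief row $g_{n\cdot}$ sums
to one, and $\sum_k \beta_k = N$, hence
$\sum_k \alpha_k = \sum_k \alpha_{0k} + N$. The posterior is summarised by
expected model probabilities $\langle r_k\rangle = \alpha_k / \alpha_S$
(`expectedModelProbs()`) and exceedance probabilities
$\varphi_k = p(r_k > r_j \,\forall j \neq k \mid Y)$
(`exceedanceProbs()`).

Only within-subject evidence *differences* enter either analysis: adding
any constant to all $K$ log evidences of one subject cancels in the FFX
normalisation and in $g_{nk}$. This offset invariance is a property test.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha0` | $[1, \ldots, 1]$ | Dirichlet prior counts: each model "observed" once. Configurable for sensitivity analyses. |
| `tol` | $10^{-4}$ | stop when $\max_k |\Delta\alpha_k|$ falls below this. Since $\sum_k \alpha_k$ is fixed at $\sum\alpha_{0k}+N$, changes in $\alpha$ are bounded by $N$ and this acts as a relative criterion in practice. |
| `maxIter` | 64 | iteration cap; hitting it flags the result not-converged rather than erroring, so one pathological voxel cannot abort a map. |
| `epSamples` | $10^6$ | Monte-Carlo draws for $\varphi$ when $K > 2$ (standard error $\le 5\times10^{-4}$); below $10^4$ a precision warning is issued. |
| `gamma` | 0.75 | display threshold on PPMs/EPMs (strictly greater-than; see below). |
| `fwhmMm` | 0 | Gaussian smoothing FWHM in mm, per axis; $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ converted to voxels via the affine. |

The stopping rule and cap are this package's choices — the variational
scheme itself only prescribes "until convergence" — as is the $10^6$
default for `epSamples`.

## Numerical choices

- **Stabilised assignment update.** The per-subject maximum of
  $\log p(y_n|m_k) + \Psi(\alpha_k) - \Psi(\alpha_S)$ is subtracted inside
  the exponential. This rescales each row of $u$ by a constant and leaves
  $g$ unchanged, but prevents overflow for log-evidence differences in the
  hundreds (tested at $\pm 5000$).
- **Exceedance probabilities.** For $K = 2$,
  $\varphi_1 = p(r_1 > \tfrac12) = 1 - I_{0.5}(\alpha_1, \alpha_2)$ with
  $I$ the regularised incomplete beta function (`stats::pbeta`), so
  $\varphi_1 + \varphi_2 = 1$ exactly and two-model maps are fully
  deterministic. For $K > 2$ the Dirichlet is sampled via normalised
  gamma draws and $\varphi_k$ is the fraction of draws in which $r_k$ is
  strictly largest; exactly tied draws (probability zero under the
  continuous density, representable only through floating point) are
  discarded rather than split. Both routes are cross-checked in the tests:
  closed form against Monte-Carlo for $K=2$, Monte-Carlo against 2-D
  numerical integration over the simplex for $K=3$.
- **Seeding.** Every stochastic operation takes an explicit seed and
  restores the caller's RNG state. Voxel-wise Monte-Carlo uses a seed
  derived deterministically from (base seed, voxel linear index), so map
  results are independent of traversal order and of mask shrinkage — a
  smaller mask never changes values at shared voxels.
- **Degenerate inputs.** $K = 1$ is rejected (nothing to select among);
  non-finite log evidences are rejected naming the offending subject and
  model; at the map level a voxel whose matrix fails validation is marked
  unanalysed (`NA`) and counted in the run metadata instead of aborting.
- **`NA`, not zero.** Unanalysed and sub-threshold voxels are encoded as
  `NA` in maps and written as such, so "not analysed" is distinguishable
  from "probability $\approx$ 0". Thresholding keeps voxels with value
  strictly greater than `gamma`, making the `value == gamma` edge case
  well defined.
- **Log-odds maps.** `toLogOdds()` uses the natural logarithm,
  $\ln(p/(1-p))$, consistent with evidence measured in nats; 0 and 1 map
  to $\mp\infty$.

## Voxel-wise maps

`voxelwiseRfx()`/`voxelwiseFfx()` apply the engines independently at every
in-mask voxel of an `EvidenceVolumeSet`; each voxel starts afresh from
`alpha0`, with no information shared between voxels (spatial priors over
$r$ are out of scope). A one-voxel mask reproduces the direct `rfxFit()`
call exactly, which the tests assert at $10^{-12}$.

Smoothing (`smoothVolumes()`) is applied to the log-evidence volumes
before group analysis, matching standard practice of smoothing
per-subject evidence maps; the common choice in whole-brain work is an
8 mm FWHM kernel, which we read as full width at half maximum. The
convolution is axis-separable with a kernel truncated at $4\sigma$ and
**mask-renormalised**: masked data and mask are convolved separately and
divided, so zero-padding outside the mask (or brain edge) does not drag
edge voxels toward zero. A constant in-mask volume therefore stays exactly
constant — asserted in the tests — and an interior impulse conserves its
mass to $10^{-6}$.

Inputs must be pre-registered on a common grid; affines are required to
agree within $10^{-4}$ elementwise and are passed through to all outputs
unchanged. No resampling is performed.

## What the synthetic generator emulates

`simulateGroupLogev()` draws a group exactly from the random-effects
generative model: assignments $m_n \sim \mathrm{Mult}(1, r_{true})$, the
generating model's log evidence from
$\mathcal{N}(\texttt{effectMean}, \texttt{effectSd})$ and the others from
$\mathcal{N}(0, \texttt{noiseSd})$, so evidence strength and
between-subject heterogeneity are controlled independently. The defaults
(`effectMean = 5`, both sd 0) give every subject a decisive 5-nat log
Bayes factor — the condition used in the parameter-recovery study.
`makeOutlierScenario()` builds the canonical robustness fixture: eleven
subjects at log BF $-1$, one at $+30$, for which FFX follows the outlier
while RFX follows the majority. `simulateEvidenceVolumes()` (defaults:
$8^3$ grid, 3 mm voxels, $3^3$ active cuboid with
$r_{true} = [0.9, 0.1]$ inside and $[0.5, 0.5]$ outside, $N = 12$, 3-nat
effects) wraps this into volumes; a subject's assignment is a per-subject
property shared across the voxels of a compartment, which is what the
hierarchical model asserts, and a per-voxel-independent mode exists purely
as a stress test.

What the generator does *not* emulate: spatially correlated noise,
subject-specific smoothness, partial-volume and registration error, or any
haemodynamics — log evidences are generated directly, never estimated from
time series. Passing tests therefore validate the group-level inference
machinery, not the upstream evidence estimation.

Two properties of these study conditions are worth stating because they
bound what any estimator can achieve. First, with $N = 200$ and
$r_1 = 0.7$ the *realised* model-1 frequency has binomial standard
deviation $\sqrt{0.7 \cdot 0.3 / 200} \approx 0.032$, so even an oracle
that knew every subject's true assignment would land within $0.05$ of
$0.7$ in only $\approx 89\%$ of replicates; the recovery rate the
acceptance script reports sits at that ceiling, and deviations of
$\langle r_1 \rangle$ from $r_{true}$ at this scale reflect sampling of
the group, not estimation error. Second, because volume-scenario
assignments are shared across voxels and the evidence is noiseless, all
background (and all active) voxels of one simulated group cross a
threshold together; detection rates across seeds therefore move in steps
of $1/\texttt{nSeeds}$ rather than smoothly.

## Problem sizes

The shipped tests and the acceptance script run the full map pipeline on
$8^3$ grids with $N = 12$, $K = 2$ (about $10^4$ voxel fits per study),
parameter recovery on 100 groups of $N = 200$, and $10^6$-sample
Monte-Carlo cross-checks; the whole suite completes in about a minute on
one CPU. These sizes were chosen because every assertion is already
sharp at them; the voxel loop is plain R and scales linearly, at roughly
a millisecond per voxel fit, for whole-brain use.

## Known limitations

- No spatial model over $r$: voxels are inferred independently, and map
  smoothness comes only from smoothing the input evidence.
- Exceedance probabilities for $K > 2$ are Monte-Carlo estimates; their
  reproducibility is guaranteed by seeding, not by determinism.
- The FFX branch produces no exceedance maps (the notion is undefined
  without a distribution over frequencies).
- Upstream log-evidence estimation, design specification, preprocessing
  and registration are out of scope; inputs are trusted to be
  co-registered log evidences in nats.
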