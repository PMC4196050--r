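---
title: "One-step blending genomic prediction: models, numerics and the simulated study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-step blending genomic prediction: models, numerics and the simulated study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genomic selection needs a reference population with many reliably
evaluated animals.  Dairy populations without a deep pool of
progeny-tested bulls must build their reference from cows, whose proofs
are far less reliable, and accuracy suffers.  One-step blending attacks
this by letting the de-regressed proofs (DRP) of *non-genotyped*
relatives — above all the dams and paternal half-sisters of the selection
candidates — contribute to the evaluation through a hybrid
pedigree–genomic relationship matrix.  This package implements the full
chain: relationship matrices, deregression, the weighted mixed model, and
validation, plus a population simulator shaped like the cow-reference
design, so every claim can be exercised end to end.

## Model

All methods fit
$$ y = 1\mu + Zg + e, \qquad g \sim N(0,\, K\sigma^2_g), \qquad
   e \sim N(0,\, D\sigma^2_e), $$
with $y$ the DRP of the reference animals and $D$ diagonal with
$d_{ii} = 1/w_i$, $w_i = r^2_i/(1-r^2_i)$, where $r^2_i$ is the
reliability of animal $i$'s DRP.  A record with reliability 0.5 has unit
weight; more reliable records carry proportionally less residual
variance.  The only fixed effect is the overall mean — the DRP are already
adjusted for systematic environment by the national evaluation they came
from.

The three methods differ in $K$:

* **GBLUP**: $K = G$ over genotyped animals only, VanRaden's first method,
  $G = ZZ'/(2\sum_j p_j(1-p_j))$ with allele counts centred by $2p_j$.
  Allele frequencies are computed from the genotyped animals themselves;
  base-population frequencies are unobservable in practice, and centring
  by own frequencies gives $\mathrm{Avg}(\mathrm{diag}(G)) \approx 1$, the
  same scale as pedigree relationships.
* **One-step blending**: $K = H$, the hybrid matrix whose genotyped block
  is exactly $G$ and whose other blocks propagate the genomic information
  along pedigree regressions:
  $H_{11} = A_{11} + A_{12}A_{22}^{-1}(G - A_{22})A_{22}^{-1}A_{21}$,
  $H_{12} = A_{12}A_{22}^{-1}G$, $H_{22} = G$.
* **Adjusted one-step blending**: $G$ is first moment-matched to the
  pedigree scale, $G_a = G\beta + \alpha$, with $(\beta, \alpha)$ solving
  the two linear equations that equate the diagonal and off-diagonal
  averages of $G_a$ with those of $A_{22}$.  The scalar $\alpha$ is added
  to *every* element, diagonal included.

Predictions for animals without records — the validation cohort, or any
non-genotyped animal — fall out of the same equations through their rows
of $K$.

## Deregression

EBV are shrunken posterior means and contain their parents' information;
used directly as pseudo-phenotypes they would both under-disperse and
double-count.  The implemented deregression removes the parent average
(PA) and the shrinkage in one step: with $r^2$ the EBV reliability and
$r^2_{PA} = (r^2_{sire} + r^2_{dam})/4$ (missing parents contribute zero
with zero reliability),
$$ r^2_{own} = \frac{r^2 - r^2_{PA}}{1 - r^2_{PA}}, \qquad
   DRP = PA + \frac{EBV - PA}{r^2_{own}}, $$
and $r^2_{own}$ becomes the DRP reliability.  Animals whose EBV
reliability does not exceed their PA reliability carry no own information
and are excluded (flagged, not an error).  Two properties pin this down:
the DRP of an evaluated animal regresses on its true breeding value with
slope 1 (raw EBV regress with slope $r^2$), and deregression can only
lose reliability ($r^2_{own} \le r^2$).  The exact single-animal variant
(`drp_mode = "direct"`, $DRP = EBV/r^2$) is the same formula with no
parent information; it is the simulator's default so that matrix building
and model fitting can be studied independently of the deregression
choice.  Cohort reliability floors are strict: a cow's DRP must exceed
0.40, a progeny-tested bull's 0.80; records at the floor are excluded.

## Numerics

**REML.** The two variance components are estimated through the variance
ratio $\delta = \sigma^2_e/\sigma^2_g$.  After whitening by $W^{1/2}$
(so the residual covariance becomes $\sigma^2_e I$) the model is rotated
onto an orthonormal basis of error contrasts (the orthogonal complement
of the whitened intercept, built by QR), where the restricted likelihood
depends on the data only through the eigenvalues $\xi_s$ of the projected
kernel and the squared rotated responses.  One symmetric
eigendecomposition then makes every likelihood evaluation O(n), and the
profiled likelihood in $\log\delta$ is maximised by a 49-point grid
bracket on $[-18, 18]$ followed by golden-section refinement to
$10^{-10}$; $\hat\sigma^2_g$ has a closed form given $\delta$.  This is a
re-parameterisation of the average-information REML used by the standard
software for this model class, with the same optimum; at desk scale the
eigendecomposition route is simpler and has no convergence failures away
from boundaries.  A solution at the $\delta$ grid boundary, or a response
with numerically zero contrast variance, is reported with
`converged = FALSE` (and fitting refuses to continue when
$\hat\sigma^2_g$ collapses to zero, since no genetic signal exists).

**Mixed model equations.** With components in hand, the dense symmetric
system
$$ \begin{pmatrix} 1'W1 & 1'WZ \\ Z'W1 & Z'WZ + K^{-1}\lambda \end{pmatrix}
   \begin{pmatrix} \hat\mu \\ \hat g \end{pmatrix} =
   \begin{pmatrix} 1'Wy \\ Z'Wy \end{pmatrix}, \quad
   \lambda = \hat\sigma^2_e/\hat\sigma^2_g, $$
is solved by Cholesky; the $g$-block of the inverse gives
$PEV_i = C^{gg}_{ii}\hat\sigma^2_e$ and the theoretical accuracy
$\sqrt{1 - PEV_i/(K_{ii}\hat\sigma^2_g)}$, clamped to $[0,1]$.  $K^{-1}$
uses a jitter ladder ($0, 10^{-8}, 10^{-6}, 10^{-4}$ added to the
diagonal until Cholesky succeeds), and any jitter used is recorded on the
fit object.  `blend_H()` itself never inverts $G$ — the block formula
needs only $A_{22}^{-1}$ — so no stabilisation of $G$ is applied by
default; an optional `stabilize_G()` ($0.95G + 0.05A_{22}$) exists for
genuinely ill-conditioned cases.  $A_{22}$ is inverted densely; desk-scale
pedigrees (up to roughly $2\times10^4$ animals) do not warrant sparse
machinery.  H rows are ordered non-genotyped block first, then the
genotyped block in G's order, with IDs on the dimnames — callers should
index by ID, never by position.

**Worth knowing about theoretical accuracy.** An animal whose record has
near-perfect reliability does not reach accuracy 1 exactly: the remaining
PEV is the uncertainty in $\hat\mu$, which only vanishes as the rest of
the data pins the mean down.  Conversely an animal with no record and no
relationship to any recorded animal has accuracy exactly 0.

## Validation accuracy

$r_v = r_{\hat g, DRP} / \bar r_{DRP}$, the Pearson correlation between
predictions and validation DRP divided by the mean square root of those
animals' DRP reliabilities.  The denominator corrects the attenuation
caused by noise in the DRP, so $r_v$ estimates the accuracy on the true
breeding-value scale and can exceed 1 when predictions out-correlate what
the DRP reliability nominally allows.  The denominator is averaged over
exactly the animals entering each report row (each subgroup), since it
corrects that row's own numerator.  Reports split validation cows by
whether their dam is genotyped, because that is where one-step blending
can and cannot add information.

## The simulator and what it does (not) emulate

`sim_config()` defaults describe a reduced-scale cow-reference design: 24
genotyped reference sires, 400 genotyped reference cows, 80 genotyped
validation cows (half with non-genotyped dams carrying DRP, half with
genotyped reference-cow dams), 40 non-genotyped dams, 25 non-genotyped
half-sib daughters per sire (600 total), and 2000 unlinked SNPs of which
200 are causal.  Cow reliabilities are drawn uniformly on (0.40, 0.95)
and bull reliabilities on (0.80, 0.95) — the floors are the customary
inclusion thresholds, and nothing in the method depends on the shape of
the reliability distribution.  Founder allele frequencies are uniform on
$(\mathrm{maf}_{\min}, 1-\mathrm{maf}_{\min})$; genotypes descend by
Mendelian gene dropping; SNPs with realized MAF below 0.01 among the
genotyped animals are removed, mirroring the usual chip edit.

True breeding values are sums of QTL allele counts times i.i.d. normal
effects, standardised so the genetic SD is the trait unit.  EBV are
generated *shrunken*, $EBV = r^2(TBV + \epsilon)$ with
$\mathrm{Var}(\epsilon) = (1-r^2)/r^2$: this gives squared correlation
$r^2$ with the true values **and** regression slope $r^2$ on them, as a
posterior mean must, so that deregression has something real to undo.

Deliberate simplifications, and what they mean for interpretation:

* **SNPs are unlinked.**  The estimators consume relationship-matrix
  moments, not LD structure; G behaves like a noisy realisation of
  $A_{22}$, which is exactly the regime the blending arithmetic assumes.
  Nothing here speaks to LD-dependent phenomena (persistence of accuracy
  across generations, within-family deviations from expected
  relationships at causal loci).
* **EBV noise is independent across animals.**  Real evaluations induce
  covariances between relatives' errors — the very thing deregression
  mitigates.  Passing tests therefore show the machinery is right, not
  that deregression fully repairs real-data error covariance.
* **Non-genotyped dams are founders** whose only pedigree tie is to their
  validation-cow daughter.  This isolates the dam-information channel
  cleanly: any one-step gain in the non-genotyped-dam subgroup is
  attributable to the dams' DRP and nothing else.
* **Half-sib daughters have unknown dams**, so within-sire-family
  A-relationships are exactly 0.25, and the half-sisters' information
  reaches a validation cow only through her sire — which is why dropping
  their DRP while keeping highly reliable sire proofs changes little,
  the mechanism behind the dams-only contrast.
* Unknown parents are unrelated founders; no selection, no overlapping
  generations, no genotyping error, single trait.

All randomness flows from one master seed; pedigree, genotype and trait
stages derive separate sub-seeds, and scenario replicates derive
per-replicate seeds, so any stage or replicate is independently
reproducible.

## Design choices where the design was open

* **Comparing GEBV between the original and adjusted one-step fits.**  The
  offset $\alpha$ adds a constant to every element of $K$, which is a
  random-intercept component shared by all animals; between two fits it
  is exchangeable with $\mu$.  GEBV are therefore compared as deviations
  from their mean, and — because a single desk-scale replicate leaves
  visible Monte-Carlo noise in the mixed-model solutions — averaged over
  scenario replicates.  Accuracy comparisons need no such care:
  correlations are location-free.
* **Variance components are re-estimated per method** (and would be per
  trait): each $K$ defines its own model, and sharing components would
  leak one method's scale into another.
* **The moment system** $\{\beta, \alpha\}$ is singular only when
  $\mathrm{Avg}(\mathrm{diag}(G)) = \mathrm{Avg}(\mathrm{offdiag}(G))$, a
  degenerate G with no scale information; this raises an error rather
  than a silent fallback.
* **Reliability floors are strict inequalities** (a cow at exactly 0.40
  is excluded), matching the usual "greater than" reading, and the filter
  is idempotent and never resurrects an excluded record.

## Problem sizes used by the test suite

The shipped tests run the replicated scenario at the default reduced
scale (20 replicates, ~1150 animals each), REML parameter recovery on 20
replicates of 2000 records in half-sib-style families, deregression on
5000 evaluated animals, exact-oracle comparisons (GLS/BLUP closed form,
dense restricted likelihoods, balanced ANOVA estimators) at n ≤ 60, and
matrix identities on random pedigrees up to 200 animals.  These sizes
were chosen so the whole suite exercises every claim in a few minutes on
a laptop while keeping Monte-Carlo error well inside the asserted
tolerances.

## Limitations

Single-trait, single-mean models only; no multi-trait or random-regression
machinery, no APY-style approximations for national-scale data, no
imputation (genotypes must be complete), and no bias/inflation regression
beyond what `plot()` shows.  The simulator's omissions listed above bound
what the replicated comparisons can demonstrate about real populations:
they validate the estimators and reproduce the qualitative mechanism —
non-genotyped dams add accuracy for their daughters, half-sisters mostly
do not when their sires are reliably proven, and the near-identity moment
adjustment changes essentially nothing — not the numerical accuracies of
any particular real population.
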