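---
title: "Scoring and permutation inference for cardiac cell-division defects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and permutation inference for cardiac cell-division defects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartperm)
```

## The scientific setting

The stage-16 *Drosophila melanogaster* embryonic heart tube is built from
repeated bilateral units, the cardiac hemisegments, scored along abdominal
segments A2–A8 (14 hemisegments per embryo). Each wild-type hemisegment
contains four Tinman-expressing cardiac cells (Tin CCs), two Seven-up
cardiac cells (Svp CCs) and two Svp pericardial cells (Svp PCs), produced
by a stereotyped division program: the Tin superprogenitor divides
symmetrically twice (1 → 2 → 4 CCs); the Svp superprogenitor divides
symmetrically once, and each daughter then divides asymmetrically into one
CC and one PC. Because the program is stereotyped, deviations in the cell
counts of a hemisegment are diagnostic of *which* division failed, and
cell-division mutants can be quantified from fixed-embryo counts alone.

`heartperm` implements that quantification: a deterministic decision table
mapping hemisegment counts to defect categories, per-embryo and
per-genotype aggregation, permutation inference on the embryo-level defect
proportions (a two-group comparison and a genetic-interaction synergy
test), and a synthetic cohort generator used to study the operating
characteristics of the tests.

## The classification decision table

With the *svp-lacZ* reporter (assay `svp_lacz`) both Svp CCs and PCs are
visible and three categories are scored per hemisegment:

| signature | call | interpretation |
|---|---|---|
| `tin_cc != 4` | `tin_symmetric` | error in a symmetric Tin division |
| `(svp_cc, svp_pc)` = (1,1) or (3,3) | `svp_earlier` | the earlier symmetric superprogenitor division made 1 or 3 progenitors |
| (1,3) or (3,1) | `svp_asymmetric` | one asymmetric division made two like daughters |
| (2,1) | `svp_asymmetric` | karyokinesis arrest: one enlarged CC nucleus replaces a CC/PC pair |
| (2,2) | no Svp defect | wild type |
| anything else | `unclassified_svp` | outside the enumerated patterns |

Tin and Svp defects are scored independently: one hemisegment can carry
both. Patterns outside the enumerated set (e.g. (2,3), (0,2)) are flagged
`unclassified_svp`, reported separately, excluded from category numerators
but kept in denominators; inventing rules for unobserved patterns would
contaminate the category counts. The enlarged-nucleus flag is advisory
metadata: classification of the karyokinesis pattern rests on the (2,1)
count signature, the only machine-readable signal.

With the anti-Svp antibody (assay `svp_antibody`) the PCs are invisible, so
the two Svp categories collapse into `svp_combined := (svp_cc != 2)`. Every
(1,1), (3,3), (1,3), (3,1) lacZ pattern is combined-visible; the (2,1)
karyokinesis signature is invisible in this mode — the package's tests
assert this correspondence exactly.

## The inference model

The unit of inference is the embryo: hemisegments within one embryo share
a defect propensity, so hemisegment-level count tests (e.g. Fisher's exact
test on pooled counts) overstate the evidence. All tests operate on the
per-embryo defect proportion $Y_j$.

**Two-group comparison.** $Y_j = \beta_0 + \beta_1 I_j + \varepsilon_j$,
with $I_j = 1$ for the test genotype; $\hat\beta_1$ is the group-mean
difference. Genotype labels are permuted among embryos; with $n$ of $N$
permuted statistics meeting the observed one, $p = (n+1)/(N+1)$. When the
number of distinct label arrangements is at most `exhaustive_threshold`
(default $10^5$), all arrangements are enumerated instead and the p-value
is the exact proportion meeting the tie rule (the identity arrangement
counts once).

**Interaction (synergy) test.** For double-heterozygote assays,
$Y_j = \beta_1 I_{p,j} + \beta_2 I_{q,j} + \beta_3 I_{p,j} I_{q,j} +
\varepsilon_j$ is fit **without an intercept** over the three mutant
genotype groups. The model is then saturated, and
$\hat\beta_3 = \bar Y_D - \bar Y_P - \bar Y_Q$: exactly the excess of the
double heterozygote over the additive sum of the two single
heterozygotes, which is the operational definition of synergy. A
`with_intercept = TRUE` variant adds $\beta_0$ and admits control
embryos as $(I_p, I_q) = (0,0)$; without controls that variant is
structurally unidentifiable (four parameters on three groups) and the
function says so. `synergy_call()` declares synergy when
$\hat\beta_3 > 0$ and $p \le \alpha$ (default 0.05); merely additive or
sub-additive outcomes are `"not_synergistic"`.

Because $I_p$ and $I_q$ are nuisance regressors, the permutation scheme
orthogonalizes the interaction regressor first (the Smith procedure):
$g_\perp = g - Z(Z^\top Z)^{-1} Z^\top g$ with $g = I_p I_q$ and
$Z = [I_p, I_q]$, then shuffles the entries of $g_\perp$ across embryos.

### Numerical form of the permuted statistic

For the identity arrangement, the coefficient of $y$ on $g_\perp$ in the
full design $[Z, g_\perp]$ equals $\hat\beta_3$ (Frisch–Waugh). For a
*shuffled* arrangement $g^\ast$ the package deliberately does **not**
refit against the unpermuted $Z$: a shuffled $g^\ast$ is no longer
orthogonal to $Z$, its refit denominator
$g^{\ast\top} M_Z g^\ast < \|g_\perp\|^2$ shrinks, and every permuted
statistic is systematically inflated relative to the observed one — in our
simulations that variant rejected a true null essentially never. Instead
the statistic is computed with the normalization held fixed across
arrangements,

$$ t(g^\ast) = \frac{\langle g^\ast,\, M_Z y\rangle}{\|g_\perp\|^2}, $$

which equals $\hat\beta_3$ exactly for the identity arrangement and makes
observed and permuted statistics members of one family. This is the
standard orthogonalized-regressor randomization statistic.

### Tie handling

Per-embryo proportions from 14 hemisegments are coarse (multiples of
1/14), and permuted statistics tie with the observed one often. The
package counts exceedances with the `geq` rule ($T^\ast \ge T_{obs}$) by
default, the convention under which $P(p \le \alpha) \le \alpha$ is
guaranteed. Counting only strict exceedances — the other common reading of
"the number of estimates which exceed the observed" — discards the tie
mass and is anticonservative on this kind of data: in our null
simulations (15 embryos per group, baseline rate 2%) the strict rule
rejected at 12% instead of 5%. `strict` remains available via
`perm_config(tie_rule = "strict")` for near-continuous responses. Note
that under `strict` the Monte-Carlo estimator $(n+1)/(N+1)$ and the
exhaustive proportion differ by about $1/M$ by construction (the identity
arrangement term), while under `geq` both estimate the same exceedance
probability; oracle-equivalence checks therefore use `geq`.

Tail is `upper` by default (the biological question is *increased*
defects); `two_sided` compares absolute coefficients. The Monte-Carlo
default is $N = 10^4$ permutations — small enough for interactive use,
with ~1% relative reproducibility of small p-values; published values are
typically run at $N = 10^6$.

## The synthetic cohort generator

The generator reproduces the statistical structure the tests assume,
nothing more:

* **Within-embryo correlation** enters on the logit scale: for each
  embryo and category, $u \sim N(0, \sigma^2_{embryo})$ and each
  hemisegment is defective with probability
  $\min\{\text{logit}^{-1}(\text{logit}(p) + u),\ 0.95\}$. The default
  $\sigma_{embryo} = 0.5$ is a modeling choice (no estimate of the
  correlation magnitude is available to calibrate against); it yields
  clearly overdispersed per-embryo proportions, which the test suite
  verifies against the binomial variance.
* **Genotype effects are additive on the probability scale**, so the
  "additive expectation" of an interaction assay — double-het rate equal
  to the sum of the single-het rates — is exactly representable. The
  double heterozygote receives `interaction_effect` on top of baseline
  and main effects; its additive-excess is therefore
  `interaction_effect - baseline` at zero dispersion. Probabilities are
  clipped to $[0, 0.95]$ to keep logits finite; an exactly zero rate is
  honoured exactly when $\sigma_{embryo} = 0$ and otherwise substituted
  by $10^{-6}$ with a warning.
* **Materialisation** writes defects through their diagnostic count
  signatures (Tin defect → `tin_cc` from {3, 5}; earlier → (1,1)/(3,3);
  asymmetric → (1,3)/(3,1)/(2,1) with the enlarged-nucleus flag on the
  karyokinesis pattern), so classification recovers exactly the category
  generated. If both Svp categories fire on one hemisegment, the earlier
  defect takes precedence — an arbitrary but deterministic rule. The
  observable asymmetric rate is therefore
  $m_{asym}(1 - m_{earlier})$; the cohort truth table records
  configured, marginal, and observable rates so that no downstream check
  compares against the wrong estimand. Simulation studies score
  `tin_symmetric` by default, which has no collision bias.

Two nonlinearities matter when interpreting the recorded truth. First,
with $\sigma_{embryo} > 0$ the *marginal* defect rate is the logit-normal
average of the configured rate, computed by numerical integration
(`marginal_defect_rate()`), not the configured rate itself. Second, that
averaging is concave at moderate rates, so a configuration that is exactly
additive on the probability scale is slightly *sub-additive* marginally
(e.g. rates 0.14/0.14/0.28 at $\sigma = 0.5$ give a marginal excess of
−0.011). The simulation harness always reports the marginal excess as the
truth for $\hat\beta_3$, and its calibration scenarios are placed at
single-heterozygote-like baseline rates (~2–6%) where the nonlinearity is
negligible.

What the generator does *not* emulate: spatial structure along the heart
tube, segment-specific rates, correlation between defect categories
within an embryo beyond the shared category-wise random effects,
scoring/imaging error, and missing hemisegments. Passing tests therefore
demonstrate correctness of the scoring rules and the calibration of the
inference machinery under embryo-level correlation — not robustness to
every feature of real confocal data.

## Scenario design in `simulation_study()`

Scenarios are parameterised by `delta`, the synergy excess over the
additive sum: the harness sets
`interaction_effect = baseline + delta`, so `delta = 0` is the additive
configuration in which $H_0: \beta_3 = 0$ holds on the probability scale,
and `delta > 0` is synergy. Two points are worth making explicit:

* An "all rates equal" configuration is **not** a null for the
  no-intercept interaction test: with every group at rate $\mu$, the
  estimand is $\mu - \mu - \mu = -\mu < 0$. Calibration must be (and is)
  evaluated under additivity.
* Calibration scenarios use a tin-defect rate of 0.10 for the two-group
  null and baseline 0.02 with single-het main effects 0.04 for the
  interaction null. These sit in the range where such genotype
  comparisons typically operate (single heterozygotes at a few percent,
  mutants and double heterozygotes up to ~20%) and keep the per-embryo
  response non-degenerate.
  At very low rates (1–3%) most embryos have zero defects, the response
  is nearly constant, and any valid permutation p-value becomes
  conservative — a property of discreteness, not an error. Even at the
  0.10 operating rate a residue of this effect remains for the two-group
  test: proportions are multiples of 1/14 and tie often, so its measured
  rejection rate sits slightly *below* nominal (the packaged calibration
  run measures ≈0.036 at a nominal 0.05), in the safe direction. The
  interaction statistic, a weighted sum with near-continuous weights,
  ties far less and calibrates within the two-sided band.

Replicate $i$ of every scenario runs under a seed derived from the study
seed and $i$, shared across the `delta` grid (common random numbers), so
power curves are monotone-coupled and reruns are bit-for-bit reproducible.

Problem sizes used by the packaged acceptance checks: 1000 replicate
cohorts for type-I and additive-null calibration and 500 per effect size
for the power grid, each with $N = 499$ permutations and 15 embryos per
genotype — sizes at which the 95% binomial band around the nominal level
is ±0.0135 and a full run completes in a few minutes on one core.

## Degenerate inputs and numerical conventions

* Duplicate (embryo, segment, side) rows, inconsistent genotype or assay
  within an embryo, mixed assays in one analysis, and lacZ records
  without `svp_pc` are hard validation errors with row numbers.
* A two-group test with a group of one embryo runs but is flagged
  degenerate with a warning.
* Rank-deficient designs error naming the collinear columns; a
  numerically zero orthogonalized regressor stops the interaction test
  ("interaction not identifiable").
* Tie comparisons use a relative tolerance of $10^{-12}$ so that
  floating-point noise cannot flip a tie into an exceedance.
* Exhaustive enumeration treats arrangements of equal $g_\perp$ values as
  one arrangement; in a balanced three-group design the two single-het
  groups share a value by symmetry, so there are $\binom{3m}{m}$ distinct
  arrangements, not the three-value multinomial count.
* Reports print percentages to one decimal and p-values to four decimals
  with a `<0.0001` floor; all stored tables keep full precision.

## Known limitations

* The interaction scheme is approximate (the embryos are not exchangeable
  across groups once main effects differ); in our simulations it is
  mildly conservative rather than anticonservative at realistic defect
  rates.
* Per-category p-values are reported without multiplicity adjustment, by
  design.
* The generator's category collisions make the observable asymmetric
  rate depend on the earlier rate; use the `rate_observable` column of
  the cohort truth for that category.
* GEE/mixed-model alternatives and the Freedman–Lane or Manly permutation
  schemes are out of scope; the result object's `scheme` field leaves
  room for them.
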