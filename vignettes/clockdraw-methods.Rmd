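---
title: "Scoring model, agreement statistics and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring model, agreement statistics and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockdraw)
```

## The scoring model

The package's atomic input is the 17-item checklist, not the drawing.
Whether a feature merits a mark is an examiner judgment made upstream of the
software; everything downstream of the marked set is deterministic. This is
the point of the algorithmic variant of the Sunderland scale: the scale's
prose descriptions are replaced by concrete binary observations, and the
score is a pure function of them.

The decision procedure is a first-match rule list (see the README table).
Three design choices in it were genuinely open and are worth recording:

**Precedence of the exclusion items.** The three overriding items are
checked in the order `o` (wrong hand use, score 6), `p` (vague clock, score
2), `q` (no attempt, score 1), first match wins. The rubric lists them in
exactly this order under its "consider initially" header. The order rarely
binds in practice because strict validation rejects co-marked combinations
(`o` with `p` or `q`, `q` with anything); it matters only for lenient-mode
scoring of inconsistent data. One observable consequence: the preimage of
score 2 (`p` marked, `o` unmarked, 15 free items) is twice the size of the
preimage of score 1 (`q` marked, `o` and `p` unmarked, 14 free items).

**Severity-first evaluation of the lower band.** When several lower-band
deficits co-occur (say, numbers out of order *and* no hands), the rules are
evaluated 3, then 4, then 5, so the most severe applicable deficit
determines the score. Hierarchical clinical scales assign the description
that fits the worst feature of the performance; the alternative (mildest
first) would let a missing-hands drawing score 5 whenever the numbers were
also concentrated, which inverts the scale's meaning. A corollary the test
suite asserts: the all-unmarked checklist scores 3, not 4 or 5.

**Items that never enter the score.** No scoring rule references items `a`
(circle), `e` (spatial position), `f` (vertical 12–6 line) or `g`
(horizontal 3–9 line). We implement only the rules the rubric makes
explicit rather than inventing a face-correctness threshold, so a profile
with, say, a missing circle but perfect numbers and hands lands in the
intact band. Such profiles are flagged `nonstandard_face` in the output so
users can audit them; the flag does not affect the score.

A fourth ambiguity sits in the intact band: the rubric's "absence of at
least one / at least 2 / all three" wording for scores 9/8/7 is resolved as
an exact missing-count partition — score = 10 minus the number of unmarked
items among `l`, `m`, `n`. This is the only reading under which the three
rows are mutually exclusive and exhaustive, and it makes the hand penalty
exactly one point per item, which the tests assert as a monotonicity
property.

Because the profile space is tiny (2^17 = 131,072), correctness is checked
exhaustively rather than by spot-checks: every profile is scored, the
partition into preimages is verified to be total and disjoint, and an
independently written condition-list scorer must agree on every profile.

## Checklist consistency

Some item combinations are logically incoherent ("no attempt" together with
"12 numbers present"). The validator applies six implication rules (q
excludes everything; p excludes `b`–`n`; o excludes `p`,`q`; `i` and `l`
require both hands; `m`/`n` require some hand item). The scale itself never
constrains item combinations, and real examiner data may be noisy, so these
are warnings by default (`lenient`); `strict` mode, which rejects violating
rows, is opt-in and is the default only where the package itself generates
data (preimage sampling, below). Whether item `i` can be marked when
neither hand is identifiable as hour or minute is genuinely undecidable
from the rubric — which is precisely why the rules are warnings rather than
errors.

## Agreement statistics

All statistics are computed from first principles on the 1–10 ordinal
scale:

- **Percent agreement**: share of drawings scored identically.
- **Cohen's κ**: chance correction from the product of the two raters'
  marginals over the *union of observed categories* — the conventional
  two-rater construction.
- **Weighted κ**: computed on the *full fixed 1–10 table* with disagreement
  weights `|i−j|/9` (linear, default) or squared (quadratic). Ordinal
  distance is a property of the instrument, not of whichever categories
  happened to occur; fixing the category space keeps weights comparable
  across rater pairs. Linear is the default because nothing in the source
  context indicates quadratic weighting; quadratic is selectable.
- **Fleiss' κ**: pooled multi-rater chance-corrected agreement.
- **Pearson r** with a two-sided p-value from the t transform on n − 2
  degrees of freedom. No multiplicity correction is applied across the
  k(k−1)/2 pairs; with six raters there are 15 correlated tests and users
  who want familywise control should apply their own correction.

"Combined" multi-rater kappa is ambiguous — Fleiss' κ and the mean of the
pairwise Cohen κs are different statistics that need not agree — so the
pooled report computes **both** and labels them distinctly rather than
guessing which convention a given source used.

A κ whose chance agreement is exactly 1 (both raters constant on the same
category) is undefined. It is returned as `NaN` with a warning — never
silently 0 or 1, which would corrupt pooled means. Pooled means skip
undefined entries and report how many were skipped (`n_undefined`).

## The synthetic cohort generator

The generator exists so that scoring and reliability analysis can be
exercised end-to-end without any study data. Its defaults encode the
published cohort marginals: 100 drawings, score mean 5.22, SD 2.02, a point
mass of 0.535 on score 5, and zero mass on scores 1 and 7.

**Maximum-entropy calibration.** Those constraints pin down only part of a
distribution over ten scores; the remaining mass must be allocated somehow,
and any allocation consistent with the constraints is equally compatible
with the published summary. We choose the least-informative completion: the
maximum-entropy distribution subject to the fixed point masses, the
exclusions, and the two moment constraints. On the free support the
solution is an exponential family `p(s) ∝ exp(λ₁s + λ₂s²)`; the two
multipliers are found by minimising the convex dual with BFGS on centred
features followed by Newton polishing, to a moment tolerance of 1e-10
(calibration errors out rather than returning a distribution off by more
than 1e-8). Infeasible specifications (mean outside the support hull,
variance outside the achievable range, point masses exceeding 1) raise an
error naming the violated constraint. A user who has a full histogram can
bypass calibration entirely by passing their own probability vector to
`sample_cohort()`.

**Preimage inversion.** A sampled score is converted to a checklist by
drawing uniformly from that score's preimage under the actual algorithm,
restricted by default to strictly consistent profiles so the synthetic
checklists are clinically plausible (a flag lifts the restriction).
Rescoring a sampled checklist returns the drawn score by construction; the
tests assert this round trip exactly, and assert with a chi-square
goodness-of-fit test at n = 10,000 that the rescored distribution matches
the calibrated one.

**Rater noise.** Simulated examiners disagree at the *item* level: each of
the 17 items is flipped independently with probability `epsilon` and the
perturbed checklist is rescored through the algorithm. This is the simplest
mechanism that produces score-level disagreement via the actual decision
procedure rather than by perturbing scores directly — small item errors can
leave the score unchanged or jump it across a rule boundary, exactly as
examiner disagreement behaves. At `epsilon = 0` every agreement statistic
attains its perfect-agreement value exactly; the tests check that pooled κ
decreases in expectation as `epsilon` grows (0 → 0.05 → 0.2, averaged over
10 seeds). The default `epsilon = 0.05` is a moderate noise level chosen to
produce visible disagreement while retaining substantial agreement in
examples; it is a free
parameter, not an estimate of real examiner behaviour.

**Correlated covariate.** `attach_covariate()` generates an MMSE-like
integer covariate (default uniform on 18–30) through a latent Gaussian
copula. Discretising both margins attenuates the correlation, so the latent
correlation is inflated analytically — each margin's attenuation factor is
the correlation between the discrete variable and its latent normal,
computable in closed form from truncated-normal category means — rather
than tuned by an inner Monte-Carlo loop. The correction uses the
first-order Hermite term only; the neglected higher-order terms are
O(ρ²) with small coefficients, well inside the ±0.03 tolerance the tests
impose at n = 10,000. Realised correlations at small n vary with ordinary
sampling error.

**What the generator does not emulate.** Real drawings have correlated item
errors (a tremor affects several items at once), examiner-specific biases,
and education/age structure; the generator's item flips are i.i.d. and the
cohort has no demographic covariates (the source cohort showed no
schooling or age correlation with the score, so none is modelled). Passing
tests therefore demonstrate the correctness of the algorithms and the
internal consistency of the simulator — not that the simulator reproduces
the error structure of human examiners.

## Numerical and reporting conventions

- Summary SDs use the sample (n − 1) denominator, matching routine
  reporting; medians use the midpoint convention for even n.
- All randomness in a simulation flows from a single integer seed; a fixed
  seed makes the CSV data outputs byte-identical across runs. The
  provenance JSON written alongside every CLI run carries a timestamp and
  the effective merged parameters, so it is excluded from the byte-identity
  contract.
- Problem sizes in the test suite: exhaustive checks run over all 131,072
  profiles; Monte-Carlo null and round-trip checks use n = 10,000 with
  three fixed seeds; the noise-monotonicity check uses 30 drawings, six
  raters and ten seeds. These sizes make the null-kappa tolerance (±0.02)
  and the round-trip tolerances comfortable for the sampling error
  involved.

## Limitations

- The package scores checklists, not images; item judgments are out of
  scope, and with them the largest real-world source of disagreement.
- The empirical reliability of the original six-examiner study cannot be
  recomputed here because the underlying 30 × 6 rating matrix was never
  published; the reliability module is validated against brute-force
  oracles and simulated data instead.
- The max-ent completion of the partially specified score histogram is a
  modelling choice. It is the canonical least-informative one, but any
  other completion matching the published constraints would be equally
  consistent with the source.
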