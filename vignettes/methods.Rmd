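---
title: "Methods: sibling sex ratios, status and the Trivers–Willard test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sibling sex ratios, status and the Trivers–Willard test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The Trivers–Willard hypothesis (TWH) predicts that parents in better
condition overproduce sons when adult condition affects male reproductive
success more strongly than female reproductive success. Human tests
usually proxy condition by socioeconomic status (SES). Two questions are
separable:

* **Precondition** — does SES relate to completed reproductive success
  *differently* in men and women? Without such a sex-specific link,
  sex-ratio adjustment confers no fitness advantage and the TWH cannot be
  tested meaningfully.
* **Prediction** — is family (or family-subunit) offspring sex ratio
  positively related to SES?

`sibsr` implements both analyses for retrospective questionnaire data in
which each respondent reports their childhood relative living standard
(ordinal 1–5), their completed fertility, and the sexes and birth years of
all their full siblings — so each responding family contributes one
sibship whose sex ratio (males / all siblings, respondent included) is the
response of interest.

## The two models

**Precondition.** A generalized linear model with Poisson error and log
link for the respondent's number of children, with standard errors scaled
by the Pearson dispersion (a quasi-Poisson fit, accommodating the
underdispersion typical of human completed fertility):

\[
\log \mathbb{E}[\text{children}] = \beta_0 + \text{SES} + \text{sex} +
\text{SES} \times \text{sex} + \gamma\,\text{n(siblings)} +
\text{settlement},
\]

where SES enters with *forward-Helmert* contrasts — each ordinal level is
compared with the mean of all **subsequent** levels — sex and settlement
with sum-to-zero contrasts, and the settlement term is included only for
the whole-country region (within Budapest it is constant). The two top
SES levels ("better than average", "very well") are merged because the top
category is rare; analyses use the four levels *worst, worse, average,
better*. Each term is tested with a type-3 Wald chi-square
(\(\chi^2 = \beta_T^\top V_T^{-1} \beta_T\), \(V_T = \phi\,(X^\top W
X)^{-1}_{TT}\)), valid as type-3 under these sum-to-zero codings. The
focal quantity is the SES×sex interaction.

**Prediction.** A binomial-logit GLM of the number of sons with the number
of siblings as denominator, on SES (same merged coding, plus settlement
for the whole country). Because online-survey response is heavily
female-biased and the respondent counts toward the sibship, raw sex ratios
are female-biased; the analysis therefore keeps every
male-representative family and draws an equal-count random sample of
female-representative families, repeats this **100 times** (the male set
fixed, only the female sample varying) and reports medians over
replicates: the omnibus SES Wald p, the 'worse'−'better' contrast
(estimate and p on the logit scale) and predicted sex ratios per SES
level. Replicates whose GLM fails (sparse-cell rank deficiency) are
recorded and excluded from the aggregates rather than redrawn, avoiding a
selection bias toward well-behaved samples.

## Family subunits

A point measure of childhood SES describes the whole sibship badly when
the family's circumstances changed between births. A *family subunit* is a
maximal run of birth-ordered siblings with (i) at most 5 years between
successive births — a gap of exactly 5 years does **not** split — and
(ii) no reported substantial financial change between their births;
analysis subunits must contain a respondent, and among
respondent-containing subunits the largest is used, ties broken uniformly
at random. A missing change flag splits conservatively. The subunit
extractor is verified against an exhaustive enumeration of maximal valid
runs for every boundary configuration up to sibship size 8.

## The synthetic world

Real questionnaire data of this kind are typically not depositable, so the
package ships a generator whose output has the statistical structure the
analysis assumes, plus ground truth for validating the record linkage and
for parameter-recovery experiments. Families are drawn as:

* size 2–6 (default probabilities 0.55/0.30/0.10/0.04/0.01, matching a
  mean sibship near 2), initial SES 1–5 (0.07/0.25/0.47/0.19/0.02: the top
  level deliberately rare), settlement type uniform over five categories;
* birth gaps of 1–8 years (mode 2–3); between consecutive births the
  family's finances change with probability 0.15, shifting SES by a
  configurable step clamped to 1..5; a sibling's "childhood SES" is the
  SES in force at their own birth (the first decade in the questionnaire
  wording; using SES at birth keeps a single well-defined value);
* offspring sex is male with probability
  \(\operatorname{logit}^{-1}(\alpha + \beta\,(\text{SES}-3))\); the
  default is the null world \(\alpha = \beta = 0\);
* children counts per sibling follow a log-linear Poisson model with
  configurable sex, SES, interaction, sibship-size and settlement effects
  (defaults: no sex or interaction effect — again the null world — a mean
  near 2.1, small positive sibship and settlement effects);
* each sibling responds to the survey independently with sex-specific
  probabilities (defaults 0.15 for women, 0.035 for men, reproducing a
  roughly 4:1 female excess among respondents); **a family is emitted only
  if someone responded**. This rejection-sampling design mirrors how a
  survey actually observes families and matters quantitatively: selecting
  a respondent *proportionally to response propensity* makes the
  probability that a family's representative is male proportional to its
  male count, which is exactly the size-biased condition under which the
  balanced-subset mean family sex ratio is 0.50 under the null. A design
  that forces a respondent into non-responding families breaks this and
  biases the balanced mean upward.
* migrant families (4.5%) have a foreign episode: an arrival index is
  drawn and all earlier-born siblings are foreign-born. Modelling
  migration at the family level (rather than iid per sibling) keeps the
  fraction of families with any foreign-born sibling near the rate the
  exclusion cascade should remove;
* per-sibling settlement mismatches (4%: misreports or childhood moves),
  identical-twin pairs with forced equal sex (0.9% of families), abortion
  involvement (logistic in SES, default ≈32% affected), rare foetuses of
  unknown sex, and respondents' family codes: shared by all respondents of
  a family with probability `p_code_shared`, individually corrupted into a
  neighbouring family's code with probability `p_code_error`.

All randomness flows from one seed through per-family substreams
(`derive_seed(seed, k)` for candidate family *k*), so outputs are
byte-identical across runs and any family is reproducible in isolation.
Per-replicate seeds in the resampling analysis are derived the same way
from the base seed.

**What the generator does not emulate** — and hence what a green test does
not establish: no mortality, no sequential partnerships or half-siblings,
no sex-selective abortion, no correlation between abortion use and
children counts, no recall bias in SES (the reported SES is the true SES
in force), and no county-level geography. Linkage recall near 90% on
default settings arises from within-family reporting heterogeneity
(migration episodes, settlement mismatches), not from the fuzzier
inconsistencies of real self-reports.

## Record linkage

Stage 1 groups respondents by explicit family code but only accepts
mutually consistent groups (equal family size, each member's own birth
year and sex present in every other member's roster, equal birthplaces);
inconsistent groups — the operationalisation of erroneous codes — are
split and their members fall through. Stage 2 links remaining respondents
pairwise when *all* keys correspond: equal sibship size, identical (birth
year, sex) roster multisets, equal childhood birthplace (country +
settlement type), and each one's reported number of children (excluding
foetuses of unknown sex) equal to the children count the other's roster
records for the matching sibling. Links are transitive, but a connected
component is accepted only if it is a clique no larger than the reported
family size; ambiguous components are conservatively left unlinked, which
by construction favours precision over recall.

Scoring is strict: a family counts as recovered only when its exact member
set is reproduced, and precision is the fraction of predicted
multi-respondent families that exactly match a true family. Two
consequences are worth knowing. First, at realistic key granularity two
unrelated families can be genuinely indistinguishable (same birth years,
sexes, settlement, matching children counts); validation fixtures that
presuppose unique keys therefore remove such truth-identified collisions
(`enforce_unique_keys()`). Second, exact-set precision is *not* monotone
in reporting noise: moderate noise creates partially recovered families
(counted as false), while heavy noise suppresses multi-respondent
predictions altogether so the few survivors are correct; the property
tests assert the defensible monotonicity (recall decreasing, noisy
precision never above noise-free precision).

## Numerical choices

* IRLS convergence: relative deviance change < 1e-10 or 100 iterations;
  nonconvergence is flagged, results still returned. Starting values are
  the usual link-transformed adjusted responses (\(y+0.1\) for Poisson,
  \((y+\tfrac12)/(m+1)\) for binomial). Means are clamped to
  \([10^{-10}, 1-10^{-10}]\) (proportions) or \(\ge 10^{-10}\) (Poisson)
  so saturated binary fits drive fitted values to their bounds without
  numerical failure.
* The coding matrix for a contrast scheme is obtained by inverting the
  weight matrix augmented with the grand-mean row; this guarantees that in
  a balanced saturated one-way model fitted coefficient *j* equals the
  *j*-th contrast of group means — the property the forward-Helmert
  interpretation relies on (verified against a least-squares oracle:
  balanced group means 1,2,3,4 give coefficients −2, −1.5, −1). Note the
  sum-coding coefficients are scaled relative to R's `contr.sum`
  (level-minus-last rather than level-minus-grand-mean); type-3 Wald
  tests are invariant to this choice.
* Marginal means average over non-focal factors at their balanced
  (zero-coded) values — the coding columns average to zero by construction
  — and numeric covariates at their observed means; proportional weighting
  was the open alternative and would differ in unbalanced data. Confidence
  intervals use the normal quantile 1.959964 on the link scale and are
  then inverse-linked, so bounds respect the response range.
* Dispersion is the Pearson statistic over residual degrees of freedom;
  point estimates never depend on it. Zero residual degrees of freedom is
  an error, not a silent NA.
* Medians over an even number of replicates use the midpoint convention
  (R's default).
* "Surely at least 45/55 years old" from calendar years alone is
  `fill_year − birth_year − 1` (the birthday may not have passed). Above
  the threshold, only an explicit "yes" to wanting more children
  disqualifies; in the 10-year window below it, a stable partnership *and*
  an explicit "no" are required.
* Representative choice within a family: abortion-free males, then
  abortion-free females, then everyone else, ties uniform at random —
  abortion-free status dominates sex, the resolution chosen for a case
  the selection rules leave open.
* `max_children` (default 12) is a configurable outlier cap rather than a
  hard-coded cutoff.

## Design decisions on genuinely open points

* Children counts of non-respondent siblings are generated and carried in
  the rosters because the pairwise matching keys need them; how such
  counts were collected in reality is not specified, so the roster column
  is the package's own convention.
* Erroneous codes are *counted as respondents* sitting in inconsistent
  code groups.
* The "largest subunit" competition is restricted to respondent-containing
  subunits before sizes are compared.
* The prediction models use the family's shared childhood settlement
  (well-defined because mixed-settlement families are excluded earlier).
* "Significant" in the fraction-of-significant-contrasts summary means raw
  contrast p < 0.05 with no cross-replicate adjustment.

## Limitations

Acceptance-style checks run on the synthetic world; they validate the
pipeline's statistical behaviour (exact linkage under unique keys,
balanced-subset sex ratio 0.50 under the null, nominal type-I error for
both focal tests, monotone power in effect and sample size, count
conservation through every cascade), not any empirical claim about real
populations. Small regional cohorts can make the saturated SES×sex model
rank-deficient when a sparse cell is empty; such fits fail loudly (or, in
the resampling analysis, are excluded and counted). The linkage algorithm
is exact-key by design — no fuzzy or probabilistic matching — so its recall
on real data is bounded by reporting consistency.
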