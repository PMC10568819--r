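---
title: "Measuring and modelling delay discounting in parent-child dyads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling delay discounting in parent-child dyads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadDD)
```

## The measurement problem

Delay discounting is the decline in a reward's subjective value with the
delay to its receipt. The adjusting-amount task measures it behaviourally: a
fixed larger-later reward (LLR, $100 here) is pitted against an immediate
amount at each of five delays (1, 7, 30, 182, 365 days), and the immediate
amount titrates after every choice until it approximates the *indifference
point* — the immediate amount subjectively equivalent to the delayed $100.

dyadDD implements that task, its quality control, the ordinal
area-under-the-curve summary, and the dyadic analysis that asks whether
indicators of economic scarcity (household income, education, Medicaid
coverage) relate to discounting differently for parents than for their
6-12-year-old children. Because the family cohorts this design targets are
not publicly distributable, the package ships a synthetic dyad generator
whose latent truth is known, so that every downstream stage is testable.

## The staircase and its conventions

The source task description fixes the LLR, the delays and the first offer
($50 vs $100) but not the adjustment schedule. We use the conventional
binary-search design, all parameters exposed in `task_config()`:

* first offer = `start_fraction * llr` (default $50);
* after each choice the offer moves toward indifference — down if the
  immediate side was chosen, up otherwise — by a step that starts at
  `start_fraction * llr / 2` ($25) and halves every trial;
* six trials per delay; the indifference point is the hypothetical seventh
  offer, i.e. the offer after the final adjustment.

This makes the staircase a bisection: for a deterministic responder whose
true indifference value lies in (0, llr), the scored point is within the
final step size, `start_fraction * llr * 2^-trials`, of the true value
($0.78125 at the defaults). The test suite verifies the bracket on 1000
random deterministic agents and three hand-traced offer sequences
(always-delayed -> 99.21875; always-immediate -> 0.78125; a threshold
responder with value $40 at 30 days -> 39.84375).

Ties (offer exactly equal to the discounted value) go to the delayed option
by default (`tie_rule`), delays are administered in ascending order, and
every stochastic operation consumes the R RNG stream so a seed fixes the
whole run. `score_choice_log()` re-derives indifference points from a
recorded log by replaying the adjustment rule and refuses logs whose offers
are inconsistent with it, naming the delay and trial.

## Quality control

A profile is *systematic* when (1) no indifference point exceeds its
predecessor by more than 20% of the LLR and (2) the last point is below the
first by at least 10% of the LLR. The source text compresses the standard
two-criterion algorithm into one sentence; we implement both criteria with
strict inequalities (a rise of exactly 20% passes; a drop of exactly 10%
passes) and make each toggleable, defaulting to the composite. Relaxing the
thresholds can only keep or gain systematic classifications, and the rule is
invariant to a common rescaling of points and LLR — both properties are
tested on 10^4 random profiles.

## Ordinal AUC

`auc_ordinal()` normalises points by the LLR and integrates by trapezoids
over *ordinal* delay ranks equally spaced on [0, 1]. The measure therefore
depends on the delays only through their order — by design, so that long
delays do not dominate the integral the way they do in the traditional
delay-weighted AUC (provided as `auc_traditional()` for comparison). The
origin convention varies across the literature: prepending an implicit
(delay 0, value 1) point makes the attainable minimum 1/(2n) rather than 0.
Since the measure is described as ranging over [0, 1] exactly, the origin is
excluded by default and available via `include_origin = TRUE`.

## Covariate coding

`categorize_income()` splits incomes about their sample median with a
sample-SD half-width ("low" below median - SD, "high" above median + SD,
boundary values inside the band). Centering a spread statistic on the median
mixes estimator families, but it is the literal reading of the stated
procedure and is location/scale equivariant. `encode_covariates()` codes
Medicaid as a dichotomy over the insurance vocabulary (Medicare and all
other types code 0), sex as male = 1 / female = 2, and minority as
race != White OR ethnicity = Hispanic/Latino — the conventional reading of a
footnote that is ambiguous as printed; the predicate is injectable for the
stricter AND variant, and "Refused" race yields a missing indicator that is
dropped listwise downstream.

Adults have no age-appropriate growth reference, so their percent over
median BMI and zBMI use the sex-specific age-20 row (240 months) as a proxy,
per `lookup_reference(role = "parent")`. The LMS z-score uses the standard
Box-Cox form ((BMI/M)^L - 1)/(L S) — the printed formula has unbalanced
parentheses; this is the parameterisation it cites — with the log branch
engaged for |L| < 1e-6, where the power form loses the accuracy the
continuity invariant demands. No real growth-chart table is bundled (it
would require an external download): `synthetic_lms_reference()` is a
clearly-labelled synthetic table with realistically shaped M(age), L and S
curves, adequate for exercising the code paths but not for clinical scoring.

## The stacked dyadic model

Parent and child rows are stacked, one row per family member, and

AUC_ord ~ predictor + member + predictor:member + (1 | family)

is fit by REML (`lme4`), with member coded parent = 0 / child = 1. The model
equations in the source list no explicit random effect although members are
described as nested within family; a family random intercept is the standard
treatment of dyadic nesting and is our default, with an OLS sensitivity path
(`random_intercept = FALSE`). When the between-family variance estimate hits
zero the mixed fit reduces to the OLS coefficients (tested to 1e-6).
Interaction inference is by Wald z — the estimator and test are not named in
the source; REML + Wald is the ecosystem default — and the interaction term
is the parent-vs-child difference test. Its null calibration (rejection rate
at alpha = 0.05 within binomial 95% bounds over 1000 replicates of 200
families) is part of the acceptance suite.

Zero-order correlations per role come from `pearson_r()` (point-biserial
when the predictor is a dummy — verified against the dedicated formula to
1e-12). `build_results_tables()` runs, for each predictor, the parent and
child correlations plus the stacked interaction, in both the all-data and
systematic-only samples; with the default nine-predictor roster that is
9 x 2 x 3 = 54 tests, and Benjamini-Hochberg flags at q = 0.10 are assigned
across whatever battery actually ran (`m` is logged in the output and
manifest). Whether the published parent/child p-values come from separate
correlations or model simple slopes is not stated; we use separate
correlations, matching their "zero-order" description.

## What the synthetic cohort emulates — and what it does not

`synthetic_config()` defaults are the stated world of the target population
and are not tuned to test outcomes:

* marginals: income log-normal moment-matched to mean $84,459 / SD $55,134
  (household income is right-skewed and only two moments are reported);
  education 15.0 (2.2) years, correlated 0.4 with log income; Medicaid 20.7%
  and minority 34.6% baseline rates, modulated by income on the logit scale;
  parent age 41.4 (7.3); child age 9.4 (1.8) truncated to [6, 12] (the
  truncation pulls the realized mean to ~9.25); parent BMI 37.1 (7.9)
  floored at the eligibility threshold of 25; child BMI drawn as ~60% (27)
  over the reference median.
* structure: a standardized scarcity composite (-log income, Medicaid,
  -education, equal weights) drives parent log-k with slope `gamma_parent`
  (default 0.5) and child log-k with `gamma_child` (default 0) — scarcity
  steepens parent but not child discounting — plus a 0.3 within-family
  residual correlation. Baseline discount rates are log(0.005) for parents
  and log(0.02) for children, residual SD 1.5 on the log scale, chosen so
  deterministic scoring lands near the observed mean AUC levels (~0.76
  parents, ~0.57 children among systematic responders).
* non-systematic responding is mechanistic, not injected: designated
  members (base rates 0.42 children / 0.19 parents, higher in scarcer
  families) receive choice-noise temperatures of $50-300 — large against
  the $100 stakes, so their choices approach coin flips and QC failure is
  likely — while ordinary members get $0.20-1.50. Realized systematic rates
  land near 0.64 (children) / 0.78 (parents); they are emergent from the
  mechanism, close to but not equal to the 0.577 / 0.813 observed in the
  study, and we deliberately do not tune the temperature to match them.

A green test on this generator establishes that the pipeline recovers the
structure the generator encodes — it does not establish anything about real
families. In particular the generator assumes conditional independence
patterns (e.g. Medicaid and minority linked to income but not to each other)
that real cohorts will violate, hyperbolic agents (the analysis never
assumes a discount function; only the generator does), a single session, no
attrition, and concordant parent/child minority status.

## Numerical and design notes

* Offers are clamped to the open interval (0, llr); with the default
  halving schedule the clamp is never active.
* Interaction recovery: with a parent-only standardized effect of -0.3 at
  n = 2000 families the acceptance suite requires detection in >= 95% of
  200 replicates with the sign always recovered. This is evaluated on the
  systematic-only sample — the design's primary analysis sample; including
  the high-noise responders dilutes power to ~0.90 at those settings.
* The expected interaction sign is `sign(gamma_parent - gamma_child)`
  because AUC falls as log-k rises and the member dummy is child = 1.
* Rank-deficient designs (tiny samples, collinear predictors) surface an NA
  interaction row rather than an error, so a whole battery never dies on
  one degenerate cell.
* BH-FDR treats NA p-values as unflaggable and excludes them from m.

## Known limitations

The generator's marginal calibration is first-and-second-moment only; joint
distributions are modelling choices. The task engine implements only the
adjusting-amount format (no fixed-choice questionnaires, no reaction times).
Percentile-based BMI eligibility categories are out of scope, as are
intervention arms and longitudinal sessions.
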