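---
title: "Effort-moderated ability estimation: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effort-moderated ability estimation: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effortirt)
```

## The problem

An ability estimate from a dichotomously scored test assumes every response
reflects an effortful attempt. When an examinee disengages and responds
rapidly — faster than the item can plausibly be read and solved — the
response is noise around the guessing rate, and treating it as effortful
contaminates the maximum-likelihood theta. `effortirt` implements the
scoring side of this problem: given pre-calibrated item parameters, it
detects rapid responses from response times, scores persons under response
models that treat rapid cells as guesses, and applies explicit corrections
to persons classified as rapid overall. Item calibration itself is out of
scope: the item file is produced by any external IRT calibration tool.

## Response models

All models give the probability of a correct response for person ability
$\theta$ (logits) and items with discrimination $a > 0$, difficulty $b$
(logits), optional guessing threshold $\gamma$ (logits) and
ability-guessing slope $k \ge 0$.

* **2PL** (`prob_2pl`): $P_2 = \mathrm{logit}^{-1}(a(\theta - b))$.
* **3PL** (`prob_3pl`, `prob_3pl_gamma`): $P_3 = c + (1-c)P_2$ with
  $c = \mathrm{logit}^{-1}(\gamma)$. The two parameterisations are an
  algebraic identity, which the test suite verifies to $10^{-12}$ on a
  dense $(\theta, \gamma)$ grid. $\gamma = -\infty$ is the no-guessing
  sentinel and any $\gamma < -15$ is numerically a zero asymptote, so the
  3PL collapses to the 2PL.
* **Ability-based guessing** (`prob_ability_guessing`): the item asymptote
  is replaced by a person-level guessing rate
  $c_{ij} = \mathrm{logit}^{-1}(\gamma + k\theta)$, increasing in ability
  when $k > 0$; $k = 0$ recovers the 3PL exactly. The default $k = 0.228$
  is the conventional value for four-option items; it is read per item from
  the item file and can be overridden by a single scalar in the
  configuration.
* **Effort-moderated mixtures** (`prob_effort_moderated`): a per-cell
  solution-behavior flag $SB \in \{0,1\}$ gates the effortful curve against
  a guessing constant: $SB \cdot P + (1 - SB) \cdot g$ with
  $g = 1/\text{n\_options}$, where $P$ is $P_2$ (`em2pl`) or $P_3$
  (`em3pl`). The informed-guessing variant (`em2pl_informed`) replaces the
  rapid branch by $k\theta + g$, crediting rapid responders with
  ability-proportional guessing success.

A single guessing rate $g$ applies to all items of a run, fixed by the
number of response options; per-item option counts would need per-item
configuration, which the file format deliberately does not carry.

Every reduction in this family (3PL at $c=0$, ability-based at $k=0$,
effort-moderated at $SB=1$) is exercised by the test suite as an exact
identity, since downstream estimation relies on them.

### Numerical choices

Logistic curves are evaluated through `stats::plogis`, which is
overflow-safe for arbitrarily large $|a(\theta - b)|$ — relevant because
the boundary convention (below) evaluates curves at $\pm\log(2J)$ and
validation sweeps go far beyond that. Probabilities entering a Bernoulli
likelihood are clamped to $[10^{-6}, 1-10^{-6}]$ so log-likelihoods stay
finite. The informed-guessing branch $k\theta + g$ is a raw linear
expression that can leave $[0,1]$; it is clamped to the same interval, with
a warning when a rapid cell actually uses a clamped value. The clamp
preserves the printed mixture formula on its valid range while keeping the
likelihood defined everywhere.

## Flagging rapid responses from times

`flag_solution_behavior` thresholds each item's response-time column at its
empirical `percentile` (default 10): a response at or below the threshold
is rapid ($SB = 0$). Three conventions are fixed here because they are
genuinely open choices:

* **Quantile dialect.** The threshold is the linear-interpolation quantile
  (`stats::quantile`, type 7). Percentile rules are only reproducible once
  a dialect is pinned; type 7 is R's default and the common
  linear-interpolation convention.
* **Ties.** A time exactly at the threshold is flagged rapid
  ($rt \le$ threshold): conservative toward detecting disengagement. In
  the degenerate case of a constant time column every response ties the
  threshold and all are flagged rapid; this is documented behavior, and a
  meaningful percentile rule needs within-item time variation.
* **Missing times** are presumed effortful: absence of timing evidence
  should not impute disengagement.

The response-time-effort index `response_time_effort` is the per-person
mean of the flags, $RTE_j = \sum_i SB_{ij}/J \in [0,1]$.
`classify_persons` then labels a person rapid ($rbe = 0$) when
$RTE < \text{cutoff}$, with an inclusive boundary ($RTE \ge$ cutoff is
effortful). The cutoff defaults to 0.90 — under the 10th-percentile rule an
engaged sample produces $RTE$ near 0.9–1.0, so 0.90 separates persons whose
flag rate exceeds what the rule produces by construction — but it is a
visible, required knob rather than a buried constant, because no principled
universal value exists; it should be set per instrument, e.g. by inspecting
the RTE distribution.

## Estimation

### Maximum likelihood

`mle_theta` maximises the Bernoulli log-likelihood
$\sum_i y_i \log P_i + (1-y_i)\log(1-P_i)$ over non-missing responses by
Newton–Raphson on the analytic score function: start 0, step tolerance
$10^{-6}$, at most 50 iterations, search confined to $\pm\log(2J)$, and a
bisection fallback on a sign-changing bracket of the score whenever a
Newton step misbehaves. 3PL-type likelihoods need not be log-concave and
the informed-guessing mixture has kinks where its clamp engages, so the
optimiser is safeguarded: candidate optima — Newton from the start, Newton
or bisection inside every downward zero-crossing of the score on a coarse
grid, and the two interval endpoints — are compared on the objective and
the best is returned. The test suite checks the whole path against an
independent fine-grid ($10^{-4}$ step) argmax of the same objective on 400
randomised instances across all model variants, and verifies the score
equation to $10^{-5}$ at smooth interior optima (at a clamp kink the score
is discontinuous and the check does not apply).

Zero-variance vectors (all correct or all incorrect) have a monotone
likelihood and no ML optimum; they take the boundary convention
$\theta = \pm\log(2J)$ with natural logarithm — for a 7-item instrument,
$\pm\log 14 = \pm 2.639$ — flagged by `at_boundary`. The same flag marks
any vector whose likelihood is still increasing at the search bound.
Missing responses are dropped from both the likelihood and the
information; an all-missing vector is an error under MLE.

Under `em2pl`/`em3pl` a rapid cell contributes a theta-free constant to the
likelihood, so a person whose every scored cell is rapid has a flat
likelihood; the scorer signals non-identifiability rather than returning a
spurious number. Batch scoring (`score_sample`) reports such rows as failed
(NA, `converged = FALSE`) and continues.

The standard error is $1/\sqrt{I(\hat\theta)}$ with test information
$I = \sum_i a_i^2 P_i Q_i$ for 2PL-type curves and the standard
expected-information form
$a_i^2 (Q_i/P_i)\,((P_i - c_i)/(1-c_i))^2$ for 3PL-type curves, using the
person-level $c_{ij}$ for the ability-based model. Rapid cells are excluded
from information under `em2pl`/`em3pl`; under `em2pl_informed` the rapid
branch retains theta dependence and contributes $k^2/(P Q)$ wherever its
linear probability is unclamped.

### Bayesian modal estimation

`bme_theta` maximises the log-posterior (likelihood plus
$\log N(\theta;\mu,\sigma^2)$ density) with the same machinery. "Bayesian"
here means the posterior *mode* with a normal prior — the modal estimator,
not EAP; the default prior is $N(0,1)$, matching the conventional scaling
of calibrated item parameters. The prior makes every vector estimable (no
boundary convention; an all-missing vector returns the prior itself), and
the standard error is the curvature-based
$1/\sqrt{I(\hat\theta) + 1/\sigma^2}$, which is strictly smaller than the
ML standard error on the same data — the suite verifies this shrinkage,
and the raw-score ordering of estimates, exhaustively over all 126 interior
vectors of a 7-item Rasch instrument.

### Rapid-responder corrections

`corrected_theta` replaces the theta of a person classified rapid:

* **Random guessing**: $\theta = \mathrm{logit}(1/\text{n\_options})$
  ($-1.0986$ for four options), identical under MLE and BME and independent
  of the response vector.
* **Ability-based**: $\theta = \mathrm{logit}(1/\text{n\_options}) +
  k\hat\theta$, where $\hat\theta$ is the person's effortful-model estimate
  from the same method being reported. This is the one reading of the
  ability-based guessing idea that stays entirely on the logit scale: the
  guessing logit $\gamma + k\theta$ evaluated at the person's estimate,
  with $\gamma$ fixed at the random-guessing logit.

Corrected estimates carry no likelihood-based uncertainty, so `se` is NA
rather than a number that would invite misuse.

## The synthetic-data generator

`simulate_dataset` emulates a testing session with disengagement: abilities
$\theta \sim N(0,1)$ by default; a fraction `rapid_person_rate` (default
0.2) of persons are rapid, and within a rapid person each item is rapid
with probability `rapid_item_rate_given_rapid` (default 1, i.e. fully
rapid rows — the hardest case for naive scoring). Engaged cells are
Bernoulli draws from the 2PL at the person's true theta; rapid cells are
Bernoulli draws at $g = 1/\text{n\_options}$. Response times are lognormal
per cell: engaged $\mu = \log 20$ s, $\sigma = 0.5$; rapid $\mu = \log 2$
s, $\sigma = 0.4$. The time scale is typical of multiple-choice cognitive
items (median 20 s engaged, 2 s rapid), and the components are separated
by $(\log 20 - \log 2)/0.5 = 4.6$ engaged-SDs on the log scale, so the
10th-percentile rule is exercised meaningfully rather than trivially: at
20% contamination the per-item threshold falls inside the rapid cluster,
flags recover true rapid cells with >90% cell-level agreement, and the RTE
cutoff recovers the person classification, as the suite checks.

All draws come from one seeded generator in a fixed, documented order —
thetas, rapid-person indicators, rapid-cell indicators, response uniforms,
time normals — so a design is reproduced bit-identically from its seed.

What the generator does *not* emulate: speed–accuracy trade-offs within
engaged responding, item-dependent time distributions, partial engagement
drifting over the session (each cell is independently rapid or not), and
generation from the 3PL or ability-based models (scoring them is in scope;
generating from them is not an exercised surface). Passing recovery tests
therefore show that the pipeline corrects the contamination process it
models, not that it captures every real disengagement pattern.

`recovery_experiment` wires the pipeline end to end — simulate, flag from
times, classify, score, correct — and reports mean signed bias and RMSE
against the generating thetas, overall and split by true rapid status. The
shipped experiments use desk-scale sizes chosen to make Monte-Carlo error
small relative to the effects under test: 500 persons × 30 items for
recovery (clean MLE |bias| < 0.1; BME RMSE ≤ MLE RMSE; the correction
shrinking error on the contaminated subgroup relative to naive 2PL), and
200 × 7 for the classification checks.

## File formats and the command line

Item files are headered CSV with required columns `a,b,k` and optional
`gamma`; a missing `gamma` column means no lower asymptote. Response and
time matrices are headered CSV, persons × items, with an optional leading
`person`/`id` column; response cells are 0/1/empty, time cells nonnegative
seconds/empty. Scored output is
`person,theta,se,method,model,correction,converged,n_iter,at_boundary` with
theta and SE at 4 decimals (full precision is kept internally). Enumerated
string flags (`--method mle|bme`, `--correction none|random|ability`)
replace integer codes throughout. `run_score_command` orchestrates a full
run and is deterministic: identical inputs and configuration give
byte-identical outputs. The thin CLI at
`system.file("cli", "effortirt.R", package = "effortirt")` exposes `score`,
`effort` and `simulate` subcommands; batch-first, with a single person as a
one-row file.

## Known limitations

* Item parameters must be calibrated externally; joint calibration,
  model-fit testing (Pearson $\chi^2$, RMSEA, information criteria) and
  marginal ML are out of scope.
* Estimators are MLE and the Bayesian mode only — no EAP, plausible
  values, or weighted-likelihood (Warm) correction.
* The ability-based corrected theta is a linear rule on the logit scale;
  other operationalisations of "informed guessing" exist and give
  different numbers for the same person.
* Corrected thetas have no standard error by construction.
* Dichotomous, unidimensional items only; no polytomous or
  multidimensional support, and no model-based response-time mixtures
  (lognormal mixture or hidden-Markov detection) — flagging is purely the
  percentile rule.
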