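# effortirt

Person ability estimation for binary test items when some examinees respond
rapidly rather than effortfully.

On multiple-choice and similar tests, a response given faster than the item
plausibly allows carries no information about ability: it is a rapid guess.
Scoring such responses as if they were effortful biases the ability estimate
downward (or upward, for lucky guessers). `effortirt` is for psychometricians
and test analysts who have item-level response data — optionally with
response times — and want theta estimates that account for rapid guessing.

## Models

For person $j$ with ability $\theta_j$ (logits) and item $i$ with
discrimination $a_i$ and difficulty $b_i$, the two-parameter logistic (2PL)
model is

$$P(Y_{ij}=1) = \frac{e^{a_i(\theta_j - b_i)}}{1 + e^{a_i(\theta_j - b_i)}}.$$

The 3PL adds a lower asymptote $c_i$ (pseudo-guessing), parameterised on the
logit metric as $\gamma_i$ with $c_i = e^{\gamma_i}/(1+e^{\gamma_i})$; a
$\gamma_i < -15$ is numerically a zero asymptote and recovers the 2PL. The
ability-based guessing model replaces $c_i$ with a person-level rate
$c_{ij} = e^{\gamma_i + k\theta_j}/(1+e^{\gamma_i + k\theta_j})$, so that
more able examinees guess more successfully (slope $k$, default 0.228).

The effort-moderated (EM) family gates these curves on a per-cell
solution-behavior flag $SB_{ij} \in \{0,1\}$:

$$P(Y_{ij}=1) = SB_{ij}\,P_i(\theta_j) + (1-SB_{ij})\,g, \qquad g = 1/\text{(number of options)},$$

with $P_i$ the 2PL or 3PL curve (`em2pl`, `em3pl`), or, in the
informed-guessing extension (`em2pl_informed`), with the rapid branch
$k\theta_j + g$ so rapid guessers earn ability-proportional credit. Flags
are derived from response times: a response at or below its item's 10th
percentile is rapid, the per-person mean of the flags is the
response-time-effort index $RTE_j = \sum_i SB_{ij} / J$, and persons with
$RTE$ below a cutoff (default 0.90) are classified rapid.

Theta is estimated per person by Newton–Raphson maximum likelihood (MLE;
zero-variance vectors take the boundary convention
$\theta = \pm\log(2J)$) or Bayesian modal estimation (BME; posterior mode
under a normal prior, default $N(0,1)$), with standard errors from the test
information function. Persons classified rapid can then be corrected: their
theta is replaced by $\mathrm{logit}(g)$ (random-guessing rule) or
$\mathrm{logit}(g) + k\hat\theta$ (ability-based rule).

## Worked example

Seven items with unit discriminations and difficulties −2, −1, −.5, 0, .5,
1, 2 logits; one person answered 1101110:

```r
library(effortirt)
items <- item_parameters(a = 1, b = c(-2, -1, -0.5, 0, 0.5, 1, 2))
y <- c(1, 1, 0, 1, 1, 1, 0)

mle_theta(y, items)
#> theta = 1.1972 (SE 0.9449), MLE/2pl
bme_theta(y, items)
#> theta = 0.6517 (SE 0.6653), BME/2pl
```

The MLE places this 5-of-7 vector at 1.20 logits; the BME shrinks it toward
the prior mean with a smaller standard error. If the person is judged a
rapid responder on a four-option test, the random-guessing correction
replaces the estimate with logit(1/4):

```r
cfg <- guessing_config(n_options = 4, correction = "random_guessing")
corrected_theta(mle_theta(y, items), rbe = 0, cfg)
#> theta = -1.0986 (SE n/a), MLE/2pl, corrected: random_guessing
```

A full sample with response times, scored under the effort-moderated 2PL
with automatic flagging and correction:

```r
d <- simulation_design(200, items, rapid_person_rate = 0.2, seed = 42)
sim <- simulate_dataset(d)
prof <- effort_profile(sim$times, percentile = 10, cutoff = 0.90)
prof
#> Effort profile: 200 persons x 7 items; 38 rapid (rbe = 0), mean RTE 0.900
est <- score_sample(sim$responses, items, method = "MLE", model = "em2pl",
                    effort = prof, cfg = cfg)
head(est, 2)
#>   person      theta        se method model correction converged n_iter at_boundary
#> 1      1  1.1971500 0.9449301    MLE em2pl       none      TRUE      6       FALSE
#> 2      2 -0.3800015 0.8767209    MLE em2pl       none      TRUE      6       FALSE
```

The 38 persons flagged rapid get the corrected theta −1.0986; the rest are
scored by the effort-moderated likelihood.

A command-line wrapper covers batch use from a shell
(`system.file("cli", "effortirt.R", package = "effortirt")`), with
subcommands `score`, `effort` and `simulate` over headered CSV files; see
`vignettes/effort-moderated-scoring.Rmd` for the file formats and the
methodological details.

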