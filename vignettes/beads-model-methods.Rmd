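---
title: "Modelling reflection impulsivity: the beads-task observer, hierarchical fitting, and the task battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reflection impulsivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reflectimp)
```

## The scientific problem

Reflection impulsivity is the tendency to commit to a decision on little
evidence. The classic probe is the beads task: beads are drawn one at a time
from one of two jars with complementary colour ratios (80:20 by default),
and the subject may view up to 20 beads before declaring a jar. The fewer
beads drawn, the more "jumping to conclusions". A companion probe is the
Information Sampling Task (IST), a 5×5 box-opening grid with a fixed-win
and a cost-per-sample (decreasing-win) reward schedule, and impulsive
discounting is measured with the 27-item Monetary Choice Questionnaire
(MCQ). This package implements the computational analysis of that battery:
a Bayesian observer model of the beads task with two free parameters,
hierarchical empirical-Bayes fitting over a cohort, deterministic scoring
of the IST and MCQ, the standard group statistics, and a synthetic-cohort
generator that makes every stage testable without access to participant
data.

## The observer model

The environment is fully known to the observer: jar A produces its majority
colour with probability $q$, jar B is the mirror image, and at most
$D_{\max}$ beads can be viewed. After $n_A$ beads of one colour and $n_B$
of the other the posterior is, by Bayes' rule,

$$P(A \mid n_A, n_B) =
  \frac{\pi_A\, q^{n_A} (1-q)^{n_B}}
       {\pi_A\, q^{n_A} (1-q)^{n_B} + (1-\pi_A)(1-q)^{n_A} q^{n_B}},$$

computed in log-odds form so that lopsided states at the 20-bead horizon
lose no precision. With a symmetric prior the posterior depends only on
$n_A - n_B$.

Declaring jar A is worth $p \cdot R_{\text{ok}} + (1-p) R_{\text{err}}$
(defaults 1 and 0, so all utilities are fractions of the declaration
reward). Sampling costs $C_s \ge 0$, the *subjective cost of sampling*, and
leads to a successor state weighted by the one-step predictive
$p q + (1-p)(1-q)$. Action values are solved by backward induction from the
forced declaration at $D_{\max}$ down to the empty state. Because the
horizon is finite, the implied declaration boundaries relax as the end of
the task approaches — the behavioural signature that distinguishes this
model from fixed evidence-threshold accounts.

Choices follow a softmax at temperature $T$, the *cognitive noise*:
$\pi(a) \propto e^{Q(a)/T}$. The value propagated to earlier depths is the
policy-weighted action value $\sum_a \pi(a) Q(a)$, not the maximum. This is
deliberate: under the expectation rule, a noisy chooser also *values* the
future less accurately, so $T$ simultaneously controls choice consistency
and how much cognitively distant outcomes influence the current decision —
high-noise agents therefore decide earlier, which is the mechanism linking
the parameter to reflection impulsivity. The soft-maximum
($T \log \sum_a e^{Q_a/T}$) alternative is available as
`beads_config(value_rule = "logsumexp")` but is off by default, since it
adds an exploration bonus that makes sampling *more* attractive as noise
grows, inverting that relationship. Both rules recover the ideal observer
as $T \to 0$.

`t = 0` is accepted as the exact deterministic limit: the policy is the
argmax of the action values, with ties broken by `tie_break`
(`prefer_sample` by default, which is what makes the zero-cost ideal
observer sample to the horizon). A vanishingly small positive temperature
cannot express a tie-break preference — softmax puts 1/2 on each tied
action — which is why the limit is implemented literally rather than by a
tiny `t`.

The first decision point comes *after* the first bead, so `draws` is at
least 1: the task flow presents a bead and then asks "draw again or
decide". The trial likelihood is the sum of log policy probabilities of
the observed actions — "sample" at each of the first `draws − 1` decision
points, the declared jar at the last — in nats throughout.

## Hierarchical fitting

Per-subject parameters $(C_s, T)$ are assumed drawn from gamma population
distributions, one per parameter, and fitted by empirical-Bayes
expectation-maximization:

* **E-step** — each subject's posterior over $(C_s, T)$ is represented on a
  fixed log-spaced grid, by default $40 \times 40$ over
  $C_s \in [10^{-4}, 0.5]$ and $T \in [0.01, 5]$. The grid is fixed across
  subjects and iterations, so the expensive part — one backward induction
  per grid node — is computed once (`policy_grid()`) and reused for every
  subject, EM iteration, and replicate cohort. Posterior masses use
  midpoint-rule cell areas; the MAP maximises the joint density, ties
  resolved toward the smallest $C_s$, then the smallest $T$.
* **M-step** — gamma maximum likelihood from the pooled posterior-weighted
  means and mean-logs, solving $\log s - \psi(s) = \log \bar{x} -
  \overline{\log x}$ by safeguarded root finding. Exact conjugacy does not
  exist for the gamma shape, hence the root solve; if the pooled moments
  are degenerate (all mass on one node) the update falls back to moment
  matching with the shape capped at $10^8$ and a warning, which `fit_em()`
  collects into `fit$notes` rather than repeating per iteration.

Convergence is declared when all four hyperparameters change by less than
$10^{-3}$ relatively (at most 200 iterations; non-convergence is a flag,
not an error — with only three trials per subject the weakly identified
$C_s$ shape can drift slowly without affecting the noise estimates). The
grid-quadrature log marginal likelihood is recorded per iteration and is
non-decreasing up to quadrature tolerance, which the tests assert.

The model-fit metric reported per subject is the log probability of the
subject's choices at the MAP parameters divided by the number of decision
points (actions). Natural logs are used; the phrase "per draw" is read as
per action, and no published value is asserted against it.

Subjects whose draws equal the horizon on *every* trial are plausibly
running a "sample everything" heuristic rather than prospective valuation;
`exclude_max_draw_subjects()` implements the conservative reanalysis that
removes them, and `run_pipeline()` always reports both the all-subjects
fit and the refit after exclusion.

## Task scoring

**IST.** $P(\text{correct})$ treats every unopened box as an independent
fair coin — the task's generative split is close to 50:50 — and returns
the exact binomial tail probability that the chosen colour reaches 13 of
the 25 cells; with at most 24 unopened cells all quantities are exact in
double precision. Points follow the two published schedules (flat 100;
250 minus 10 per opened box, floored at 0), with the incorrect-decision
penalty (default 100) configurable because the instrument's loss side is
not printed with the win schedule. Errors are classified as *sampling*
(wrong decision consistent with the opened-box majority, ties included)
versus *discrimination* (wrong decision against the opened evidence),
following the instrument's literature; the pipeline reports the
sampling-error rate.

**MCQ.** Each of the 27 items defines an indifference rate
$k^* = (\text{delayed}/\text{immediate} - 1)/\text{delay}$ under hyperbolic
discounting $V = A/(1 + kD)$. The assigned $k$ is the candidate boundary
whose implied choice pattern agrees with the responses on the most items,
ties resolved by the geometric mean of the maximisers; consistency is the
maximal agreement divided by 27. The canonical item amounts ship as an
editable CSV (`inst/extdata/mcq_items.csv`) — data, not code. Note that a
discounter steeper than the largest boundary cannot be assigned a
perfectly consistent candidate (the boundary item itself disagrees), so
perfect-recovery properties hold on the interior of the candidate range.

**Group statistics.** Outliers beyond 3 SD of their own group mean are
removed in a single pass (zero-SD groups remove nothing). Beads and IST
sampling outcomes are square-root transformed and the discount rate is
log10-transformed before two-sided pooled-variance t-tests (Welch by
flag); the IST secondary outcomes enter a 2×2 mixed ANOVA (between:
group; within: reward condition) on their raw scale, since the transform
convention for those outcomes is not specified by the source battery; the
fitted noise parameter is compared by Wilcoxon rank-sum (the normal
approximation is used automatically when grid-valued MAPs tie); severity
covariates are correlated with raw beads draws by Pearson. Transformed
values are computed on the fly, so the original scale is always
preserved.

## The synthetic cohort

`cohort_spec()` encodes the emulated study: 30 + 30 subjects, three beads
trials each, and group populations
$C_s \sim \Gamma(\text{mean } 0.02, \text{sd } 0.01)$ in both groups,
$T \sim \Gamma(0.25, 0.12)$ for healthy volunteers versus
$\Gamma(0.6, 0.35)$ for binge drinkers — the clinical group has the
higher, more variable noise, and the cost of sampling is small and
identical, so any group difference in sampling is attributable to noise.
IST agents open boxes until the opened-colour margin reaches a
per-subject threshold (mean 5, SD 1.5), reduced by a cost-sensitivity of
2 under the decreasing-win schedule; boards carry a 13–17 majority drawn
uniformly. MCQ agents discount hyperbolically with log-normal $k$
(identical across groups — the emulated study found no group difference
in discounting) and logistic choice noise on the value difference. A
severity covariate is drawn per group (means 4 vs 16) with a 0.3
correlation to the generating noise. Everything is a deterministic
function of the spec's seed.

What the generator does *not* emulate: real bead orders (unpublished, so
sequences are drawn i.i.d. from the true jar), confidence ratings (stored
as the posterior of the declared jar, never modelled), questionnaire item
responses, serial dependence across trials, and any model mismatch — the
beads data are generated by the fitted model itself. Passing recovery
tests therefore demonstrates that the estimation machinery is correct and
well-calibrated at study scale, not that the model is the true account of
human sampling.

Three trials per subject (the realistic block structure) identify the
population contrast but not individual parameters; recovery studies in
the tests and acceptance suite use 20 trials per subject, following the
package's own sizing rule, with 52 subjects (24 + 28 where the two-group
design is emulated — the analysed sizes after the conservative
exclusion). Under the generator's conditions mean draws are low (roughly
1.6–3.5 across the plausible noise range), so a subject at the horizon on
every trial is several SDs from the group mean; the pipeline's outlier
pass therefore skips always-at-horizon subjects, leaving them to the
dedicated exclusion rule that reports them explicitly.

## Numerical choices and degenerate inputs

* All probability arithmetic in log space; likelihoods in nats.
* Softmax rows are max-stabilised; unavailable actions carry $-\infty$
  log-probability, so the terminal sampling probability is exactly 0.
* Exact ties at $T = 0$ are resolved with a $10^{-12}$ tolerance in the
  configured preference order.
* The E-step grid bounds clip genuinely extreme subjects to the boundary
  nodes; widen `param_grid()` if MAPs pile up at an edge.
* Empty cohorts, missing columns, out-of-range draws, duplicate opened
  cells, non-positive discount rates under log10, and subjects missing
  from one table all produce located diagnostics or typed errors rather
  than silent propagation.

## Problem sizes used by the test and acceptance suites

Oracle-equivalence checks run at horizons 3–6, where exhaustive recursion
and path enumeration are feasible; recovery simulations use 52 subjects ×
20 trials with 20 seeded replicates; the end-to-end pipeline checks use
the default 60-subject cohort. These sizes were chosen so the full
validation runs comfortably on a laptop while keeping every statistical
claim at its stated replicate count.

## Known limitations

* The E-step is a grid, not a Laplace approximation or MCMC: posterior
  summaries inherit grid resolution, and MAPs are grid-valued (ties in
  rank tests are expected and handled).
* $C_s$ is weakly identified when small — the very regime the emulated
  study reports — so its population SD should be read qualitatively.
* The IST agent is a stopping-threshold heuristic, not an ideal observer
  of the grid; it exists to generate realistic-looking records, not to be
  fitted.
* The feedback variant of the beads task (monetary reward per correct
  declaration) is treated as the same model.
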