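---
title: "Constructing and validating a utility-balanced discrete choice experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and validating a utility-balanced discrete choice experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcekit)
```

## The problem

Discrete choice experiments (DCEs) elicit preferences by asking respondents
to choose repeatedly among hypothetical alternatives described by a common
set of attributes. dcekit was built around a nurse job-preference
instrument: nine job attributes — six with two levels and three with three
levels — describing salary, commute, working hours, vacation, care quality,
overtime, shift-plan influence, leadership support and bonus shifts. The
full factorial of that instrument contains `2^6 * 3^3 = 1728` hypothetical
jobs, far more than anyone can evaluate, so a fractional design of 18
choice sets with three generic alternatives ("Job A/B/C", forced choice)
is selected by optimizing a statistical criterion.

The package covers the whole workflow: instrument definition, constrained
D-efficient design search, design diagnostics, blocking, a
dominant-alternative consistency test, respondent simulation, and
conditional logit estimation with odds-scale reporting.

## Design criterion and constraints

Under the multinomial logit (MNL) model, the information a design carries
about the utility coefficients $\beta$ is

$$ I(\beta) \;=\; \sum_{s} X_s' \left( \mathrm{diag}(\pi_s) - \pi_s \pi_s' \right) X_s, $$

where $X_s$ is the effect-coded matrix of the $J$ alternatives in choice
set $s$ and $\pi_s$ their MNL choice probabilities. The D-error is
$\det(I)^{-1/p}$ with $p$ the number of parameters; an efficient design
minimizes it. With zero prior coefficients — the default, appropriate when
no earlier estimates exist — every within-set probability is $1/J$ and the
information reduces to a closed form that the implementation exploits for
fast candidate evaluation.

Raw D-efficiency ignores two behavioural problems. A choice set containing
a *dominant* alternative (at least as attractive on every attribute,
strictly better on one, against every competitor) reveals nothing about
trade-offs; and sets whose alternatives differ wildly in overall
attractiveness are nearly as uninformative. Both are operationalized
through a per-level point scheme: each level carries 0 points (least
attractive) to 1 point (most attractive) within its attribute, so a
profile's total score ranges from 0 to 9 on the nurse instrument. The
search enforces, per choice set, a score gap (max minus min) of at most
4.5 points — half the ceiling — and the absence of any dominant
alternative.

### The search

`search_design()` uses two nested loops. The inner loop seeks efficiency:
each set is initialised with randomly drawn constraint-satisfying profiles
from the candidate pool (the full factorial by default), then improved by
coordinate exchange — one alternative at a time is swapped against pool
candidates, accepting only swaps that raise $\log\det I$ while keeping the
set feasible. The outer loop independently re-verifies the balance and
dominance constraints on the finished candidate and discards and
regenerates it if either fails; the best feasible design over
`n_random_starts` restarts is returned. The incumbent D-error is
non-increasing within a run, and a run is fully reproducible from its
seed.

Attribute-level balance is treated as a hard constraint as well. The
number of sets (18) is chosen divisible by every level count precisely so
that each level can appear equally often; the search repairs the initial
design towards balance and restricts exchanges so that every level's count
stays within `level_balance_cap` (default 1 profile) of its ideal
$S \cdot J / L$. On the nurse instrument this costs essentially nothing:
the balanced constrained optimum reaches the same D-error (≈ 0.078) as
the unconstrained exchange, while guaranteeing that the 54 profile rows
split 27/27 (±1) and 18/18/18 on two- and three-level attributes.

Degenerate inputs are handled explicitly: a singular information matrix
(Cholesky diagonal ratio below `1e-12`, e.g. duplicate-profile sets) is
scored as infinitely bad rather than erroring, so the exchange can move
past it; an infeasible constraint configuration (say, a zero gap threshold
on an instrument without score ties) stops with a classed
`dce_infeasible` error, and an exhausted outer loop returns the best
design found, flagged `feasible = FALSE`, under a warning of the same
class.

### Effect coding

Each $L$-level attribute contributes $L-1$ columns. The *least attractive*
level is the reference: it codes $-1$ in all of the attribute's columns,
while non-reference level $k$ codes $+1$ in its own column. The reference
choice is a convention — efficiency and fitted probabilities are invariant
to it — but anchoring at the least attractive level makes every
main-effect coefficient expected-positive, which keeps odds-ratio
summaries and forest plots readable. On the full factorial the coding is
exactly balanced (columns sum to zero) and orthogonal *between*
attributes; columns within a 3-level attribute are correlated by
construction ($r = 0.5$ on the factorial), which is why the diagnostics
report between-attribute and overall correlations separately.

## Diagnostics, blocking and the consistency test

`design_report()` reproduces the standard design checks: pairwise Pearson
correlations of the effect-coded columns over the 54 profile rows
(orthogonality, warn — never fail — above a configurable 0.3), level
frequencies and proportions (balance, tolerance 1 profile), per-set score
gaps and per-set dominance flags. Diagnostics are pure functions of the
design and serialize losslessly to JSON.

`block_design()` splits the 18 sets into two blocks of nine so each
respondent faces a manageable survey. Following the "randomly selected
while maintaining level balance" recipe, it rejection-samples random
equal-size partitions until each block's per-level counts deviate from the
block ideal by at most a tolerance (default 1 profile); the draw is
seeded, and an unattainable tolerance returns the best partition found
under a classed warning rather than failing silently. Rejection sampling
was chosen over deterministic optimization because the procedure is
explicitly a *random* selection subject to a balance screen.

`consistency_set()` builds the comprehension screen shown to every
respondent as the first task: alternative 1 holds the most attractive
level of every attribute and therefore dominates; the remaining
alternatives are strictly worse everywhere (on the nurse instrument the
score gap is the maximal 9.0). The set is exempt from the balance rule,
never enters the efficiency search, and is estimation-poisonous by
design — the fitter refuses any panel still containing it.

## Simulated respondents

Because the package must be testable without human data,
`simulate_panel()` generates synthetic panels under a mixture of
behaviours:

* **utility maximizers** draw $U_j = \lambda\, x_j'\beta + \varepsilon_j$
  with i.i.d. standard Gumbel $\varepsilon$ — exactly the MNL
  data-generating process the conditional logit assumes, so parameter
  recovery is a well-posed check. The scale $\lambda$ (default 1)
  interpolates between uniform choice ($\lambda \to 0$, or $\beta = 0$)
  and deterministic choice ($\lambda \to \infty$).
* **random responders** choose uniformly — they pass the consistency test
  at rate $1/J$;
* **lexicographic responders** always take the best level of one focal
  attribute, ties broken uniformly — a common simplifying heuristic in
  real panels.

Respondents alternate deterministically between blocks (a balanced,
reproducible stand-in for uniform randomization), answer the consistency
set first, and may optionally drop out partway (`dropout_rate`) to
exercise the incomplete-response exclusion path in the reader.

What the simulator deliberately does *not* emulate: preference
heterogeneity across respondents (a mixed logit generator would be needed
to stress that), attribute non-attendance, ordering or fatigue effects,
and sociodemographic covariates. Passing recovery tests therefore show
that the estimator inverts its own data-generating process on realistic
design geometry — not that real nurses behave like the simulator.

## Estimation

`fit_conditional_logit()` maximizes the grouped conditional logit
log-likelihood

$$ \ell(\beta) = \sum_i \left[ x_{c_i}'\beta - \log \sum_{j=1}^{J} \exp(x_{ij}'\beta) \right] $$

(one stratum per respondent-set pair) by Newton-Raphson with step halving
from $\beta = 0$, stopping when the gradient norm falls below `1e-8`. The
likelihood is implemented directly rather than through the Cox
partial-likelihood trick because the forced-choice, fixed-$J$ structure
makes the direct form exact and simple; `survival::clogit` serves as an
independent cross-check in the test suite, and a separate
direct-summation evaluator (`loglik_direct()`) validates the optimizer's
vectorised objective to near machine precision. Concavity guarantees a
unique maximum whenever the MLE exists; separation is reported as a
non-convergence flag with diagnostics, never a silent estimate. Standard
errors come from the inverse observed information; Wald intervals default
to 95% (the level is a parameter). No respondent-level clustering
correction is applied by default, matching plain conditional logit
reporting.

`odds_summary()` and `plot()` present $\exp(\beta)$ per non-reference
level with intervals, grouped by attribute and sorted within attribute —
the forest-plot layout conventional for DCE attribute effects. Reference
levels sit at odds 1 by convention.

## Numerical and scope choices

* **Problem sizes in the tests.** Parameter-recovery checks use 50
  replicates of 400 simulated respondents (plus 8-seed batches at
  n = 50/200/800 for the RMSE trend); consistency-rate checks use 900
  random responders with four-sigma binomial bands. These sizes give the
  Monte-Carlo checks comfortable power while keeping the suite quick.
* **Exhaustive oracles.** On toy spaces small enough to enumerate every
  possible design, the search is required to hit the enumerated optimum
  exactly. Those comparisons disable the dominance filter and the
  level-balance cap: on a 2-binary-attribute pool only a single
  non-dominated pair exists, so the constrained design class is empty and
  the comparison would be vacuous.
* **"More alternatives help"** is a heuristic, not a theorem: on the
  saturated 2-attribute toy the J=2 optimum (D-error 0.5) beats J=3
  (0.5625), while on a 3-attribute toy with two sets J=2 cannot identify
  the parameters at all and J=3 can. The package's test encodes the
  latter, well-posed instance.
* **Balance-gap reading.** "No alternative exceeds another by more than
  4.5 points" is enforced as the per-set max-minus-min gap; for scalar
  scores all pairwise readings coincide.
* **Ties and duplicates.** Duplicate profiles within a set and duplicate
  choice sets across the design are forbidden outright: they contribute
  no information and make dominance ill-defined.

## Known limitations

Bayesian D-efficient designs with empirical priors are out of scope, as
are fully integrated utility-balanced search criteria (the balance rule
here is a hard constraint on an otherwise standard D-efficiency search),
interaction effects, continuous attribute coding, mixed logit and
willingness-to-pay transformations. The coordinate exchange is a local
search: the returned design is the best over its restarts and provably
optimal only where enumeration is possible.
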