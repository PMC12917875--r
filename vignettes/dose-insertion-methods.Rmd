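---
title: "Mid-trial dose insertion for dual-agent dose finding: models and methods"
author: "mtcinsert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mid-trial dose insertion for dual-agent dose finding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtcinsert)
```

## The problem

Phase I combination trials escalate through a prespecified I x J grid of dose
pairs of two agents, looking for the maximum tolerated dose combination — the
pair whose dose-limiting-toxicity (DLT) probability is closest to a target
$\theta$ (0.30 throughout). Because the grid is fixed before any data are
seen, it can happen that *no* combination on it is close to $\theta$: every
cell is either clearly subtherapeutic or clearly toxic. `mtcinsert`
implements a formal mid-trial remedy: monitor the posterior over *maximum
tolerated contours* (MTC) — the monotone partitions of the grid into cells
below and above $\theta$ — and, when one contour becomes sufficiently
probable, insert new dose levels at the midpoints the contour crosses.

## The contour model

Each combination's toxicity $\pi_{ij}$ carries an independent
Beta$(a_{ij}, b_{ij})$ prior; with $y_{ij}$ DLTs in $n_{ij}$ patients the
posterior is Beta$(a_{ij}+y_{ij},\, b_{ij}+n_{ij}-y_{ij})$ and
$p_{ij} = P(\pi_{ij} \le \theta \mid \text{data})$ is a beta CDF
(`below_target_prob()`). A *contour* is a binary monotone matrix $C$ (1 =
above the MTC); monotonicity makes the number of eligible contours
$\binom{I+J}{I}$ — 20 on a 3 x 3 grid (`enumerate_contours()`). The posterior
probability of each contour is

$$P(\mathrm{MTC} = C \mid \text{data}) \propto
  \prod_{i,j} (1-p_{ij})^{C[i,j]}\, p_{ij}^{\,1-C[i,j]},$$

normalised over the full set (`contour_distribution()`). An insertion is
*triggered* when the modal contour's probability strictly exceeds a threshold
$\lambda$; $\lambda = 1$ disables insertions and $\lambda < 0.5$ is not
recommended, since two contours can then be near-equally supported precisely
because some $\pi_{ij}$ is close to $\theta$ — the case where treating more
patients beats inserting. New levels go at the midpoint of every adjacent
level pair the modal contour crosses (`insertion_candidates()`), never
outside the original dose range, so the grid is bounded by
$(2I_0-1) \times (2J_0-1)$ and at most $I_0+J_0-2$ levels can ever be added.
Insertions are confined to a window of 18–42 treated patients (of 48) and to
one timepoint per trial; both are configurable (`design_config()`).

## Prior parameterisation: medians, not means

The calibrated prior centres rise linearly from 0.05 at the lowest
combination in steps of 0.025 (`pipe_prior()`), with a shared prior sample
size $s = 1/(IJ)$ that shrinks when the grid grows. The hyperparameters are
derived by **median matching**: solve $a+b=s$ with
$P(\pi \le m) = 0.5$ (`beta_from_median()`). This is a deliberate and
consequential choice. With $s$ this small the prior is bimodal, and

* an untested combination has $P(\pi \le \theta) \approx 0.52$–$0.55$ —
  essentially *neutral*, so contours and the overdose rule are driven by
  data;
* its posterior *mean* sits near 0.45, matching the behaviour of the
  original product-of-independent-beta-probabilities (PIPE) software.

The naive mean-matching alternative ($a = ms$) makes every untested cell
look safe with probability $\approx 1-m \approx 0.9$. Those optimistic cells
then anchor the contour posterior from above: a combination observed with
2/3 DLTs can still have a contour-averaged overdose probability near zero,
because calling it toxic would force the monotone contour to also call the
(optimistically believed safe) cells above it toxic. The overdose rule is
then inert and the design cannot reproduce sensible exposure patterns.
Mean matching remains available via `design_config(prior_param = "mean")`
for sensitivity analyses.

A related note on the conjugate update: the posterior is
Beta$(a+y,\, b+n-y)$. (One sometimes sees the first shape written with $n$
in place of $y$; that form is not a conjugate update and contradicts the
noninformative-prior behaviour above, so it is not offered.)

## The PIPE host design

After each cohort the contour posterior is re-estimated and drives three
decisions:

* **Safety.** The contour-averaged overdose measure
  $q_{ij} = \sum_s C_s[i,j]\, P(\mathrm{MTC}=C_s)$ bars any combination with
  $q_{ij} \ge \varepsilon$ (default 0.5); the trial stops if the lowest
  combination fails (`overdose_measure()`, `pipe_admissible()`).
* **Allocation.** Candidates are restricted to combinations within one dose
  level of a previously treated combination, excluding simultaneous
  escalation of both agents. One candidate is drawn with probability
  proportional to $1/(n_{ij} + s)$ — inverse sample size, with the prior
  sample size keeping untested cells finite (`pipe_next_dose()`).
* **Selection.** At the end, among combinations *closest to below* the final
  contour estimate with at least six patients, the one whose posterior mean
  toxicity is nearest $\theta$ is selected, ties broken at random
  (`pipe_select_final()`).

Two allocation phases are distinguished, and this is the package's main
interpretive choice (`adjacency_phase`). *Before* an insertion the candidate
set is the whole safe neighbourhood: with weak neutral priors, the
weighted randomisation then spreads cohorts widely, which is both what the
reference exposure patterns show and a precondition for the trigger — the
contour posterior can only concentrate once every cell, including interior
ones, carries decisive data. (Filtering candidates to the estimated
contour's frontier throughout starves interior cells, and in staircase
toxicity landscapes the trigger then fires in ~2% of trials instead of
~30%.) *After* an insertion the contour is, by construction of the trigger,
well identified; candidates are then filtered to cells adjacent to it, and
the design keeps preferring combinations that involve a new level whenever
its own rules admit one (`persist_restrict = TRUE`). With a
single-next-cohort restriction instead, the inserted combinations
accumulate roughly half as many patients and are rarely selectable; the
persistent preference reproduces the reference exposure on acceptable
combinations. Both switches are configurable for sensitivity analyses.

## The logistic-model host design

The second host is a five-parameter Bayesian logistic model: single-agent
toxicities $\psi_A = \mathrm{logit}^{-1}(\alpha_1 + \alpha_2 \tilde d_A)$
and $\psi_B$ likewise, combined without interaction as
$p^\dagger = 1-(1-\psi_A)(1-\psi_B)$ and modified by an interaction odds
multiplier

$$\mathrm{odds} = \mathrm{odds}^\dagger \times
  \exp\{\eta \log(1 + e^{\tilde d_A} e^{\tilde d_B})\}$$

(`joint_tox_prob()`; the classical $\exp(\eta \tilde d_A \tilde d_B)$ form
is available via `blrm_interaction = "classical"`). Standardized doses are
(0.10, 0.25, 0.40) per agent, with midpoint interpolation for inserted
levels; operational priors are normal on
$(\alpha_1, \log\alpha_2, \beta_1, \log\beta_2, \eta)$ with means
$(-2, 0.5, -2, 0.5, 0)$ and variances $(10, 0.25, 10, 0.25, 0.25)$.
Sampling is by componentwise random-walk Metropolis with burn-in step
adaptation plus an adaptive joint move along the empirical posterior
covariance (2000 retained draws after 1000 burn-in; split R-hat above 1.1
raises a warning but still returns). Escalation follows patient gain —
the admissible combination with estimated toxicity closest to $\theta$ from
below, using the plug-in estimate (posterior parameter means substituted
into the model) by default — under escalation-with-overdose-control:
$P(\pi_{ij} > 0.33) \le 0.40$, plus the same neighbourhood rule. If no
admissible combination has an estimate at or below $\theta$, the smallest
estimate is used (the "closest from below" rule is otherwise undefined);
when nothing is admissible the trial terminates. The insertion machinery is
identical for both hosts: it runs on the beta framework, before any
escalation decision.

## Alternative insertion rules

Two interval-based rules are provided for comparison
(`insertion_rule = "alt1"` / `"alt2"`), both built on
$P(\pi_{ij} \in [0, 0.16))$ and $P(\pi_{ij} \in (0.33, 1])$ with
monotonicity enforced by clamping each cell to its lower neighbours
(`interval_probs()`). Rule 1 triggers when *every* combination is
confidently outside the acceptable band (each exceeds its cutoff for
underdosing *or* overdosing; the literal per-cell conjunction is
unsatisfiable for cutoffs at or above 0.5 since the two region
probabilities cannot sum beyond 1, and is kept only behind
`strict = TRUE`). Rule 2 triggers when some combination looks confidently
underdosed while an adjacent escalation looks confidently overdosed, and no
tested combination has an observed DLT rate inside $[1/6, 1/3]$. Calibrated
cutoffs are $C_1 = C_2 = 0.7$ (rule 1) and $0.6$ (rule 2). Insertion
locations scan for under/over steps between adjacent levels and feed the
same grid-expansion code as the contour rule.

## Simulation engine and what the generator does (not) emulate

`run_trial()` simulates one trial: per-patient Bernoulli outcomes at the
current combination's true toxicity, posterior update, insertion check
(window, rule), then escalation; `run_study()` replicates it with seeds
`base_seed + 1, ..., base_seed + n_reps`, so different thresholds share
outcome streams rep-for-rep (common random numbers) while reps stay
independent. Everything is reproducible from
(scenario, design, rule, config, seed); at $\lambda = 1$ the engine is
bitwise identical to disabling the insertion module.

True-toxicity scenarios are monotone matrices; the built-in ones (A1–A3,
Z1–Z2) are landscapes where no original combination is acceptable (A) or
calibration extremes (Z). Inserted levels receive midpoint-interpolated
true toxicities (four-diagonal means at new-row x new-column cells), which
preserves monotonicity exactly. This generator emulates the idealised
setting of design evaluation: exchangeable patients, instantly observed
binary DLTs, true toxicities constant in time, and interpolated truths that
land exactly halfway between neighbours. It does not emulate late-onset or
graded toxicities, patient heterogeneity, accrual gaps around an insertion,
or real dose-toxicity curves whose midpoint dose need not have midpoint
risk — so passing operating-characteristic checks here says the *decision
rules* behave as intended, not that a real trial's inserted dose will be
acceptable.

Operating characteristics (`summarize_trials()`) classify the selected
combination by its true toxicity — subtherapeutic $[0, 0.16)$, acceptable
$[0.16, 0.33]$, correct $[0.275, 0.325]$ (a subset of acceptable), toxic
$(0.33, 1]$ — with all trials (including non-selecting ones) in the
denominator. The accuracy index
$100 - 100\, I J \sum (\pi_{ij}-\theta)^2 \rho_{ij} / \sum (\pi_{ij}-\theta)^2$
is computed with the normalising sum and the factor $IJ$ fixed on the
original grid while selections of inserted combinations contribute their
interpolated truth — this keeps runs with and without insertions on one
scale (an expanded-grid normalisation would change the index of the
no-insertion reference). The utility index is
$\mathrm{PCS} + \mathrm{PAS} - 2\,\mathrm{PTS}$.

## Case-study replay

`replay_case_study()` reruns either host on a reduced 3 x 3 grid of a
published neratinib x temsirolimus trial. Fixed per-combination response
streams make the comparison fair: the observed outcomes come first in a
random permutation (the same permutation for both designs at the same
seed), later patients draw individual DLT risks from
Beta$(1+y, 1+n-y)$, and combinations never tested in the source study use
Beta$(3,3)$ — centred at 0.5 to reflect that they were avoided for cause.
For combinations created mid-trial by an insertion the source study has no
data at all; their streams draw risks from Beta$(1+\bar y, 1+\bar n-\bar y)$
with $\bar n, \bar y$ midpoint-interpolated from the flanking
combinations' observed totals, the same interpolation the truth expansion
uses.

## Numerical choices and degenerate inputs

* Beta CDFs are exact (`pbeta`); no Monte Carlo enters the contour layer.
* Contour weights are computed in log space; inputs with $p_{ij}$ exactly 0
  or 1 fall back to direct products with $0^0 = 1$, and a fully conflicting
  pattern (all weights zero) raises an error rather than returning noise.
* Contour sets are enumerated once per shape, cached, and canonically
  ordered (lexicographic on row-major flattening); argmax ties break to the
  first index, making runs reproducible.
* Median-matching roots are solved to 1e-12 and cached per (centre, sample
  size).
* Ties in patient-gain escalation break by column-major index order
  (deterministic); ties in PIPE selection break uniformly at random, as
  specified for the single-selection modification.

## Problem sizes used in the shipped checks

The package's own test suite regenerates everything it asserts: exhaustive
contour enumeration is cross-checked against brute force up to 3 x 3
(512 matrices) and by the count formula up to 5 x 5; replicated studies use
1000 trials per scenario/threshold for operating characteristics and
40–400 where only qualitative behaviour is asserted; the logistic-model
recovery check uses 480 patients per combination and one 3000-iteration
chain. These sizes were chosen so that Monte-Carlo standard errors
(≈1.5 percentage points on a selection proportion at 1000 reps) sit well
below the differences that matter.

## Known limitations

* Insertion rates and downstream selection quality in staircase landscapes
  (toxicity rising only at the far corner) are sensitive to how quickly the
  whole grid accumulates decisive data; with the default window, triggers
  there fire in roughly a third of trials, and published figures for such
  landscapes sit somewhat higher than this engine produces. The exposure
  profiles and the no-insertion reference case reproduce closely.
* Selection of an inserted combination whose true toxicity is just below
  $\theta$ is capped by a knife-edge: small-sample records like 2/6 DLTs
  put such a cell marginally above the estimated contour, and no selection
  rule that also preserves the no-insertion safety profile recovers these.
* Only two agents; only midpoint insertions; no extrapolation beyond the
  original dose range; continuous-dose insertion is out of scope.
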