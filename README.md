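# mtcinsert

Mid-trial dose-level insertion for dual-agent phase I dose-finding trials.

Phase I combination trials escalate through a prespecified I × J grid of dose
pairs, aiming for the maximum tolerated dose combination — the pair whose
dose-limiting-toxicity (DLT) probability is closest to a target θ (0.30 by
default). When no combination on the initial grid is close to θ, the trial is
set up to fail before it starts. `mtcinsert` implements a formal remedy for
biostatisticians designing or evaluating such trials: monitor the posterior
distribution over **maximum tolerated contours** (MTC) — the monotone
partitions of the grid into combinations below and above θ — and insert new
dose levels mid-trial once one contour is identified with enough certainty.

The core quantities, for independent beta-binomial posteriors with
p<sub>ij</sub> = P(π<sub>ij</sub> ≤ θ | data):

- contour posterior: P(MTC = C | data) ∝ ∏<sub>ij</sub>
  (1 − p<sub>ij</sub>)<sup>C[i,j]</sup> p<sub>ij</sub><sup>1 − C[i,j]</sup>,
  normalised over all binomial(I+J, I) monotone binary matrices C;
- insertion trigger: max<sub>C</sub> P(MTC = C | data) > λ, with new levels
  at the midpoints the modal contour crosses (λ = 1 disables insertions);
- overdose measure: q<sub>ij</sub> = Σ<sub>C</sub> C[i,j] · P(MTC = C | data),
  barring combinations with q<sub>ij</sub> ≥ ε.

The insertion machinery is embedded in two host escalation designs — the
model-assisted PIPE design (contour-guided weighted randomisation) and a
five-parameter dual-agent Bayesian logistic regression model with
escalation-with-overdose-control — plus two alternative interval-probability
insertion rules, a seeded simulation engine for operating characteristics,
and a replay of a published neratinib × temsirolimus case study.

## A worked example

Simulate one PIPE trial under a hostile truth (no acceptable combination in
the starting 3 × 3 grid) with the contour insertion rule at λ = 0.6:

```r
library(mtcinsert)

scen <- load_scenario("A1")
scen
#> Scenario A1 (rows = Agent A, cols = Agent B):
#>      [,1] [,2] [,3]
#> [1,] 0.10 0.45 0.50
#> [2,] 0.45 0.50 0.60
#> [3,] 0.50 0.60 0.65

run_trial(scen, design = "pipe", insertion_rule = "mtc",
          config = design_config(lambda = 0.6), seed = 3)
#> Trial result (completed, n = 48)
#> Selected combination at levels (1, 1.5) [inserted]
#> True toxicity 0.275 (correct)
#> Insertion at cohort 6
#> Trial state on a 4 x 4 grid ( 48 patients, 10 DLTs )
#>       1    [1.5] 2   3
#> 1     0/12 4/27  2/3 0/0
#> [1.5] 2/3  0/0   0/0 0/0
#> 2     2/3  0/0   0/0 0/0
#> 3     0/0  0/0   0/0 0/0
```

After 18 patients the contour separating d<sub>11</sub> (true toxicity 0.10)
from its neighbours (0.45+) exceeded λ, so a level of each agent was inserted
at the bracketed midpoints `[1.5]`; the trial then concentrated on the new
combinations and selected one with true toxicity 0.275 — inside the correct
band [0.275, 0.325] that the original grid never contained.

Replicated operating characteristics:

```r
run_study("A1", lambda = 0.6, n_reps = 200, base_seed = 1)
#> Operating characteristics, scenario A1 (200 trials)
#>   PCS 20.0%  PAS 20.0%  PSS 57.5%  PTS 18.0%  none 4.5%
#>   insertions 46.5%  accuracy index 31.6  utility index 4.0
#>   mean patients on acceptable 7.5, on toxic 20.9
```

Without insertions (λ = 1) the acceptable-exposure line is exactly 0 in this
scenario — there is nothing acceptable to treat on. The case-study replay is
one call: `replay_case_study("pipe", lambda = 0.6, seed = 2)`.

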