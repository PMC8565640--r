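---
title: "Methods: deriving and stress-testing a CAA prioritisation framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving and stress-testing a CAA prioritisation framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caaprior)
```

`caaprior` packages the quantitative machinery of a multi-criteria
prioritisation framework for elective coronary artery angiography (CAA):
modified-Delphi factor selection, analytic-hierarchy-process (AHP) factor
weighting, a 100-point weighted additive patient score with urgency tiers,
and a waiting-list simulator that compares priority scheduling against
first-come-first-served (FIFO). This vignette explains each model, its
assumptions, and the design choices made where the methodology is genuinely
open.

## The scoring model

A patient's priority is a weighted additive score over seven factors.
Factor $i$ carries weight $w_i$ (the $w_i$ sum to 1), a physician assigns
an integer score $s_i \in \{0, \dots, 10\}$, and the total is

$$T = 10 \sum_{i=1}^{7} w_i s_i \in [0, 100].$$

Additivity assumes the factors contribute independently to urgency — the
usual (and strong) assumption of weighted-sum multi-criteria models; it is
what makes the score auditable factor by factor.

Two readings of the physician score scale circulate for frameworks of this
family: 1–10 and 0–10. We adopt 0–10 because the published per-factor point
ranges start at 0 (e.g. 0–22 for the top-weighted factor), which requires a
zero score to be attainable; a 1–10 variant is a one-line change
(`framework_config(..., score_min = 1)`).

Tier bounds are inclusive at the lower edge: $T \ge 80$ is tier 1 (seen
within 4 weeks), $50 \le T < 80$ tier 2 (8 weeks), otherwise tier 3. The
third tier's "three to four months" target is rendered as 16 weeks by
default and is configurable. Tier assignment always uses the unrounded
total; totals are only rounded for display.

Ranking ties are not addressed by scoring alone, so `rank_waitlist()`
breaks them deterministically: higher waiting-time factor score first, then
earlier referral date, then patient id. The ranking is therefore a pure
function of the roster — re-ordering the input can never re-order the list.

## AHP weighting

Experts compare factors pairwise on the Saaty 1–9 ratio scale; entry
$a_{ij}$ of the comparison matrix estimates $w_i / w_j$ and
$a_{ji} = 1/a_{ij}$. `derive_weights()` returns the L1-normalised principal
right eigenvector, computed by power iteration on the raw matrix with L1
normalisation at every step, stopping when successive iterates differ by
less than $10^{-12}$ in the max norm (cap 10,000 iterations). For a
positive matrix the Perron–Frobenius eigenvalue is simple, so power
iteration converges geometrically; the eigenvalue is recovered as
$\lambda_{\max} = \mathbf{1}^\top A w$ for the normalised $w$. The test
suite cross-checks this routine against a dense eigendecomposition on
1,000 random reciprocal matrices of orders 3–9.

Consistency is diagnosed the standard way:
$CI = (\lambda_{\max} - n)/(n - 1)$, $CR = CI / RI(n)$ with Saaty's random
index table ($RI(3) = 0.58, \dots, RI(10) = 1.49$), acceptable when
$CR < 0.10$. Matrices of order $\le 2$ are always perfectly consistent and
get $CR = 0$. Round-off can push $\lambda_{\max}$ infinitesimally below $n$
on a perfectly consistent matrix, so the diagnostics are clamped at zero.

Panels are aggregated by the element-wise geometric mean of the individual
matrices (aggregation of individual judgments). Whether historical studies
aggregated judgments or averaged per-expert priority vectors is typically
unreported; we aggregate judgments because the geometric mean is the only
symmetric aggregation that keeps the group matrix reciprocal, and a test
verifies that aggregating a noisy simulated panel lands closer to the true
weights than the panel's worst member.

`validate_matrix()` enforces structure (unit diagonal, reciprocity within a
relative tolerance, positivity) and never repairs: a reciprocity violation
is an error naming the cell. The in-memory tolerance is strict
($10^{-9}$); the CSV readers pass $10^{-6}$ so that reciprocals rounded to
a few decimals in hand-edited files still load.

## Modified-Delphi arithmetic

Each candidate factor is scored by every panellist on a 9-point Likert
scale along two dimensions: importance for prioritisation and measurement
capability. Decisions work off per-factor medians (midpoint convention for
even panels). The published selection language mixes "average" and
"median"; we take the median as decisive — it is what the banded rules
reference and it is robust to single outlying panellists — and report the
mean alongside for transparency.

The bands: a factor is **selected** when its median exceeds 7 on *both*
dimensions (it must be both important and measurable), **eliminated** as
soon as *either* median falls below 4, and **advances** otherwise. Medians
of exactly 7 or exactly 4 advance. The two-dimension combination rule is a
design choice (the source methodology states the bands per score, not the
conjunction); requiring both dimensions for selection and either for
elimination is the conservative reading.

The agreement rate of a factor is the fraction of panellists whose score
lies in the same Likert band (1–3 / 4–7 / 8–9) as the factor's median, a
simple consensus measure in $[0, 1]$. A factor's overall rate is the
minimum over the two dimensions — the panel must have converged on both
judgments. A round may terminate when every non-eliminated factor reaches
0.80; a rate of exactly 0.80 counts (the threshold is an argument of
`run_round()`). Real Delphi studies sometimes override the arithmetic by
researcher judgment; `run_round(select_override = ...)` models this as an
explicit, logged list — never silently.

## The waiting-list simulator

The simulator answers the question the framework raises: *what does
priority scheduling change, relative to FIFO, on the same stream of
referrals?*

* **Time step**: one week, with weekly re-ranking. Wait targets are stated
  in months, so weeks give adequate resolution while keeping a year of
  operation at ~52 ranking events.
* **Arrivals**: Poisson counts per week with configurable mean.
* **Severity structure**: each patient draws a latent severity
  $u \sim \mathrm{Beta}(a, b)$ and scores each of the six static factors as
  independent $\mathrm{Binomial}(10, u)$, inducing the positive
  inter-factor correlation real patients show. The default $a = b = 1$
  (uniform case mix) is the neutral choice — it makes the marginal factor
  score Beta-Binomial$(10, 1, 1)$ with mean exactly 5, which the test suite
  verifies analytically.
* **Waiting-time factor**: the one dynamic score. The framework treats it
  as physician-assigned; a simulator needs a mechanical rule, so it grows
  linearly with elapsed wait, $\min(10, \lfloor 10\,t/h \rfloor)$ with
  saturation horizon $h = 16$ weeks by default (matching the longest tier
  target). It is monotone nondecreasing and capped.
* **Service**: up to `capacity` patients per week from the head of the
  ranked queue; FIFO ranks by arrival order. How often a real list would be
  re-scored, and whether waiting time would really be scored mechanically,
  is unknown — both are flagged as modelling choices, not facts.
* **Metrics**: a patient's tier is fixed at arrival (waiting-time score 0),
  so per-tier target attainment asks whether each *clinical urgency class*
  was seen within its window. Attainment is computed over "decided"
  patients — those served within target, or whose target window closed
  before the horizon — so late arrivals with still-open windows do not bias
  the rate. Patients still queued at the horizon are reported as censored
  with their elapsed wait.
* **Policy comparison**: both policies consume the identical generated
  stream (common random numbers), so every difference is attributable to
  the queue discipline; per-tier attainment and mean-wait deltas come with
  percentile bootstrap intervals from paired patient resampling.

For speed the simulator's inner loop computes priority totals vectorised
(static points plus the waiting-time contribution) instead of calling
`rank_waitlist()` each week; a test pins the equivalence by checking that
one framework-policy week serves exactly the head of `rank_waitlist()` on
the same queue.

What passing simulations do **not** show: the generator has no seasonality,
no balking or death on the list, no dependence of severity on time waited,
and physician scores in real use carry measurement error the Binomial model
does not emulate. Conclusions about the *direction* of the policy effect
(priority scheduling protects the urgent tier under load, at some cost to
tier 3) are robust in this model; magnitudes are illustrative only, and the
simulator is deliberately not calibrated to any specific service's data.

## Numerical and interface choices

* Weights are never rounded internally; published weights are stored to
  two decimals (they sum to 1.00 exactly) and derived weights are reported
  at full precision.
* Degenerate inputs fail loudly with located diagnostics: non-square or
  non-reciprocal matrices name the offending cell, rosters name missing
  factor columns, out-of-bounds scores name the patient and factor.
* All randomness flows from explicit seeds (`simulation_config(seed = )`,
  the CLI `--seed` flag); identical inputs and seed give identical outputs.
* Dates are ISO-8601; CSV is comma-separated UTF-8 with a header; JSON
  configuration is validated on load with the same rules as in-code
  construction.
* Problem sizes used by the test suite — 1,000 random matrices for the
  eigensolver cross-check, 10,000+ patients for the generator calibration,
  100 paired replicates at utilisation 0.9 over a two-year horizon for the
  policy property — were chosen to make the checked properties
  statistically sharp at desk scale.

## Known limitations

* The factor-selection counts of any specific historical study are not
  reproducible from arithmetic alone: they depend on unpublished expert
  responses and on panel judgment between rounds (merging and renaming of
  factors). The package reproduces the *rules*, and its tests check them
  against independent oracles on simulated panels.
* AHP group aggregation is geometric-mean only; consensus-convergence
  protocols, fuzzy AHP and incomplete-matrix imputation are out of scope.
* The simulator models throughput and waiting, not health outcomes or
  costs.
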