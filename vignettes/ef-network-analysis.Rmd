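---
title: "Modeling the organization of executive functions with adaptive assessments and psychometric networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the organization of executive functions with adaptive assessments and psychometric networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efnet)
```

## The scientific problem

Executive functions (EFs) — the goal-directed control abilities usually
organized as working memory (WM), context monitoring (CM) and interference
resolution (IR) — are hypothesized to begin as a single undifferentiated
capacity in childhood and to differentiate into separable components with
age (the *differentiation hypothesis*). Testing that claim across a wide
age range runs into two methodological problems:

1. **Measurement.** A fixed task is too hard for eight-year-olds or too
   easy for thirteen-year-olds; floor and ceiling effects confound age
   comparisons. Adaptive tasks that adjust challenge trial-by-trial equate
   difficulty across ability, so the same battery can be administered to
   every age and at every wave.
2. **Modeling.** Confirmatory factor analysis (CFA) compares fixed
   competing structures, but a strong *Common-EF* factor — variance shared
   by every EF task — inflates correlations between factors and makes
   nested model comparisons ambiguous. Partial-correlation networks
   condition every pairwise association on all other tasks, which removes
   the common variance from the edges: communities found in such a network
   are groups that cohere *beyond* Common EF.

`efnet` implements both measurement and modeling as a single reusable
pipeline, exercised end-to-end on synthetic cohorts whose latent structure
is known exactly. The design emulated throughout is an accelerated
longitudinal study: three school cohorts (grades 3–4, 5–6, 7–8), each
assessed four times at six-month intervals (fall/spring of two school
years) with a battery of one basic response-time task (BRT) and eight EF
tasks.

## The adaptive response window

Six battery tasks use an adaptive response deadline. The student's response
earns "correct" feedback only when it is both accurate and inside the
current window `w`; the staircase then updates

* correct-in-window → `w ← max(floor, w − step_down)`
* late or incorrect response → `w ← w + step_up`
* no response (a withheld go/no-go trial or a lapse) → `w` unchanged.

This is the weighted 1-up/1-down rule: in equilibrium, down-steps balance
up-steps, so the proportion of *responses* earning correct feedback
converges to `step_up / (step_up + step_down)` regardless of ability. With
the package defaults (`step_down = 10` ms, `step_up = 30` ms, initial
window 1,200 ms, floor 200 ms) the target is 75%. Ability moves the
*equilibrium window*, not the feedback rate — which is exactly the design
goal: equal challenge across ages.

Two modeling choices matter here and are deliberate:

* **Updates occur on responded trials only.** The design target is a
  percentage *of responses*; including withheld trials in the staircase
  would bias the per-response rate away from the step-ratio equilibrium.
* **Accuracy stays high across the ability range** (logistic accuracy with
  a 0.95 baseline for choice tasks; a Gaussian signal-detection model with
  a base-rate-aware criterion for go/no-go tasks). The equilibrium is
  reachable only while overall accuracy exceeds the target rate; in a
  deadline-adaptive battery the deadline, not the error rate, carries the
  difficulty. When a low-ability profile's accuracy does fall below the
  target (plausible for the target-infrequent detection task), the window
  grows without bound and the feedback rate settles below 75% — mirroring
  the real-world observation that not every task hits its design target.

Response times are shifted lognormal: `rt = 180 + exp(N(log(speed) +
condition_shift − 0.10 · ability, 0.30))`, where `speed` is a per-student
latent median-RT scale (lognormal around 450 ms at age 120 months,
decreasing ~0.4%/month of age). The span tasks use a different staircase:
sequence length starts at 2, grows by one per correct reproduction, and a
block ends after two failures at one length; blocks repeat until at least
six attempts have been administered (multi-block administration, which also
keeps nearly all students above the five-trial inclusion rule). Per-attempt
success is logistic in (ability − length demand).

## Latent structure and the metric-level generator

Each student carries abilities `(g, wm, cm, ir)`: a Common-EF general
factor orthogonal to three correlated specific components (0.25 among
themselves by default), plus a linear growth slope per month that is larger
for younger cohorts (0.030/0.020/0.015 SD/month) — the age-by-time
interaction.

For the network and CFA stages the package generates metric-level data
directly from the factor model `Σ = Λ Φ Λᵀ + Ψ`. The loading matrix has a
general first column (loading 0.45 on all eight metrics, a Common-EF share
of ~20% of variance) and `k` specific block columns (loading 0.60), with
uniquenesses chosen for unit variances — a bifactor-style generation that
lets unity (the general column) and diversity (`k` and the block pattern)
be dialed independently. Defaults plant the developmental pattern the
pipeline is designed to detect: the youngest cohort has `k = 2` with a
*different* pair of components collapsed at each wave, while the older
cohorts hold a stable `k = 3`; per-stratum loading jitter ("structural
drift", SD 0.15/0.05/0.03 by cohort) makes the youngest cohort's networks
additionally less stable over time. A BRT column correlated 0.40 with the
general factor (rescaled to milliseconds) supports the speed-adjustment
stage.

These values are realistic for EF batteries (standardized loadings 0.5–0.7,
factor correlations 0.4–0.6 once the general variance is folded in) and are
fixed as the package's study conditions; they are configurable but the
defaults are not tuned per analysis.

What the generator does *not* emulate: school-level clustering effects on
metrics (schools are labels only), practice effects beyond linear growth,
non-normal metric distributions, missingness that depends on ability
(MCAR by default; an informative mechanism would stress FIML differently),
and ordinal coarseness of span scores in the metric-level generator.
Passing tests therefore show that the estimators recover the truth of this
generating model, not that the model captures every feature of classroom
data.

## Metrics and quality control

Metrics of interest per task: mean RT for BRT (both hands pooled), maximum
attempted span length for the two span tasks, SD of correct target RTs for
sustained attention, log-linear-corrected `d′ = z(H) − z(F)` for impulsive
attention and the tap-and-trace dual-task block, Rate Correct Score
(`n_correct / (mean RT in s × n_responded)`) for Stroop and flanker, and
mean correct RT for the visual-search task. The +0.5 log-linear correction
keeps `d′` finite at perfect hit or zero false-alarm rates; sustained-RT
variability uses correct target responses only.

The exclusion cascade runs task-wise so students are never wholly dropped
(except red-green colorblind screening, which removes the student):

1. trial filter — anticipations (RT < 200 ms, strict) and no-response
   trials where a response was expected. "Expected" applies to
   forced-response tasks only: in go/no-go tasks a missing response is a
   miss or a correct rejection, both of which `d′` needs.
2. task inclusion — at least five responded trials per condition and
   easiest-condition accuracy above chance by a one-sided exact binomial
   test at α = 0.05 (chance 0.5 for two-choice and go/no-go, 0.25 for the
   four-choice color task).
3. robust outliers — |x − median| > 3 × 1.4826 × MAD within each cohort ×
   timepoint × task cell (degenerate MAD ⇒ any value off the median).
4. influence — Cook's distance > 1 in the OLS of metric on BRT and age.

Steps 3–4 iterate to a fixed point, which makes the whole cascade
idempotent: applying QC to its own output changes nothing. A single pass is
not idempotent (removing extremes shifts the median and MAD), and a
screening operator that keeps finding new "outliers" each time it is
re-applied is awkward to reason about; the fixed-point form typically adds
well under one percent of additional exclusions on clean data.

## Speed adjustment and the feedback-rate model

Within every cohort × timepoint, each metric is replaced by the
standardized residual of its OLS regression on BRT — the processing-speed
covariate designed to be regressed out of all EF metrics. Partial
correlations are scale-invariant, so standardization affects only reported
edge magnitudes, not the network; residualizing within stratum matches the
per-stratum modeling downstream. A descriptive OLS of per-student feedback
percentage on cohort and linear time (numerator df 3), with a
percentile-bootstrap CI on R², checks that the staircase — not age — sets
challenge: on the synthetic battery the model R² stays below 0.20 for every
task.

## Networks: FIML moments and partial correlations

Each cohort × timepoint stratum gets a fully saturated (non-regularized)
Gaussian graphical model. Missing cells are handled by full-information
maximum likelihood via EM on the multivariate normal: per missingness
pattern, the E-step fills conditional means and covariances of missing
given observed; the M-step updates the mean and denominator-`n`
covariance; iteration stops when the observed-data log-likelihood changes
by < 1e-8 (cap 5,000). On complete data one iteration reproduces the
closed-form ML moments exactly, which is the main correctness anchor; EM's
monotone likelihood is asserted as a property. Preconditions (every
variable seen twice, every pair jointly observed) are checked up front.

Edges are `pcor_ij = −Θ_ij / √(Θ_ii Θ_jj)` from `Θ = Σ⁻¹`. The |pcor| ≤ 0.1
display threshold affects plotting only; every analysis uses the full
matrix.

## Communities: signed Spinglass with modal reporting

Communities minimize the signed Potts Hamiltonian

`H(σ) = −Σ_{i<j} [(w⁺_ij − γ⁺ p⁺_ij) − (w⁻_ij − γ⁻ p⁻_ij)] δ(σ_i, σ_j)`

with `w±` the positive/negative edge parts and `p±` configuration-model
null expectations (`γ⁺ = γ⁻ = 1`). Negative partial correlations inside a
community raise the energy, which is why this objective — unlike
modularity-based detectors — is safe on signed networks. The optimizer is
simulated annealing in C++: heat-bath single-spin updates over a geometric
schedule (T from 1 to 0.01, cooling 0.99), a zero-temperature descent, and
12 internal restarts per call keeping the best energy; a call is
deterministic given its seed. On 8-node networks the annealed solution
matches the exhaustive minimum over all 4,140 set partitions in ≥ 99% of
seeded cases (tested against an independent enumeration oracle).

Because annealing is stochastic, detection is repeated (1,000× by default)
with consecutive seeds; partitions are canonicalized (labels by first
appearance in node order) and counted, and the modal grouping is reported
with its frequency. Ties break by lower mean energy, then lexicographically.

## Network stability across cohorts

Edge weights are Fisher-transformed (`atanh`) before any comparison. For
every pair of the 12 stratum networks the 28 transformed edge weights are
Pearson-correlated (CI by the Fisher method on n = 28), giving a 12 × 12
matrix. Each cohort's own 4-choose-2 = 6 between-timepoint correlations are
Fisher-transformed again and compared across cohorts with a one-way
fixed-effects ANOVA — df (2, 15), `η² = SSB/(SSB + SSW)` — and Tukey HSD
post-hocs, all on the z scale. Working on the z scale throughout is what
reproduces the published reference values bundled with the package
(η² = 0.60 and an oldest-vs-youngest Tukey difference of 0.43 at 2 d.p.
from the printed 12 × 12 table; the raw-scale recomputation gives η² ≈ 0.69
instead). The printed F (11.29) is recovered only to ≈ 11.1 because the
table's two-decimal rounding propagates; the middle-vs-youngest contrast
similarly recomputes to 0.32 against a printed 0.34. Observations are
treated as independent, as in the reference analysis.

## CFA: five structures, conservative selection

Five simple-structure models over the 8 metrics: one undifferentiated
factor (`F1`), the three two-factor collapses (`F2_IR_CM`, `F2_WM_CM`,
`F2_WM_IR`), and the differentiated `F3`. Identification is by unit factor
variances, leaving factor correlations free — which is what the redundancy
rule inspects (|φ| > 0.70, i.e. more than 49% shared variance, strictly).
Fitting minimizes the normal-theory ML discrepancy with analytic gradients
(`nlminb`, three jittered restarts; uniquenesses log-parameterized, so a
Heywood tendency shows up as a boundary flag rather than a negative
variance). Factor correlations are *unconstrained*: bounding them at 1
would make the 1-vs-2-factor comparison a boundary test and shrink its
empirical size to roughly α/2, whereas with free correlations the plain
likelihood-ratio difference `Δχ² = χ²_nested − χ²_comparison` is
asymptotically χ²(Δdf) and calibrates to its nominal level (verified by a
500-replicate null simulation). Positive-definiteness of the implied
covariance is still enforced inside the objective.

Fit indices: `χ² = (n−1)·F_ML`; CFI against the independence baseline;
`RMSEA = √(max(χ²−df, 0)/(df(n−1)))`; `AIC = χ² + 2q`; and the sample-size
adjusted `BICc = χ² + ln((n+2)/24)·q`. Robust (scaled) variants are out of
scope; under the generator's multivariate normal data the plain and scaled
statistics coincide asymptotically.

Model selection applies the conservative rule: `F3` only if it beats every
two-factor permutation; otherwise a two-factor model only if every
permutation beats `F1` (the winning permutation then chosen by AIC);
otherwise `F1`. Degrees of freedom are 20/19/17 for 1/2/3 factors, so the
1-vs-2 tests have Δdf = 1 and the 2-vs-3 tests Δdf = 2.

## Orchestration, determinism, problem sizes

`run_pipeline()` drives simulate → metrics → QC → adjust → networks →
communities → stability → CFA, writing CSV/JSON artifacts plus a manifest
(config hash, seed, package version); a rerun under the same configuration
is byte-identical. A single seed fans out per stage through a
counter-based mix (`fan_seed()`), so any stage can be re-run alone with
stable randomness. Trial-level simulation feeds the metric/QC/feedback
stages; the network, community and CFA stages run on metric-level data,
which is where their planted-truth benchmarks live. `ingest_external()`
adapts a long-format CSV onto the metric schema for users with their own
data; nothing in the pipeline depends on it.

The test suite exercises the estimators at sizes chosen to balance
Monte-Carlo error against wall time: staircase equilibria over 4,000–5,000
trials; covariance convergence at n = 10,000; community recovery at
n = 400 per stratum with 1,000 detection repeats; FIML-vs-complete-data
equality exactly; CFA recovery at n = 10,000 and test-size calibration over
500 Wishart-sampled null replicates at n = 250; the full 12-stratum
stability analysis at n = 400. These are the package's chosen benchmark
sizes, reported here so that users scaling up know the defaults were
validated at this resolution.

## Known limitations

* The staircase simulator is a design model, not a cognitive model: RT
  distributions are stationary within a session and ignore sequential
  effects, fatigue and motivation.
* FIML assumes multivariate normality and MCAR/MAR missingness; the
  generator's default missingness is MCAR, so tests do not probe MAR
  sensitivity.
* The stability ANOVA treats the 18 within-cohort correlations as
  independent observations, as in the reference analysis; they share
  networks, so the nominal df overstate the information available.
* Spinglass exactness is verified exhaustively only at 8 nodes; larger
  node sets rely on the annealer's restarts without an enumeration check.
* The CFA fitter covers simple-structure patterns with unit-variance
  factors — the five structures compared here — not general SEM.
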