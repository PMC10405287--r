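# efnet

Simulation and analysis of adaptive executive-function (EF) assessment in
an accelerated longitudinal design, with psychometric-network and
latent-variable modeling of how EFs are organized across development.

## Who this is for

Developmental and cognitive researchers who want to (a) prototype adaptive,
classroom-scale EF batteries whose staircases equate challenge across ages,
and (b) compare the two main modeling routes for the *differentiation
hypothesis* — that EFs begin as one undifferentiated capacity and separate
into working memory (WM), context monitoring (CM) and interference
resolution (IR) with age — on data whose latent structure is known exactly.

## What's inside

* **Synthetic cohorts** (`ef_config()`, `simulate_population()`,
  `simulate_trials()`): three school cohorts (grades 3–4, 5–6, 7–8), four
  waves at 6-month gaps, trial-level data for a basic response-time task
  (BRT) plus eight EF tasks with adaptive response-window and span
  staircases, latent Common-EF + WM/CM/IR abilities, growth, gender and
  missingness.
* **Task metrics** (`build_metric_table()`): mean RT, span length, RT
  variability to infrequent targets, log-linear-corrected d′, Rate Correct
  Score (RCS), per-task staircase feedback rates.
* **Quality control** (`apply_qc()`): colorblind screening, anticipatory /
  expected-no-response trial filters, five-trials-per-condition and exact
  binomial above-chance inclusion, 3-MAD and Cook's-distance (> 1) outlier
  screens, with an auditable flag report.
* **Speed adjustment** (`residualize_on_brt()`, `feedback_rate_model()`):
  standardized within-stratum residuals on BRT; cohort + time model of
  feedback rates with bootstrap R² intervals.
* **Networks** (`fiml_moments()`, `partial_correlations()`,
  `estimate_network()`): saturated partial-correlation networks per cohort
  × timepoint, missing data by full-information maximum likelihood (EM).
* **Communities** (`spinglass_partition()`, `modal_partition()`): signed
  Spinglass community detection (Potts Hamiltonian with configuration-model
  nulls for positive and negative weights, simulated annealing in C++),
  repeated 1,000× with the modal grouping reported.
* **Stability** (`network_stability()`, `within_cohort_anova()`,
  `tukey_hsd()`): Fisher-z edge-weight correlations between all 12
  networks, one-way ANOVA (df 2, 15) with η² and Tukey post-hocs on the
  within-cohort correlation sets.
* **CFA** (`fit_cfa()`, `chisq_difference()`, `model_selection_report()`):
  the five competing structures (1 factor, three 2-factor collapses, 3
  factors) fit by normal-theory ML with CFI / RMSEA / AIC / BICc,
  likelihood-ratio difference tests, the |φ| > 0.70 factor-redundancy rule,
  and the conservative complexity-selection rule.
* **Orchestration** (`run_pipeline()`): one call from config to serialized
  artifacts, byte-reproducible under a fixed seed.

The core statistics in one line each: network edges are
`pcor_ij = −Θ_ij/√(Θ_ii Θ_jj)` with `Θ = Σ⁻¹` estimated by FIML;
communities minimize
`H(σ) = −Σ_{i<j} [(w⁺_ij − γ⁺p⁺_ij) − (w⁻_ij − γ⁻p⁻_ij)] δ(σ_i,σ_j)`;
stability is Pearson's r between `atanh`-transformed edge vectors; CFA
minimizes `F_ML = ln|Σ(θ)| + tr(SΣ(θ)⁻¹) − ln|S| − p` with
`χ² = (n−1)F_ML`; and the staircase feedback equilibrium is
`step_up/(step_up + step_down)`.

## Worked example

Generate one stratum with a known three-block structure, estimate its
network, detect communities, and fit the competing factor models:

```r
library(efnet)

cfg <- ef_config(seed = 2024)
d   <- generate_metric_dataset(cfg, "G78", 1, n = 450)
adj <- residualize_on_brt(d)
net <- estimate_network(adj, "G78", 1)
net
#> <ef_network> G78 t1: 8 nodes, n = 450 (450 complete)
#>   |pcor| > 0.1 on 9 of 28 edges

modal_partition(net, n_runs = 1000, seed_base = 1)
#> <ef_modal_partition> modal grouping in 100.0% of 1000 runs
#> <ef_partition> 3 communities (H = -1.5446)
#>   [0] forward_span, backward_span
#>   [1] sustained_rt_sd, impulsive_dprime, tap_trace_dprime
#>   [2] stroop_rcs, flanker_rcs, boxed_mean_rt
```

The modal partition recovers the planted WM / CM / IR communities in every
one of the 1,000 seeded runs; `H` is the signed Hamiltonian of that
grouping. The CFA route reaches the same conclusion:

```r
fm   <- fiml_moments(as.matrix(adj[, ef_metric_columns()]))
fits <- fit_cfa_battery(fm$cov, fm$n)
glance(fits$F3)
#> # A tibble: 1 × 12
#>   structure chisq    df p_value   cfi  rmsea   aic  bicc     n n_free converged
#>   <chr>     <dbl> <dbl>   <dbl> <dbl>  <dbl> <dbl> <dbl> <int>  <dbl> <lgl>
#> 1 F3         19.5    17   0.299 0.997 0.0182  57.5  75.3   450     19 TRUE

model_selection_report(fits)$selected
#> [1] "F3"
```

The three-factor model fits (χ²(17) = 19.5, p = 0.30, CFI 0.997,
RMSEA 0.018) and every nested difference test prefers more structure, so
the conservative rule selects the differentiated model — as it should on
data generated with three distinct components.

The bundled reference correlation matrix (from a published two-year
accelerated longitudinal EF study, grades 3–8) reproduces that study's
network-stability analysis:

```r
ref <- reference_network_correlations()
res <- within_cohort_anova(ref$corr_matrix, ref$blocks)
res$anova
#>   f_statistic   df1   df2 p_value eta_squared
#> 1        11.1     2    15 0.00112       0.596
res$tukey
#>   comparison difference  ci_low ci_high p_value
#> 1 G56-G34         0.323  0.0747   0.572 0.0109
#> 2 G78-G34         0.433  0.184    0.682 0.00110
#> 3 G78-G56         0.110 -0.139    0.358 0.501
```

Cross-timepoint network correlations are significantly lower in the
youngest cohort (η² = 0.60): EF organization is still in flux through
grades 3–4 and stabilizes by grade 5.

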