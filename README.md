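# repairflux

Irradiated cells shut down mitochondrial respiration within about an hour
("mitochondrial shutdown"), lean on compensatory glycolysis, and only
partially recover oxidative metabolism over 24 h — while DNA double-strand
breaks, visible as γH2A.X foci, are repaired over the same window.
`repairflux` is an R package for the integrated statistical analysis of
these two processes: it turns extracellular-flux traces (OCR/ECAR) and
per-nucleus focus counts into interpretable Bayesian summaries and couples
repair kinetics to metabolic recovery. It is aimed at radiation biologists
and biostatisticians analysing Mito / Glycolysis Stress Test plates and
γH2A.X focus tables across panels of cell lines.

## What it computes

* **Stress-test parameters** per well from injection-phase traces
  (basal / ATP-linked / proton-leak / maximal / spare OCR; glycolysis,
  glycolytic capacity and reserve from ECAR), RFU-normalised, and log2 fold
  changes versus matched unirradiated controls
  (`flux_params()`, `log2_fold_change()`).
* **Multilevel normal models** of log-metabolic parameters with cell-line
  deflections and nested replicate effects, summarised by posterior
  medians, 50%/95% highest-density intervals and P⁻, the posterior
  probability of a negative deflection (`fit_metabolic_glm()`,
  `fit_time_course_glm()`, `hdi()`, `p_minus()`).
* **A hierarchical binomial–beta model of focus-count kinetics**: counts
  are binomial per nucleus with the nuclear area (in 0.1·Pixel² unit areas)
  as trials,

      k_i     ~ Binomial(A_i, p_{r,t})
      p_{r,t} ~ Beta(mean = p_t, var = v_t)        (replicate level)
      v_t     = σ² X_t / k_t,  X_t ~ χ²(k_t), truncated
      p_t     ~ U(0,1);  k_t, σ² ~ χ²(2)

  fitted by MCMC with posterior predictive checks and PSIS-LOO comparison
  against simpler pooled models (`fit_foci_model()`, `ppc_foci()`,
  `loo_compare_foci()`).
* **Repair-kinetics comparison**: five-timepoint repair vectors
  (posterior medians of p_t at 0, 0.5, 2, 6, 24 h), pairwise Euclidean
  distances, hierarchical clustering for the heatmap, and residual-damage
  percentages (`repair_vector()`, `distance_matrix()`, `cluster_order()`,
  `residual_damage()`).
* **Repair–metabolism coupling**: focus probabilities interpolated to the
  metabolic grid (0, 1, 6, 24 h) and regressed, per cell line, on
  log-metabolic parameters — Bayesian slopes/intercepts with a
  least-squares line alongside (`interpolate_foci_to_metab_grid()`,
  `fit_coupling()`, `coupling_panel()`).
* **A seeded synthetic-data generator** reproducing the assumed study
  design (3 replicates × ≥50 nuclei × 5 times; 8–16 wells per condition;
  1 h shutdown with staged recovery), including a jointly coupled study
  with a known true repair–metabolism slope (`simulate_foci_dataset()`,
  `simulate_flux_plate()`, `simulate_coupled_study()`), and a one-call
  pipeline (`run_all()`).

All user-facing functions take and return tibbles; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate a coupled study (true coupling slope −0.05), extract flux
parameters and fold changes, fit the focus model, and couple the two:

```r
library(repairflux)

study <- simulate_coupled_study(foci_sim_config(seed = 1),
                                flux_sim_config(seed = 1),
                                coupling_slope = -0.05, seed = 1)

params <- compute_mito_params(study$flux, normalize = FALSE)
log2_fold_change(params, parameters = "basal")
#> # A tibble: 6 × 7
#>   parameter cell_line treatment timepoint_h log2_fc n_treated n_control
#>   <chr>     <chr>     <chr>           <dbl>   <dbl>     <int>     <int>
#> 1 basal     CL1       IR                  1  -0.777        12        12
#> 2 basal     CL1       IR                  6  -0.738        12        12
#> 3 basal     CL1       IR                 24  -0.329        12        12
#> 4 basal     CL2       IR                  1  -0.854        12        12
#> 5 basal     CL2       IR                  6  -0.857        12        12
#> 6 basal     CL2       IR                 24  -0.337        12        12
```

Basal respiration drops to roughly 2^−0.8 ≈ 0.58 of control at 1 h and
recovers incompletely by 24 h (2^−0.33 ≈ 0.80) — the mitochondrial
shutdown and its staged recovery. The focus model recovers the repair time
course per unit nuclear area:

```r
fit <- fit_foci_model(dplyr::filter(study$foci, cell_line == "CL1"),
                      chains = 2, iter = 2000, seed = 2)
tidy(fit)
#> # A tibble: 5 × 8
#>   time_h  median hdi50_lo hdi50_hi hdi95_lo hdi95_hi  rhat   ess
#>    <dbl>   <dbl>    <dbl>    <dbl>    <dbl>    <dbl> <dbl> <dbl>
#> 1    0   0.00223  0.00157  0.00247 0.000997  0.00682  1.00  186.
#> 2    0.5 0.0273   0.0203   0.0306  0.0115    0.0651   1.01  244.
#> 3    2   0.0403   0.0331   0.0451  0.0154    0.0734   1.01  175.
#> 4    6   0.0293   0.0280   0.0304  0.0167    0.0521   1.01  103.
#> 5   24   0.0126   0.00902  0.0133  0.00582   0.0294   1.01  189.
```

Damage rises from a baseline focus probability of 0.002 per unit area,
peaks after irradiation, and is largely cleared by 24 h. Interpolating to
the metabolic grid and regressing on log basal respiration recovers the
configured coupling:

```r
q  <- setNames(tidy(fit)$median, tidy(fit)$time_h)
pg <- interpolate_foci_to_metab_grid(q)
metab <- params |>
  dplyr::filter(cell_line == "CL1",
                (treatment == "IR" & timepoint_h > 0) |
                (treatment == "control" & timepoint_h == 0)) |>
  dplyr::group_by(timepoint_h) |>
  dplyr::summarise(log_metab = log(mean(basal)))
fit_coupling(dplyr::left_join(pg, metab,
                              by = c("time_h" = "timepoint_h")), seed = 3)
#> Coupling fit (n = 4): LS slope -0.05583, Pr(slope < 0) = 0.962
#> # A tibble: 2 × 5
#>   term       median hdi95_lo   hdi95_hi  rhat
#>   <chr>       <dbl>    <dbl>      <dbl> <dbl>
#> 1 intercept  0.245    0.0252  0.323      1.00
#> 2 slope     -0.0520  -0.0684 -0.0000286  1.00
```

The least-squares slope (−0.056) sits near the simulated truth (−0.05):
more residual DNA damage goes with a deeper metabolic deficit. `autoplot()`
on any fitted object draws the corresponding figure (forest plot of
deflections, repair curve with HDI ribbons, clustered distance heatmap,
coupling scatter with posterior lines).

## The acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch on a seeded
synthetic study — simulation, flux parameterisation, fold changes, the
multilevel GLM, per-cell-line focus fits with PPC and LOO, repair
distances with clustering, and the coupling models — and writes its JSON
summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Stage outputs (all plain text, byte-reproducible at a fixed seed) are
written to a temporary working directory and logged to stderr.

See the methods vignette (`vignettes/repairflux-methods.Rmd`) for the full
model descriptions, priors, numerical choices and known limitations.
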