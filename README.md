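# migdyn

Tools for analysing T-cell reinvigoration under immune checkpoint blockade
(anti-PD-1, anti-CTLA-4, and their combination) in 3D organotypic
tumor-spheroid cultures, in two coupled layers:

1. **Migration dynamics.** Single-cell tracks (positions every 15 min over
   ≥ 130 h) are modelled as a heterogeneous random walk
   `u(t) = q(t) u(t−1) + a(t) n(t)` — a first-order autoregressive process
   whose persistence `q(t) ∈ [−1, 1]` and activity `a(t) > 0` (µm/step)
   vary in time. A sequential Bayesian grid filter estimates both
   parameters per time step; mean-square-displacement (MSD) statistics
   quantify anomalous diffusion (log–log slope < 1 = sub-diffusive); and a
   forward simulator closes the validation loop (estimate → resimulate →
   compare MSDs). The activity track is the single cell's functional
   read-out: checkpoint signalling shows up as an activity decline.

2. **Tumor–immune population dynamics.** Lymphocyte activity is split by
   PD-1 expression state (`Lu → Lp → Le` at rate α, an Erlang-2 delay of
   mean 2/α ≈ 9 h) and coupled to the live tumor-cell count `C` through a
   spherical accessibility law `Cacc = C / (1 + C^(1/3)/6)`:

   ```
   dLu/dt = −γ·Cacc·Lu − α·Lu − ξ·C·Lu
   dLp/dt = −γ·Cacc·Lp − α·Lp + α·Lu − ξ·C·Lp
   dLe/dt = −γ·Cacc·Le − β·Cacc·Le + α·Lp − ξ·C·Le
   dC/dt  = −σ·Cacc·(Lu + Lp + Le)
   ```

   CTLA-4 suppression (γ) acts instantly on all compartments; PD-1
   suppression (β) acts only on the fully expressed pool, hence with
   delay. The rates are estimated in three stages — (ξ, σ) from combined
   blockade, γ from anti-PD-1, (α, β) from anti-CTLA-4 — by quasi-Newton
   least squares against activity curves and final tumor counts.
   Per-channel cumulative-inactivation tallies let the model compare how
   much immune activity each checkpoint silences as a function of tumor
   size.

Seeded generators (`make_condition_template()`, `generate_cohort()`,
`generate_ode_observations()`) emulate the study conditions — cohorts of
9/12/28 cells, condition-specific activity profiles, noisy forward-model
observations — so the whole pipeline runs and validates without external
data. The package is intended for quantitative-biology researchers
studying checkpoint-blockade response kinetics in live-imaging or
organoid/spheroid systems.

## Worked example

```r
library(migdyn)

# a synthetic anti-CTLA-4 cohort: 28 cells, 130 h at 15-min steps
tpl    <- make_condition_template("anti_ctla4", seed = 1)
tracks <- generate_cohort(tpl, seed = 1)

# population MSD and anomalous-diffusion exponent over the fitted window
msd <- ensemble_msd(tracks, max_lag_fraction = 0.06)
fit_power_law(msd, window = c(1, 20))
#> MSD power-law fit: exponent 0.8878, D 0.1262 um^2/step (lags 1-20, R^2 0.993)

# per-cell activity/persistence tracks, then the population average
ptracks <- infer_tracks(tracks, forget_sd = c(0.25, 1.5), smooth = TRUE)
pop     <- population_activity(ptracks)
head(pop, 3)
#> # A tibble: 3 x 7
#>   cell_id     step q_mean    q_se a_mean  a_se n_cells
#>   <chr>      <int>  <dbl>   <dbl>  <dbl> <dbl>   <int>
#> 1 population     1 0.0564 0.00503   2.15 0.128      28
#> 2 population     2 0.0564 0.00503   2.13 0.125      28
#> 3 population     3 0.0564 0.00503   2.10 0.117      28

# staged estimation of the five ODE rates from synthetic observations
obs <- generate_observation_triple(noise = 0, count_noise = 0, seed = 1)
fit <- staged_fit(obs$combo, obs$anti_pd1, obs$anti_ctla4, seed = 1)
tidy(fit)
#> # A tibble: 5 x 5
#>   parameter definition                          per_hour    per_step stage
#>   <chr>     <chr>                                  <dbl>       <dbl> <chr>
#> 1 sigma     tumor cell death rate            0.000000880 0.000000220 combo
#> 2 gamma     CTLA-4-induced inactivation rate 0.00000960  0.00000240  anti_pd1
#> 3 beta      PD-1-induced inactivation rate   0.0000633   0.0000158   anti_ctla4
#> 4 xi        non-checkpoint inactivation rate 0.000000550 0.000000137 combo
#> 5 alpha     PD-1 expression rate             0.220       0.0550      anti_ctla4
```

The exponent below 1 quantifies the cohort's sub-diffusive migration; the
population activity track is the time-resolved read-out of reinvigoration;
and the rate table reports each suppression channel in per-hour and
per-15-min-step units. β/γ ≈ 6.6 — PD-1's per-contact suppression is the
stronger pathway — yet `cumulative_inactivation_ratio()` on untreated
simulations shows CTLA-4 silencing more total activity once the tumor is
large, because PD-1's Erlang-2 expression delay wastes its advantage; the
dominance grows monotonically with initial tumor size.

`run_full(run_config(out_dir))` orchestrates everything (cohorts → MSD →
inference → population activity → staged fit) and writes TSV/JSON outputs
stamped with a config hash; `autoplot()` methods cover MSD curves,
parameter tracks and model trajectories; fitted objects support
`tidy()`/`glance()`.

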