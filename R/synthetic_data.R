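#' Condition template for synthetic migration cohorts
#'
#' Encodes the qualitative activity dynamics observed per treatment arm as a
#' deterministic per-step (q, a) base profile plus cohort settings:
#'
#' * `combo` (9 cells): high activity with slow fluctuating decline -
#'   sustained reinvigoration under combined blockade.
#' * `anti_pd1` (12 cells): markedly lower initial activity with an
#'   immediate, steady exponential decline towards the noise floor.
#' * `anti_ctla4` (28 cells): high initial activity, a plateau of roughly
#'   `2 / alpha` hours (about 9 h at `alpha = 0.22` per hour - the mean of
#'   the Erlang-2 PD-1 expression delay) and then a rapid decline, generated
#'   from the model's own Erlang-2 survival form `(1 + alpha t) exp(-alpha t)`.
#' * `control` (6 cells): no significant movement, activity at the noise
#'   floor throughout.
#'
#' All templates cover 130 h at 15-min steps. A small residual activity
#' floor (`a_floor`, default 0.05 um/step) represents localisation noise and
#' residual motility of suppressed cells.
#'
#' @param condition One of `"combo"`, `"anti_pd1"`, `"anti_ctla4"`,
#'   `"control"`.
#' @param n_steps Number of displacement steps (default 520 = 130 h).
#' @param step_h Hours per step.
#' @param seed Default seed carried by the template.
#' @return A `condition_template` list with the cohort size, step settings,
#'   heterogeneity sd and a tibble `profile` of per-step `t_h`, `a`, `q`.
#' @export
make_condition_template <- function(condition = c("combo", "anti_pd1",
                                                  "anti_ctla4", "control"),
                                    n_steps = 520L, step_h = 0.25,
                                    seed = 1L) {
  condition <- match.arg(condition)
  t_h <- (seq_len(n_steps) - 1L) * step_h
  a_floor <- 0.05
  base <- switch(condition,
    combo = 2.0 * exp(-0.002 * t_h) * (1 + 0.25 * sin(2 * pi * t_h / 30)),
    anti_pd1 = 0.8 * exp(-0.03 * t_h),
    anti_ctla4 = 2.0 * (1 + 0.22 * t_h) * exp(-0.22 * t_h),
    control = rep(0, n_steps)
  )
  a <- pmax(base, a_floor)
  q <- 0.05 + 0.05 * sin(2 * pi * t_h / 50)
  n_cells <- switch(condition, combo = 9L, anti_pd1 = 12L,
                    anti_ctla4 = 28L, control = 6L)
  structure(
    list(
      condition = condition,
      n_cells = n_cells,
      n_steps = n_steps,
      step_h = step_h,
      a_floor = a_floor,
      cell_sd = 0.2,
      seed = seed,
      profile = tibble::tibble(t_h = t_h, a = a, q = q)
    ),
    class = "condition_template"
  )
}

#' Generate a seeded synthetic migration cohort
#'
#' Simulates `n_cells` heterogeneous-random-walk tracks from the template's
#' base profile. Cell-to-cell heterogeneity multiplies each cell's activity
#' profile by a log-normal factor (sd `cell_sd` on the log scale); per-cell
#' simulation seeds derive deterministically from the cohort seed, so the
#' cohort is bit-reproducible.
#'
#' @param template A [make_condition_template()] result.
#' @param seed Cohort seed; defaults to the template's.
#' @return A `track_table` with the template's condition label.
#' @export
generate_cohort <- function(template, seed = template$seed) {
  stopifnot(inherits(template, "condition_template"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cohort_subseed(seed, 0L))
  mult <- exp(stats::rnorm(template$n_cells, mean = 0, sd = template$cell_sd))
  profiles <- purrr::map(seq_len(template$n_cells), function(i) {
    ar_profile(
      q = template$profile$q,
      a = pmax(template$profile$a * mult[[i]], template$a_floor)
    )
  })
  names(profiles) <- sprintf("%s_%02d", template$condition,
                             seq_len(template$n_cells))
  simulate_cohort(profiles, seed = seed, step_h = template$step_h,
                  condition = template$condition)
}

#' Default relative tolerances on tumor-cell counts
#'
#' Presets matching the live/dead-staining tolerances of the spheroid
#' system: +/-30% on the ~22,000-cell initial count and +/-15%, +/-40% and
#' +/-35% on the final counts of the combo, anti-PD-1 and anti-CTLA-4 arms.
#'
#' @return Named numeric vector of relative tolerances.
#' @export
count_tolerance_presets <- function() {
  c(initial = 0.30, combo = 0.15, anti_pd1 = 0.40, anti_ctla4 = 0.35)
}

#' Generate noisy observations from a forward ODE simulation
#'
#' Integrates the tumor-lymphocyte model, samples total activity on a
#' regular grid and applies multiplicative Gaussian noise; the final tumor
#' count is perturbed by a uniform relative error. The generating truth is
#' recorded in the observation metadata for recovery scoring. Activity
#' values pushed negative by noise are clipped at zero (counted in the
#' metadata).
#'
#' @param params [rate_parameters()] in per-hour units (generating truth).
#' @param scenario Condition / scenario label (`"combo"`, `"anti_pd1"`,
#'   `"anti_ctla4"`).
#' @param state0 Initial state from [immune_state()].
#' @param noise Relative sd of the multiplicative activity noise
#'   (default 0.05).
#' @param count_noise Half-width of the uniform relative perturbation on the
#'   final count (default 0).
#' @param t_end,dt_obs Observation horizon and sampling interval in hours
#'   (defaults 130 and 1).
#' @param seed Integer seed.
#' @return An [ode_observation()] whose `truth` records the generating
#'   parameters, seed, true final count and clip count.
#' @export
generate_ode_observations <- function(params, scenario, state0,
                                      noise = 0.05, count_noise = 0,
                                      t_end = 130, dt_obs = 1, seed = 1L) {
  stopifnot(inherits(params, "rate_parameters"), noise >= 0,
            count_noise >= 0)
  traj <- integrate_checkpoint(params, scenario, state0, t_end = t_end,
                               dt = dt_obs, rtol = 1e-10, atol = 1e-10)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  L <- traj$L_total
  obs_act <- L * (1 + noise * stats::rnorm(length(L)))
  n_clipped <- sum(obs_act < 0)
  if (n_clipped > 0) {
    message(n_clipped, " noisy activity value(s) clipped at 0")
    obs_act <- pmax(obs_act, 0)
  }
  C_true <- traj$C[nrow(traj)]
  c_final <- C_true * (1 + stats::runif(1, -count_noise, count_noise))
  ode_observation(
    activity = tibble::tibble(
      t_h = traj$t_h,
      activity = obs_act,
      se = ifelse(noise > 0, noise * pmax(L, 1e-12), NA_real_)
    ),
    c0 = state0[["C"]],
    c_final = c_final,
    condition = scenario,
    c_tol = count_noise,
    truth = list(params = params, scenario = scenario, state0 = state0,
                 noise = noise, count_noise = count_noise, seed = seed,
                 c_final_true = C_true, n_clipped = n_clipped)
  )
}

#' Generate the synthetic observation triple at the reference rates
#'
#' Convenience wrapper producing the three staged-fitting observations
#' (combo, anti-PD-1, anti-CTLA-4) from one seed, using [default_rates()]
#' and a 22,000-cell initial tumor. The initial activities (combo 3.8e4,
#' anti-PD-1 2.9e4, anti-CTLA-4 2.4e5) are calibrated so that the forward
#' simulation at the reference rates reproduces the spheroid system's
#' final tumor counts (14,000 / 20,000 / 13,000): the reference rates are
#' only consistent with those printed counts when the dynamical model's
#' activity variable is of this order, i.e. the model's activity unit
#' carries an implicit scale factor relative to the um-per-step migration
#' activity.
#'
#' @param noise Relative activity noise sd.
#' @param count_noise Half-width of the relative final-count perturbation.
#' @param seed Integer seed (per-condition seeds derived from it).
#' @param c0 Initial tumor-cell count.
#' @return Named list of three [ode_observation()]s.
#' @export
generate_observation_triple <- function(noise = 0, count_noise = 0,
                                        seed = 1L, c0 = 22000) {
  params <- default_rates()
  l0 <- c(combo = 3.8e4, anti_pd1 = 2.9e4, anti_ctla4 = 2.4e5)
  out <- purrr::imap(l0, function(L0, cond) {
    generate_ode_observations(
      params, scenario = cond, state0 = immune_state(Lu = L0, C = c0),
      noise = noise, count_noise = count_noise,
      seed = cohort_subseed(seed, match(cond, names(l0)))
    )
  })
  names(out) <- names(l0)
  out
}
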