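#' Accessible tumor cells in a spherical spheroid
#'
#' Lymphocytes only reach the surface layer of a tumor spheroid. Under a
#' simple spherical geometry the accessible count is
#' `Cacc = C / (1 + C^(1/3) / 6)`, which approaches `6 C^(2/3)` (the surface
#' shell) for large `C` and equals `C` in the small-spheroid limit.
#'
#' @param C Live tumor-cell count (>= 0); vectorised.
#' @return Accessible tumor-cell count, `0 <= Cacc <= C`.
#' @export
accessible_fraction <- function(C) {
  if (any(C < 0)) stop("tumor-cell count C must be >= 0", call. = FALSE)
  C / (1 + C^(1 / 3) / 6)
}

#' Rate parameters of the tumor-lymphocyte model
#'
#' @param sigma Tumor-cell death rate per unit immune activity.
#' @param gamma CTLA-4-induced inactivation rate per accessible tumor cell.
#' @param beta PD-1-induced inactivation rate per accessible tumor cell.
#' @param xi Non-checkpoint inactivation rate per tumor cell.
#' @param alpha PD-1 expression (compartment-advance) rate.
#' @param time_unit `"per_hour"` or `"per_step"`.
#' @return A `rate_parameters` list.
#' @export
rate_parameters <- function(sigma, gamma, beta, xi, alpha,
                            time_unit = c("per_hour", "per_step")) {
  time_unit <- match.arg(time_unit)
  r <- c(sigma = sigma, gamma = gamma, beta = beta, xi = xi, alpha = alpha)
  if (any(r < 0)) stop("all rates must be >= 0", call. = FALSE)
  structure(list(sigma = sigma, gamma = gamma, beta = beta, xi = xi,
                 alpha = alpha, time_unit = time_unit),
            class = "rate_parameters")
}

#' Reference rate estimates for the organotypic spheroid system
#'
#' The per-hour rate set estimated for patient-derived tumor spheroids with
#' autologous immune cells: sigma = 8.8e-7 (tumor-cell death per unit immune
#' activity), gamma = 9.6e-6 (CTLA-4 channel), beta = 6.33e-5 (PD-1
#' channel), xi = 5.5e-7 (non-checkpoint suppression), alpha = 0.22 (PD-1
#' expression). Used as the generating truth of the synthetic-data study.
#'
#' @return A `rate_parameters` object in per-hour units.
#' @export
default_rates <- function() {
  rate_parameters(sigma = 8.8e-7, gamma = 9.6e-6, beta = 6.33e-5,
                  xi = 5.5e-7, alpha = 0.22, time_unit = "per_hour")
}

#' Convert rates between per-hour and per-step units
#'
#' All five rates are first-order in time, so converting to per-step units
#' multiplies by the step length in hours (and the reverse divides).
#'
#' @param params A [rate_parameters()] object.
#' @param step_h Hours per step (default 0.25, i.e. 15 min).
#' @param to Target unit, `"per_step"` or `"per_hour"`.
#' @return A `rate_parameters` object in the target unit.
#' @export
convert_rate_units <- function(params, step_h = 0.25,
                               to = c("per_step", "per_hour")) {
  stopifnot(inherits(params, "rate_parameters"), step_h > 0)
  to <- match.arg(to)
  if (!params$time_unit %in% c("per_hour", "per_step")) {
    stop("unknown time_unit: ", params$time_unit, call. = FALSE)
  }
  if (params$time_unit == to) return(params)
  f <- if (to == "per_step") step_h else 1 / step_h
  rate_parameters(params$sigma * f, params$gamma * f, params$beta * f,
                  params$xi * f, params$alpha * f, time_unit = to)
}

#' Scenario configuration: which suppression channels are blocked
#'
#' Antibody blockade removes a channel from the dynamics: combined blockade
#' silences both checkpoints (and makes PD-1 expression inert, so alpha is
#' zeroed too); anti-PD-1 zeroes beta; anti-CTLA-4 zeroes gamma; untreated
#' leaves every channel active.
#'
#' @param condition One of `"combo"`, `"anti_pd1"`, `"anti_ctla4"`,
#'   `"untreated"`.
#' @return A `scenario_config` list with the condition and the names of the
#'   zeroed rates.
#' @export
scenario_config <- function(condition = c("combo", "anti_pd1", "anti_ctla4",
                                          "untreated")) {
  condition <- match.arg(condition)
  zeroed <- switch(condition,
    combo = c("gamma", "beta", "alpha"),
    anti_pd1 = "beta",
    anti_ctla4 = "gamma",
    untreated = character(0)
  )
  structure(list(condition = condition, zeroed = zeroed),
            class = "scenario_config")
}

#' Apply a scenario mask to rate parameters
#'
#' @param params A [rate_parameters()] object.
#' @param scenario A [scenario_config()] (or condition string).
#' @return `rate_parameters` with the blocked channels set to zero.
#' @export
apply_scenario <- function(params, scenario) {
  if (is.character(scenario)) scenario <- scenario_config(scenario)
  stopifnot(inherits(params, "rate_parameters"),
            inherits(scenario, "scenario_config"))
  vals <- params[c("sigma", "gamma", "beta", "xi", "alpha")]
  vals[scenario$zeroed] <- 0
  rate_parameters(vals$sigma, vals$gamma, vals$beta, vals$xi, vals$alpha,
                  time_unit = params$time_unit)
}

#' Initial immune state
#'
#' State of the tumor-lymphocyte system: activities of the three lymphocyte
#' subpopulations by PD-1 expression (unexpressed `Lu`, partially expressed
#' `Lp`, fully expressed `Le`; activity is unit-free), the live tumor-cell
#' count `C`, cumulative inactivated activity per suppression channel
#' (`I_ctla4`, `I_pd1`, `I_other`) and cumulative tumor-cell deaths
#' `D_tumor`.
#'
#' @param Lu,Lp,Le Initial subpopulation activities (>= 0).
#' @param C Initial live tumor-cell count (>= 0).
#' @return A named numeric state vector with zeroed tallies.
#' @export
immune_state <- function(Lu, Lp = 0, Le = 0, C = 22000) {
  s <- c(Lu = Lu, Lp = Lp, Le = Le, C = C,
         I_ctla4 = 0, I_pd1 = 0, I_other = 0, D_tumor = 0)
  if (any(s < 0)) stop("state components must be >= 0", call. = FALSE)
  s
}

#' Time derivative of the immune state
#'
#' The model couples three lymphocyte-activity compartments to the tumor
#' count. PD-1 expression advances `Lu -> Lp -> Le` at rate `alpha` (two
#' first-order transitions, i.e. an Erlang-2 delay in PD-1-mediated
#' suppression); CTLA-4 suppresses all three compartments at `gamma` per
#' accessible tumor cell; PD-1 suppresses only `Le` at `beta` per accessible
#' cell; non-checkpoint factors suppress at `xi` per (total) tumor cell; and
#' total lymphocyte activity kills tumor cells at `sigma` per accessible
#' cell. Suppressed activity and dead tumor cells accumulate in per-channel
#' tallies so that conservation holds exactly along a solution.
#'
#' @param state Named state vector as from [immune_state()].
#' @param params A [rate_parameters()] object (masking applied beforehand
#'   with [apply_scenario()], or pass `scenario`).
#' @param scenario Optional scenario to apply to `params`.
#' @return Named vector of time derivatives (per the params' time unit).
#' @export
derivatives <- function(state, params, scenario = NULL) {
  if (!is.null(scenario)) params <- apply_scenario(params, scenario)
  # adaptive steps may overshoot marginally below zero; rates are evaluated
  # at the physical (non-negative) state
  Lu <- max(state[["Lu"]], 0); Lp <- max(state[["Lp"]], 0)
  Le <- max(state[["Le"]], 0)
  C <- max(state[["C"]], 0)
  Cacc <- accessible_fraction(C)
  L_tot <- Lu + Lp + Le
  with(params, {
    dLu <- -gamma * Cacc * Lu - alpha * Lu - xi * C * Lu
    dLp <- -gamma * Cacc * Lp - alpha * Lp + alpha * Lu - xi * C * Lp
    dLe <- -gamma * Cacc * Le - beta * Cacc * Le + alpha * Lp - xi * C * Le
    dC <- -sigma * Cacc * L_tot
    c(Lu = dLu, Lp = dLp, Le = dLe, C = dC,
      I_ctla4 = gamma * Cacc * L_tot,
      I_pd1 = beta * Cacc * Le,
      I_other = xi * C * L_tot,
      D_tumor = -dC)
  })
}

#' Integrate the tumor-lymphocyte model
#'
#' Adaptive integration (deSolve's `lsoda`) with output sampled on a fixed
#' grid. Rates must be in per-hour units since time is in hours; convert
#' per-step rates first with [convert_rate_units()].
#'
#' @param params A [rate_parameters()] object, `time_unit = "per_hour"`.
#' @param scenario A [scenario_config()] or condition string.
#' @param state0 Initial state from [immune_state()].
#' @param t_end Final time (hours).
#' @param dt Output sampling interval (hours, default 0.25).
#' @param rtol,atol Integrator tolerances.
#' @return A `checkpoint_trajectory` tibble with columns `t_h`, `Lu`, `Lp`,
#'   `Le`, `L_total`, `C`, `Cacc`, `I_ctla4`, `I_pd1`, `I_other`, `D_tumor`.
#' @export
integrate_checkpoint <- function(params, scenario, state0, t_end,
                                 dt = 0.25, rtol = 1e-10, atol = 1e-10) {
  stopifnot(inherits(params, "rate_parameters"), dt > 0, t_end >= dt)
  if (params$time_unit != "per_hour") {
    stop("integrator runs in hours; convert rates with convert_rate_units()",
         call. = FALSE)
  }
  masked <- apply_scenario(params, scenario)
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  rhs <- function(t, y, p) list(derivatives(y, masked))
  sol <- deSolve::ode(y = state0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  sol <- as.data.frame(sol)
  lo <- min(sol$Lu, sol$Lp, sol$Le, sol$C)
  scale0 <- max(abs(state0))
  if (lo < -1e-6 * scale0) {
    stop("integration produced negative state components beyond tolerance",
         call. = FALSE)
  }
  for (cn in c("Lu", "Lp", "Le", "C")) sol[[cn]] <- pmax(sol[[cn]], 0)
  out <- tibble::tibble(
    t_h = sol$time,
    Lu = sol$Lu, Lp = sol$Lp, Le = sol$Le,
    L_total = sol$Lu + sol$Lp + sol$Le,
    C = sol$C,
    Cacc = accessible_fraction(sol$C),
    I_ctla4 = sol$I_ctla4, I_pd1 = sol$I_pd1, I_other = sol$I_other,
    D_tumor = sol$D_tumor
  )
  structure(out, class = c("checkpoint_trajectory", class(out)),
            scenario = if (is.character(scenario)) scenario else scenario$condition,
            params = masked)
}

#' CTLA-4 versus PD-1 cumulative-inactivation ratio
#'
#' Ratio of the cumulative immune activity suppressed through the CTLA-4
#' channel to that suppressed through the PD-1 channel at the end of a
#' trajectory. A value above 1 means CTLA-4 silenced more immune activity
#' than PD-1 despite PD-1's larger per-contact rate - the signature of the
#' Erlang-2 expression delay.
#'
#' @param trajectory A `checkpoint_trajectory`.
#' @return A list with `ratio` (Inf when the PD-1 tally is zero),
#'   `infinite` flag, and the two final tallies.
#' @export
cumulative_inactivation_ratio <- function(trajectory) {
  stopifnot(inherits(trajectory, "checkpoint_trajectory"))
  last <- trajectory[nrow(trajectory), ]
  if (last$I_pd1 == 0) {
    list(ratio = Inf, infinite = TRUE,
         I_ctla4 = last$I_ctla4, I_pd1 = 0)
  } else {
    list(ratio = last$I_ctla4 / last$I_pd1, infinite = FALSE,
         I_ctla4 = last$I_ctla4, I_pd1 = last$I_pd1)
  }
}

#' Plot a model trajectory
#'
#' @param object A `checkpoint_trajectory`.
#' @param ... Unused.
#' @return A ggplot with lymphocyte activities (top) and tumor count
#'   (bottom).
#' @export
autoplot.checkpoint_trajectory <- function(object, ...) {
  act <- object |>
    tibble::as_tibble() |>
    dplyr::select("t_h", "Lu", "Lp", "Le", "L_total") |>
    tidyr::pivot_longer(-"t_h", names_to = "compartment",
                        values_to = "activity")
  p1 <- ggplot2::ggplot(act, ggplot2::aes(.data$t_h, .data$activity,
                                          colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "immune activity") +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(tibble::as_tibble(object),
                        ggplot2::aes(.data$t_h, .data$C)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "tumor cells") +
    ggplot2::theme_minimal()
  patchwork::wrap_plots(p1, p2, ncol = 1L)
}
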