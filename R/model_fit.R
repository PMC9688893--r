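#' Bundle an activity time series and tumor counts into an observation
#'
#' One fitting stage consumes a population activity curve (with optional
#' standard errors), the initial tumor-cell count and the final tumor-cell
#' count with its relative tolerance.
#'
#' @param activity Data frame with columns `t_h`, `activity` and optionally
#'   `se`.
#' @param c0 Initial live tumor-cell count (> 0).
#' @param c_final Final live tumor-cell count.
#' @param condition `"combo"`, `"anti_pd1"` or `"anti_ctla4"`.
#' @param c_tol Relative tolerance on `c_final` (reporting only).
#' @param truth Optional named list recording generating parameters (kept as
#'   metadata for recovery scoring of synthetic observations).
#' @return An `ode_observation` list.
#' @export
ode_observation <- function(activity, c0, c_final,
                            condition = c("combo", "anti_pd1", "anti_ctla4"),
                            c_tol = NA_real_, truth = NULL) {
  condition <- match.arg(condition)
  stopifnot(is.data.frame(activity), c0 > 0)
  activity <- tibble::as_tibble(activity)
  if (nrow(activity) == 0L) stop("empty activity series", call. = FALSE)
  stopifnot(all(c("t_h", "activity") %in% names(activity)))
  if (!"se" %in% names(activity)) activity$se <- NA_real_
  structure(
    list(activity = activity[order(activity$t_h), ], c0 = c0,
         c_final = c_final, condition = condition, c_tol = c_tol,
         truth = truth),
    class = "ode_observation"
  )
}

# initial state implied by an observation: all activity starts in Lu
# (for the anti-CTLA-4 stage this is the stated assumption; for the other
# scenarios the split is dynamically irrelevant), optionally overridden
obs_state0 <- function(obs, Lp0 = 0, Le0 = 0) {
  L0 <- obs$activity$activity[[1]]
  immune_state(Lu = max(L0 - Lp0 - Le0, 0), Lp = Lp0, Le = Le0, C = obs$c0)
}

# L_total at the observation times and C at t_end, fast path for fitting:
# only the four dynamical states are integrated (the tallies are not needed
# for the loss) and the RHS avoids named-vector overhead
simulate_at <- function(params_masked, state0, times, rtol = 1e-8,
                        atol = 1e-8) {
  tt <- sort(unique(c(0, times)))
  sg <- params_masked$sigma; gm <- params_masked$gamma
  bt <- params_masked$beta; xi <- params_masked$xi
  al <- params_masked$alpha
  rhs <- function(t, y, p) {
    Lu <- max(y[1L], 0); Lp <- max(y[2L], 0); Le <- max(y[3L], 0)
    C <- max(y[4L], 0)
    Cacc <- C / (1 + C^(1 / 3) / 6)
    gc <- gm * Cacc; xc <- xi * C
    list(c(
      -(gc + al + xc) * Lu,
      -(gc + al + xc) * Lp + al * Lu,
      -(gc + bt * Cacc + xc) * Le + al * Lp,
      -sg * Cacc * (Lu + Lp + Le)
    ))
  }
  y0 <- c(state0[["Lu"]], state0[["Lp"]], state0[["Le"]], state0[["C"]])
  sol <- suppressWarnings(
    deSolve::ode(y = y0, times = tt, func = rhs, parms = NULL,
                 method = "lsoda", rtol = rtol, atol = atol)
  )
  if (nrow(sol) < length(tt)) return(NULL)
  idx <- match(times, sol[, 1L])
  list(L_total = sol[idx, 2L] + sol[idx, 3L] + sol[idx, 4L],
       C_end = sol[nrow(sol), 5L])
}

#' Weighted least-squares loss of the tumor-lymphocyte model
#'
#' Sum of squared residuals between the simulated total lymphocyte activity
#' and the observed activity series (inverse-variance weighted when standard
#' errors are present), plus `w_c` times the squared relative error of the
#' simulated final tumor count against the observed one. A failed simulation
#' yields a large finite loss so quasi-Newton iterations can recover.
#'
#' @param params A [rate_parameters()] object (per hour).
#' @param obs An [ode_observation()].
#' @param scenario Scenario to apply; defaults to the observation condition.
#' @param w_c Weight of the final-count term; default the number of activity
#'   points, so the count term is comparable to the activity term.
#' @param Lp0,Le0 Optional initial activity in the partially/fully expressed
#'   compartments.
#' @return Scalar loss.
#' @export
checkpoint_loss <- function(params, obs, scenario = obs$condition,
                            w_c = NULL, Lp0 = 0, Le0 = 0) {
  stopifnot(inherits(obs, "ode_observation"))
  if (is.null(w_c)) w_c <- nrow(obs$activity)
  masked <- apply_scenario(params, scenario)
  state0 <- obs_state0(obs, Lp0 = Lp0, Le0 = Le0)
  t_end <- max(obs$activity$t_h)
  # rate combinations whose fastest timescale is far below the observation
  # resolution describe instantaneous collapse, not the data; skip the
  # integrator and return a large penalty
  Cacc0 <- accessible_fraction(obs$c0)
  L0 <- state0[["Lu"]] + state0[["Lp"]] + state0[["Le"]]
  decay0 <- (masked$gamma + masked$beta) * Cacc0 + masked$xi * obs$c0 +
    masked$alpha
  kill0 <- masked$sigma * Cacc0 * L0
  if (decay0 > 200 || kill0 > 200 * obs$c0) return(1e25)
  sim <- tryCatch(
    simulate_at(masked, state0, obs$activity$t_h),
    error = function(e) NULL
  )
  if (is.null(sim) || anyNA(sim$L_total)) return(1e30)
  w <- ifelse(is.finite(obs$activity$se) & obs$activity$se > 0,
              1 / obs$activity$se^2, 1)
  act_term <- sum(w * (sim$L_total - obs$activity$activity)^2)
  cnt_term <- w_c * ((sim$C_end - obs$c_final) / obs$c_final)^2
  act_term + cnt_term
}

# quasi-Newton fit of log-transformed free rates; coarse log-grid search,
# then seeded multi-starts log-uniform within +/- `decades` around the grid
# optimum, best loss wins (ties to the first start)
fit_rates <- function(obs, free, fixed, scenario = obs$condition,
                      Lp0 = 0, Le0 = 0, n_starts = 5L, decades = 2,
                      seed = 1L, grid_ranges = NULL, maxit = 500L) {
  full <- function(logfree) {
    vals <- fixed
    vals[free] <- exp(logfree)
    rate_parameters(vals[["sigma"]], vals[["gamma"]], vals[["beta"]],
                    vals[["xi"]], vals[["alpha"]], time_unit = "per_hour")
  }
  objective <- function(logfree) {
    checkpoint_loss(full(logfree), obs, scenario = scenario,
                    Lp0 = Lp0, Le0 = Le0)
  }
  default_ranges <- list(
    sigma = c(1e-9, 1e-4), xi = c(1e-9, 1e-4),
    gamma = c(1e-8, 1e-3), beta = c(1e-8, 1e-3), alpha = c(1e-3, 10)
  )
  if (is.null(grid_ranges)) grid_ranges <- default_ranges
  axes <- lapply(free, function(p) {
    rg <- log(grid_ranges[[p]])
    seq(rg[1], rg[2], length.out = 7L)
  })
  grid_pts <- as.matrix(expand.grid(axes))
  grid_loss <- apply(grid_pts, 1L, objective)
  x0 <- grid_pts[which.min(grid_loss), ]

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  starts <- c(list(x0), lapply(seq_len(n_starts - 1L), function(i) {
    x0 + stats::runif(length(x0), -decades, decades) * log(10)
  }))
  runs <- lapply(starts, function(s) {
    tryCatch(
      stats::optim(s, objective, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-12)),
      error = function(e) list(par = s, value = objective(s),
                               convergence = 99L, counts = c(0L, 0L))
    )
  })
  best <- runs[[which.min(vapply(runs, function(r) r$value, numeric(1)))]]
  est <- stats::setNames(exp(best$par), free)
  structure(
    list(
      estimates = est,
      fixed = fixed[setdiff(names(fixed), free)],
      loss = best$value,
      convergence = best$convergence == 0L,
      iterations = unname(best$counts[[1]]),
      at_lower_bound = stats::setNames(est < 1e-10, free),
      condition = obs$condition,
      scenario = scenario,
      params = full(best$par),
      c_final_sim = {
        sim <- simulate_at(apply_scenario(full(best$par), scenario),
                           obs_state0(obs, Lp0, Le0),
                           max(obs$activity$t_h))
        sim$C_end
      },
      c_final_obs = obs$c_final,
      c_tol = obs$c_tol,
      obs = obs,
      Lp0 = Lp0, Le0 = Le0
    ),
    class = "checkpoint_fit"
  )
}

#' @export
print.checkpoint_fit <- function(x, ...) {
  cat(sprintf("checkpoint model fit (%s stage)\n", x$condition))
  for (nm in names(x$estimates)) {
    cat(sprintf("  %-6s %.4g /hr%s\n", nm, x$estimates[[nm]],
                if (x$at_lower_bound[[nm]]) "  [at lower bound]" else ""))
  }
  cat(sprintf("  loss %.4g, converged %s, simulated final count %.0f (obs %.0f)\n",
              x$loss, x$convergence, x$c_final_sim, x$c_final_obs))
  invisible(x)
}

#' @export
tidy.checkpoint_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    at_lower_bound = unname(x$at_lower_bound),
    stage = x$condition
  )
}

#' @export
glance.checkpoint_fit <- function(x, ...) {
  tibble::tibble(
    loss = x$loss, converged = x$convergence, iterations = x$iterations,
    c_final_sim = x$c_final_sim, c_final_obs = x$c_final_obs,
    stage = x$condition
  )
}

#' Stage 1: non-checkpoint suppression and tumor-killing rates
#'
#' Under combined blockade both checkpoints (and PD-1 expression) are
#' silenced, leaving only the non-checkpoint suppression rate `xi` and the
#' tumor-cell death rate `sigma` active; both are estimated jointly from the
#' combined-blockade activity curve and final tumor count.
#'
#' @param obs An [ode_observation()] with `condition = "combo"`.
#' @param n_starts,seed Multi-start settings.
#' @return A `checkpoint_fit` with estimates `xi`, `sigma`.
#' @export
fit_stage_combo <- function(obs, n_starts = 5L, seed = 1L) {
  stopifnot(inherits(obs, "ode_observation"))
  if (obs$condition != "combo") {
    stop("stage-1 observation must have condition 'combo'", call. = FALSE)
  }
  fit_rates(obs, free = c("xi", "sigma"),
            fixed = c(sigma = NA_real_, gamma = 0, beta = 0, xi = NA_real_,
                      alpha = 0),
            n_starts = n_starts, seed = seed)
}

#' Stage 2: CTLA-4 suppression rate from the anti-PD-1 condition
#'
#' With PD-1 blocked, the activity decline is driven by CTLA-4 (rate
#' `gamma`) plus the previously fixed non-checkpoint channel. `xi` and
#' `sigma` come from the combined-blockade stage; the simulated final tumor
#' count is reported against the observed one as validation.
#'
#' @param obs An [ode_observation()] with `condition = "anti_pd1"`.
#' @param xi,sigma Rates fixed from [fit_stage_combo()].
#' @param alpha PD-1 expression rate carried in the state (dynamically inert
#'   while `beta = 0`).
#' @inheritParams fit_stage_combo
#' @return A `checkpoint_fit` with estimate `gamma`.
#' @export
fit_stage_pd1_blockade <- function(obs, xi, sigma, alpha = 0.22,
                                   n_starts = 5L, seed = 1L) {
  stopifnot(inherits(obs, "ode_observation"))
  if (obs$condition != "anti_pd1") {
    stop("stage-2 observation must have condition 'anti_pd1'", call. = FALSE)
  }
  fit_rates(obs, free = "gamma",
            fixed = c(sigma = sigma, gamma = NA_real_, beta = 0, xi = xi,
                      alpha = alpha),
            n_starts = n_starts, seed = seed)
}

#' Stage 3: PD-1 expression and suppression rates from the anti-CTLA-4
#' condition
#'
#' With CTLA-4 blocked, the delayed activity decline identifies the PD-1
#' expression rate `alpha` (the delay scale, mean `2/alpha` hours) and the
#' PD-1 suppression rate `beta`. All initial activity is placed in the
#' PD-1-unexpressed compartment unless `Lp0`/`Le0` override it.
#'
#' @param obs An [ode_observation()] with `condition = "anti_ctla4"`.
#' @param xi,sigma Rates fixed from [fit_stage_combo()].
#' @param Lp0,Le0 Optional initial activity already expressing PD-1.
#' @inheritParams fit_stage_combo
#' @return A `checkpoint_fit` with estimates `alpha`, `beta`.
#' @export
fit_stage_ctla4_blockade <- function(obs, xi, sigma, Lp0 = 0, Le0 = 0,
                                     n_starts = 5L, seed = 1L) {
  stopifnot(inherits(obs, "ode_observation"))
  if (obs$condition != "anti_ctla4") {
    stop("stage-3 observation must have condition 'anti_ctla4'",
         call. = FALSE)
  }
  fit_rates(obs, free = c("alpha", "beta"),
            fixed = c(sigma = sigma, gamma = 0, beta = NA_real_,
                      xi = xi, alpha = NA_real_),
            Lp0 = Lp0, Le0 = Le0, n_starts = n_starts, seed = seed)
}

#' Profile the loss along one fitted rate
#'
#' Rescales one estimated rate by a set of factors while holding the others
#' at their fitted values, and evaluates the loss at each point. A flat
#' profile (small relative loss increase across factors well away from 1)
#' flags a poorly identified parameter - e.g. `alpha` when the activity
#' series is truncated before the decline sets in.
#'
#' @param fit A `checkpoint_fit`.
#' @param param Name of the estimated rate to profile.
#' @param factors Multiplicative factors (default 2^(-2..2)).
#' @return Tibble with `factor`, `value`, `loss` and `rel_increase` over the
#'   fitted loss.
#' @export
loss_profile <- function(fit, param, factors = 2^seq(-2, 2, by = 0.5)) {
  stopifnot(inherits(fit, "checkpoint_fit"), param %in% names(fit$estimates))
  base <- fit$params
  losses <- vapply(factors, function(f) {
    p <- base
    p[[param]] <- fit$estimates[[param]] * f
    pr <- rate_parameters(p$sigma, p$gamma, p$beta, p$xi, p$alpha,
                          time_unit = "per_hour")
    checkpoint_loss(pr, fit$obs, scenario = fit$scenario,
                    Lp0 = fit$Lp0, Le0 = fit$Le0)
  }, numeric(1))
  loss0 <- checkpoint_loss(base, fit$obs, scenario = fit$scenario,
                           Lp0 = fit$Lp0, Le0 = fit$Le0)
  tibble::tibble(
    factor = factors,
    value = fit$estimates[[param]] * factors,
    loss = losses,
    rel_increase = (losses - loss0) / max(loss0, .Machine$double.eps)
  )
}

#' Run the full three-stage estimation protocol
#'
#' Stages run in order: (1) `xi`, `sigma` from combined blockade; (2)
#' `gamma` from anti-PD-1 with stage-1 rates fixed; (3) `alpha`, `beta` from
#' anti-CTLA-4 with stage-1 rates fixed. A failure in one stage aborts the
#' downstream stages while preserving the completed ones.
#'
#' @param obs_combo,obs_pd1,obs_ctla4 [ode_observation()] objects for the
#'   three conditions.
#' @param step_h Hours per step used for the per-step unit column of the
#'   report.
#' @inheritParams fit_stage_combo
#' @return A `staged_fit` list with elements `stages` (the three
#'   `checkpoint_fit`s), `rates` (combined [rate_parameters()], per hour)
#'   and `report` (tibble of the five rates in per-hour and per-step units).
#' @export
staged_fit <- function(obs_combo, obs_pd1, obs_ctla4, step_h = 0.25,
                       n_starts = 5L, seed = 1L) {
  for (o in list(obs_combo, obs_pd1, obs_ctla4)) {
    if (!inherits(o, "ode_observation")) {
      stop("all three observations are required", call. = FALSE)
    }
  }
  if (obs_combo$condition != "combo") {
    stop("missing combo observation: stage 1 cannot run", call. = FALSE)
  }
  s1 <- fit_stage_combo(obs_combo, n_starts = n_starts, seed = seed)
  stages <- list(combo = s1)
  if (!is.finite(s1$loss) || s1$loss >= 1e30) {
    stop("stage 1 failed; downstream stages aborted", call. = FALSE)
  }
  s2 <- fit_stage_pd1_blockade(obs_pd1, xi = s1$estimates[["xi"]],
                               sigma = s1$estimates[["sigma"]],
                               n_starts = n_starts, seed = seed)
  stages$anti_pd1 <- s2
  s3 <- fit_stage_ctla4_blockade(obs_ctla4, xi = s1$estimates[["xi"]],
                                 sigma = s1$estimates[["sigma"]],
                                 n_starts = n_starts, seed = seed)
  stages$anti_ctla4 <- s3

  rates_h <- rate_parameters(
    sigma = s1$estimates[["sigma"]],
    gamma = s2$estimates[["gamma"]],
    beta = s3$estimates[["beta"]],
    xi = s1$estimates[["xi"]],
    alpha = s3$estimates[["alpha"]],
    time_unit = "per_hour"
  )
  rates_s <- convert_rate_units(rates_h, step_h = step_h, to = "per_step")
  nm <- c("sigma", "gamma", "beta", "xi", "alpha")
  report <- tibble::tibble(
    parameter = nm,
    definition = c("tumor cell death rate",
                   "CTLA-4-induced inactivation rate",
                   "PD-1-induced inactivation rate",
                   "non-checkpoint inactivation rate",
                   "PD-1 expression rate"),
    per_hour = vapply(nm, function(p) rates_h[[p]], numeric(1)),
    per_step = vapply(nm, function(p) rates_s[[p]], numeric(1)),
    stage = c("combo", "anti_pd1", "anti_ctla4", "combo", "anti_ctla4")
  )
  structure(list(stages = stages, rates = rates_h, rates_per_step = rates_s,
                 report = report, step_h = step_h),
            class = "staged_fit")
}

#' @export
print.staged_fit <- function(x, ...) {
  cat("three-stage tumor-lymphocyte model fit\n")
  print(x$report)
  invisible(x)
}

#' @export
tidy.staged_fit <- function(x, ...) x$report

#' @export
glance.staged_fit <- function(x, ...) {
  tibble::tibble(
    loss_combo = x$stages$combo$loss,
    loss_anti_pd1 = x$stages$anti_pd1$loss,
    loss_anti_ctla4 = x$stages$anti_ctla4$loss,
    converged = all(vapply(x$stages, function(s) s$convergence, logical(1)))
  )
}
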