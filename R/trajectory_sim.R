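#' Profile of time-varying AR(1) parameters for simulation
#'
#' @param q Persistence per step, recycled to `n_steps`; values in `[-1, 1]`.
#' @param a Activity per step (um/step), recycled to `n_steps`; values >= 0.
#' @param n_steps Number of displacement steps.
#' @param u0 Initial displacement preceding the first simulated one (default
#'   the origin, so the first step is pure noise).
#' @return An `ar_profile` list with vectors `q`, `a` of length `n_steps`
#'   and `u0`.
#' @export
ar_profile <- function(q, a, n_steps = max(length(q), length(a)),
                       u0 = c(0, 0)) {
  q <- rep_len(q, n_steps)
  a <- rep_len(a, n_steps)
  if (any(a < 0)) stop("activity a must be >= 0", call. = FALSE)
  if (any(abs(q) > 1)) stop("persistence q must lie in [-1, 1]", call. = FALSE)
  structure(list(q = q, a = a, u0 = as.numeric(u0)), class = "ar_profile")
}

#' Simulate one 2D AR(1) trajectory
#'
#' Forward simulation of the heterogeneous random walk
#' `u(t) = q(t) u(t-1) + a(t) n(t)` with independent standard-normal noise
#' components; positions are cumulative sums of the displacements starting
#' from the origin. Bitwise reproducible for a fixed seed.
#'
#' @param profile An [ar_profile()].
#' @param seed Integer seed.
#' @param cell_id Cell label for the output table.
#' @param step_h Hours per step.
#' @return A single-cell `track_table` with `n_steps + 1` points.
#' @export
simulate_ar1 <- function(profile, seed = 1L, cell_id = "sim1",
                         step_h = 0.25) {
  stopifnot(inherits(profile, "ar_profile"))
  n <- length(profile$q)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  noise <- matrix(stats::rnorm(2L * n), n, 2L)
  u <- matrix(0, n, 2L)
  u_prev <- profile$u0
  for (t in seq_len(n)) {
    u[t, ] <- profile$q[t] * u_prev + profile$a[t] * noise[t, ]
    u_prev <- u[t, ]
  }
  pos <- rbind(c(0, 0), apply(u, 2L, cumsum))
  as_track_table(
    tibble::tibble(
      cell_id = cell_id,
      frame = seq_len(n + 1L) - 1L,
      x = pos[, 1],
      y = pos[, 2]
    ),
    step_h = step_h
  )
}

# deterministic sub-seed for cell i of a cohort; keeps seeds within 32-bit
# integer range
cohort_subseed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 10007 + i * 7919) %% 2147483647)
}

#' Simulate a cohort of AR(1) trajectories
#'
#' One cell per profile. Per-cell seeds are derived deterministically from
#' the master seed (`(seed * 10007 + i * 7919) mod (2^31 - 1)` for cell
#' `i`), so a cohort is reproducible cell by cell.
#'
#' @param profiles A named list of [ar_profile()] objects; names become cell
#'   ids (default `cell01`, `cell02`, ...).
#' @param seed Master integer seed.
#' @param step_h Hours per step.
#' @param condition Condition label for the output table.
#' @return A `track_table` with `length(profiles)` cells.
#' @export
simulate_cohort <- function(profiles, seed = 1L, step_h = 0.25,
                            condition = NA_character_) {
  stopifnot(length(profiles) >= 1L)
  ids <- names(profiles)
  if (is.null(ids)) ids <- sprintf("cell%02d", seq_along(profiles))
  if (anyDuplicated(ids)) stop("duplicate cell ids", call. = FALSE)
  tabs <- purrr::imap(profiles, function(p, nm) {
    i <- match(nm, ids)
    simulate_ar1(p, seed = cohort_subseed(seed, i), cell_id = ids[[i]],
                 step_h = step_h)
  })
  as_track_table(dplyr::bind_rows(tabs), step_h = step_h,
                 condition = condition)
}

#' Turn an inferred parameter track into simulation profiles
#'
#' Uses the per-step posterior means of `q` and `a` for each cell, the
#' inverse of the estimation step: estimating parameters from tracks,
#' simulating with them and re-estimating is the model's internal validation
#' loop.
#'
#' @param tracks A `parameter_track` covering one or more cells.
#' @param activity Which activity point estimate to simulate with:
#'   `"gmean"` (posterior geometric mean, default - unbiased on the log
#'   scale, so resimulated displacement magnitudes are not inflated by the
#'   posterior's right skew) or `"mean"` (arithmetic posterior mean).
#' @return Named list of [ar_profile()] objects, one per cell.
#' @export
profiles_from_track <- function(tracks, activity = c("gmean", "mean")) {
  stopifnot(is.data.frame(tracks))
  activity <- match.arg(activity)
  acol <- if (activity == "gmean" && "a_gmean" %in% names(tracks)) {
    "a_gmean"
  } else {
    "a_mean"
  }
  grouped <- dplyr::group_by(tracks, .data$cell_id)
  out <- dplyr::group_map(grouped, function(d, key) {
    ar_profile(q = pmin(1, pmax(-1, d$q_mean)), a = pmax(0, d[[acol]]))
  })
  stats::setNames(out, dplyr::group_keys(grouped)$cell_id)
}
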