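#' Parameter grid for the heterogeneous random walk filter
#'
#' The AR(1) migration model `u(t) = q(t) u(t-1) + a(t) n(t)` has persistence
#' `q` on `[-1, 1]` (anti-persistent through ballistic) and activity `a > 0`
#' (standard deviation of the Gaussian step noise, um per step). The
#' sequential filter represents the joint posterior on a fixed rectangular
#' grid over these two parameters.
#'
#' @param n_q,n_a Number of grid values for persistence and activity
#'   (default 51 each).
#' @param a_max Upper end of the activity grid (um/step). The inference
#'   default is 3 times the largest windowed RMS displacement component of
#'   the series, which covers the activity's likelihood mass for any
#'   persistence.
#' @param a_min Lower end of the activity grid (default `a_max / 100`).
#' @param log_a Space the activity grid logarithmically? Default `TRUE`:
#'   activity is a scale parameter that can decay over orders of magnitude
#'   within one track, and a log grid resolves both the active and the
#'   suppressed regime; with the index-space drift kernel this corresponds
#'   to multiplicative activity drift.
#' @return A `parameter_grid` list with numeric vectors `q` (spanning exactly
#'   `[-1, 1]`) and `a` (strictly positive and increasing).
#' @export
parameter_grid <- function(n_q = 51L, n_a = 51L, a_max = 3,
                           a_min = a_max / 100, log_a = TRUE) {
  stopifnot(n_q >= 2L, n_a >= 2L, a_max > 0, a_min > 0, a_min < a_max)
  a <- if (log_a) {
    exp(seq(log(a_min), log(a_max), length.out = n_a))
  } else {
    seq(a_min, a_max, length.out = n_a)
  }
  structure(
    list(q = seq(-1, 1, length.out = n_q), a = a),
    class = "parameter_grid"
  )
}

#' AR(1) step likelihood
#'
#' Density of observing displacement `u_t` given the previous displacement
#' `u_prev`, persistence `q` and activity `a`: the product over the x and y
#' components of a normal density with mean `q * u_prev` and standard
#' deviation `a`. When `u_prev = (0, 0)` the density does not depend on `q`
#' (persistence is unidentifiable at that step).
#'
#' @param u_t,u_prev Numeric length-2 displacement vectors (um/step).
#' @param q Persistence in `[-1, 1]`; may be a vector.
#' @param a Activity (> 0); may be a vector.
#' @param log Return the log density?
#' @return Density values, recycled over `q` and `a`.
#' @export
step_likelihood <- function(u_t, u_prev, q, a, log = FALSE) {
  if (any(a <= 0)) stop("activity a must be > 0", call. = FALSE)
  ll <- stats::dnorm(u_t[[1]], mean = q * u_prev[[1]], sd = a, log = TRUE) +
    stats::dnorm(u_t[[2]], mean = q * u_prev[[2]], sd = a, log = TRUE)
  if (log) ll else exp(ll)
}

# log-likelihood over the full grid: n_q x n_a matrix
grid_loglik <- function(u_t, u_prev, grid) {
  r2 <- (u_t[[1]] - grid$q * u_prev[[1]])^2 +
    (u_t[[2]] - grid$q * u_prev[[2]])^2
  inv2a2 <- 1 / (2 * grid$a^2)
  -outer(r2, inv2a2) - rep(log(2 * pi * grid$a^2), each = length(grid$q))
}

# column-normalised Gaussian drift kernel with reflecting boundaries;
# sd is in grid cells
drift_kernel <- function(n, sd) {
  if (sd <= 0) return(diag(n))
  p <- ceiling(4 * sd)
  ext <- seq(1L - p, n + p)
  src <- ifelse(ext < 1L, 2L - ext, ifelse(ext > n, 2L * n - ext, ext))
  K <- matrix(0, n, n)
  for (k in seq_along(ext)) {
    w <- stats::dnorm(seq_len(n) - ext[k], sd = sd)
    K[, src[k]] <- K[, src[k]] + w
  }
  sweep(K, 2L, colSums(K), "/")
}

# default activity-grid ceiling: 3 x the largest windowed per-component RMS
# displacement. The component RMS bounds the activity from above for any
# persistence (sd(u) = a / sqrt(1 - q^2) >= a); windowing keeps the bound
# tight when activity peaks early and decays.
default_a_max <- function(ux, uy, window = 25L) {
  s <- (ux^2 + uy^2) / 2
  n <- length(s)
  w <- min(window, n)
  cs <- cumsum(c(0, s))
  win_means <- (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
  max(3 * sqrt(max(win_means)), 1e-6)
}

marginal_summary <- function(p, values, level = 0.90) {
  p <- p / sum(p)
  cdf <- cumsum(p)
  lo_p <- (1 - level) / 2
  c(
    mean = sum(p * values),
    lo = values[which(cdf >= lo_p)[1]],
    hi = values[which(cdf >= 1 - lo_p)[1]]
  )
}

#' Sequential Bayesian inference of time-varying AR(1) parameters
#'
#' Grid-based filter for one displacement series. The first step starts from
#' a uniform prior over the grid; each posterior is propagated to the next
#' step's prior by convolution with a separable Gaussian drift kernel
#' (reflected at the grid boundaries), which lets the parameter estimates
#' track slow changes in persistence and activity. Each step's prior is
#' multiplied by the AR(1) step likelihood and renormalised.
#'
#' @param series A data frame with columns `ux`, `uy` — the displacement
#'   series of one cell (as one group from [to_displacements()]).
#' @param grid A [parameter_grid()]; by default 51 x 51 with `a_max` set to
#'   3 times the largest 25-step windowed RMS displacement component, which
#'   covers the activity's likelihood mass while keeping the grid fine near
#'   the data scale.
#' @param forget_sd Drift-kernel standard deviation in grid cells; a single
#'   value or a pair `c(q, a)` to let persistence drift more slowly than
#'   activity (persistence varies only moderately over an experiment while
#'   activity can decline sharply). Default 0.5 for both. `0` disables
#'   forgetting (static-parameter posterior).
#' @param u0 Displacement preceding the first one in the series (default
#'   `c(0, 0)`, so the first step is treated as pure noise).
#' @param level Credible-interval mass (default 0.90).
#' @param cell_id Label carried into the output.
#' @param smooth Run a backward pass after the forward filter and report
#'   smoothed posteriors (each step conditioned on the whole series)?
#'   Smoothing removes the filter's tracking lag and roughly halves the
#'   estimator variance, which matters when the estimated profile is used to
#'   resimulate trajectories; the default `FALSE` is the purely sequential
#'   filter.
#' @param return_posterior Also return the per-step joint posterior array?
#' @return A `parameter_track` tibble with one row per step: posterior mean
#'   and central credible interval of `q` and `a`, plus the posterior
#'   geometric mean of `a` (`a_gmean`, the estimator used for trajectory
#'   resimulation, where the arithmetic mean's skew bias would inflate the
#'   mean-square displacement). With
#'   `return_posterior = TRUE`, a list with elements `track` and `posterior`
#'   (array `n_steps x n_q x n_a`).
#' @export
sequential_infer <- function(series, grid = NULL, forget_sd = 0.5, u0 = c(0, 0),
                             level = 0.90, cell_id = "cell",
                             smooth = FALSE, return_posterior = FALSE) {
  ux <- series$ux
  uy <- series$uy
  n <- length(ux)
  stopifnot(n >= 1L)
  if (is.null(grid)) {
    grid <- parameter_grid(a_max = default_a_max(ux, uy))
  }
  n_q <- length(grid$q)
  n_a <- length(grid$a)
  forget_sd <- rep_len(forget_sd, 2L)
  Kq <- drift_kernel(n_q, forget_sd[[1]])
  Ka <- drift_kernel(n_a, forget_sd[[2]])

  prior <- matrix(1 / (n_q * n_a), n_q, n_a)
  log_a <- log(grid$a)
  track <- matrix(NA_real_, n, 7L)
  keep_filtered <- smooth || return_posterior
  post_arr <- if (keep_filtered) array(NA_real_, c(n, n_q, n_a)) else NULL
  u_prev <- u0
  for (t in seq_len(n)) {
    ll <- grid_loglik(c(ux[t], uy[t]), u_prev, grid)
    post <- prior * exp(ll - max(ll))
    post <- post / sum(post)
    qs <- marginal_summary(rowSums(post), grid$q, level)
    pa <- colSums(post)
    as <- marginal_summary(pa, grid$a, level)
    track[t, ] <- c(qs, as, exp(sum(pa / sum(pa) * log_a)))
    if (keep_filtered) post_arr[t, , ] <- post
    prior <- Kq %*% post %*% t(Ka)
    prior <- prior / sum(prior)
    u_prev <- c(ux[t], uy[t])
  }
  if (smooth) {
    # backward pass: the smoothed step-t posterior is the filtered one
    # reweighted by the likelihood of all later displacements
    beta <- matrix(1 / (n_q * n_a), n_q, n_a)
    for (t in seq(n, 1L)) {
      post <- post_arr[t, , ] * beta
      post <- post / sum(post)
      if (return_posterior) post_arr[t, , ] <- post
      qs <- marginal_summary(rowSums(post), grid$q, level)
      pa <- colSums(post)
      as <- marginal_summary(pa, grid$a, level)
      track[t, ] <- c(qs, as, exp(sum(pa / sum(pa) * log_a)))
      if (t > 1L) {
        u_prev_t <- c(ux[t - 1L], uy[t - 1L])
        ll <- grid_loglik(c(ux[t], uy[t]), u_prev_t, grid)
        msg <- exp(ll - max(ll)) * beta
        beta <- t(Kq) %*% msg %*% Ka
        beta <- beta / sum(beta)
      }
    }
  }
  out <- tibble::tibble(
    cell_id = cell_id,
    step = seq_len(n),
    q_mean = track[, 1], q_lo = track[, 2], q_hi = track[, 3],
    a_mean = track[, 4], a_lo = track[, 5], a_hi = track[, 6],
    a_gmean = track[, 7]
  )
  out <- structure(out, class = c("parameter_track", class(out)),
                   grid = grid, forget_sd = forget_sd, level = level,
                   smoothed = smooth)
  if (return_posterior) list(track = out, posterior = post_arr) else out
}

#' Infer AR(1) parameter tracks for every cell of a track table
#'
#' Maps [sequential_infer()] over the displacement series of all cells.
#'
#' @param table A `track_table`.
#' @inheritParams sequential_infer
#' @return A `parameter_track` tibble stacked over cells.
#' @export
infer_tracks <- function(table, grid = NULL, forget_sd = 0.5, level = 0.90,
                         smooth = FALSE) {
  disp <- to_displacements(table)
  out <- disp |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_map(function(d, key) {
      sequential_infer(d, grid = grid, forget_sd = forget_sd, level = level,
                       cell_id = key$cell_id[[1]], smooth = smooth)
    }) |>
    dplyr::bind_rows()
  structure(out, class = c("parameter_track", class(tibble::tibble())),
            forget_sd = forget_sd, level = level,
            step_h = attr(table, "step_h"))
}

#' Population-averaged activity and persistence
#'
#' Per-step unweighted mean of the per-cell posterior means over the cells
#' observed at that step, with the standard error of that mean. Steps with
#' no observed cell are omitted.
#'
#' @param tracks A `parameter_track` tibble covering one or more cells.
#' @return A `parameter_track` tibble with `cell_id = "population"` and
#'   columns `step`, `q_mean`, `q_se`, `a_mean`, `a_se`, `n_cells`.
#' @export
population_activity <- function(tracks) {
  stopifnot(is.data.frame(tracks), nrow(tracks) > 0L)
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  out <- tracks |>
    dplyr::group_by(.data$step) |>
    dplyr::summarise(
      # standard errors first: summarise evaluates sequentially, so the
      # means must not shadow the per-cell columns yet
      q_se = se(.data$q_mean), a_se = se(.data$a_mean),
      q_mean = mean(.data$q_mean), a_mean = mean(.data$a_mean),
      n_cells = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("step", "q_mean", "q_se", "a_mean", "a_se", "n_cells") |>
    dplyr::mutate(cell_id = "population", .before = 1L)
  structure(out, class = c("parameter_track", class(out)),
            step_h = attr(tracks, "step_h"))
}

#' Plot activity and persistence tracks
#'
#' @param object A `parameter_track`.
#' @param ... Unused.
#' @return A ggplot object with one panel per parameter.
#' @export
autoplot.parameter_track <- function(object, ...) {
  long <- object |>
    tibble::as_tibble() |>
    dplyr::select(dplyr::any_of(c("cell_id", "step", "q_mean", "a_mean"))) |>
    tidyr::pivot_longer(c("q_mean", "a_mean"),
                        names_to = "parameter", values_to = "value") |>
    dplyr::mutate(parameter = dplyr::recode(.data$parameter,
                                            q_mean = "persistence q",
                                            a_mean = "activity a"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "time step", y = NULL) +
    ggplot2::theme_minimal()
}
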