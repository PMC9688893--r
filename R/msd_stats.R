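#' Time-averaged mean-square displacement of a single track
#'
#' For a track `X(t)` of `n` points the time-averaged MSD at lag `tau` steps
#' is the mean of `|X(t + tau) - X(t)|^2` over all admissible start times
#' `t`. Lags run from 1 up to `max_lag_fraction * (n - 1)`: the longest lags
#' are excluded because they average very few pairs and amplify noise.
#'
#' @param positions Either a two-column numeric matrix of `(x, y)` positions
#'   ordered in time, or a `track_table` containing exactly one cell.
#' @param max_lag_fraction Largest lag as a fraction of the number of steps
#'   (default 0.75).
#' @param step_h Hours per step; taken from the `track_table` when available.
#' @return An `msd_curve`: tibble with columns `lag_steps`, `lag_h`,
#'   `msd` (um^2) and `n_pairs`.
#' @export
time_averaged_msd <- function(positions, max_lag_fraction = 0.75,
                              step_h = 0.25) {
  if (inherits(positions, "track_table")) {
    stopifnot(dplyr::n_distinct(positions$cell_id) == 1L)
    step_h <- attr(positions, "step_h")
    positions <- cell_positions(positions, positions$cell_id[[1]])
  }
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2L, max_lag_fraction > 0,
            max_lag_fraction <= 1)
  n <- nrow(positions)
  if (n < 3L) stop("track must have at least 3 points", call. = FALSE)
  max_lag <- max(1L, floor(max_lag_fraction * (n - 1L)))
  msd <- numeric(max_lag)
  n_pairs <- integer(max_lag)
  for (lag in seq_len(max_lag)) {
    idx <- seq_len(n - lag)
    d <- positions[idx + lag, , drop = FALSE] - positions[idx, , drop = FALSE]
    msd[lag] <- mean(rowSums(d^2))
    n_pairs[lag] <- length(idx)
  }
  structure(
    tibble::tibble(
      lag_steps = seq_len(max_lag),
      lag_h = seq_len(max_lag) * step_h,
      msd = msd,
      n_pairs = n_pairs
    ),
    class = c("msd_curve", "tbl_df", "tbl", "data.frame")
  )
}

#' Ensemble (population-averaged) mean-square displacement
#'
#' Computes the time-averaged MSD of every cell and averages across cells
#' with equal per-cell weight, so long tracks do not dominate the ensemble.
#' A lag is reported while at least one cell contributes to it; `n_cells`
#' records how many do.
#'
#' @param table A `track_table` with one or more cells.
#' @inheritParams time_averaged_msd
#' @return An `msd_curve` tibble with columns `lag_steps`, `lag_h`, `msd`,
#'   `n_pairs` (summed over cells) and `n_cells`.
#' @export
ensemble_msd <- function(table, max_lag_fraction = 0.75) {
  stopifnot(inherits(table, "track_table"))
  cells <- unique(table$cell_id)
  if (length(cells) == 0L) stop("empty track table", call. = FALSE)
  step_h <- attr(table, "step_h")
  per_cell <- purrr::map(cells, function(cl) {
    time_averaged_msd(cell_positions(table, cl),
                      max_lag_fraction = max_lag_fraction, step_h = step_h)
  })
  out <- dplyr::bind_rows(per_cell) |>
    dplyr::group_by(.data$lag_steps, .data$lag_h) |>
    dplyr::summarise(
      msd = mean(.data$msd),
      n_pairs = sum(.data$n_pairs),
      n_cells = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$lag_steps)
  structure(out, class = c("msd_curve", "tbl_df", "tbl", "data.frame"))
}

#' Fit a power law to an MSD curve
#'
#' Ordinary least squares on `log(msd)` versus `log(lag_steps)` over a lag
#' window. The slope is the anomalous-diffusion exponent (1 for Brownian,
#' 2 for ballistic, < 1 for sub-diffusion); the intercept gives a diffusion
#' coefficient under the convention `MSD(tau) = 4 D tau^exponent` with `tau`
#' in steps, i.e. `D = exp(intercept) / 4`. Zero-MSD lags are dropped before
#' fitting.
#'
#' @param curve An `msd_curve`.
#' @param window Integer range of lags (in steps) to fit; default all lags
#'   present in the curve.
#' @return A `powerlaw_fit` list with elements `exponent`,
#'   `diffusion_coefficient`, `intercept`, `fit_range`, `n_lags`,
#'   `r_squared`.
#' @export
fit_power_law <- function(curve, window = NULL) {
  stopifnot(is.data.frame(curve), all(c("lag_steps", "msd") %in% names(curve)))
  if (is.null(window)) window <- range(curve$lag_steps)
  keep <- curve$lag_steps >= min(window) & curve$lag_steps <= max(window) &
    curve$msd > 0
  dat <- curve[keep, ]
  if (nrow(dat) < 3L) {
    stop("need at least 3 positive-MSD lags in the fit window", call. = FALSE)
  }
  fit <- stats::lm(log(msd) ~ log(lag_steps), data = dat)
  co <- stats::coef(fit)
  y <- log(dat$msd)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(
      exponent = unname(co[[2]]),
      intercept = unname(co[[1]]),
      diffusion_coefficient = exp(unname(co[[1]])) / 4,
      fit_range = c(min(dat$lag_steps), max(dat$lag_steps)),
      n_lags = nrow(dat),
      r_squared = r2
    ),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "MSD power-law fit: exponent %.4f, D %.4g um^2/step (lags %d-%d, R^2 %.3f)\n",
    x$exponent, x$diffusion_coefficient, x$fit_range[1], x$fit_range[2],
    x$r_squared
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble::tibble(
    term = c("exponent", "diffusion_coefficient"),
    estimate = c(x$exponent, x$diffusion_coefficient)
  )
}

#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble::tibble(
    exponent = x$exponent,
    diffusion_coefficient = x$diffusion_coefficient,
    r_squared = x$r_squared,
    n_lags = x$n_lags,
    lag_min = x$fit_range[1],
    lag_max = x$fit_range[2]
  )
}

#' Plot an MSD curve on log-log axes
#'
#' @param object An `msd_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_h, y = .data$msd)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag (h)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
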