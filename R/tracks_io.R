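#' Read a single-cell track table
#'
#' Reads a delimited text file of cell positions (one row per cell per frame)
#' into a validated track table. The expected columns are `cell_id`, `frame`
#' (or `time`, interpreted as hours and converted with `step_h`), `x` and `y`
#' in micrometres. An optional `z` column is accepted and dropped with a
#' warning: the tracks analysed here are 2D projections of trajectories in 3D
#' culture. Lines starting with `#` are comments.
#'
#' Frames must be unique and strictly increasing within a cell. A gap in the
#' frame sequence splits the track into separate segments (suffixed
#' `<cell_id>.s2`, `.s3`, ...) rather than interpolating across the gap, so
#' that every consecutive pair of rows is exactly one imaging interval apart
#' and displacement-based likelihoods stay unbiased.
#'
#' @param path Path to a TSV or CSV file with a header.
#' @param step_h Imaging interval in hours per frame (default 0.25, i.e.
#'   15 min).
#' @param condition Optional condition label attached to the table
#'   (`"combo"`, `"anti_pd1"`, `"anti_ctla4"` or `"control"`).
#' @return A `track_table`: a tibble with columns `cell_id` (character),
#'   `frame` (integer, 0-based), `time_h`, `x`, `y`, carrying `step_h` and
#'   `condition` attributes.
#' @seealso [write_tracks()], [to_displacements()]
#' @export
read_tracks <- function(path, step_h = 0.25, condition = NA_character_) {
  if (!file.exists(path)) {
    stop("track file does not exist: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(first, "#") & nzchar(first)]
  if (length(first) == 0L) stop("track file is empty: ", path, call. = FALSE)
  delim <- if (grepl("\t", first[[1]])) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, comment = "#", show_col_types = FALSE,
    progress = FALSE
  )
  names(raw) <- tolower(names(raw))
  if (!"frame" %in% names(raw) && "time" %in% names(raw)) {
    raw$frame <- as.integer(round(raw$time / step_h))
    raw$time <- NULL
  }
  needed <- c("cell_id", "frame", "x", "y")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop(
      "track file is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if ("z" %in% names(raw)) {
    warning("dropping z column: tracks are treated as 2D projections",
            call. = FALSE)
    raw$z <- NULL
  }
  tab <- tibble::tibble(
    cell_id = as.character(raw$cell_id),
    frame = as.integer(raw$frame),
    x = as.numeric(raw$x),
    y = as.numeric(raw$y)
  )
  as_track_table(tab, step_h = step_h, condition = condition)
}

#' Build a validated track table from a data frame
#'
#' Validates the track-table invariants (no duplicate cell/frame pairs,
#' strictly increasing frames within a cell, at least two points per cell),
#' splits tracks at frame gaps, sorts by `(cell_id, frame)` and recomputes
#' `time_h = frame * step_h`.
#'
#' @param x A data frame with columns `cell_id`, `frame`, `x`, `y`.
#' @inheritParams read_tracks
#' @return A `track_table` tibble.
#' @export
as_track_table <- function(x, step_h = 0.25, condition = NA_character_) {
  stopifnot(is.data.frame(x), step_h > 0)
  tab <- tibble::as_tibble(x)[, c("cell_id", "frame", "x", "y")]
  tab$cell_id <- as.character(tab$cell_id)
  tab$frame <- as.integer(tab$frame)
  if (any(tab$frame < 0L, na.rm = TRUE)) {
    stop("negative frame index in track table", call. = FALSE)
  }

  dup <- tab |>
    dplyr::count(.data$cell_id, .data$frame) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop(
      "duplicate (cell_id, frame) pairs for cell(s): ",
      paste(unique(dup$cell_id), collapse = ", "),
      call. = FALSE
    )
  }

  # frames must already be strictly increasing within each cell: out-of-order
  # rows signal a corrupted export, not a sorting preference
  bad <- tab |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(mono = all(diff(.data$frame) > 0L)) |>
    dplyr::filter(!.data$mono)
  if (nrow(bad) > 0L) {
    stop(
      "non-monotone frames within cell(s): ",
      paste(bad$cell_id, collapse = ", "),
      call. = FALSE
    )
  }
  tab <- dplyr::arrange(tab, .data$cell_id, .data$frame)

  # split segments at frame gaps instead of interpolating
  tab <- tab |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(.seg = cumsum(c(1L, diff(.data$frame) > 1L))) |>
    dplyr::ungroup()
  n_gaps <- tab |>
    dplyr::distinct(.data$cell_id, .data$.seg) |>
    dplyr::count(.data$cell_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(n_gaps) > 0L) {
    warning(
      "frame gaps: split ", nrow(n_gaps), " cell(s) into segments (",
      paste(n_gaps$cell_id, collapse = ", "), ")",
      call. = FALSE
    )
    tab$cell_id <- ifelse(tab$.seg > 1L,
                          paste0(tab$cell_id, ".s", tab$.seg),
                          tab$cell_id)
  }
  tab$.seg <- NULL

  short <- tab |>
    dplyr::count(.data$cell_id) |>
    dplyr::filter(.data$n < 2L)
  if (nrow(short) > 0L) {
    warning("dropping ", nrow(short), " cell(s)/segment(s) with < 2 points",
            call. = FALSE)
    tab <- dplyr::filter(tab, !.data$cell_id %in% short$cell_id)
  }

  tab <- dplyr::mutate(tab, time_h = .data$frame * step_h,
                       .after = "frame")
  structure(
    tab,
    step_h = step_h,
    condition = condition,
    class = c("track_table", class(tab))
  )
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf(
    "# track_table: %d cells, %d points, step_h = %g h, condition = %s\n",
    dplyr::n_distinct(x$cell_id), nrow(x), attr(x, "step_h"),
    attr(x, "condition")
  ))
  NextMethod()
}

#' Write a track table to tab-separated text
#'
#' The output has a fixed column order (`cell_id`, `frame`, `time_h`, `x`,
#' `y`), a `#` metadata line recording `step_h` and the condition label, and
#' round-trips exactly through [read_tracks()].
#'
#' @param table A `track_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(table, path) {
  stopifnot(inherits(table, "track_table"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# step_h=%s condition=%s",
                     format(attr(table, "step_h"), digits = 17),
                     attr(table, "condition")), con)
  utils::write.table(
    as.data.frame(table)[, c("cell_id", "frame", "time_h", "x", "y")],
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Per-step displacement series of every cell
#'
#' Differences successive positions within each cell:
#' `u(t) = X(t) - X(t-1)` in micrometres per imaging step. The displacement
#' series is the observable of the heterogeneous-random-walk layer.
#'
#' @param table A `track_table`.
#' @return A tibble with columns `cell_id`, `step` (1-based index of the
#'   displacement), `ux`, `uy`, carrying the `step_h` attribute.
#' @export
to_displacements <- function(table) {
  stopifnot(inherits(table, "track_table"))
  disp <- table |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::reframe(
      step = seq_len(dplyr::n() - 1L),
      ux = diff(.data$x),
      uy = diff(.data$y)
    )
  structure(disp, step_h = attr(table, "step_h"))
}

# positions of one cell as an n x 2 matrix, ordered by frame
cell_positions <- function(table, cell) {
  rows <- table[table$cell_id == cell, , drop = FALSE]
  rows <- rows[order(rows$frame), ]
  cbind(rows$x, rows$y)
}
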