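# small builders used across test files

track_tbl <- function(cell_id, frame, x, y) {
  tibble::tibble(cell_id = cell_id, frame = as.integer(frame), x = x, y = y)
}

# one cell moving along given positions (n x 2 matrix)
track_from_positions <- function(pos, cell_id = "c1", step_h = 0.25) {
  as_track_table(
    track_tbl(cell_id, seq_len(nrow(pos)) - 1L, pos[, 1], pos[, 2]),
    step_h = step_h
  )
}

# brute-force time-averaged MSD at one lag (independent double-loop oracle)
oracle_msd_lag <- function(pos, lag) {
  n <- nrow(pos)
  vals <- numeric(n - lag)
  for (t in seq_len(n - lag)) {
    vals[t] <- sum((pos[t + lag, ] - pos[t, ])^2)
  }
  mean(vals)
}

write_track_file <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

table1_rates <- function() default_rates()
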