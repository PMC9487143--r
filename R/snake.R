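# The snake: an ordered vector of cells, each pairing an end time (ps since
# stream origin) with an output (row, col) coordinate.  A photon belongs to
# the first cell whose end time strictly exceeds its arrival time, provided
# the arrival also falls inside that cell's own active interval; photons in
# the mirror-turnaround gaps outside the visible window belong to no cell.

#' Build the 2D snake for one frame
#'
#' Models the raster trajectory of the scanned beam over one frame as an
#' ordered vector of pixel cells.  Line `k` occupies
#' `[start_k, start_k + T_line)` where `start_k` is the k-th measured (or
#' nominal) line-sync time; the visible window of duration
#' `fill_fraction * T_line` is centered in the line, so it opens at offset
#' `t0 = (1 - ff)/2 * T_line` (plus `bidir_phase_ps` on odd lines).  Within
#' the window, pixel boundaries are uniform in time with dwell
#' `tau = ff * T_line / columns`, each boundary rounded to integer
#' picoseconds; column `c`'s cell ends at `window_start + round((c+1) tau)`.
#' On odd lines of a bidirectional scan the within-sweep column order is
#' reversed.
#'
#' @param cfg A valid [experiment_config()].
#' @param frame_start_ps Time of the frame's first line sync (ps).
#' @param line_starts Optional vector of `rows` measured line-sync times; when
#'   given, each line's cells are anchored to its measured sync (the nominal
#'   period still fixes window width and dwell), reproducing the per-frame
#'   on-the-fly rebuild against jittered syncs.
#' @return A `snake` object: parallel vectors `end_ps`, `start_ps`, `row`,
#'   `col` (coordinates 0-based) of length `rows * columns`, with strictly
#'   increasing `end_ps`.
#' @export
build_snake_2d <- function(cfg, frame_start_ps = 0, line_starts = NULL) {
  rows <- cfg$rows
  cols <- cfg$columns
  Tl <- cfg$line_period_ps
  ff <- cfg$fill_fraction
  if (is.null(line_starts)) {
    line_starts <- frame_start_ps + (seq_len(rows) - 1) * Tl
  } else {
    stopifnot(length(line_starts) == rows)
    frame_start_ps <- line_starts[1L]
  }
  tau <- ff * Tl / cols
  if (tau < 1) {
    stop(sprintf(
      "pixel dwell %.3g ps is below the 1 ps timestamp resolution (too many columns for the line period)",
      tau), call. = FALSE)
  }
  t0 <- ps_round((1 - ff) / 2 * Tl)
  odd <- (seq_len(rows) - 1L) %% 2L == 1L
  win_start <- line_starts + t0 + ifelse(odd, cfg$bidir_phase_ps, 0)

  bounds <- ps_round(outer(0:cols, rep(1, rows)) * tau)  # (cols+1) x rows
  starts <- sweep(bounds[seq_len(cols), , drop = FALSE], 2L, win_start, "+")
  ends   <- sweep(bounds[1L + seq_len(cols), , drop = FALSE], 2L, win_start, "+")

  sweep_idx <- 0:(cols - 1L)
  col_of <- vapply(seq_len(rows), function(r) {
    if (odd[r] && cfg$bidirectional) rev(sweep_idx) else sweep_idx
  }, integer(cols))

  snake <- list(
    end_ps = as.vector(ends),
    start_ps = as.vector(starts),
    row = rep(0:(rows - 1L), each = cols),
    col = as.vector(col_of),
    frame_start_ps = frame_start_ps,
    first_cell_start_ps = starts[1L, 1L],
    line_period_ps = Tl,
    rows = rows,
    cols = cols,
    line_starts_ps = line_starts
  )
  class(snake) <- "snake"
  if (any(diff(snake$end_ps) <= 0) || any(snake$end_ps <= snake$start_ps))
    stop("snake end times are not strictly increasing; check line sync ordering",
         call. = FALSE)
  snake
}

#' @export
print.snake <- function(x, ...) {
  cat(sprintf("<snake> %d x %d cells, frame start %s ps, ends [%s .. %s] ps\n",
              x$rows, x$cols, format(x$frame_start_ps, big.mark = ","),
              format(x$end_ps[1L], big.mark = ","),
              format(x$end_ps[length(x$end_ps)], big.mark = ",")))
  invisible(x)
}

#' Shift a snake to the next frame
#'
#' Returns a new snake identical in shape, translated so that its frame
#' starts at `next_frame_start_ps`.  No allocation state leaks between
#' frames; this is the cheap path used when syncs arrive at the nominal
#' period (a jittered frame is rebuilt from its measured line syncs with
#' [build_snake_2d()] instead).
#'
#' @param snake A `snake`.
#' @param cfg The configuration the snake was built from.
#' @param next_frame_start_ps Start time of the next frame; must exceed the
#'   current `frame_start_ps`.
#' @return A new `snake`.
#' @export
advance_snake <- function(snake, cfg, next_frame_start_ps) {
  stopifnot(next_frame_start_ps > snake$frame_start_ps)
  delta <- next_frame_start_ps - snake$frame_start_ps
  snake$end_ps <- snake$end_ps + delta
  snake$start_ps <- snake$start_ps + delta
  snake$frame_start_ps <- next_frame_start_ps
  snake$first_cell_start_ps <- snake$first_cell_start_ps + delta
  snake$line_starts_ps <- snake$line_starts_ps + delta
  snake
}

#' Axial phase map of the TAG lens
#'
#' The TAG lens sweeps focal depth sinusoidally at its resonance frequency,
#' unsynchronized with the lateral scanners.  Given the most recent TAG sync
#' pulse, depth at time `t` is `z = (1 + sin(phi)) / 2` with
#' `phi = 2 pi (t - last_sync) / period + phase0`, and the plane index is the
#' uniform-in-z bin `min(floor(z * planes), planes - 1)`.
#'
#' @param tag_period_ps TAG oscillation period in integer picoseconds.
#' @param last_sync_ps Time of the most recent TAG sync pulse (ps).
#' @param phase0_rad Oscillation phase at the sync pulse (radians).
#' @param planes Even plane count, at least 2.
#' @return An `axial_phase_map` object.
#' @export
axial_phase_map <- function(tag_period_ps, last_sync_ps = 0, phase0_rad = 0,
                            planes = 2L) {
  planes <- as.integer(planes)
  stopifnot(tag_period_ps > 0, planes >= 2L, planes %% 2L == 0L)
  structure(list(tag_period_ps = tag_period_ps,
                 last_sync_ps = last_sync_ps,
                 phase0_rad = phase0_rad,
                 planes = planes),
            class = "axial_phase_map")
}

# Vectorized plane computation from explicit sync times (allocator fast path).
plane_from_phase <- function(t_ps, last_sync_ps, tag_period_ps, phase0_rad, planes) {
  frac <- ((t_ps - last_sync_ps) %% tag_period_ps) / tag_period_ps
  z <- (1 + sin(2 * pi * frac + phase0_rad)) / 2
  pmin(floor(z * planes), planes - 1L)
}

#' Map a time to its TAG plane index
#'
#' Pure and deterministic; periodic in `t_ps` with period `tag_period_ps`
#' (exactly so for integer-multiple offsets, since the phase is reduced
#' modulo one period before the sine is taken).
#'
#' @param map An [axial_phase_map()].
#' @param t_ps Arrival time(s), ps; must not precede `last_sync_ps`.
#' @return Integer plane indices in `0 .. planes - 1`.
#' @export
plane_of <- function(map, t_ps) {
  stopifnot(all(t_ps >= map$last_sync_ps))
  as.integer(plane_from_phase(t_ps, map$last_sync_ps, map$tag_period_ps,
                              map$phase0_rad, map$planes))
}
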