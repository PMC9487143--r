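# Shared fixture builders and brute-force oracles.

cfg_2d <- function(rows = 16L, cols = 16L, line_frequency_hz = 1e5, ...) {
  experiment_config(
    channels = list(channel_spec(1, "line_sync"), channel_spec(2, "spectral")),
    rows = rows, columns = cols, line_frequency_hz = line_frequency_hz, ...)
}

cfg_3d <- function(rows = 16L, cols = 16L, planes = 4L,
                   line_frequency_hz = 15360, tag_frequency_hz = 189000, ...) {
  experiment_config(
    channels = list(channel_spec(1, "line_sync"), channel_spec(2, "spectral"),
                    channel_spec(5, "tag_sync")),
    rows = rows, columns = cols, planes = planes,
    line_frequency_hz = line_frequency_hz, tag_frequency_hz = tag_frequency_hz, ...)
}

cfg_demux <- function(rows = 16L, cols = 16L, line_frequency_hz = 1e5, ...) {
  experiment_config(
    channels = list(channel_spec(1, "line_sync"), channel_spec(2, "spectral"),
                    channel_spec(3, "laser_sync")),
    rows = rows, columns = cols, line_frequency_hz = line_frequency_hz,
    demultiplex = TRUE, ...)
}

# Left-to-right linear scan over the snake: the independent reference for
# find_cell.  Returns the first cell whose end time strictly exceeds t,
# discarding photons outside that cell's own [start, end) interval.
linear_find_cell <- function(snake, t) {
  for (i in seq_along(snake$end_ps)) {
    if (snake$end_ps[i] > t) {
      return(if (t >= snake$start_ps[i]) i else CELL_DISCARDED_EARLY)
    }
  }
  CELL_AFTER_FRAME
}

random_snake <- function() {
  rows <- sample(1:10, 1)
  cols <- sample(1:16, 1)
  ff <- runif(1, 0.4, 1)
  cfg <- cfg_2d(rows, cols, line_frequency_hz = 10^runif(1, 4, 6),
                fill_fraction = ff, bidirectional = sample(c(TRUE, FALSE), 1))
  s <- build_snake_2d(cfg, frame_start_ps = round(runif(1, 0, 1e9)))
  attr(s, "cfg") <- cfg
  s
}

# 6-connected flood fill over a 3D logical mask; returns the component label
# array (0 = background).
label_components_3d <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  lab <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      co <- arrayInd(v, d)
      for (step in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
        nb <- co + step
        if (any(nb < 1L) || any(nb > d)) next
        ni <- nb[1L] + d[1L] * (nb[2L] - 1L) + d[1L] * d[2L] * (nb[3L] - 1L)
        if (mask[ni] && labels[ni] == 0L) {
          labels[ni] <- lab
          queue <- c(queue, ni)
        }
      }
    }
  }
  labels
}
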