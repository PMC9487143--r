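# Photon-to-cell allocation.  A photon is assigned to the first snake cell
# whose end time strictly exceeds the photon's arrival time ("exceeds" is
# read strictly: a photon exactly at a cell's end time belongs to the next
# cell, which is exact in integer picoseconds).  Photons falling before the
# first cell or inside a mirror-turnaround gap are discarded rather than
# snapped to the nearest cell.

#' Sentinel codes returned by [find_cell()]
#'
#' `CELL_DISCARDED_EARLY` (0): the photon precedes the first cell's interval
#' or falls in an inter-line turnaround gap.  `CELL_AFTER_FRAME` (-1): the
#' photon arrives at or after the frame's last cell end time.
#'
#' @export
CELL_DISCARDED_EARLY <- 0L

#' @rdname CELL_DISCARDED_EARLY
#' @export
CELL_AFTER_FRAME <- -1L

#' Locate the snake cell owning each arrival time
#'
#' Binary search (via `findInterval`) for the smallest cell index whose end
#' time strictly exceeds `t_ps`; the result is contractually identical to a
#' left-to-right linear scan over the snake.  The candidate cell only owns
#' the photon if `t_ps` also lies inside the cell's active interval
#' `[start, end)`; otherwise the photon sits in a turnaround gap and is
#' discarded.
#'
#' @param snake A [build_snake_2d()] snake.
#' @param t_ps Vector of arrival times (ps).
#' @return Integer vector: 1-based cell index, or [CELL_DISCARDED_EARLY], or
#'   [CELL_AFTER_FRAME].
#' @export
find_cell <- function(snake, t_ps) {
  # findInterval counts end times <= t, so `idx + 1` is the first cell whose
  # end time strictly exceeds t -- the strict-"exceeds" tie-break for free.
  idx <- findInterval(t_ps, snake$end_ps) + 1L
  n <- length(snake$end_ps)
  out <- idx
  after <- idx > n
  out[after] <- CELL_AFTER_FRAME
  ok <- !after
  gap <- ok & t_ps < snake$start_ps[pmin(idx, n)]
  out[gap] <- CELL_DISCARDED_EARLY
  out
}

#' Infer per-line start times from frame syncs
#'
#' With a frame_sync-only wiring there is one sync per frame; line starts are
#' inferred by dividing each measured frame interval into `rows` equal parts.
#' The last frame, having no closing sync, uses the nominal frame period
#' (`rows * line_period_ps`).
#'
#' @param frame_sync_times Increasing vector of frame sync times (ps).
#' @param rows Lines per frame.
#' @param cfg The [experiment_config()] supplying the nominal period.
#' @return Numeric vector of `length(frame_sync_times) * rows` line starts.
#' @export
infer_line_starts <- function(frame_sync_times, rows, cfg) {
  stopifnot(length(frame_sync_times) >= 1L)
  nominal <- rows * cfg$line_period_ps
  periods <- c(diff(frame_sync_times), nominal)
  starts <- lapply(seq_along(frame_sync_times), function(i) {
    frame_sync_times[i] + ps_round((0:(rows - 1L)) * periods[i] / rows)
  })
  unlist(starts)
}

# Repair dropped line syncs: any gap larger than 1.5x the nominal period gets
# inferred syncs inserted at nominal spacing.  Returns the repaired vector
# and the number of insertions.
repair_line_syncs <- function(times, nominal_ps) {
  if (length(times) < 2L) return(list(times = times, inferred = 0L))
  gaps <- diff(times)
  need <- which(gaps > 1.5 * nominal_ps)
  if (length(need) == 0L) return(list(times = times, inferred = 0L))
  inserted <- lapply(need, function(i) {
    n_missing <- max(0L, as.integer(round(gaps[i] / nominal_ps)) - 1L)
    if (n_missing == 0L) return(numeric(0))
    times[i] + seq_len(n_missing) * nominal_ps
  })
  extra <- unlist(inserted)
  list(times = sort(c(times, extra)), inferred = length(extra))
}

empty_photon_records <- function() {
  data.frame(spectral_channel = integer(0), demux_stream = integer(0),
             frame = integer(0), row = integer(0), col = integer(0),
             plane = integer(0), time_ps = numeric(0))
}

#' Process a time-tag stream into photon records
#'
#' The reconstruction event loop.  Sync tags drive the state: every `rows`
#' line syncs open a new frame with a freshly built snake (measured sync
#' times anchor each line, so jitter is tracked per frame); frame-sync-only
#' wirings infer line starts by equal division of the frame interval; gaps
#' larger than 1.5 nominal line periods are repaired with inferred syncs
#' (counted in the run statistics).  TAG sync tags update the axial phase
#' map; when `cfg$demultiplex` is true, laser sync tags (possibly only every
#' Nth pulse) anchor the demultiplexing gate via nominal-period phase
#' tracking.  Each spectral tag is then allocated to its snake cell (plus
#' TAG plane when `planes > 1`) and emitted as one photon record.
#'
#' Every spectral tag is classified into exactly one of allocated /
#' discarded-early (turnaround) / after-frame / pre-sync; the conservation
#' identity is asserted on every run.
#'
#' @param tags Data frame with columns `channel`, `time_ps` (non-decreasing),
#'   as returned by [read_tag_stream()] or [simulate_acquisition()].
#' @param cfg A valid [experiment_config()].
#' @return List with `records` (data frame: `spectral_channel`,
#'   `demux_stream`, `frame`, `row`, `col`, `plane`, `time_ps`) and `stats`
#'   (a `run_stats` object).
#' @export
process_stream <- function(tags, cfg) {
  violations <- validate_config(cfg)
  if (length(violations) > 0L)
    stop("invalid configuration:\n  - ", paste(violations, collapse = "\n  - "),
         call. = FALSE)
  stopifnot(all(diff(tags$time_ps) >= 0))

  rows <- cfg$rows
  known_inputs <- vapply(cfg$channels, function(ch) ch$input_number, integer(1))
  unknown <- setdiff(unique(tags$channel), known_inputs)
  if (length(unknown) > 0L)
    warning("stream contains tags on undeclared channels (ignored): ",
            paste(unknown, collapse = ", "), call. = FALSE)

  line_ch <- channel_input(cfg, "line_sync")
  frame_ch <- channel_input(cfg, "frame_sync")
  tag_ch <- channel_input(cfg, "tag_sync")
  laser_ch <- channel_input(cfg, "laser_sync")
  spec_ch <- spectral_inputs(cfg)

  inferred_lines <- 0L
  if (!is.null(line_ch)) {
    line_starts <- tags$time_ps[tags$channel == line_ch]
    rep <- repair_line_syncs(line_starts, cfg$line_period_ps)
    line_starts <- rep$times
    inferred_lines <- rep$inferred
  } else {
    frame_syncs <- tags$time_ps[tags$channel == frame_ch]
    if (length(frame_syncs) == 0L) line_starts <- numeric(0)
    else line_starts <- infer_line_starts(frame_syncs, rows, cfg)
  }
  n_frames <- length(line_starts) %/% rows

  is_spectral <- tags$channel %in% spec_ch
  photons_t <- tags$time_ps[is_spectral]
  photons_ch <- tags$channel[is_spectral]
  total_spectral <- length(photons_t)

  tag_syncs <- if (!is.null(tag_ch)) tags$time_ps[tags$channel == tag_ch] else numeric(0)
  laser_refs <- if (!is.null(laser_ch)) tags$time_ps[tags$channel == laser_ch] else numeric(0)

  counts <- c(allocated = 0L, discarded_early = 0L, after_frame = 0L, pre_sync = 0L)

  records <- empty_photon_records()
  if (n_frames > 0L && total_spectral > 0L) {
    frame_first_line <- line_starts[seq(1L, by = rows, length.out = n_frames)]
    frame_end <- c(frame_first_line[-1L],
                   line_starts[n_frames * rows] + cfg$line_period_ps)

    # Pre-sync: before the first frame opens, or (planes > 1) before the
    # first TAG sync, or (demux) before the first laser reference.
    pre <- photons_t < frame_first_line[1L]
    if (cfg$planes > 1L) {
      pre <- pre | (if (length(tag_syncs)) photons_t < tag_syncs[1L] else TRUE)
    }
    if (cfg$demultiplex) {
      pre <- pre | (if (length(laser_refs)) photons_t < laser_refs[1L] else TRUE)
    }
    counts["pre_sync"] <- sum(pre)

    fidx <- findInterval(photons_t, frame_first_line)  # 0 = before first frame
    live <- !pre & fidx >= 1L
    safe_f <- pmin(pmax(fidx, 1L), n_frames)
    beyond <- live & photons_t >= frame_end[safe_f]
    # Photons at/after the end of the frame they fall in (including anything
    # after the last complete frame) are after-frame for that frame.
    out_frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      sel <- live & fidx == f & !beyond
      sel_after <- live & fidx == f & beyond
      counts["after_frame"] <- counts["after_frame"] + sum(sel_after)
      if (!any(sel)) next
      ls <- line_starts[((f - 1L) * rows + 1L):(f * rows)]
      snake <- build_snake_2d(cfg, line_starts = ls)
      t_f <- photons_t[sel]
      cell <- find_cell(snake, t_f)
      counts["discarded_early"] <- counts["discarded_early"] + sum(cell == CELL_DISCARDED_EARLY)
      counts["after_frame"] <- counts["after_frame"] + sum(cell == CELL_AFTER_FRAME)
      hit <- cell >= 1L
      if (!any(hit)) next
      t_hit <- t_f[hit]
      cells <- cell[hit]
      plane <- if (cfg$planes > 1L) {
        last_sync <- tag_syncs[findInterval(t_hit, tag_syncs)]
        as.integer(plane_from_phase(t_hit, last_sync, cfg$tag_period_ps,
                                    cfg$tag_phase0_rad, cfg$planes))
      } else {
        integer(length(t_hit))
      }
      demux <- if (cfg$demultiplex) {
        dcfg <- demux_config(cfg$laser_period_ps)
        vp <- phase_track(laser_refs, cfg$laser_period_ps)(t_hit)
        demux_stream_index(t_hit, vp, dcfg)
      } else {
        rep(NA_integer_, length(t_hit))
      }
      counts["allocated"] <- counts["allocated"] + sum(hit)
      out_frames[[f]] <- data.frame(
        spectral_channel = photons_ch[sel][hit],
        demux_stream = demux,
        frame = f - 1L,
        row = snake$row[cells],
        col = snake$col[cells],
        plane = plane,
        time_ps = t_hit
      )
    }
    out_frames <- Filter(Negate(is.null), out_frames)
    if (length(out_frames) > 0L) records <- do.call(rbind, out_frames)
  } else {
    counts["pre_sync"] <- total_spectral
  }

  stopifnot(sum(counts) == total_spectral)  # conservation identity

  per_channel <- table(factor(photons_ch, levels = sort(spec_ch)))
  stats <- structure(list(
    total_spectral = total_spectral,
    allocated = unname(counts["allocated"]),
    discarded_early = unname(counts["discarded_early"]),
    after_frame = unname(counts["after_frame"]),
    pre_sync = unname(counts["pre_sync"]),
    inferred_lines = inferred_lines,
    frames = n_frames,
    per_channel = per_channel
  ), class = "run_stats")

  list(records = records, stats = stats)
}

#' @export
print.run_stats <- function(x, ...) {
  cat(sprintf(
    "<run_stats> %d frames | %d spectral tags: %d allocated, %d turnaround, %d after-frame, %d pre-sync",
    x$frames, x$total_spectral, x$allocated, x$discarded_early,
    x$after_frame, x$pre_sync))
  if (x$inferred_lines > 0L) cat(sprintf(" | %d line syncs inferred", x$inferred_lines))
  cat("\n")
  invisible(x)
}
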