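# Virtual microscope: emits time-tag streams with the statistical and
# timing structure the reconstruction assumes -- line/frame syncs at the
# scanner rate, TAG syncs at the lens resonance with a random initial phase
# (the lens is unsynchronized with the scanners), laser reference pulses,
# and Bernoulli-per-pulse photon tags whose probability follows the ground
# truth intensity at the beam's instantaneous position.  Every emitted
# photon's true (row, col, plane, beam) is recorded in an emission ledger,
# the oracle against which reconstructions are scored.

#' Build a deterministic test phantom
#'
#' @param kind `"uniform"` (constant field, the fluorescein-bath analogue),
#'   `"grid"` (regular bright lines), `"blobs"` (Gaussian spots, soma-like),
#'   or `"vessels3d"` (connected bright tubes threading all planes,
#'   vasculature-like; requires 3 dims).
#' @param dims `c(rows, cols)` or `c(rows, cols, planes)`.
#' @param spacing Grid line spacing in pixels (`"grid"`).
#' @param n_blobs,blob_sigma Spot count and width in pixels (`"blobs"`).
#' @param n_vessels Number of tubes (`"vessels3d"`).
#' @param seed Seed for the stochastic phantoms (`"blobs"`, `"vessels3d"`);
#'   the phantom is a pure function of `(kind, dims, ..., seed)`.
#' @return A `ground_truth` array, non-negative, normalized to max 1.
#' @export
make_phantom <- function(kind = c("uniform", "grid", "blobs", "vessels3d"),
                         dims, spacing = 8L, n_blobs = 6L, blob_sigma = 2.5,
                         n_vessels = 3L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(all(dims >= 1))
  gt <- switch(kind,
    uniform = array(1, dim = dims),
    grid = {
      stopifnot(length(dims) >= 2L)
      g <- array(0, dim = dims)
      r_idx <- seq(1L, dims[1L], by = spacing)
      c_idx <- seq(1L, dims[2L], by = spacing)
      if (length(dims) == 2L) {
        g[r_idx, ] <- 1
        g[, c_idx] <- 1
      } else {
        g[r_idx, , ] <- 1
        g[, c_idx, ] <- 1
      }
      g
    },
    blobs = {
      stopifnot(length(dims) == 2L)
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(seed)
      g <- array(0, dim = dims)
      rr <- row(g); cc <- col(g)
      for (i in seq_len(n_blobs)) {
        cy <- stats::runif(1, 1, dims[1L])
        cx <- stats::runif(1, 1, dims[2L])
        g <- g + exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * blob_sigma^2))
      }
      g
    },
    vessels3d = {
      stopifnot(length(dims) == 3L)
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(seed)
      g <- array(0, dim = dims)
      for (v in seq_len(n_vessels)) {
        r0 <- stats::runif(1, 4, dims[1L] - 3)
        c0 <- stats::runif(1, 4, dims[2L] - 3)
        for (p in seq_len(dims[3L])) {
          # tube drifts laterally by at most one pixel per plane; a radius-1.6
          # disk keeps consecutive plane sections overlapping (6-connected)
          rr <- pmin(pmax(round(r0 + c(-1, 0, 1)), 1), dims[1L])
          cc <- pmin(pmax(round(c0 + c(-1, 0, 1)), 1), dims[2L])
          g[rr, cc, p] <- 1
          r0 <- min(max(r0 + stats::runif(1, -1, 1), 2), dims[1L] - 1)
          c0 <- min(max(c0 + stats::runif(1, -1, 1), 2), dims[2L] - 1)
        }
      }
      g
    })
  if (max(gt) > 0) gt <- gt / max(gt)
  class(gt) <- c("ground_truth", class(gt))
  gt
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulation parameters
#'
#' @param cfg A valid [experiment_config()] describing the virtual
#'   acquisition geometry.
#' @param p_pulse_max Ceiling on the per-pulse excitation probability
#'   (default 0.1; kept below 0.1 so excitation saturation does not broaden
#'   the effective point-spread function).
#' @param brightness Scales the peak per-pulse excitation probability:
#'   `p = brightness * p_pulse_max * I(x)` with `I` the normalized ground
#'   truth.  `brightness * p_pulse_max` must not exceed 1.
#' @param n_frames Number of frames (volumetric: volumes) to simulate.
#' @param seed RNG seed; the stream is a pure function of (ground truth,
#'   parameters, seed).
#' @param beam_delay_ps Optical delay of the second beam in a two-beam
#'   (demultiplexed) run; defaults to half the laser period.
#' @param beam_delay_error_ps Deterministic error added to the second
#'   beam's delay (the beams not being exactly half a period apart).
#' @param sync_jitter_ps Gaussian jitter (1 SD, ps) on line sync times.
#' @param lifetime_ps Mean of an optional exponential emission delay
#'   between excitation pulse and photon arrival (0 = prompt emission).
#'   Gating is by arrival time alone, so a finite lifetime is the channel
#'   through which beam-delay error turns into demultiplexing crosstalk.
#' @param laser_ref_every Store only every Nth laser pulse on the
#'   laser_sync channel (tests the nominal-period phase tracking).
#' @return A `sim_params` object.
#' @export
sim_params <- function(cfg, p_pulse_max = 0.1, brightness = 1, n_frames = 1L,
                       seed = 1L, beam_delay_ps = NULL, beam_delay_error_ps = 0,
                       sync_jitter_ps = 0, lifetime_ps = 0, laser_ref_every = 1L) {
  if (is.null(beam_delay_ps)) beam_delay_ps <- cfg$laser_period_ps / 2
  if (brightness * p_pulse_max > 1)
    stop("brightness * p_pulse_max exceeds 1: not a probability", call. = FALSE)
  structure(list(cfg = cfg, p_pulse_max = p_pulse_max, brightness = brightness,
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 beam_delay_ps = ps_round(beam_delay_ps),
                 beam_delay_error_ps = ps_round(beam_delay_error_ps),
                 sync_jitter_ps = sync_jitter_ps,
                 lifetime_ps = lifetime_ps,
                 laser_ref_every = as.integer(laser_ref_every)),
            class = "sim_params")
}

# Within-sweep column index from the same rounded integer boundaries the
# snake uses: b_c = round(c * tau).  Computed inline (not via find_cell) so
# the ledger stays an independent statement of where the beam was.  A pulse
# exactly at a boundary belongs to the next column (strict "exceeds").
sweep_column <- function(offset_ps, bounds) {
  findInterval(offset_ps, bounds[-1L])
}

#' Simulate a photon-counting acquisition
#'
#' Emits a time-merged, time-sorted tag stream containing line syncs at the
#' configured line rate (with optional jitter), frame syncs when a
#' frame_sync channel is declared, TAG syncs at the lens frequency with a
#' seeded random initial phase, laser reference pulses (every pulse or every
#' Nth), and photon tags on every spectral channel.  Photons are drawn per
#' laser pulse as a Bernoulli trial with probability
#' `brightness * p_pulse_max * I(x(t), z(t))`, where `x(t)` is the
#' instantaneous scan position (uniform in time across the visible window,
#' mirroring the snake's binning) and `z(t)` the TAG depth at the pulse.
#' In a demultiplexed configuration a second pulse train, offset by
#' `beam_delay + beam_delay_error`, excites `gt_beam2` (defaults to the
#' same ground truth).
#'
#' The first line sync is placed late enough that every sync train (TAG,
#' laser) has fired at least once before the first frame opens, as on a real
#' instrument where the free-running lens and laser long predate the
#' acquisition start.
#'
#' @param gt Ground truth from [make_phantom()] (dims must match
#'   `cfg$rows x cfg$columns (x cfg$planes)`).
#' @param p A [sim_params()] object.
#' @param gt_beam2 Optional second ground truth excited by beam 2.
#' @return A `tt_simulation`: list with `tags` (a [tag_stream()]), `ledger`
#'   (data frame `time_ps`, `spectral_channel`, `beam`, `frame`, `row`,
#'   `col`, `plane`), and `info` (pulse/photon bookkeeping).
#' @export
simulate_acquisition <- function(gt, p, gt_beam2 = NULL) {
  cfg <- p$cfg
  violations <- validate_config(cfg)
  if (length(violations) > 0L)
    stop("invalid configuration:\n  - ", paste(violations, collapse = "\n  - "),
         call. = FALSE)
  gdim <- dim(gt)
  want <- if (cfg$planes > 1L) c(cfg$rows, cfg$columns, cfg$planes) else c(cfg$rows, cfg$columns)
  stopifnot(identical(as.integer(gdim), as.integer(want)))
  if (is.null(gt_beam2)) gt_beam2 <- gt else stopifnot(identical(dim(gt_beam2), gdim))

  set.seed(p$seed)
  Tl <- cfg$line_period_ps
  Tp <- cfg$laser_period_ps
  rows <- cfg$rows; cols <- cfg$columns
  n_lines <- rows * p$n_frames
  volumetric <- cfg$planes > 1L
  demux <- cfg$demultiplex
  n_beams <- if (demux) 2L else 1L
  spec_ch <- spectral_inputs(cfg)

  # Acquisition start: after at least one period of every free-running train.
  lead <- 0
  if (volumetric) lead <- lead + cfg$tag_period_ps
  if (demux) lead <- lead + Tp
  line_starts <- lead + (0:(n_lines - 1L)) * Tl
  if (p$sync_jitter_ps > 0) {
    line_starts <- line_starts + ps_round(stats::rnorm(n_lines, 0, p$sync_jitter_ps))
    if (any(diff(line_starts) <= 0))
      stop("sync jitter too large: line syncs reordered", call. = FALSE)
  }
  stream_end <- line_starts[n_lines] + Tl

  # Free-running TAG train with a random initial phase in [0, period).
  tag_times <- numeric(0)
  if (volumetric) {
    Ptag <- cfg$tag_period_ps
    u0 <- ps_round(stats::runif(1, 0, Ptag))
    tag_times <- seq(u0, stream_end, by = Ptag)
  }

  t0 <- ps_round((1 - cfg$fill_fraction) / 2 * Tl)
  tau <- cfg$fill_fraction * Tl / cols
  bounds <- ps_round((0:cols) * tau)
  win_len <- bounds[cols + 1L]
  beam_offset <- c(0, p$beam_delay_ps + p$beam_delay_error_ps)[seq_len(n_beams)]

  pmax_eff <- p$brightness * p$p_pulse_max
  photon_parts <- list()
  ledger_parts <- list()
  n_window_pulses <- 0
  part <- 0L
  for (ln in seq_len(n_lines)) {
    frame <- (ln - 1L) %/% rows
    r <- (ln - 1L) %% rows
    odd <- r %% 2L == 1L
    ws <- line_starts[ln] + t0 + if (odd) cfg$bidir_phase_ps else 0
    we <- ws + win_len
    for (b in seq_len(n_beams)) {
      ob <- beam_offset[b]
      k0 <- ceiling((ws - ob) / Tp)
      k1 <- ceiling((we - ob) / Tp) - 1
      if (k1 < k0) next
      tp <- ob + (k0:k1) * Tp
      n_window_pulses <- n_window_pulses + length(tp)
      sweep_idx <- sweep_column(tp - ws, bounds)
      colv <- if (odd && cfg$bidirectional) cols - 1L - sweep_idx else sweep_idx
      planev <- if (volumetric) {
        last_sync <- tag_times[findInterval(tp, tag_times)]
        as.integer(plane_from_phase(tp, last_sync, cfg$tag_period_ps,
                                    cfg$tag_phase0_rad, cfg$planes))
      } else rep(0L, length(tp))
      g <- if (b == 1L) gt else gt_beam2
      inten <- if (volumetric) g[cbind(r + 1L, colv + 1L, planev + 1L)]
               else g[cbind(r + 1L, colv + 1L)]
      pr <- pmax_eff * inten
      for (ch in spec_ch) {
        hit <- stats::runif(length(tp)) < pr
        if (!any(hit)) next
        arrive <- tp[hit]
        if (p$lifetime_ps > 0)
          arrive <- arrive + ps_round(stats::rexp(sum(hit), 1 / p$lifetime_ps))
        part <- part + 1L
        photon_parts[[part]] <- data.frame(channel = ch, time_ps = arrive)
        ledger_parts[[part]] <- data.frame(
          time_ps = arrive, spectral_channel = ch, beam = b - 1L,
          frame = frame, row = r, col = colv[hit], plane = planev[hit])
      }
    }
  }

  sync_parts <- list(data.frame(channel = channel_input(cfg, "line_sync") %||% integer(0),
                                time_ps = if (is.null(channel_input(cfg, "line_sync"))) numeric(0) else line_starts))
  fch <- channel_input(cfg, "frame_sync")
  if (!is.null(fch)) {
    fr_starts <- line_starts[seq(1L, by = rows, length.out = p$n_frames)]
    sync_parts[[length(sync_parts) + 1L]] <- data.frame(channel = fch, time_ps = fr_starts)
  }
  tch <- channel_input(cfg, "tag_sync")
  if (!is.null(tch) && length(tag_times) > 0L)
    sync_parts[[length(sync_parts) + 1L]] <- data.frame(channel = tch, time_ps = tag_times)
  lch <- channel_input(cfg, "laser_sync")
  if (!is.null(lch)) {
    refs <- seq(0, stream_end, by = Tp * p$laser_ref_every)
    sync_parts[[length(sync_parts) + 1L]] <- data.frame(channel = lch, time_ps = refs)
  }

  all_tags <- do.call(rbind, c(sync_parts, photon_parts))
  ord <- order(all_tags$time_ps, all_tags$channel)
  tags <- tag_stream(all_tags$channel[ord], all_tags$time_ps[ord])

  ledger <- if (part > 0L) do.call(rbind, ledger_parts) else
    data.frame(time_ps = numeric(0), spectral_channel = integer(0),
               beam = integer(0), frame = integer(0), row = integer(0),
               col = integer(0), plane = integer(0))
  ledger <- ledger[order(ledger$time_ps, ledger$spectral_channel), , drop = FALSE]
  rownames(ledger) <- NULL

  structure(list(tags = tags, ledger = ledger,
                 info = list(n_photons = nrow(ledger),
                             n_window_pulses = n_window_pulses,
                             n_frames = p$n_frames,
                             lead_ps = lead,
                             tag_phase_origin_ps = if (volumetric) tag_times[1L] else NA_real_)),
            class = "tt_simulation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tt_simulation <- function(x, ...) {
  cat(sprintf("<tt_simulation> %d tags (%d photons over %d frames)\n",
              nrow(x$tags), x$info$n_photons, x$info$n_frames))
  invisible(x)
}

#' Score a reconstruction against the emission ledger
#'
#' Quantifies the round trip simulator -> stream -> allocator: photon
#' conservation, the fraction of allocated photons whose reconstructed
#' (row, col, plane) equals the ledger's true coordinate, the normalized
#' (Pearson) cross-correlation between the summed depth projection and the
#' ground truth's own projection, and -- for demultiplexed runs -- the
#' crosstalk fraction (photons whose demux stream differs from their true
#' beam).
#'
#' @param gt The ground truth passed to [simulate_acquisition()].
#' @param recon The [process_stream()] result for the simulated stream.
#' @param ledger The simulation's emission ledger.
#' @param cfg The shared [experiment_config()].
#' @return A `round_trip_report` list: `photon_conservation` (emitted
#'   photons equal spectral tags seen), `allocated_fraction`,
#'   `per_voxel_exactness`, `ncc`, `crosstalk`.
#' @export
round_trip_report <- function(gt, recon, ledger, cfg) {
  records <- recon$records
  stats <- recon$stats
  conservation <- nrow(ledger) == stats$total_spectral &&
    stats$allocated + stats$discarded_early + stats$after_frame + stats$pre_sync ==
      stats$total_spectral

  key_r <- paste(records$time_ps, records$spectral_channel)
  key_l <- paste(ledger$time_ps, ledger$spectral_channel)
  m <- match(key_r, key_l)
  matched <- !is.na(m)
  exact <- if (any(matched)) {
    mean(records$row[matched] == ledger$row[m[matched]] &
         records$col[matched] == ledger$col[m[matched]] &
         records$plane[matched] == ledger$plane[m[matched]] &
         records$frame[matched] == ledger$frame[m[matched]])
  } else NA_real_

  crosstalk <- if (cfg$demultiplex && any(matched)) {
    mean(records$demux_stream[matched] != ledger$beam[m[matched]])
  } else NA_real_

  ncc <- if (nrow(records) > 0L) {
    stacks <- accumulate_run(records, cfg)
    proj <- summed_projection(Reduce(`+`, stacks))
    gt_proj <- if (length(dim(gt)) == 3L) apply(gt, c(1L, 2L), max) else unclass(gt)
    if (stats::sd(proj) == 0 || stats::sd(gt_proj) == 0) NA_real_
    else stats::cor(as.vector(proj), as.vector(gt_proj))
  } else NA_real_

  structure(list(photon_conservation = conservation,
                 allocated_fraction = if (stats$total_spectral > 0)
                   stats$allocated / stats$total_spectral else NA_real_,
                 matched_fraction = mean(matched),
                 per_voxel_exactness = exact,
                 ncc = ncc,
                 crosstalk = crosstalk),
            class = "round_trip_report")
}

#' @export
print.round_trip_report <- function(x, ...) {
  cat(sprintf(paste0("<round_trip_report> conservation: %s | allocated: %.3f | ",
                     "exactness: %s | ncc: %s | crosstalk: %s\n"),
              x$photon_conservation, x$allocated_fraction,
              format(x$per_voxel_exactness, digits = 4),
              format(x$ncc, digits = 4), format(x$crosstalk, digits = 4)))
  invisible(x)
}

#' Voxel coverage of the volumetric scan trajectory
#'
#' Deterministic bookkeeping of which voxels the beam can populate: the
#' trajectory `t -> (row, col, plane(t))` is sampled at every laser pulse in
#' the visible windows, per volume.  Because the TAG lens is unsynchronized
#' with the scanners, a single volume skips voxels (each pixel's dwell spans
#' only part of a TAG cycle) while the phase drift between volumes fills the
#' gaps across a recording.
#'
#' @param cfg A valid volumetric [experiment_config()].
#' @param n_frames Number of volumes to trace.
#' @param tag_phase_origin_ps Time of the first TAG sync (fixes the initial
#'   phase; default 0).
#' @return List: `per_volume_unvisited` (fraction of voxels not sampled in
#'   each single volume), `cumulative_unvisited` (same for the union of
#'   volumes 1..k), `planes_visited_cumulative` (logical, per plane).
#' @export
scan_coverage <- function(cfg, n_frames, tag_phase_origin_ps = 0) {
  stopifnot(cfg$planes > 1L)
  rows <- cfg$rows; cols <- cfg$columns; planes <- cfg$planes
  Tl <- cfg$line_period_ps; Tp <- cfg$laser_period_ps; Ptag <- cfg$tag_period_ps
  t0 <- ps_round((1 - cfg$fill_fraction) / 2 * Tl)
  bounds <- ps_round((0:cols) * (cfg$fill_fraction * Tl / cols))
  win_len <- bounds[cols + 1L]
  n_vox <- rows * cols * planes
  seen_any <- logical(n_vox)
  per_vol <- numeric(n_frames)
  cum <- numeric(n_frames)
  planes_seen <- logical(planes)
  for (f in seq_len(n_frames)) {
    seen <- logical(n_vox)
    for (r in 0:(rows - 1L)) {
      odd <- r %% 2L == 1L
      ws <- tag_phase_origin_ps + ((f - 1L) * rows + r) * Tl + t0 +
        if (odd) cfg$bidir_phase_ps else 0
      k0 <- ceiling(ws / Tp); k1 <- ceiling((ws + win_len) / Tp) - 1
      if (k1 < k0) next
      tp <- (k0:k1) * Tp
      sweep_idx <- sweep_column(tp - ws, bounds)
      colv <- if (odd && cfg$bidirectional) cols - 1L - sweep_idx else sweep_idx
      planev <- as.integer(plane_from_phase(tp, tag_phase_origin_ps, Ptag,
                                            cfg$tag_phase0_rad, planes))
      lin <- 1L + r + rows * (colv + cols * planev)
      seen[lin] <- TRUE
    }
    per_vol[f] <- 1 - sum(seen) / n_vox
    seen_any <- seen_any | seen
    cum[f] <- 1 - sum(seen_any) / n_vox
    pl <- array(seen_any, dim = c(rows, cols, planes))
    planes_seen <- apply(pl, 3L, any)
  }
  list(per_volume_unvisited = per_vol,
       cumulative_unvisited = cum,
       planes_visited_cumulative = planes_seen)
}
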