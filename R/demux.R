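# Temporal demultiplexing: two excitation pulse trains share one physical
# spectral channel, the second delayed by half the laser inter-pulse period
# (6.25 ns for an 80 MHz source).  A photon is sorted into a per-beam stream
# by its arrival time relative to the most recent reference pulse: the first
# half-period gates stream 0, the second gates stream 1.

#' Demultiplexing gate parameters
#'
#' @param laser_period_ps Laser inter-pulse period `T` (integer ps; 12500
#'   for 80 MHz).
#' @param n_streams Number of interleaved beams (2; kept in the type so a
#'   generalization does not change the schema).
#' @param shift_ps Gate offset; defaults to `T / n_streams` (the
#'   duplicated-and-shifted pulse train of the digitizer).
#' @return A `demux_config` object.
#' @export
demux_config <- function(laser_period_ps, n_streams = 2L, shift_ps = NULL) {
  if (is.null(shift_ps)) shift_ps <- laser_period_ps / n_streams
  stopifnot(laser_period_ps > 0, n_streams == 2L,
            shift_ps > 0, shift_ps < laser_period_ps)
  structure(list(laser_period_ps = laser_period_ps,
                 n_streams = as.integer(n_streams),
                 shift_ps = shift_ps),
            class = "demux_config")
}

#' Gate a photon into its demultiplexed stream
#'
#' With `Delta = (t_photon - t_ref_pulse) mod T`, the photon lands in stream
#' 0 when `Delta < shift` and in stream 1 otherwise.  Gate boundaries are
#' half-open `[0, shift)` / `[shift, T)`: a photon exactly at the boundary
#' goes to the later stream, consistent with the allocator's strict
#' "exceeds" convention.  Periodic in `t_photon` with period `T`.
#'
#' @param t_photon_ps Photon arrival time(s), ps.
#' @param t_ref_pulse_ps Reference pulse time(s) (`<= t_photon_ps`).
#' @param dcfg A [demux_config()].
#' @return Integer stream indices in `{0, 1}`.
#' @export
demux_stream_index <- function(t_photon_ps, t_ref_pulse_ps, dcfg) {
  stopifnot(all(t_photon_ps >= t_ref_pulse_ps))
  delta <- (t_photon_ps - t_ref_pulse_ps) %% dcfg$laser_period_ps
  as.integer(delta >= dcfg$shift_ps)
}

#' Pair each photon with the most recent laser pulse
#'
#' The digitizer-side conditional filter: a laser pulse is only recorded
#' when a photon follows it, so the recorded event rate tracks the photon
#' rate rather than the far higher pulse repetition rate.  A single merged
#' pass pairs every photon with the latest pulse not after it; photons
#' preceding all pulses are dropped and counted.
#'
#' @param photons Time-ordered photon arrival times (ps).
#' @param pulses Time-ordered laser pulse times (ps).
#' @return Data frame with columns `photon_ps`, `pulse_ps`; attributes
#'   `dropped` (photons before any pulse) and `recorded_pulses` (number of
#'   distinct pulses actually paired).
#' @export
pair_with_last_pulse <- function(photons, pulses) {
  stopifnot(!is.unsorted(photons), !is.unsorted(pulses))
  idx <- findInterval(photons, pulses)
  keep <- idx >= 1L
  out <- data.frame(photon_ps = photons[keep], pulse_ps = pulses[idx[keep]])
  attr(out, "dropped") <- sum(!keep)
  attr(out, "recorded_pulses") <- length(unique(idx[keep]))
  out
}

#' Reconstruct the pulse train from sparse references
#'
#' When only every Nth laser pulse is stored, intermediate (virtual) pulses
#' are extrapolated at the nominal period from the latest stored reference.
#' Exact when the true train is perfectly periodic; with pulse-period drift
#' the phase error is bounded by the drift accumulated between references.
#'
#' @param pulse_times Time-ordered reference pulse times (ps).
#' @param T_nominal Nominal inter-pulse period (integer ps).
#' @return A function mapping query times `t` to the most recent (possibly
#'   virtual) pulse time at or before `t`.  Queries before the first
#'   reference return `NA`.
#' @export
phase_track <- function(pulse_times, T_nominal) {
  stopifnot(!is.unsorted(pulse_times), T_nominal > 0)
  force(pulse_times); force(T_nominal)
  function(t) {
    idx <- findInterval(t, pulse_times)
    ref <- ifelse(idx >= 1L, pulse_times[pmax(idx, 1L)], NA_real_)
    ref + floor((t - ref) / T_nominal) * T_nominal
  }
}
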