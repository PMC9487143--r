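#' @keywords internal
"_PACKAGE"

# Channel roles understood by the allocator.  Only `spectral` may repeat.
CHANNEL_ROLES <- c("line_sync", "frame_sync", "tag_sync", "laser_sync", "spectral")

# The digitizer exposes at most 18 discriminated inputs.
MAX_DIGITIZER_INPUTS <- 18L

PS_PER_SECOND <- 1e12

ps_round <- function(x) floor(x + 0.5)

#' Describe one digitizer input channel
#'
#' A channel pairs a physical digitizer input with the role its signal plays
#' during reconstruction.  The sign of `input_number` carries edge polarity:
#' negative inputs (e.g. `-2`) trigger on the falling edge of the signal.
#' The discriminator threshold is carried as metadata only; tag streams are
#' already discriminated when they reach this package.
#'
#' @param input_number Signed non-zero integer, `|input_number| <= 18`.
#' @param role One of `"line_sync"`, `"frame_sync"`, `"tag_sync"`,
#'   `"laser_sync"`, `"spectral"`.
#' @param threshold Discriminator threshold in volts (metadata).
#' @param label Free-text label.
#' @return A `channel_spec` object (named list).
#' @export
channel_spec <- function(input_number, role, threshold = 0, label = role) {
  role <- match.arg(role, CHANNEL_ROLES)
  spec <- list(
    input_number = as.integer(input_number),
    role = role,
    threshold = as.numeric(threshold),
    label = as.character(label)
  )
  class(spec) <- "channel_spec"
  spec
}

#' Assemble an experiment configuration
#'
#' The configuration is the single source of truth consumed by every other
#' module: acquisition geometry (rows, columns, planes), scan timing (line
#' frequency, fill fraction, bidirectional phase), laser and TAG-lens
#' constants, and the channel map.  All period fields are converted to
#' integer picoseconds at construction time (rounding to nearest), so that
#' downstream cell-boundary arithmetic is exact and tie-breaks are
#' well-defined.
#'
#' @param channels List of [channel_spec()] objects.
#' @param rows,columns Image dimensions in pixels.
#' @param planes Number of axial planes; 1 means 2D.  Volumetric
#'   configurations require an even plane count and a `tag_sync` channel.
#' @param bidirectional Are consecutive lines scanned in opposite directions?
#' @param fill_fraction Fraction of the line period mapped to visible
#'   columns, in (0, 1]; the remainder is mirror turnaround and is discarded.
#'   The visible window is centered in the line period.
#' @param line_frequency_hz Line rate in Hz.  For a resonant scanner in
#'   bidirectional mode this is twice the mirror frequency.  May be `NULL`
#'   when a frame_sync channel is the sole sync source, in which case the
#'   line period is inferred from `frame_rate_hz` and `rows`.
#' @param frame_rate_hz Nominal frame rate; used only with frame-sync-only
#'   configurations and for the last frame of a recording.
#' @param laser_period_ps Laser inter-pulse period in integer picoseconds
#'   (12500 for an 80 MHz source).
#' @param tag_frequency_hz TAG-lens resonance frequency in Hz (about 189 kHz
#'   for the lens modeled here); required when `planes > 1`.
#' @param tag_phase0_rad Phase of the TAG oscillation at its sync pulse, in
#'   radians; fixes where plane 0 sits relative to the sync.
#' @param demultiplex Split each spectral channel into two interleaved
#'   excitation streams gated on time-since-last-laser-pulse?
#' @param bidir_phase_ps Shift (ps) applied to the visible window of odd
#'   lines only; the offline counterpart of the line-shift correction.
#' @param rolling_window_frames Number of frames summed by the rolling
#'   display buffer.
#' @param filename Output path stem.
#' @param replay_existing Replay a stored stream instead of acquiring.
#' @return An `experiment_config` object.
#' @seealso [parse_config()], [validate_config()]
#' @export
experiment_config <- function(channels,
                              rows,
                              columns,
                              planes = 1L,
                              bidirectional = TRUE,
                              fill_fraction = 0.8,
                              line_frequency_hz = NULL,
                              frame_rate_hz = NULL,
                              laser_period_ps = 12500,
                              tag_frequency_hz = NULL,
                              tag_phase0_rad = 0,
                              demultiplex = FALSE,
                              bidir_phase_ps = 0,
                              rolling_window_frames = 1L,
                              filename = "tagscope_run",
                              replay_existing = FALSE) {
  if (inherits(channels, "channel_spec")) channels <- list(channels)
  cfg <- list(
    channels = channels,
    rows = as.integer(rows),
    columns = as.integer(columns),
    planes = as.integer(planes),
    bidirectional = isTRUE(bidirectional),
    fill_fraction = as.numeric(fill_fraction),
    line_frequency_hz = if (is.null(line_frequency_hz)) NULL else as.numeric(line_frequency_hz),
    frame_rate_hz = if (is.null(frame_rate_hz)) NULL else as.numeric(frame_rate_hz),
    laser_period_ps = ps_round(as.numeric(laser_period_ps)),
    tag_frequency_hz = if (is.null(tag_frequency_hz)) NULL else as.numeric(tag_frequency_hz),
    tag_phase0_rad = as.numeric(tag_phase0_rad),
    demultiplex = isTRUE(demultiplex),
    bidir_phase_ps = ps_round(as.numeric(bidir_phase_ps)),
    rolling_window_frames = as.integer(rolling_window_frames),
    filename = as.character(filename),
    replay_existing = isTRUE(replay_existing)
  )
  # Derived integer-picosecond periods (rounded once, here).
  if (!is.null(cfg$line_frequency_hz) && cfg$line_frequency_hz > 0) {
    cfg$line_period_ps <- ps_round(PS_PER_SECOND / cfg$line_frequency_hz)
  } else if (!is.null(cfg$frame_rate_hz) && cfg$frame_rate_hz > 0) {
    cfg$line_period_ps <- ps_round(PS_PER_SECOND / cfg$frame_rate_hz / cfg$rows)
  } else {
    cfg$line_period_ps <- NA_real_
  }
  if (!is.null(cfg$tag_frequency_hz) && cfg$tag_frequency_hz > 0) {
    cfg$tag_period_ps <- ps_round(PS_PER_SECOND / cfg$tag_frequency_hz)
  } else {
    cfg$tag_period_ps <- NA_real_
  }
  class(cfg) <- "experiment_config"
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %d x %d x %d (%s)\n",
              x$rows, x$columns, x$planes,
              if (x$planes > 1L) "volumetric" else "2D"))
  cat(sprintf("  line period: %s ps | fill fraction: %g | %s\n",
              format(x$line_period_ps, big.mark = ","), x$fill_fraction,
              if (x$bidirectional) "bidirectional" else "unidirectional"))
  if (x$demultiplex) {
    cat(sprintf("  demultiplex: on (laser period %s ps)\n",
                format(x$laser_period_ps, big.mark = ",")))
  }
  for (ch in x$channels) {
    cat(sprintf("  channel %+d  %-10s  %s\n", ch$input_number, ch$role, ch$label))
  }
  invisible(x)
}

channels_by_role <- function(cfg, role) {
  Filter(function(ch) ch$role == role, cfg$channels)
}

channel_input <- function(cfg, role) {
  chs <- channels_by_role(cfg, role)
  if (length(chs) == 0L) return(NULL)
  vapply(chs, function(ch) ch$input_number, integer(1))
}

spectral_inputs <- function(cfg) channel_input(cfg, "spectral")

# ---------------------------------------------------------------------------
# Configuration file parsing (TOML dialect)
#
# The on-disk format is a small TOML dialect: top-level `key = value` pairs
# plus `[[channels]]` array-of-tables entries.  Values may be double-quoted
# strings, booleans, or numbers (underscore digit separators and scientific
# notation accepted).  No installed package parses TOML, and the subset used
# by configuration files here is tiny, so it is parsed directly.
# ---------------------------------------------------------------------------

CONFIG_KEYS <- c("rows", "columns", "planes", "bidirectional", "fill_fraction",
                 "line_frequency_hz", "frame_rate_hz", "laser_period_ps",
                 "tag_frequency_hz", "tag_phase0_rad", "demultiplex",
                 "bidir_phase_ps", "rolling_window_frames", "filename",
                 "replay_existing")
CHANNEL_KEYS <- c("input_number", "role", "threshold", "label")

strip_inline_comment <- function(line) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  in_str <- FALSE
  for (i in seq_along(chars)) {
    if (chars[i] == '"') in_str <- !in_str
    if (chars[i] == "#" && !in_str) return(substr(line, 1L, i - 1L))
  }
  line
}

parse_toml_value <- function(raw, lineno) {
  raw <- trimws(raw)
  if (raw == "") stop(sprintf("config line %d: empty value", lineno), call. = FALSE)
  if (startsWith(raw, '"')) {
    if (!endsWith(raw, '"') || nchar(raw) < 2L)
      stop(sprintf("config line %d: unterminated string", lineno), call. = FALSE)
    return(substr(raw, 2L, nchar(raw) - 1L))
  }
  if (raw %in% c("true", "false")) return(raw == "true")
  num <- suppressWarnings(as.numeric(gsub("_", "", raw, fixed = TRUE)))
  if (is.na(num))
    stop(sprintf("config line %d: cannot parse value '%s'", lineno, raw), call. = FALSE)
  num
}

#' Parse an experiment configuration file
#'
#' Reads the TOML-dialect configuration consumed by the whole pipeline:
#' top-level scalar keys matching the fields of [experiment_config()] and a
#' `[[channels]]` array of tables with `input_number`, `role`, `threshold`
#' and `label` entries.  Omitted optional fields take the documented
#' defaults (`bidirectional = true`, `fill_fraction = 0.8`, `planes = 1`,
#' `demultiplex = false`, `rolling_window_frames = 1`, `bidir_phase_ps = 0`).
#'
#' Unknown keys are an error in strict mode (the default) so that typos
#' surface immediately; with `lenient = TRUE` they downgrade to warnings.
#'
#' @param text Either a path to a configuration file or the file contents as
#'   a single string (anything containing a newline or an `=` is treated as
#'   contents).
#' @param lenient Downgrade unknown-key errors to warnings.
#' @return An [experiment_config()] object.
#' @export
parse_config <- function(text, lenient = FALSE) {
  if (length(text) == 1L && !grepl("[\n=]", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  }
  fields <- list()
  channels <- list()
  current <- NULL   # NULL = top level, otherwise index into channels
  complain <- function(msg) {
    if (lenient) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  for (i in seq_along(lines)) {
    line <- trimws(strip_inline_comment(lines[i]))
    if (line == "") next
    if (grepl("^\\[\\[\\s*channels\\s*\\]\\]$", line)) {
      channels[[length(channels) + 1L]] <- list()
      current <- length(channels)
      next
    }
    if (startsWith(line, "[")) {
      complain(sprintf("config line %d: unknown table '%s'", i, line))
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0L)
      stop(sprintf("config line %d: expected 'key = value', got '%s'", i, line),
           call. = FALSE)
    key <- trimws(substr(line, 1L, eq - 1L))
    val <- parse_toml_value(substr(line, eq + 1L, nchar(line)), i)
    if (is.null(current)) {
      if (!key %in% CONFIG_KEYS) {
        complain(sprintf("config line %d: unknown key '%s'", i, key))
        next
      }
      fields[[key]] <- val
    } else {
      if (!key %in% CHANNEL_KEYS) {
        complain(sprintf("config line %d: unknown channel key '%s'", i, key))
        next
      }
      channels[[current]][[key]] <- val
    }
  }
  if (!all(c("rows", "columns") %in% names(fields)))
    stop("config must declare 'rows' and 'columns'", call. = FALSE)
  chans <- lapply(channels, function(tab) {
    if (is.null(tab$input_number) || is.null(tab$role))
      stop("each [[channels]] table needs 'input_number' and 'role'", call. = FALSE)
    channel_spec(tab$input_number, tab$role,
                 threshold = if (is.null(tab$threshold)) 0 else tab$threshold,
                 label = if (is.null(tab$label)) tab$role else tab$label)
  })
  args <- fields
  args$channels <- chans
  do.call(experiment_config, args)
}

#' Serialize a configuration back to its file format
#'
#' Inverse of [parse_config()]: `parse_config(serialize_config(cfg))`
#' reproduces `cfg` field-for-field.
#'
#' @param cfg An [experiment_config()].
#' @param path Optional file path; when given the text is also written there.
#' @return The configuration text, invisibly when `path` is given.
#' @export
serialize_config <- function(cfg, path = NULL) {
  fmt <- function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (is.logical(v)) if (v) "true" else "false"
    else format(v, scientific = FALSE, trim = TRUE)
  }
  out <- character(0)
  for (key in CONFIG_KEYS) {
    v <- cfg[[key]]
    if (is.null(v)) next
    out <- c(out, sprintf("%s = %s", key, fmt(v)))
  }
  for (ch in cfg$channels) {
    out <- c(out, "", "[[channels]]",
             sprintf("input_number = %d", ch$input_number),
             sprintf('role = "%s"', ch$role),
             sprintf("threshold = %s", fmt(ch$threshold)),
             sprintf('label = "%s"', ch$label))
  }
  text <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Validate an experiment configuration
#'
#' Checks every structural invariant the reconstruction relies on and
#' returns the violations as data rather than raising: an empty character
#' vector means the configuration is valid.
#'
#' The invariants: exactly one of line_sync / frame_sync among the channels;
#' at least one spectral channel; at most 18 channels, each with a non-zero
#' input number of magnitude at most 18 and no duplicated inputs; at most
#' one channel per role except spectral; volumetric mode (`planes > 1`)
#' requires an even plane count, a tag_sync channel and a TAG frequency;
#' demultiplexing requires a laser_sync channel and a positive laser period;
#' plus positivity/range checks on the scalar geometry fields.
#'
#' @param cfg An [experiment_config()].
#' @return Character vector of human-readable violation messages (empty if
#'   valid).
#' @export
validate_config <- function(cfg) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)

  roles <- vapply(cfg$channels, function(ch) ch$role, character(1))
  inputs <- vapply(cfg$channels, function(ch) ch$input_number, integer(1))

  n_line <- sum(roles == "line_sync")
  n_frame <- sum(roles == "frame_sync")
  if (n_line + n_frame != 1L)
    add("exactly one of a line_sync or a frame_sync channel is required (not both, not neither)")
  if (sum(roles == "spectral") < 1L)
    add("at least one spectral channel is required")
  if (length(cfg$channels) > MAX_DIGITIZER_INPUTS)
    add(sprintf("at most %d channels are supported; %d declared",
                MAX_DIGITIZER_INPUTS, length(cfg$channels)))
  if (any(inputs == 0L))
    add("channel input_number must be non-zero")
  if (any(abs(inputs) > MAX_DIGITIZER_INPUTS))
    add(sprintf("channel input numbers must satisfy |input| <= %d", MAX_DIGITIZER_INPUTS))
  if (anyDuplicated(inputs))
    add("channel input numbers must be unique")
  for (role in setdiff(CHANNEL_ROLES, "spectral")) {
    if (sum(roles == role) > 1L)
      add(sprintf("at most one %s channel is allowed", role))
  }
  if (cfg$rows < 1L || cfg$columns < 1L)
    add("rows and columns must be positive")
  if (!is.finite(cfg$fill_fraction) || cfg$fill_fraction <= 0 || cfg$fill_fraction > 1)
    add("fill_fraction must lie in (0, 1]")
  if (cfg$planes > 1L) {
    if (cfg$planes %% 2L != 0L)
      add("planes must be even and >1 for volumetric mode")
    if (sum(roles == "tag_sync") == 0L)
      add("volumetric mode (planes > 1) requires a tag_sync channel")
    if (is.na(cfg$tag_period_ps))
      add("volumetric mode requires tag_frequency_hz > 0")
  }
  if (cfg$demultiplex) {
    if (sum(roles == "laser_sync") == 0L)
      add("demultiplex = true requires a laser_sync channel")
    if (!is.finite(cfg$laser_period_ps) || cfg$laser_period_ps <= 0)
      add("demultiplex = true requires laser_period_ps > 0")
  }
  if (is.na(cfg$line_period_ps))
    add("either line_frequency_hz or frame_rate_hz must be given to fix the line period")
  if (cfg$rolling_window_frames < 1L)
    add("rolling_window_frames must be positive")
  v
}
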