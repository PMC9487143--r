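# Accumulation: photon records become per-channel count buffers.  Counts
# are photons -- integer sums throughout; the rolling display buffer keeps
# the window SUM, with the divisor applied only at render/export time, so
# the "brightness = photons detected" property stays exact.

#' Create an empty frame buffer
#'
#' @param rows,cols,planes Buffer dimensions.
#' @param frame_index 0-based frame index the buffer belongs to.
#' @return A `frame_buffer`: a `rows x cols x planes` integer array of
#'   zeros with a `frame_index` attribute.
#' @export
frame_buffer <- function(rows, cols, planes = 1L, frame_index = 0L) {
  buf <- array(0L, dim = c(rows, cols, planes))
  attr(buf, "frame_index") <- as.integer(frame_index)
  class(buf) <- c("frame_buffer", class(buf))
  buf
}

#' Add a batch of photon records to a frame buffer
#'
#' Each record adds exactly 1 to its (row, col, plane) cell; duplicates
#' accumulate and the result is independent of record order (the hashmap
#' step of the rendering pipeline, realized as a tabulation over linear
#' voxel indices).
#'
#' @param buffer A [frame_buffer()].
#' @param records Photon-record data frame; all rows must belong to the
#'   buffer's frame, and coordinates must lie inside the buffer (an
#'   out-of-bounds record is an allocator contract breach and a hard error).
#' @return The updated buffer.
#' @export
increment <- function(buffer, records) {
  d <- dim(buffer)
  if (nrow(records) == 0L) return(buffer)
  fi <- attr(buffer, "frame_index")
  if (!is.null(fi) && !all(records$frame == fi))
    stop("records belong to a different frame than the buffer", call. = FALSE)
  if (any(records$row < 0L | records$row >= d[1L] |
          records$col < 0L | records$col >= d[2L] |
          records$plane < 0L | records$plane >= d[3L]))
    stop("photon record outside buffer bounds (allocator contract breach)",
         call. = FALSE)
  lin <- 1L + records$row + d[1L] * (records$col + d[2L] * records$plane)
  counts <- tabulate(lin, nbins = prod(d))
  buffer[] <- as.integer(buffer) + counts
  buffer
}

buffer_key <- function(channel, stream) {
  ifelse(is.na(stream), sprintf("ch%d", channel), sprintf("ch%d.s%d", channel, stream))
}

#' Accumulate a whole run of photon records into per-channel stacks
#'
#' Spectral channels and demux streams are never blended: each
#' (spectral_channel, demux_stream) pair gets its own
#' `rows x cols x planes x frames` count array, keyed `"ch<k>"` or
#' `"ch<k>.s<j>"`.
#'
#' @param records Photon-record data frame from [process_stream()] or
#'   [read_photon_records()].
#' @param cfg The [experiment_config()] of the run.
#' @param n_frames Number of frames; defaults to `max(records$frame) + 1`.
#' @return Named list of 4D integer count arrays.
#' @export
accumulate_run <- function(records, cfg, n_frames = NULL) {
  if (is.null(n_frames)) {
    n_frames <- if (nrow(records) == 0L) 0L else max(records$frame) + 1L
  }
  keys <- buffer_key(records$spectral_channel, records$demux_stream)
  out <- list()
  for (key in sort(unique(keys))) {
    sel <- records[keys == key, , drop = FALSE]
    d <- c(cfg$rows, cfg$columns, cfg$planes, n_frames)
    lin <- 1L + sel$row + d[1L] * (sel$col + d[2L] * (sel$plane + d[3L] * sel$frame))
    arr <- array(tabulate(lin, nbins = prod(d)), dim = d)
    out[[key]] <- arr
  }
  out
}

#' Rolling display window over the last N frames
#'
#' @param window Positive window length N in frames.
#' @return A `rolling_view` holding a ring of the last N frame buffers and
#'   their running elementwise sum.
#' @export
rolling_view <- function(window) {
  stopifnot(window >= 1L)
  structure(list(window = as.integer(window), ring = list(), sum = NULL),
            class = "rolling_view")
}

#' Push a completed frame into the rolling view
#'
#' Advances the ring (evicting the oldest frame once N frames are held) and
#' updates the running sum.  During warm-up, fewer than N frames are summed.
#' The display convention is the window SUM; divide by the frame count at
#' render time to show an average.
#'
#' @param view A [rolling_view()].
#' @param buffer A completed [frame_buffer()] (or plain count array).
#' @return The updated view; read the display buffer with [current_sum()].
#' @export
push_frame <- function(view, buffer) {
  b <- array(as.numeric(buffer), dim = dim(buffer))
  if (is.null(view$sum)) view$sum <- array(0, dim = dim(b))
  stopifnot(identical(dim(view$sum), dim(b)))
  view$ring[[length(view$ring) + 1L]] <- b
  view$sum <- view$sum + b
  if (length(view$ring) > view$window) {
    view$sum <- view$sum - view$ring[[1L]]
    view$ring <- view$ring[-1L]
  }
  view
}

#' Current display buffer of a rolling view
#'
#' @param view A [rolling_view()].
#' @param average Divide by the number of frames currently held?
#' @param check Recompute the sum from the ring and assert it matches the
#'   running sum (invariant check).
#' @return The summed (or averaged) display buffer.
#' @export
current_sum <- function(view, average = FALSE, check = FALSE) {
  if (is.null(view$sum)) stop("rolling view is empty", call. = FALSE)
  if (check) {
    ref <- Reduce(`+`, view$ring)
    stopifnot(max(abs(ref - view$sum)) == 0)
  }
  if (average) view$sum / length(view$ring) else view$sum
}

#' Depth projection of a recorded run
#'
#' The offline rendering path: frames are summed elementwise across the
#' whole recording, then the maximum across planes is taken (a maximum
#' z-projection of the summed volume).  Brightness normalization along z
#' and smoothing filters are deliberate post-export steps, not applied here.
#'
#' @param buffers Either a `rows x cols x planes x frames` array (as
#'   returned per channel by [accumulate_run()]) or a list of
#'   `rows x cols x planes` frames.
#' @return A `rows x cols` matrix.
#' @export
summed_projection <- function(buffers) {
  if (is.list(buffers)) {
    summed <- Reduce(`+`, lapply(buffers, function(b) array(as.numeric(b), dim = dim(b))))
  } else {
    stopifnot(length(dim(buffers)) %in% c(3L, 4L))
    if (length(dim(buffers)) == 3L) dim(buffers) <- c(dim(buffers), 1L)
    summed <- apply(buffers, c(1L, 2L, 3L), sum)
  }
  apply(summed, c(1L, 2L), max)
}
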