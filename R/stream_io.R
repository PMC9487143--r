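# Tag-stream and artifact serialization.
#
# Tag streams use an open little-endian dialect: a 16-byte header (8-byte
# magic "TAGSCOPE", uint32 version, uint32 reserved) followed by fixed-width
# 12-byte records (int32 channel, uint64 time_ps).  A CSV dialect (columns
# channel,time_ps) serves as a human-readable fixture format.  Timestamps
# are integer picoseconds held in doubles; values stay well below 2^53 so
# the arithmetic is exact.  Vendors' proprietary replay containers are not
# parsed here; `convert_vendor_stream()` documents where a converter would
# plug in.

TAG_STREAM_MAGIC <- "TAGSCOPE"
TAG_STREAM_VERSION <- 1L
TAG_RECORD_BYTES <- 12L
TWO32 <- 4294967296

#' Construct a tag-stream data frame
#'
#' @param channel Signed integer channel ids.
#' @param time_ps Non-decreasing integer picosecond timestamps.
#' @return A `tag_stream` data frame with columns `channel`, `time_ps`.
#' @export
tag_stream <- function(channel = integer(0), time_ps = numeric(0)) {
  stopifnot(length(channel) == length(time_ps))
  df <- data.frame(channel = as.integer(channel), time_ps = as.numeric(time_ps))
  class(df) <- c("tag_stream", "data.frame")
  df
}

# Split non-negative integer doubles into (lo, hi) unsigned 32-bit words,
# represented as R's signed integers for writeBin.
uint64_split <- function(x) {
  lo <- x %% TWO32
  hi <- x %/% TWO32
  as_signed32 <- function(w) as.integer(ifelse(w >= TWO32 / 2, w - TWO32, w))
  list(lo = as_signed32(lo), hi = as_signed32(hi))
}

uint64_join <- function(lo, hi) {
  unsign <- function(w) ifelse(w < 0, w + TWO32, as.numeric(w))
  unsign(hi) * TWO32 + unsign(lo)
}

#' Write a time-tag stream
#'
#' @param tags A [tag_stream()] (or any data frame with `channel`,
#'   `time_ps`), time-ordered.
#' @param path Output path.  Extension `.csv` selects the CSV dialect;
#'   anything else the binary dialect.
#' @return Number of tags written, invisibly.
#' @export
write_tag_stream <- function(tags, path) {
  stopifnot(all(diff(tags$time_ps) >= 0), all(tags$time_ps >= 0))
  n <- nrow(tags)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(
      data.frame(channel = tags$channel,
                 time_ps = format(tags$time_ps, scientific = FALSE, trim = TRUE)),
      path, row.names = FALSE, quote = FALSE)
    return(invisible(n))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(TAG_STREAM_MAGIC, con, nchars = 8L, eos = NULL)
  writeBin(c(TAG_STREAM_VERSION, 0L), con, size = 4L, endian = "little")
  if (n > 0L) {
    words <- uint64_split(tags$time_ps)
    interleaved <- as.vector(rbind(as.integer(tags$channel), words$lo, words$hi))
    writeBin(interleaved, con, size = 4L, endian = "little")
  }
  invisible(n)
}

#' Read a time-tag stream
#'
#' Reads either dialect written by [write_tag_stream()] (bit-exact round
#' trip).  Timestamp monotonicity is enforced with zero slack: the first
#' out-of-order record raises an error naming its index.  Tags on channels
#' absent from any configuration are passed through untouched; it is the
#' allocator's job to warn about undeclared channels.
#'
#' @param path Path to a binary or CSV tag stream.
#' @return A [tag_stream()] data frame in stored order.
#' @export
read_tag_stream <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, colClasses = c(channel = "integer", time_ps = "numeric"))
    tags <- tag_stream(df$channel, df$time_ps)
  } else {
    size <- file.info(path)$size
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readChar(con, 8L, useBytes = TRUE)
    if (!identical(magic, TAG_STREAM_MAGIC))
      stop("not a tagscope tag stream (bad magic)", call. = FALSE)
    hdr <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
    if (hdr[1L] != TAG_STREAM_VERSION)
      stop("unsupported tag stream version ", hdr[1L], call. = FALSE)
    payload <- size - 16L
    if (payload %% TAG_RECORD_BYTES != 0L)
      stop(sprintf("truncated tag stream: %d stray bytes after byte offset %d",
                   payload %% TAG_RECORD_BYTES,
                   16L + (payload %/% TAG_RECORD_BYTES) * TAG_RECORD_BYTES),
           call. = FALSE)
    n <- payload %/% TAG_RECORD_BYTES
    if (n == 0L) return(tag_stream())
    words <- readBin(con, "integer", n = 3L * n, size = 4L, endian = "little")
    m <- matrix(words, nrow = 3L)
    tags <- tag_stream(m[1L, ], uint64_join(m[2L, ], m[3L, ]))
  }
  bad <- which(diff(tags$time_ps) < 0)
  if (length(bad) > 0L)
    stop(sprintf("tag stream violates time order at record %d", bad[1L] + 1L),
         call. = FALSE)
  tags
}

#' Document where a vendor-format converter would plug in
#'
#' Proprietary digitizer replay containers have undocumented byte layouts
#' and are not parsed by this package.  A converter producing either open
#' dialect of [write_tag_stream()] can be registered by wrapping it into a
#' function `path -> tag_stream`; this stub only raises.
#'
#' @param path Path to a vendor stream.
#' @export
convert_vendor_stream <- function(path) {
  stop("no vendor stream converter is registered; convert the recording to ",
       "the open binary or CSV tag-stream dialect (see ?write_tag_stream)",
       call. = FALSE)
}

# ---------------------------------------------------------------------------
# Photon records (the ".arrow_stream" role): one row per displayed photon,
# columnar, re-renderable into images without the original tag stream.
# ---------------------------------------------------------------------------

#' Write allocated photon records
#'
#' Serializes the allocator's output one row per photon in an Arrow IPC
#' stream (or CSV when the path ends in `.csv`), with the spectral channel
#' as a column partition.  Re-accumulating the written records reproduces
#' the online frame buffers count-for-count.
#'
#' @param records Photon-record data frame from [process_stream()].
#' @param path Output path (`.arrows` Arrow IPC recommended; `.csv` fallback).
#' @return Number of rows written, invisibly.
#' @export
write_photon_records <- function(records, path) {
  cols <- c("spectral_channel", "demux_stream", "frame", "row", "col",
            "plane", "time_ps")
  stopifnot(all(cols %in% names(records)))
  records <- as.data.frame(records)[, cols]
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  } else {
    arrow::write_ipc_stream(records, path)
  }
  invisible(nrow(records))
}

#' Read photon records written by [write_photon_records()]
#'
#' @param path Path to an Arrow IPC stream or CSV of photon records.
#' @return Photon-record data frame.
#' @export
read_photon_records <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
  } else {
    df <- as.data.frame(arrow::read_ipc_stream(path))
  }
  df$demux_stream <- as.integer(df$demux_stream)
  df
}

# ---------------------------------------------------------------------------
# Count stacks: multi-page 16-bit unsigned TIFF, one page per plane per
# frame in plane-major order within each frame.
# ---------------------------------------------------------------------------

#' Write a count buffer as a multi-page 16-bit TIFF
#'
#' @param buffer A single frame (`rows x cols` matrix or
#'   `rows x cols x planes` array) or a run (`rows x cols x planes x frames`
#'   array) of non-negative counts.  Counts above 65535 are saturated with a
#'   warning.
#' @param path Output TIFF path.
#' @return Number of pages written, invisibly.
#' @export
write_stack <- function(buffer, path) {
  if (is.matrix(buffer)) dim(buffer) <- c(dim(buffer), 1L, 1L)
  if (length(dim(buffer)) == 3L) dim(buffer) <- c(dim(buffer), 1L)
  stopifnot(length(dim(buffer)) == 4L, all(is.finite(buffer)), all(buffer >= 0))
  if (any(buffer > 65535)) {
    warning("counts above 65535 saturated to 65535 in TIFF export", call. = FALSE)
    buffer <- pmin(buffer, 65535)
  }
  d <- dim(buffer)
  pages <- vector("list", d[3L] * d[4L])
  k <- 0L
  for (f in seq_len(d[4L])) {
    for (p in seq_len(d[3L])) {
      k <- k + 1L
      pages[[k]] <- buffer[, , p, f] / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(k)
}

#' Read a count stack written by [write_stack()]
#'
#' @param path TIFF path.
#' @param planes Plane count used to refold pages into
#'   `rows x cols x planes x frames` (default 1).
#' @return Integer count array.
#' @export
read_stack <- function(path, planes = 1L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  n <- length(pages)
  stopifnot(n %% planes == 0L)
  d <- dim(pages[[1L]])
  out <- array(0, dim = c(d[1L], d[2L], planes, n %/% planes))
  k <- 0L
  for (f in seq_len(n %/% planes)) {
    for (p in seq_len(planes)) {
      k <- k + 1L
      out[, , p, f] <- round(pages[[k]] * 65535)
    }
  }
  out
}
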