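# Recording container I/O.
#
# Format: a pair of files, `<path>` holding the sample matrix as little-endian
# IEEE-754 float32 (channel-interleaved, time-major), and `<path>.json` a JSON
# header with the format version, sampling rate, dimensions, channel labels,
# unit-sphere positions, units and event annotations. Samples round-trip
# within float32 quantization; labels, positions and events round-trip
# exactly. Channel labels are limited to 16 ASCII characters (EDF-style).

FT_FORMAT_VERSION <- "fpvstag-rec-1"
FT_LABEL_MAX <- 16L

#' Write a recording to disk
#'
#' Serializes an `ft_recording` to the package's documented two-file container
#' (float32 sample file plus JSON header with labels, positions, sampling rate
#' and event annotations). See [read_recording()] for the inverse.
#'
#' @param rec An `ft_recording`.
#' @param path Output path for the sample file; the header is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ft_recording"))
  if (any(nchar(rec$labels) > FT_LABEL_MAX))
    ft_stop("channel label longer than %d characters", "ft_io_error", FT_LABEL_MAX)
  header <- list(
    format = FT_FORMAT_VERSION,
    fs = rec$fs,
    n_samples = nrow(rec$samples),
    n_channels = ncol(rec$samples),
    units = rec$units,
    dtype = "float32le",
    labels = rec$labels,
    positions = as.data.frame(rec$montage)[, c("label", "x", "y", "z")],
    events = rec$events)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  # time-major interleave: sample 1 of all channels, then sample 2, ...
  writeBin(as.numeric(t(rec$samples)), con, size = 4, endian = "little")
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Path of the sample file (the header is read from
#'   `paste0(path, ".json")`).
#' @return An `ft_recording`.
#' @export
read_recording <- function(path) {
  hpath <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(hpath))
    ft_stop("recording files not found at %s(.json)", "ft_io_error", path)
  h <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (!identical(h$format, FT_FORMAT_VERSION))
    ft_stop("unsupported recording format '%s'", "ft_io_error", h$format)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, numeric(), n = h$n_samples * h$n_channels, size = 4,
               endian = "little")
  samples <- matrix(x, nrow = h$n_samples, ncol = h$n_channels, byrow = TRUE)
  montage <- structure(h$positions, class = c("ft_montage", "data.frame"))
  events <- as.data.frame(h$events)
  if (nrow(events) == 0)
    events <- data.frame(time = numeric(0), label = character(0))
  structure(list(samples = samples, fs = h$fs, labels = h$labels,
                 montage = montage, events = events, units = h$units),
            class = "ft_recording")
}

#' Write a long-format table as tab-separated values
#'
#' Convenience writer for response, subject, behaviour and time-course tables.
#'
#' @param tbl A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_tsv()]
#' @param path Input path.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
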