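# On-disk session container.
#
# Traces are stored as a raw IEEE-754 little-endian float64 array
# (`traces.bin`, sample-major: all samples of channel 1, then channel 2, ...)
# with a JSON text sidecar (`meta.json`) holding fs, dimensions, channel
# metadata and session id. Trial, gaze and critical-region tables are
# tab-separated text with a one-line header. The binary payload roundtrips
# bit-exactly; tables roundtrip losslessly via full-precision formatting.

TRIAL_COLUMNS <- c("trial_id", "list_id", "image_id", "phase", "condition",
                   "correct", "image_onset_s", "image_offset_s",
                   "response_time_s")

#' Write / read an iEEG recording container
#'
#' `write_recording()` creates (or reuses) a directory holding `traces.bin`
#' (float64, little-endian, sample-major) and `meta.json`. `read_recording()`
#' validates the sidecar against the array (declared sample/channel counts
#' must match the payload size) and refuses traces containing NaN.
#'
#' @param rec an `ieeg_recording`.
#' @param dir container directory.
#' @return `write_recording()` the directory invisibly; `read_recording()`
#'   an `ieeg_recording`.
#' @export
write_recording <- function(rec, dir) {
  stop_if_not(inherits(rec, "ieeg_recording"), "rec must be an ieeg_recording")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "traces.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$traces), con, size = 8L, endian = "little")
  meta <- list(session_id = rec$session_id,
               fs = rec$fs,
               n_samples = nrow(rec$traces),
               n_channels = ncol(rec$traces),
               storage = list(dtype = "float64", endian = "little",
                              order = "sample-major"),
               channels = rec$channels)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       pretty = TRUE)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  bin_path <- file.path(dir, "traces.bin")
  stop_if_not(file.exists(meta_path), "missing sidecar meta.json in %s", dir)
  stop_if_not(file.exists(bin_path), "missing traces.bin in %s", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("fs", "n_samples", "n_channels", "channels", "session_id"))
    stop_if_not(!is.null(meta[[f]]), "sidecar is missing field '%s'", f)
  n_expected <- meta$n_samples * meta$n_channels
  n_bytes <- file.size(bin_path)
  stop_if_not(n_bytes == 8 * n_expected,
              "sidecar declares %d values but traces.bin holds %g",
              n_expected, n_bytes / 8)
  con <- file(bin_path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "double", n = n_expected, size = 8L,
               endian = "little")
  stop_if_not(!anyNA(v), "traces.bin contains NaN values")
  traces <- matrix(v, nrow = meta$n_samples, ncol = meta$n_channels)
  channels <- as.data.frame(meta$channels, stringsAsFactors = FALSE)
  new_recording(traces, as.numeric(meta$fs), channels,
                session_id = meta$session_id)
}

write_tsv <- function(df, path) {
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read the trial event table (TSV)
#'
#' Tab-separated with a one-line header; `read_trials()` fails with the name
#' of any missing mandatory column.
#'
#' @param trials trial table data frame.
#' @param path file path.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  stop_if_not(length(missing) == 0, "trial table is missing column(s): %s",
              paste(missing, collapse = ", "))
  write_tsv(trials[TRIAL_COLUMNS], path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(df))
  stop_if_not(length(missing) == 0, "trial table is missing column(s): %s",
              paste(missing, collapse = ", "))
  df$correct <- as.logical(df$correct)
  df
}

#' Write / read a gaze stream and critical-region table (TSV)
#'
#' @param gaze data frame with `t_s`, `x_deg`, `y_deg`.
#' @param regions data frame with `image_id`, `x0`, `y0`, `x1`, `y1` (deg).
#' @param path file path.
#' @export
write_gaze <- function(gaze, path) {
  missing <- setdiff(c("t_s", "x_deg", "y_deg"), names(gaze))
  stop_if_not(length(missing) == 0, "gaze table is missing column(s): %s",
              paste(missing, collapse = ", "))
  write_tsv(gaze[c("t_s", "x_deg", "y_deg")], path)
}

#' @rdname write_gaze
#' @export
read_gaze <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("t_s", "x_deg", "y_deg"), names(df))
  stop_if_not(length(missing) == 0, "gaze table is missing column(s): %s",
              paste(missing, collapse = ", "))
  stop_if_not(!is.unsorted(df$t_s), "gaze timestamps must be non-decreasing")
  df
}

#' @rdname write_gaze
#' @export
write_regions <- function(regions, path) {
  missing <- setdiff(c("image_id", "x0", "y0", "x1", "y1"), names(regions))
  stop_if_not(length(missing) == 0, "region table is missing column(s): %s",
              paste(missing, collapse = ", "))
  write_tsv(regions[c("image_id", "x0", "y0", "x1", "y1")], path)
}

#' @rdname write_gaze
#' @export
read_regions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("image_id", "x0", "y0", "x1", "y1"), names(df))
  stop_if_not(length(missing) == 0, "region table is missing column(s): %s",
              paste(missing, collapse = ", "))
  df
}

#' Serialise ground truth alongside a synthetic dataset
#'
#' @param truth a `sim_ground_truth`.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(truth, path) {
  x <- unclass(truth)
  x$config <- unclass(x$config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$config <- structure(x$config, class = "sim_config")
  structure(x, class = "sim_ground_truth")
}

#' Write a full synthetic session to a directory
#'
#' Convenience wrapper writing the recording container, the trial table and
#' (if present) gaze, regions and ground truth.
#'
#' @param sim output of [generate_recording()], optionally with a `gaze`
#'   element from [generate_gaze()].
#' @param dir target directory.
#' @export
write_session <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_recording(sim$recording, file.path(dir, "recording"))
  write_trials(sim$trials, file.path(dir, "events.tsv"))
  if (!is.null(sim$truth))
    write_ground_truth(sim$truth, file.path(dir, "ground_truth.json"))
  if (!is.null(sim$gaze)) {
    write_gaze(sim$gaze$gaze, file.path(dir, "gaze.tsv"))
    write_regions(sim$gaze$regions, file.path(dir, "regions.tsv"))
  }
  invisible(dir)
}
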