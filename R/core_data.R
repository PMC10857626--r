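#' Construct a sensor recording
#'
#' A sensor recording holds equal-length, time-aligned sample streams
#' (e.g. `acc_x`, `acc_y`, `acc_z`, `gyr_x`, `mag_x`, `audio`) together
#' with a per-sample activity label and the sampling rate.
#'
#' @param channels named list of equal-length numeric vectors; names must
#'   be unique.
#' @param labels character vector of per-sample activity labels, same
#'   length as every channel.
#' @param sampling_rate_hz positive sampling rate in Hz.
#' @param subject_id opaque subject identifier.
#' @return an object of class `sensor_recording`.
#' @export
sensor_recording <- function(channels, labels, sampling_rate_hz,
                             subject_id = "subject-1") {
  if (!is.list(channels) || length(channels) < 1L)
    stop("`channels` must be a non-empty named list of numeric vectors")
  nm <- names(channels)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("channel names must be present and unique")
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all channels must have identical length")
  n <- lens[[1]]
  if (n < 1L) stop("channels must contain at least one sample")
  for (ch in nm) {
    if (!is.numeric(channels[[ch]]))
      stop("channel `", ch, "` is not numeric")
  }
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("labels must have the same length as the channels (", n, ")")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("`sampling_rate_hz` must be a single positive number")
  structure(
    list(channels = lapply(channels, as.numeric), labels = labels,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         subject_id = as.character(subject_id)),
    class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat("<sensor_recording> subject:", x$subject_id,
      "| fs:", x$sampling_rate_hz, "Hz |", length(x$labels), "samples\n")
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  cat("  labels:", paste(sort(unique(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a recording
#' @param recording a `sensor_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(recording) length(recording$labels)

#' Read a sensor-log CSV
#'
#' The file must have a header with one numeric column per channel plus a
#' final (or anywhere-positioned) `label` column. Column order is
#' preserved as channel order.
#'
#' @param path path to the CSV file.
#' @param sampling_rate_hz sampling rate of the logged stream, in Hz.
#' @param subject_id subject identifier to attach.
#' @return a [sensor_recording()].
#' @export
read_recording_csv <- function(path, sampling_rate_hz,
                               subject_id = "subject-1") {
  df <- data.table::fread(path, sep = ",", header = TRUE,
                          data.table = FALSE, fill = FALSE)
  if (!"label" %in% names(df))
    stop("sensor-log CSV is missing the required `label` column: ", path)
  chn <- setdiff(names(df), "label")
  if (length(chn) == 0L) stop("sensor-log CSV has no channel columns: ", path)
  channels <- list()
  for (ch in chn) {
    v <- df[[ch]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA")
      if (length(bad) > 0L)
        stop("non-numeric value in channel `", ch, "` at row ", bad[1])
      v <- num
    }
    channels[[ch]] <- v
  }
  sensor_recording(channels, as.character(df$label), sampling_rate_hz,
                   subject_id)
}

#' Write a sensor recording to CSV
#'
#' Inverse of [read_recording_csv()]: one column per channel plus a final
#' `label` column.
#'
#' @param recording a `sensor_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "sensor_recording"))
  df <- as.data.frame(recording$channels, check.names = FALSE)
  df$label <- recording$labels
  data.table::fwrite(df, path)
  invisible(path)
}

#' Majority label of a window
#'
#' Returns the most frequent label; ties are broken by lexicographic
#' order of the tied label strings, so the result is deterministic and
#' dataset-independent.
#'
#' @param sample_labels non-empty character vector.
#' @return a single label string, always an element of the input.
#' @export
assign_window_label <- function(sample_labels) {
  if (length(sample_labels) == 0L)
    stop("cannot assign a label to an empty window")
  tab <- table(as.character(sample_labels))
  winners <- names(tab)[tab == max(tab)]
  sort(winners)[1]
}

#' Construct a feature table
#'
#' Rows are windows, columns are named features, plus a `label` column.
#' Feature values must be finite (no NaN/Inf) and feature names unique.
#'
#' @param values numeric matrix or data frame (windows x features).
#' @param feature_names character vector of unique feature names; taken
#'   from `values` column names when omitted.
#' @param labels per-row label vector.
#' @return a data frame of class `feature_table` whose last column is
#'   `label`.
#' @export
feature_table <- function(values, feature_names = NULL, labels) {
  values <- as.matrix(values)
  if (is.null(feature_names)) feature_names <- colnames(values)
  if (is.null(feature_names))
    stop("feature names must be supplied or present as column names")
  feature_names <- as.character(feature_names)
  if (anyDuplicated(feature_names))
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  if (ncol(values) != length(feature_names))
    stop("number of feature names does not match number of columns")
  if ("label" %in% feature_names)
    stop("`label` is reserved and cannot be a feature name")
  labels <- as.character(labels)
  if (nrow(values) != length(labels))
    stop("row count (", nrow(values), ") != label count (", length(labels), ")")
  if (nrow(values) > 0L && any(!is.finite(values)))
    stop("feature table contains non-finite values (NaN/Inf/NA)")
  df <- as.data.frame(values)
  names(df) <- feature_names
  df$label <- labels
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Feature names of a feature table
#' @param table a `feature_table`.
#' @return character vector of feature column names (excludes `label`).
#' @export
feature_names <- function(table) setdiff(names(table), "label")

#' Numeric feature matrix of a feature table
#' @param table a `feature_table`.
#' @return numeric matrix (windows x features).
#' @export
feature_matrix <- function(table) {
  as.matrix(table[, feature_names(table), drop = FALSE])
}

validate_feature_table <- function(table) {
  fn <- feature_names(table)
  if (anyDuplicated(fn)) stop("duplicate feature names")
  m <- feature_matrix(table)
  if (nrow(m) > 0L && any(!is.finite(m)))
    stop("feature table contains non-finite values (NaN/Inf/NA)")
  invisible(table)
}

#' Write a feature table to CSV
#'
#' Header is the feature names followed by `label`; values round-trip
#' through [read_feature_table()] to at least 12 significant digits.
#'
#' @param table a `feature_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  data.table::fwrite(as.data.frame(table), path)
  invisible(path)
}

#' Read a feature table from CSV
#' @param path path to a CSV written by [write_feature_table()].
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- data.table::fread(path, sep = ",", header = TRUE,
                          data.table = FALSE)
  if (!"label" %in% names(df))
    stop("feature CSV is missing the `label` column: ", path)
  fn <- setdiff(names(df), "label")
  if (nrow(df) == 0L) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(fn),
                dimnames = list(NULL, fn))
    return(feature_table(m, fn, character(0)))
  }
  feature_table(as.matrix(df[, fn, drop = FALSE]), fn,
                as.character(df$label))
}
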