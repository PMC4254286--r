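#' Construct a validated onset series
#'
#' An onset series holds the absolute timestamps (in seconds from the start of
#' the recording) at which an external beat tracker detected beats or barlines
#' (downbeats). Timestamps must be non-negative and strictly increasing:
#' duplicate timestamps would produce zero-length intervals, which break the
#' percentage transforms downstream, so they are rejected rather than dropped.
#'
#' @param timestamps Numeric vector of onset times in seconds.
#' @param kind `"beat"` or `"bar"`.
#' @param source_id Free-text identifier carried through to summary output.
#' @return An object of class `onset_series` with fields `timestamps`,
#'   `kind`, and `source_id`.
#' @examples
#' onset_series(c(0, 0.5, 1, 1.5), kind = "beat")
#' @export
onset_series <- function(timestamps, kind = c("beat", "bar"), source_id = "") {
  kind <- match.arg(kind)
  timestamps <- as.numeric(timestamps)
  if (anyNA(timestamps)) {
    stop("onset timestamps contain missing values", call. = FALSE)
  }
  bad <- which(timestamps < 0)
  if (length(bad)) {
    stop(sprintf("negative onset timestamp at index %d (%.6g)", bad[1],
                 timestamps[bad[1]]), call. = FALSE)
  }
  if (length(timestamps) >= 2) {
    d <- diff(timestamps)
    bad <- which(d <= 0)
    if (length(bad)) {
      stop(sprintf(
        "onset timestamps not strictly increasing at index %d (%.6g after %.6g)",
        bad[1] + 1, timestamps[bad[1] + 1], timestamps[bad[1]]), call. = FALSE)
    }
  }
  structure(list(timestamps = timestamps, kind = kind,
                 source_id = as.character(source_id)[1]),
            class = "onset_series")
}

#' @export
print.onset_series <- function(x, ...) {
  cat(sprintf("<onset_series> %d %s onsets", length(x$timestamps), x$kind))
  if (length(x$timestamps) >= 2) {
    cat(sprintf(" spanning %.3f s", diff(range(x$timestamps))))
  }
  if (nzchar(x$source_id)) cat(sprintf(" [%s]", x$source_id))
  cat("\n")
  invisible(x)
}

#' @export
length.onset_series <- function(x) length(x$timestamps)

#' External point estimates attached to an onset record
#'
#' Beat-tracking services often ship point estimates of average tempo (bpm)
#' and time signature (beats per bar) alongside the raw onsets. These are
#' optional; when a tempo estimate is present the Estimated Tempo Mismatch
#' statistic can be computed against it.
#'
#' @param tempo External tempo estimate in beats per minute, or `NULL`.
#' @param time_signature External integer beats-per-bar estimate, or `NULL`.
#' @return An object of class `external_estimates`.
#' @export
external_estimates <- function(tempo = NULL, time_signature = NULL) {
  if (!is.null(tempo)) {
    tempo <- as.numeric(tempo)[1]
    if (is.na(tempo) || tempo <= 0) stop("external tempo must be > 0", call. = FALSE)
  }
  if (!is.null(time_signature)) {
    time_signature <- as.integer(time_signature)[1]
    if (is.na(time_signature) || time_signature < 1) {
      stop("external time signature must be >= 1", call. = FALSE)
    }
  }
  structure(list(tempo = tempo, time_signature = time_signature),
            class = "external_estimates")
}

#' Derive an interval series by first-order differencing
#'
#' Converts beat (or bar) onset timestamps into the series of inter-beat
#' (inter-bar) intervals. Each interval is paired with the timestamp that
#' opens it, so every later stage can reason in real time.
#'
#' @param series An [onset_series()] with at least two timestamps.
#' @return An object of class `interval_series` with fields `values` (interval
#'   durations in seconds), `start_times` (the onset opening each interval),
#'   and `kind`.
#' @examples
#' b <- onset_series(c(0, 0.5, 1.25))
#' intervals_from_onsets(b)$values  # 0.50 0.75
#' @export
intervals_from_onsets <- function(series) {
  stopifnot(inherits(series, "onset_series"))
  ts <- series$timestamps
  if (length(ts) < 2) stop("insufficient onsets: need at least 2 timestamps", call. = FALSE)
  structure(list(values = diff(ts),
                 start_times = ts[-length(ts)],
                 kind = series$kind),
            class = "interval_series")
}

#' @export
print.interval_series <- function(x, ...) {
  cat(sprintf("<interval_series> %d %s intervals, mean %.4f s\n",
              length(x$values), x$kind, mean(x$values)))
  invisible(x)
}

#' @export
length.interval_series <- function(x) length(x$values)

#' Construct an interval series directly
#'
#' Mostly useful for building fixtures with known ground truth; analysis of
#' real records goes through [intervals_from_onsets()].
#'
#' @param values Positive interval durations in seconds.
#' @param start_times Timestamp opening each interval (strictly increasing,
#'   same length as `values`).
#' @param kind `"beat"` or `"bar"`.
#' @return An object of class `interval_series`.
#' @export
interval_series <- function(values, start_times, kind = "beat") {
  stopifnot(length(values) == length(start_times), all(values > 0))
  structure(list(values = as.numeric(values),
                 start_times = as.numeric(start_times), kind = kind),
            class = "interval_series")
}

#' Read beat/bar onset records from CSV or JSON
#'
#' Two plain-text dialects are supported. CSV: one timestamp (seconds, `.`
#' decimal separator) per line, with beats and bars in separate files. JSON:
#' a single object with keys `beats_start` (required), `bars_start`
#' (optional), `tempo` and `time_signature` (optional external point
#' estimates), and `id` (optional identifier) — mirroring the analysis fields
#' distributed with large beat-tracked corpora such as the Million Song
#' Dataset.
#'
#' @param path Path to the beats CSV file or to the JSON record.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @param bars_path Optional path to a bars CSV (ignored for JSON input).
#' @return A list with elements `beats` (an [onset_series()]), `bars` (an
#'   [onset_series()], possibly empty), and `external`
#'   (an [external_estimates()]).
#' @export
read_onsets <- function(path, format = c("auto", "csv", "json"), bars_path = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "csv") {
    beats <- onset_series(scan(path, what = numeric(), quiet = TRUE),
                          kind = "beat", source_id = basename(path))
    bars <- if (!is.null(bars_path)) {
      onset_series(scan(bars_path, what = numeric(), quiet = TRUE),
                   kind = "bar", source_id = basename(bars_path))
    } else {
      onset_series(numeric(0), kind = "bar")
    }
    return(list(beats = beats, bars = bars, external = external_estimates()))
  }
  rec <- jsonlite::fromJSON(path)
  if (is.null(rec$beats_start)) {
    stop(sprintf("%s: required field 'beats_start' is missing", path), call. = FALSE)
  }
  id <- if (!is.null(rec$id)) rec$id else basename(path)
  beats <- onset_series(rec$beats_start, kind = "beat", source_id = id)
  if (is.null(rec$bars_start)) {
    warning(sprintf("%s: no 'bars_start' field; meter statistics unavailable", path),
            call. = FALSE)
    bars <- onset_series(numeric(0), kind = "bar", source_id = id)
  } else {
    bars <- onset_series(rec$bars_start, kind = "bar", source_id = id)
  }
  ext <- external_estimates(tempo = rec$tempo, time_signature = rec$time_signature)
  list(beats = beats, bars = bars, external = ext)
}

#' Write an onset record as a JSON file
#'
#' Inverse of [read_onsets()] for the JSON dialect; timestamps round-trip
#' bit-exactly (full double precision is serialized).
#'
#' @param beats,bars [onset_series()] objects (`bars` may be empty or `NULL`).
#' @param path Output path.
#' @param external Optional [external_estimates()].
#' @param id Optional record identifier.
#' @return `path`, invisibly.
#' @export
write_onsets_json <- function(beats, path, bars = NULL, external = NULL, id = NULL) {
  rec <- list(beats_start = beats$timestamps)
  if (!is.null(bars) && length(bars$timestamps)) rec$bars_start <- bars$timestamps
  if (!is.null(external)) {
    rec$tempo <- external$tempo
    rec$time_signature <- external$time_signature
  }
  if (!is.null(id)) rec$id <- id else if (nzchar(beats$source_id)) rec$id <- beats$source_id
  # I(17) forces full shortest-round-trip precision so timestamps survive
  # a write/read cycle bit-exactly
  jsonlite::write_json(rec[!vapply(rec, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

summary_columns <- c(
  "id", "stable_duration_s", "stable_percentage", "run_percentage",
  "estimated_tempo_bpm", "etm_percent", "estimated_meter", "meter_is_integer",
  "pdl_max", "spc_max", "ptd_max", "segment_start_s", "segment_end_s",
  "theta_local", "theta_run", "theta_gap")

#' Write summary-statistics records to TSV or JSON
#'
#' One row (or JSON record) per analyzed file, in the canonical column order.
#' Statistics that are undefined for a record — e.g. every segment-dependent
#' statistic when no Stable Segment was found — are written as empty TSV
#' fields (`null` in JSON), never as zeros: absence of a segment is not the
#' same as a segment with zero duration.
#'
#' @param stats A single `beats_summary` or a list of them (may be empty).
#' @param path Output file path, or `""` for standard output (TSV only).
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_summary <- function(stats, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(stats, "beats_summary")) stats <- list(stats)
  df <- summary_table(stats)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    recs <- lapply(stats, function(s) {
      r <- as.list(as.data.frame(s))
      lapply(r, function(v) if (is.na(v)) NULL else v)
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Bind summary records into the canonical table
#'
#' @param stats List of `beats_summary` objects (may be empty).
#' @return A data frame with the canonical summary columns, zero or more rows.
#' @export
summary_table <- function(stats) {
  if (!length(stats)) {
    df <- as.data.frame(setNames(
      replicate(length(summary_columns), numeric(0), simplify = FALSE),
      summary_columns))
    df$id <- character(0)
    return(df)
  }
  do.call(rbind, lapply(stats, as.data.frame))
}

#' Read a summary TSV back into a data frame
#'
#' @param path Path to a TSV written by [write_summary()].
#' @return Data frame with the canonical columns; empty fields become `NA`.
#' @export
read_summary <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(summary_columns, names(df))
  if (length(missing_cols)) {
    stop(sprintf("summary table lacks columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}
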