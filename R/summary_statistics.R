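# The nine summary statistics (A-I) computed for a Stable Segment:
#   A Stable Duration        B Stable Percentage     C Run Percentage
#   D Estimated Tempo        E Estimated Tempo Mismatch
#   F Estimated Meter        G PDL_max   H SPC_max   I PTD_max

#' Stable Duration (statistic A)
#'
#' Duration in seconds between the first and last timestamps of the Stable
#' Segment, i.e. its full span including bridged Gaps.
#'
#' @param segment A `stable_segment`.
#' @return Seconds.
#' @export
stable_duration <- function(segment) {
  stopifnot(inherits(segment, "stable_segment"))
  segment$end_time - segment$start_time
}

#' Stable Percentage (statistic B)
#'
#' The Stable Duration as a percentage of the span of the whole beat series
#' (first to last detected beat). A value of 100 indicates temporal stability
#' from the first detected beat to the last.
#'
#' @param segment A `stable_segment`.
#' @param beats The beat [onset_series()] the segment was derived from.
#' @return Percent in (0, 100].
#' @export
stable_percentage <- function(segment, beats) {
  stopifnot(inherits(segment, "stable_segment"), inherits(beats, "onset_series"))
  span <- max(beats$timestamps) - min(beats$timestamps)
  100 * stable_duration(segment) / span
}

#' Run Percentage (statistic C)
#'
#' Percentage of the Stable Duration comprised of Runs (as opposed to bridged
#' Gaps). Equals 100 exactly when the segment contains no Gaps.
#'
#' @param segment A `stable_segment`.
#' @return Percent in (0, 100].
#' @export
run_percentage <- function(segment) {
  stopifnot(inherits(segment, "stable_segment"))
  100 * sum(segment$runs$duration) / stable_duration(segment)
}

#' Estimated Tempo (statistic D)
#'
#' The tempo location lambda of the entire interval series converted to beats
#' per minute. The whole series is used, not just the Stable Segment, so the
#' statistic is defined even for recordings without one.
#'
#' @param lambda Tempo location in seconds (> 0).
#' @return Beats per minute.
#' @examples
#' estimated_tempo(1.0001)  # 59.994 bpm
#' @export
estimated_tempo <- function(lambda) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  60 / lambda
}

#' Estimated Tempo Mismatch (statistic E)
#'
#' Signed percentage error of the internally estimated tempo relative to an
#' external point estimate: positive when the internal estimate exceeds the
#' external one.
#'
#' @param tempo_beats Internal tempo estimate in bpm.
#' @param tempo_ext External tempo estimate in bpm (> 0).
#' @return Signed percent.
#' @export
estimated_tempo_mismatch <- function(tempo_beats, tempo_ext) {
  if (!is.finite(tempo_ext) || tempo_ext <= 0) {
    stop("external tempo must be > 0", call. = FALSE)
  }
  100 * (tempo_beats - tempo_ext) / tempo_ext
}

#' Estimated Meter (statistic F)
#'
#' A real-valued operationalization of meter. For consecutive bar timestamps
#' `r_i < r_{i+1}` lying inside the Stable Segment, `n_i` counts the beat
#' timestamps `b` with `r_i <= b < r_{i+1}` (half-open bar windows).
#' Estimated Meter is the mean of the `n_i`; only when all `n_i` agree is the
#' meter a true integer, which the companion flag records — fractional values
#' expose recordings whose meter is unstable within the segment.
#'
#' @param beats Beat [onset_series()].
#' @param bars Bar [onset_series()].
#' @param segment A `stable_segment`.
#' @return List with `meter` (mean beats per bar, `NA` when fewer than two
#'   bar timestamps fall inside the segment) and `is_integer` (logical flag,
#'   `NA` when meter is `NA`).
#' @export
estimated_meter <- function(beats, bars, segment) {
  stopifnot(inherits(segment, "stable_segment"))
  r <- bars$timestamps
  r <- r[r >= segment$start_time & r <= segment$end_time]
  if (length(r) < 2) return(list(meter = NA_real_, is_integer = NA))
  b <- beats$timestamps
  n_i <- vapply(seq_len(length(r) - 1), function(i) {
    sum(b >= r[i] & b < r[i + 1])
  }, numeric(1))
  list(meter = mean(n_i), is_integer = length(unique(n_i)) == 1L)
}

segment_interval_idx <- function(segment) {
  unlist(lapply(seq_len(nrow(segment$runs)), function(k) {
    segment$runs$first[k]:segment$runs$last[k]
  }))
}

#' Maximum absolute PDL across Runs (statistic G)
#'
#' Largest `|PDL|` over intervals belonging to the segment's Runs; Gap
#' intervals are excluded. Bounded above by `theta_local` by construction of
#' the mask, though the observed maximum may be smaller.
#'
#' @param segment A `stable_segment`.
#' @param mask The [stability_mask()] the segment was derived from.
#' @return Percent, >= 0.
#' @export
pdl_max <- function(segment, mask) {
  stopifnot(inherits(segment, "stable_segment"), inherits(mask, "stability_mask"))
  max(abs(mask$pdl[segment_interval_idx(segment)]))
}

#' Maximum absolute SPC across Runs (statistic H)
#'
#' Largest `|SPC|` over successive interval pairs lying inside the same Run
#' of the segment. Pairs straddling a Run boundary are excluded; a
#' single-interval Run contributes nothing.
#'
#' @param segment A `stable_segment`.
#' @param mask The [stability_mask()] the segment was derived from.
#' @return Percent, >= 0 (0 when no Run holds two intervals).
#' @export
spc_max <- function(segment, mask) {
  stopifnot(inherits(segment, "stable_segment"), inherits(mask, "stability_mask"))
  vals <- unlist(lapply(seq_len(nrow(segment$runs)), function(k) {
    f <- segment$runs$first[k]; l <- segment$runs$last[k]
    if (l > f) abs(mask$spc[f:(l - 1)]) else numeric(0)
  }))
  if (!length(vals)) 0 else max(vals)
}

#' Windowed linear tempo-drift fits within a Run
#'
#' Lays 10-s windows over a Run, each advanced by half a window from the
#' previous (so consecutive windows overlap by half), and fits an ordinary
#' least-squares line of interval value against interval start time within
#' each window. The fitted line is evaluated at the window boundaries and the
#' percentage of tempo drift is `PTD = 100 * (y_end - y_start) / y_start`.
#' Windows are anchored at the Run start; a trailing remainder shorter than a
#' full window is fitted as one final truncated window. Windows holding fewer
#' than 3 intervals are skipped (a notice is emitted when
#' `options(beatstab.verbose = TRUE)`).
#'
#' @param run One row of a segment's `runs` data frame (list or data frame
#'   row with `first`, `last`, `start_time`, `end_time`).
#' @param intervals The full `interval_series`.
#' @param window Window length in seconds (default 10).
#' @param overlap_fraction Fraction of a window shared with its successor
#'   (default 0.5, i.e. windows advance by `window/2`).
#' @return Data frame with one row per fitted window: `window_start`,
#'   `window_end`, `slope`, `y_start`, `y_end`, `ptd`. Zero rows when no
#'   window holds enough intervals.
#' @export
ptd_windows <- function(run, intervals, window = 10, overlap_fraction = 0.5) {
  stopifnot(inherits(intervals, "interval_series"))
  step <- window * (1 - overlap_fraction)
  run_start <- run$start_time
  run_end <- run$end_time
  eps <- 1e-9
  starts <- seq(run_start, run_end, by = step)
  full <- starts[starts + window <= run_end + eps]
  wins <- lapply(full, function(s) c(s, s + window))
  if (!length(full)) {
    wins <- list(c(run_start, run_end))  # run shorter than one window
  } else {
    nxt <- full[length(full)] + step
    if (nxt < run_end - eps) wins <- c(wins, list(c(nxt, run_end)))
  }
  idx_all <- run$first:run$last
  x_all <- intervals$start_times[idx_all]
  y_all <- intervals$values[idx_all]
  rows <- lapply(wins, function(w) {
    inw <- x_all >= w[1] - eps & x_all < w[2] - eps
    if (sum(inw) < 3) {
      if (isTRUE(getOption("beatstab.verbose", FALSE))) {
        message(sprintf("skipping window [%.2f, %.2f): only %d interval(s)",
                        w[1], w[2], sum(inw)))
      }
      return(NULL)
    }
    x <- x_all[inw]; y <- y_all[inw]
    if (max(x) - min(x) < eps) return(NULL)
    slope <- stats::cov(x, y) / stats::var(x)
    intercept <- mean(y) - slope * mean(x)
    y0 <- intercept + slope * w[1]
    y1 <- intercept + slope * w[2]
    data.frame(window_start = w[1], window_end = w[2], slope = slope,
               y_start = y0, y_end = y1, ptd = 100 * (y1 - y0) / y0)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(window_start = numeric(0), window_end = numeric(0),
                      slope = numeric(0), y_start = numeric(0),
                      y_end = numeric(0), ptd = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Maximum absolute percentage of tempo drift (statistic I)
#'
#' Largest `|PTD|` over all fitted windows of all Runs of the segment
#' (see [ptd_windows()]); 0 when no window qualifies.
#'
#' @param segment A `stable_segment`.
#' @param intervals The full `interval_series`.
#' @param window,overlap_fraction Passed to [ptd_windows()].
#' @return Percent, >= 0.
#' @export
ptd_max <- function(segment, intervals, window = 10, overlap_fraction = 0.5) {
  stopifnot(inherits(segment, "stable_segment"))
  ptds <- unlist(lapply(seq_len(nrow(segment$runs)), function(k) {
    ptd_windows(segment$runs[k, ], intervals, window, overlap_fraction)$ptd
  }))
  if (!length(ptds)) 0 else max(abs(ptds))
}

#' Full stability analysis of one onset record
#'
#' Orchestrates the whole pipeline: interval differencing, tempo location by
#' adaptive KDE, PDL/SPC stability masking, Run/Gap decomposition, Stable
#' Segment selection, and the nine summary statistics. When no Run satisfies
#' the Run duration threshold the recording has no Stable Segment: only the
#' Estimated Tempo (and, given an external estimate, the mismatch) are
#' populated and every segment-dependent statistic is `NA`.
#'
#' @param beats Beat [onset_series()] (required, at least 3 onsets).
#' @param bars Bar [onset_series()] or `NULL`; needed only for Estimated
#'   Meter.
#' @param external [external_estimates()] or `NULL`; needed only for the
#'   tempo mismatch.
#' @param thresholds A [beats_thresholds()].
#' @param grid_points KDE grid size, passed through to [location_lambda()].
#' @return An object of class `beats_summary`: the nine statistics plus
#'   `lambda`, the thresholds used, segment start/stop timestamps, the
#'   segment/mask/intervals objects (for inspection and plotting), and the
#'   record `id`.
#' @examples
#' sim <- generate_onsets(list(section_spec(120, 0.5)), beats_per_bar = 4, seed = 1)
#' s <- summarize_onsets(sim$beats, sim$bars)
#' s$estimated_tempo  # ~120 bpm
#' @export
summarize_onsets <- function(beats, bars = NULL, external = NULL,
                             thresholds = beats_thresholds(),
                             grid_points = 2^14) {
  stopifnot(inherits(beats, "onset_series"), inherits(thresholds, "beats_thresholds"))
  intervals <- intervals_from_onsets(beats)
  loc <- location_lambda(intervals, grid_points = grid_points)
  lambda <- loc$lambda
  pdl <- pdl_series(intervals, lambda)
  spc <- spc_series(intervals)
  mask <- stability_mask(pdl, spc, thresholds$theta_local)
  rg <- find_runs_gaps(mask, intervals)
  segment <- select_stable_segment(rg$runs, rg$gaps, thresholds)

  tempo <- estimated_tempo(lambda)
  etm <- if (!is.null(external) && !is.null(external$tempo)) {
    estimated_tempo_mismatch(tempo, external$tempo)
  } else NA_real_

  if (is.null(segment)) {
    out <- list(stable_duration = NA_real_, stable_percentage = NA_real_,
                run_percentage = NA_real_, estimated_tempo = tempo,
                etm = etm, estimated_meter = NA_real_, meter_is_integer = NA,
                pdl_max = NA_real_, spc_max = NA_real_, ptd_max = NA_real_,
                segment_start = NA_real_, segment_end = NA_real_)
  } else {
    met <- if (!is.null(bars) && length(bars$timestamps) >= 2) {
      estimated_meter(beats, bars, segment)
    } else list(meter = NA_real_, is_integer = NA)
    out <- list(stable_duration = stable_duration(segment),
                stable_percentage = stable_percentage(segment, beats),
                run_percentage = run_percentage(segment),
                estimated_tempo = tempo, etm = etm,
                estimated_meter = met$meter, meter_is_integer = met$is_integer,
                pdl_max = pdl_max(segment, mask),
                spc_max = spc_max(segment, mask),
                ptd_max = ptd_max(segment, intervals),
                segment_start = segment$start_time,
                segment_end = segment$end_time)
  }
  out$lambda <- lambda
  out$thresholds <- thresholds
  out$id <- beats$source_id
  out$segment <- segment
  out$mask <- mask
  out$intervals <- intervals
  structure(out, class = "beats_summary")
}

#' @export
print.beats_summary <- function(x, ...) {
  cat(sprintf("<beats_summary>%s\n",
              if (nzchar(x$id)) paste0(" ", x$id) else ""))
  cat(sprintf("  estimated tempo   %.3f bpm (lambda = %.6f s)\n",
              x$estimated_tempo, x$lambda))
  if (is.na(x$stable_duration)) {
    cat("  no Stable Segment under the given thresholds\n")
  } else {
    cat(sprintf("  stable segment    [%.3f, %.3f] s (duration %.2f s, %.1f%% of file)\n",
                x$segment_start, x$segment_end, x$stable_duration,
                x$stable_percentage))
    cat(sprintf("  run percentage    %.1f%%\n", x$run_percentage))
    if (!is.na(x$estimated_meter)) {
      cat(sprintf("  estimated meter   %.3g beats/bar%s\n", x$estimated_meter,
                  if (isTRUE(x$meter_is_integer)) " (integer)" else ""))
    }
    cat(sprintf("  PDL_max %.3f%%  SPC_max %.3f%%  PTD_max %.3f%%\n",
                x$pdl_max, x$spc_max, x$ptd_max))
  }
  if (!is.na(x$etm)) cat(sprintf("  tempo mismatch    %+.3f%%\n", x$etm))
  invisible(x)
}

#' @export
as.data.frame.beats_summary <- function(x, ...) {
  data.frame(
    id = x$id,
    stable_duration_s = x$stable_duration,
    stable_percentage = x$stable_percentage,
    run_percentage = x$run_percentage,
    estimated_tempo_bpm = x$estimated_tempo,
    etm_percent = x$etm,
    estimated_meter = x$estimated_meter,
    meter_is_integer = x$meter_is_integer,
    pdl_max = x$pdl_max,
    spc_max = x$spc_max,
    ptd_max = x$ptd_max,
    segment_start_s = x$segment_start,
    segment_end_s = x$segment_end,
    theta_local = x$thresholds$theta_local,
    theta_run = x$thresholds$theta_run,
    theta_gap = x$thresholds$theta_gap,
    stringsAsFactors = FALSE)
}
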