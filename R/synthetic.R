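# Synthetic onset-series generator. Every stage of the pipeline is testable
# without external data: multi-tempo sections with Gaussian jitter, linear
# tempo drifts, matched-moment permutations, and injected gap perturbations
# all have known ground truth.

#' Specification of one tempo section
#'
#' A section is a block of `n_intervals` inter-beat intervals around
#' `mean_interval` seconds. Gaussian jitter (sd `jitter_sd`) is added to each
#' interval value; `drift_total` imposes a linear ramp so the underlying
#' interval moves from `mean_interval` to `mean_interval * (1 +
#' drift_total/100)` across the section. The jitter default of 0.5% of the
#' section mean is well below the default 5% local stability threshold, so
#' masks are governed by section structure rather than noise.
#'
#' @param n_intervals Number of intervals (>= 1).
#' @param mean_interval Section mean interval in seconds (> 0).
#' @param jitter_sd Jitter standard deviation in seconds (>= 0); default
#'   0.5% of `mean_interval`.
#' @param drift_total Signed percent change of the underlying interval across
#'   the section (default 0).
#' @return An object of class `section_spec`.
#' @export
section_spec <- function(n_intervals, mean_interval,
                         jitter_sd = 0.005 * mean_interval, drift_total = 0) {
  if (n_intervals < 1) stop("n_intervals must be >= 1", call. = FALSE)
  if (mean_interval <= 0) stop("mean_interval must be > 0", call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  structure(list(n_intervals = as.integer(n_intervals),
                 mean_interval = mean_interval,
                 jitter_sd = jitter_sd, drift_total = drift_total),
            class = "section_spec")
}

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic beat (and bar) onset series
#'
#' Draws interval values section by section — `mean * (1 + drift ramp) +
#' N(0, jitter_sd)` — and accumulates them from time 0 into beat onsets.
#' When `beats_per_bar` is given, a bar onset is placed at every
#' `beats_per_bar`-th beat starting from the first. Deterministic for a
#' fixed seed.
#'
#' @param sections List of [section_spec()] objects (a single one is
#'   accepted bare).
#' @param beats_per_bar Integer beats per bar for the generated bar series,
#'   or `NULL` for no bars.
#' @param seed Integer RNG seed.
#' @return List with `beats` and `bars` ([onset_series()]; `bars` is empty
#'   when `beats_per_bar` is `NULL`).
#' @examples
#' # three tempo sections: 120 bpm, 80 bpm, 60 bpm
#' sim <- generate_onsets(list(
#'   section_spec(20, 0.50), section_spec(20, 0.75), section_spec(40, 1.00)),
#'   seed = 1)
#' length(sim$beats$timestamps)  # 81 onsets -> 80 intervals
#' @export
generate_onsets <- function(sections, beats_per_bar = NULL, seed = 1) {
  if (inherits(sections, "section_spec")) sections <- list(sections)
  stopifnot(all(vapply(sections, inherits, logical(1), "section_spec")))
  values <- with_seed(seed, {
    unlist(lapply(sections, function(s) {
      ramp <- if (s$n_intervals > 1) {
        (seq_len(s$n_intervals) - 1) / (s$n_intervals - 1)
      } else 0
      base <- s$mean_interval * (1 + s$drift_total / 100 * ramp)
      base + stats::rnorm(s$n_intervals, 0, s$jitter_sd)
    }))
  })
  if (any(values <= 0)) {
    stop("section parameters produced non-positive intervals", call. = FALSE)
  }
  onsets <- c(0, cumsum(values))
  beats <- onset_series(onsets, kind = "beat", source_id = "synthetic")
  bars <- if (!is.null(beats_per_bar)) {
    bpb <- as.integer(beats_per_bar)
    if (bpb < 1) stop("beats_per_bar must be >= 1", call. = FALSE)
    onset_series(onsets[seq(1, length(onsets), by = bpb)], kind = "bar",
                 source_id = "synthetic")
  } else {
    onset_series(numeric(0), kind = "bar")
  }
  list(beats = beats, bars = bars)
}

#' Randomly permute an interval series
#'
#' Reorders the interval values (same multiset, so the mean, standard
#' deviation, and every other order-free statistic are preserved exactly)
#' and recomputes the start times by cumulative summation from the original
#' first start time. Smooth and shuffled orderings of the same multiset
#' separate the order-sensitive stability statistics (SPC_max, PTD_max) from
#' the order-free ones (PDL_max).
#'
#' @param intervals An `interval_series`.
#' @param seed Integer RNG seed.
#' @return A new `interval_series` with permuted values.
#' @export
permute_intervals <- function(intervals, seed = 1) {
  stopifnot(inherits(intervals, "interval_series"))
  v <- intervals$values
  if (length(v) < 2) stop("need at least 2 intervals to permute", call. = FALSE)
  perm <- with_seed(seed, sample(length(v)))
  v <- v[perm]
  t0 <- intervals$start_times[1]
  interval_series(v, t0 + c(0, cumsum(v[-length(v)])), kind = intervals$kind)
}

#' Inject an unstable gap into an interval series
#'
#' Scales `gap_intervals` consecutive interval values, starting at the first
#' interval opening at or after `at_time`, by `1 + deviation/100`. With a
#' deviation beyond the local stability threshold this guarantees those
#' intervals are flagged unstable, carving a Gap of known position and
#' duration (emulating, e.g., a beat tracker tripping over an unexpected
#' syncopation). Start times are recomputed so downstream timing stays
#' consistent.
#'
#' @param intervals An `interval_series`.
#' @param at_time Time (seconds) at or after which the gap starts.
#' @param gap_intervals Number of consecutive intervals to perturb.
#' @param deviation Signed percent scaling of the perturbed intervals.
#' @return A new `interval_series`.
#' @export
inject_gap <- function(intervals, at_time, gap_intervals, deviation) {
  stopifnot(inherits(intervals, "interval_series"))
  idx0 <- which(intervals$start_times >= at_time)[1]
  if (is.na(idx0)) {
    stop(sprintf("at_time = %g s lies beyond the interval series", at_time),
         call. = FALSE)
  }
  idx <- idx0:(idx0 + gap_intervals - 1)
  if (max(idx) > length(intervals$values)) {
    stop("gap extends beyond the interval series", call. = FALSE)
  }
  v <- intervals$values
  v[idx] <- v[idx] * (1 + deviation / 100)
  if (any(v <= 0)) stop("deviation produced non-positive intervals", call. = FALSE)
  t0 <- intervals$start_times[1]
  interval_series(v, t0 + c(0, cumsum(v[-length(v)])), kind = intervals$kind)
}

#' Rebuild an onset series from an interval series
#'
#' Cumulative summation from the opening timestamp: the inverse of
#' [intervals_from_onsets()].
#'
#' @param intervals An `interval_series`.
#' @param source_id Identifier for the rebuilt series.
#' @return An [onset_series()] with `length(intervals) + 1` timestamps.
#' @export
onsets_from_intervals <- function(intervals, source_id = "") {
  stopifnot(inherits(intervals, "interval_series"))
  t0 <- intervals$start_times[1]
  onset_series(c(t0, t0 + cumsum(intervals$values)), kind = intervals$kind,
               source_id = source_id)
}
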