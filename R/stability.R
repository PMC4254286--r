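# Stability segmentation: percentage transforms, the 0/1 stability mask,
# Run/Gap decomposition, and Stable Segment selection.

#' Initialization thresholds for stability segmentation
#'
#' Three user-set thresholds govern what counts as temporally stable:
#' `theta_local` (percent, default 5.0) bounds both the deviation of an
#' interval from the tempo location lambda and the change between successive
#' intervals; `theta_run` (seconds, default 10) is the minimum duration a Run
#' of stable intervals must reach to qualify for the Stable Segment;
#' `theta_gap` (seconds, default 2.5) is the maximum duration of an unstable
#' Gap that may be bridged between qualifying Runs. The defaults are
#' illustrative rather than prescriptive and every entry point accepts
#' overrides.
#'
#' @param theta_local Local stability threshold in percent (> 0).
#' @param theta_run Minimum Run duration in seconds (> 0).
#' @param theta_gap Maximum bridgeable Gap duration in seconds (> 0).
#' @return An object of class `beats_thresholds`.
#' @export
beats_thresholds <- function(theta_local = 5.0, theta_run = 10, theta_gap = 2.5) {
  vals <- c(theta_local = theta_local, theta_run = theta_run, theta_gap = theta_gap)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all thresholds must be positive and finite", call. = FALSE)
  }
  structure(list(theta_local = theta_local, theta_run = theta_run,
                 theta_gap = theta_gap), class = "beats_thresholds")
}

#' @export
print.beats_thresholds <- function(x, ...) {
  cat(sprintf("<beats_thresholds> theta_local = %g%%, theta_run = %g s, theta_gap = %g s\n",
              x$theta_local, x$theta_run, x$theta_gap))
  invisible(x)
}

#' Percentage deviation from lambda (PDL)
#'
#' `PDL_i = 100 * (S_i - lambda) / lambda` for each interval `S_i`: the
#' signed relative deviation of an interval from the tempo location. Being a
#' percentage, it is comparable across recordings in different tempo ranges.
#'
#' @param intervals An `interval_series` or numeric vector of intervals.
#' @param lambda Tempo location in seconds (> 0).
#' @return Signed numeric vector, one value per interval.
#' @export
pdl_series <- function(intervals, lambda) {
  values <- if (inherits(intervals, "interval_series")) intervals$values else as.numeric(intervals)
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  100 * (values - lambda) / lambda
}

#' Successive percentage change (SPC)
#'
#' `SPC_i = 100 * (S_{i+1} - S_i) / S_i`: the signed relative change from
#' each interval to the next, quantifying beat-to-beat stability
#' independently of the deviation from lambda.
#'
#' @param intervals An `interval_series` or numeric vector of intervals
#'   (all > 0).
#' @return Signed numeric vector of length `n - 1`.
#' @export
spc_series <- function(intervals) {
  values <- if (inherits(intervals, "interval_series")) intervals$values else as.numeric(intervals)
  if (any(values <= 0)) stop("interval values must be positive", call. = FALSE)
  n <- length(values)
  if (n < 2) return(numeric(0))
  100 * diff(values) / values[-n]
}

#' Per-interval stability flags from the PDL and SPC transforms
#'
#' Stability is determined in two passes. First, interval `i` is provisionally
#' flagged stable (1) iff `|PDL_i| <= theta_local`. Second, scanning the pairs
#' `{i, i+1}` in ascending order, wherever the *current* flags are `{1, 1}`
#' the flag of `i+1` is revised to 0 iff `|SPC_i| > theta_local`. The scan
#' uses the partially revised flags, so one large successive change
#' terminates a run at that point rather than punching a one-element hole:
#' within any resulting run of 1s, every `|PDL| <= theta_local` and every
#' internal `|SPC| <= theta_local`. Pairs whose current flags are not
#' `{1, 1}` are never revised.
#'
#' @param pdl Signed PDL vector (length n).
#' @param spc Signed SPC vector (length n - 1).
#' @param theta_local Local stability threshold in percent.
#' @return An object of class `stability_mask`: list with `pdl`, `spc`,
#'   `flags` (integer 0/1, length n), and `theta_local`.
#' @export
stability_mask <- function(pdl, spc, theta_local = 5.0) {
  n <- length(pdl)
  if (length(spc) != max(n - 1, 0)) {
    stop("spc must have length(pdl) - 1 elements", call. = FALSE)
  }
  flags <- as.integer(abs(pdl) <= theta_local)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      if (flags[i] == 1L && flags[i + 1] == 1L && abs(spc[i]) > theta_local) {
        flags[i + 1] <- 0L
      }
    }
  }
  structure(list(pdl = pdl, spc = spc, flags = flags,
                 theta_local = theta_local), class = "stability_mask")
}

#' Decompose a stability mask into Runs and Gaps
#'
#' A Run is a maximal string of stable (1) intervals; a Gap is a maximal
#' string of unstable (0) intervals. Durations are the sum of the member
#' interval values, equivalently the beat-timestamp span of the member
#' intervals, so Run and Gap durations tile the series exactly.
#'
#' @param mask A [stability_mask()].
#' @param intervals The `interval_series` the mask was computed from.
#' @return List with `runs` and `gaps`, each a data frame with columns
#'   `first`, `last` (interval indices), `start_time`, `end_time`, and
#'   `duration` (seconds). Either may have zero rows.
#' @export
find_runs_gaps <- function(mask, intervals) {
  stopifnot(inherits(mask, "stability_mask"), inherits(intervals, "interval_series"))
  flags <- mask$flags
  if (length(flags) != length(intervals$values)) {
    stop("mask and interval series lengths differ", call. = FALSE)
  }
  spans_of <- function(value) {
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    firsts <- ends - r$lengths + 1L
    keep <- r$values == value
    data.frame(first = firsts[keep], last = ends[keep])
  }
  annotate <- function(df) {
    if (!nrow(df)) {
      return(data.frame(first = integer(0), last = integer(0),
                        start_time = numeric(0), end_time = numeric(0),
                        duration = numeric(0)))
    }
    df$start_time <- intervals$start_times[df$first]
    df$end_time <- intervals$start_times[df$last] + intervals$values[df$last]
    df$duration <- vapply(seq_len(nrow(df)), function(k) {
      sum(intervals$values[df$first[k]:df$last[k]])
    }, numeric(1))
    df
  }
  list(runs = annotate(spans_of(1L)), gaps = annotate(spans_of(0L)))
}

#' Select the Stable Segment
#'
#' The Stable Segment is the longest consecutive chain of qualifying Runs
#' bridged across Gaps: a Run qualifies when its duration is at least
#' `theta_run`, and two consecutive qualifying Runs may be chained when the
#' full time between the end of the first and the start of the next —
#' including any sub-threshold runs inside that span, which are not segment
#' members but whose time must be conserved — is at most `theta_gap`. Among
#' all chains the one maximizing the spanned duration (`end - start`) is
#' returned; ties break toward the earliest start. When no Run qualifies the
#' recording has no Stable Segment and `NULL` is returned.
#'
#' @param runs,gaps Data frames from [find_runs_gaps()].
#' @param thresholds A [beats_thresholds()].
#' @return An object of class `stable_segment` (list with `runs`, `gaps`,
#'   `start_time`, `end_time`), or `NULL`.
#' @export
select_stable_segment <- function(runs, gaps, thresholds = beats_thresholds()) {
  stopifnot(inherits(thresholds, "beats_thresholds"))
  q <- runs[runs$duration >= thresholds$theta_run, , drop = FALSE]
  if (!nrow(q)) return(NULL)
  q <- q[order(q$start_time), , drop = FALSE]
  m <- nrow(q)
  bridge <- if (m >= 2) q$start_time[-1] - q$end_time[-m] else numeric(0)
  group <- cumsum(c(0, as.integer(bridge > thresholds$theta_gap)))
  best <- NULL
  best_span <- -Inf
  for (g in unique(group)) {
    rows <- which(group == g)
    span <- q$end_time[rows[length(rows)]] - q$start_time[rows[1]]
    if (span > best_span + 1e-12) {
      best_span <- span
      best <- rows
    }
  }
  seg_runs <- q[best, , drop = FALSE]
  rownames(seg_runs) <- NULL
  k <- nrow(seg_runs)
  seg_gaps <- if (k >= 2) {
    data.frame(start_time = seg_runs$end_time[-k],
               end_time = seg_runs$start_time[-1],
               duration = seg_runs$start_time[-1] - seg_runs$end_time[-k])
  } else {
    data.frame(start_time = numeric(0), end_time = numeric(0),
               duration = numeric(0))
  }
  structure(list(runs = seg_runs, gaps = seg_gaps,
                 start_time = seg_runs$start_time[1],
                 end_time = seg_runs$end_time[k]),
            class = "stable_segment")
}

#' @export
print.stable_segment <- function(x, ...) {
  cat(sprintf("<stable_segment> [%.3f, %.3f] s: %d run(s), %d bridged gap(s), span %.3f s\n",
              x$start_time, x$end_time, nrow(x$runs), nrow(x$gaps),
              x$end_time - x$start_time))
  invisible(x)
}
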