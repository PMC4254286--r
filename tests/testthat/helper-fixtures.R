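# Fixture builders and independent oracles shared across the test files.

# Interval series with constant value, built from first principles.
iso_intervals <- function(n, value = 0.5, t0 = 0) {
  interval_series(rep(value, n), t0 + (0:(n - 1)) * value)
}

# Beat onsets for a run/gap/run layout: isochronous runs at `beat` seconds
# separated by `gap_n` intervals scaled to `gap_value` seconds each.
run_gap_run_onsets <- function(run_n = 60, beat = 0.5, gap_n = 2, gap_value = 1.0) {
  values <- c(rep(beat, run_n), rep(gap_value, gap_n), rep(beat, run_n))
  onset_series(c(0, cumsum(values)), kind = "beat", source_id = "rgr")
}

# The three-tempo-section demonstration series: 20 intervals of mean 0.5 s
# (120 bpm), 20 of 0.75 s (80 bpm), 40 of 1.00 s (60 bpm), Gaussian jitter
# with sd 0.5% of each section mean.
three_section_sim <- function(seed = 1, beats_per_bar = NULL) {
  generate_onsets(list(section_spec(20, 0.50), section_spec(20, 0.75),
                       section_spec(40, 1.00)),
                  beats_per_bar = beats_per_bar, seed = seed)
}

# Interval series whose values follow a given function of time, sampled at
# the self-generated onset times (each interval's value is f(start_time)).
intervals_from_profile <- function(f, t_end, t0 = 0) {
  t <- t0
  values <- numeric(0)
  starts <- numeric(0)
  while (t < t_end) {
    v <- f(t)
    stopifnot(v > 0)
    values <- c(values, v)
    starts <- c(starts, t)
    t <- t + v
  }
  interval_series(values, starts)
}

# Independent brute-force oracle for Stable Segment selection: enumerate
# every contiguous range of qualifying runs, check all bridged gaps, and
# maximize the spanned duration (ties -> earliest start).
oracle_stable_segment_span <- function(runs, thresholds) {
  q <- runs[runs$duration >= thresholds$theta_run, , drop = FALSE]
  if (!nrow(q)) return(NULL)
  q <- q[order(q$start_time), , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(q))) {
    for (j in i:nrow(q)) {
      ok <- TRUE
      if (j > i) {
        for (k in i:(j - 1)) {
          if (q$start_time[k + 1] - q$end_time[k] > thresholds$theta_gap) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) next
      span <- q$end_time[j] - q$start_time[i]
      if (is.null(best) || span > best$span + 1e-12) {
        best <- list(span = span, start = q$start_time[i], end = q$end_time[j])
      }
    }
  }
  best
}

# Random interval series with a random stability structure: blocks of
# near-lambda intervals interleaved with strongly deviating blocks.
random_blocky_intervals <- function(seed, lambda = 0.5, max_blocks = 12) {
  set.seed(seed)
  n_blocks <- sample(2:max_blocks, 1)
  values <- unlist(lapply(seq_len(n_blocks), function(b) {
    len <- sample(1:40, 1)
    if (runif(1) < 0.5) {
      lambda * (1 + runif(len, -0.04, 0.04))   # stable block
    } else {
      lambda * (1 + runif(len, 0.2, 0.8))      # unstable block
    }
  }))
  interval_series(values, c(0, cumsum(values[-length(values)])))
}
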