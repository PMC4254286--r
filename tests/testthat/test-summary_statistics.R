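# Shared fixture: two 30 s isochronous runs at 0.5 s bridged by a 2 s gap.
analyzed_run_gap_run <- function(gap_n = 2, gap_value = 1.0) {
  b <- run_gap_run_onsets(run_n = 60, beat = 0.5, gap_n = gap_n,
                          gap_value = gap_value)
  iv <- intervals_from_onsets(b)
  mask <- stability_mask(pdl_series(iv, 0.5), spc_series(iv), 5)
  rg <- find_runs_gaps(mask, iv)
  seg <- select_stable_segment(rg$runs, rg$gaps, beats_thresholds())
  list(beats = b, intervals = iv, mask = mask, segment = seg)
}

test_that("stable duration and percentages match the worked arithmetic", {
  fx <- analyzed_run_gap_run()
  expect_equal(stable_duration(fx$segment), 62.0)
  expect_equal(round(run_percentage(fx$segment), 1), 96.8)

  # segment spanning the whole file gives 100%
  span <- max(fx$beats$timestamps) - min(fx$beats$timestamps)
  expect_equal(stable_percentage(fx$segment, fx$beats), 100 * 62 / span)

  # 10 s + 10 s runs with a 2.5 s gap: 2000 / 22.5
  b <- run_gap_run_onsets(run_n = 20, beat = 0.5, gap_n = 5, gap_value = 0.5)
  iv <- intervals_from_onsets(b)
  flags <- c(rep(1L, 20), rep(0L, 5), rep(1L, 20))
  mask <- stability_mask(ifelse(flags == 1L, 0, 50), rep(0, 44), 5)
  rg <- find_runs_gaps(mask, iv)
  seg <- select_stable_segment(rg$runs, rg$gaps, beats_thresholds())
  expect_equal(run_percentage(seg), 2000 / 22.5)
  expect_equal(round(run_percentage(seg), 1), 88.9)

  # no gaps -> run percentage exactly 100
  iso <- intervals_from_onsets(onset_series(seq(0, 30, by = 0.5)))
  m <- stability_mask(rep(0, 60), rep(0, 59), 5)
  rg <- find_runs_gaps(m, iso)
  seg <- select_stable_segment(rg$runs, rg$gaps, beats_thresholds())
  expect_equal(run_percentage(seg), 100)
  expect_equal(nrow(seg$gaps), 0)
})

test_that("tempo conversion and mismatch follow their formulas", {
  expect_equal(round(estimated_tempo(1.0001), 3), 59.994)
  expect_equal(estimated_tempo(0.5), 120)
  expect_equal(estimated_tempo(1.0), 60)
  expect_error(estimated_tempo(0), "lambda")

  expect_equal(estimated_tempo_mismatch(120, 120), 0)
  expect_equal(estimated_tempo_mismatch(61.2, 60), 2.0)
  expect_equal(estimated_tempo_mismatch(58.8, 60), -2.0)
  expect_error(estimated_tempo_mismatch(60, 0), "external tempo")
})

test_that("estimated meter counts beats in half-open bar windows", {
  fx <- analyzed_run_gap_run()

  # bars every 4 beats -> exactly 4.0, integer
  bars <- onset_series(fx$beats$timestamps[seq(1, 121, by = 4)], kind = "bar")
  met <- estimated_meter(fx$beats, bars, fx$segment)
  expect_equal(met$meter, 4.0)
  expect_true(met$is_integer)

  # alternating 3- and 4-beat bars in equal counts -> 3.5, not integer
  beats <- onset_series(seq(0, by = 0.5, length.out = 141))
  idx <- cumsum(c(1, rep(c(3, 4), 20)))
  bars <- onset_series(beats$timestamps[idx], kind = "bar")
  iv <- intervals_from_onsets(beats)
  m <- stability_mask(rep(0, 140), rep(0, 139), 5)
  rg <- find_runs_gaps(m, iv)
  seg <- select_stable_segment(rg$runs, rg$gaps, beats_thresholds())
  met <- estimated_meter(beats, bars, seg)
  expect_equal(met$meter, 3.5)
  expect_false(met$is_integer)

  # n_i = {4, 4, 4, 5} -> 4.25, not integer
  idx <- cumsum(c(1, 4, 4, 4, 5))
  bars <- onset_series(beats$timestamps[idx], kind = "bar")
  met <- estimated_meter(beats, bars, seg)
  expect_equal(met$meter, 4.25)
  expect_false(met$is_integer)

  # fewer than two in-segment bars: statistic absent
  far <- onset_series(c(1000, 1004), kind = "bar")
  expect_true(is.na(estimated_meter(fx$beats, far, fx$segment)$meter))
})

test_that("PDL and SPC maxima cover run intervals only and respect the bound", {
  fx <- analyzed_run_gap_run()
  # gap intervals (PDL = +100%) are excluded: all run intervals equal lambda
  expect_equal(pdl_max(fx$segment, fx$mask), 0)
  expect_equal(spc_max(fx$segment, fx$mask), 0)

  # perturb one in-run interval by +2%: both maxima see it
  iv <- fx$intervals
  iv$values[30] <- 0.51
  mask <- stability_mask(pdl_series(iv, 0.5), spc_series(iv), 5)
  rg <- find_runs_gaps(mask, iv)
  seg <- select_stable_segment(rg$runs, rg$gaps, beats_thresholds())
  expect_equal(pdl_max(seg, mask), 2.0)
  expect_equal(spc_max(seg, mask), 2.0)
  expect_lte(pdl_max(seg, mask), 5)
  expect_lte(spc_max(seg, mask), 5)

  # run intervals {0.50, 0.51, 0.50}: SPC_max = 2
  iv3 <- interval_series(c(0.50, 0.51, 0.50), c(0, 0.5, 1.01))
  m3 <- stability_mask(pdl_series(iv3, 0.5), spc_series(iv3), 5)
  rg3 <- find_runs_gaps(m3, iv3)
  seg3 <- structure(list(runs = rg3$runs, gaps = rg3$gaps,
                         start_time = 0, end_time = 1.51),
                    class = "stable_segment")
  expect_equal(spc_max(seg3, m3), 2.0)
})

test_that("windowed drift fits reproduce the printed regression endpoints", {
  # interval value falls linearly from 0.5064 at t = 10 to 0.4897 at t = 20,
  # after a rising 0-10 s stretch from 0.4997 to 0.5029
  profile <- function(t) {
    if (t < 10) 0.4997 + (0.5029 - 0.4997) / 10 * t
    else 0.5064 + (0.4897 - 0.5064) / 10 * (t - 10)
  }
  iv <- intervals_from_profile(profile, t_end = 20.2)
  run <- data.frame(first = 1, last = length(iv$values),
                    start_time = 0,
                    end_time = iv$start_times[length(iv$values)] +
                      iv$values[length(iv$values)])
  wf <- ptd_windows(run, iv)
  w10 <- wf[abs(wf$window_start - 10) < 1e-9, ]
  expect_equal(w10$y_start, 0.5064, tolerance = 1e-6)
  expect_equal(w10$y_end, 0.4897, tolerance = 1e-6)
  expect_equal(round(w10$ptd, 2), -3.30)

  # constant intervals: zero slope, zero drift
  iso <- iso_intervals(40, 0.5)
  run_iso <- data.frame(first = 1, last = 40, start_time = 0, end_time = 20)
  wf_iso <- ptd_windows(run_iso, iso)
  expect_true(all(abs(wf_iso$slope) < 1e-12))
  expect_true(all(abs(wf_iso$ptd) < 1e-10))

  # noiseless linear ramp 0.50 -> 0.52 across one 10 s window: PTD = 4%
  ramp <- intervals_from_profile(function(t) 0.50 + 0.002 * t, t_end = 10)
  run_r <- data.frame(first = 1, last = length(ramp$values),
                      start_time = 0, end_time = 10)
  wf_r <- ptd_windows(run_r, ramp)
  expect_equal(wf_r$ptd[1], 100 * (0.52 - 0.50) / 0.50, tolerance = 1e-6)
})

test_that("ptd_max aggregates over all windows and runs", {
  profile <- function(t) {
    if (t < 10) 0.4997 + (0.5029 - 0.4997) / 10 * t
    else 0.5064 + (0.4897 - 0.5064) / 10 * (t - 10)
  }
  iv <- intervals_from_profile(profile, t_end = 20.2)
  mask <- stability_mask(pdl_series(iv, 0.5), spc_series(iv), 5)
  rg <- find_runs_gaps(mask, iv)
  seg <- select_stable_segment(rg$runs, rg$gaps, beats_thresholds())
  expect_equal(round(ptd_max(seg, iv), 2), 3.30)

  # all-constant segment: drift is exactly zero
  fx <- analyzed_run_gap_run()
  expect_lt(ptd_max(fx$segment, fx$intervals), 1e-10)

  # monotone accelerando of 4% per 10 s stays below the 5% local threshold
  acc <- intervals_from_profile(function(t) 0.5 * (1 + 0.004 * t), t_end = 60)
  m <- stability_mask(rep(0, length(acc$values)),
                      rep(0, length(acc$values) - 1), 5)
  rg <- find_runs_gaps(m, acc)
  seg <- select_stable_segment(rg$runs, rg$gaps, beats_thresholds())
  pm <- ptd_max(seg, acc)
  expect_gt(pm, 3.5)
  expect_lt(pm, 5)
})

test_that("full-pipeline summaries behave across the three scenario classes", {
  # near-perfect isochrony: stability from first beat to last, tiny maxima
  sim <- generate_onsets(list(section_spec(240, 0.5, jitter_sd = 0.0002)),
                         beats_per_bar = 4, seed = 21)
  s <- summarize_onsets(sim$beats, sim$bars, external_estimates(tempo = 120))
  expect_equal(s$stable_percentage, 100)
  expect_lt(s$pdl_max, 0.5)
  expect_lt(s$spc_max, 0.5)
  expect_lt(s$ptd_max, 0.5)
  expect_lt(abs(s$etm), 1)
  expect_equal(s$estimated_meter, 4.0)

  # a > theta_gap unstable middle splits the file: longer side wins
  iv <- intervals_from_onsets(
    generate_onsets(list(section_spec(200, 0.5, jitter_sd = 0.0005)),
                    seed = 5)$beats)
  iv2 <- inject_gap(iv, at_time = 60, gap_intervals = 8, deviation = 50)
  s2 <- summarize_onsets(onsets_from_intervals(iv2, "gapped"))
  expect_equal(s2$segment_start, 0)
  expect_lt(abs(s2$stable_duration - 60), 1)
  expect_equal(s2$run_percentage, 100)

  # all runs shorter than theta_run: no stable segment, tempo still reported
  short <- generate_onsets(list(section_spec(10, 0.5)), seed = 2)
  s3 <- summarize_onsets(short$beats, external = external_estimates(tempo = 120))
  expect_true(is.na(s3$stable_duration))
  expect_true(is.na(s3$pdl_max))
  expect_false(is.na(s3$estimated_tempo))
  expect_false(is.na(s3$etm))
})

test_that("permutations preserve order-free statistics but not order-sensitive ones", {
  # smooth sinusoidal tempo wobble, +/-2% around 0.5 s
  n <- 120
  v <- 0.5 * (1 + 0.02 * sin(2 * pi * (1:n) / n))
  smooth <- interval_series(v, c(0, cumsum(v[-n])))
  shuffled <- permute_intervals(smooth, seed = 8)

  expect_equal(sort(shuffled$values), sort(smooth$values))
  expect_identical(mean(shuffled$values), mean(smooth$values))

  stats_of <- function(iv) {
    lam <- location_lambda(iv)$lambda
    mask <- stability_mask(pdl_series(iv, lam), spc_series(iv), 5)
    rg <- find_runs_gaps(mask, iv)
    seg <- select_stable_segment(rg$runs, rg$gaps, beats_thresholds())
    list(pdl = pdl_max(seg, mask), spc = spc_max(seg, mask),
         ptd = ptd_max(seg, iv), whole = nrow(seg$runs) == 1 &&
           seg$runs$first == 1 && seg$runs$last == length(iv$values))
  }
  a <- stats_of(smooth)
  b <- stats_of(shuffled)
  # both orderings keep the whole series in one run, so PDL_max is identical
  expect_true(a$whole && b$whole)
  expect_equal(b$pdl, a$pdl, tolerance = 1e-12)
  # order-sensitive statistics separate the two orderings
  expect_gt(b$spc / a$spc, 1.5)
  expect_gt(abs(b$ptd - a$ptd) / a$ptd, 0.25)
})

test_that("a planted 120 bpm dominant tempo is recovered within 1%", {
  sim <- generate_onsets(list(section_spec(120, 0.5), section_spec(40, 0.75)),
                         seed = 31)
  s <- summarize_onsets(sim$beats, external = external_estimates(tempo = 120))
  expect_lt(abs(s$estimated_tempo - 120) / 120, 0.01)
  expect_lt(abs(s$etm), 1)
})
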