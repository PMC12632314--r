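# Single-channel and population ON/OFF segmentation against the ISI, gap
# definitions and independent brute-force oracles.

ms <- function(x) x / 1000

test_that("single-channel segmentation follows the ISI and flanking rules", {
  p <- off_params()
  # one 70-ms gap flanked by two 30-ms ON runs
  seg <- segment_channel(ms(c(0, 10, 20, 30, 100, 115, 130)), p)
  expect_equal(nrow(seg$off), 1)
  expect_equal(seg$off$start, 0.030)
  expect_equal(seg$off$end, 0.100)
  expect_equal(nrow(seg$on), 2)
  # both gaps 45 ms < 50 ms: no OFF
  seg2 <- segment_channel(ms(c(0, 10, 20, 30, 75, 120, 135, 150)), p)
  expect_equal(nrow(seg2$off), 0)
  # empty and single-spike trains
  expect_equal(nrow(segment_channel(numeric(0), p)$off), 0)
  expect_equal(nrow(segment_channel(0.5, p)$on), 0)
})

test_that("one qualifying flank suffices by default, two single-spike flanks never do", {
  p_either <- off_params(flank_rule = "either")
  p_both <- off_params(flank_rule = "both")
  train <- ms(c(0, 10, 20, 30, 100, 200, 210, 220, 230))
  seg_e <- segment_channel(train, p_either)
  expect_equal(nrow(seg_e$off), 2)          # both gaps accepted one-sided
  expect_equal(seg_e$off$start, c(0.030, 0.100))
  expect_equal(seg_e$off$end, c(0.100, 0.200))
  seg_b <- segment_channel(train, p_both)
  expect_equal(nrow(seg_b$off), 0)          # single-spike run fails both-sided
  # an OFF surrounded by two single-spike runs is rejected in both modes
  lone <- ms(c(0, 100, 200))
  expect_equal(nrow(segment_channel(lone, p_either)$off), 0)
  # brute-force scan agrees on random lattice trains, both readings
  set.seed(31)
  for (rep in 1:100) {
    tt <- sort(unique(round(runif(rpois(1, 100), 0, 5), 3)))
    for (fr in c("either", "both")) {
      got <- segment_channel(tt, off_params(flank_rule = fr))$off
      want <- oracle_segment(tt, flank_rule = fr)
      expect_intervals_equal(iv_to_mat(got), want)
    }
  }
})

test_that("quorum rule and duration bounds classify global periods", {
  p <- off_params()
  mk_off <- function(n_off, s, e) c(
    lapply(seq_len(n_off), function(i) interval_set(s, e, "single_off")),
    lapply(seq_len(16 - n_off), function(i) interval_set()))
  # 12 of 16 OFF over [1.0, 1.1) -> one global OFF
  res <- detect_global(mk_off(12, 1.0, 1.1), p, span = c(0, 2))
  expect_equal(nrow(res$global_off), 1)
  expect_equal(res$global_off$start, 1.0)
  expect_equal(res$global_off$end, 1.1)
  # 11 of 16: below quorum, no global OFF
  res11 <- detect_global(mk_off(11, 1.0, 1.1), p, span = c(0, 2))
  expect_equal(nrow(res11$global_off), 0)
  # 450-ms quorum run is unclassified, not truncated
  res450 <- detect_global(mk_off(12, 1.0, 1.45), p, span = c(0, 2))
  expect_equal(nrow(res450$global_off), 0)
  expect_true(any(abs(res450$unclassified$start - 1.0) < 1e-12 &
                    abs(res450$unclassified$end - 1.45) < 1e-12))
  # channel-count mismatch is an error, not a silent rescale
  expect_error(detect_global(mk_off(12, 1, 1.1)[1:8], p), "n_channels")
})

test_that("implementation matches the brute-force oracle on random instances", {
  set.seed(32)
  p <- off_params()
  for (rep in 1:60) {
    inst <- random_off_instance()
    per_ch <- lapply(inst$trains, function(tt) segment_channel(tt, p)$off)
    got <- detect_global(per_ch, p, span = c(0, inst$duration))
    want <- oracle_global(lapply(per_ch, iv_to_mat), c(0, inst$duration))
    expect_intervals_equal(iv_to_mat(got$global_off), want$off)
    expect_intervals_equal(iv_to_mat(got$global_on), want$on)
  }
})

test_that("fallback mode detects merged-train silence including edges", {
  p <- off_params(mode = "fallback")
  sp <- spike_train_set(list(c(0.1, 0.2), c(0.13, 0.31)), 0.5)
  off <- detect_fallback(sp, p)
  # merged spikes 0.1, 0.13, 0.2, 0.31: qualifying gaps are the edges
  # [0, 0.1) and [0.31, 0.5) plus [0.13, 0.2) and [0.2, 0.31)
  expect_equal(nrow(off), 4)
  expect_equal(off$start, c(0, 0.13, 0.2, 0.31))
  # empty recording is one long OFF
  sp0 <- spike_train_set(list(numeric(0)), 2)
  off0 <- detect_fallback(sp0, p)
  expect_equal(nrow(off0), 1)
  expect_equal(c(off0$start, off0$end), c(0, 2))
})

test_that("fallback gap counts match the Poisson expectation", {
  set.seed(33)
  lam <- 320  # merged rate of 16 channels at 20 Hz
  dur <- 60
  counts <- sapply(1:5, function(i) {
    trains <- lapply(1:16, function(ch) sort(runif(rpois(1, 20 * dur), 0, dur)))
    sp <- spike_train_set(trains, dur)
    nrow(detect_fallback(sp, off_params(mode = "fallback")))
  })
  expected <- dur * lam * exp(-lam * 0.05)
  se <- sqrt(expected)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("off statistics report frequency and duration over windows", {
  off <- interval_set(seq(0, 290, by = 10) + 1, seq(0, 290, by = 10) + 1.1,
                      "global_off")
  stats_ <- off_statistics(off, interval_set(0, 600, "w"))
  expect_equal(stats_$frequency_per_min, 3.0)
  expect_equal(stats_$mean_duration_ms, 100, tolerance = 1e-6)
  none <- off_statistics(interval_set(), interval_set(0, 60, "w"))
  expect_equal(none$frequency_per_min, 0)
  expect_true(is.na(none$mean_duration_ms))
  expect_error(off_statistics(off, interval_set()), "zero duration")
})

test_that("detected OFF frequency recovers the generator ground truth", {
  cfg <- generator_config(seed = 17, session_length = 600,
                          state_schedule = "NREM",
                          channel_jitter_sd_ms = 2, participation_prob = 1)
  s <- simulate_session(cfg)
  det <- detect_off_periods(s$spikes, off_params())
  truth <- s$truth$population_off
  w <- interval_set(0, 600, "w")
  f_det <- off_statistics(det$global_off, w)$frequency_per_min
  f_true <- off_statistics(truth, w)$frequency_per_min
  expect_lt(abs(f_det - f_true) / f_true, 0.1)
  expect_lt(abs(f_det - 30) / 30, 0.1)
})
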