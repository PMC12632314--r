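# Event-locked averages and the OFF-locked slope/peak metrics.

# LFP with a given per-event snippet placed at each event midpoint
traces_with_snippets <- function(events, fn, fs = 400, dur = 60,
                                 noise_sd = 0) {
  n <- dur * fs
  x <- rnorm(n, 0, noise_sd)
  tt <- (0:(n - 1)) / fs
  m <- iv_to_mat(events)
  for (i in seq_len(nrow(m))) {
    mid <- (m[i, 1] + m[i, 2]) / 2
    x <- x + fn(tt - mid)
  }
  continuous_traces(matrix(x, 1), fs, kind = "lfp")
}

fixed_events <- function(n = 20, dur_ev = 0.1, spacing = 2) {
  s <- spacing * seq_len(n)
  interval_set(s, s + dur_ev, "global_off")
}

test_that("event-locked average recovers identical snippets exactly", {
  ev <- fixed_events()
  tr <- traces_with_snippets(ev, function(t) exp(-t^2 / (2 * 0.05^2)))
  avg <- event_locked_average(tr, ev, "off_midpoint", half_width = 200)
  expect_equal(avg$n_events, 20)
  expect_true(all(avg$sem < 1e-12))
  direct <- exp(-(avg$lags / 400)^2 / (2 * 0.05^2))
  expect_equal(avg$mean[1, ], direct, tolerance = 1e-6)
  # single event: the average is that snippet
  one <- interval_set(30, 30.1, "global_off")
  avg1 <- event_locked_average(tr, one, "off_midpoint", half_width = 50)
  expect_equal(avg1$n_events, 1)
  # edge events are dropped; all-dropped is an error
  expect_error(event_locked_average(tr, interval_set(0.001, 0.05, "x"),
                                    "off_start", half_width = 400),
               "dropped")
})

test_that("noise averages toward the template at the CLT rate", {
  set.seed(51)
  ev <- fixed_events(n = 200, spacing = 1)
  tmpl <- function(t) 0.5 * exp(-t^2 / (2 * 0.04^2))
  tr <- traces_with_snippets(ev, tmpl, dur = 230, noise_sd = 0.2)
  avg <- event_locked_average(tr, ev, "off_midpoint", half_width = 100)
  direct <- tmpl(avg$lags / 400)
  expect_lt(max(abs(avg$mean[1, ] - direct)), 4 * 0.2 / sqrt(avg$n_events))
})

test_that("ramp slope is recovered exactly by polynomial exactness", {
  ev <- fixed_events(n = 5, spacing = 5)
  # global linear ramp 2 units/s: alignment to off_start
  fs <- 400
  x <- 2 * (0:(30 * fs - 1)) / fs
  tr <- continuous_traces(matrix(x, 1), fs, kind = "lfp")
  avg <- event_locked_average(tr, ev, "off_start", half_width = 100)
  expect_equal(unname(initiation_slope(avg)), 2, tolerance = 1e-9)
  # constant trace: zero slope; offsets do not matter
  trc <- continuous_traces(matrix(rep(3.3, 30 * fs), 1), fs, kind = "lfp")
  avgc <- event_locked_average(trc, ev, "off_start", half_width = 100)
  expect_equal(unname(initiation_slope(avgc)), 0, tolerance = 1e-12)
})

test_that("termination slope mirrors initiation on mirrored ramps", {
  fs <- 400
  tt <- (0:(20 * fs - 1)) / fs
  tr_up <- continuous_traces(matrix(2 * tt, 1), fs, kind = "lfp")
  tr_dn <- continuous_traces(matrix(-2 * tt, 1), fs, kind = "lfp")
  a_up <- event_locked_average(tr_up, interval_set(10, 10.1, "off"),
                               "off_start", half_width = 100)
  a_dn <- event_locked_average(tr_dn, interval_set(9.9, 10.0, "off"),
                               "off_end", half_width = 100)
  # time reversal flips the derivative sign; magnitudes agree exactly
  expect_equal(abs(unname(termination_slope(a_dn))),
               abs(unname(initiation_slope(a_up))), tolerance = 1e-9)
})

test_that("slopes and peaks are offset-invariant and scale linearly", {
  set.seed(52)
  ev <- fixed_events(n = 30, spacing = 1.5, dur_ev = 0.12)
  tmpl <- function(t) 0.3 * ifelse(t <= 0, exp(-t^2 / (2 * 0.03^2)),
                                   exp(-t^2 / (2 * 0.12^2)))
  tr <- traces_with_snippets(ev, tmpl, dur = 60, noise_sd = 0.02)
  a1 <- event_locked_average(tr, ev, "off_start", half_width = 200)
  tr2 <- tr; tr2$data <- tr$data * 2.5 + 7
  a2 <- event_locked_average(tr2, ev, "off_start", half_width = 200)
  expect_equal(unname(initiation_slope(a2)),
               2.5 * unname(initiation_slope(a1)), tolerance = 1e-9)
  m1 <- event_locked_average(tr, ev, "off_midpoint", half_width = 200)
  m2 <- event_locked_average(tr2, ev, "off_midpoint", half_width = 200)
  expect_equal(unname(off_peak_amplitude(m2)),
               2.5 * unname(off_peak_amplitude(m1)) + 7, tolerance = 1e-9)
})

test_that("peak metrics find triangular and negative-going extrema", {
  ev <- interval_set(10, 10.1, "off")
  fs <- 400
  tt <- (0:(20 * fs - 1)) / fs
  tri <- pmax(0, 1.5 * (1 - abs(tt - 10.05) / 0.05))
  tr <- continuous_traces(matrix(tri, 1), fs, kind = "lfp")
  avg <- event_locked_average(tr, ev, "off_midpoint", half_width = 100)
  expect_equal(unname(off_peak_amplitude(avg)), 1.5, tolerance = 1e-9)
  trn <- continuous_traces(matrix(-1.2 / 1.5 * tri, 1), fs, kind = "lfp")
  avgn <- event_locked_average(trn, ev, "off_midpoint", half_width = 100)
  expect_equal(unname(off_peak_amplitude(avgn, polarity = "negative")),
               -1.2, tolerance = 1e-9)
  # flat zero trace
  tr0 <- continuous_traces(matrix(0, 1, 20 * fs), fs, kind = "lfp")
  avg0 <- event_locked_average(tr0, ev, "off_midpoint", half_width = 100)
  expect_equal(unname(off_peak_amplitude(avg0)), 0)
})

test_that("generator-kernel slope matches the closed form", {
  # identical fixed-duration events so the average equals one kernel
  fs <- 400
  ev <- fixed_events(n = 10, dur_ev = 0.1, spacing = 3)
  amp <- 0.3; rise <- 0.03; decay <- 0.12
  fn <- function(t) amp * ifelse(t <= 0, exp(-t^2 / (2 * rise^2)),
                                 exp(-t^2 / (2 * decay^2)))
  tr <- traces_with_snippets(ev, fn, dur = 40)
  avg <- event_locked_average(tr, ev, "off_start", half_width = 300)
  analytic <- kernel_max_rise_slope(amp, 30)
  # the rise maximum sits 20 ms after OFF start for 100-ms events: inside
  # the +/- 10-sample search window at 400 Hz
  got <- unname(initiation_slope(avg))
  expect_lt(abs(got - analytic) / analytic, 0.02)
  avg_e <- event_locked_average(tr, ev, "off_end", half_width = 300)
  got_t <- unname(termination_slope(avg_e))
  # termination: decaying flank has max decay-side slope below the rise value
  expect_lt(got_t, got)
})
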