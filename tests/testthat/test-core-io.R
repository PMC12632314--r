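# Domain types, interval arithmetic, restriction, and file round trips.

test_that("interval arithmetic behaves as a measure", {
  set.seed(11)
  for (rep in 1:50) {
    s1 <- sort(runif(6, 0, 8))
    a <- interval_set(s1[c(1, 3, 5)], s1[c(2, 4, 6)], "a")
    s2 <- sort(runif(4, 0, 8))
    b <- interval_set(s2[c(1, 3)], s2[c(2, 4)], "b")
    lhs <- interval_duration(interval_union(a, b)) +
      interval_duration(interval_intersect(a, b))
    rhs <- interval_duration(a) + interval_duration(b)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("complement partitions the span", {
  a <- interval_set(c(1, 4), c(2, 6), "x")
  comp <- interval_complement(a, c(0, 10))
  expect_equal(interval_duration(a) + interval_duration(comp), 10)
  expect_equal(nrow(interval_intersect(a, comp)), 0)
})

test_that("restrict follows the half-open convention and is idempotent", {
  sp <- spike_train_set(list(c(1.0, 2.0, 3.0)), duration = 5)
  w <- interval_set(1.5, 2.5, "w")
  r <- restrict(sp, w)
  expect_equal(r$trains[[1]], 2.0)
  # interval clipping
  iv <- interval_set(0, 10, "x")
  expect_equal(restrict(iv, interval_set(5, 20, "w"))$start, 5)
  expect_equal(restrict(iv, interval_set(5, 20, "w"))$end, 10)
  # identity on the full span
  expect_equal(restrict(sp, interval_set(0, 5, "w"))$trains[[1]],
               sp$trains[[1]])
  # idempotence over random cases
  set.seed(21)
  for (rep in 1:20) {
    tt <- sort(runif(50, 0, 10))
    x <- spike_train_set(list(tt), 10)
    s <- sort(runif(4, 0, 10))
    w <- interval_set(s[c(1, 3)], s[c(2, 4)], "w")
    once <- restrict(x, w)
    expect_identical(restrict(once, w)$trains, once$trains)
  }
})

test_that("restricting clips retained duration to the window intersection", {
  iv <- interval_set(c(0, 6), c(4, 9), "x")
  w <- interval_set(c(2, 8), c(7, 12), "w")
  r <- restrict(iv, w)
  expect_equal(interval_duration(r),
               interval_duration(interval_intersect(iv, w)))
})

test_that("TSV and binary round trips are the identity", {
  td <- withr::local_tempdir()
  # empty interval set
  p <- file.path(td, "empty.tsv")
  write_intervals(interval_set(), p)
  expect_equal(nrow(read_intervals(p)), 0)
  # hypnogram
  h <- hypnogram(c("Wake", "NREM", "REM"), c(0, 100, 250), c(100, 250, 300))
  write_hypnogram(h, file.path(td, "h.tsv"))
  expect_equal(read_hypnogram(file.path(td, "h.tsv")), h)
  # spike train set with a silent channel
  set.seed(5)
  sp <- spike_train_set(c(lapply(1:15, function(i) sort(runif(700, 0, 600))),
                          list(numeric(0))), 600)
  write_spike_trains(sp, file.path(td, "s.tsv"))
  got <- read_spike_trains(file.path(td, "s.tsv"))
  expect_equal(got$channel_ids, sp$channel_ids)
  expect_equal(got$duration, sp$duration)
  for (i in seq_along(sp$trains))
    expect_equal(got$trains[[i]], sp$trains[[i]], tolerance = 1e-8)
  # traces: bit-exact float64 binary
  tr <- continuous_traces(matrix(rnorm(400), 4), 100, t0 = 1.5, kind = "lfp")
  write_traces(tr, file.path(td, "t.bin"))
  expect_equal(read_traces(file.path(td, "t.bin")), tr)
  # pose
  pos <- array(rnorm(60), dim = c(10, 3, 2))
  pt <- pose_track(pos, 1, c("nose", "head", "tail"))
  write_pose(pt, file.path(td, "p.tsv"))
  got <- read_pose(file.path(td, "p.tsv"))
  expect_equal(got$positions, pt$positions, tolerance = 1e-5)
  expect_equal(got$node_names, pt$node_names)
})

test_that("random interval sets and hypnograms survive the round trip", {
  td <- withr::local_tempdir()
  set.seed(33)
  for (rep in 1:200) {
    n <- sample(0:6, 1)
    if (n == 0) { iv <- interval_set() } else {
      edges <- sort(runif(2 * n, 0, 100))
      iv <- interval_set(edges[seq(1, 2 * n, 2)], edges[seq(2, 2 * n, 2)],
                         sample(letters[1:3], 1))
    }
    p <- file.path(td, "rt.tsv")
    write_intervals(iv, p)
    got <- read_intervals(p)
    expect_equal(nrow(got), nrow(iv))
    if (nrow(iv)) {
      expect_equal(got$start, iv$start, tolerance = 1e-8)
      expect_equal(got$end, iv$end, tolerance = 1e-8)
      expect_equal(got$label, iv$label)
    }
  }
})

test_that("malformed files and invariant violations are rejected", {
  td <- withr::local_tempdir()
  p <- file.path(td, "bad.tsv")
  writeLines(c("state\tstart_s", "Wake\t0"), p)
  expect_error(read_hypnogram(p), "missing column")
  writeLines(c("state\tstart_s\tend_s", "Flying\t0\t10"), p)
  expect_error(read_hypnogram(p), "unknown vigilance state")
  expect_error(interval_set(5, 3), "start must be < end")
  expect_error(interval_set(c(0, 1), c(2, 3), "x"), "overlapping")
  expect_error(hypnogram(c("Wake", "NREM"), c(0, 5), c(10, 15)),
               "non-overlapping")
  expect_error(spike_train_set(list(c(-1, 2)), 5), "\\[0, duration\\)")
})

test_that("protocol constructor enforces duty cycle and durations", {
  expect_error(stimulation_protocol(10, 200, 60, 30), "duty cycle")
  expect_silent(stimulation_protocol(1, 180, 600, 45))
  proto <- off_induction_protocol()
  expect_equal(nrow(proto), 4)
  expect_true(proto$repeat_until_sleep[4])
})
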