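# Condition-window extraction and the gated statistics harness.

test_that("recovery accumulates NREM to exactly one hour with mid-bout truncation", {
  hyp <- hypnogram(c("Wake", "NREM", "Wake", "NREM", "NREM"),
                   c(0, 1000, 3400, 4000, 6100),
                   c(1000, 3400, 4000, 6000, 9000))
  rec <- resolve_condition("recovery_1h_nrem", hyp, light_onset = 0,
                           sd_end = 500)
  expect_equal(interval_duration(rec), 3600)
  expect_false(attr(rec, "short"))
  # first bout (after sd_end) is 2400 s; second adds 1200 s and is truncated
  expect_equal(rec$start, c(1000, 4000))
  expect_equal(rec$end, c(3400, 5200))
  rec30 <- resolve_condition("recovery_first_30min", hyp, 0, 500)
  expect_equal(interval_duration(rec30), 1800)
  expect_equal(rec30$end[nrow(rec30)], 2800)
})

test_that("insufficient NREM returns a short flagged window", {
  hyp <- hypnogram(c("Wake", "NREM"), c(0, 100), c(100, 700))
  rec <- resolve_condition("recovery_1h_nrem", hyp, 0, 0)
  expect_true(attr(rec, "short"))
  expect_equal(interval_duration(rec), 600)
  none <- resolve_condition("recovery_1h_nrem",
                            hypnogram("Wake", 0, 100), 0, 0)
  expect_equal(nrow(none), 0)
  expect_true(attr(none, "short"))
})

test_that("circadian-matched windows map onto recovery under a +24 h shift", {
  set.seed(81)
  # non-overlapping NREM bouts, repeated identically on two days
  gaps <- runif(120, 200, 800)
  durs <- runif(120, 100, 1200)
  e0 <- cumsum(gaps + durs)
  s0 <- e0 - durs
  keep <- e0 < 86000
  s0 <- s0[keep]; e0 <- e0[keep]
  hyp <- hypnogram(rep("NREM", 2 * length(s0)),
                   c(s0, s0 + 86400), c(e0, e0 + 86400))
  sd_end <- 86400 + 43200
  rec <- resolve_condition("recovery_1h_nrem", hyp, 0, sd_end)
  circ <- resolve_condition("circadian_matched_1h", hyp, 0, sd_end)
  expect_equal(interval_duration(circ), 3600)
  expect_lt(max(abs(circ$start + 86400 - rec$start)), 1e-6)
  expect_lt(max(abs(circ$end + 86400 - rec$end)), 1e-6)
})

test_that("baseline and SD anchor windows resolve as defined", {
  hyp <- hypnogram(c("NREM", "Wake", "NREM"), c(100, 20000, 50000),
                   c(15000, 50000, 60000))
  base <- resolve_condition("baseline_12h", hyp, light_onset = 0)
  # only the first bout falls inside the 12-h light period [0, 43200)
  expect_equal(interval_duration(base), 15000 - 100)
  sd1 <- resolve_condition("sd_first_hour", hyp, 0, sd_end = 86400 + 18000)
  expect_equal(c(sd1$start, sd1$end), c(86400, 90000))
  ind <- resolve_condition("induction", hyp, 0, sd_end = 104400)
  expect_equal(c(ind$start, ind$end), c(102600, 104400))
  expect_error(resolve_condition("induction", hyp, 0), "sd_end")
})

test_that("normality gates choose the right paired test and effect size", {
  set.seed(82)
  a <- rnorm(10, 1); b <- rnorm(10, 0)
  res <- paired_compare(a, b)
  expect_equal(res$test_name,
               if (shapiro.test(a - b)$p.value > 0.05) "paired_ttest"
               else "wilcoxon_signed_rank")
  # identical vectors: t = 0, g = 0
  same <- paired_compare(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$effect_size, 0)
  # heavily discrete/skewed differences fail Shapiro and go nonparametric
  x <- c(rep(0.01, 8), 4, 9)
  y <- rep(0, 10)
  expect_lt(shapiro.test(x - y)$p.value, 0.05)
  res_np <- paired_compare(x, y)
  expect_equal(res_np$test_name, "wilcoxon_signed_rank")
  expect_equal(res_np$effect_method, "rank_biserial")
  expect_equal(res_np$effect_size, 1)      # all differences positive
  expect_error(paired_compare(1:2, 2:3), "n >= 3")
})

test_that("unpaired gate picks Mann-Whitney for non-normal groups", {
  set.seed(83)
  a <- rexp(20)^3; b <- rexp(20)^3
  res <- paired_compare(a, b, paired = FALSE)
  expect_equal(res$test_name, "mann_whitney_u")
  expect_true(abs(res$effect_size) <= 1)
  g <- paired_compare(rnorm(15, 0.1), rnorm(15), paired = FALSE)
  expect_true(g$test_name %in% c("unpaired_ttest", "mann_whitney_u"))
})

test_that("BH adjustment matches the hand example and is monotone", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(84)
  p <- runif(50)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_error(fdr_adjust(c(0.5, 1.2)))
})

test_that("multigroup comparison gates Levene and runs Tukey post-hocs", {
  set.seed(85)
  g <- factor(rep(c("a", "b", "c"), each = 10))
  # null: three identical-distribution groups
  v0 <- rnorm(30)
  r0 <- multigroup_compare(v0, g)
  expect_true(r0$omnibus$p_value > 0.05 || !is.null(r0$posthoc))
  # strong effect: means 0/0/5
  v1 <- c(rnorm(10), rnorm(10), rnorm(10, 5))
  r1 <- multigroup_compare(v1, g)
  expect_lt(r1$omnibus$p_value, 0.001)
  sig <- r1$posthoc$contrast[r1$posthoc$p_adj < 0.05]
  expect_setequal(sig, c("c-a", "c-b"))
  # unequal variances trigger the Welch branch
  v2 <- c(rnorm(10, 0, 0.1), rnorm(10, 0.1, 0.1), rnorm(10, 3, 8))
  lev_p <- car::leveneTest(v2 ~ g)[["Pr(>F)"]][1]
  r2 <- multigroup_compare(v2, g)
  if (lev_p < 0.05) expect_equal(r2$omnibus$test, "welch_anova")
  expect_error(multigroup_compare(rnorm(20), factor(rep(c("a", "b"), 10))),
               "3 groups")
})
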