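# ON/OFF segmentation. Single channel: ON = spike run with all ISIs < 50 ms
# (run spans first to last spike); candidate OFF = inter-run gap >= 50 ms,
# accepted when the flanking rule holds (at least one adjacent ON run
# >= 30 ms by default). Population: n(t) = number of channels currently in a
# single-channel OFF; maximal runs with n >= quorum lasting 50-400 ms are
# global OFF, maximal sub-quorum runs lasting 50-2000 ms are global ON,
# out-of-bounds runs are left unclassified.

#' Parameters for ON/OFF segmentation
#'
#' @param min_off_ms minimum OFF (silence) duration, ms.
#' @param min_flank_on_ms minimum flanking ON-run duration, ms.
#' @param max_isi_in_on_ms ISIs at or above this break an ON run, ms.
#' @param quorum channels that must be simultaneously OFF for a global OFF.
#' @param n_channels expected channel count (quorum is defined against it).
#' @param global_off_bounds,global_on_bounds duration bounds (ms) for global
#'   OFF and global ON periods.
#' @param flank_rule `"either"`: at least one adjacent ON run must be at
#'   least `min_flank_on_ms` (an OFF may not be surrounded by two
#'   single-spike runs); `"both"`: both flanks must qualify.
#' @param mode `"standard"` (quorum definition) or `"fallback"` (all-channel
#'   silence, for recordings with very low MUA).
#' @return A list of class `off_params`.
#' @export
off_params <- function(min_off_ms = 50, min_flank_on_ms = 30,
                       max_isi_in_on_ms = 50, quorum = 12L,
                       n_channels = 16L,
                       global_off_bounds = c(50, 400),
                       global_on_bounds = c(50, 2000),
                       flank_rule = c("either", "both"),
                       mode = c("standard", "fallback")) {
  flank_rule <- match.arg(flank_rule)
  mode <- match.arg(mode)
  stopifnot(min_off_ms > 0, quorum <= n_channels,
            global_off_bounds[1] < global_off_bounds[2],
            global_on_bounds[1] < global_on_bounds[2])
  structure(list(min_off_ms = min_off_ms, min_flank_on_ms = min_flank_on_ms,
                 max_isi_in_on_ms = max_isi_in_on_ms, quorum = as.integer(quorum),
                 n_channels = as.integer(n_channels),
                 global_off_bounds = global_off_bounds,
                 global_on_bounds = global_on_bounds,
                 flank_rule = flank_rule, mode = mode),
            class = "off_params")
}

#' Single-channel ON/OFF segmentation
#'
#' ON periods span the first to last spike of runs whose internal ISIs are
#' all below `max_isi_in_on_ms` (single spikes give zero-width runs, which
#' are kept as run markers but not emitted as ON intervals). Inter-run gaps
#' of at least `min_off_ms` become OFF periods when the flanking rule is
#' satisfied. Silence touching the recording edges is never an OFF period
#' (no flanking ON run exists there).
#'
#' @param train sorted spike times (seconds).
#' @param params an [off_params()].
#' @return List with `on` and `off` [interval_set()]s (labels `"single_on"`,
#'   `"single_off"`).
#' @export
segment_channel <- function(train, params = off_params()) {
  train <- as.numeric(train)
  empty <- list(on = interval_set(), off = interval_set())
  if (length(train) == 0) return(empty)
  isi_max <- params$max_isi_in_on_ms / 1000
  brk <- which(diff(train) >= isi_max)
  run_start <- train[c(1L, brk + 1L)]
  run_end <- train[c(brk, length(train))]
  run_len <- run_end - run_start
  on <- if (any(run_len > 0))
    interval_set(run_start[run_len > 0], run_end[run_len > 0], "single_on")
  else interval_set()
  n_run <- length(run_start)
  if (n_run < 2) return(list(on = on, off = interval_set()))
  gap_s <- run_end[-n_run]; gap_e <- run_start[-1]
  big <- (gap_e - gap_s) >= params$min_off_ms / 1000
  flank_ok <- if (params$flank_rule == "either")
    run_len[-n_run] >= params$min_flank_on_ms / 1000 |
      run_len[-1] >= params$min_flank_on_ms / 1000
  else
    run_len[-n_run] >= params$min_flank_on_ms / 1000 &
      run_len[-1] >= params$min_flank_on_ms / 1000
  keep <- big & flank_ok
  off <- if (any(keep)) interval_set(gap_s[keep], gap_e[keep], "single_off")
  else interval_set()
  list(on = on, off = off)
}

#' Global (population) OFF/ON detection by channel quorum
#'
#' Computes the step function `n(t)` = number of channels simultaneously in
#' a single-channel OFF period. Maximal intervals with `n >= quorum` whose
#' duration lies within `global_off_bounds` are global OFF periods; maximal
#' intervals with `n < quorum` within `global_on_bounds` are global ON
#' periods; maximal intervals violating their duration bound are returned
#' unclassified (never truncated or split).
#'
#' @param per_channel_off list of per-channel OFF [interval_set()]s (one per
#'   channel, as from [segment_channel()]).
#' @param params an [off_params()]; `length(per_channel_off)` must equal
#'   `params$n_channels` (no silent quorum rescaling).
#' @param span numeric length-2 recording span `[start, end)` in seconds.
#' @return List with `global_off`, `global_on` and `unclassified`
#'   [interval_set()]s.
#' @export
detect_global <- function(per_channel_off, params = off_params(),
                          span = NULL) {
  if (length(per_channel_off) != params$n_channels)
    stop(sprintf("got %d channels but params$n_channels = %d; set an explicit quorum/n_channels",
                 length(per_channel_off), params$n_channels))
  mats <- lapply(per_channel_off, iv_mat)
  starts <- unlist(lapply(mats, function(m) m[, 1]), use.names = FALSE)
  ends <- unlist(lapply(mats, function(m) m[, 2]), use.names = FALSE)
  if (is.null(span)) {
    span <- c(0, if (length(ends)) max(ends) else 0)
  }
  empty <- list(global_off = interval_set(), global_on = interval_set(),
                unclassified = interval_set())
  # event-boundary sweep of n(t)
  ev_t <- c(starts, ends, span)
  ev_d <- c(rep(1L, length(starts)), rep(-1L, length(ends)), 0L, 0L)
  keep <- ev_t >= span[1] & ev_t <= span[2]
  ev_t <- ev_t[keep]; ev_d <- ev_d[keep]
  o <- order(ev_t)
  ev_t <- ev_t[o]; ev_d <- ev_d[o]
  # collapse simultaneous events
  grp <- cumsum(!duplicated(ev_t))
  t_u <- ev_t[!duplicated(ev_t)]
  d_u <- as.vector(tapply(ev_d, grp, sum))
  n_t <- cumsum(d_u)                     # level on [t_u[i], t_u[i+1])
  if (length(t_u) < 2) return(empty)
  seg_s <- t_u[-length(t_u)]; seg_e <- t_u[-1]
  hi <- n_t[-length(n_t)] >= params$quorum
  # maximal runs of constant quorum status
  r <- rle(hi)
  idx_end <- cumsum(r$lengths); idx_start <- idx_end - r$lengths + 1L
  run_s <- seg_s[idx_start]; run_e <- seg_e[idx_end]
  run_hi <- r$values
  dur_ms <- (run_e - run_s) * 1000
  off_ok <- run_hi & dur_ms >= params$global_off_bounds[1] &
    dur_ms <= params$global_off_bounds[2]
  on_ok <- !run_hi & dur_ms >= params$global_on_bounds[1] &
    dur_ms <= params$global_on_bounds[2]
  uncl <- !(off_ok | on_ok)
  mk <- function(sel, lb) if (any(sel))
    interval_set(run_s[sel], run_e[sel], lb) else interval_set()
  list(global_off = mk(off_ok, "global_off"),
       global_on = mk(on_ok, "global_on"),
       unclassified = mk(uncl, "unclassified"))
}

#' Fallback OFF detection: all-channel silence
#'
#' For recordings with very low multi-unit activity: OFF periods are gaps of
#' at least `min_off_ms` in the merged all-channel spike train, with no
#' flanking or upper-duration condition. Silent stretches touching the
#' recording edges count.
#'
#' @param spikes a [spike_train_set()].
#' @param params an [off_params()] (only `min_off_ms` is used).
#' @return An [interval_set()] labelled `"global_off"`.
#' @export
detect_fallback <- function(spikes, params = off_params(mode = "fallback")) {
  merged <- sort(unlist(spikes$trains, use.names = FALSE))
  min_off <- params$min_off_ms / 1000
  pts <- c(0, merged, spikes$duration)
  gs <- pts[-length(pts)]; ge <- pts[-1]
  keep <- (ge - gs) >= min_off
  if (!any(keep)) return(interval_set())
  interval_set(gs[keep], ge[keep], "global_off")
}

#' Run single-channel segmentation and global detection on a spike set
#'
#' Convenience wrapper: [segment_channel()] per channel, then
#' [detect_global()] (or [detect_fallback()] when `params$mode` is
#' `"fallback"`).
#'
#' @param spikes a [spike_train_set()].
#' @param params an [off_params()].
#' @return As [detect_global()], plus `per_channel_off` (list).
#' @export
detect_off_periods <- function(spikes, params = off_params()) {
  if (params$mode == "fallback") {
    off <- detect_fallback(spikes, params)
    return(list(global_off = off, global_on = interval_set(),
                unclassified = interval_set(), per_channel_off = NULL))
  }
  per_ch <- lapply(spikes$trains, function(tt) segment_channel(tt, params)$off)
  res <- detect_global(per_ch, params, span = c(0, spikes$duration))
  res$per_channel_off <- per_ch
  res
}

#' OFF-period frequency and mean duration within condition windows
#'
#' Frequency counts OFF periods falling fully inside the union of the
#' windows, per minute of window time; mean duration is over those events.
#'
#' @param global_off an [interval_set()] of global OFF periods.
#' @param condition_windows an [interval_set()] of condition windows.
#' @return List with `frequency_per_min`, `mean_duration_ms`, and `n_events`
#'   (`mean_duration_ms` is `NA` when no events fall in the windows).
#' @export
off_statistics <- function(global_off, condition_windows) {
  w <- iv_union_mat(iv_mat(condition_windows))
  tot <- if (nrow(w)) sum(w[, 2] - w[, 1]) else 0
  if (tot <= 0) stop("condition windows have zero duration")
  m <- iv_mat(global_off)
  inside <- logical(nrow(m))
  if (nrow(m)) {
    idx <- findInterval(m[, 1], w[, 1])
    inside <- idx > 0 & m[, 1] >= w[cbind(pmax(idx, 1L), 1L)] &
      m[, 2] <= w[cbind(pmax(idx, 1L), 2L)]
  }
  n <- sum(inside)
  list(frequency_per_min = n / (tot / 60),
       mean_duration_ms = if (n) mean((m[inside, 2] - m[inside, 1]) * 1000) else NA_real_,
       n_events = n)
}

#' Match detected OFF periods to ground-truth events
#'
#' Greedy one-to-one matching of detected to true event midpoints within a
#' tolerance; used for parameter-recovery validation against the synthetic
#' generator's ground truth.
#'
#' @param detected,truth [interval_set()]s.
#' @param tol_ms midpoint tolerance in ms.
#' @return List with `hit_rate` (fraction of true events matched), `n_true`,
#'   `n_detected`, `n_matched`.
#' @export
match_off_events <- function(detected, truth, tol_ms = 25) {
  md <- iv_mat(detected); mt <- iv_mat(truth)
  if (nrow(mt) == 0) return(list(hit_rate = NA_real_, n_true = 0L,
                                 n_detected = nrow(md), n_matched = 0L))
  mid_d <- (md[, 1] + md[, 2]) / 2
  mid_t <- (mt[, 1] + mt[, 2]) / 2
  used <- logical(length(mid_d)); matched <- 0L
  for (tm in mid_t) {
    if (!length(mid_d)) break
    dd <- abs(mid_d - tm); dd[used] <- Inf
    j <- which.min(dd)
    if (length(j) && dd[j] <= tol_ms / 1000) { used[j] <- TRUE; matched <- matched + 1L }
  }
  list(hit_rate = matched / nrow(mt), n_true = nrow(mt),
       n_detected = nrow(md), n_matched = matched)
}
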