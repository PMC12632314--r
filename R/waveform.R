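# OFF-locked LFP waveform metrics: event-triggered averages, then
# Savitzky-Golay-smoothed derivative maxima (initiation/termination slope)
# and the field-potential peak near the OFF midpoint.

#' Event-locked average of LFP snippets
#'
#' Extracts snippets around each event's alignment point (`off_start`,
#' `off_end` or `off_midpoint`) and averages them per channel and lag.
#' Events whose snippet would cross the recording edge are dropped.
#'
#' @param lfp a [continuous_traces()].
#' @param events an [interval_set()] of OFF periods.
#' @param alignment `"off_start"`, `"off_end"` or `"off_midpoint"`.
#' @param half_width snippet half-width in samples (default 1 s each side).
#' @param max_events optional cap on the number of events used (e.g. the
#'   first 1500 OFF periods of a condition); `NULL` uses all.
#' @return List of class `event_locked_average` with `lags` (samples),
#'   `mean` and `sem` (channels x lags), `n_events`, `alignment`,
#'   `sample_rate`.
#' @export
event_locked_average <- function(lfp, events,
                                 alignment = c("off_start", "off_end",
                                               "off_midpoint"),
                                 half_width = NULL, max_events = NULL) {
  alignment <- match.arg(alignment)
  fs <- lfp$sample_rate
  if (is.null(half_width)) half_width <- round(fs)
  m <- iv_mat(events)
  if (nrow(m) == 0) stop("no events")
  if (!is.null(max_events)) m <- m[seq_len(min(nrow(m), max_events)), , drop = FALSE]
  anchor <- switch(alignment,
                   off_start = m[, 1],
                   off_end = m[, 2],
                   off_midpoint = (m[, 1] + m[, 2]) / 2)
  ci <- round((anchor - lfp$t0) * fs) + 1L
  ok <- ci - half_width >= 1L & ci + half_width <= ncol(lfp$data)
  ci <- ci[ok]
  if (!length(ci)) stop("all events dropped at the recording edges")
  lags <- -half_width:half_width
  n_ch <- nrow(lfp$data)
  mean_m <- matrix(0, n_ch, length(lags))
  sem_m <- matrix(0, n_ch, length(lags))
  for (ch in seq_len(n_ch)) {
    x <- lfp$data[ch, ]
    snips <- vapply(ci, function(c0) x[(c0 - half_width):(c0 + half_width)],
                    numeric(length(lags)))      # lags x events
    mean_m[ch, ] <- rowMeans(snips)
    sem_m[ch, ] <- if (length(ci) > 1)
      apply(snips, 1, sd) / sqrt(length(ci)) else 0
  }
  structure(list(lags = lags, mean = mean_m, sem = sem_m,
                 n_events = length(ci), alignment = alignment,
                 sample_rate = fs, channel_ids = lfp$channel_ids),
            class = "event_locked_average")
}

slope_metric <- function(avg, search_samples, sg_window, sg_order) {
  if (sg_window > length(avg$lags)) stop("Savitzky-Golay window exceeds snippet")
  zero <- which(avg$lags == 0L)
  if (zero - search_samples < 1 ||
      zero + search_samples > length(avg$lags))
    stop("snippet does not cover the slope search window")
  fs <- avg$sample_rate
  out <- numeric(nrow(avg$mean))
  for (ch in seq_len(nrow(avg$mean))) {
    sm <- signal::sgolayfilt(avg$mean[ch, ], p = sg_order, n = sg_window)
    d <- diff(sm) * fs                          # slope between samples i, i+1
    lo <- zero - search_samples; hi <- zero + search_samples - 1L
    out[ch] <- max(d[lo:hi])
  }
  names(out) <- avg$channel_ids
  out
}

#' OFF-period initiation slope
#'
#' On an average aligned to OFF start: Savitzky-Golay smoothing, first
#' difference times the sample rate, maximum within +/- `search_samples`
#' samples of the OFF start sample. Units: signal units per second
#' (mV/s for an LFP in mV).
#'
#' @param avg an [event_locked_average()] with alignment `"off_start"`.
#' @param search_samples search half-width (default 10 samples).
#' @param sg_window,sg_order Savitzky-Golay window (samples, odd) and
#'   polynomial order.
#' @return Named per-channel slope vector.
#' @export
initiation_slope <- function(avg, search_samples = 10L,
                             sg_window = 11L, sg_order = 3L) {
  if (avg$alignment != "off_start")
    warning("initiation_slope expects alignment 'off_start'")
  slope_metric(avg, search_samples, sg_window, sg_order)
}

#' OFF-period termination slope
#'
#' As [initiation_slope()], on an average aligned to OFF end.
#'
#' @inheritParams initiation_slope
#' @param avg an [event_locked_average()] with alignment `"off_end"`.
#' @return Named per-channel slope vector.
#' @export
termination_slope <- function(avg, search_samples = 10L,
                              sg_window = 11L, sg_order = 3L) {
  if (avg$alignment != "off_end")
    warning("termination_slope expects alignment 'off_end'")
  slope_metric(avg, search_samples, sg_window, sg_order)
}

#' OFF-period peak amplitude
#'
#' Peak of the mean waveform within +/- `search_samples` samples of the OFF
#' midpoint: the signed maximum for positive-going (SOM-like) recordings,
#' the signed minimum for negative-going (ACR-like) ones.
#'
#' @param avg an [event_locked_average()] with alignment `"off_midpoint"`.
#' @param search_samples search half-width (default 20 samples).
#' @param polarity `"positive"` or `"negative"`.
#' @return Named per-channel peak vector (signed).
#' @export
off_peak_amplitude <- function(avg, search_samples = 20L,
                               polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (avg$alignment != "off_midpoint")
    warning("off_peak_amplitude expects alignment 'off_midpoint'")
  zero <- which(avg$lags == 0L)
  if (zero - search_samples < 1 ||
      zero + search_samples > length(avg$lags))
    stop("snippet does not cover the peak search window")
  sel <- (zero - search_samples):(zero + search_samples)
  out <- apply(avg$mean[, sel, drop = FALSE], 1,
               if (polarity == "positive") max else min)
  names(out) <- avg$channel_ids
  out
}
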