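#' @useDynLib offsync, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median mad rnorm rexp rlnorm rpois runif rbinom sd var
#'   fft t.test wilcox.test shapiro.test p.adjust aov oneway.test TukeyHSD
#'   quantile approx complete.cases
#' @importFrom utils read.delim write.table head tail
"_PACKAGE"

VIGILANCE_STATES <- c("Wake", "NREM", "REM", "IS", "Unsure", "Artifact")
SLEEP_STATES <- c("NREM", "REM", "IS")

#' Multichannel continuous traces
#'
#' Container for sampled signals (wideband, LFP, EEG or EMG): a channels x
#' samples matrix plus sampling metadata. Time of sample `i` (1-based) is
#' `t0 + (i - 1) / sample_rate` seconds from session start.
#'
#' @param data numeric matrix, channels x samples.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param channel_ids unique channel labels; defaults to `ch01, ch02, ...`.
#' @param t0 time of the first sample in seconds from session start (>= 0).
#' @param kind one of `"wideband"`, `"lfp"`, `"eeg"`, `"emg"`.
#' @return An object of class `continuous_traces`.
#' @export
continuous_traces <- function(data, sample_rate,
                              channel_ids = NULL, t0 = 0,
                              kind = c("wideband", "lfp", "eeg", "emg")) {
  kind <- match.arg(kind)
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  storage.mode(data) <- "double"
  if (is.null(channel_ids)) {
    channel_ids <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  stopifnot(sample_rate > 0, t0 >= 0, length(channel_ids) == nrow(data))
  if (anyDuplicated(channel_ids)) stop("channel_ids must be unique")
  structure(
    list(data = data, sample_rate = as.numeric(sample_rate),
         channel_ids = as.character(channel_ids), t0 = as.numeric(t0),
         kind = kind),
    class = "continuous_traces")
}

#' @export
print.continuous_traces <- function(x, ...) {
  cat(sprintf("<continuous_traces> kind=%s, %d channels x %d samples @ %.4f Hz, t0=%.3f s\n",
              x$kind, nrow(x$data), ncol(x$data), x$sample_rate, x$t0))
  invisible(x)
}

n_samples <- function(traces) ncol(traces$data)

#' Sample times of a traces object
#' @param traces a [continuous_traces()] object.
#' @return numeric vector of sample times in seconds from session start.
#' @export
trace_times <- function(traces) {
  traces$t0 + (seq_len(ncol(traces$data)) - 1) / traces$sample_rate
}

#' Per-channel spike train set
#'
#' Sorted spike times per channel over a known recording span. All times are
#' seconds from session start, in `[0, duration)`.
#'
#' @param trains list of numeric vectors of spike times (one per channel).
#' @param duration recording span in seconds.
#' @param channel_ids unique channel labels.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(trains, duration, channel_ids = NULL) {
  stopifnot(is.list(trains), duration > 0)
  if (is.null(channel_ids)) {
    channel_ids <- if (!is.null(names(trains)) && all(nzchar(names(trains))))
      names(trains) else sprintf("ch%02d", seq_along(trains))
  }
  stopifnot(length(channel_ids) == length(trains))
  if (anyDuplicated(channel_ids)) stop("channel_ids must be unique")
  trains <- lapply(trains, function(tt) {
    tt <- as.numeric(tt)
    if (is.unsorted(tt, strictly = TRUE)) tt <- sort(unique(tt))
    if (length(tt) && (tt[1] < 0 || tt[length(tt)] >= duration))
      stop("spike times must lie in [0, duration)")
    tt
  })
  names(trains) <- channel_ids
  structure(list(trains = trains, duration = as.numeric(duration),
                 channel_ids = as.character(channel_ids)),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %d channels, %d spikes over %.1f s\n",
              length(x$trains), sum(lengths(x$trains)), x$duration))
  invisible(x)
}

#' Labeled half-open time intervals
#'
#' Sorted intervals `[start, end)` in seconds with a text label. Intervals
#' sharing a label must be non-overlapping; the constructor sorts by start
#' within label.
#'
#' @param start,end interval bounds in seconds, `start < end` elementwise.
#' @param label character label(s), recycled.
#' @return A data frame of class `interval_set` with columns
#'   `label`, `start`, `end`.
#' @export
interval_set <- function(start = numeric(0), end = numeric(0), label = "interval") {
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(length(start) == length(end))
  label <- rep_len(as.character(label), length(start))
  if (any(start >= end)) stop("interval_set: start must be < end")
  df <- data.frame(label = label, start = start, end = end,
                   stringsAsFactors = FALSE)
  df <- df[order(df$label, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (lb in unique(df$label)) {
    sub <- df[df$label == lb, ]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop(sprintf("interval_set: overlapping intervals with label '%s'", lb))
  }
  class(df) <- c("interval_set", "data.frame")
  df
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %d intervals, %.3f s total\n",
              nrow(x), interval_duration(x)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

as_interval_set <- function(df) {
  interval_set(df$start, df$end, df$label)
}

#' Vigilance-state hypnogram
#'
#' Sorted, non-overlapping bouts of scored arousal states. States are drawn
#' from the fixed vocabulary Wake, NREM, REM, IS (intermediate state),
#' Unsure, Artifact.
#'
#' @param state character vector of states.
#' @param start,end bout bounds in seconds, half-open `[start, end)`.
#' @return A data frame of class `hypnogram` with columns `state`, `start`, `end`.
#' @export
hypnogram <- function(state = character(0), start = numeric(0), end = numeric(0)) {
  state <- as.character(state)
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(length(state) == length(start), length(start) == length(end))
  bad <- setdiff(unique(state), VIGILANCE_STATES)
  if (length(bad)) stop("unknown vigilance state(s): ", paste(bad, collapse = ", "))
  if (any(start >= end)) stop("hypnogram: start must be < end")
  o <- order(start)
  state <- state[o]; start <- start[o]; end <- end[o]
  if (length(start) > 1 && any(start[-1] < end[-length(end)]))
    stop("hypnogram bouts must be non-overlapping")
  df <- data.frame(state = state, start = start, end = end,
                   stringsAsFactors = FALSE)
  class(df) <- c("hypnogram", "data.frame")
  df
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d bouts spanning [%.1f, %.1f] s\n",
              nrow(x), if (nrow(x)) min(x$start) else NA, if (nrow(x)) max(x$end) else NA))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

#' Extract state bouts from a hypnogram as an interval set
#'
#' @param hyp a [hypnogram()].
#' @param states states to keep.
#' @return An [interval_set()] labelled by state.
#' @export
hypnogram_bouts <- function(hyp, states) {
  sub <- hyp[hyp$state %in% states, , drop = FALSE]
  interval_set(sub$start, sub$end, sub$state)
}

#' Staged optogenetic stimulation protocol
#'
#' Ordered stages, each a pulse train: `pulse_rate` Hz with `on_time_ms` of
#' light per pulse, for `stage_duration_s` seconds, followed by a laser-off
#' break of `break_s` seconds. A stage flagged `repeat_until_sleep` loops
#' (stage + break) until sleep onset.
#'
#' @param pulse_rate pulses per second, per stage.
#' @param on_time_ms laser-on time per pulse in milliseconds.
#' @param stage_duration_s stage length in seconds.
#' @param break_s laser-off break after the stage, seconds.
#' @param repeat_until_sleep logical; loop the stage until sleep onset.
#' @return Data frame of class `stimulation_protocol`.
#' @export
stimulation_protocol <- function(pulse_rate, on_time_ms, stage_duration_s,
                                 break_s, repeat_until_sleep = FALSE) {
  n <- length(pulse_rate)
  df <- data.frame(pulse_rate = as.numeric(pulse_rate),
                   on_time_ms = as.numeric(on_time_ms),
                   stage_duration_s = as.numeric(stage_duration_s),
                   break_s = as.numeric(break_s),
                   repeat_until_sleep = rep_len(as.logical(repeat_until_sleep), n),
                   stringsAsFactors = FALSE)
  if (any(df$pulse_rate * df$on_time_ms > 1000))
    stop("stimulation_protocol: duty cycle exceeds 1 (pulse_rate * on_time > 1000 ms)")
  if (any(df$stage_duration_s <= 0) || any(df$on_time_ms <= 0) || any(df$break_s < 0))
    stop("stimulation_protocol: durations must be positive")
  class(df) <- c("stimulation_protocol", "data.frame")
  df
}

#' The four-stage OFF-induction protocol
#'
#' The default optogenetic OFF-period induction pattern: pulses at 1 Hz/180 ms
#' for 10 min, 2 Hz/140 ms for 10 min, 3 Hz/100 ms for 5 min (45-s breaks),
#' then 3 Hz/80 ms 5-min bouts with 30-s breaks repeated until sleep onset.
#'
#' @return A [stimulation_protocol()] with four stages.
#' @export
off_induction_protocol <- function() {
  stimulation_protocol(
    pulse_rate = c(1, 2, 3, 3),
    on_time_ms = c(180, 140, 100, 80),
    stage_duration_s = c(600, 600, 300, 300),
    break_s = c(45, 45, 45, 30),
    repeat_until_sleep = c(FALSE, FALSE, FALSE, TRUE))
}

#' Pose-tracking trajectories
#'
#' Overhead-video pose output: per-frame x/y positions (pixels) of a set of
#' body nodes, at a fixed frame rate (1 frame/s by default in this workflow).
#'
#' @param positions numeric array frames x nodes x 2 (x, y).
#' @param frame_rate frames per second (> 0).
#' @param node_names unique node labels.
#' @return Object of class `pose_track`.
#' @export
pose_track <- function(positions, frame_rate = 1, node_names = NULL) {
  stopifnot(is.array(positions), length(dim(positions)) == 3,
            dim(positions)[3] == 2, frame_rate > 0)
  if (is.null(node_names)) node_names <- sprintf("node%02d", seq_len(dim(positions)[2]))
  stopifnot(length(node_names) == dim(positions)[2])
  if (anyDuplicated(node_names)) stop("node_names must be unique")
  if (anyNA(positions)) stop("pose_track: missing frames must be pre-filled")
  structure(list(positions = positions, frame_rate = as.numeric(frame_rate),
                 node_names = as.character(node_names)),
            class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames x %d nodes @ %g fps\n",
              dim(x$positions)[1], dim(x$positions)[2], x$frame_rate))
  invisible(x)
}
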