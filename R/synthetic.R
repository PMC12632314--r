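# Synthetic session generator: semi-Markov vigilance states, renewal-process
# population OFF events inside NREM, per-channel participation and entry/exit
# jitter, Poisson ON firing, OFF-locked slow-wave LFP over 1/f background,
# state-dependent EMG tone, and pose random walks.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Configuration for the synthetic session generator
#'
#' Defaults define the generator's standard operating point: 16 channels,
#' population OFF events arriving at 0.5 events/s inside NREM with log-normal
#' durations (median 120 ms, log-sd 0.3, i.e. inside the detectable
#' 50-400 ms band), 100 Hz multi-unit ON firing, 2 ms across-channel
#' entry/exit jitter, 95% per-channel participation, a positive-going
#' slow-wave kernel of 0.3 mV locked to each channel's OFF midpoint, and
#' 1/f LFP background noise.
#'
#' @param seed integer RNG seed; identical seeds give bit-identical sessions.
#' @param n_channels number of recording channels.
#' @param session_length session length in seconds.
#' @param state_schedule `NULL` (simulate a hypnogram), a [hypnogram()], or a
#'   single state name (e.g. `"NREM"`) for a uniform session.
#' @param off_rate_nrem population OFF events per second of NREM.
#' @param off_duration_median_ms,off_duration_sigma log-normal OFF duration:
#'   median in ms and log-scale sd.
#' @param on_firing_rate per-channel Poisson MUA rate (Hz) outside OFF periods.
#' @param off_firing_rate residual rate (Hz) inside a channel's own OFF periods.
#' @param channel_jitter_sd_ms sd (ms) of each channel's OFF entry/exit jitter;
#'   the generator's synchrony dial.
#' @param participation_prob probability a channel joins a population OFF event.
#' @param min_off_gap_ms refractory ON gap between consecutive population OFFs.
#' @param lfp_polarity `"positive"` (SOM-like positive-going slow waves) or
#'   `"negative"` (ACR-like negative-going).
#' @param kernel_amplitude_mv,kernel_rise_ms,kernel_decay_ms slow-wave kernel:
#'   peak amplitude (mV) and rise/decay time scales (ms) of the asymmetric
#'   smooth bump centred on the OFF midpoint.
#' @param noise_exponent,noise_rms_mv 1/f^exponent LFP background and its RMS.
#' @param lfp_rate,emg_rate sample rates (Hz) for the synthetic LFP and EMG.
#' @param emg_rms_by_state named RMS (mV) of EMG tone per vigilance state.
#' @param pose_step_sd_by_state named per-frame random-walk step sd (pixels)
#'   per state for [simulate_pose()].
#' @param pose_frame_rate pose frames per second.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_channels = 16L,
                             session_length = 600,
                             state_schedule = NULL,
                             off_rate_nrem = 0.5,
                             off_duration_median_ms = 120,
                             off_duration_sigma = 0.3,
                             on_firing_rate = 100,
                             off_firing_rate = 0,
                             channel_jitter_sd_ms = 2,
                             participation_prob = 0.95,
                             min_off_gap_ms = 100,
                             lfp_polarity = c("positive", "negative"),
                             kernel_amplitude_mv = 0.3,
                             kernel_rise_ms = 30,
                             kernel_decay_ms = 120,
                             noise_exponent = 1,
                             noise_rms_mv = 0.05,
                             lfp_rate = 400,
                             emg_rate = 1017,
                             emg_rms_by_state = c(Wake = 0.05, NREM = 0.015,
                                                  REM = 0.005, IS = 0.01,
                                                  Unsure = 0.02, Artifact = 0.1),
                             pose_step_sd_by_state = c(Wake = 5, NREM = 0.1,
                                                       REM = 0.1, IS = 0.1,
                                                       Unsure = 1, Artifact = 1),
                             pose_frame_rate = 1) {
  lfp_polarity <- match.arg(lfp_polarity)
  stopifnot(n_channels >= 1, session_length > 0,
            participation_prob >= 0, participation_prob <= 1,
            channel_jitter_sd_ms >= 0, off_rate_nrem >= 0)
  mean_dur <- exp(log(off_duration_median_ms / 1000) + off_duration_sigma^2 / 2)
  if (off_rate_nrem * mean_dur > 1)
    stop("generator_config: off_rate x mean OFF duration > 1 (overlapping regime)")
  if (off_rate_nrem > 0 &&
      1 / off_rate_nrem <= mean_dur + min_off_gap_ms / 1000)
    stop("generator_config: off_rate too high for the refractory ON gap")
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  cfg
}

# asymmetric smooth slow-wave bump, peak 1 at t = 0:
# exp(-t^2 / (2 rise^2)) for t <= 0, exp(-t^2 / (2 decay^2)) for t > 0
slow_wave_kernel_eval <- function(t, rise_s, decay_s) {
  s <- ifelse(t <= 0, rise_s, decay_s)
  exp(-t^2 / (2 * s^2))
}

#' Closed-form maximum rise slope of the slow-wave kernel
#'
#' For the generator's asymmetric-Gaussian kernel of peak amplitude `A` and
#' rise scale `sigma_r`, the rising-flank derivative attains its maximum
#' `A * exp(-1/2) / sigma_r` at `t = -sigma_r` before the peak.
#'
#' @param amplitude_mv kernel peak amplitude (mV).
#' @param rise_ms rise scale (ms).
#' @return slope in mV/s.
#' @export
kernel_max_rise_slope <- function(amplitude_mv, rise_ms) {
  amplitude_mv * exp(-0.5) / (rise_ms / 1000)
}

# 1/f^alpha noise by spectral shaping of white noise, scaled to target RMS
pink_noise <- function(n, exponent, rms) {
  w <- rnorm(n)
  if (exponent == 0 || rms == 0) return(w * rms)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))          # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)            # symmetric frequency index
  H <- 1 / f^(exponent / 2)
  H[1] <- 0                          # zero out DC
  x <- Re(fft(W * H, inverse = TRUE)) / n
  x * rms / sd(x)
}

simulate_hypnogram_internal <- function(session_length, light_onset = 0) {
  # semi-Markov walk: Wake -> NREM -> (IS -> REM -> Wake | Wake); bout
  # statistics follow a diurnal rhythm (sleep-rich light phase, wake-rich
  # dark phase; ~45% total sleep over a day, as in home-cage mice)
  states <- character(0); starts <- numeric(0); ends <- numeric(0)
  t <- 0; cur <- "Wake"
  while (t < session_length) {
    light <- ((t - light_onset) %% 86400) < 43200
    dur <- if (light) switch(cur,
      Wake = rlnorm(1, log(120), 0.5),
      NREM = rlnorm(1, log(240), 0.4),
      IS   = runif(1, 10, 30),
      REM  = rlnorm(1, log(90), 0.4))
    else switch(cur,
      Wake = rlnorm(1, log(600), 0.5),
      NREM = rlnorm(1, log(120), 0.4),
      IS   = runif(1, 10, 30),
      REM  = rlnorm(1, log(60), 0.4))
    dur <- min(dur, session_length - t)
    states <- c(states, cur); starts <- c(starts, t); ends <- c(ends, t + dur)
    t <- t + dur
    cur <- switch(cur,
      Wake = "NREM",
      NREM = if (runif(1) < 0.3) "IS" else "Wake",
      IS   = "REM",
      REM  = "Wake")
  }
  hypnogram(states, starts, ends)
}

#' Simulate a vigilance-state hypnogram
#'
#' Semi-Markov bout alternation (Wake/NREM with occasional IS-to-REM
#' transitions) with log-normal bout durations and a diurnal rhythm:
#' the light phase (first 12 h of each day from `light_onset`) is
#' sleep-rich, the dark phase wake-rich, giving roughly 45% total sleep
#' over a full day.
#'
#' @param session_length length in seconds.
#' @param seed RNG seed.
#' @param light_onset time of light onset (seconds; phase reference).
#' @return A [hypnogram()] covering `[0, session_length)`.
#' @export
simulate_hypnogram <- function(session_length, seed = 1L, light_onset = 0) {
  with_seed(seed, simulate_hypnogram_internal(session_length, light_onset))
}

resolve_schedule <- function(config) {
  if (is.null(config$state_schedule)) {
    simulate_hypnogram_internal(config$session_length)
  } else if (inherits(config$state_schedule, "hypnogram")) {
    config$state_schedule
  } else if (is.character(config$state_schedule) &&
             length(config$state_schedule) == 1) {
    hypnogram(config$state_schedule, 0, config$session_length)
  } else stop("state_schedule must be NULL, a hypnogram, or a state name")
}

# renewal process of OFF events inside one bout [s, e):
# inter-onset gap = duration + refractory + Exp(mean chosen so the realized
# event rate equals off_rate in expectation)
draw_off_events <- function(s, e, rate, med_s, sigma, refractory_s) {
  if (rate <= 0) return(cbind(numeric(0), numeric(0)))
  mean_dur <- exp(log(med_s) + sigma^2 / 2)
  exp_mean <- 1 / rate - mean_dur - refractory_s
  starts <- numeric(0); ends <- numeric(0)
  t <- s + rexp(1, 1 / exp_mean)
  repeat {
    d <- rlnorm(1, log(med_s), sigma)
    if (t + d > e) break
    starts <- c(starts, t); ends <- c(ends, t + d)
    t <- t + d + refractory_s + rexp(1, 1 / exp_mean)
  }
  cbind(starts, ends)
}

#' Simulate a complete synthetic session
#'
#' Generates spikes, LFP, EMG and ground truth with the statistical structure
#' the analysis assumes: population OFF events arrive as a renewal process at
#' `off_rate_nrem` inside NREM bouts only; each channel joins an event with
#' `participation_prob` and jitters its entry and exit by
#' `Normal(0, channel_jitter_sd_ms)`; spikes are per-channel Poisson at
#' `on_firing_rate` outside the channel's own OFF periods (and
#' `off_firing_rate` inside them); the LFP is a sum of slow-wave kernels
#' centred on each channel's own OFF midpoints (sign per `lfp_polarity`) over
#' 1/f background noise; the EMG is state-scaled noise.
#'
#' @param config a [generator_config()].
#' @return A list with elements `spikes` ([spike_train_set()]), `lfp` and
#'   `emg` ([continuous_traces()]), and `truth` (list with `population_off`,
#'   `per_channel_off`, `hypnogram`, `laser`, `true_sleep_fraction`).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    L <- config$session_length
    hyp <- resolve_schedule(config)
    nrem <- hyp[hyp$state == "NREM", , drop = FALSE]

    # population OFF events, bout by bout
    ev <- do.call(rbind, lapply(seq_len(nrow(nrem)), function(i)
      draw_off_events(nrem$start[i], nrem$end[i], config$off_rate_nrem,
                      config$off_duration_median_ms / 1000,
                      config$off_duration_sigma,
                      config$min_off_gap_ms / 1000)))
    if (is.null(ev) || nrow(ev) == 0) ev <- matrix(numeric(0), ncol = 2)
    population_off <- if (nrow(ev))
      interval_set(ev[, 1], ev[, 2], "population_off") else interval_set()

    # per-channel membership and jitter
    jit_sd <- config$channel_jitter_sd_ms / 1000
    per_channel_off <- vector("list", config$n_channels)
    for (ch in seq_len(config$n_channels)) {
      if (nrow(ev)) {
        joins <- runif(nrow(ev)) < config$participation_prob
        en <- ev[joins, 1] + rnorm(sum(joins), 0, jit_sd)
        ex <- ev[joins, 2] + rnorm(sum(joins), 0, jit_sd)
        ok <- en < ex & en >= 0 & ex <= L
        per_channel_off[[ch]] <- if (any(ok))
          interval_set(en[ok], ex[ok], "single_off") else interval_set()
      } else per_channel_off[[ch]] <- interval_set()
    }

    # spikes: homogeneous Poisson thinned inside the channel's OFF intervals
    trains <- vector("list", config$n_channels)
    for (ch in seq_len(config$n_channels)) {
      n <- rpois(1, config$on_firing_rate * L)
      tt <- sort(runif(n, 0, L))
      m <- iv_mat(per_channel_off[[ch]])
      if (nrow(m)) {
        inside <- iv_contains(m, tt)
        keep <- tt[!inside]
        if (config$off_firing_rate > 0) {
          off_t <- sum(m[, 2] - m[, 1])
          k <- rpois(1, config$off_firing_rate * off_t)
          if (k > 0) {
            # uniform within the union of OFF intervals
            u <- runif(k, 0, off_t)
            cum <- c(0, cumsum(m[, 2] - m[, 1]))
            seg <- findInterval(u, cum, rightmost.closed = TRUE)
            keep <- sort(c(keep, m[seg, 1] + (u - cum[seg])))
          }
        }
        tt <- sort(keep)
      }
      trains[[ch]] <- tt
    }
    spikes <- spike_train_set(trains, L)

    # LFP: slow-wave kernels on each channel's own OFF midpoints + 1/f noise
    fs <- config$lfp_rate
    ns <- floor(L * fs)
    rise <- config$kernel_rise_ms / 1000
    decay <- config$kernel_decay_ms / 1000
    sign_ <- if (config$lfp_polarity == "positive") 1 else -1
    amp <- sign_ * config$kernel_amplitude_mv
    lfp <- matrix(0, nrow = config$n_channels, ncol = ns)
    half_lo <- ceiling(4 * rise * fs); half_hi <- ceiling(4 * decay * fs)
    for (ch in seq_len(config$n_channels)) {
      x <- pink_noise(ns, config$noise_exponent, config$noise_rms_mv)
      m <- iv_mat(per_channel_off[[ch]])
      if (nrow(m)) {
        mids <- (m[, 1] + m[, 2]) / 2
        for (mid in mids) {
          c0 <- round(mid * fs) + 1
          i0 <- max(1, c0 - half_lo); i1 <- min(ns, c0 + half_hi)
          if (i0 > i1) next
          tt <- ((i0:i1) - c0) / fs
          x[i0:i1] <- x[i0:i1] + amp * slow_wave_kernel_eval(tt, rise, decay)
        }
      }
      lfp[ch, ] <- x
    }
    lfp <- continuous_traces(lfp, fs, kind = "lfp")

    # EMG: state-scaled white noise, one channel
    efs <- config$emg_rate
    ne <- floor(L * efs)
    emg_sig <- rnorm(ne)
    tt <- (seq_len(ne) - 1) / efs
    scale <- rep(config$emg_rms_by_state[["Wake"]], ne)
    for (i in seq_len(nrow(hyp))) {
      idx <- tt >= hyp$start[i] & tt < hyp$end[i]
      scale[idx] <- config$emg_rms_by_state[[hyp$state[i]]]
    }
    emg <- continuous_traces(matrix(emg_sig * scale, nrow = 1), efs,
                             channel_ids = "emg", kind = "emg")

    sleep_t <- sum(with(hyp[hyp$state %in% SLEEP_STATES, ], end - start))
    truth <- list(population_off = population_off,
                  per_channel_off = per_channel_off,
                  hypnogram = hyp,
                  laser = interval_set(),
                  true_sleep_fraction = sleep_t / L)
    list(spikes = spikes, lfp = lfp, emg = emg, truth = truth)
  })
}

#' Simulate a pose track over a hypnogram
#'
#' Node positions follow a 2-D random walk whose per-frame step is a
#' log-normal displacement magnitude (log-sd 0.6, the bursty, thin-left-tail
#' shape of rodent locomotion speeds) in a uniformly random direction,
#' calibrated so that the mean squared per-frame displacement is
#' `2 * sd^2` for the state's `pose_step_sd_by_state` value: mobile in
#' Wake, near-stationary in sleep.
#'
#' @param hyp a [hypnogram()]; frames cover its span.
#' @param config a [generator_config()] (step sds, frame rate, seed).
#' @param nodes node names.
#' @param origin starting position (pixels).
#' @param step_sdlog log-scale sd of the step-magnitude distribution.
#' @return A [pose_track()].
#' @export
simulate_pose <- function(hyp, config,
                          nodes = c("nose", "head", "centre", "tail"),
                          origin = c(200, 200), step_sdlog = 0.6) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed + 7L, {
    fr <- config$pose_frame_rate
    span <- c(min(hyp$start), max(hyp$end))
    nf <- floor((span[2] - span[1]) * fr)
    tt <- span[1] + (seq_len(nf) - 1) / fr
    sds <- rep(config$pose_step_sd_by_state[["Wake"]], nf)
    for (i in seq_len(nrow(hyp))) {
      idx <- tt >= hyp$start[i] & tt < hyp$end[i]
      sds[idx] <- config$pose_step_sd_by_state[[hyp$state[i]]]
    }
    # E[mag^2] = exp(2 mu + 2 sdlog^2) = 2 sd^2
    mu <- (log(2 * sds^2) - 2 * step_sdlog^2) / 2
    pos <- array(0, dim = c(nf, length(nodes), 2))
    for (j in seq_along(nodes)) {
      mag <- rlnorm(nf, mu, step_sdlog)
      theta <- runif(nf, 0, 2 * pi)
      mag[1] <- 0
      pos[, j, 1] <- origin[1] + (j - 1) * 10 + cumsum(mag * cos(theta))
      pos[, j, 2] <- origin[2] + (j - 1) * 10 + cumsum(mag * sin(theta))
    }
    pose_track(pos, fr, node_names = nodes)
  })
}

#' Expand a stimulation protocol into laser on-intervals
#'
#' Emits the laser on-intervals of each stage in order: within a stage, one
#' pulse per `1/pulse_rate` seconds, each `on_time_ms` long; a laser-off
#' break follows each stage. A stage flagged `repeat_until_sleep` loops
#' (stage + break) until `sleep_onset`, and no light is emitted at or after
#' `sleep_onset` (the final pulse is truncated if it straddles it).
#'
#' @param protocol a [stimulation_protocol()].
#' @param start protocol start time (seconds from session start).
#' @param sleep_onset time of sleep onset, or `NULL` if never reached
#'   (required if any stage repeats until sleep).
#' @return An [interval_set()] of laser-on intervals labelled `"laser"`.
#' @export
generate_protocol <- function(protocol, start = 0, sleep_onset = NULL) {
  stopifnot(inherits(protocol, "stimulation_protocol"))
  if (!is.null(sleep_onset) && sleep_onset <= start)
    stop("sleep_onset must be after start")
  if (any(protocol$repeat_until_sleep) && is.null(sleep_onset))
    stop("sleep_onset required when a stage repeats until sleep")
  t <- start
  on_s <- numeric(0); on_e <- numeric(0)
  stage_pulses <- function(t0, rate, on_dur, stage_len) {
    k <- seq_len(floor(rate * stage_len)) - 1
    cbind(t0 + k / rate, t0 + k / rate + on_dur)
  }
  for (i in seq_len(nrow(protocol))) {
    rate <- protocol$pulse_rate[i]
    on_dur <- protocol$on_time_ms[i] / 1000
    len <- protocol$stage_duration_s[i]
    brk <- protocol$break_s[i]
    if (!protocol$repeat_until_sleep[i]) {
      p <- stage_pulses(t, rate, on_dur, len)
      on_s <- c(on_s, p[, 1]); on_e <- c(on_e, p[, 2])
      t <- t + len + brk
    } else {
      while (t < sleep_onset) {
        p <- stage_pulses(t, rate, on_dur, len)
        on_s <- c(on_s, p[, 1]); on_e <- c(on_e, p[, 2])
        t <- t + len + brk
      }
    }
  }
  if (!is.null(sleep_onset)) {
    keep <- on_s < sleep_onset
    on_s <- on_s[keep]; on_e <- pmin(on_e[keep], sleep_onset)
  }
  if (!length(on_s)) return(interval_set())
  interval_set(on_s, on_e, "laser")
}

#' Synthesize a wideband trace from ground-truth spike times
#'
#' Places a stereotyped biphasic (negative-dominant) spike template at each
#' ground-truth spike time over Gaussian noise, for end-to-end detection
#' recovery tests. SNR is `trough_amplitude / noise_sd`.
#'
#' @param spikes a [spike_train_set()].
#' @param sample_rate wideband rate in Hz.
#' @param noise_sd Gaussian noise sd (signal units).
#' @param trough_amplitude template trough depth (signal units, positive).
#' @param seed RNG seed for the noise.
#' @return A [continuous_traces()] of kind `"wideband"`.
#' @export
simulate_wideband <- function(spikes, sample_rate = 24414.0625,
                              noise_sd = 1, trough_amplitude = 10,
                              seed = 1L) {
  with_seed(seed, {
    ns <- ceiling(spikes$duration * sample_rate)
    # biphasic template: sharp negative trough (~0.12 ms FWHM), slower
    # positive rebound
    tt <- seq(-0.5e-3, 1e-3, by = 1 / sample_rate)
    w <- -exp(-tt^2 / (2 * (0.05e-3)^2)) +
      0.35 * exp(-(tt - 0.4e-3)^2 / (2 * (0.2e-3)^2))
    w <- w * trough_amplitude / abs(min(w))
    off <- which.min(w) - 1L     # trough sample within template
    nw <- length(w)
    out <- matrix(rnorm(length(spikes$trains) * ns, 0, noise_sd),
                  nrow = length(spikes$trains))
    for (ch in seq_along(spikes$trains)) {
      idx <- round(spikes$trains[[ch]] * sample_rate) + 1L
      for (i0 in idx) {
        a <- i0 - off; b <- a + nw - 1L
        wa <- max(1L, a); wb <- min(ns, b)
        if (wa > wb) next
        out[ch, wa:wb] <- out[ch, wa:wb] + w[(wa - a + 1L):(wb - a + 1L)]
      }
    }
    continuous_traces(out, sample_rate, channel_ids = spikes$channel_ids,
                      kind = "wideband")
  })
}
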