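# Wideband -> MUA spike times and firing rates: zero-phase 300-12000 Hz FIR
# band-pass, global common median reference, MAD noise estimate, k*sigma
# threshold crossing with refractory deduplication, 2-s firing-rate windows.

# zero-phase FIR filtering: apply |H(f)|^2 in the frequency domain with
# zero padding (equivalent to forward-backward filtering of the linear-phase
# FIR, without group delay)
fir_zero_phase <- function(x, b) {
  n <- length(x); nb <- length(b)
  nfft <- stats::nextn(n + 2 * nb, 2)
  H <- fft(c(b, rep(0, nfft - nb)))
  X <- fft(c(x, rep(0, nfft - n)))
  y <- Re(fft(X * H * Conj(H), inverse = TRUE)) / nfft
  # forward-backward filtering leaves the signal centred at its original
  # samples up to the (linear) phase of H applied twice with conjugation,
  # which cancels exactly; take the first n samples shifted by the group
  # delay of b applied forward then backward (net zero shift)
  y[seq_len(n)]
}

#' Preprocess wideband traces for MUA detection
#'
#' Zero-phase FIR band-pass (default 300-12000 Hz) per channel, then a global
#' common median reference: the per-sample median across channels is
#' subtracted from every channel.
#'
#' @param traces a [continuous_traces()] of kind `"wideband"`.
#' @param band filter pass-band in Hz.
#' @param order FIR order (taps - 1); the default gives > 60 dB stop-band
#'   attenuation with a Hamming design.
#' @return Preprocessed [continuous_traces()].
#' @export
preprocess_wideband <- function(traces, band = c(300, 12000), order = 512) {
  stopifnot(inherits(traces, "continuous_traces"))
  if (traces$kind != "wideband")
    warning("preprocess_wideband() applied to kind '", traces$kind, "'")
  fs <- traces$sample_rate
  if (fs < 2 * band[2])
    stop(sprintf("sample_rate %.1f Hz below 2x high cut %.0f Hz", fs, band[2]))
  wn <- band / (fs / 2)
  b <- signal::fir1(order, wn, type = "pass")
  out <- traces
  for (ch in seq_len(nrow(out$data))) {
    x <- out$data[ch, ]
    # pre-centering keeps the zero-padded edges transient-free; the
    # band-pass removes any DC in-band anyway
    out$data[ch, ] <- fir_zero_phase(x - mean(x), b)
  }
  if (nrow(out$data) == 1) {
    warning("single-channel recording: common median reference removes the signal's own median")
    out$data[1, ] <- 0
  } else {
    med <- col_medians(out$data)
    out$data <- sweep(out$data, 2, med)
  }
  out
}

#' MAD-based per-channel noise estimate
#'
#' `sigma = median(|x - median(x)|) / 0.6745` per channel, the Gaussian-
#' consistent robust scale.
#'
#' @param traces preprocessed [continuous_traces()].
#' @return A list of class `noise_estimate` with `per_channel_sigma` (named)
#'   and `method = "mad"`.
#' @export
estimate_noise <- function(traces) {
  sig <- apply(traces$data, 1, function(x) median(abs(x - median(x))) / 0.6745)
  names(sig) <- traces$channel_ids
  if (any(sig == 0)) warning("constant channel(s): sigma = 0")
  structure(list(per_channel_sigma = sig, method = "mad"),
            class = "noise_estimate")
}

#' Threshold-crossing MUA spike detection
#'
#' Per channel, local extrema beyond `k * sigma` in the configured polarity
#' are returned as spike times; peaks within the refractory window of a
#' previously accepted peak are suppressed (one waveform, one spike).
#'
#' @param traces preprocessed [continuous_traces()].
#' @param noise a [estimate_noise()] result.
#' @param k threshold multiplier (default 4).
#' @param polarity `"negative"` (extracellular convention), `"positive"`, or
#'   `"both"`.
#' @param refractory_ms dead time after an accepted peak.
#' @return A [spike_train_set()].
#' @export
detect_spikes <- function(traces, noise, k = 4,
                          polarity = c("negative", "positive", "both"),
                          refractory_ms = 1) {
  polarity <- match.arg(polarity)
  stopifnot(k > 0)
  fs <- traces$sample_rate
  refr <- refractory_ms / 1000
  trains <- vector("list", nrow(traces$data))
  for (ch in seq_len(nrow(traces$data))) {
    sig <- noise$per_channel_sigma[ch]
    if (sig == 0) {
      warning(sprintf("channel %s skipped: sigma = 0", traces$channel_ids[ch]))
      trains[[ch]] <- numeric(0)
      next
    }
    x <- traces$data[ch, ]
    if (polarity == "positive") x <- -x
    cand <- if (polarity == "both") {
      ax <- abs(x)
      which(ax > k * sig &
              ax >= c(Inf, ax[-length(ax)]) & ax > c(ax[-1], Inf))
    } else {
      which(x < -k * sig &
              x <= c(-Inf, x[-length(x)]) & x < c(x[-1], -Inf))
    }
    if (length(cand) > 1) {
      tt <- (cand - 1) / fs
      keep <- logical(length(tt)); last <- -Inf
      for (i in seq_along(tt)) {
        if (tt[i] - last >= refr) { keep[i] <- TRUE; last <- tt[i] }
      }
      cand <- cand[keep]
    }
    trains[[ch]] <- traces$t0 + (cand - 1) / fs
  }
  dur <- traces$t0 + ncol(traces$data) / fs
  spike_train_set(trains, dur, channel_ids = traces$channel_ids)
}

#' Firing-rate series in fixed windows
#'
#' Spike count per window / window length, per channel, in windows tiling
#' `[0, duration)`; a trailing partial window is dropped.
#'
#' @param spikes a [spike_train_set()].
#' @param window window length in seconds (default 2).
#' @return A list of class `firing_rate_series` with `times` (window
#'   centres), `rates` (channels x windows, Hz) and `window`.
#' @export
firing_rate <- function(spikes, window = 2) {
  stopifnot(window > 0)
  n_win <- floor(spikes$duration / window)
  if (n_win == 0) stop("recording shorter than one window")
  edges <- (0:n_win) * window
  rates <- t(vapply(spikes$trains, function(tt) {
    if (!length(tt)) return(rep(0, n_win))
    h <- findInterval(tt, edges, rightmost.closed = FALSE)
    tabulate(h[h >= 1 & h <= n_win], nbins = n_win) / window
  }, numeric(n_win)))
  dimnames(rates) <- NULL
  structure(list(times = edges[-1] - window / 2, rates = rates,
                 window = window, channel_ids = spikes$channel_ids),
            class = "firing_rate_series")
}

#' Derive an LFP from wideband traces
#'
#' FIR low-pass (anti-alias corner 160 Hz by default) then integer-factor
#' decimation to approximately the target rate; the realized rate
#' `sample_rate / round(sample_rate / target_rate)` is stored on the result.
#'
#' @param traces wideband [continuous_traces()].
#' @param target_rate nominal output rate (Hz, default 400).
#' @param corner anti-alias low-pass corner (Hz).
#' @param order FIR order.
#' @return A [continuous_traces()] of kind `"lfp"`.
#' @export
make_lfp <- function(traces, target_rate = 400, corner = 160, order = 512) {
  fs <- traces$sample_rate
  fac <- max(1L, round(fs / target_rate))
  b <- signal::fir1(order, corner / (fs / 2), type = "low")
  idx <- seq(1, ncol(traces$data), by = fac)
  out <- matrix(0, nrow = nrow(traces$data), ncol = length(idx))
  for (ch in seq_len(nrow(traces$data)))
    out[ch, ] <- fir_zero_phase(traces$data[ch, ], b)[idx]
  continuous_traces(out, fs / fac, channel_ids = traces$channel_ids,
                    t0 = traces$t0, kind = "lfp")
}
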