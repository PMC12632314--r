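# Multitaper spectral estimation: 4-s DPSS windows (NW = 4, 2K-1 = 7 tapers,
# eigenvalue-weighted), 50% overlap, one-sided PSD in power per Hz so band
# integrals recover variance contributions.

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-half-bandwidth
#' product `nw`, via the standard symmetric tridiagonal eigenproblem, together
#' with their spectral concentration eigenvalues (Rayleigh quotients against
#' the sinc kernel). Tapers are unit-energy. Results are cached per
#' `(n, nw, k)`.
#'
#' @param n taper length in samples.
#' @param nw time-half-bandwidth product.
#' @param k number of tapers (default `2 * nw - 1`).
#' @return List with `tapers` (n x k matrix) and `eigen` (concentrations).
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  key <- sprintf("n%d_nw%g_k%d", n, nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  w <- nw / n
  i <- seq_len(n) - 1
  diag_v <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off_v <- (seq_len(n - 1) * (n - seq_len(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diag_v
  A[cbind(seq_len(n - 1), 2:n)] <- off_v
  A[cbind(2:n, seq_len(n - 1))] <- off_v
  es <- eigen(A, symmetric = TRUE)
  v <- es$vectors[, seq_len(k), drop = FALSE]
  # sign convention: symmetric tapers positive mean, antisymmetric positive
  # initial slope
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    if (abs(s) > 1e-8) { if (s < 0) v[, j] <- -v[, j] }
    else if (v[2, j] - v[1, j] < 0) v[, j] <- -v[, j]
  }
  v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  # concentration eigenvalues via the sinc kernel
  d <- outer(i, i, "-")
  S <- sin(2 * pi * w * d) / (pi * d)
  diag(S) <- 2 * w
  lam <- vapply(seq_len(k), function(j) drop(crossprod(v[, j], S %*% v[, j])),
                numeric(1))
  res <- list(tapers = v, eigen = pmin(pmax(lam, 0), 1))
  .dpss_cache[[key]] <- res
  res
}

#' Spectral estimation parameters
#'
#' @param window window length in seconds (default 4).
#' @param nw time-half-bandwidth product (default 4).
#' @param overlap fractional window overlap in `[0, 1)` (default 0.5).
#' @param k number of tapers (default `2 * nw - 1`).
#' @param bands named list of band edges in Hz.
#' @return List of class `spectral_params`.
#' @export
spectral_params <- function(window = 4, nw = 4, overlap = 0.5,
                            k = 2 * nw - 1,
                            bands = list(delta = c(0.5, 4), theta = c(4, 8),
                                         alpha = c(8, 13), sigma = c(11, 16),
                                         beta = c(13, 30))) {
  stopifnot(window > 0, overlap >= 0, overlap < 1, nw >= 1, k >= 1)
  for (b in bands) stopifnot(b[1] < b[2])
  structure(list(window = window, nw = nw, overlap = overlap, k = k,
                 bands = bands),
            class = "spectral_params")
}

#' Multitaper spectrogram
#'
#' Short-time multitaper PSD: per window, the constant (mean) is removed,
#' the `k` DPSS tapers are applied, and the eigenvalue-weighted average of
#' one-sided taper periodograms is returned in power per Hz.
#'
#' @param traces a [continuous_traces()] (typically LFP or EEG).
#' @param params a [spectral_params()].
#' @return List of class `spectrogram` with `times` (window centres, s),
#'   `freqs` (Hz), `power` (freqs x windows x channels array),
#'   `channel_ids`, `sample_rate`.
#' @export
spectrogram <- function(traces, params = spectral_params()) {
  fs <- traces$sample_rate
  nwin <- round(params$window * fs)
  if (nwin > ncol(traces$data))
    stop("signal shorter than one spectral window")
  hop <- max(1L, round(nwin * (1 - params$overlap)))
  starts <- seq(1L, ncol(traces$data) - nwin + 1L, by = hop)
  dp <- dpss_tapers(nwin, params$nw, params$k)
  wts <- dp$eigen / sum(dp$eigen)
  nfreq <- nwin %/% 2 + 1L
  freqs <- (seq_len(nfreq) - 1) * fs / nwin
  one_sided <- c(1, rep(2, nfreq - 2L), if (nwin %% 2 == 0) 1 else 2)
  power <- array(0, dim = c(nfreq, length(starts), nrow(traces$data)))
  for (ch in seq_len(nrow(traces$data))) {
    x <- traces$data[ch, ]
    for (wi in seq_along(starts)) {
      seg <- x[starts[wi]:(starts[wi] + nwin - 1L)]
      seg <- seg - mean(seg)
      tap <- dp$tapers * seg
      X <- stats::mvfft(tap)
      p <- (Mod(X[seq_len(nfreq), , drop = FALSE])^2 %*% wts) / fs
      power[, wi, ch] <- p * one_sided
    }
  }
  structure(list(times = traces$t0 + (starts - 1 + nwin / 2) / fs,
                 freqs = freqs, power = power,
                 channel_ids = traces$channel_ids, sample_rate = fs),
            class = "spectrogram")
}

trapz_band <- function(freqs, p, lo, hi) {
  sel <- which(freqs >= lo & freqs <= hi)
  if (length(sel) < 2) stop("band contains fewer than two frequency bins")
  f <- freqs[sel]
  colSums((p[sel[-1], , drop = FALSE] + p[sel[-length(sel)], , drop = FALSE]) / 2 *
            diff(f))
}

#' Band power from a spectrogram
#'
#' Trapezoidal integral of the PSD over `[lo, hi]` Hz, per window and
#' channel. The delta band (0.5-4 Hz) gives slow-wave activity (SWA).
#'
#' @param sg a [spectrogram()].
#' @param band numeric `c(lo, hi)` in Hz, or a band name from `params$bands`.
#' @param params a [spectral_params()] (used to resolve band names).
#' @return List of class `bandpower_series` with `times`, `values`
#'   (channels x windows), `band`, `normalization = "none"`.
#' @export
bandpower <- function(sg, band = "delta", params = spectral_params()) {
  if (is.character(band)) {
    nm <- band
    band <- params$bands[[band]]
    if (is.null(band)) stop("unknown band name: ", nm)
  } else nm <- sprintf("%g-%g Hz", band[1], band[2])
  if (band[2] > max(sg$freqs) + 1e-9)
    stop("band exceeds the Nyquist frequency of the spectrogram")
  n_win <- dim(sg$power)[2]
  vals <- t(vapply(seq_len(dim(sg$power)[3]), function(ch) {
    p <- matrix(sg$power[, , ch], ncol = n_win)
    trapz_band(sg$freqs, p, band[1], band[2])
  }, numeric(n_win)))
  structure(list(times = sg$times, values = vals, band = nm,
                 normalization = "none", channel_ids = sg$channel_ids),
            class = "bandpower_series")
}

#' Normalize a band-power series
#'
#' `baseline_mean`: divide each channel by its mean over windows whose
#' centres fall inside `reference_windows` (the convention used to express
#' SWA relative to the NREM mean of the 12-hour light-period baseline).
#' `contralateral`: divide per window and channel by a partner series.
#'
#' @param series a [bandpower_series()].
#' @param reference_windows an [interval_set()] (baseline mode).
#' @param mode `"baseline_mean"` or `"contralateral"`.
#' @param partner partner [bandpower_series()] (contralateral mode).
#' @return A normalized [bandpower_series()].
#' @export
normalize_bandpower <- function(series, reference_windows = NULL,
                                mode = c("baseline_mean", "contralateral"),
                                partner = NULL) {
  mode <- match.arg(mode)
  out <- series
  if (mode == "baseline_mean") {
    stopifnot(!is.null(reference_windows))
    sel <- iv_contains(iv_mat(reference_windows), series$times)
    if (!any(sel)) stop("no window centres fall inside the reference windows")
    ref <- rowMeans(series$values[, sel, drop = FALSE], na.rm = TRUE)
    if (any(!is.finite(ref)) || any(ref == 0)) stop("zero or missing reference mean")
    out$values <- sweep(series$values, 1, ref, "/")
    out$normalization <- "baseline_mean"
  } else {
    stopifnot(!is.null(partner))
    if (!all(dim(partner$values) == dim(series$values)))
      stop("partner series must be channel- and window-matched")
    out$values <- series$values / partner$values
    out$normalization <- "contralateral"
  }
  out
}

#' Mask band-power windows by vigilance state
#'
#' Sets to `NA` every window whose centre falls inside a bout of the given
#' states (by default Artifact and Unsure, which are excluded from all
#' condition-level means).
#'
#' @param series a [bandpower_series()].
#' @param hyp a [hypnogram()].
#' @param states states to mask.
#' @return The masked [bandpower_series()].
#' @export
mask_bandpower <- function(series, hyp, states = c("Artifact", "Unsure")) {
  bouts <- hyp[hyp$state %in% states, , drop = FALSE]
  if (nrow(bouts)) {
    sel <- iv_contains(cbind(bouts$start, bouts$end), series$times)
    series$values[, sel] <- NA_real_
  }
  series
}

#' Condition mean of a band-power series
#'
#' Mean over windows whose centres fall inside the condition windows,
#' per channel (NA windows excluded).
#'
#' @param series a [bandpower_series()].
#' @param windows an [interval_set()].
#' @return Named numeric vector, one mean per channel.
#' @export
bandpower_condition_mean <- function(series, windows) {
  sel <- iv_contains(iv_mat(windows), series$times)
  if (!any(sel)) stop("no window centres inside the condition windows")
  out <- rowMeans(series$values[, sel, drop = FALSE], na.rm = TRUE)
  names(out) <- series$channel_ids
  out
}
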