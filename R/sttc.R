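# Spike-time tiling coefficient (STTC) synchrony. T_X is the proportion of
# spikes in train X with at least one partner spike in the other train
# within +/- dt; P_X is the fraction of the recording window already tiled
# by +/- dt around X's own spikes (union, clipped to the window). The
# default formula pairs each train's T with its own P:
#   STTC = 1/2 [ (T_A - P_A)/(1 - T_A P_A) + (T_B - P_B)/(1 - T_B P_B) ]
# the cross-paired original (Cutts & Eglen) is available as an alternative.

#' STTC parameters
#'
#' @param dt_ms coincidence/tiling half-window in ms (default 5).
#' @param clip_epsilon clipping margin for the Fisher-Z transform.
#' @param formula `"as_printed"` (each train's T paired with its own P) or
#'   `"cutts_eglen"` (cross-paired original).
#' @return List of class `sttc_params`.
#' @export
sttc_params <- function(dt_ms = 5, clip_epsilon = 1e-6,
                        formula = c("as_printed", "cutts_eglen")) {
  formula <- match.arg(formula)
  stopifnot(dt_ms > 0, clip_epsilon > 0, clip_epsilon < 1)
  structure(list(dt_ms = dt_ms, clip_epsilon = clip_epsilon, formula = formula),
            class = "sttc_params")
}

# proportion of spikes in a with a spike of b within +/- dt
tiling_T <- function(a, b, dt) {
  if (!length(a)) return(NA_real_)
  if (!length(b)) return(0)
  idx <- findInterval(a, b)
  d_lo <- ifelse(idx >= 1, a - b[pmax(idx, 1L)], Inf)
  d_hi <- ifelse(idx < length(b), b[pmin(idx + 1L, length(b))] - a, Inf)
  mean(pmin(d_lo, d_hi) <= dt)
}

# fraction of [s, e) tiled by the union of [t - dt, t + dt], clipped.
# For sorted spikes the union measure is sum(min(2 dt, gap)) plus edge terms,
# which avoids materializing the interval union.
tiling_P <- function(a, dt, s, e) {
  n <- length(a)
  if (!n) return(0)
  body_ <- if (n > 1) sum(pmin(diff(a), 2 * dt)) else 0
  total <- body_ + (min(a[n] + dt, e) - max(a[1] - dt, s)) -
    if (n > 1) (a[n] - a[1]) else 0
  total / (e - s)
}

sttc_core <- function(ta, tb, pa, pb, formula) {
  pair <- function(t_, p_) {
    den <- 1 - t_ * p_
    if (abs(den) < 1e-12) return(NA_real_)
    (t_ - p_) / den
  }
  if (formula == "as_printed") {
    v <- c(pair(ta, pa), pair(tb, pb))
  } else {
    v <- c(pair(ta, pb), pair(tb, pa))
  }
  if (anyNA(v)) {
    warning("STTC denominator near zero; returning NA")
    return(NA_real_)
  }
  mean(v)
}

#' Spike-time tiling coefficient for one train pair
#'
#' Computed within a window (a single epoch): both trains are restricted to
#' the window, tiling fractions are clipped at the window edges, and the
#' configured formula combines them. An empty train gives `NA` (undefined,
#' not zero).
#'
#' @param a,b numeric spike-time vectors (seconds, sorted).
#' @param window an [interval_set()] with one interval, a numeric
#'   `c(start, end)`, or a single duration (window `[0, duration)`).
#' @param params an [sttc_params()].
#' @return STTC in `[-1, 1]`, or `NA`.
#' @export
sttc_pair <- function(a, b, window, params = sttc_params()) {
  if (inherits(window, "interval_set") || is.data.frame(window)) {
    m <- iv_mat(window)
    if (nrow(m) != 1) stop("sttc_pair expects a single window; use sttc_condition for multi-epoch input")
    s <- m[1, 1]; e <- m[1, 2]
  } else if (length(window) == 2) { s <- window[1]; e <- window[2] }
  else { s <- 0; e <- window }
  stopifnot(e > s)
  dt <- params$dt_ms / 1000
  a <- a[a >= s & a < e]; b <- b[b >= s & b < e]
  if (!length(a) || !length(b)) return(NA_real_)
  sttc_core(tiling_T(a, b, dt), tiling_T(b, a, dt),
            tiling_P(a, dt, s, e), tiling_P(b, dt, s, e),
            params$formula)
}

#' Per-condition STTC matrix
#'
#' For every unordered channel pair, the STTC is computed per epoch (each
#' continuous bout within the condition) and averaged across epochs; epochs
#' where a pair is undefined are excluded, and bouts shorter than `2 * dt`
#' are skipped. Both the raw epoch-averaged coefficients (`values`) and the
#' epoch-averaged Fisher-Z coefficients (`z_values`, used for statistics)
#' are returned.
#'
#' @param spikes a [spike_train_set()].
#' @param condition_bouts an [interval_set()] of epochs.
#' @param params an [sttc_params()].
#' @return List of class `sttc_matrix` with `values`, `z_values` (symmetric
#'   channel matrices), `n_epochs`, `channel_ids`.
#' @export
sttc_condition <- function(spikes, condition_bouts, params = sttc_params()) {
  m <- iv_mat(condition_bouts)
  if (nrow(m) == 0) stop("condition has no bouts")
  dt <- params$dt_ms / 1000
  m <- m[m[, 2] - m[, 1] >= 2 * dt, , drop = FALSE]
  if (nrow(m) == 0) stop("all bouts shorter than 2 * dt")
  nc <- length(spikes$trains)
  vals <- matrix(NA_real_, nc, nc, dimnames = list(spikes$channel_ids,
                                                   spikes$channel_ids))
  zvals <- vals
  eps <- params$clip_epsilon
  for (i in seq_len(nc)) {
    vals[i, i] <- if (length(spikes$trains[[i]])) 1 else NA_real_
    zvals[i, i] <- if (length(spikes$trains[[i]])) atanh(1 - eps) else NA_real_
    if (i == nc) break
    for (j in (i + 1):nc) {
      rs <- vapply(seq_len(nrow(m)), function(bi)
        sttc_pair(spikes$trains[[i]], spikes$trains[[j]], m[bi, ], params),
        numeric(1))
      rs <- rs[!is.na(rs)]
      if (length(rs)) {
        vals[i, j] <- vals[j, i] <- mean(rs)
        zvals[i, j] <- zvals[j, i] <- mean(fisher_z(rs, eps))
      }
    }
  }
  structure(list(values = vals, z_values = zvals, n_epochs = nrow(m),
                 channel_ids = spikes$channel_ids),
            class = "sttc_matrix")
}

#' Fisher-Z transform with clipping
#'
#' `z = atanh(clip(r, -1 + eps, 1 - eps))`.
#'
#' @param r coefficient(s) in `[-1, 1]`.
#' @param epsilon clipping margin (default 1e-6).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r, epsilon = 1e-6) {
  atanh(pmin(pmax(r, -1 + epsilon), 1 - epsilon))
}

#' Entry-wise condition difference of STTC matrices
#'
#' Difference of two channel-aligned STTC matrices, computed on the Fisher-Z
#' scale by default (e.g. condition minus baseline, or optrode minus
#' contralateral control).
#'
#' @param mat_a,mat_b [sttc_condition()] results.
#' @param space `"z"` or `"r"`.
#' @return A symmetric numeric matrix of differences.
#' @export
sttc_difference <- function(mat_a, mat_b, space = c("z", "r")) {
  space <- match.arg(space)
  if (!identical(mat_a$channel_ids, mat_b$channel_ids))
    stop("STTC matrices are not channel-aligned")
  if (space == "z") mat_a$z_values - mat_b$z_values
  else mat_a$values - mat_b$values
}

#' Mean off-diagonal STTC of a matrix
#'
#' @param mat an [sttc_condition()] result.
#' @param space `"r"` or `"z"`.
#' @return Mean over unordered channel pairs (NA entries dropped).
#' @export
sttc_mean <- function(mat, space = c("r", "z")) {
  space <- match.arg(space)
  v <- if (space == "r") mat$values else mat$z_values
  mean(v[upper.tri(v)], na.rm = TRUE)
}
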