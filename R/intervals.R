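# Interval arithmetic on half-open [start, end) intervals in seconds.
# Internal helpers work on 2-column matrices; user-facing functions accept
# interval_set data frames.

iv_mat <- function(x) {
  if (inherits(x, "interval_set") || is.data.frame(x))
    cbind(x$start, x$end)
  else if (is.matrix(x)) x
  else stop("expected interval_set or 2-column matrix")
}

# union of possibly-overlapping intervals -> disjoint sorted matrix
iv_union_mat <- function(m) {
  if (nrow(m) == 0) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out_s <- numeric(nrow(m)); out_e <- numeric(nrow(m))
  k <- 1L; out_s[1] <- m[1, 1]; out_e[1] <- m[1, 2]
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    if (m[i, 1] <= out_e[k]) {
      if (m[i, 2] > out_e[k]) out_e[k] <- m[i, 2]
    } else {
      k <- k + 1L; out_s[k] <- m[i, 1]; out_e[k] <- m[i, 2]
    }
  }
  cbind(out_s[1:k], out_e[1:k])
}

iv_intersect_mat <- function(a, b) {
  a <- iv_union_mat(a); b <- iv_union_mat(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(numeric(0), ncol = 2))
  out <- vector("list", nrow(a))
  j0 <- 1L
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1], b[, 1]); e <- pmin(a[i, 2], b[, 2])
    keep <- s < e
    out[[i]] <- cbind(s[keep], e[keep])
  }
  m <- do.call(rbind, out)
  if (is.null(m)) matrix(numeric(0), ncol = 2) else m[order(m[, 1]), , drop = FALSE]
}

iv_complement_mat <- function(m, span) {
  # complement of union(m) within [span[1], span[2])
  m <- iv_union_mat(m)
  m <- iv_intersect_mat(m, matrix(span, ncol = 2))
  if (nrow(m) == 0) return(matrix(span, ncol = 2))
  s <- c(span[1], m[, 2]); e <- c(m[, 1], span[2])
  keep <- s < e
  cbind(s[keep], e[keep])
}

#' Total duration of an interval set
#'
#' Measure of the union of the intervals (overlaps across labels counted once
#' when `distinct = TRUE`, the default sums per-row lengths).
#'
#' @param x an [interval_set()] (or data frame with start/end).
#' @param distinct if `TRUE`, measure of the union; else sum of row lengths.
#' @return duration in seconds.
#' @export
interval_duration <- function(x, distinct = FALSE) {
  m <- iv_mat(x)
  if (nrow(m) == 0) return(0)
  if (distinct) m <- iv_union_mat(m)
  sum(m[, 2] - m[, 1])
}

#' Union of two interval sets
#'
#' @param a,b [interval_set()] objects.
#' @param label label for the result.
#' @return An [interval_set()] of disjoint intervals covering `a` union `b`.
#' @export
interval_union <- function(a, b = NULL, label = "union") {
  m <- if (is.null(b)) iv_mat(a) else rbind(iv_mat(a), iv_mat(b))
  m <- iv_union_mat(m)
  interval_set(m[, 1], m[, 2], label)
}

#' Intersection of two interval sets
#'
#' @param a,b [interval_set()] objects.
#' @param label label for the result.
#' @return An [interval_set()] of the pointwise intersection.
#' @export
interval_intersect <- function(a, b, label = "intersection") {
  m <- iv_intersect_mat(iv_mat(a), iv_mat(b))
  interval_set(m[, 1], m[, 2], label)
}

#' Complement of an interval set within a span
#'
#' @param a an [interval_set()].
#' @param span numeric length-2, `[start, end)` of the covering window.
#' @param label label for the result.
#' @return An [interval_set()] covering `span` minus `a`.
#' @export
interval_complement <- function(a, span, label = "complement") {
  m <- iv_complement_mat(iv_mat(a), span)
  interval_set(m[, 1], m[, 2], label)
}

#' Test membership of time points in an interval set
#'
#' @param times numeric time points (seconds).
#' @param intervals an [interval_set()] (or hypnogram-like data frame).
#' @return Logical vector: is each time inside the union of the intervals
#'   (half-open convention)?
#' @export
in_intervals <- function(times, intervals) {
  iv_contains(iv_mat(intervals), times)
}

# is each time point inside the union of intervals? (half-open)
iv_contains <- function(m, times) {
  if (nrow(m) == 0) return(rep(FALSE, length(times)))
  m <- iv_union_mat(m)
  idx <- findInterval(times, m[, 1])
  idx > 0 & times < m[cbind(pmax(idx, 1L), 2L)]
}

#' Restrict an object to a set of time windows
#'
#' Keeps only content falling inside the union of `windows` (half-open
#' convention): spikes inside the windows, intervals clipped to the windows,
#' hypnogram bouts clipped, or a contiguous trace segment.
#'
#' @param x a [spike_train_set()], [interval_set()], [hypnogram()] or
#'   [continuous_traces()] object.
#' @param windows an [interval_set()] of windows.
#' @param ... unused.
#' @return An object of the same class as `x`.
#' @export
restrict <- function(x, windows, ...) UseMethod("restrict")

#' @export
restrict.spike_train_set <- function(x, windows, ...) {
  m <- iv_union_mat(iv_mat(windows))
  trains <- lapply(x$trains, function(tt) tt[iv_contains(m, tt)])
  out <- x
  out$trains <- trains
  out
}

#' @export
restrict.interval_set <- function(x, windows, ...) {
  w <- iv_mat(windows)
  pieces <- lapply(unique(x$label), function(lb) {
    m <- iv_intersect_mat(iv_mat(x[x$label == lb, ]), w)
    if (nrow(m)) data.frame(label = lb, start = m[, 1], end = m[, 2]) else NULL
  })
  df <- do.call(rbind, pieces)
  if (is.null(df)) interval_set() else interval_set(df$start, df$end, df$label)
}

#' @export
restrict.hypnogram <- function(x, windows, ...) {
  w <- iv_mat(windows)
  pieces <- lapply(seq_len(nrow(x)), function(i) {
    m <- iv_intersect_mat(cbind(x$start[i], x$end[i]), w)
    if (nrow(m)) data.frame(state = x$state[i], start = m[, 1], end = m[, 2]) else NULL
  })
  df <- do.call(rbind, pieces)
  if (is.null(df)) hypnogram() else hypnogram(df$state, df$start, df$end)
}

#' @export
restrict.continuous_traces <- function(x, windows, ...) {
  m <- iv_union_mat(iv_mat(windows))
  if (nrow(m) != 1)
    stop("restrict() on traces supports a single contiguous window; extract segments per window instead")
  fs <- x$sample_rate
  i0 <- max(1L, ceiling((m[1, 1] - x$t0) * fs - 1e-9) + 1L)
  i1 <- min(ncol(x$data), ceiling((m[1, 2] - x$t0) * fs - 1e-9))
  if (i0 > i1) stop("restrict(): window does not overlap the recording")
  continuous_traces(x$data[, i0:i1, drop = FALSE], fs,
                    channel_ids = x$channel_ids,
                    t0 = x$t0 + (i0 - 1) / fs, kind = x$kind)
}
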