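# Video-pose actigraphy: per-frame squared displacement averaged across
# nodes, robust Z-scoring, the -mean/std threshold, sleep/wake labels and
# total-sleep-fraction validation against a reference hypnogram; plus the
# floor-texture-recognition novelty ratio.

#' Node-averaged movement series from a pose track
#'
#' Per frame transition and node, the squared displacement
#' `dx^2 + dy^2` (pixels^2); the movement value is the mean across nodes.
#'
#' @param track a [pose_track()].
#' @return List of class `movement_series` with `movement` (length
#'   frames - 1), `frame_rate`; element `i` covers the transition from frame
#'   `i` to `i + 1`.
#' @export
movement_series <- function(track) {
  nf <- dim(track$positions)[1]
  if (nf < 2) stop("movement_series needs at least 2 frames")
  dx <- track$positions[-1, , 1, drop = FALSE] -
    track$positions[-nf, , 1, drop = FALSE]
  dy <- track$positions[-1, , 2, drop = FALSE] -
    track$positions[-nf, , 2, drop = FALSE]
  mv <- rowMeans(matrix(dx^2 + dy^2, nrow = nf - 1))
  structure(list(movement = mv, frame_rate = track$frame_rate),
            class = "movement_series")
}

#' Sleep/wake classification from movement
#'
#' The movement series is robust Z-scored (`(m - median) / (1.4826 * MAD)`),
#' a threshold is set at `-mean(z) / sd(z)`, and frames with `z` below the
#' threshold are labelled sleep. Degenerate series (MAD zero) fall back to
#' standard-deviation scaling; if that is also zero every frame is labelled
#' wake (no evidence of quiescence bimodality).
#'
#' @param ms a [movement_series()].
#' @return List of class `actigraphy_result` with `labels`
#'   (`"sleep"`/`"wake"` per transition frame), `threshold` (z-units),
#'   `sleep_fraction`, `frame_rate`.
#' @export
classify_sleep <- function(ms) {
  m <- ms$movement
  ctr <- median(m)
  scale_ <- mad(m)            # 1.4826 * median(|m - median|)
  if (scale_ == 0) {
    warning("MAD of movement is zero; falling back to sd scaling")
    scale_ <- sd(m)
  }
  if (!is.finite(scale_) || scale_ == 0) {
    labels <- rep("wake", length(m))
    return(structure(list(labels = labels, threshold = NA_real_,
                          sleep_fraction = 0, frame_rate = ms$frame_rate),
                     class = "actigraphy_result"))
  }
  z <- (m - ctr) / scale_
  tau <- -mean(z) / sd(z)
  labels <- ifelse(z < tau, "sleep", "wake")
  structure(list(labels = labels, threshold = tau,
                 sleep_fraction = mean(labels == "sleep"),
                 frame_rate = ms$frame_rate),
            class = "actigraphy_result")
}

#' Signed sleep-fraction error against a reference hypnogram
#'
#' Predicted sleep fraction (actigraphy) minus the reference fraction of
#' NREM + REM + IS time, over a window.
#'
#' @param pred an [classify_sleep()] result (frame `i` covers
#'   `[(i - 1), i) / frame_rate` from the track start).
#' @param reference a [hypnogram()].
#' @param window numeric `c(start, end)` in seconds, or `NULL` for the full
#'   overlap of prediction and reference.
#' @param t0 time of the first pose frame (seconds from session start).
#' @return Signed error in `[-1, 1]`.
#' @export
sleep_fraction_error <- function(pred, reference, window = NULL, t0 = 0) {
  fr <- pred$frame_rate
  frame_t <- t0 + (seq_along(pred$labels) - 0.5) / fr
  if (is.null(window))
    window <- c(max(t0, min(reference$start)),
                min(t0 + length(pred$labels) / fr, max(reference$end)))
  if (window[2] <= window[1]) stop("zero-length comparison window")
  sel <- frame_t >= window[1] & frame_t < window[2]
  if (!any(sel)) stop("no frames inside the window")
  pred_frac <- mean(pred$labels[sel] == "sleep")
  ref_sleep <- hypnogram_bouts(reference, SLEEP_STATES)
  ref_frac <- interval_duration(
    interval_intersect(ref_sleep, interval_set(window[1], window[2], "w"))) /
    (window[2] - window[1])
  pred_frac - ref_frac
}

#' Novelty ratio for the floor-texture recognition task
#'
#' Fraction of frames in the testing window with the nose node on the novel
#' side of the arena.
#'
#' @param track a [pose_track()].
#' @param split_x arena midline x-coordinate (pixels).
#' @param novel_side `"left"` or `"right"`.
#' @param window testing window in seconds from track start (default the
#'   first 300 s).
#' @param node node name used for position (default `"nose"`).
#' @return Ratio in `[0, 1]`.
#' @export
novelty_ratio <- function(track, split_x, novel_side = c("left", "right"),
                          window = c(0, 300), node = "nose") {
  novel_side <- match.arg(novel_side)
  ni <- match(node, track$node_names)
  if (is.na(ni)) stop("node '", node, "' not present in the track")
  fr <- track$frame_rate
  ft <- (seq_len(dim(track$positions)[1]) - 1) / fr
  sel <- ft >= window[1] & ft < window[2]
  if (!any(sel)) stop("no frames inside the testing window")
  x <- track$positions[sel, ni, 1]
  if (novel_side == "right") mean(x >= split_x) else mean(x < split_x)
}
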