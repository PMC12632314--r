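# File formats: TSV with one header line (comment lines starting with '#'
# carry object-level metadata such as recording duration); continuous traces
# are a flat channel-major float64 binary with a JSON sidecar.

write_tsv_meta <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    for (k in names(meta))
      writeLines(sprintf("# %s=%s", k, paste(meta[[k]], collapse = ",")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[substr(kv, 1, eq - 1)]] <- strsplit(substr(kv, eq + 1, nchar(kv)), ",")[[1]]
  }
  body <- lines[!grepl("^#", lines)]
  df <- tryCatch(
    read.delim(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("malformed TSV '%s': %s", path, conditionMessage(e))))
  list(df = df, meta = meta)
}

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("malformed file '%s': missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
}

#' Read and write interval sets
#'
#' TSV with columns `label`, `start_s`, `end_s`.
#'
#' @param x an [interval_set()].
#' @param path file path.
#' @return `write_intervals` returns `path` invisibly; `read_intervals` an
#'   [interval_set()].
#' @export
write_intervals <- function(x, path) {
  write_tsv_meta(data.frame(label = x$label, start_s = x$start, end_s = x$end),
                 path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  r <- read_tsv_meta(path)
  require_columns(r$df, c("label", "start_s", "end_s"), path)
  interval_set(r$df$start_s, r$df$end_s, r$df$label)
}

#' Read and write hypnograms
#'
#' TSV with columns `state`, `start_s`, `end_s`.
#'
#' @param x a [hypnogram()].
#' @param path file path.
#' @return `write_hypnogram` returns `path` invisibly; `read_hypnogram` a
#'   [hypnogram()].
#' @export
write_hypnogram <- function(x, path) {
  write_tsv_meta(data.frame(state = x$state, start_s = x$start, end_s = x$end),
                 path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  r <- read_tsv_meta(path)
  require_columns(r$df, c("state", "start_s", "end_s"), path)
  hypnogram(r$df$state, r$df$start_s, r$df$end_s)
}

#' Read and write spike train sets
#'
#' TSV with columns `channel`, `time_s`; recording duration and the full
#' channel roster (including silent channels) are carried in `#` metadata
#' lines so the round trip is the identity.
#'
#' @param x a [spike_train_set()].
#' @param path file path.
#' @return `write_spike_trains` returns `path` invisibly; `read_spike_trains`
#'   a [spike_train_set()].
#' @export
write_spike_trains <- function(x, path) {
  df <- data.frame(
    channel = rep(x$channel_ids, lengths(x$trains)),
    time_s = sprintf("%.9f", unlist(x$trains, use.names = FALSE)))
  write_tsv_meta(df, path,
                 meta = list(duration_s = sprintf("%.9f", x$duration),
                             channels = x$channel_ids))
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  r <- read_tsv_meta(path)
  if (is.null(r$meta$duration_s))
    stop(sprintf("malformed spike file '%s': missing '# duration_s=' metadata", path))
  duration <- as.numeric(r$meta$duration_s)
  channels <- r$meta$channels
  if (nrow(r$df)) require_columns(r$df, c("channel", "time_s"), path)
  trains <- lapply(channels, function(ch) {
    if (nrow(r$df)) as.numeric(r$df$time_s[r$df$channel == ch]) else numeric(0)
  })
  spike_train_set(trains, duration, channel_ids = channels)
}

#' Read and write continuous traces
#'
#' Flat channel-major float64 binary plus a JSON sidecar (`<path>.json`)
#' holding `channel_ids`, `sample_rate`, `dtype`, `t0`, `kind`, `n_samples`.
#'
#' @param x a [continuous_traces()].
#' @param path binary file path (sidecar written as `path` + `.json`).
#' @return `write_traces` returns `path` invisibly; `read_traces` a
#'   [continuous_traces()].
#' @export
write_traces <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  # channel-major: channel 1's samples, then channel 2's, ...
  writeBin(as.vector(t(x$data)), con, size = 8)
  jsonlite::write_json(
    list(channel_ids = x$channel_ids, sample_rate = x$sample_rate,
         dtype = "float64", t0 = x$t0, kind = x$kind,
         n_samples = ncol(x$data)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(meta$dtype, "float64")) stop("unsupported dtype: ", meta$dtype)
  n_ch <- length(meta$channel_ids)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n_ch * meta$n_samples, size = 8)
  if (length(vals) != n_ch * meta$n_samples)
    stop(sprintf("malformed traces file '%s': expected %d values, got %d",
                 path, n_ch * meta$n_samples, length(vals)))
  continuous_traces(matrix(vals, nrow = n_ch, byrow = TRUE), meta$sample_rate,
                    channel_ids = meta$channel_ids, t0 = meta$t0,
                    kind = meta$kind)
}

#' Read and write pose tracks
#'
#' TSV with columns `frame`, `node`, `x`, `y` and a `# frame_rate=` metadata
#' line.
#'
#' @param x a [pose_track()].
#' @param path file path.
#' @return `write_pose` returns `path` invisibly; `read_pose` a [pose_track()].
#' @export
write_pose <- function(x, path) {
  nf <- dim(x$positions)[1]; nn <- dim(x$positions)[2]
  df <- data.frame(
    frame = rep(seq_len(nf), each = nn),
    node = rep(x$node_names, times = nf),
    x = sprintf("%.6f", as.vector(t(x$positions[, , 1]))),
    y = sprintf("%.6f", as.vector(t(x$positions[, , 2]))))
  write_tsv_meta(df, path, meta = list(frame_rate = sprintf("%.9f", x$frame_rate)))
}

#' @rdname write_pose
#' @export
read_pose <- function(path) {
  r <- read_tsv_meta(path)
  require_columns(r$df, c("frame", "node", "x", "y"), path)
  if (is.null(r$meta$frame_rate))
    stop(sprintf("malformed pose file '%s': missing '# frame_rate=' metadata", path))
  nodes <- unique(r$df$node)
  frames <- sort(unique(r$df$frame))
  if (!identical(frames, seq_along(frames)))
    stop(sprintf("pose file '%s' has missing frames", path))
  pos <- array(NA_real_, dim = c(length(frames), length(nodes), 2))
  ni <- match(r$df$node, nodes)
  pos[cbind(r$df$frame, ni, 1L)] <- as.numeric(r$df$x)
  pos[cbind(r$df$frame, ni, 2L)] <- as.numeric(r$df$y)
  pose_track(pos, as.numeric(r$meta$frame_rate), node_names = nodes)
}
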