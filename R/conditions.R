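# Condition-window extraction. "Recovery sleep" = the first 1 hour of
# cumulative NREM sleep after the end of sleep deprivation, truncated
# mid-bout so it totals exactly 3600 s; "circadian-matched baseline" = the
# same accumulation starting exactly 24 h before the recovery start.

accumulate_nrem <- function(hyp, from, quota,
                            exclude = c("Artifact", "Unsure")) {
  nrem <- hyp[hyp$state == "NREM" & hyp$end > from, , drop = FALSE]
  if (nrow(nrem) == 0) {
    out <- interval_set()
    attr(out, "short") <- TRUE
    attr(out, "accumulated") <- 0
    return(out)
  }
  s <- pmax(nrem$start, from); e <- nrem$end
  acc <- cumsum(e - s)
  k <- which(acc >= quota)[1]
  if (is.na(k)) {
    out <- interval_set(s, e, "condition")
    attr(out, "short") <- TRUE
    attr(out, "accumulated") <- acc[length(acc)]
    return(out)
  }
  excess <- acc[k] - quota
  e[k] <- e[k] - excess
  out <- interval_set(s[1:k], e[1:k], "condition")
  attr(out, "short") <- FALSE
  attr(out, "accumulated") <- quota
  out
}

#' Resolve a named analysis condition to time windows
#'
#' Conditions are anchored on `light_onset` (start of the baseline light
#' period, day before the experiment) and `sd_end` (end of sleep
#' deprivation):
#' * `baseline_12h` - all NREM bouts in the 12-h baseline light period;
#' * `sd_first_hour` - the first hour of the SD (starting at light onset on
#'   the experiment day, `light_onset + 86400`);
#' * `induction` - the last 30 minutes of the SD;
#' * `recovery_1h_nrem` - the first 1 h of cumulative NREM after `sd_end`
#'   (final bout truncated to total exactly 3600 s);
#' * `recovery_first_30min` - the first 1800 s of that accumulation;
#' * `circadian_matched_1h` - 1 h of cumulative NREM starting exactly 24 h
#'   before the recovery start.
#'
#' If there is not enough NREM to fill a quota the window is returned short,
#' with attribute `short = TRUE`.
#'
#' @param name condition name (see above).
#' @param hyp a [hypnogram()].
#' @param light_onset baseline light onset (seconds from session start).
#' @param sd_end end of sleep deprivation (seconds from session start).
#' @return An [interval_set()] with attributes `short` and `accumulated`.
#' @export
resolve_condition <- function(name = c("baseline_12h", "sd_first_hour",
                                       "induction", "recovery_1h_nrem",
                                       "recovery_first_30min",
                                       "circadian_matched_1h"),
                              hyp, light_onset = 0, sd_end = NULL) {
  name <- match.arg(name)
  if (name %in% c("sd_first_hour", "induction", "recovery_1h_nrem",
                  "recovery_first_30min", "circadian_matched_1h") &&
      is.null(sd_end))
    stop("sd_end anchor required for condition '", name, "'")
  switch(name,
    baseline_12h = {
      out <- restrict(hypnogram_bouts(hyp, "NREM"),
                      interval_set(light_onset, light_onset + 43200, "w"))
      attr(out, "short") <- FALSE
      out
    },
    sd_first_hour = {
      sd_start <- light_onset + 86400
      interval_set(sd_start, sd_start + 3600, "condition")
    },
    induction = interval_set(sd_end - 1800, sd_end, "condition"),
    recovery_1h_nrem = accumulate_nrem(hyp, sd_end, 3600),
    recovery_first_30min = {
      rec <- accumulate_nrem(hyp, sd_end, 3600)
      if (nrow(rec) == 0) return(rec)
      out <- accumulate_nrem(hyp, sd_end, 1800)
      out
    },
    circadian_matched_1h = {
      rec <- accumulate_nrem(hyp, sd_end, 3600)
      if (nrow(rec) == 0) stop("no recovery NREM to anchor the circadian match")
      accumulate_nrem(hyp, rec$start[1] - 86400, 3600)
    })
}
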