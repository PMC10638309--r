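#' Participant exclusion by stop-success rate
#'
#' Participants whose overall stop-success rate is below 25% did not
#' perform the task accurately and are removed (strict inequality:
#' exactly 25% is retained).
#'
#' @param data trial table with `participant`, `stimulus`, `response`.
#' @param min_rate exclusion threshold (0.25).
#' @return list with `data` (retained rows) and `report` (per
#'   participant: stop-success rate, excluded flag).
#' @export
exclude_participants <- function(data, min_rate = 0.25) {
  stop_trial <- data$stimulus != "DS"
  correct <- ifelse(data$stimulus == "LS", "LR", "RR")
  rates <- vapply(split(seq_len(nrow(data)), data$participant), function(i) {
    i <- i[stop_trial[i]]
    mean(data$response[i] == correct[i])
  }, numeric(1))
  report <- data.frame(participant = names(rates),
                       stop_success_rate = unname(rates),
                       excluded = unname(rates) < min_rate,
                       stringsAsFactors = FALSE)
  keep <- report$participant[!report$excluded]
  list(data = data[data$participant %in% keep, ], report = report)
}

#' Simultaneity cleaning of bimanual responses
#'
#' Dual-response trials with more than 50 ms between the left and right
#' button presses are removed (strict: exactly 50 ms is kept); the
#' remaining dual responses get `rt_ms` set to the mean of the two
#' presses. Idempotent.
#'
#' @param data trial table with `response`, `left_press_ms`,
#'   `right_press_ms`.
#' @param max_gap_ms asynchrony threshold (50 ms).
#' @return list with `data` and `report` (`n_removed`,
#'   `removed_fraction`).
#' @export
clean_bimanual <- function(data, max_gap_ms = 50) {
  dr <- which(data$response == "DR")
  if (any(is.na(data$left_press_ms[dr]) | is.na(data$right_press_ms[dr]))) {
    stop("DR-labelled trial with a missing press time: inconsistent ",
         "labelling", call. = FALSE)
  }
  gap <- abs(data$left_press_ms[dr] - data$right_press_ms[dr])
  drop <- dr[gap > max_gap_ms]
  keep_dr <- setdiff(dr, drop)
  data$rt_ms[keep_dr] <- (data$left_press_ms[keep_dr] +
                            data$right_press_ms[keep_dr]) / 2
  out <- if (length(drop)) data[-drop, ] else data
  list(data = out,
       report = data.frame(n_removed = length(drop),
                           removed_fraction = length(drop) / max(nrow(data), 1)))
}

#' Flag anticipatory ("lucky guess") unimanual responses
#'
#' Unimanual responses on stop trials faster than 100 ms after the stop
#' signal are more plausibly anticipations than reprogrammed responses.
#' They are flagged (strict inequality), not removed.
#'
#' @param data trial table with `stimulus`, `response`, `rt_ms`,
#'   `ssd_ms`.
#' @param threshold_ms relative-RT threshold (100 ms).
#' @return list with `data` (adds logical `fast_guess`) and `report`
#'   (flag counts per condition).
#' @export
flag_fast_guesses <- function(data, threshold_ms = 100) {
  uni <- data$stimulus != "DS" & data$response %in% c("LR", "RR") &
    !is.na(data$rt_ms)
  rel <- data$rt_ms - data$ssd_ms
  data$fast_guess <- uni & !is.na(rel) & rel < threshold_ms
  rep <- stats::aggregate(fast_guess ~ condition, data = data, FUN = base::sum)
  list(data = data, report = rep)
}

#' Per-subject behavioural and EMG summary measures
#'
#' Computes the derived measures per participant and condition: mean
#' successful bi-go RT; mean successful (correct unimanual) stop RT;
#' the stopping delay (stop RT minus bi-go RT, the interference effect);
#' relative RT (stop RT minus that trial's SSD, averaged); relative EMG
#' onset (responding hand's RT-burst onset minus SSD); the proportion of
#' successful stops with a partial burst in either hand; mean
#' CancelTime; and, across conditions, proactive slowing (proactive
#' minus reactive mean bi-go RT). Fields without qualifying trials are
#' `NA`, not zero.
#'
#' @param data cleaned trial table (see [clean_bimanual()]).
#' @param emg optional feature table from [extract_emg_features()].
#' @return data.frame, one row per participant x condition, plus the
#'   cross-condition `proactive_slowing_ms` replicated on both rows of a
#'   participant.
#' @export
summarize_subject <- function(data, emg = NULL) {
  correct_uni <- ifelse(data$stimulus == "LS", "LR", "RR")
  rows <- list()
  for (p in unique(data$participant)) {
    for (cn in unique(data$condition)) {
      d <- data[data$participant == p & data$condition == cn, ]
      cu <- correct_uni[data$participant == p & data$condition == cn]
      go_rt <- d$rt_ms[d$stimulus == "DS" & d$response == "DR"]
      succ <- d$stimulus != "DS" & d$response == cu
      stop_rt <- d$rt_ms[succ]
      rel_rt <- d$rt_ms[succ] - d$ssd_ms[succ]
      mean_or_na <- function(x) if (length(x)) mean(x, na.rm = TRUE) else NA_real_
      row <- data.frame(
        participant = p, condition = cn,
        n_go = base::sum(d$stimulus == "DS"),
        n_stop = base::sum(d$stimulus != "DS"),
        go_rt_ms = mean_or_na(go_rt),
        stop_rt_ms = mean_or_na(stop_rt),
        stop_success_rate = mean(succ[d$stimulus != "DS"]),
        stopping_delay_ms = mean_or_na(stop_rt) - mean_or_na(go_rt),
        relative_rt_ms = mean_or_na(rel_rt),
        mean_ssd_ms = mean_or_na(d$ssd_ms[d$stimulus != "DS"]),
        stringsAsFactors = FALSE)
      if (!is.null(emg)) {
        e <- emg[emg$participant == p & emg$condition == cn, ]
        key <- function(x) paste(x$participant, x$condition, x$trial)
        succ_ids <- key(d[succ, , drop = FALSE])
        es <- e[key(e) %in% succ_ids, ]
        has_partial <- tapply(!is.na(es$partial_peak_ms),
                              paste(es$trial), any)
        resp_hand <- ifelse(es$response == "LR", "left", "right")
        onset_rel <- es$rt_onset_ms[es$hand == resp_hand] -
          es$ssd_ms[es$hand == resp_hand]
        row$partial_burst_proportion <- if (length(has_partial))
          mean(has_partial) else NA_real_
        row$cancel_time_ms <- mean_or_na(
          es$cancel_time_ms[!is.na(es$cancel_time_ms)])
        row$relative_emg_onset_ms <- mean_or_na(onset_rel[!is.na(onset_rel)])
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  for (p in unique(out$participant)) {
    i <- out$participant == p
    pro <- out$go_rt_ms[i & out$condition == "proactive"]
    rea <- out$go_rt_ms[i & out$condition == "reactive"]
    out$proactive_slowing_ms[i] <-
      if (length(pro) && length(rea)) pro - rea else NA_real_
  }
  out
}
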