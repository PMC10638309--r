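#' Synthetic EMG configuration
#'
#' Settings for the raw-EMG generator. Bursts are amplitude-modulated
#' band-limited (20-500 Hz) noise under a smooth window. RT-generating
#' bursts start one electromechanical offset (60 ms) before the button
#' press and use a fast initial rise (so raw threshold crossings pin the
#' true onset) followed by a ramp to the peak and a half-cosine decay.
#' Partial bursts on successful stops use a symmetric raised-cosine
#' window centred on the planted peak at `ssd + t_stop` (so the 10 Hz
#' envelope peak is an unbiased read-out of the planted CancelTime),
#' with the ~50 ms truncated decay that motivates the detectability
#' arithmetic. The default burst amplitude is 10 baseline-noise SDs
#' (SNR 10); partial bursts are half the RT-burst amplitude.
#'
#' @param fs_hz sampling rate.
#' @param t0_ms trace start relative to go onset.
#' @param t_end_ms trace end relative to go onset.
#' @param noise_sd baseline Gaussian noise SD (mV).
#' @param snr burst peak amplitude in units of `noise_sd`.
#' @param partial_amp_frac partial-burst amplitude as a fraction of the
#'   RT-burst amplitude.
#' @param em_offset_ms electromechanical offset: press minus EMG onset.
#' @param rt_rise_ms,rt_decay_ms RT-burst onset-to-peak and
#'   peak-to-offset times.
#' @param partial_rise_ms,partial_decay_ms partial-burst onset-to-peak
#'   and peak-to-offset (truncated decay) times.
#' @param plant_mirror if `TRUE`, also plant a "mirror" burst in the
#'   stopping hand peaking after the responding hand's RT-burst onset
#'   (for stress-testing the partial-burst constraints).
#' @return a list of settings.
#' @export
emg_synth_config <- function(fs_hz = 2000, t0_ms = -400, t_end_ms = 1200,
                             noise_sd = 0.02, snr = 10,
                             partial_amp_frac = 0.5, em_offset_ms = 60,
                             rt_rise_ms = 50, rt_decay_ms = 80,
                             partial_rise_ms = 50, partial_decay_ms = 50,
                             plant_mirror = FALSE) {
  list(fs_hz = fs_hz, t0_ms = t0_ms, t_end_ms = t_end_ms,
       noise_sd = noise_sd, snr = snr, partial_amp_frac = partial_amp_frac,
       em_offset_ms = em_offset_ms, rt_rise_ms = rt_rise_ms,
       rt_decay_ms = rt_decay_ms, partial_rise_ms = partial_rise_ms,
       partial_decay_ms = partial_decay_ms, plant_mirror = plant_mirror)
}

# RT-burst amplitude window: 6 ms half-cosine rise to 0.85 (sharp onset),
# linear ramp to 1 at the peak, half-cosine decay to 0 at the offset
burst_window <- function(tt, onset, peak, offset, rise_ms = 6) {
  w <- numeric(length(tt))
  r_end <- min(onset + rise_ms, peak)
  i <- tt >= onset & tt < r_end
  w[i] <- 0.85 * 0.5 * (1 - cos(pi * (tt[i] - onset) / (r_end - onset)))
  i <- tt >= r_end & tt <= peak
  if (peak > r_end) {
    w[i] <- 0.85 + 0.15 * (tt[i] - r_end) / (peak - r_end)
  } else {
    w[i] <- 1
  }
  i <- tt > peak & tt <= offset
  w[i] <- 0.5 * (1 + cos(pi * (tt[i] - peak) / (offset - peak)))
  w
}

# symmetric raised-cosine window (partial bursts): envelope peak sits at
# the planted peak
cos_window <- function(tt, onset, peak, offset) {
  w <- numeric(length(tt))
  i <- tt >= onset & tt <= peak
  w[i] <- 0.5 * (1 - cos(pi * (tt[i] - onset) / (peak - onset)))
  i <- tt > peak & tt <= offset
  w[i] <- 0.5 * (1 + cos(pi * (tt[i] - peak) / (offset - peak)))
  w
}

#' Generate raw synthetic EMG for simulated trials
#'
#' Builds two-channel raw EMG for each row of a simulated behaviour
#' table, tying burst timing to the latent race outcome: every pressing
#' hand gets an RT-generating burst with onset `press - 60` ms; on
#' successful stops whose stop-over-go margin lies inside the
#' detectability window, a partial burst peaking at `ssd + t_stop` is
#' planted in each hand (skipped in the responding hand when it would
#' collide with the RT burst, i.e. when its offset would come within
#' 20 ms of the RT-burst onset). Baseline Gaussian noise is added
#' throughout.
#'
#' @param trials observed-trial table from [generate_behaviour()]
#'   (columns `condition`, `trial`, `stimulus`, `ssd_ms`, `response`,
#'   `rt_ms`, `left_press_ms`, `right_press_ms`, and `participant`).
#' @param latents row-matched latent table (columns `t_go`, `t_stop`,
#'   `margin_ms`, `stop_success`).
#' @param config settings from [emg_synth_config()].
#' @param window detectability window from [censoring_window()].
#' @param seed integer seed.
#' @return list with `traces` (list of [emg_trace()]) and `truth`
#'   (data.frame of planted bursts: participant, condition, trial, hand,
#'   kind, onset/peak/offset times, amplitude).
#' @export
synth_emg <- function(trials, latents, config = emg_synth_config(),
                      window = censoring_window(), seed = 1) {
  stopifnot(nrow(trials) == nrow(latents))
  set.seed(as.integer(seed))
  fs <- config$fs_hz
  nspl <- round((config$t_end_ms - config$t0_ms) / 1000 * fs) + 1
  tt <- config$t0_ms + (seq_len(nspl) - 1) / fs * 1000
  bf <- signal::butter(2, c(20, 500) / (fs / 2), type = "pass")
  carrier <- function() {
    x <- as.numeric(signal::filtfilt(bf, stats::rnorm(nspl)))
    x / stats::sd(x)
  }
  amp <- config$snr * config$noise_sd
  traces <- vector("list", nrow(trials))
  truth <- list()
  add_truth <- function(i, hand, kind, onset, peak, offset, a) {
    truth[[length(truth) + 1L]] <<- data.frame(
      participant = trials$participant[i], condition = trials$condition[i],
      trial = trials$trial[i], hand = hand, kind = kind,
      onset_ms = onset, peak_ms = peak, offset_ms = offset, amp = a,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(trials))) {
    ch <- list(left = stats::rnorm(nspl, 0, config$noise_sd),
               right = stats::rnorm(nspl, 0, config$noise_sd))
    plant <- function(hand, kind, onset, peak, offset, a,
                      shape = burst_window) {
      if (onset < tt[1] || offset > tt[nspl]) {
        stop("burst events lie outside the trace extent", call. = FALSE)
      }
      w <- shape(tt, onset, peak, offset)
      ch[[hand]] <<- ch[[hand]] + a * carrier() * w
      add_truth(i, hand, kind, onset, peak, offset, a)
    }
    presses <- c(left = trials$left_press_ms[i],
                 right = trials$right_press_ms[i])
    rt_onsets <- presses - config$em_offset_ms
    for (hand in c("left", "right")) {
      if (!is.na(presses[[hand]])) {
        onset <- rt_onsets[[hand]]
        plant(hand, "rt", onset, onset + config$rt_rise_ms,
              onset + config$rt_rise_ms + config$rt_decay_ms, amp)
      }
    }
    margin <- latents$margin_ms[i]
    if (isTRUE(latents$stop_success[i]) && !is.na(margin) &&
        margin >= window$lower_margin_ms && margin <= window$upper_margin_ms) {
      p_peak <- trials$ssd_ms[i] + latents$t_stop[i]
      p_onset <- p_peak - config$partial_rise_ms
      p_off <- p_peak + config$partial_decay_ms
      p_amp <- config$partial_amp_frac * amp
      resp_hand <- if (trials$response[i] == "LR") "left" else "right"
      stop_hand <- setdiff(c("left", "right"), resp_hand)
      rt_on <- rt_onsets[[resp_hand]]
      # plant only partials that are classifiable under the model's
      # assumptions: the cancelled burst must peak before the new
      # response's EMG commences
      classifiable <- is.na(rt_on) || p_peak + 10 <= rt_on
      if (classifiable) {
        plant(stop_hand, "partial", p_onset, p_peak, p_off, p_amp,
              shape = cos_window)
        if (is.na(rt_on) || p_off + 25 <= rt_on) {
          plant(resp_hand, "partial", p_onset, p_peak, p_off, p_amp,
                shape = cos_window)
        }
      }
    }
    if (isTRUE(config$plant_mirror) && isTRUE(latents$stop_success[i]) &&
        !is.na(trials$rt_ms[i])) {
      resp_hand <- if (trials$response[i] == "LR") "left" else "right"
      stop_hand <- setdiff(c("left", "right"), resp_hand)
      m_onset <- rt_onsets[[resp_hand]] + 10
      plant(stop_hand, "mirror", m_onset, m_onset + 40, m_onset + 100,
            0.5 * amp)
    }
    traces[[i]] <- emg_trace(
      ch$left, ch$right, fs_hz = fs, t0_ms = config$t0_ms,
      go_time_ms = 0, stop_time_ms = trials$ssd_ms[i],
      press_left_ms = presses[["left"]], press_right_ms = presses[["right"]],
      participant = trials$participant[i], trial = trials$trial[i])
  }
  list(traces = traces,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(participant = numeric(0), condition = character(0),
                    trial = numeric(0), hand = character(0),
                    kind = character(0), onset_ms = numeric(0),
                    peak_ms = numeric(0), offset_ms = numeric(0),
                    amp = numeric(0)))
}

#' Extract EMG features for a set of trials
#'
#' Runs the full pipeline -- band-pass, burst detection, envelope,
#' per-participant normalisation to the mean successful reactive bi-go
#' peak, RT-burst and partial-burst identification, CancelTime -- over a
#' list of traces and their behaviour rows.
#'
#' @param traces list of [emg_trace()] objects.
#' @param trials row-matched behaviour table (`stimulus`, `condition`,
#'   `response`, `rt_ms`, `ssd_ms`, per-hand presses, `participant`,
#'   `trial`).
#' @param ... passed to [detect_bursts()].
#' @return list with `features` (one row per trial x hand: burst onsets,
#'   peaks, normalised amplitudes, `cancel_time_ms`), and
#'   `reference_peaks` per participant.
#' @export
extract_emg_features <- function(traces, trials, ...) {
  stopifnot(length(traces) == nrow(trials))
  stop_trial <- trials$stimulus != "DS"
  correct <- ifelse(trials$stimulus == "LS", "LR",
                    ifelse(trials$stimulus == "RS", "RR", "DR"))
  success_stop <- stop_trial & trials$response == correct
  filt <- lapply(traces, emg_bandpass)
  envs <- lapply(filt, emg_envelope)
  # per-participant normalisation reference: successful reactive bi-go
  ref_peak <- numeric(0)
  for (p in unique(trials$participant)) {
    ref_idx <- which(trials$participant == p & trials$stimulus == "DS" &
                       trials$response == "DR" &
                       trials$condition == "reactive")
    if (!length(ref_idx)) {
      stop("participant ", p, " has no successful reactive bi-go trials ",
           "to normalise against", call. = FALSE)
    }
    peaks <- vapply(ref_idx, function(i) {
      max(envs[[i]]$left, envs[[i]]$right)
    }, numeric(1))
    ref_peak[as.character(p)] <- mean(peaks)
  }
  rows <- list()
  for (i in seq_along(traces)) {
    tr <- filt[[i]]
    ref <- ref_peak[[as.character(trials$participant[i])]]
    hands <- list(left = trials$left_press_ms[i],
                  right = trials$right_press_ms[i])
    bursts <- lapply(c(left = "left", right = "right"), function(h) {
      b <- detect_bursts(tr[[h]], fs_hz = tr$fs_hz, t0_ms = tr$t0_ms, ...)
      burst_peaks(b, envs[[i]][[h]], fs_hz = tr$fs_hz, t0_ms = tr$t0_ms)
    })
    rt_bursts <- lapply(c(left = "left", right = "right"), function(h) {
      if (is.na(hands[[h]])) return(NULL)
      find_rt_burst(bursts[[h]], rt_ms = hands[[h]],
                    go_time_ms = tr$go_time_ms)
    })
    resp_hand <- if (trials$response[i] == "LR") "left"
                 else if (trials$response[i] == "RR") "right" else NA
    resp_rt_onset <- if (!is.na(resp_hand) && !is.null(rt_bursts[[resp_hand]]))
      rt_bursts[[resp_hand]]$onset_ms else Inf
    for (h in c("left", "right")) {
      rb <- rt_bursts[[h]]
      pb <- NULL
      if (success_stop[i]) {
        pb <- find_partial_burst(bursts[[h]], ssd_ms = trials$ssd_ms[i],
                                 rt_burst_onset_ms = resp_rt_onset,
                                 reference_peak = ref, stop_success = TRUE,
                                 go_time_ms = tr$go_time_ms)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant = trials$participant[i], condition = trials$condition[i],
        trial = trials$trial[i], hand = h, stimulus = trials$stimulus[i],
        response = trials$response[i], ssd_ms = trials$ssd_ms[i],
        rt_ms = trials$rt_ms[i],
        n_bursts = nrow(bursts[[h]]),
        rt_onset_ms = if (!is.null(rb)) rb$onset_ms else NA_real_,
        rt_peak_ms = if (!is.null(rb)) rb$peak_time_ms else NA_real_,
        rt_peak_norm = if (!is.null(rb)) rb$peak_amp / ref else NA_real_,
        partial_onset_ms = if (!is.null(pb)) pb$onset_ms else NA_real_,
        partial_peak_ms = if (!is.null(pb)) pb$peak_time_ms else NA_real_,
        partial_peak_norm = if (!is.null(pb)) pb$peak_amp / ref else NA_real_,
        cancel_time_ms = if (!is.null(pb))
          cancel_time(pb, trials$ssd_ms[i]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(features = do.call(rbind, rows), reference_peaks = ref_peak)
}
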