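#' EMG trace container
#'
#' A two-channel (left/right first dorsal interosseous) EMG recording
#' for one trial, with event markers on the trial clock: all times are
#' in ms relative to go onset, and the trace starts at `t0_ms`
#' (typically negative, covering the pre-go baseline).
#'
#' @param left,right channel samples in mV (equal length).
#' @param fs_hz sampling rate (2000 Hz default).
#' @param t0_ms time of the first sample relative to go onset.
#' @param go_time_ms go onset (0 by convention).
#' @param stop_time_ms stop-signal time (SSD) or `NA` on go trials.
#' @param press_left_ms,press_right_ms button-press times or `NA`.
#' @param participant,trial identifiers.
#' @return an `emg_trace` object.
#' @export
emg_trace <- function(left, right, fs_hz = 2000, t0_ms = -300,
                      go_time_ms = 0, stop_time_ms = NA,
                      press_left_ms = NA, press_right_ms = NA,
                      participant = NA, trial = NA) {
  stopifnot(length(left) == length(right), fs_hz > 0)
  t_end <- t0_ms + (length(left) - 1) / fs_hz * 1000
  for (m in c(go_time_ms, stop_time_ms, press_left_ms, press_right_ms)) {
    if (!is.na(m) && (m < t0_ms || m > t_end)) {
      stop("event marker at ", m, " ms lies outside the trace extent [",
           t0_ms, ", ", round(t_end, 1), "]", call. = FALSE)
    }
  }
  structure(list(left = left, right = right, fs_hz = fs_hz, t0_ms = t0_ms,
                 go_time_ms = go_time_ms, stop_time_ms = stop_time_ms,
                 press_left_ms = press_left_ms, press_right_ms = press_right_ms,
                 participant = participant, trial = trial),
            class = "emg_trace")
}

#' EMG signal conditioning
#'
#' `emg_bandpass()` applies a zero-phase (forward-backward) 4th-order
#' Butterworth band-pass at 20-500 Hz to each channel, removing DC and
#' movement artefact below the passband. `emg_envelope()` full-wave
#' rectifies a (filtered) channel and low-pass filters it at 10 Hz,
#' again zero-phase, yielding the non-negative envelope used for all
#' amplitude and peak-time measures.
#'
#' @param x an `emg_trace` (band-pass) or numeric channel (envelope).
#' @param fs_hz sampling rate, required when `x` is a plain vector.
#' @param band passband edges in Hz.
#' @return same shape as the input: filtered `emg_trace`, or envelope
#'   vector.
#' @export
emg_bandpass <- function(x, band = c(20, 500), fs_hz = NULL) {
  if (inherits(x, "emg_trace")) {
    x$left <- emg_bandpass(x$left, band, x$fs_hz)
    x$right <- emg_bandpass(x$right, band, x$fs_hz)
    return(x)
  }
  if (is.null(fs_hz)) stop("fs_hz required for vector input", call. = FALSE)
  if (fs_hz <= 2 * band[2]) {
    stop("sampling rate ", fs_hz, " Hz cannot support a ", band[2],
         " Hz cutoff (need fs > 2 x high cutoff)", call. = FALSE)
  }
  # order 2 per band edge = 4th-order band-pass
  bf <- signal::butter(2, band / (fs_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' @rdname emg_bandpass
#' @param cutoff_hz envelope low-pass cutoff.
#' @export
emg_envelope <- function(x, cutoff_hz = 10, fs_hz = NULL) {
  if (inherits(x, "emg_trace")) {
    return(list(left = emg_envelope(x$left, cutoff_hz, x$fs_hz),
                right = emg_envelope(x$right, cutoff_hz, x$fs_hz)))
  }
  if (is.null(fs_hz)) stop("fs_hz required for vector input", call. = FALSE)
  bf <- signal::butter(2, cutoff_hz / (fs_hz / 2), type = "low")
  env <- as.numeric(signal::filtfilt(bf, abs(x)))
  pmax(env, 0)
}

#' Single-threshold EMG burst detection
#'
#' The quietest 500 ms segment of the rectified channel (minimum RMS,
#' sliding one sample at a time, earliest window on ties) defines the
#' baseline; the detection threshold is `baseline mean + 3 SD` of the
#' rectified baseline samples. Supra-threshold samples are clustered by
#' merging gaps shorter than `merge_gap_ms` (20 ms); within each
#' cluster, the onset is the first supra-threshold sample followed by
#' sustained activity (occupancy of at least `occupancy` over the next
#' 10 ms) and the offset is the last preceded by sustained activity, so
#' isolated noise spikes adjacent to a burst do not drag its onset.
#' Clusters with no sustained activity or spanning less than
#' `min_duration_ms` are discarded. Detection is invariant to positive
#' rescaling of the trace.
#'
#' @param x numeric channel (band-pass filtered), in trace order.
#' @param fs_hz sampling rate.
#' @param t0_ms time of the first sample (ms from go onset).
#' @param baseline_ms baseline window length (500 ms).
#' @param threshold_sd threshold in baseline SDs above the baseline mean.
#' @param merge_gap_ms bursts separated by less than this are merged.
#' @param min_duration_ms minimum burst span.
#' @param occupancy minimum supra-threshold fraction over the 10 ms
#'   after an onset candidate.
#' @return data.frame with `onset_ms`, `offset_ms` (threshold crossings
#'   on the raw rectified signal), one row per burst.
#' @export
detect_bursts <- function(x, fs_hz = 2000, t0_ms = 0, baseline_ms = 500,
                          threshold_sd = 3, merge_gap_ms = 20,
                          min_duration_ms = 10, occupancy = 0.4) {
  n <- length(x)
  w <- round(baseline_ms / 1000 * fs_hz)
  if (n < w) {
    stop("trace (", round(n / fs_hz * 1000), " ms) is shorter than the ",
         baseline_ms, " ms baseline window", call. = FALSE)
  }
  r <- abs(x)
  # running RMS over the baseline window; earliest minimum wins
  cs <- cumsum(c(0, r^2))
  ms2 <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  b0 <- which.min(ms2)
  base <- r[b0:(b0 + w - 1)]
  thr <- mean(base) + threshold_sd * stats::sd(base)
  supra <- r > thr
  if (!any(supra)) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0)))
  }
  gap <- round(merge_gap_ms / 1000 * fs_hz)
  occ_w <- round(10 / 1000 * fs_hz)
  idx <- which(supra)
  # cluster supra samples: gaps < merge_gap start a new cluster
  brk <- c(0, which(diff(idx) >= gap), length(idx))
  out <- list()
  occ <- c(cumsum(supra), rep(base::sum(supra), occ_w))
  fwd_occ <- function(i) (occ[min(i + occ_w, n)] - occ[i] + supra[i]) / occ_w
  bwd_occ <- function(i) (occ[i] - occ[max(i - occ_w, 1)]) / occ_w
  for (b in seq_len(length(brk) - 1)) {
    cl <- idx[(brk[b] + 1):brk[b + 1]]
    on_cand <- cl[vapply(cl, fwd_occ, numeric(1)) >= occupancy]
    off_cand <- cl[vapply(cl, bwd_occ, numeric(1)) >= occupancy]
    if (!length(on_cand) || !length(off_cand)) next
    onset <- on_cand[1]; offset <- max(off_cand)
    if ((offset - onset) / fs_hz * 1000 < min_duration_ms) next
    out[[length(out) + 1L]] <- c(onset, offset)
  }
  if (!length(out)) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0)))
  }
  m <- do.call(rbind, out)
  data.frame(onset_ms = t0_ms + (m[, 1] - 1) / fs_hz * 1000,
             offset_ms = t0_ms + (m[, 2] - 1) / fs_hz * 1000)
}

#' Annotate bursts with envelope peaks
#'
#' The peak of a burst is the maximum of the EMG envelope within the
#' burst's raw-threshold onset/offset span.
#'
#' @param bursts data.frame from [detect_bursts()].
#' @param envelope envelope samples for the same channel.
#' @param fs_hz,t0_ms sampling rate and first-sample time.
#' @return `bursts` with `peak_time_ms` and `peak_amp` columns.
#' @export
burst_peaks <- function(bursts, envelope, fs_hz = 2000, t0_ms = 0) {
  n <- length(envelope)
  bursts$peak_time_ms <- rep(NA_real_, nrow(bursts))
  bursts$peak_amp <- rep(NA_real_, nrow(bursts))
  for (j in seq_len(nrow(bursts))) {
    i0 <- max(1, round((bursts$onset_ms[j] - t0_ms) / 1000 * fs_hz) + 1)
    i1 <- min(n, round((bursts$offset_ms[j] - t0_ms) / 1000 * fs_hz) + 1)
    seg <- envelope[i0:i1]
    pk <- which.max(seg)
    bursts$peak_time_ms[j] <- t0_ms + (i0 + pk - 2) / fs_hz * 1000
    bursts$peak_amp[j] <- seg[pk]
  }
  bursts
}

#' Identify the RT-generating burst
#'
#' The burst that produced the overt button press: the last burst whose
#' onset falls after the go signal and at least 50 ms before the
#' response time.
#'
#' @param bursts data.frame of bursts for one hand (times in ms from go
#'   onset).
#' @param rt_ms the hand's press time (ms from go onset).
#' @param go_time_ms go onset (0 by convention).
#' @param min_lead_ms minimum onset-to-press lead (50 ms).
#' @return the qualifying burst row, or `NULL` if none qualifies.
#' @export
find_rt_burst <- function(bursts, rt_ms, go_time_ms = 0, min_lead_ms = 50) {
  ok <- bursts$onset_ms > go_time_ms & bursts$onset_ms <= rt_ms - min_lead_ms
  if (!any(ok)) return(NULL)
  bursts[max(which(ok)), , drop = FALSE]
}

#' Identify the partial (cancelled) burst on a successful stop trial
#'
#' The earliest burst satisfying all four constraints: (i) onset after
#' the go signal; (ii) envelope peak after the stop signal (inhibition
#' responds to the stop signal); (iii) envelope peak before the onset of
#' the responding hand's RT-generating burst (excludes mirror/spurious
#' activity accompanying or following the new response); and (iv) peak
#' amplitude above 10% of the participant's average successful bi-go
#' peak (excludes negligible bursts).
#'
#' @param bursts data.frame of bursts with peak annotations (one hand).
#' @param ssd_ms stop-signal delay (ms from go onset).
#' @param rt_burst_onset_ms onset of the responding hand's RT-generating
#'   burst; `Inf` if no RT burst was found.
#' @param reference_peak the participant's mean successful bi-go
#'   envelope peak, in the same units as `peak_amp`.
#' @param stop_success partial bursts are only defined on successful
#'   stop trials; passing `FALSE` is an error.
#' @param go_time_ms go onset.
#' @param min_amp_frac amplitude constraint as a fraction of
#'   `reference_peak`.
#' @return the qualifying burst row, or `NULL`.
#' @export
find_partial_burst <- function(bursts, ssd_ms, rt_burst_onset_ms,
                               reference_peak, stop_success = TRUE,
                               go_time_ms = 0, min_amp_frac = 0.1) {
  if (!isTRUE(stop_success)) {
    stop("partial bursts are only assessed on successful stop trials",
         call. = FALSE)
  }
  if (is.null(rt_burst_onset_ms) || is.na(rt_burst_onset_ms)) {
    rt_burst_onset_ms <- Inf
  }
  ok <- bursts$onset_ms > go_time_ms &
    bursts$peak_time_ms > ssd_ms &
    bursts$peak_time_ms < rt_burst_onset_ms &
    bursts$peak_amp > min_amp_frac * reference_peak
  if (!any(ok)) return(NULL)
  bursts[which(ok)[1], , drop = FALSE]
}

#' EMG CancelTime
#'
#' The latency from the stop signal to the peak of the partial burst: a
#' single-trial EMG proxy for the latency of the stopping process.
#'
#' @param partial a burst row with `peak_time_ms` (ms from go onset).
#' @param ssd_ms stop-signal delay.
#' @return CancelTime in ms (strictly positive by constraint (ii)).
#' @export
cancel_time <- function(partial, ssd_ms) {
  stopifnot(!is.null(partial), nrow(partial) == 1)
  partial$peak_time_ms - ssd_ms
}

#' Normalise envelopes to the mean successful bi-go peak
#'
#' The participant's reference peak is the mean of the per-trial
#' envelope maxima over a reference set of trials (successful bimanual
#' go trials from the reactive condition); all envelopes are divided by
#' it, so the reference set's mean normalised peak is exactly 1 and the
#' normalisation is invariant to rescaling the raw recordings.
#'
#' @param envelopes list of numeric envelope vectors (one per trial, or
#'   per trial x hand).
#' @param reference_idx indices into `envelopes` of the reference trials.
#' @return list with `envelopes` (normalised) and `reference_peak`.
#' @export
normalize_envelopes <- function(envelopes, reference_idx) {
  if (!length(reference_idx)) {
    stop("empty reference set: at least one successful reactive bi-go ",
         "trial is required for normalisation", call. = FALSE)
  }
  peaks <- vapply(envelopes[reference_idx], max, numeric(1))
  ref <- mean(peaks)
  list(envelopes = lapply(envelopes, function(e) e / ref),
       reference_peak = ref)
}

#' Across-participant average EMG profiles
#'
#' Aligns each trial's normalised envelope to a chosen reference (go
#' onset, stop signal, EMG onset of the RT-generating burst, or its
#' peak), averages within participant, then across participants, with a
#' pointwise t-based 95% confidence interval. Trials whose alignment
#' reference is missing are skipped (with a message).
#'
#' @param trials list of per-trial records: each a list with `envelope`
#'   (numeric), `fs_hz`, `t0_ms`, `participant`, and reference times
#'   `go_ms`, `stop_ms`, `emg_onset_ms`, `peak_ms` (any may be `NA`).
#' @param alignment one of `"go"`, `"stop"`, `"emg_onset"`, `"peak"`.
#' @param window_ms time window around the reference (default
#'   `c(-200, 500)`).
#' @return data.frame with `time_ms`, `mean`, `lower`, `upper`, `n`
#'   (participants contributing).
#' @export
average_profiles <- function(trials, alignment = c("go", "stop",
                                                   "emg_onset", "peak"),
                             window_ms = c(-200, 500)) {
  alignment <- match.arg(alignment)
  ref_field <- c(go = "go_ms", stop = "stop_ms",
                 emg_onset = "emg_onset_ms", peak = "peak_ms")[[alignment]]
  fs <- trials[[1]]$fs_hz
  grid <- seq(window_ms[1], window_ms[2], by = 1000 / fs)
  part <- vapply(trials, function(tr) tr$participant, numeric(1))
  skipped <- 0L
  rows <- list()
  for (tr in trials) {
    ref <- tr[[ref_field]]
    if (is.null(ref) || is.na(ref)) { skipped <- skipped + 1L; next }
    tt <- tr$t0_ms + (seq_along(tr$envelope) - 1) / tr$fs_hz * 1000 - ref
    rows[[length(rows) + 1L]] <- list(
      participant = tr$participant,
      y = stats::approx(tt, tr$envelope, xout = grid, rule = 1)$y)
  }
  if (skipped > 0) {
    message(skipped, " trial(s) skipped: missing '", alignment,
            "' alignment reference")
  }
  if (length(unique(vapply(rows, `[[`, numeric(1), "participant"))) < 2) {
    stop("profile averaging needs trials from at least 2 participants",
         call. = FALSE)
  }
  ids <- unique(vapply(rows, `[[`, numeric(1), "participant"))
  pmeans <- vapply(ids, function(id) {
    ys <- do.call(rbind, lapply(rows[vapply(rows, `[[`, numeric(1),
                                            "participant") == id],
                                `[[`, "y"))
    colMeans(ys, na.rm = TRUE)
  }, numeric(length(grid)))
  m <- rowMeans(pmeans, na.rm = TRUE)
  nn <- rowSums(!is.na(pmeans))
  se <- apply(pmeans, 1, stats::sd, na.rm = TRUE) / sqrt(nn)
  tq <- stats::qt(0.975, pmax(nn - 1, 1))
  data.frame(time_ms = grid, mean = m,
             lower = m - tq * se, upper = m + tq * se, n = nn)
}
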