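test_that("band-pass attenuates out-of-band tones and passes in-band", {
  fs <- 2000
  t <- (0:7999) / fs
  amp_ratio <- function(f) {
    x <- sin(2 * pi * f * t)
    y <- emg_bandpass(x, fs_hz = fs)
    # steady-state amplitude away from the edges
    mid <- 2000:6000
    max(abs(y[mid])) / 1
  }
  expect_lt(20 * log10(amp_ratio(5)), -20)     # below passband
  expect_gt(20 * log10(amp_ratio(100)), -1)    # in passband
  # band-limiting reduces white-noise power
  set.seed(2)
  x <- rnorm(8000)
  expect_lt(sd(emg_bandpass(x, fs_hz = fs)), sd(x))
  expect_error(emg_bandpass(x, fs_hz = 900), "cutoff")
})

test_that("envelope is rectification-symmetric and recovers 2a/pi plateaus", {
  fs <- 2000
  x <- numeric(4000)
  t <- (0:3999) / fs
  seg <- t >= 0.5 & t <= 1.5
  a <- 0.8
  x[seg] <- a * sin(2 * pi * 150 * t[seg])
  env <- emg_envelope(x, fs_hz = fs)
  expect_true(all(env >= 0))
  # plateau of the rectified sine = 2a/pi
  plateau <- mean(env[t >= 0.8 & t <= 1.2])
  expect_equal(plateau, 2 * a / pi, tolerance = 0.1 * 2 * a / pi)
  expect_equal(emg_envelope(-x, fs_hz = fs), env)
  expect_equal(emg_envelope(numeric(4000), fs_hz = fs), numeric(4000))
})

test_that("burst detection finds planted tone bursts with accurate onsets", {
  tr <- tone_trace(bursts = list(c(300, 450)), seed = 4)
  b <- detect_bursts(tr$x, fs_hz = 2000, t0_ms = 0)
  expect_equal(nrow(b), 1)
  expect_lt(abs(b$onset_ms - 300), 5)
  expect_lt(abs(b$offset_ms - 450), 10)
  # detection is invariant to positive rescaling
  b5 <- detect_bursts(5 * tr$x, fs_hz = 2000, t0_ms = 0)
  expect_equal(b, b5)
})

test_that("bursts separated by less than 20 ms merge; larger gaps do not", {
  tr1 <- tone_trace(bursts = list(c(100, 150), c(160, 200)), seed = 5)
  b1 <- detect_bursts(tr1$x, fs_hz = 2000, t0_ms = 0)
  expect_equal(nrow(b1), 1)
  expect_lt(abs(b1$onset_ms - 100), 5)
  expect_lt(abs(b1$offset_ms - 200), 10)
  tr2 <- tone_trace(bursts = list(c(100, 150), c(175, 200)), seed = 5)
  b2 <- detect_bursts(tr2$x, fs_hz = 2000, t0_ms = 0)
  expect_equal(nrow(b2), 2)
})

test_that("noise-only traces yield no bursts; short traces error", {
  for (s in 1:5) {
    tr <- tone_trace(bursts = list(), seed = 100 + s)
    expect_equal(nrow(detect_bursts(tr$x, fs_hz = 2000)), 0)
  }
  expect_error(detect_bursts(rnorm(400), fs_hz = 2000), "baseline")
})

test_that("RT-generating burst is the last qualifying burst", {
  bursts <- data.frame(onset_ms = c(-50, 250, 380, 400),
                       offset_ms = c(-10, 300, 395, 425))
  rb <- find_rt_burst(bursts, rt_ms = 430)
  expect_equal(rb$onset_ms, 380)      # last with onset <= 430 - 50
  # a burst starting less than 50 ms before the press does not qualify
  expect_null(find_rt_burst(data.frame(onset_ms = 400, offset_ms = 425),
                            rt_ms = 430))
  # bursts before the go signal are excluded
  expect_null(find_rt_burst(data.frame(onset_ms = -50, offset_ms = -10),
                            rt_ms = 430))
})

test_that("partial-burst constraints enforce the model's timing assumptions", {
  base <- data.frame(onset_ms = 150, offset_ms = 260, peak_time_ms = 180,
                     peak_amp = 0.5)
  # (ii) peak must follow the stop signal
  expect_null(find_partial_burst(base, ssd_ms = 200,
                                 rt_burst_onset_ms = 470,
                                 reference_peak = 1))
  # (iii) peak must precede the responding hand's RT-burst onset
  late <- transform(base, peak_time_ms = 500, offset_ms = 520)
  expect_null(find_partial_burst(late, ssd_ms = 200,
                                 rt_burst_onset_ms = 470,
                                 reference_peak = 1))
  # (iv) negligible amplitudes are excluded
  weak <- transform(base, peak_time_ms = 230, peak_amp = 0.05)
  expect_null(find_partial_burst(weak, ssd_ms = 200,
                                 rt_burst_onset_ms = 470,
                                 reference_peak = 1))
  # earliest qualifying burst wins
  two <- data.frame(onset_ms = c(150, 200), offset_ms = c(260, 300),
                    peak_time_ms = c(230, 280), peak_amp = c(0.5, 0.6))
  pb <- find_partial_burst(two, ssd_ms = 200, rt_burst_onset_ms = 470,
                           reference_peak = 1)
  expect_equal(pb$peak_time_ms, 230)
  expect_equal(cancel_time(pb, 200), 30)
  expect_error(find_partial_burst(two, 200, 470, 1, stop_success = FALSE),
               "successful stop")
})

test_that("normalisation uses the mean reference peak and is scale-free", {
  envs <- list(c(0, 0.4, 0), c(0, 0.6, 0), c(0, 0.5, 0))
  nm <- normalize_envelopes(envs, reference_idx = 1:2)
  expect_equal(nm$reference_peak, 0.5)
  expect_equal(max(nm$envelopes[[3]]), 1)
  # mean normalised reference peak is exactly 1
  expect_equal(mean(vapply(nm$envelopes[1:2], max, numeric(1))), 1)
  nm2 <- normalize_envelopes(lapply(envs, `*`, 2), reference_idx = 1:2)
  expect_equal(nm2$envelopes, nm$envelopes)
  # single reference trial normalises itself to 1
  nm3 <- normalize_envelopes(envs, reference_idx = 2)
  expect_equal(max(nm3$envelopes[[2]]), 1)
  expect_error(normalize_envelopes(envs, integer(0)), "reference")
})

test_that("profile averaging aligns, averages and bounds correctly", {
  fs <- 2000
  shape <- exp(-((0:999) / fs * 1000 - 250)^2 / (2 * 40^2))
  mk <- function(participant, shift) {
    list(envelope = c(numeric(shift), shape)[1:1000], fs_hz = fs, t0_ms = 0,
         participant = participant, go_ms = 0, stop_ms = NA,
         emg_onset_ms = NA, peak_ms = 250 + shift / fs * 1000)
  }
  trials <- list(mk(1, 0), mk(1, 100), mk(2, 50), mk(2, 150))
  # peak-aligned averaging of shifted copies recovers the common shape
  pk <- average_profiles(trials, "peak", window_ms = c(-100, 100))
  expect_equal(max(pk$mean), 1, tolerance = 1e-6)
  expect_true(all(pk$upper - pk$lower < 1e-6))   # identical profiles: CI 0
  # go-aligned averaging of jittered bursts has a lower peak
  go <- average_profiles(trials, "go", window_ms = c(0, 400))
  expect_lt(max(go$mean), max(pk$mean))
  # missing alignment references skip trials with a log message
  trials[[1]]$peak_ms <- NA
  expect_message(average_profiles(trials, "peak", window_ms = c(-100, 100)),
                 "skipped")
})
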