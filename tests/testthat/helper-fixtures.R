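# shared fixtures: small parameter sets and a memoised tiny hierarchical
# fit reused across test files

study_scale_params <- function(gf = 0, tf = 0, eps_wrong = 0) {
  sis_params(
    dual_go = list(reactive = runner_params(380, 50, 70),
                   proactive = runner_params(410, 50, 70)),
    dual_stop = runner_params(150, 30, 50),
    sel_left = list(reactive = runner_params(256, 40, 60),
                    proactive = runner_params(229, 40, 60)),
    sel_right = list(reactive = runner_params(256, 40, 60),
                     proactive = runner_params(229, 40, 60)),
    gf = gf, tf = tf, eps_wrong = eps_wrong)
}

.fixture_env <- new.env(parent = emptyenv())

tiny_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  co <- sample_group(group_truth(), n_subjects = 2, seed = 301)
  bhv <- generate_behaviour(co, design = study_design(trials_per_condition = 36),
                            seed = 302)
  d <- bhv$trials[, c("participant", "condition", "trial", "stimulus",
                      "ssd_ms", "response", "rt_ms")]
  fit <- fit_sis(d, variant = 1, seed = 303,
                 sampler = list(ind_iterations = 15, window = 20,
                                max_windows = 1, retain = 60))
  .fixture_env$fit <- fit
  fit
}

# plant a pure tone burst in Gaussian noise (sharp onset/offset)
tone_trace <- function(n_ms = 1500, fs = 2000, bursts = list(),
                       noise_sd = 0.02, snr = 10, freq = 150, seed = 1) {
  set.seed(seed)
  n <- round(n_ms / 1000 * fs)
  tt <- (seq_len(n) - 1) / fs * 1000
  x <- stats::rnorm(n, 0, noise_sd)
  for (b in bursts) {
    i <- tt >= b[1] & tt <= b[2]
    x[i] <- x[i] + snr * noise_sd * sin(2 * pi * freq * tt[i] / 1000)
  }
  list(x = x, t = tt)
}
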