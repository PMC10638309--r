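make_trials <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

test_that("participants are excluded below a 25% stop-success rate", {
  d <- make_trials(
    participant = rep(c(1, 2, 3), each = 8),
    condition = "reactive",
    stimulus = rep(c("DS", "LS", "LS", "LS", "LS", "RS", "RS", "RS"), 3),
    response = c("DR", "LR", "DR", "DR", "DR", "DR", "DR", "DR",   # 1/7 correct
                 "DR", "LR", "LR", "DR", "DR", "RR", "DR", "DR",   # 3/7 correct
                 "DR", "LR", "LR", "LR", "LR", "RR", "RR", "RR")   # 7/7 correct
  )
  # participant 1: 14% stop success -> excluded; 2 and 3 retained
  out <- exclude_participants(d)
  expect_true(out$report$excluded[out$report$participant == "1"])
  expect_false(out$report$excluded[out$report$participant == "3"])
  expect_false("1" %in% unique(out$data$participant))
  # boundary: exactly 25% is retained (strict inequality)
  d2 <- make_trials(
    participant = 9, condition = "reactive",
    stimulus = c("DS", "LS", "LS", "LS", "LS"),
    response = c("DR", "LR", "DR", "DR", "DR"))
  out2 <- exclude_participants(d2)
  expect_equal(out2$report$stop_success_rate, 0.25)
  expect_false(out2$report$excluded)
  # no exclusions leaves the dataset unchanged; the operation is idempotent
  out3 <- exclude_participants(out$data)
  expect_identical(out3$data, out$data)
})

test_that("bimanual simultaneity cleaning drops, averages and is idempotent", {
  d <- make_trials(
    participant = 1, condition = "reactive", stimulus = "DS",
    response = "DR", rt_ms = NA,
    left_press_ms = c(430, 430, 430), right_press_ms = c(500, 450, 480))
  out <- clean_bimanual(d)
  expect_equal(nrow(out$data), 2)              # 70 ms gap removed
  expect_equal(out$data$rt_ms, c(440, 455))    # averaged; 50 ms kept
  expect_equal(out$report$n_removed, 1)
  out2 <- clean_bimanual(out$data)
  expect_identical(out2$data, out$data)
  expect_equal(out2$report$n_removed, 0)
  bad <- make_trials(participant = 1, condition = "reactive",
                     stimulus = "DS", response = "DR", rt_ms = NA,
                     left_press_ms = 430, right_press_ms = NA)
  expect_error(clean_bimanual(bad), "inconsistent")
})

test_that("fast guesses are flagged strictly below 100 ms relative RT", {
  d <- make_trials(
    participant = 1, condition = c("reactive", "reactive", "proactive"),
    stimulus = "LS", response = "LR",
    rt_ms = c(350, 370, 500), ssd_ms = c(270, 270, 300))
  out <- flag_fast_guesses(d)
  expect_equal(out$data$fast_guess, c(TRUE, FALSE, FALSE))  # 80, 100, 200
  expect_equal(out$report$fast_guess[out$report$condition == "reactive"], 1)
})

test_that("subject summaries implement the derived-measure definitions", {
  d <- make_trials(
    participant = 1,
    condition = rep(c("reactive", "proactive"), each = 4),
    stimulus = c("DS", "DS", "LS", "RS", "DS", "DS", "LS", "RS"),
    response = c("DR", "DR", "LR", "RR", "DR", "DR", "LR", "RR"),
    rt_ms = c(440, 460, 550, 560, 470, 490, 555, 545),
    ssd_ms = c(NA, NA, 260, 280, NA, NA, 280, 260))
  s <- summarize_subject(d)
  rea <- s[s$condition == "reactive", ]
  expect_equal(rea$go_rt_ms, 450)
  expect_equal(rea$stop_rt_ms, 555)
  expect_equal(rea$stopping_delay_ms, 105)
  expect_equal(rea$relative_rt_ms, mean(c(550 - 260, 560 - 280)))  # 285
  expect_equal(unique(s$proactive_slowing_ms), 480 - 450)
  # absent fields stay NA rather than zero
  d2 <- d[d$stimulus == "DS", ]
  s2 <- summarize_subject(d2)
  expect_true(all(is.na(s2$stop_rt_ms)))
  expect_true(all(is.na(s2$relative_rt_ms)))
})

test_that("summaries recover the generating structure from the simulator", {
  co <- list(study_scale_params(), study_scale_params())
  bhv <- generate_behaviour(co, design = study_design(trials_per_condition = 432),
                            seed = 41)
  s <- summarize_subject(bhv$trials)
  agg <- function(cn, col) mean(s[[col]][s$condition == cn])
  # stopping delay ~ (SSD on successful stops + selective mean) - dual-go
  # mean; the staircase makes SSD and stop success anti-correlated, so
  # the SSD average must be taken over the successful subset
  d <- bhv$trials
  succ <- d$stimulus != "DS" &
    d$response == ifelse(d$stimulus == "LS", "LR", "RR")
  exp_delay_rea <- mean(d$ssd_ms[succ & d$condition == "reactive"]) +
    316 - 450
  expect_lt(abs(agg("reactive", "stopping_delay_ms") - exp_delay_rea), 15)
  # relative RT tracks the selective runner running time
  expect_lt(abs(agg("reactive", "relative_rt_ms") - 316), 12)
  expect_lt(abs(agg("proactive", "relative_rt_ms") - 289), 12)
  # proactive slowing tracks the dual-go difference (+30 ms)
  expect_lt(abs(mean(s$proactive_slowing_ms) - 30), 12)
  # staircase keeps successes near half
  expect_lt(abs(agg("reactive", "stop_success_rate") - 0.5), 0.08)
})

test_that("EMG-derived summary fields follow their definitions", {
  # 4 successful stops; partials on 1 of them (25%); known CancelTimes
  d <- make_trials(
    participant = 1, condition = "reactive",
    stimulus = c("DS", "LS", "LS", "RS", "RS"),
    response = c("DR", "LR", "LR", "RR", "RR"),
    rt_ms = c(450, 540, 560, 530, 550),
    ssd_ms = c(NA, 250, 260, 240, 250))
  emg <- data.frame(
    participant = 1, condition = "reactive",
    trial = rep(0:4, each = 2),
    hand = rep(c("left", "right"), 5),
    stimulus = rep(d$stimulus, each = 2),
    response = rep(d$response, each = 2),
    ssd_ms = rep(d$ssd_ms, each = 2),
    rt_ms = rep(d$rt_ms, each = 2),
    n_bursts = 1,
    rt_onset_ms = c(390, 392, 470, NA, 490, NA, NA, 460, NA, 480),
    rt_peak_ms = NA, rt_peak_norm = NA,
    partial_onset_ms = NA,
    partial_peak_ms = c(NA, NA, 370, 380, NA, NA, NA, NA, NA, NA),
    partial_peak_norm = NA,
    cancel_time_ms = c(NA, NA, 120, 130, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  d$trial <- 0:4
  s <- summarize_subject(d, emg)
  expect_equal(s$partial_burst_proportion, 0.25)   # 1 of 4 successful stops
  expect_equal(s$cancel_time_ms, 125)
  # responding-hand RT-burst onset minus SSD, over successful stops
  expect_equal(s$relative_emg_onset_ms,
               mean(c(470 - 250, 490 - 260, 460 - 240, 480 - 250)))
})

test_that("trial tables and parameter sets round-trip through text", {
  p <- study_scale_params(gf = 0.02, tf = 0.05, eps_wrong = 0.01)
  f <- tempfile(fileext = ".json")
  write_params(p, f)
  p2 <- read_params(f)
  expect_equal(p2$dual_go$proactive$mu, 410)
  expect_equal(p2$gf, 0.02)
  expect_equal(sisstop:::param_matrix(p2), sisstop:::param_matrix(p))
  unlink(f)
  d <- data.frame(participant = 1, condition = "reactive", trial = 0,
                  stimulus = "LS", ssd_ms = 250, response = "LR",
                  rt_ms = 540.25)
  f2 <- tempfile(fileext = ".tsv")
  write_trials(d, f2)
  d2 <- read_trials(f2)
  expect_equal(d2, d)
  unlink(f2)
})
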