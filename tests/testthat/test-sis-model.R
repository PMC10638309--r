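test_that("race rule resolves deterministic latent configurations", {
  # stop finish 250 + 100 = 350 < t_go 400: successful stop, response at
  # ssd + t_sel = 540; and the failed-stop counterpart
  p <- sis_params(runner_params(400, 1e-5, 1e-5), runner_params(100, 1e-5, 1e-5),
                  runner_params(290, 1e-5, 1e-5), runner_params(290, 1e-5, 1e-5))
  tr <- data.frame(stimulus = "LS", condition = "reactive", ssd_ms = 250)
  set.seed(1)
  out <- simulate_trials(p, tr)
  expect_equal(out$response, "LR")
  expect_equal(out$rt_ms, 540, tolerance = 1e-3)
  expect_true(out$stop_success)
  p2 <- sis_params(runner_params(400, 1e-5, 1e-5), runner_params(200, 1e-5, 1e-5),
                   runner_params(290, 1e-5, 1e-5), runner_params(290, 1e-5, 1e-5))
  out2 <- simulate_trials(p2, tr)
  expect_equal(out2$response, "DR")
  expect_equal(out2$rt_ms, 400, tolerance = 1e-3)
  expect_false(out2$stop_success)
  # nothing launches when both failure draws fire
  p3 <- sis_params(runner_params(400, 1e-5, 1e-5), runner_params(200, 1e-5, 1e-5),
                   runner_params(290, 1e-5, 1e-5), runner_params(290, 1e-5, 1e-5),
                   gf = 1, tf = 1)
  out3 <- simulate_trials(p3, tr)
  expect_equal(out3$response, "NR")
})

test_that("stop-win probability is monotone, bounded and matches Monte Carlo", {
  go <- runner_params(400, 50, 50)
  stp <- runner_params(150, 30, 30)
  # dominance limit
  expect_gt(stop_win_probability(runner_params(450, 20, 1e-3),
                                 runner_params(150, 20, 1e-3), 0), 0.999)
  ssds <- c(0, 100, 200, 300, 400)
  pw <- vapply(ssds, function(d) stop_win_probability(go, stp, d), numeric(1))
  expect_true(all(diff(pw) <= 0))
  expect_true(all(pw >= 0 & pw <= 1))
  # Monte-Carlo oracle
  set.seed(5)
  n <- 1e6
  t_go <- rexgauss(n, 400, 50, 50)
  t_st <- rexgauss(n, 150, 30, 30)
  mc <- mean(250 + t_st < t_go)
  se <- sqrt(mc * (1 - mc) / n)
  expect_lt(abs(stop_win_probability(go, stp, 250) - mc), 3 * se)
})

test_that("likelihood cell probabilities sum to 1 and match simulation", {
  p <- sis_params(runner_params(400, 50, 50), runner_params(150, 30, 30),
                  runner_params(250, 40, 50), runner_params(250, 40, 50),
                  gf = 0.03, tf = 0.08, eps_wrong = 0.02)
  for (cell in list(c("LS", 150), c("LS", 300), c("RS", 250), c("DS", NA))) {
    probs <- response_probabilities(p, cell[1], "reactive",
                                    as.numeric(cell[2]))
    expect_equal(sum(probs), 1, tolerance = 1e-4)
  }
  set.seed(21)
  n <- 4e4
  tr <- data.frame(stimulus = "LS", condition = "reactive", ssd_ms = 250)
  sim <- simulate_trials(p, tr[rep(1, n), ])
  freq <- table(factor(sim$response, c("NR", "DR", "LR", "RR"))) / n
  probs <- response_probabilities(p, "LS", "reactive", 250)
  for (r in names(probs)) {
    se <- sqrt(probs[r] * (1 - probs[r]) / n)
    expect_lt(abs(freq[[r]] - probs[[r]]), 3 * se + 1e-5)
  }
})

test_that("log-likelihood handles limits, floors and ordering", {
  p <- study_scale_params()
  # DS/NR in a no-omission model has only the deadline tail, floored
  d <- data.frame(stimulus = "DS", condition = "reactive",
                  response = "NR", rt_ms = NA, ssd_ms = NA)
  ll <- sis_loglik(p, d)
  expect_gte(ll, log(1e-10))
  expect_equal(ll, log(max(sexgauss(1100, 380, 50, 70), 1e-10)))
  # far SSD: failed-stop density approaches the plain go density
  d2 <- data.frame(stimulus = "LS", condition = "reactive",
                   response = "DR", rt_ms = 420, ssd_ms = 1050)
  expect_equal(sis_loglik(p, d2), log(dexgauss(420, 380, 50, 70)),
               tolerance = 1e-10)
  # rare unmodelled cell sits exactly on the floor
  d3 <- data.frame(stimulus = "DS", condition = "reactive",
                   response = "LR", rt_ms = 400, ssd_ms = NA)
  expect_equal(sis_loglik(p, d3), log(1e-10))
  # order invariance: dataset loglik is a sum over trials
  set.seed(3)
  tr <- data.frame(stimulus = rep(c("DS", "LS", "RS"), 40),
                   condition = "reactive",
                   ssd_ms = rep(c(NA, 250, 200), 40))
  sim <- simulate_trials(study_scale_params(gf = .02, tf = .05), tr)
  dd <- sim[, c("stimulus", "condition", "response", "rt_ms", "ssd_ms")]
  perm <- sample(nrow(dd))
  expect_equal(sis_loglik(p, dd), sis_loglik(p, dd[perm, ]))
  expect_equal(sis_loglik(p, dd), sum(sis_loglik(p, dd, sum = FALSE)))
  # invalid RTs are rejected
  bad <- data.frame(stimulus = "DS", condition = "reactive",
                    response = "DR", rt_ms = 1200, ssd_ms = NA)
  expect_error(sis_loglik(p, bad), "deadline")
})

test_that("failed stops are faster than go responses (race selection)", {
  p <- study_scale_params()
  set.seed(9)
  tr <- data.frame(stimulus = rep(c("DS", "LS"), each = 4000),
                   condition = "reactive",
                   ssd_ms = rep(c(NA, 250), each = 4000))
  sim <- simulate_trials(p, tr)
  go_rt <- sim$rt_ms[sim$stimulus == "DS" & sim$response == "DR"]
  fail_rt <- sim$rt_ms[sim$stimulus == "LS" & sim$response == "DR"]
  expect_lt(mean(fail_rt), mean(go_rt))
})

test_that("successful-stop RT minus SSD follows the selective runner", {
  p <- study_scale_params()
  set.seed(13)
  n <- 1e4
  tr <- data.frame(stimulus = "LS", condition = "reactive", ssd_ms = 250)
  sim <- simulate_trials(p, tr[rep(1, n), ])
  rel <- sim$rt_ms[sim$response == "LR"] - 250
  ref <- rexgauss(2e4, 256, 40, 60)
  ref <- ref[ref <= 1100 - 250]      # deadline truncation
  expect_gt(stats::ks.test(rel, ref)$p.value, 0.01)
})

test_that("the detectability window arithmetic and bias sim behave", {
  w <- censoring_window()
  expect_identical(w$lower_margin_ms, 90)
  expect_identical(w$upper_margin_ms, 115)
  expect_error(censoring_window(upper_margin_ms = 80), "lower margin")
  # no censoring, no bias (up to Monte-Carlo error)
  p <- study_scale_params()
  set.seed(31)
  cb <- censoring_bias_sim(p, censoring_window(peak_to_offset_ms = 1e-9,
                                               min_gap_ms = 0,
                                               onset_to_press_ms = 0,
                                               upper_margin_ms = 1e7),
                           n_trials = 4000)
  expect_true(all(abs(cb$bias_ms) < 3))
  expect_true(all(cb$censored_fraction > 0.97))
  # empty censored subset errors informatively
  expect_error(
    censoring_bias_sim(p, censoring_window(peak_to_offset_ms = 5000,
                                           min_gap_ms = 0,
                                           onset_to_press_ms = 0,
                                           upper_margin_ms = 5001),
                       n_trials = 200),
    "window")
})
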