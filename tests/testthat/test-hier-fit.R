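test_that("variant vary-maps encode the condition constraints", {
  expect_equal(sis_variant(1)$vary,
               c(dual_go = TRUE, dual_stop = FALSE, sel_left = TRUE,
                 sel_right = TRUE))
  expect_false(sis_variant(3)$vary[["dual_go"]])
  expect_false(sis_variant(4)$vary[["sel_left"]])
  expect_true(all(sis_variant(5)$vary))
  expect_error(sis_variant(2), "unknown variant")
  # nesting by construction: a condition-invariant parameter vector
  # mapped through variant 1 and its variant-5 embedding (both
  # conditions set equal) gives the identical dataset likelihood
  p1 <- sisstop:::variant_param_table(sis_variant(1))
  p5 <- sisstop:::variant_param_table(sis_variant(5))
  th1 <- setNames(c(380, 410, 50, 50, 70, 70,   # dual_go by condition
                    150, 30, 50,                 # dual_stop shared
                    256, 229, 40, 40, 60, 60,    # sel_left
                    256, 229, 40, 40, 60, 60,    # sel_right
                    -2, -1.6, -2.3), p1$name)
  th5 <- setNames(numeric(nrow(p5)), p5$name)
  for (nm in p5$name) {
    nm1 <- sub("[.](reactive|proactive)$", ".shared", nm)
    th5[nm] <- if (nm %in% names(th1)) th1[[nm]] else th1[[nm1]]
  }
  pars1 <- sisstop:::vector_to_params(th1, p1)
  pars5 <- sisstop:::vector_to_params(th5, p5)
  d <- data.frame(stimulus = c("DS", "LS", "RS", "LS"),
                  condition = c("reactive", "reactive", "proactive", "proactive"),
                  response = c("DR", "LR", "DR", "NR"),
                  rt_ms = c(450, 540, 420, NA),
                  ssd_ms = c(NA, 250, 200, 300))
  expect_equal(sis_loglik(pars5, d), sis_loglik(pars1, d))
  # parameter counts: 3 per runner per condition block + 3 probabilities
  expect_equal(nrow(sis_priors(sis_variant(1))), 24)
  expect_equal(nrow(sis_priors(sis_variant(5))), 27)
  expect_equal(nrow(sis_priors(sis_variant(4))), 18)
})

test_that("split R-hat and ESS behave on constructed chains", {
  set.seed(8)
  clean <- matrix(rnorm(4 * 500), 4, 500)
  expect_lt(split_rhat(clean), 1.01)
  expect_gt(ess_basic(clean), 1000)
  offset <- clean
  offset[1, ] <- offset[1, ] + 10
  expect_gt(split_rhat(offset), 1.1)
  # within-chain drift is caught by splitting
  drift <- matrix(rep(seq(0, 1, length.out = 500), each = 4), 4, 500,
                  byrow = FALSE) + rnorm(2000, 0, 0.01)
  expect_gt(split_rhat(drift), 1.1)
  # zero-variance chains: undefined, reported as failure with a reason
  const <- matrix(1, 4, 500)
  expect_true(is.nan(split_rhat(const)))
  diag <- convergence_diagnostics(const)
  expect_false(diag$pass)
  expect_match(diag$reason, "undefined")
  diag2 <- convergence_diagnostics(clean)
  expect_true(diag2$pass)
  expect_error(convergence_diagnostics(matrix(rnorm(40), 1, 40)), "chains")
  expect_error(convergence_diagnostics(matrix(rnorm(40), 2, 20)), "50")
})

test_that("hierarchical fitting validates its inputs", {
  d <- data.frame(participant = 1, condition = "reactive", stimulus = "DS",
                  ssd_ms = NA, response = "DR", rt_ms = 450)
  expect_error(fit_sis(d, variant = 1), "at least 2 participants")
  d2 <- rbind(transform(d, participant = 1), transform(d, participant = 2))
  expect_error(fit_sis(d2, variant = 1), "lacks go or stop")
})

test_that("a small hierarchical fit is reproducible and structurally sound", {
  fit <- tiny_fit()
  expect_s3_class(fit, "sis_fit")
  k <- nrow(fit$param_table)
  expect_equal(k, 24)
  expect_gte(dim(fit$subj)[1], 3 * k)     # chain count contract
  expect_equal(dim(fit$subj)[2], 60)
  expect_equal(dim(fit$subj)[4], 2)
  expect_true(all(is.finite(fit$ll)))
  # draws respect the parameter supports
  for (j in seq_len(k)) {
    expect_true(all(fit$subj[, , j, ] >= fit$param_table$lower[j]))
    expect_true(all(fit$subj[, , j, ] <= fit$param_table$upper[j]))
  }
  # posterior running times sit at a plausible human scale
  rt <- running_times(fit)
  expect_true(all(rt$median > 100 & rt$median < 700))
  # exact reproducibility under the same seed and settings
  fit2 <- fit_sis(fit$data, variant = 1, seed = 303,
                  sampler = list(ind_iterations = 15, window = 20,
                                 max_windows = 1, retain = 60))
  expect_identical(fit$subj, fit2$subj)
  expect_identical(fit$group, fit2$group)
  # methods run
  expect_output(print(fit), "Hierarchical SIS fit")
  expect_named(coef(fit), fit$param_table$name, ignore.order = TRUE)
  sim <- simulate(fit, nsim = 1, seed = 5)
  expect_equal(nrow(sim), nrow(fit$data))
  expect_true(all(sim$response %in% c("NR", "DR", "LR", "RR")))
})

test_that("BPIC follows its definition and degenerates correctly", {
  fit <- tiny_fit()
  b <- suppressWarnings(bpic(fit))
  expect_equal(b$bpic, b$mean_dev + 2 * (b$mean_dev - b$dev_at_mean))
  expect_equal(b$pD, b$mean_dev - b$dev_at_mean)
  # point-mass posterior: pD = 0 and BPIC = mean deviance
  degen <- fit
  theta_bar <- apply(fit$subj, c(3, 4), mean)
  for (i in seq_len(dim(fit$subj)[4])) {
    degen$subj[, , , i] <- rep(theta_bar[, i],
                               each = dim(fit$subj)[1] * dim(fit$subj)[2])
  }
  ptab <- fit$param_table
  lls <- vapply(seq_along(fit$subjects), function(i) {
    th <- setNames(theta_bar[, i], ptab$name)
    pars <- sisstop:::vector_to_params(th, ptab, fit$conditions)
    di <- fit$data[fit$data$participant == fit$subjects[i], ]
    sis_loglik(pars, di, deadline_ms = fit$deadline_ms)
  }, numeric(1))
  degen$ll[] <- sum(lls)
  b0 <- bpic(degen)
  expect_equal(b0$pD, 0, tolerance = 1e-6)
  expect_equal(b0$bpic, b0$mean_dev, tolerance = 1e-6)
  # comparison table is ordered with delta from the best
  tab <- compare_sis(list(fit, fit))
  expect_equal(tab$delta_bpic, c(0, 0))
})

test_that("posterior contrasts are draw-wise and respect variant constraints", {
  fit <- tiny_fit()
  # a parameter contrasted with itself is identically zero
  ct0 <- posterior_contrasts(fit, "dual_go", "reactive", "dual_go",
                             condition2 = "reactive")
  expect_true(all(ct0$draws == 0))
  expect_equal(ct0$ci, c(0, 0))
  # condition contrast of a shared runner is undefined under variant 1
  expect_error(
    posterior_contrasts(fit, "dual_stop", "proactive",
                        condition2 = "reactive"),
    "condition-invariant")
  # proactive slowing contrast has the right scale and sign
  ct <- posterior_contrasts(fit, "dual_go", "proactive", "dual_go",
                            condition2 = "reactive")
  expect_gt(ct$median, 0)
  expect_lt(ct$median, 120)
})
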