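#' Runner and SIS model parameter containers
#'
#' `runner_params()` holds the ex-Gaussian finish-time parameters of one
#' racing accumulator; `sis_params()` bundles the four runners of the
#' SIS (simultaneously inhibit and start) model together with the
#' failure probabilities. A selective stop signal is assumed to
#' simultaneously inhibit the initial bimanual response (the dual-stop
#' runner races the dual-go runner) and trigger a new unimanual response
#' (the selective runner of the continuing hand, started at SSD).
#'
#' Each runner argument may be a single `runner_params` (shared across
#' conditions) or a named list with one `runner_params` per condition
#' (e.g. `list(reactive = ..., proactive = ...)`).
#'
#' @param mu,sigma,tau ex-Gaussian parameters in ms.
#' @param dual_go runner for the bimanual go response (starts at go onset).
#' @param dual_stop runner inhibiting the bimanual response (starts at SSD).
#' @param sel_left,sel_right runners for the left/right unimanual
#'   response (start at SSD; `sel_left` generates the LR response on
#'   right-stop trials).
#' @param gf go-failure probability (the go runner never launches).
#' @param tf trigger-failure probability of the stop signal (neither the
#'   dual-stop nor the selective runner launches).
#' @param eps_wrong probability that the wrong hand's selective runner is
#'   triggered instead of the correct one.
#' @param p_floor per-trial likelihood floor absorbing unmodelled rare
#'   cells (e.g. unimanual responses to a dual stimulus).
#' @param conditions condition labels the parameter set covers.
#' @return an object of class `runner_params` / `sis_params`.
#' @examples
#' p <- sis_params(
#'   dual_go = list(reactive = runner_params(380, 50, 70),
#'                  proactive = runner_params(410, 50, 70)),
#'   dual_stop = runner_params(150, 30, 50),
#'   sel_left = runner_params(250, 40, 60),
#'   sel_right = runner_params(250, 40, 60))
#' @export
runner_params <- function(mu, sigma, tau) {
  check_exg(mu, sigma, tau)
  structure(list(mu = mu, sigma = sigma, tau = tau), class = "runner_params")
}

#' @rdname runner_params
#' @export
sis_params <- function(dual_go, dual_stop, sel_left, sel_right,
                       gf = 0, tf = 0, eps_wrong = 0, p_floor = 1e-10,
                       conditions = c("reactive", "proactive")) {
  for (p in c(gf, tf, eps_wrong)) {
    if (!is.finite(p) || p < 0 || p > 1) {
      stop("gf, tf and eps_wrong must be probabilities in [0, 1]",
           call. = FALSE)
    }
  }
  stopifnot(is.finite(p_floor), p_floor > 0)
  obj <- structure(list(
    dual_go = per_condition(dual_go, conditions),
    dual_stop = per_condition(dual_stop, conditions),
    sel_left = per_condition(sel_left, conditions),
    sel_right = per_condition(sel_right, conditions),
    gf = gf, tf = tf, eps_wrong = eps_wrong, p_floor = p_floor,
    conditions = conditions
  ), class = "sis_params")
  obj
}

per_condition <- function(x, conditions) {
  if (inherits(x, "runner_params")) {
    stats::setNames(rep(list(x), length(conditions)), conditions)
  } else if (is.list(x) && all(conditions %in% names(x))) {
    lapply(stats::setNames(conditions, conditions), function(cn) {
      r <- x[[cn]]
      stopifnot(inherits(r, "runner_params"))
      r
    })
  } else {
    stop("runner must be a runner_params or a named per-condition list",
         call. = FALSE)
  }
}

runner_for <- function(params, runner, condition) {
  params[[runner]][[condition]]
}

#' @export
print.sis_params <- function(x, ...) {
  cat("SIS model parameters (ms)\n")
  for (r in c("dual_go", "dual_stop", "sel_left", "sel_right")) {
    for (cn in x$conditions) {
      p <- x[[r]][[cn]]
      cat(sprintf("  %-9s %-9s mu=%6.1f sigma=%5.1f tau=%6.1f  (mu+tau=%6.1f)\n",
                  r, cn, p$mu, p$sigma, p$tau, p$mu + p$tau))
    }
  }
  cat(sprintf("  gf=%.3f tf=%.3f eps_wrong=%.3f\n", x$gf, x$tf, x$eps_wrong))
  invisible(x)
}

# 12-column runner matrix (one row per condition) for the C++ likelihood
param_matrix <- function(params) {
  t(vapply(params$conditions, function(cn) {
    unlist(lapply(c("dual_go", "dual_stop", "sel_left", "sel_right"),
                  function(r) {
                    p <- params[[r]][[cn]]
                    c(p$mu, p$sigma, p$tau)
                  }))
  }, numeric(12)))
}

STIM_LEVELS <- c("DS", "LS", "RS")
RESP_LEVELS <- c("NR", "DR", "LR", "RR")

#' Simulate SIS race trials
#'
#' Draws the latent finish times of every runner and applies the race
#' rule to produce observed responses. On a stop trial the dual-go
#' runner (launched at go onset unless a go failure occurs) races the
#' dual-stop runner (launched at SSD unless a trigger failure occurs);
#' if the go runner finishes first the trial is a failed stop (dual
#' response at `t_go`), otherwise the selective runner of the continuing
#' hand -- also launched at SSD -- produces a unimanual response at
#' `ssd + t_sel`. Responses beyond the deadline are recorded as `NR`.
#'
#' @param params a [sis_params()] object.
#' @param trials data.frame with columns `stimulus` (`DS`/`LS`/`RS`),
#'   `condition`, and `ssd_ms` (ignored on `DS` rows); a `deadline_ms`
#'   column is optional.
#' @param deadline_ms response window used where `trials` has no
#'   `deadline_ms` column.
#' @return `trials` augmented with latent times (`t_go`, `t_stop`,
#'   `t_sel`, launch flags), `response`, `rt_ms`, `stop_success` and
#'   `margin_ms` (`t_go - (ssd + t_stop)` when both runners launched).
#' @examples
#' p <- sis_params(runner_params(380, 50, 70), runner_params(150, 30, 50),
#'                 runner_params(250, 40, 60), runner_params(250, 40, 60))
#' tr <- data.frame(stimulus = c("DS", "LS"), condition = "reactive",
#'                  ssd_ms = c(NA, 250))
#' simulate_trials(p, tr)
#' @export
simulate_trials <- function(params, trials, deadline_ms = 1100) {
  n <- nrow(trials)
  stopifnot(all(trials$stimulus %in% STIM_LEVELS),
            all(trials$condition %in% params$conditions))
  deadline <- if ("deadline_ms" %in% names(trials)) trials$deadline_ms
              else rep(deadline_ms, n)
  go_launch <- stats::runif(n) >= params$gf
  stop_trial <- trials$stimulus != "DS"
  stop_launch <- stop_trial & stats::runif(n) >= params$tf
  wrong_sel <- stats::runif(n) < params$eps_wrong

  t_go <- t_stop <- t_sel <- rep(NA_real_, n)
  for (cn in params$conditions) {
    idx <- which(trials$condition == cn)
    if (!length(idx)) next
    dg <- runner_for(params, "dual_go", cn)
    st <- runner_for(params, "dual_stop", cn)
    t_go[idx] <- rexgauss(length(idx), dg$mu, dg$sigma, dg$tau)
    t_stop[idx] <- rexgauss(length(idx), st$mu, st$sigma, st$tau)
    for (sside in c("LS", "RS")) {
      sidx <- idx[trials$stimulus[idx] == sside]
      if (!length(sidx)) next
      correct <- if (sside == "LS") "sel_left" else "sel_right"
      wrong <- if (sside == "LS") "sel_right" else "sel_left"
      rn <- ifelse(wrong_sel[sidx], wrong, correct)
      for (r in unique(rn)) {
        ri <- sidx[rn == r]
        pr <- runner_for(params, r, cn)
        t_sel[ri] <- rexgauss(length(ri), pr$mu, pr$sigma, pr$tau)
      }
    }
  }

  ssd <- ifelse(stop_trial, trials$ssd_ms, NA_real_)
  response <- rep("NR", n)
  rt <- rep(NA_real_, n)
  stop_success <- rep(NA, n)

  # dual-stimulus trials
  ds <- which(!stop_trial)
  hit <- ds[go_launch[ds] & t_go[ds] <= deadline[ds]]
  response[hit] <- "DR"
  rt[hit] <- t_go[hit]

  # stop trials
  stp <- which(stop_trial)
  stop_wins <- stop_launch & (!go_launch | (ssd + t_stop < t_go))
  failed <- stp[go_launch[stp] & !stop_wins[stp]]
  hit <- failed[t_go[failed] <= deadline[failed]]
  response[hit] <- "DR"
  rt[hit] <- t_go[hit]
  stop_success[stp] <- FALSE
  succ <- stp[stop_wins[stp]]
  uni_rt <- ssd[succ] + t_sel[succ]
  hit <- succ[uni_rt <= deadline[succ]]
  rt[hit] <- ssd[hit] + t_sel[hit]
  uni_resp <- ifelse(
    xor(trials$stimulus[hit] == "LS", wrong_sel[hit]), "LR", "RR")
  response[hit] <- uni_resp
  # a successful inhibition counts as a successful stop only if the
  # correct unimanual response is registered in time
  correct_resp <- ifelse(trials$stimulus[stp] == "LS", "LR", "RR")
  stop_success[stp] <- response[stp] == correct_resp

  out <- trials
  out$deadline_ms <- deadline
  out$go_launched <- go_launch
  out$stop_launched <- ifelse(stop_trial, stop_launch, NA)
  out$t_go <- ifelse(go_launch, t_go, NA_real_)
  out$t_stop <- ifelse(stop_trial & stop_launch, t_stop, NA_real_)
  out$t_sel <- ifelse(stop_trial & stop_launch, t_sel, NA_real_)
  out$response <- response
  out$rt_ms <- rt
  out$stop_success <- stop_success
  out$margin_ms <- ifelse(stop_trial & go_launch & stop_launch,
                          t_go - (ssd + t_stop), NA_real_)
  out
}

#' Probability that the stop runner beats the go runner
#'
#' `Pwin(d) = P(ssd + T_stop < T_go)` for independent ex-Gaussian
#' runners, computed by adaptive quadrature (absolute tolerance 1e-6).
#' This is the probability that the initial bimanual response is
#' successfully inhibited given both runners launched, and is
#' non-increasing in SSD.
#'
#' @param go,stop [runner_params()] for the dual-go and dual-stop runners.
#' @param ssd stop-signal delay in ms.
#' @return a probability.
#' @examples
#' stop_win_probability(runner_params(450, 50, 1e-3),
#'                      runner_params(150, 30, 1e-3), ssd = 0)
#' @export
stop_win_probability <- function(go, stop, ssd) {
  stopifnot(inherits(go, "runner_params"), inherits(stop, "runner_params"))
  f <- function(s) {
    dexgauss(s, stop$mu, stop$sigma, stop$tau) *
      sexgauss(ssd + s, go$mu, go$sigma, go$tau)
  }
  res <- tryCatch(
    stats::integrate(f, 0, Inf, abs.tol = 1e-6, rel.tol = 1e-8,
                     stop.on.error = TRUE),
    error = function(e) stop("quadrature failed for Pwin(ssd = ", ssd,
                             "): ", conditionMessage(e), call. = FALSE))
  min(max(res$value, 0), 1)
}

prepare_loglik_data <- function(params, data) {
  need <- c("stimulus", "condition", "response")
  stopifnot(all(need %in% names(data)))
  stim <- match(data$stimulus, STIM_LEVELS) - 1L
  resp <- match(data$response, RESP_LEVELS) - 1L
  cond <- match(data$condition, params$conditions) - 1L
  if (anyNA(stim) || anyNA(resp) || anyNA(cond)) {
    stop("unknown stimulus/response/condition label in data", call. = FALSE)
  }
  list(stim = stim, resp = resp, cond = cond)
}

#' SIS model log-likelihood
#'
#' Exact per-trial log density (responses with an RT) or log probability
#' (`NR` cells, with the beyond-deadline mass of every response path
#' folded in). Each trial's likelihood is floored at `params$p_floor`
#' before taking the log, so rare unmodelled cells (e.g. a unimanual
#' response to a dual stimulus) contribute a fixed small density rather
#' than `-Inf`. The dataset log-likelihood is the sum over trials and is
#' invariant to trial ordering.
#'
#' @param params a [sis_params()] object.
#' @param data data.frame of observed trials with columns `stimulus`,
#'   `condition`, `response`, `rt_ms` (`NA` for `NR`), `ssd_ms` (stop
#'   trials only).
#' @param deadline_ms response window in ms.
#' @param sum if `TRUE` return the summed log-likelihood, otherwise the
#'   per-trial vector.
#' @return log-likelihood (scalar or per-trial vector).
#' @export
sis_loglik <- function(params, data, deadline_ms = 1100, sum = TRUE) {
  idx <- prepare_loglik_data(params, data)
  rt <- data$rt_ms
  has_rt <- idx$resp != 0L
  if (any(has_rt & (is.na(rt) | rt <= 0 | rt > deadline_ms))) {
    stop("every non-NR trial must have an RT in (0, deadline]; ",
         "responses beyond the deadline are NR by definition", call. = FALSE)
  }
  ssd <- if ("ssd_ms" %in% names(data)) data$ssd_ms else rep(NA_real_, nrow(data))
  if (any(idx$stim != 0L & is.na(ssd))) {
    stop("stop trials must carry ssd_ms", call. = FALSE)
  }
  ll <- sis_loglik_cpp(idx$stim, idx$resp,
                       ifelse(is.na(rt), -1, rt),
                       ifelse(is.na(ssd), 0, ssd),
                       idx$cond, param_matrix(params),
                       params$gf, params$tf, params$eps_wrong,
                       params$p_floor, deadline_ms)
  if (sum) base::sum(ll) else ll
}

#' Response-category probabilities for one stimulus/SSD cell
#'
#' Integrates the SIS trial likelihood over RT to give the probability
#' of each response category (`NR`, `DR`, `LR`, `RR`) for a given
#' stimulus, condition and SSD. Probabilities sum to 1 up to the
#' integration tolerance; they are the analytic counterpart of
#' [simulate_trials()] frequencies.
#'
#' @inheritParams sis_loglik
#' @param stimulus one of `"DS"`, `"LS"`, `"RS"`.
#' @param condition condition label present in `params`.
#' @param ssd_ms stop-signal delay (ignored for `DS`).
#' @return named numeric vector of four probabilities.
#' @export
response_probabilities <- function(params, stimulus, condition,
                                   ssd_ms = NA, deadline_ms = 1100) {
  stopifnot(stimulus %in% STIM_LEVELS, condition %in% params$conditions)
  gf <- params$gf; tf <- params$tf; eps <- params$eps_wrong
  dg <- runner_for(params, "dual_go", condition)
  T <- deadline_ms
  quad <- function(f, lo, hi) {
    stats::integrate(f, lo, hi, abs.tol = 1e-8, rel.tol = 1e-8)$value
  }
  if (stimulus == "DS") {
    p_dr <- (1 - gf) * pexgauss(T, dg$mu, dg$sigma, dg$tau)
    p_nr <- gf + (1 - gf) * sexgauss(T, dg$mu, dg$sigma, dg$tau)
    return(c(NR = p_nr, DR = p_dr, LR = 0, RR = 0))
  }
  st <- runner_for(params, "dual_stop", condition)
  u_name <- if (stimulus == "LS") "sel_left" else "sel_right"
  w_name <- if (stimulus == "LS") "sel_right" else "sel_left"
  U <- runner_for(params, u_name, condition)
  W <- runner_for(params, w_name, condition)
  d <- ssd_ms
  pw <- stop_win_probability(dg, st, d)
  # failed stop (dual response) inside the deadline
  f_dr <- function(t) {
    dexgauss(t, dg$mu, dg$sigma, dg$tau) *
      (tf + (1 - tf) * sexgauss(t - d, st$mu, st$sigma, st$tau))
  }
  p_dr <- (1 - gf) * quad(f_dr, 0, T)
  launch <- gf + (1 - gf) * pw
  p_u <- (1 - tf) * (1 - eps) * launch * pexgauss(T - d, U$mu, U$sigma, U$tau)
  p_w <- (1 - tf) * eps * launch * pexgauss(T - d, W$mu, W$sigma, W$tau)
  smix <- (1 - eps) * sexgauss(T - d, U$mu, U$sigma, U$tau) +
    eps * sexgauss(T - d, W$mu, W$sigma, W$tau)
  tail_go <- quad(function(t) dexgauss(t, dg$mu, dg$sigma, dg$tau) *
                    sexgauss(t - d, st$mu, st$sigma, st$tau), T, Inf)
  p_nr <- gf * tf + (1 - gf) * tf * sexgauss(T, dg$mu, dg$sigma, dg$tau) +
    gf * (1 - tf) * smix +
    (1 - gf) * (1 - tf) * (tail_go + pw * smix)
  probs <- c(NR = p_nr, DR = p_dr, LR = 0, RR = 0)
  probs[if (stimulus == "LS") "LR" else "RR"] <- p_u
  probs[if (stimulus == "LS") "RR" else "LR"] <- p_w
  probs
}

#' Detectability window for partial EMG bursts
#'
#' A partial EMG burst is only physically detectable when the stop
#' runner beats the go runner by a margin inside a window. The lower
#' margin bound (stopping "too slow" to leave a detectable gap) is the
#' sum of three latency components: the partial burst's peak-to-offset
#' time (~50 ms), the minimum offset-to-onset gap the burst detector can
#' resolve (20 ms), and the time from RT-burst onset to the button press
#' excluding electromechanical delay (~20 ms) -- 90 ms in total. The
#' upper bound (stopping "too fast" for any muscle activity to emerge)
#' defaults to 115 ms, which yields a proportion of partial-burst trials
#' consistent with observation (~18% of successful stops).
#'
#' @param peak_to_offset_ms,min_gap_ms,onset_to_press_ms the three
#'   components of the lower margin bound.
#' @param upper_margin_ms margin above which stopping is too fast to
#'   leave a partial burst.
#' @return a `censoring_window` object with `lower_margin_ms` and
#'   `upper_margin_ms`.
#' @examples
#' censoring_window()  # lower 90, upper 115
#' @export
censoring_window <- function(peak_to_offset_ms = 50, min_gap_ms = 20,
                             onset_to_press_ms = 20, upper_margin_ms = 115) {
  lower <- peak_to_offset_ms + min_gap_ms + onset_to_press_ms
  if (!(lower > 0 && upper_margin_ms > lower)) {
    stop("censoring window requires 0 < lower margin < upper margin",
         call. = FALSE)
  }
  structure(list(lower_margin_ms = lower, upper_margin_ms = upper_margin_ms),
            class = "censoring_window")
}

#' Censoring bias in EMG-based stopping-latency estimates
#'
#' CancelTime-style estimates of stopping latency are only available on
#' successful stop trials with a detectable partial burst, i.e. trials
#' where the stop runner's winning margin over the go runner falls in a
#' detectability window. This simulation quantifies the resulting
#' selection bias: it simulates staircased selective-stop trials per
#' condition, and compares the mean stop-runner finish time over all
#' successful stops against the mean over the margin-censored subset.
#'
#' @param params a [sis_params()] object.
#' @param window a [censoring_window()].
#' @param n_trials stop trials simulated per condition.
#' @param ssd_start_ms,step_ms staircase settings (1-up/1-down).
#' @return data.frame per condition: mean stop finish over all
#'   successful stops (`mean_uncensored`), over the censored subset
#'   (`mean_censored`), `bias_ms` (censored - uncensored; negative =
#'   down-bias), and `censored_fraction` of successful stops.
#' @export
censoring_bias_sim <- function(params, window = censoring_window(),
                               n_trials = 10000, ssd_start_ms = 200,
                               step_ms = 50) {
  stopifnot(inherits(window, "censoring_window"))
  out <- lapply(params$conditions, function(cn) {
    sim <- simulate_stop_series(params, cn, n_trials, ssd_start_ms, step_ms)
    ok <- sim$stop_success
    cens <- ok & !is.na(sim$margin_ms) &
      sim$margin_ms >= window$lower_margin_ms &
      sim$margin_ms <= window$upper_margin_ms
    if (!any(cens)) {
      stop("no successful stop trials fall inside the censoring window in ",
           "condition '", cn, "'; increase n_trials or widen the window",
           call. = FALSE)
    }
    data.frame(
      condition = cn,
      mean_uncensored = mean(sim$t_stop[ok]),
      mean_censored = mean(sim$t_stop[cens]),
      bias_ms = mean(sim$t_stop[cens]) - mean(sim$t_stop[ok]),
      censored_fraction = base::sum(cens) / base::sum(sim$stop_success),
      stop_success_rate = mean(sim$stop_success)
    )
  })
  do.call(rbind, out)
}

#' Simulate a sequence of staircased selective-stop trials
#'
#' Runs `n_trials` consecutive selective-stop trials of one condition
#' through the SIS race model with a live 1-up/1-down SSD staircase
#' (alternating left-/right-stop, independent staircase keys). Latent
#' finish times are drawn up front -- they do not depend on SSD -- and
#' only the staircase evolves sequentially, so long series are cheap.
#' The long-run stop-success proportion converges to 50% whenever the
#' success probability decreases with SSD and the staircase stays off
#' its clamps.
#'
#' @param params a [sis_params()] object.
#' @param condition condition label present in `params`.
#' @param n_trials number of stop trials.
#' @param ssd_start_ms,step_ms staircase settings.
#' @param deadline_ms response window.
#' @return data.frame with one row per stop trial: `ssd_ms`, latent
#'   finish times, `stop_success`, `margin_ms`.
#' @export
simulate_stop_series <- function(params, condition, n_trials,
                                 ssd_start_ms = 200, step_ms = 50,
                                 deadline_ms = 1100) {
  n <- n_trials
  stim <- rep(c("LS", "RS"), length.out = n)
  side <- ifelse(stim == "LS", "right", "left")
  dg <- runner_for(params, "dual_go", condition)
  st_r <- runner_for(params, "dual_stop", condition)
  go_launch <- stats::runif(n) >= params$gf
  stop_launch <- stats::runif(n) >= params$tf
  wrong_sel <- stats::runif(n) < params$eps_wrong
  t_go <- rexgauss(n, dg$mu, dg$sigma, dg$tau)
  t_stop <- rexgauss(n, st_r$mu, st_r$sigma, st_r$tau)
  sel_name <- ifelse(xor(stim == "LS", wrong_sel), "sel_left", "sel_right")
  t_sel <- numeric(n)
  for (r in unique(sel_name)) {
    ri <- which(sel_name == r)
    pr <- runner_for(params, r, condition)
    t_sel[ri] <- rexgauss(length(ri), pr$mu, pr$sigma, pr$tau)
  }
  floor_ms <- 0
  ceiling_ms <- deadline_ms - 100
  ssd_now <- stats::setNames(rep(ssd_start_ms, 2), c("left", "right"))
  ssd <- numeric(n)
  success <- logical(n)
  for (i in seq_len(n)) {
    d <- ssd_now[[side[i]]]
    ssd[i] <- d
    stop_wins <- stop_launch[i] && (!go_launch[i] || d + t_stop[i] < t_go[i])
    success[i] <- stop_wins && !wrong_sel[i] && (d + t_sel[i] <= deadline_ms)
    delta <- if (success[i]) step_ms else -step_ms
    ssd_now[[side[i]]] <- min(max(d + delta, floor_ms), ceiling_ms)
  }
  data.frame(
    stimulus = stim, condition = condition, ssd_ms = ssd,
    t_go = ifelse(go_launch, t_go, NA_real_),
    t_stop = ifelse(stop_launch, t_stop, NA_real_),
    t_sel = ifelse(stop_launch, t_sel, NA_real_),
    stop_success = success,
    margin_ms = ifelse(go_launch & stop_launch, t_go - (ssd + t_stop),
                       NA_real_),
    stringsAsFactors = FALSE
  )
}
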