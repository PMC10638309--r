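#' Ground-truth settings for a synthetic selective-stopping study
#'
#' `group_truth()` defines the hyper-means and between-subject SDs of
#' every SIS parameter under a chosen variant, at the scale typical of
#' human selective-stopping studies: reactive bimanual go running time
#' around 450 ms, slowed to about 480 ms by proactive cues; a
#' condition-invariant dual-stop runner around 200 ms; selective
#' (unimanual) runners around 316 ms reactive and 289 ms proactive; and
#' small go-failure, trigger-failure and wrong-hand rates. Probability
#' parameters are held on the probit scale.
#'
#' `study_design()` collects the task-design settings: two conditions of
#' 576 trials each, one third selective-stop trials balanced
#' left/right, SSD staircased by 50 ms from 200 ms, 1100 ms deadline.
#'
#' @param variant a [sis_variant()]; the truth is expressed in its
#'   parameterisation.
#' @param means,sds optional named overrides of individual hyper-means
#'   or SDs.
#' @return `group_truth`: list with `variant`, `means`, `sds` (named by
#'   sampled parameter); `study_design`: list of design settings.
#' @examples
#' tr <- group_truth()
#' tr$means[["dual_go.mu.proactive"]] - tr$means[["dual_go.mu.reactive"]]
#' @export
group_truth <- function(variant = sis_variant(1), means = NULL, sds = NULL) {
  ptab <- variant_param_table(variant)
  base_means <- list(
    dual_go = list(reactive = c(mu = 380, sigma = 50, tau = 70),
                   proactive = c(mu = 410, sigma = 50, tau = 70)),
    dual_stop = list(reactive = c(mu = 150, sigma = 30, tau = 50),
                     proactive = c(mu = 150, sigma = 30, tau = 50)),
    sel_left = list(reactive = c(mu = 256, sigma = 40, tau = 60),
                    proactive = c(mu = 229, sigma = 40, tau = 60)),
    sel_right = list(reactive = c(mu = 256, sigma = 40, tau = 60),
                     proactive = c(mu = 229, sigma = 40, tau = 60))
  )
  base_probs <- c(gf = stats::qnorm(0.02), tf = stats::qnorm(0.05),
                  eps_wrong = stats::qnorm(0.01))
  sd_by_par <- c(mu = 20, sigma = 8, tau = 10,
                 gf = 0.15, tf = 0.15, eps_wrong = 0.15)
  m <- s <- stats::setNames(numeric(nrow(ptab)), ptab$name)
  for (j in seq_len(nrow(ptab))) {
    row <- ptab[j, ]
    if (row$runner == "prob") {
      m[j] <- base_probs[[row$par]]
    } else if (row$condition == "shared") {
      m[j] <- mean(vapply(c("reactive", "proactive"),
                          function(cn) base_means[[row$runner]][[cn]][[row$par]],
                          numeric(1)))
    } else {
      m[j] <- base_means[[row$runner]][[row$condition]][[row$par]]
    }
    s[j] <- sd_by_par[[row$par]]
  }
  if (!is.null(means)) m[names(means)] <- means
  if (!is.null(sds)) s[names(sds)] <- sds
  if (any(s < 0)) stop("hyper-SDs must be non-negative", call. = FALSE)
  structure(list(variant = variant, means = m, sds = s),
            class = "group_truth")
}

#' @rdname group_truth
#' @param trials_per_condition,stop_fraction,ssd_start_ms,step_ms,deadline_ms
#'   design settings.
#' @param conditions condition labels.
#' @export
study_design <- function(conditions = c("reactive", "proactive"),
                         trials_per_condition = 576, stop_fraction = 1 / 3,
                         ssd_start_ms = 200, step_ms = 50,
                         deadline_ms = 1100) {
  list(conditions = conditions, trials_per_condition = trials_per_condition,
       stop_fraction = stop_fraction, ssd_start_ms = ssd_start_ms,
       step_ms = step_ms, deadline_ms = deadline_ms)
}

#' Draw a synthetic cohort of subject-level SIS parameters
#'
#' Subject parameter vectors are drawn from truncated normals around the
#' ground-truth hyper-means; draws are reproducible given the seed.
#'
#' @param truth a [group_truth()] object.
#' @param n_subjects cohort size.
#' @param seed integer seed.
#' @return list with `theta` (subjects x parameters matrix), `params`
#'   (list of [sis_params()] per subject) and the `truth` used.
#' @export
sample_group <- function(truth = group_truth(), n_subjects = 8, seed = 1) {
  ptab <- variant_param_table(truth$variant)
  if (any(truth$means < ptab$lower | truth$means > ptab$upper)) {
    stop("hyper-means must lie inside the parameter supports", call. = FALSE)
  }
  set.seed(as.integer(seed))
  k <- nrow(ptab)
  theta <- matrix(NA_real_, n_subjects, k,
                  dimnames = list(NULL, ptab$name))
  for (j in seq_len(k)) {
    theta[, j] <- rtnorm(n_subjects, truth$means[j], truth$sds[j],
                         ptab$lower[j], ptab$upper[j])
  }
  params <- lapply(seq_len(n_subjects), function(i) {
    vector_to_params(theta[i, ], ptab)
  })
  list(theta = theta, params = params, truth = truth)
}

# truncated-normal draws by inverse CDF (exact, vectorised); sd = 0
# degenerates to the mean
rtnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Simulate a full synthetic study with live SSD staircases
#'
#' Runs every subject through both conditions of the selective-stopping
#' task: schedules from [build_schedule()], per-(condition, side) SSD
#' staircases updated trial by trial, and responses generated by the SIS
#' race rule. Bimanual responses get per-hand press times with a small
#' Gaussian asynchrony (SD 25 ms) around the dual-go finish so that
#' simultaneity cleaning has realistic work to do. Latent finish times
#' are retained for recovery tests.
#'
#' @param cohort output of [sample_group()], or a list of
#'   [sis_params()] (one per subject).
#' @param design a [study_design()] list.
#' @param seed integer seed; subject and condition streams are split
#'   deterministically from it.
#' @param asynchrony_sd_ms SD of the bimanual press asynchrony.
#' @return list with `trials` (observed table: participant, condition,
#'   trial, stimulus, ssd_ms, response, rt_ms, per-hand press times),
#'   `latents` (row-matched latent finish times, launch flags, margins,
#'   `stop_success`), and `staircase` (SSD trajectory per condition and
#'   side).
#' @export
generate_behaviour <- function(cohort, design = study_design(), seed = 1,
                               asynchrony_sd_ms = 25) {
  params_list <- if (!is.null(cohort$params)) cohort$params else cohort
  ns <- length(params_list)
  obs <- lat <- stair <- list()
  for (i in seq_len(ns)) {
    for (ci in seq_along(design$conditions)) {
      cn <- design$conditions[ci]
      sub_seed <- (as.integer(seed) + 7919L * i + 104729L * ci) %% 2147483647L
      res <- simulate_condition(params_list[[i]], cn, design, sub_seed,
                                asynchrony_sd_ms)
      res$trials$participant <- i
      res$latents$participant <- i
      res$staircase$participant <- i
      obs[[length(obs) + 1L]] <- res$trials
      lat[[length(lat) + 1L]] <- res$latents
      stair[[length(stair) + 1L]] <- res$staircase
    }
  }
  list(trials = do.call(rbind, obs), latents = do.call(rbind, lat),
       staircase = do.call(rbind, stair))
}

simulate_condition <- function(params, condition, design, seed,
                               asynchrony_sd_ms) {
  set.seed(seed)
  sched <- build_schedule(condition, design$trials_per_condition,
                          design$stop_fraction,
                          deadline_ms = design$deadline_ms)
  n <- nrow(sched)
  stim <- sched$stimulus
  stop_trial <- stim != "DS"
  side <- ifelse(stim == "LS", "right", "left")   # hand required to stop
  deadline <- design$deadline_ms

  go_launch <- stats::runif(n) >= params$gf
  stop_launch <- stop_trial & stats::runif(n) >= params$tf
  wrong_sel <- stats::runif(n) < params$eps_wrong
  dg <- runner_for(params, "dual_go", condition)
  st <- runner_for(params, "dual_stop", condition)
  t_go <- rexgauss(n, dg$mu, dg$sigma, dg$tau)
  t_stop <- rexgauss(n, st$mu, st$sigma, st$tau)
  t_sel <- rep(NA_real_, n)
  sel_name <- ifelse(xor(stim == "LS", wrong_sel), "sel_left", "sel_right")
  for (r in c("sel_left", "sel_right")) {
    ri <- which(stop_trial & sel_name == r)
    if (!length(ri)) next
    pr <- runner_for(params, r, condition)
    t_sel[ri] <- rexgauss(length(ri), pr$mu, pr$sigma, pr$tau)
  }

  ssd_now <- stats::setNames(rep(design$ssd_start_ms, 2), c("left", "right"))
  floor_ms <- 0; ceiling_ms <- deadline - 100
  ssd <- rep(NA_real_, n)
  stop_wins <- success <- rep(NA, n)
  for (t in which(stop_trial)) {
    d <- ssd_now[[side[t]]]
    ssd[t] <- d
    stop_wins[t] <- stop_launch[t] &&
      (!go_launch[t] || d + t_stop[t] < t_go[t])
    success[t] <- stop_wins[t] && !wrong_sel[t] &&
      (d + t_sel[t] <= deadline)
    delta <- if (success[t]) design$step_ms else -design$step_ms
    ssd_now[[side[t]]] <- min(max(d + delta, floor_ms), ceiling_ms)
  }

  response <- rep("NR", n)
  rt <- left_press <- right_press <- rep(NA_real_, n)
  asyn <- stats::rnorm(n, 0, asynchrony_sd_ms)
  # dual responses: go trials, and failed stops where the go runner won
  dr <- (go_launch & !stop_trial & t_go <= deadline) |
    (stop_trial & go_launch & !stop_wins & t_go <= deadline)
  response[dr] <- "DR"
  left_press[dr] <- t_go[dr] + asyn[dr] / 2
  right_press[dr] <- t_go[dr] - asyn[dr] / 2
  rt[dr] <- t_go[dr]
  # unimanual responses after successful inhibition
  uni <- which(stop_trial & stop_wins & (ssd + t_sel <= deadline))
  resp_uni <- ifelse(sel_name[uni] == "sel_left", "LR", "RR")
  response[uni] <- resp_uni
  rt[uni] <- ssd[uni] + t_sel[uni]
  left_press[uni[resp_uni == "LR"]] <- rt[uni[resp_uni == "LR"]]
  right_press[uni[resp_uni == "RR"]] <- rt[uni[resp_uni == "RR"]]

  trials <- data.frame(
    condition = condition, trial = sched$trial, stimulus = stim,
    cue = sched$cue, ssd_ms = ssd, response = response, rt_ms = rt,
    left_press_ms = left_press, right_press_ms = right_press,
    foreperiod_ms = sched$foreperiod_ms, deadline_ms = deadline,
    stringsAsFactors = FALSE)
  latents <- data.frame(
    condition = condition, trial = sched$trial, stimulus = stim,
    ssd_ms = ssd, go_launched = go_launch,
    stop_launched = ifelse(stop_trial, stop_launch, NA),
    t_go = ifelse(go_launch, t_go, NA_real_),
    t_stop = ifelse(stop_trial & stop_launch, t_stop, NA_real_),
    t_sel = ifelse(stop_trial & stop_launch, t_sel, NA_real_),
    margin_ms = ifelse(stop_trial & go_launch & stop_launch,
                       t_go - (ssd + t_stop), NA_real_),
    stop_success = success, response = response, rt_ms = rt,
    stringsAsFactors = FALSE)
  staircase <- data.frame(
    condition = condition, trial = sched$trial[stop_trial],
    side = side[stop_trial], ssd_ms = ssd[stop_trial],
    stop_success = success[stop_trial], stringsAsFactors = FALSE)
  list(trials = trials, latents = latents, staircase = staircase)
}
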