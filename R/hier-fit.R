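#' Hierarchical Bayesian estimation of the SIS model
#'
#' Fits the SIS race model to multi-participant trial data by
#' differential-evolution MCMC (DE-MCMC), in two stages: each
#' participant is first fitted separately, and those individual
#' posteriors seed the chains of the hierarchical run, which samples
#' subject-level parameters together with truncated-normal group
#' location/scale parameters. Sampling proceeds in windows until
#' split-R-hat convergence, after which a fixed post-convergence window
#' of iterations is retained for all analyses.
#'
#' Chains follow the crossover rule `theta* = theta + gamma (theta_a -
#' theta_b) + U(-e, e)` with `gamma = 2.38 / sqrt(2 k)` (occasionally 1,
#' for mode jumps), with at least `3 k` chains for `k` sampled
#' parameters.
#'
#' @param data data.frame of cleaned observed trials with columns
#'   `participant`, `condition`, `stimulus` (`DS`/`LS`/`RS`),
#'   `ssd_ms` (stop trials), `response` (`NR`/`DR`/`LR`/`RR`), `rt_ms`.
#' @param variant a [sis_variant()] or variant id (1, 3, 4 or 5).
#' @param priors prior table from [sis_priors()]; defaults to the
#'   package's weakly-informative settings.
#' @param sampler named list overriding sampler settings:
#'   `n_chains` (default `3 * k`), `ind_iterations` (individual-stage
#'   iterations, 150), `window` (iterations per convergence check, 50),
#'   `max_windows` (8), `retain` (post-convergence iterations, 250),
#'   `rhat_tol` (1.10), `gamma_jump_prob` (0.1), `jitter` (0.001),
#'   `migrate_prob` (probability per burn-in iteration of a chain
#'   migration move, 0.05; migration clones states, so it is kept rare
#'   to preserve ensemble diversity).
#' @param seed integer seed; fits are exactly reproducible given the
#'   same data, settings and seed.
#' @param deadline_ms response window in ms.
#' @param conditions condition labels (order fixes the contrast sign).
#' @return an object of class `sis_fit` carrying retained draws
#'   (`subj`: chains x iterations x parameters x subjects; `group`:
#'   chains x iterations x 2k location/scale parameters), per-iteration
#'   summed log-likelihoods, the parameter table, convergence
#'   diagnostics and sampler metadata.
#' @seealso [bpic()], [posterior_contrasts()], [convergence_diagnostics()]
#' @export
fit_sis <- function(data, variant = 1, priors = NULL, sampler = list(),
                    seed = 1, deadline_ms = 1100,
                    conditions = c("reactive", "proactive")) {
  if (!inherits(variant, "sis_variant")) variant <- sis_variant(variant)
  stopifnot(all(c("participant", "condition", "stimulus", "response")
                %in% names(data)))
  subjects <- sort(unique(data$participant))
  if (length(subjects) < 2) {
    stop("hierarchical fitting requires at least 2 participants",
         call. = FALSE)
  }
  for (s in subjects) {
    d <- data[data$participant == s, ]
    if (!any(d$stimulus == "DS") || !any(d$stimulus != "DS")) {
      stop("participant ", s, " lacks go or stop trials", call. = FALSE)
    }
  }
  ptab <- if (is.null(priors)) sis_priors(variant, conditions) else priors
  k <- nrow(ptab)
  cfg <- utils::modifyList(list(
    n_chains = 3L * k, ind_iterations = 150L, window = 50L,
    max_windows = 8L, retain = 250L, rhat_tol = 1.10,
    gamma_jump_prob = 0.1, jitter = 1e-3, migrate_prob = 0.05,
    ess_min = 200
  ), sampler)
  nch <- cfg$n_chains
  if (nch < 3 * k) {
    stop("crossover sampling needs at least 3 x ", k, " chains", call. = FALSE)
  }
  set.seed(as.integer(seed))

  dat <- lapply(subjects, function(s) {
    prep_subject(data[data$participant == s, ], conditions, deadline_ms)
  })
  ns <- length(subjects)
  pm_idx <- parmat_index(ptab, conditions)
  lower <- ptab$lower; upper <- ptab$upper

  ll_fun <- function(theta, d) {
    pm <- matrix(theta[pm_idx], nrow = length(conditions))
    base::sum(sis_loglik_cpp(d$stim, d$resp, d$rt, d$ssd, d$cond, pm,
                             stats::pnorm(theta[k - 2L]),
                             stats::pnorm(theta[k - 1L]),
                             stats::pnorm(theta[k]),
                             1e-10, deadline_ms))
  }

  gamma_s <- 2.38 / sqrt(2 * k)
  propose <- function(states, gamma0) {
    n <- nrow(states)
    a <- integer(n); b <- integer(n)
    for (c in seq_len(n)) {
      ab <- sample.int(n - 1L, 2L)
      ab[ab >= c] <- ab[ab >= c] + 1L
      a[c] <- ab[1]; b[c] <- ab[2]
    }
    g <- ifelse(stats::runif(n) < cfg$gamma_jump_prob, 1, gamma0)
    states + g * (states[a, , drop = FALSE] - states[b, , drop = FALSE]) +
      matrix(stats::runif(n * ncol(states), -cfg$jitter, cfg$jitter), n)
  }

  ## ---- stage 1: individual fits (start points for the hierarchy) ----
  ind_prior <- function(theta) {
    base::sum(dtnorm_log(theta, ptab$loc_mean, ptab$loc_sd * 1.5,
                         lower, upper))
  }
  subj_state <- vector("list", ns)      # one nch x k matrix per subject
  for (i in seq_len(ns)) {
    start <- start_heuristic(data[data$participant == subjects[i], ],
                             ptab, conditions)
    states <- jitter_start(start, nch, ptab)
    tgt <- apply(states, 1, function(th) ll_fun(th, dat[[i]]) + ind_prior(th))
    for (it in seq_len(cfg$ind_iterations)) {
      prop <- propose(states, gamma_s)
      for (c in seq_len(nch)) {
        th <- prop[c, ]
        if (any(th < lower | th > upper)) next
        t_new <- ll_fun(th, dat[[i]]) + ind_prior(th)
        if (is.finite(t_new) &&
            log(stats::runif(1)) < t_new - tgt[c]) {
          states[c, ] <- th; tgt[c] <- t_new
        }
      }
    }
    subj_state[[i]] <- states
  }

  ## ---- stage 2: hierarchical run ----
  # chain-wise mean and SD over subjects of the individual-stage states
  loc <- Reduce(`+`, subj_state) / ns                      # nch x k
  sq <- Reduce(`+`, lapply(subj_state, function(m) (m - loc)^2))
  scale0 <- sqrt(sq / max(ns - 1, 1))
  loc <- loc * matrix(exp(stats::rnorm(nch * k, 0, 0.02)), nch)
  loc <- pmin(pmax(loc, rep(lower, each = nch) + 1e-6),
              rep(upper, each = nch) - 1e-6)
  scale0 <- pmin(pmax(scale0 * matrix(exp(stats::rnorm(nch * k, 0, 0.05)), nch),
                      rep(ptab$scale_lower, each = nch) + 1e-6),
                 rep(ptab$scale_upper, each = nch) - 1e-6)
  group <- cbind(loc, scale0)           # nch x 2k

  cur_ll <- matrix(NA_real_, nch, ns)   # data loglik per chain x subject
  for (i in seq_len(ns)) {
    cur_ll[, i] <- apply(subj_state[[i]], 1, ll_fun, d = dat[[i]])
  }
  group_dens <- function(gvec, theta_mat) {
    # theta_mat: k x ns matrix of one chain's subject params
    colSums(dtnorm_log(theta_mat, gvec[1:k], gvec[(k + 1):(2 * k)],
                       lower, upper))
  }
  hyper_dens <- function(gvec) {
    base::sum(dtnorm_log(gvec[1:k], ptab$loc_mean, ptab$loc_sd,
                         lower, upper)) +
      base::sum(dtnorm_log(gvec[(k + 1):(2 * k)], ptab$scale_mean,
                           ptab$scale_sd, ptab$scale_lower, ptab$scale_upper))
  }
  cur_gd <- matrix(NA_real_, nch, ns)   # group density per chain x subject
  cur_hyper <- numeric(nch)
  for (c in seq_len(nch)) {
    theta_mat <- vapply(subj_state, function(m) m[c, ], numeric(k))
    cur_gd[c, ] <- group_dens(group[c, ], theta_mat)
    cur_hyper[c] <- hyper_dens(group[c, ])
  }
  gamma_g <- 2.38 / sqrt(2 * 2)       # per-parameter (loc, scale) blocks
  blocks <- split(seq_len(k), paste(ptab$runner, ptab$condition))

  one_iteration <- function(migrate = FALSE) {
    # group-level crossover, blocked per sampled parameter: each block
    # updates that parameter's population location and scale jointly,
    # vectorised across chains
    for (j in seq_len(k)) {
      cols <- c(j, k + j)
      cur <- group[, cols, drop = FALSE]
      a <- b <- integer(nch)
      for (c in seq_len(nch)) {
        ab <- sample.int(nch - 1L, 2L)
        ab[ab >= c] <- ab[ab >= c] + 1L
        a[c] <- ab[1]; b[c] <- ab[2]
      }
      g <- ifelse(stats::runif(nch) < cfg$gamma_jump_prob, 1, gamma_g)
      prop <- cur + g * (cur[a, , drop = FALSE] - cur[b, , drop = FALSE]) +
        matrix(stats::runif(2 * nch, -cfg$jitter, cfg$jitter), nch)
      ok <- prop[, 1] >= lower[j] & prop[, 1] <= upper[j] &
        prop[, 2] >= ptab$scale_lower[j] & prop[, 2] <= ptab$scale_upper[j]
      prop[!ok, 1] <- cur[!ok, 1]
      prop[!ok, 2] <- cur[!ok, 2]
      S <- vapply(subj_state, function(m) m[, j], numeric(nch))  # nch x ns
      curd <- dtnorm_log(S, cur[, 1], cur[, 2], lower[j], upper[j])
      newd <- dtnorm_log(S, prop[, 1], prop[, 2], lower[j], upper[j])
      hyp_cur <- dtnorm_log(cur[, 1], ptab$loc_mean[j], ptab$loc_sd[j],
                            lower[j], upper[j]) +
        dtnorm_log(cur[, 2], ptab$scale_mean[j], ptab$scale_sd[j],
                   ptab$scale_lower[j], ptab$scale_upper[j])
      hyp_new <- dtnorm_log(prop[, 1], ptab$loc_mean[j], ptab$loc_sd[j],
                            lower[j], upper[j]) +
        dtnorm_log(prop[, 2], ptab$scale_mean[j], ptab$scale_sd[j],
                   ptab$scale_lower[j], ptab$scale_upper[j])
      delta <- rowSums(newd) - rowSums(curd) + hyp_new - hyp_cur
      acc <- ok & is.finite(delta) & log(stats::runif(nch)) < delta
      if (any(acc)) {
        group[acc, cols] <<- prop[acc, ]
        cur_gd[acc, ] <<- cur_gd[acc, , drop = FALSE] +
          (newd - curd)[acc, , drop = FALSE]
        cur_hyper[acc] <<- cur_hyper[acc] + (hyp_new - hyp_cur)[acc]
      }
    }
    # subject-level crossover (full parameter vector; needs the data
    # likelihood, so chains are walked individually), followed by a
    # random-block refresh that speeds within-chain mixing of weakly
    # identified dimensions
    bl <- blocks[[sample.int(length(blocks), 1L)]]
    gamma_b <- 2.38 / sqrt(2 * length(bl))
    for (i in seq_len(ns)) {
      prop <- propose(subj_state[[i]], gamma_s)
      for (pass in 1:2) {
        if (pass == 2) {
          states <- subj_state[[i]]
          prop <- states
          prop[, bl] <- propose(states[, bl, drop = FALSE], gamma_b)
        }
        for (c in seq_len(nch)) {
          th <- prop[c, ]
          if (any(th < lower | th > upper)) next
          gd_new <- base::sum(dtnorm_log(th, group[c, 1:k],
                                         group[c, (k + 1):(2 * k)],
                                         lower, upper))
          if (!is.finite(gd_new)) next
          ll_new <- ll_fun(th, dat[[i]])
          delta <- (ll_new + gd_new) - (cur_ll[c, i] + cur_gd[c, i])
          if (is.finite(delta) && log(stats::runif(1)) < delta) {
            subj_state[[i]][c, ] <<- th
            cur_ll[c, i] <<- ll_new
            cur_gd[c, i] <<- gd_new
          }
        }
      }
    }
    # migration (burn-in only): a random cycle of chains trades full
    # states so stragglers can join the converged ensemble
    if (migrate && stats::runif(1) < cfg$migrate_prob) {
      m <- max(2L, round(0.1 * nch))
      cyc <- sample.int(nch, m)
      tot <- rowSums(cur_ll) + rowSums(cur_gd) + cur_hyper
      from <- c(cyc[-1], cyc[1])
      for (s in seq_len(m)) {
        c_to <- cyc[s]; c_from <- from[s]
        if (log(stats::runif(1)) < tot[c_from] - tot[c_to]) {
          group[c_to, ] <<- group[c_from, ]
          for (i in seq_len(ns)) {
            subj_state[[i]][c_to, ] <<- subj_state[[i]][c_from, ]
          }
          cur_ll[c_to, ] <<- cur_ll[c_from, ]
          cur_gd[c_to, ] <<- cur_gd[c_from, ]
          cur_hyper[c_to] <<- cur_hyper[c_from]
          tot[c_to] <- tot[c_from]
        }
      }
    }
  }

  # burn in windows until split-R-hat on the group parameters passes
  converged <- FALSE
  windows_run <- 0L
  rhat_trace <- numeric(0)
  gstore <- array(NA_real_, c(nch, cfg$window, 2 * k))
  while (windows_run < cfg$max_windows && !converged) {
    for (it in seq_len(cfg$window)) {
      one_iteration(migrate = TRUE)
      gstore[, it, ] <- group
    }
    windows_run <- windows_run + 1L
    rh <- apply(gstore, 3, split_rhat)
    rhat_trace <- c(rhat_trace, max(rh, na.rm = TRUE))
    converged <- all(is.finite(rh)) && max(rh) < cfg$rhat_tol
  }

  # retained post-convergence window
  nr <- cfg$retain
  subj_draws <- array(NA_real_, c(nch, nr, k, ns),
                      dimnames = list(NULL, NULL, ptab$name, subjects))
  group_draws <- array(NA_real_, c(nch, nr, 2 * k),
                       dimnames = list(NULL, NULL,
                                       c(paste0("loc.", ptab$name),
                                         paste0("scale.", ptab$name))))
  ll_draws <- matrix(NA_real_, nch, nr)
  for (it in seq_len(nr)) {
    one_iteration()
    for (i in seq_len(ns)) subj_draws[, it, , i] <- subj_state[[i]]
    group_draws[, it, ] <- group
    ll_draws[, it] <- rowSums(cur_ll)
  }

  fit <- structure(list(
    variant = variant, param_table = ptab, conditions = conditions,
    subjects = subjects, subj = subj_draws, group = group_draws,
    ll = ll_draws, data = data, deadline_ms = deadline_ms,
    sampler = cfg, seed = seed, converged = converged,
    burn_windows = windows_run, rhat_trace = rhat_trace
  ), class = "sis_fit")
  fit$diagnostics <- convergence_diagnostics(fit)
  fit
}

# integer index matrix: parmat[cond, col] = theta[pm_idx[cond, col]]
parmat_index <- function(ptab, conditions) {
  idx <- matrix(0L, nrow = length(conditions), ncol = 12)
  col <- 0L
  for (r in RUNNERS) {
    for (p in EXG_PARS) {
      col <- col + 1L
      for (ci in seq_along(conditions)) {
        idx[ci, col] <- which(ptab$runner == r & ptab$par == p &
                                ptab$condition %in% c(conditions[ci], "shared"))[1]
      }
    }
  }
  idx
}

prep_subject <- function(d, conditions, deadline_ms) {
  stim <- match(d$stimulus, STIM_LEVELS) - 1L
  resp <- match(d$response, RESP_LEVELS) - 1L
  cond <- match(d$condition, conditions) - 1L
  if (anyNA(stim) || anyNA(resp) || anyNA(cond)) {
    stop("unknown stimulus/response/condition label", call. = FALSE)
  }
  rt <- d$rt_ms
  if (any(resp != 0L & (is.na(rt) | rt <= 0 | rt > deadline_ms))) {
    stop("non-NR trials must have rt_ms in (0, deadline]", call. = FALSE)
  }
  ssd <- if ("ssd_ms" %in% names(d)) d$ssd_ms else rep(NA_real_, nrow(d))
  list(stim = stim, resp = resp, rt = ifelse(is.na(rt), -1, rt),
       ssd = ifelse(is.na(ssd), 0, ssd), cond = cond)
}

# moment-based start values from a subject's own data
start_heuristic <- function(d, ptab, conditions) {
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  moments <- function(x, m0, s0) {
    x <- x[is.finite(x)]
    if (length(x) < 5) return(c(m0, s0))
    c(mean(x), stats::sd(x))
  }
  exg_from_moments <- function(ms) {
    tau <- clamp(0.5 * ms[2], 20, 300)
    mu <- clamp(ms[1] - tau, 30, 1500)
    sigma <- clamp(sqrt(max(ms[2]^2 - tau^2, 400)), 10, 200)
    c(mu = mu, sigma = sigma, tau = tau)
  }
  vals <- list()
  for (cn in conditions) {
    dc <- d[d$condition == cn, ]
    go <- moments(dc$rt_ms[dc$stimulus == "DS" & dc$response == "DR"],
                  450, 110)
    sl <- moments(dc$rt_ms[dc$stimulus == "LS" & dc$response == "LR"] -
                    dc$ssd_ms[dc$stimulus == "LS" & dc$response == "LR"],
                  300, 80)
    sr <- moments(dc$rt_ms[dc$stimulus == "RS" & dc$response == "RR"] -
                    dc$ssd_ms[dc$stimulus == "RS" & dc$response == "RR"],
                  300, 80)
    vals[[cn]] <- list(dual_go = exg_from_moments(go),
                       dual_stop = c(mu = 150, sigma = 30, tau = 50),
                       sel_left = exg_from_moments(sl),
                       sel_right = exg_from_moments(sr))
  }
  ds <- d[d$stimulus == "DS", ]
  gf0 <- clamp(mean(ds$response == "NR"), 0.005, 0.3)
  stp <- d[d$stimulus != "DS", ]
  wrong <- mean((stp$stimulus == "LS" & stp$response == "RR") |
                  (stp$stimulus == "RS" & stp$response == "LR"))
  eps0 <- clamp(ifelse(is.finite(wrong), wrong * 2, 0.01), 0.005, 0.2)
  probs <- c(gf = stats::qnorm(gf0), tf = stats::qnorm(0.05),
             eps_wrong = stats::qnorm(eps0))
  theta <- numeric(nrow(ptab))
  for (j in seq_len(nrow(ptab))) {
    row <- ptab[j, ]
    if (row$runner == "prob") {
      theta[j] <- probs[[row$par]]
    } else if (row$condition == "shared") {
      theta[j] <- mean(vapply(conditions,
                              function(cn) vals[[cn]][[row$runner]][[row$par]],
                              numeric(1)))
    } else {
      theta[j] <- vals[[row$condition]][[row$runner]][[row$par]]
    }
  }
  theta
}

jitter_start <- function(start, nch, ptab) {
  k <- length(start)
  states <- matrix(start, nch, k, byrow = TRUE)
  ms <- ptab$runner != "prob"
  states[, ms] <- states[, ms] * exp(matrix(stats::rnorm(nch * base::sum(ms),
                                                         0, 0.08), nch))
  states[, !ms] <- states[, !ms] + matrix(stats::rnorm(nch * base::sum(!ms),
                                                       0, 0.2), nch)
  pmin(pmax(states, rep(ptab$lower, each = nch) + 1e-6),
       rep(ptab$upper, each = nch) - 1e-6)
}
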