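#' SIS model variants
#'
#' The model variants differ in which runners' ex-Gaussian parameters
#' are allowed to differ between the proactive and reactive conditions.
#' Variant 1 lets the dual-go and both selective runners vary but
#' constrains the dual-stop runner to be condition-invariant; variant 3
#' additionally fixes the dual-go runner; variant 4 instead fixes the
#' selective runners; variant 5 lets all four runners vary. (Variant ids
#' are kept as 1/3/4/5 for traceability with the numbering convention
#' they come from; 2 is deliberately absent.) The failure probabilities
#' `gf`, `tf`, `eps_wrong` are shared across conditions in all variants
#' and sampled on the probit scale.
#'
#' @param id variant id: 1, 3, 4 or 5.
#' @return a `sis_variant` object with the per-runner `vary` map.
#' @examples
#' sis_variant(1)$vary
#' @export
sis_variant <- function(id) {
  id <- as.integer(id)
  vary <- switch(as.character(id),
    "1" = c(dual_go = TRUE,  dual_stop = FALSE, sel_left = TRUE,  sel_right = TRUE),
    "3" = c(dual_go = FALSE, dual_stop = FALSE, sel_left = TRUE,  sel_right = TRUE),
    "4" = c(dual_go = TRUE,  dual_stop = FALSE, sel_left = FALSE, sel_right = FALSE),
    "5" = c(dual_go = TRUE,  dual_stop = TRUE,  sel_left = TRUE,  sel_right = TRUE),
    stop("unknown variant id: ", id, " (must be 1, 3, 4 or 5)", call. = FALSE)
  )
  structure(list(id = id, vary = vary), class = "sis_variant")
}

RUNNERS <- c("dual_go", "dual_stop", "sel_left", "sel_right")
EXG_PARS <- c("mu", "sigma", "tau")
PROB_PARS <- c("gf", "tf", "eps_wrong")

# parameter-vector layout for a variant: one entry per sampled parameter
variant_param_table <- function(variant,
                                conditions = c("reactive", "proactive")) {
  rows <- list()
  for (r in RUNNERS) {
    conds <- if (variant$vary[[r]]) conditions else "shared"
    for (p in EXG_PARS) {
      for (cn in conds) {
        rows[[length(rows) + 1L]] <- data.frame(
          name = paste(r, p, cn, sep = "."), runner = r, par = p,
          condition = cn, stringsAsFactors = FALSE)
      }
    }
  }
  for (p in PROB_PARS) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = p, runner = "prob", par = p, condition = "shared",
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  bounds <- list(mu = c(1, 2000), sigma = c(1, 500), tau = c(1, 1000),
                 gf = c(-6, 6), tf = c(-6, 6), eps_wrong = c(-6, 6))
  tab$lower <- vapply(tab$par, function(p) bounds[[p]][1], numeric(1))
  tab$upper <- vapply(tab$par, function(p) bounds[[p]][2], numeric(1))
  tab
}

# subject-level parameter vector -> sis_params (probit probabilities
# mapped back through pnorm)
vector_to_params <- function(theta, ptab,
                             conditions = c("reactive", "proactive"),
                             p_floor = 1e-10) {
  runner_list <- lapply(stats::setNames(RUNNERS, RUNNERS), function(r) {
    rows <- ptab[ptab$runner == r, ]
    lapply(stats::setNames(conditions, conditions), function(cn) {
      pick <- function(p) {
        i <- which(rows$par == p &
                     rows$condition %in% c(cn, "shared"))[1]
        theta[[rows$name[i]]]
      }
      runner_params(pick("mu"), pick("sigma"), pick("tau"))
    })
  })
  sis_params(dual_go = runner_list$dual_go,
             dual_stop = runner_list$dual_stop,
             sel_left = runner_list$sel_left,
             sel_right = runner_list$sel_right,
             gf = stats::pnorm(theta[["gf"]]),
             tf = stats::pnorm(theta[["tf"]]),
             eps_wrong = stats::pnorm(theta[["eps_wrong"]]),
             p_floor = p_floor, conditions = conditions)
}

# 12-col runner matrix + probabilities straight from a parameter vector
# (fast path used inside the sampler; avoids building S3 objects)
vector_to_parmat <- function(theta, ptab,
                             conditions = c("reactive", "proactive")) {
  m <- matrix(0, nrow = length(conditions), ncol = 12)
  col <- 0L
  for (r in RUNNERS) {
    rows <- ptab[ptab$runner == r, ]
    for (p in EXG_PARS) {
      col <- col + 1L
      for (ci in seq_along(conditions)) {
        i <- which(rows$par == p &
                     rows$condition %in% c(conditions[ci], "shared"))[1]
        m[ci, col] <- theta[[rows$name[i]]]
      }
    }
  }
  m
}

#' Weakly-informative default priors for hierarchical SIS fitting
#'
#' Group-location priors are truncated normals wide enough to cover
#' plausible human latencies: `mu ~ N(400, 200)` on (1, 2000) ms,
#' `sigma ~ N(50, 50)` on (1, 500), `tau ~ N(100, 100)` on (1, 1000);
#' failure probabilities get `N(-1.5, 1)` on the probit scale. Group
#' scales (between-subject SDs) get half-width truncated normals.
#'
#' @param variant a [sis_variant()].
#' @param conditions condition labels.
#' @return a data.frame with one row per sampled parameter: location
#'   prior mean/SD, scale prior mean/SD and support bounds.
#' @export
sis_priors <- function(variant, conditions = c("reactive", "proactive")) {
  ptab <- variant_param_table(variant, conditions)
  loc <- list(mu = c(400, 200), sigma = c(50, 50), tau = c(100, 100),
              gf = c(-1.5, 1), tf = c(-1.5, 1), eps_wrong = c(-1.5, 1))
  scl <- list(mu = c(30, 30), sigma = c(15, 15), tau = c(20, 20),
              gf = c(0.5, 0.5), tf = c(0.5, 0.5), eps_wrong = c(0.5, 0.5))
  ptab$loc_mean <- vapply(ptab$par, function(p) loc[[p]][1], numeric(1))
  ptab$loc_sd <- vapply(ptab$par, function(p) loc[[p]][2], numeric(1))
  ptab$scale_mean <- vapply(ptab$par, function(p) scl[[p]][1], numeric(1))
  ptab$scale_sd <- vapply(ptab$par, function(p) scl[[p]][2], numeric(1))
  ptab$scale_lower <- ifelse(ptab$runner == "prob", 0.01, 0.1)
  ptab$scale_upper <- ifelse(ptab$runner == "prob", 3, 300)
  ptab
}

# log density of a truncated normal (vectorised over x/mean/sd)
dtnorm_log <- function(x, mean, sd, lower, upper) {
  out <- stats::dnorm(x, mean, sd, log = TRUE) -
    log(stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd))
  out[x < lower | x > upper] <- -Inf
  out
}
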