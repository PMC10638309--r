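#' Posterior contrasts on runner running times
#'
#' Contrasts are computed on the running-time (`mu + tau`) scale from
#' individual-level estimates: for every retained posterior draw the
#' subject-level `mu + tau` of each side of the contrast is averaged
#' across subjects, the difference is taken draw-wise, and the draws are
#' summarised by the median and central 95% credible interval.
#'
#' @param fit a [fit_sis()] object.
#' @param runner1,runner2 runner names (`"dual_go"`, `"dual_stop"`,
#'   `"sel_left"`, `"sel_right"`); `runner2` defaults to `runner1` for a
#'   between-condition contrast of the same runner.
#' @param condition1,condition2 condition labels for each side.
#' @return list with `median`, `ci` (95% credible interval), and the
#'   draw vector (`draws`), all in ms.
#' @examples
#' \dontrun{
#' posterior_contrasts(fit, "dual_go", "proactive", "dual_go", "reactive")
#' }
#' @export
posterior_contrasts <- function(fit, runner1, condition1,
                                runner2 = runner1, condition2) {
  stopifnot(inherits(fit, "sis_fit"))
  d1 <- runtime_draws(fit, runner1, condition1)
  d2 <- runtime_draws(fit, runner2, condition2)
  if (runner1 == runner2 && !fit$variant$vary[[runner1]] &&
      condition1 != condition2) {
    stop("runner '", runner1, "' is constrained to be condition-invariant ",
         "under variant ", fit$variant$id,
         "; a between-condition contrast is not defined", call. = FALSE)
  }
  draws <- d1 - d2
  list(median = stats::median(draws),
       ci = unname(stats::quantile(draws, c(0.025, 0.975))),
       draws = draws)
}

# draw-wise subject-averaged mu + tau of one runner in one condition
runtime_draws <- function(fit, runner, condition) {
  ptab <- fit$param_table
  stopifnot(runner %in% RUNNERS, condition %in% fit$conditions)
  idx <- function(p) {
    which(ptab$runner == runner & ptab$par == p &
            ptab$condition %in% c(condition, "shared"))[1]
  }
  rt <- fit$subj[, , idx("mu"), , drop = FALSE] +
    fit$subj[, , idx("tau"), , drop = FALSE]
  # average over subjects (margin 4), flatten chains x iterations
  as.numeric(apply(rt, c(1, 2), mean))
}

#' Posterior group-level running-time summaries
#'
#' Median and 95% credible interval of the subject-averaged `mu + tau`
#' of each runner in each condition.
#'
#' @param fit a [fit_sis()] object.
#' @return data.frame with one row per runner by condition.
#' @export
running_times <- function(fit) {
  rows <- list()
  for (r in RUNNERS) {
    conds <- if (fit$variant$vary[[r]]) fit$conditions else fit$conditions[1]
    for (cn in fit$conditions) {
      dr <- runtime_draws(fit, r, cn)
      rows[[length(rows) + 1L]] <- data.frame(
        runner = r, condition = if (fit$variant$vary[[r]]) cn else "shared",
        median = stats::median(dr),
        lower = unname(stats::quantile(dr, 0.025)),
        upper = unname(stats::quantile(dr, 0.975)))
      if (!fit$variant$vary[[r]]) break
    }
  }
  unique(do.call(rbind, rows))
}
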