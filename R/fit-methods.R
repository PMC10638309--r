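#' @export
print.sis_fit <- function(x, ...) {
  dm <- dim(x$subj)
  cat(sprintf("Hierarchical SIS fit (variant %d)\n", x$variant$id))
  cat(sprintf("  %d subjects, %d trials\n", length(x$subjects), nrow(x$data)))
  cat(sprintf("  %d chains x %d retained iterations, %d sampled parameters\n",
              dm[1], dm[2], dm[3]))
  cat(sprintf("  burn-in windows: %d (%s)\n", x$burn_windows,
              if (x$converged) "converged" else "max windows reached"))
  dg <- x$diagnostics
  cat(sprintf("  max R-hat %.3f, min ESS %.0f (%s)\n",
              max(dg$table$rhat), min(dg$table$ess),
              if (dg$pass) "pass" else dg$reason))
  invisible(x)
}

#' @export
summary.sis_fit <- function(object, ...) {
  out <- list(running_times = running_times(object),
              diagnostics = object$diagnostics$table,
              variant = object$variant$id,
              converged = object$converged)
  class(out) <- "summary.sis_fit"
  out
}

#' @export
print.summary.sis_fit <- function(x, ...) {
  cat(sprintf("SIS variant %d: posterior running times (mu + tau, ms)\n",
              x$variant))
  rt <- x$running_times
  rt$median <- round(rt$median, 1)
  rt$lower <- round(rt$lower, 1)
  rt$upper <- round(rt$upper, 1)
  print(rt, row.names = FALSE)
  cat(sprintf("max R-hat %.3f, min ESS %.0f\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess)))
  invisible(x)
}

#' @export
coef.sis_fit <- function(object, level = c("group", "subject"), ...) {
  level <- match.arg(level)
  if (level == "group") {
    k <- nrow(object$param_table)
    med <- apply(object$group[, , seq_len(k), drop = FALSE], 3,
                 stats::median)
    stats::setNames(med, object$param_table$name)
  } else {
    m <- apply(object$subj, c(3, 4), stats::median)
    dimnames(m) <- list(object$param_table$name, object$subjects)
    m
  }
}

#' Posterior-predictive simulation from a fitted SIS model
#'
#' Draws a retained posterior draw per replicate and simulates each
#' subject's trials (same design rows as the fitted data) through the
#' race model.
#'
#' @param object a [fit_sis()] object.
#' @param nsim number of posterior-predictive datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `nsim` data.frames shaped like the fitted data.
#' @export
simulate.sis_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  nch <- dim(object$subj)[1]; nit <- dim(object$subj)[2]
  ptab <- object$param_table
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    ch <- sample.int(nch, 1); it <- sample.int(nit, 1)
    reps <- lapply(seq_along(object$subjects), function(i) {
      th <- stats::setNames(object$subj[ch, it, , i], ptab$name)
      pars <- vector_to_params(th, ptab, object$conditions)
      d <- object$data[object$data$participant == object$subjects[i], ]
      sim <- simulate_trials(pars, d[, c("stimulus", "condition", "ssd_ms")],
                             deadline_ms = object$deadline_ms)
      data.frame(participant = object$subjects[i],
                 condition = sim$condition, stimulus = sim$stimulus,
                 ssd_ms = sim$ssd_ms, response = sim$response,
                 rt_ms = sim$rt_ms, stringsAsFactors = FALSE)
    })
    out[[r]] <- do.call(rbind, reps)
  }
  if (nsim == 1) out[[1]] else out
}

#' Plot posterior running times of a fitted SIS model
#'
#' Dot-and-interval plot (posterior median and 95% credible interval)
#' of each runner's `mu + tau` per condition.
#'
#' @param x a [fit_sis()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sis_fit <- function(x, ...) {
  rt <- running_times(x)
  lab <- paste(rt$runner, rt$condition)
  n <- nrow(rt)
  op <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(rt$median, seq_len(n), xlim = range(rt$lower, rt$upper),
                 yaxt = "n", ylab = "", xlab = "running time mu + tau (ms)",
                 pch = 19, ...)
  graphics::segments(rt$lower, seq_len(n), rt$upper, seq_len(n))
  graphics::axis(2, at = seq_len(n), labels = lab, las = 1, cex.axis = 0.8)
  invisible(rt)
}
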