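#' Bayesian predictive information criterion
#'
#' `BPIC = Dbar + 2 pD`, where `Dbar` is the posterior mean deviance
#' (`-2` times the summed data log-likelihood over subjects) and
#' `pD = Dbar - D(theta_bar)` is the effective number of parameters,
#' with `D(theta_bar)` the deviance at the posterior mean of the
#' subject-level parameters. Lower is better; BPIC penalises complexity
#' about twice as strongly as DIC.
#'
#' @param fit a [fit_sis()] object with retained log-likelihoods.
#' @return an object of class `sis_bpic`: list with `bpic`, `mean_dev`
#'   (`Dbar`), `dev_at_mean` (`D(theta_bar)`), `pD`. A negative `pD`
#'   (possible multimodality) attaches a warning but the value is still
#'   returned.
#' @seealso [compare_sis()] for a multi-fit comparison table.
#' @export
bpic <- function(fit) {
  stopifnot(inherits(fit, "sis_fit"))
  d_bar <- mean(-2 * fit$ll)
  theta_bar <- apply(fit$subj, c(3, 4), mean)    # k x ns posterior means
  ptab <- fit$param_table
  k <- nrow(ptab)
  pm_idx <- parmat_index(ptab, fit$conditions)
  d_hat <- 0
  for (i in seq_along(fit$subjects)) {
    d <- prep_subject(fit$data[fit$data$participant == fit$subjects[i], ],
                      fit$conditions, fit$deadline_ms)
    th <- theta_bar[, i]
    pm <- matrix(th[pm_idx], nrow = length(fit$conditions))
    d_hat <- d_hat - 2 * base::sum(sis_loglik_cpp(
      d$stim, d$resp, d$rt, d$ssd, d$cond, pm,
      stats::pnorm(th[k - 2L]), stats::pnorm(th[k - 1L]),
      stats::pnorm(th[k]), 1e-10, fit$deadline_ms))
  }
  pD <- d_bar - d_hat
  if (pD < 0) {
    warning("negative pD (", round(pD, 2),
            "): posterior may be multimodal", call. = FALSE)
  }
  structure(list(bpic = d_bar + 2 * pD, mean_dev = d_bar,
                 dev_at_mean = d_hat, pD = pD, variant = fit$variant$id),
            class = "sis_bpic")
}

#' @export
print.sis_bpic <- function(x, ...) {
  cat(sprintf("BPIC (variant %d): %.2f  [Dbar %.2f, pD %.2f]\n",
              x$variant, x$bpic, x$mean_dev, x$pD))
  invisible(x)
}

#' Compare SIS model variants by BPIC
#'
#' @param ... fitted `sis_fit` objects (optionally named).
#' @return data.frame sorted by BPIC with a `delta_bpic` column relative
#'   to the best variant.
#' @export
compare_sis <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "sis_fit")) {
    fits <- fits[[1]]
  }
  rows <- lapply(fits, function(f) {
    b <- suppressWarnings(bpic(f))
    data.frame(variant = f$variant$id, bpic = b$bpic, pD = b$pD,
               mean_dev = b$mean_dev)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$bpic), ]
  out$delta_bpic <- out$bpic - out$bpic[1]
  rownames(out) <- NULL
  out
}
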