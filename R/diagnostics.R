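#' MCMC convergence diagnostics
#'
#' Split-R-hat and effective sample size for every sampled parameter
#' (group locations/scales and subject-level parameters) of a
#' [fit_sis()] object, or for a plain chains-by-iterations matrix.
#' Chains are split in half so within-chain drift inflates R-hat. The
#' check passes when all R-hat values are below `rhat_tol` and all
#' effective sample sizes exceed `ess_min`.
#'
#' @param fit a `sis_fit` object, a chains-by-iterations matrix, or a
#'   named list of such matrices (one per parameter).
#' @param rhat_tol,ess_min pass thresholds (defaults 1.10 and 200).
#' @return a list with a per-parameter data.frame (`table`), `pass`,
#'   and `reason` when failing.
#' @export
convergence_diagnostics <- function(fit, rhat_tol = 1.10, ess_min = 200) {
  if (inherits(fit, "sis_fit")) {
    g <- fit$group
    mats <- stats::setNames(
      lapply(seq_len(dim(g)[3]), function(j) g[, , j]),
      dimnames(g)[[3]])
    for (s in seq_along(fit$subjects)) {
      for (j in seq_len(dim(fit$subj)[3])) {
        mats[[paste0(dimnames(fit$subj)[[3]][j], ".s", fit$subjects[s])]] <-
          fit$subj[, , j, s]
      }
    }
  } else if (is.matrix(fit)) {
    mats <- list(draws = fit)
  } else {
    stopifnot(is.list(fit), all(vapply(fit, is.matrix, logical(1))))
    mats <- fit
  }
  if (nrow(mats[[1]]) < 2) stop("need at least 2 chains", call. = FALSE)
  if (ncol(mats[[1]]) < 50) {
    stop("need at least 50 retained iterations for diagnostics",
         call. = FALSE)
  }
  tab <- data.frame(
    parameter = names(mats),
    rhat = vapply(mats, split_rhat, numeric(1)),
    ess = vapply(mats, ess_basic, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  bad_rhat <- !is.finite(tab$rhat) | tab$rhat >= rhat_tol
  bad_ess <- !is.finite(tab$ess) | tab$ess <= ess_min
  pass <- !any(bad_rhat) && !any(bad_ess)
  reason <- NULL
  if (any(!is.finite(tab$rhat))) {
    reason <- "R-hat undefined (zero-variance chains)"
  } else if (any(bad_rhat)) {
    reason <- sprintf("max R-hat %.3f >= %.2f", max(tab$rhat), rhat_tol)
  } else if (any(bad_ess)) {
    reason <- sprintf("min ESS %.0f <= %.0f", min(tab$ess), ess_min)
  }
  list(table = tab, pass = pass, reason = reason,
       rhat_tol = rhat_tol, ess_min = ess_min)
}

#' @rdname convergence_diagnostics
#' @param draws chains-by-iterations matrix of posterior draws.
#' @export
split_rhat <- function(draws) {
  m <- nrow(draws); n <- ncol(draws)
  half <- n %/% 2
  x <- rbind(draws[, seq_len(half), drop = FALSE],
             draws[, (n - half + 1):n, drop = FALSE])
  mns <- rowMeans(x)
  vars <- apply(x, 1, stats::var)
  W <- mean(vars)
  B <- half * stats::var(mns)
  if (!is.finite(W) || W <= 0) return(NaN)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' @rdname convergence_diagnostics
#' @export
ess_basic <- function(draws) {
  m <- nrow(draws); n <- ncol(draws)
  W <- mean(apply(draws, 1, stats::var))
  if (!is.finite(W) || W <= 0) return(NaN)
  # chain-averaged autocorrelations, Geyer initial-positive truncation
  centred <- draws - rowMeans(draws)
  max_lag <- min(n - 1L, 200L)
  rho <- numeric(max_lag)
  denom <- rowSums(centred^2) / n
  live <- denom > 0                     # chains stuck at one value carry
  if (!any(live)) return(NaN)           # no autocorrelation information
  for (t in seq_len(max_lag)) {
    acov <- rowSums(centred[, 1:(n - t), drop = FALSE] *
                      centred[, (t + 1):n, drop = FALSE]) / n
    rho[t] <- mean(acov[live] / denom[live])
    if (t >= 2 && (rho[t] + rho[t - 1]) < 0) {
      rho <- rho[1:(t - 2)]
      break
    }
  }
  ess <- m * n / (1 + 2 * base::sum(pmax(rho, 0)))
  min(ess, m * n)
}
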