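#' Read and write trial tables
#'
#' Trial tables are tab-separated text with a header row, times in ms
#' and a 0-based trial index, so they round-trip between the simulator,
#' the fitting functions and external tools.
#'
#' @param data trial data.frame.
#' @param path file path.
#' @return `read_trials` returns the data.frame.
#' @export
write_trials <- function(data, path) {
  utils::write.table(data, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Serialise SIS parameters as JSON
#'
#' Parameter sets are stored as structured text keyed by runner and
#' condition, with failure probabilities on the natural (probability)
#' scale.
#'
#' @param params a [sis_params()] object.
#' @param path file path.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "sis_params"))
  obj <- list(conditions = params$conditions,
              gf = params$gf, tf = params$tf, eps_wrong = params$eps_wrong,
              p_floor = params$p_floor)
  for (r in RUNNERS) {
    obj[[r]] <- lapply(params[[r]], function(p) {
      list(mu = p$mu, sigma = p$sigma, tau = p$tau)
    })
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  runners <- lapply(stats::setNames(RUNNERS, RUNNERS), function(r) {
    lapply(obj[[r]], function(p) runner_params(p$mu, p$sigma, p$tau))
  })
  sis_params(dual_go = runners$dual_go, dual_stop = runners$dual_stop,
             sel_left = runners$sel_left, sel_right = runners$sel_right,
             gf = obj$gf, tf = obj$tf, eps_wrong = obj$eps_wrong,
             p_floor = obj$p_floor, conditions = obj$conditions)
}

#' Read and write EMG traces as delimited text with a JSON sidecar
#'
#' The two channels are written as a tab-separated table (columns
#' `left`, `right`, mV); sampling rate, trace start and event markers go
#' to `<path>.json`.
#'
#' @param trace an [emg_trace()].
#' @param path path of the signal file.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "emg_trace"))
  utils::write.table(data.frame(left = trace$left, right = trace$right),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- trace[c("fs_hz", "t0_ms", "go_time_ms", "stop_time_ms",
                  "press_left_ms", "press_right_ms", "participant", "trial")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  sig <- utils::read.delim(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nn <- function(x) if (is.null(x)) NA else x
  emg_trace(sig$left, sig$right, fs_hz = meta$fs_hz, t0_ms = meta$t0_ms,
            go_time_ms = meta$go_time_ms, stop_time_ms = nn(meta$stop_time_ms),
            press_left_ms = nn(meta$press_left_ms),
            press_right_ms = nn(meta$press_right_ms),
            participant = nn(meta$participant), trial = nn(meta$trial))
}
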