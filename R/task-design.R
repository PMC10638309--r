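#' Build a trial schedule for one condition of the selective-stop task
#'
#' Generates the trial list for a reactive or proactive block of the
#' bimanual response-selective stop signal task. One third of trials (by
#' default) are selective-stop trials, split equally between left-stop
#' (stimulus `RS`) and right-stop (stimulus `LS`); the rest are bimanual
#' go trials (`DS`). In the proactive condition every trial carries a
#' "maybe stop left/right" cue; on stop trials the cue is congruent with
#' the hand that must stop, and on go trials cue sides are balanced.
#' Foreperiods (fixation/cue to go onset) are drawn uniformly from
#' 500-700 ms and the response window after go onset is 1100 ms.
#'
#' Stimulus coding follows the stimulus/response cell convention:
#' `LS` = left stimulus = stop the right hand (correct response `LR`),
#' `RS` = right stimulus = stop the left hand (correct response `RR`).
#'
#' @param condition `"reactive"` or `"proactive"`.
#' @param n_trials number of trials; must be divisible by 6 so that stop
#'   trials split evenly left/right at `stop_fraction = 1/3`.
#' @param stop_fraction proportion of stop trials (default 1/3).
#' @param seed integer seed; the schedule is fully reproducible.
#' @param foreperiod_range_ms,deadline_ms timing constants in ms.
#' @param practice if `TRUE`, prepend 30 practice trials of the same
#'   condition, flagged in the `practice` column and excluded from
#'   analysis counts.
#' @return a data.frame with one row per trial: `trial` (0-based index),
#'   `condition`, `cue`, `stimulus`, `foreperiod_ms`, `deadline_ms`,
#'   `practice`.
#' @examples
#' sched <- build_schedule("reactive", 576, seed = 1)
#' table(sched$stimulus)  # 384 DS, 96 LS, 96 RS
#' @export
build_schedule <- function(condition = c("reactive", "proactive"),
                           n_trials, stop_fraction = 1 / 3, seed = NULL,
                           foreperiod_range_ms = c(500, 700),
                           deadline_ms = 1100, practice = FALSE) {
  condition <- match.arg(condition)
  n_stop <- n_trials * stop_fraction
  if (n_trials %% 6 != 0 || n_stop != round(n_stop) || (n_stop %% 2) != 0) {
    stop("n_trials must be divisible by 6 so stop trials (fraction ",
         format(stop_fraction), ") split evenly into left- and right-stop",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  n_practice <- if (practice) 30L else 0L
  n_all <- n_trials + n_practice
  stim <- c(rep("LS", n_stop / 2), rep("RS", n_stop / 2),
            rep("DS", n_trials - n_stop))
  stim <- sample(stim)
  if (practice) {
    pstop <- round(n_practice * stop_fraction / 2)
    pstim <- sample(c(rep("LS", pstop), rep("RS", pstop),
                      rep("DS", n_practice - 2 * pstop)))
    stim <- c(pstim, stim)
  }
  cue <- rep("none", n_all)
  if (condition == "proactive") {
    # congruent cue on stop trials; balanced sides on go trials
    cue[stim == "LS"] <- "maybe-stop-right"
    cue[stim == "RS"] <- "maybe-stop-left"
    go_idx <- which(stim == "DS")
    sides <- rep(c("maybe-stop-left", "maybe-stop-right"),
                 length.out = length(go_idx))
    cue[go_idx] <- sample(sides)
  }
  data.frame(
    trial = seq_len(n_all) - 1L,
    condition = condition,
    cue = cue,
    stimulus = stim,
    foreperiod_ms = stats::runif(n_all, foreperiod_range_ms[1],
                                 foreperiod_range_ms[2]),
    deadline_ms = deadline_ms,
    practice = rep(c(TRUE, FALSE), c(n_practice, n_trials)),
    stringsAsFactors = FALSE
  )
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' SSD staircase
#'
#' The stop-signal delay (SSD) is tracked by a 1-up/1-down staircase,
#' independently for each (condition, stop-side) combination: SSD is
#' increased by `step_ms` after a successful stop (the next stop comes
#' later, making stopping harder) and reduced by `step_ms` after a
#' failed stop, then clamped to `[floor_ms, ceiling_ms]`. This negative
#' feedback drives long-run stop-success rates to approximately 50%.
#'
#' @param conditions condition labels to track.
#' @param start_ms initial SSD (200 ms by default).
#' @param step_ms staircase step (50 ms).
#' @param floor_ms,ceiling_ms clamp bounds; the defaults keep SSD
#'   non-negative and the stop signal displayable before the response
#'   deadline.
#' @return a `staircase` object: a list with an `ssd_ms` named vector
#'   (keys `"condition:side"`) and the step/clamp settings.
#' @examples
#' st <- staircase_init()
#' st <- staircase_update(st, "reactive", "left", stop_success = TRUE)
#' st$ssd_ms[["reactive:left"]]  # 250
#' @export
staircase_init <- function(conditions = c("reactive", "proactive"),
                           start_ms = 200, step_ms = 50,
                           floor_ms = 0, ceiling_ms = 1000) {
  stopifnot(floor_ms <= start_ms, start_ms <= ceiling_ms)
  keys <- as.vector(outer(conditions, c("left", "right"), paste, sep = ":"))
  structure(list(
    ssd_ms = stats::setNames(rep(start_ms, length(keys)), keys),
    step_ms = step_ms, floor_ms = floor_ms, ceiling_ms = ceiling_ms
  ), class = "staircase")
}

#' @rdname staircase_init
#' @param state a `staircase` object.
#' @param condition,side key of the staircase to update (`side` is the
#'   hand that had to stop, `"left"` or `"right"`).
#' @param stop_success logical: was the stop successful?
#' @export
staircase_update <- function(state, condition, side, stop_success) {
  key <- paste(condition, side, sep = ":")
  if (!key %in% names(state$ssd_ms)) {
    stop("unknown staircase key: ", key, call. = FALSE)
  }
  delta <- if (isTRUE(stop_success)) state$step_ms else -state$step_ms
  new <- state$ssd_ms[[key]] + delta
  state$ssd_ms[[key]] <- min(max(new, state$floor_ms), state$ceiling_ms)
  state
}

#' Classify the overt response on one trial
#'
#' Maps the per-hand press times of a trial onto the response labels of
#' the stimulus/response cells -- `NR` (no response), `DR` (dual
#' response), `LR` (left response), `RR` (right response) -- plus the
#' feedback category shown to the participant ("success", "failed to
#' stop", "stopped wrong hand", "missed").
#'
#' @param stimulus `"DS"`, `"LS"` (right-stop) or `"RS"` (left-stop).
#' @param left_press_ms,right_press_ms press times in ms from go onset,
#'   or `NA` if that hand did not press within the deadline.
#' @param deadline_ms response window (presses beyond it count as absent).
#' @return list with `response` and `feedback`.
#' @examples
#' classify_response("LS", left_press_ms = 540, right_press_ms = NA)
#' @export
classify_response <- function(stimulus, left_press_ms = NA,
                              right_press_ms = NA, deadline_ms = 1100) {
  stopifnot(stimulus %in% c("DS", "LS", "RS"))
  l <- !is.na(left_press_ms) && left_press_ms <= deadline_ms
  r <- !is.na(right_press_ms) && right_press_ms <= deadline_ms
  response <- if (l && r) "DR" else if (l) "LR" else if (r) "RR" else "NR"
  feedback <-
    if (stimulus == "DS") {
      if (response == "DR") "success" else if (response == "NR") "missed"
      else "wrong response"
    } else {
      correct <- if (stimulus == "LS") "LR" else "RR"
      if (response == "DR") "failed to stop"
      else if (response == correct) "success"
      else if (response == "NR") "missed"
      else "stopped wrong hand"
    }
  list(response = response, feedback = feedback)
}
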