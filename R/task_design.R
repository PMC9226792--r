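#' Default design parameters of the selective stop-signal session
#'
#' Encodes the published session layout: 700 trials, half reactive and half
#' proactive, a 60/40 go/stop split, stop trials balanced over left and right
#' within each condition, stop-signal delays drawn uniformly from a 50-500 ms
#' grid, and the stimulus timings (cue 200 ms, fixation gap 1300 ms, go
#' stimulus 100 ms, stop circle 200 ms).
#'
#' @param n_total total number of trials.
#' @param go_frac fraction of go trials (the rest are stop trials).
#' @param conditions character vector of condition labels; trials are split
#'   equally among them.
#' @param ssd_grid_ms allowed stop-signal delays in ms; sampled uniformly.
#' @param cue_ms,gap_ms,stim_ms,stop_ms stimulus timings in ms.
#' @param max_consecutive_stop run-length cap on consecutive stop trials in
#'   the pseudorandom order.
#' @return a list of class `design_params`.
#' @export
design_params <- function(n_total = 700L,
                          go_frac = 0.6,
                          conditions = c("reactive", "proactive"),
                          ssd_grid_ms = seq(50, 500, by = 50),
                          cue_ms = 200, gap_ms = 1300,
                          stim_ms = 100, stop_ms = 200,
                          max_consecutive_stop = 3L) {
  stopifnot(n_total > 0, go_frac > 0, go_frac < 1,
            length(conditions) >= 1,
            all(ssd_grid_ms >= 50), all(ssd_grid_ms <= 500))
  p <- list(n_total = as.integer(n_total), go_frac = go_frac,
            conditions = conditions, ssd_grid_ms = ssd_grid_ms,
            cue_ms = cue_ms, gap_ms = gap_ms, stim_ms = stim_ms,
            stop_ms = stop_ms,
            max_consecutive_stop = as.integer(max_consecutive_stop))
  class(p) <- "design_params"
  p
}

check_integral_splits <- function(p) {
  n_cond <- length(p$conditions)
  per_cond <- p$n_total / n_cond
  if (per_cond != round(per_cond))
    stop("total trial count ", p$n_total, " is not divisible into ",
         n_cond, " equal conditions", call. = FALSE)
  n_go <- p$n_total * p$go_frac
  if (abs(n_go - round(n_go)) > 1e-9)
    stop("go fraction ", p$go_frac, " of ", p$n_total,
         " trials is not an integral go count", call. = FALSE)
  go_per_cond <- round(n_go) / n_cond
  if (go_per_cond != round(go_per_cond))
    stop("go count ", round(n_go), " does not split evenly over ",
         n_cond, " conditions", call. = FALSE)
  stop_per_cond <- per_cond - go_per_cond
  if (stop_per_cond %% 2 != 0)
    stop("stop count per condition (", stop_per_cond,
         ") does not split evenly over left/right", call. = FALSE)
  list(per_cond = as.integer(per_cond),
       go_per_cond = as.integer(go_per_cond),
       stop_per_cond = as.integer(stop_per_cond),
       stop_per_dir = as.integer(stop_per_cond / 2))
}

#' Sample stop-signal delays uniformly from a grid
#'
#' Stop-signal delays vary randomly from trial to trial on a fixed grid
#' (no adaptive staircase), so the probability of responding given a stop
#' signal is estimable within a session.
#'
#' @param n number of draws.
#' @param grid allowed SSD values in ms, each within \[50, 500\].
#' @param seed optional integer seed for reproducible draws.
#' @return numeric vector of `n` delays, each an element of `grid`.
#' @export
sample_ssd <- function(n, grid = seq(50, 500, by = 50), seed = NULL) {
  if (length(grid) == 0) stop("SSD grid is empty", call. = FALSE)
  if (any(grid < 50 | grid > 500))
    stop("SSD grid values must lie within [50, 500] ms", call. = FALSE)
  draw <- function() grid[sample.int(length(grid), n, replace = TRUE)]
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a selective stop-signal task schedule
#'
#' Builds the per-trial specification for one session: per condition the go
#' and stop counts from the configured proportions, stop trials balanced over
#' left/right, proactive trials cued in the direction of a potential stop
#' (cues are congruent), reactive trials cued non-informatively, and the
#' whole session permuted pseudorandomly subject to a cap on consecutive
#' stop trials.
#'
#' @param params a [design_params()] list.
#' @param seed integer seed; identical seeds give identical schedules.
#' @return an object of class `task_schedule`: list with `trials` (data frame
#'   with one row per trial), `seed` and `design`.
#' @export
generate_schedule <- function(params = design_params(), seed = 1L) {
  splits <- check_integral_splits(params)
  build <- function() {
    rows <- lapply(params$conditions, function(cond) {
      n_stop_dir <- splits$stop_per_dir
      trial_type <- c(rep("go", splits$go_per_cond),
                      rep("stop", splits$stop_per_cond))
      stop_dir <- c(rep(NA_character_, splits$go_per_cond),
                    rep(c("left", "right"), each = n_stop_dir))
      df <- data.frame(condition = cond, trial_type = trial_type,
                       stop_direction = stop_dir,
                       stringsAsFactors = FALSE)
      # proactive cues are informative and congruent with a potential stop;
      # proactive go trials get a random (uninformative-in-effect) direction
      if (cond == "reactive") {
        df$cue_direction <- "none"
      } else {
        df$cue_direction <- ifelse(df$trial_type == "stop", df$stop_direction,
                                   sample(c("left", "right"),
                                          nrow(df), replace = TRUE))
      }
      df
    })
    trials <- do.call(rbind, rows)
    ord <- permute_with_runcap(trials$trial_type == "stop",
                               params$max_consecutive_stop)
    trials <- trials[ord, , drop = FALSE]
    n_stop <- sum(trials$trial_type == "stop")
    trials$ssd_ms <- NA_real_
    trials$ssd_ms[trials$trial_type == "stop"] <-
      params$ssd_grid_ms[sample.int(length(params$ssd_grid_ms),
                                    n_stop, replace = TRUE)]
    trials$index <- seq_len(nrow(trials)) - 1L
    trials$cue_duration_ms <- params$cue_ms
    trials$gap_duration_ms <- params$gap_ms
    trials$stimulus_duration_ms <- params$stim_ms
    rownames(trials) <- NULL
    trials[, c("index", "condition", "trial_type", "cue_direction",
               "stop_direction", "ssd_ms", "cue_duration_ms",
               "gap_duration_ms", "stimulus_duration_ms")]
  }
  trials <- withr::with_seed(as.integer(seed), build())
  structure(list(trials = trials, seed = as.integer(seed), design = params),
            class = "task_schedule")
}

# Random permutation with no run of `is_special` longer than `max_run`:
# shuffle, then repair any over-long special run by swapping its last element
# with a random non-special position, re-checking the whole sequence until
# clean (expected few iterations at the default 40% special rate).
permute_with_runcap <- function(is_special, max_run) {
  n <- length(is_special)
  ord <- sample.int(n)
  for (iter in 1:10000) {
    flags <- is_special[ord]
    r <- rle(flags)
    bad <- which(r$values & r$lengths > max_run)
    if (length(bad) == 0) return(ord)
    ends <- cumsum(r$lengths)
    i <- ends[bad[1]]                       # last trial of the first long run
    j <- sample(which(!flags), 1)
    tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
  }
  stop("could not satisfy the run-length constraint; relax ",
       "max_consecutive_stop or the stop fraction", call. = FALSE)
}

#' @export
print.task_schedule <- function(x, ...) {
  tt <- table(x$trials$condition, x$trials$trial_type)
  cat("Selective stop-signal task schedule:", nrow(x$trials), "trials (seed",
      x$seed, ")\n")
  print(tt)
  invisible(x)
}

#' Validate a task schedule against the design invariants
#'
#' Checks every per-trial rule (cue/stop direction consistency, SSD bounds,
#' congruent proactive cues) and the session-level counts. The validator
#' reports; it never raises.
#'
#' @param schedule a `task_schedule` or a bare trial data frame.
#' @return character vector of violations (empty if the schedule is valid);
#'   each entry names the trial index or count rule broken.
#' @export
validate_schedule <- function(schedule) {
  tr <- if (inherits(schedule, "task_schedule")) schedule$trials else schedule
  v <- character(0)
  collect <- function(mask, msg) {
    idx <- tr$index[which(mask)]
    if (length(idx)) sprintf("trial %d: %s", idx, msg) else character(0)
  }
  is_go <- tr$trial_type == "go"
  is_stop <- tr$trial_type == "stop"
  v <- c(v,
    collect(tr$condition == "reactive" & tr$cue_direction != "none",
            "reactive trial must have cue_direction 'none'"),
    collect(tr$condition == "proactive" &
              !tr$cue_direction %in% c("left", "right"),
            "proactive trial must have a left/right cue"),
    collect(is_go & !is.na(tr$stop_direction),
            "go trial must have no stop_direction"),
    collect(is_go & !is.na(tr$ssd_ms), "go trial must have no SSD"),
    collect(is_stop & (is.na(tr$ssd_ms) | tr$ssd_ms < 50 | tr$ssd_ms > 500),
            "stop trial SSD must lie in [50, 500] ms"),
    collect(is_stop & !tr$stop_direction %in% c("left", "right"),
            "stop trial must have a left/right direction"),
    collect(is_stop & tr$condition == "proactive" &
              !is.na(tr$stop_direction) &
              tr$cue_direction != tr$stop_direction,
            "proactive stop cue must match stop direction"))
  if (inherits(schedule, "task_schedule")) {
    p <- schedule$design
    sp <- tryCatch(check_integral_splits(p), error = function(e) NULL)
    if (!is.null(sp)) {
      if (nrow(tr) != p$n_total)
        v <- c(v, sprintf("count: %d trials, expected %d", nrow(tr), p$n_total))
      for (cond in p$conditions) {
        sub <- tr[tr$condition == cond, ]
        if (nrow(sub) != sp$per_cond)
          v <- c(v, sprintf("count: condition %s has %d trials, expected %d",
                            cond, nrow(sub), sp$per_cond))
        if (sum(sub$trial_type == "go") != sp$go_per_cond)
          v <- c(v, sprintf("count: condition %s go trials != %d",
                            cond, sp$go_per_cond))
        for (d in c("left", "right"))
          if (sum(sub$trial_type == "stop" & sub$stop_direction == d,
                  na.rm = TRUE) != sp$stop_per_dir)
            v <- c(v, sprintf("count: condition %s stop-%s trials != %d",
                              cond, d, sp$stop_per_dir))
      }
    }
    runs <- rle(tr$trial_type == "stop")
    if (any(runs$values & runs$lengths > p$max_consecutive_stop))
      v <- c(v, sprintf("order: more than %d consecutive stop trials",
                        p$max_consecutive_stop))
  }
  v
}

#' Per-trial event onsets in ms from trial start
#'
#' Cue at 0 ms, fixation gap after the cue, go/stop stimulus after the gap,
#' and on stop trials the stop signal SSD ms after the go stimulus.
#'
#' @param schedule a `task_schedule`.
#' @return data frame with `cue_onset_ms`, `stim_onset_ms`, `stop_onset_ms`.
#' @export
trial_onsets <- function(schedule) {
  tr <- schedule$trials
  stim <- tr$cue_duration_ms + tr$gap_duration_ms
  data.frame(index = tr$index,
             cue_onset_ms = 0,
             stim_onset_ms = stim,
             stop_onset_ms = ifelse(tr$trial_type == "stop",
                                    stim + tr$ssd_ms, NA_real_))
}
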