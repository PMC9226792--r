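#' Classify trials of a selective stop-signal session
#'
#' Applies the published outcome taxonomy. Go trials: `go_correct` when at
#' least one hand responded, `go_omission` when neither did. Stop trials:
#' `stop_success` when the cued (to-be-stopped) hand withheld its response;
#' `stop_failed` when both hands responded; `stop_choice_error` when, on an
#' unsuccessful stop, the wrong response pattern was executed (only the
#' to-be-stopped hand responded).
#'
#' @param raw per-trial response log: data frame with `index`, `left_rt_ms`,
#'   `right_rt_ms` (NA = no response), one row per scheduled trial.
#' @param schedule a `task_schedule` aligned with `raw`.
#' @return data frame of class `behavioral_trials` with a `classification`
#'   column over the five exhaustive, mutually exclusive classes.
#' @export
classify_trials <- function(raw, schedule) {
  tr <- schedule$trials
  if (nrow(raw) != nrow(tr))
    stop("log has ", nrow(raw), " rows but schedule has ", nrow(tr),
         " trials", call. = FALSE)
  raw <- raw[match(tr$index, raw$index), ]
  if (any(is.na(raw$index)))
    stop("log/schedule mismatch at trial index ",
         tr$index[which(is.na(raw$index))[1]], call. = FALSE)
  has_l <- !is.na(raw$left_rt_ms)
  has_r <- !is.na(raw$right_rt_ms)
  cls <- character(nrow(tr))
  is_go <- tr$trial_type == "go"
  cls[is_go] <- ifelse(has_l[is_go] | has_r[is_go], "go_correct",
                       "go_omission")
  is_stop <- !is_go
  cued_resp <- ifelse(tr$stop_direction == "left", has_l, has_r)
  other_resp <- ifelse(tr$stop_direction == "left", has_r, has_l)
  cls[is_stop] <- ifelse(!cued_resp[is_stop], "stop_success",
                         ifelse(other_resp[is_stop], "stop_failed",
                                "stop_choice_error"))
  out <- data.frame(index = tr$index, condition = tr$condition,
                    trial_type = tr$trial_type,
                    stop_direction = tr$stop_direction,
                    ssd_ms = tr$ssd_ms,
                    left_rt_ms = raw$left_rt_ms,
                    right_rt_ms = raw$right_rt_ms,
                    classification = cls, stringsAsFactors = FALSE)
  class(out) <- c("behavioral_trials", "data.frame")
  out
}

# per-trial go RT: mean of the hands that responded (bimanual task)
trial_go_rt <- function(trials) {
  rowMeans(cbind(trials$left_rt_ms, trials$right_rt_ms), na.rm = TRUE)
}

#' Go-trial performance metrics
#'
#' Mean go reaction time (time from go stimulus onset to response, averaged
#' over the two hands within a trial) over responded go trials, and the
#' omission count, optionally within one condition.
#'
#' @param trials classified trials ([classify_trials()]).
#' @param condition optional condition filter (`"reactive"`/`"proactive"`).
#' @return list with `mean_rt_ms`, `omission_count`, `n_go`.
#' @export
go_metrics <- function(trials, condition = NULL) {
  g <- trials[trials$trial_type == "go", ]
  if (!is.null(condition)) g <- g[g$condition == condition, ]
  if (nrow(g) == 0) stop("no go trials after filtering", call. = FALSE)
  responded <- g$classification == "go_correct"
  rts <- trial_go_rt(g[responded, ])
  list(mean_rt_ms = mean(rts), omission_count = sum(!responded),
       n_go = nrow(g))
}

#' Integration-method SSRT estimate
#'
#' Estimates the latency of the stop process by integrating the go-RT
#' distribution up to the probability of responding given a stop signal:
#' go RTs are sorted ascending after appending one copy of the maximum RT
#' per go omission, the rank `n = ceiling(p_respond * N)` is taken, and the
#' mean stop-signal delay is subtracted from the nth RT.
#'
#' @param go_rts numeric vector of go reaction times (ms), responded trials.
#' @param p_respond probability of responding given a stop signal, in
#'   (0, 1\]. A value of 0 leaves the stop latency undefined (no finite
#'   estimate); the function then returns `NA` with a warning.
#' @param mean_ssd_ms mean stop-signal delay over the stratum's stop trials.
#' @param omission_count number of go omissions to replace with the maximum
#'   observed go RT before ranking.
#' @return list of class `ssrt_estimate`: `value_ms`, `n_rank`, `p_respond`,
#'   `mean_ssd_ms`, `n_go_rts`.
#' @export
estimate_ssrt_integration <- function(go_rts, p_respond, mean_ssd_ms,
                                      omission_count = 0) {
  if (length(go_rts) == 0) stop("empty go RT vector", call. = FALSE)
  if (p_respond < 0 || p_respond > 1)
    stop("p_respond must lie in [0, 1]", call. = FALSE)
  if (p_respond == 0) {
    warning("p(respond | signal) = 0: stop latency undefined")
    est <- list(value_ms = NA_real_, n_rank = NA_integer_, p_respond = 0,
                mean_ssd_ms = mean_ssd_ms,
                n_go_rts = length(go_rts) + omission_count)
    class(est) <- "ssrt_estimate"
    return(est)
  }
  rts <- sort(c(go_rts, rep(max(go_rts), omission_count)))
  n <- length(rts)
  n_rank <- min(n, max(1L, as.integer(ceiling(p_respond * n))))
  est <- list(value_ms = rts[n_rank] - mean_ssd_ms, n_rank = n_rank,
              p_respond = p_respond, mean_ssd_ms = mean_ssd_ms, n_go_rts = n)
  class(est) <- "ssrt_estimate"
  est
}

#' @export
print.ssrt_estimate <- function(x, ...) {
  cat(sprintf("SSRT (integration): %.1f ms  [rank %d/%d, p(resp|sig)=%.3f, mean SSD %.1f ms]\n",
              x$value_ms, x$n_rank, x$n_go_rts, x$p_respond, x$mean_ssd_ms))
  invisible(x)
}

#' Per-subject behavioural summary (session scorecard)
#'
#' Scores one classified session into the standard report: per condition the
#' go mean RT and omission count, and per condition x stop direction the
#' choice-error count and the integration-method SSRT computed from that
#' condition's go-RT distribution and that stratum's stop trials.
#'
#' @param trials classified trials ([classify_trials()]).
#' @param choice_errors_respond count choice errors as "responding" when
#'   computing p(respond | signal) (both failed stops and choice errors are
#'   unsuccessful stops; default `TRUE`).
#' @param go_rt_hand which go-RT distribution feeds the per-direction SSRT:
#'   `"cued"` (default) uses the stopped hand's own go RTs, matching the
#'   per-effector race the estimate refers to; `"mean"` uses the per-trial
#'   mean of the two hands.
#' @return data frame with one row per condition: `rt_go_ms`, `om_go`,
#'   `ssrt_right_ms`, `ssrt_left_ms`, `che_stopr`, `che_stopl`.
#' @export
behavior_metrics <- function(trials, choice_errors_respond = TRUE,
                             go_rt_hand = c("cued", "mean")) {
  go_rt_hand <- match.arg(go_rt_hand)
  conds <- unique(trials$condition)
  rows <- lapply(conds, function(cond) {
    gm <- go_metrics(trials, cond)
    go_sub <- trials[trials$trial_type == "go" & trials$condition == cond &
                       trials$classification == "go_correct", ]
    per_dir <- sapply(c("right", "left"), function(d) {
      go_rts <- if (go_rt_hand == "mean") trial_go_rt(go_sub) else
        na.omit(go_sub[[paste0(d, "_rt_ms")]])
      st <- trials[trials$trial_type == "stop" &
                     trials$condition == cond &
                     trials$stop_direction == d, ]
      responded <- st$classification %in%
        c("stop_failed", if (choice_errors_respond) "stop_choice_error")
      p_resp <- mean(responded)
      che <- sum(st$classification == "stop_choice_error")
      ssrt <- if (p_resp == 0) NA_real_ else
        estimate_ssrt_integration(go_rts, p_resp, mean(st$ssd_ms),
                                  gm$omission_count)$value_ms
      c(ssrt = ssrt, che = che)
    })
    data.frame(condition = cond, rt_go_ms = gm$mean_rt_ms,
               om_go = gm$omission_count,
               ssrt_right_ms = per_dir["ssrt", "right"],
               ssrt_left_ms = per_dir["ssrt", "left"],
               che_stopr = per_dir["che", "right"],
               che_stopl = per_dir["che", "left"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
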