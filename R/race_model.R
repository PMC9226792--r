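#' Horse-race model parameters
#'
#' Parameters of the independent race between the go process and the stop
#' process that generates selective stop-signal behaviour. Go finish times
#' per hand are ex-Gaussian (mean `go_mu + go_tau`); stop-process latencies
#' are Gaussian truncated at zero. On proactive trials every go finish is
#' shifted by `proactive_slowing_ms` (preparatory slowing), and the stop
#' latency may differ between conditions.
#'
#' @param go_mu,go_sigma,go_tau ex-Gaussian go finish-time parameters (ms).
#' @param stop_mu,stop_sigma stop-process latency mean and SD (ms). Either
#'   may be a length-2 named vector `c(reactive =, proactive =)` or a scalar
#'   applied to both conditions.
#' @param proactive_slowing_ms additive go-finish shift on proactive trials.
#' @param trigger_failure_p probability the stop process fails to launch.
#' @param choice_error_p probability that a failed selective stop produces a
#'   wrong-hand response pattern (the to-be-stopped hand responds alone).
#' @param go_omission_p probability of answering neither hand on a go trial.
#' @return list of class `race_params`.
#' @export
race_params <- function(go_mu = 450, go_sigma = 50, go_tau = 120,
                        stop_mu = c(reactive = 350, proactive = 340),
                        stop_sigma = 30,
                        proactive_slowing_ms = 5,
                        trigger_failure_p = 0,
                        choice_error_p = 0.06,
                        go_omission_p = 0.05) {
  p <- list(go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
            stop_mu = cond_vec(stop_mu), stop_sigma = cond_vec(stop_sigma),
            proactive_slowing_ms = proactive_slowing_ms,
            trigger_failure_p = trigger_failure_p,
            choice_error_p = choice_error_p,
            go_omission_p = go_omission_p)
  validate_race_params(p)
  p
}

cond_vec <- function(x) {
  if (length(x) == 1) c(reactive = unname(x), proactive = unname(x))
  else if (all(c("reactive", "proactive") %in% names(x)))
    x[c("reactive", "proactive")]
  else stop("condition-specific parameters need names 'reactive'/'proactive'",
            call. = FALSE)
}

validate_race_params <- function(p) {
  if (any(c(p$go_sigma, p$go_tau, p$stop_sigma) <= 0))
    stop("race-model scale parameters must be positive", call. = FALSE)
  probs <- c(p$trigger_failure_p, p$choice_error_p, p$go_omission_p)
  if (any(probs < 0 | probs > 1))
    stop("race-model probabilities must lie in [0, 1]", call. = FALSE)
  if (p$proactive_slowing_ms < 0)
    stop("proactive_slowing_ms must be non-negative", call. = FALSE)
  class(p) <- "race_params"
  invisible(p)
}

# ex-Gaussian deviates: normal plus exponential component
rexgauss <- function(n, mu, sigma, tau) rnorm(n, mu, sigma) + rexp(n, 1 / tau)

# Gaussian truncated at zero via rejection (negligible truncation at the
# latencies used here)
rtnorm0 <- function(n, mu, sigma) {
  x <- rnorm(n, mu, sigma)
  while (any(neg <- x < 0)) x[neg] <- rnorm(sum(neg), mu, sigma)
  x
}

#' Simulate selective stop-signal behaviour under the race model
#'
#' Each hand races its own ex-Gaussian go process. On go trials both hands
#' respond (or neither, on an omission). On stop trials the non-cued hand
#' always responds; the cued hand is inhibited iff the stop process, starting
#' at the stop-signal delay, finishes before that hand's go process and no
#' trigger failure occurs. A failed selective stop yields either a full
#' bimanual response or, with probability `choice_error_p`, a wrong-hand
#' pattern in which only the to-be-stopped hand responds.
#'
#' @param schedule a `task_schedule`.
#' @param params a [race_params()] list.
#' @param seed integer seed.
#' @return data frame of class `behavioral_trials`: one row per trial with
#'   `left_rt_ms`, `right_rt_ms` (NA = no response) and the latent race
#'   quantities (`stop_latency_ms`, `inhibited`).
#' @export
simulate_behavior <- function(schedule, params = race_params(), seed = 1L) {
  validate_race_params(params)
  tr <- schedule$trials
  n <- nrow(tr)
  run <- function() {
    proact <- tr$condition == "proactive"
    slow <- ifelse(proact, params$proactive_slowing_ms, 0)
    finish_l <- rexgauss(n, params$go_mu, params$go_sigma, params$go_tau) + slow
    finish_r <- rexgauss(n, params$go_mu, params$go_sigma, params$go_tau) + slow
    left <- finish_l
    right <- finish_r
    stop_lat <- rep(NA_real_, n)
    inhibited <- rep(NA, n)

    is_go <- tr$trial_type == "go"
    omit <- is_go & runif(n) < params$go_omission_p
    left[omit] <- NA
    right[omit] <- NA

    is_stop <- !is_go
    idx <- which(is_stop)
    if (length(idx)) {
      mu <- params$stop_mu[tr$condition[idx]]
      sg <- params$stop_sigma[tr$condition[idx]]
      stop_lat[idx] <- rtnorm0(length(idx), mu, sg)
      cued_finish <- ifelse(tr$stop_direction[idx] == "left",
                            finish_l[idx], finish_r[idx])
      trig_fail <- runif(length(idx)) < params$trigger_failure_p
      won <- (tr$ssd_ms[idx] + stop_lat[idx] < cued_finish) & !trig_fail
      inhibited[idx] <- won
      choice <- !won & runif(length(idx)) < params$choice_error_p
      for (k in seq_along(idx)) {
        i <- idx[k]
        cued_left <- tr$stop_direction[i] == "left"
        if (won[k]) {          # successful selective stop: cued hand withheld
          if (cued_left) left[i] <- NA else right[i] <- NA
        } else if (choice[k]) { # wrong-hand pattern: only cued hand responds
          if (cued_left) right[i] <- NA else left[i] <- NA
        }                       # else failed stop: both hands respond
      }
    }
    out <- data.frame(index = tr$index, condition = tr$condition,
                      trial_type = tr$trial_type,
                      cue_direction = tr$cue_direction,
                      stop_direction = tr$stop_direction,
                      ssd_ms = tr$ssd_ms,
                      left_rt_ms = left, right_rt_ms = right,
                      stop_latency_ms = stop_lat, inhibited = inhibited,
                      stringsAsFactors = FALSE)
    class(out) <- c("behavioral_trials", "data.frame")
    out
  }
  withr::with_seed(as.integer(seed), run())
}
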