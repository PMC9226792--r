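EEG_CHANNELS <- c("Fz", "F3", "F4", "Cz", "C3", "C4", "EOG")
FRONTAL <- c("Fz", "F3", "F4")
CENTRAL <- c("Cz", "C3", "C4")

frontal_weights <- c(Fz = 1, F3 = 0.9, F4 = 0.95, Cz = 0, C3 = 0, C4 = 0,
                     EOG = 0)
central_weights <- c(Fz = 0, F3 = 0, F4 = 0, Cz = 1, C3 = 0.85, C4 = 0.9,
                     EOG = 0)

#' ERP template parameters for the synthetic EEG generator
#'
#' Each component is a Gaussian bump in time with a signed peak amplitude, a
#' peak latency inside its measurement window, a temporal width, and a
#' per-channel scalp weighting. Amplitudes may be condition-specific
#' (`c(reactive =, proactive =)`). Background activity is 1/f-shaped noise;
#' blinks are stereotyped 400 ms biphasic frontal/EOG waveforms; gross
#' artifacts are high-amplitude bursts injected per trial.
#'
#' @param p3cue_amp,p3go_amp,n2stop_amp,p3stop_amp peak amplitudes in
#'   microvolts (N2 negative), scalar or per-condition.
#' @param p3cue_lat,p3go_lat,n2stop_lat,p3stop_lat peak latencies in ms
#'   after the locking event.
#' @param width_ms Gaussian temporal SD of every bump.
#' @param noise_rms_uv background noise RMS per channel; 0 = noiseless.
#' @param noise_exponent spectral exponent of the 1/f^a background.
#' @param blink_rate_per_min expected blink count per minute (Poisson).
#' @param blink_amp_uv blink amplitude on the EOG channel.
#' @param gross_artifact_p per-trial probability of a gross artifact burst.
#' @param gross_artifact_uv burst amplitude (must exceed the 100 uV
#'   rejection threshold to be useful).
#' @return list of class `erp_templates`.
#' @export
erp_templates <- function(p3cue_amp = 4, p3cue_lat = 400,
                          p3go_amp = 2.2, p3go_lat = 380,
                          n2stop_amp = -2, n2stop_lat = 270,
                          p3stop_amp = 3.2, p3stop_lat = 380,
                          width_ms = 45,
                          noise_rms_uv = 8, noise_exponent = 1,
                          blink_rate_per_min = 4, blink_amp_uv = 150,
                          gross_artifact_p = 0.02,
                          gross_artifact_uv = 150) {
  comp <- function(amp, lat, weights, lo, hi) {
    amp <- cond_vec(amp)
    if (lat < lo || lat > hi)
      stop("component latency ", lat, " outside its measurement window [",
           lo, ", ", hi, "] ms", call. = FALSE)
    list(amp = amp, lat = lat, width = width_ms, weights = weights)
  }
  if (any(cond_vec(n2stop_amp) >= 0))
    stop("N2 amplitude must be negative", call. = FALSE)
  if (any(cond_vec(p3cue_amp) <= 0) || any(cond_vec(p3go_amp) <= 0) ||
      any(cond_vec(p3stop_amp) <= 0))
    stop("P3 amplitudes must be positive", call. = FALSE)
  t <- list(
    components = list(
      P3cue  = comp(p3cue_amp,  p3cue_lat,  frontal_weights, 300, 550),
      P3go   = comp(p3go_amp,   p3go_lat,   central_weights, 280, 500),
      N2stop = comp(n2stop_amp, n2stop_lat, frontal_weights, 200, 350),
      P3stop = comp(p3stop_amp, p3stop_lat, central_weights, 280, 500)),
    noise_rms_uv = noise_rms_uv, noise_exponent = noise_exponent,
    blink_rate_per_min = blink_rate_per_min, blink_amp_uv = blink_amp_uv,
    gross_artifact_p = gross_artifact_p,
    gross_artifact_uv = gross_artifact_uv)
  class(t) <- "erp_templates"
  t
}

# Gaussian bump sampled at times t (ms) relative to locking event
gauss_bump <- function(t_ms, amp, lat, width) {
  amp * exp(-((t_ms - lat)^2) / (2 * width^2))
}

# biphasic 400 ms blink waveform, unit peak
blink_waveform <- function(sfreq) {
  n <- round(0.4 * sfreq)
  t <- seq_len(n) / sfreq                       # 0..0.4 s
  w <- sin(pi * t / 0.4) * exp(-((t - 0.12) / 0.12)^2) -
    0.3 * sin(2 * pi * t / 0.4)
  w / max(abs(w))
}

# 1/f^a-shaped noise with a given RMS, via spectral shaping of white noise
pink_noise <- function(n, rms, exponent) {
  if (rms <= 0) return(numeric(n))
  white <- rnorm(n)
  spec <- fft(white)
  f <- c(1, seq_len(n - 1))                     # avoid f=0 blow-up
  f <- pmin(f, n - f + 1)                       # symmetric frequency index
  spec <- spec / (f^(exponent / 2))
  x <- Re(fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x * rms / sqrt(mean(x^2))
}

#' Synthesize a continuous EEG record for a simulated session
#'
#' Lays the session's trials on a continuous timeline and adds, per trial,
#' the cue-locked component (P3-cue), the go-locked component on go trials
#' (P3-Go) and the stop-signal-locked components on stop trials (N2-stop,
#' P3-stop), each weighted over the scalp channels. Background 1/f noise,
#' Poisson blinks (frontal + EOG) and per-trial gross artifact bursts are
#' superimposed. With `noise_rms_uv = 0`, `blink_rate_per_min = 0` and
#' `gross_artifact_p = 0` each epoch equals its injected template exactly.
#'
#' @param schedule a `task_schedule`.
#' @param behavior output of [simulate_behavior()] for the same schedule.
#' @param templates an [erp_templates()] list.
#' @param seed integer seed.
#' @param sfreq sampling rate in Hz.
#' @param iti_ms inter-trial interval appended after each trial.
#' @return list of class `simulated_session` with elements `eeg` (an
#'   `eeg_recording`: channels x samples matrix, labels, sfreq), `events`
#'   (marker table with onset samples), `schedule`, `behavior` and `truth`
#'   (injected parameters plus blink/artifact ground truth).
#' @export
simulate_eeg <- function(schedule, behavior, templates = erp_templates(),
                         seed = 1L, sfreq = 500, iti_ms = 900) {
  tr <- schedule$trials
  ons <- trial_onsets(schedule)
  trial_len_ms <- tr$cue_duration_ms + tr$gap_duration_ms + 1200 + iti_ms
  trial_start_ms <- cumsum(c(0, head(trial_len_ms, -1))) + 400 # lead-in
  n_samp <- ceiling((tail(trial_start_ms, 1) + tail(trial_len_ms, 1) + 400) *
                      sfreq / 1000)
  nch <- length(EEG_CHANNELS)

  run <- function() {
    X <- matrix(0, nrow = nch, ncol = n_samp,
                dimnames = list(EEG_CHANNELS, NULL))
    events <- list()
    add_bump <- function(X, onset_ms, comp, condition) {
      amp <- comp$amp[[condition]]
      span_ms <- comp$lat + c(-4, 4) * comp$width
      s0 <- max(1L, floor((onset_ms + span_ms[1]) * sfreq / 1000))
      s1 <- min(n_samp, ceiling((onset_ms + span_ms[2]) * sfreq / 1000))
      if (s1 <= s0) return(X)
      t_rel <- (s0:s1) * 1000 / sfreq - onset_ms
      bump <- gauss_bump(t_rel, amp, comp$lat, comp$width)
      w <- comp$weights[EEG_CHANNELS]
      X[, s0:s1] <- X[, s0:s1] + outer(unname(w), bump)
      X
    }
    truth_artifact <- logical(nrow(tr))
    for (i in seq_len(nrow(tr))) {
      t0 <- trial_start_ms[i]
      cue_ms <- t0 + ons$cue_onset_ms[i]
      stim_ms <- t0 + ons$stim_onset_ms[i]
      cond <- tr$condition[i]
      X <- add_bump(X, cue_ms, templates$components$P3cue, cond)
      events[[length(events) + 1]] <- data.frame(
        onset_sample = round(cue_ms * sfreq / 1000), code = "cue",
        condition = cond, direction = tr$cue_direction[i],
        ssd_ms = NA_real_, trial_index = tr$index[i])
      if (tr$trial_type[i] == "go") {
        X <- add_bump(X, stim_ms, templates$components$P3go, cond)
        events[[length(events) + 1]] <- data.frame(
          onset_sample = round(stim_ms * sfreq / 1000), code = "go",
          condition = cond, direction = "both", ssd_ms = NA_real_,
          trial_index = tr$index[i])
      } else {
        stop_ms <- t0 + ons$stop_onset_ms[i]
        X <- add_bump(X, stop_ms, templates$components$N2stop, cond)
        X <- add_bump(X, stop_ms, templates$components$P3stop, cond)
        events[[length(events) + 1]] <- data.frame(
          onset_sample = round(stop_ms * sfreq / 1000), code = "stop",
          condition = cond, direction = tr$stop_direction[i],
          ssd_ms = tr$ssd_ms[i], trial_index = tr$index[i])
      }
      # response markers
      b <- behavior[behavior$index == tr$index[i], ]
      for (side in c("left", "right")) {
        rt <- b[[paste0(side, "_rt_ms")]]
        if (length(rt) == 1 && !is.na(rt))
          events[[length(events) + 1]] <- data.frame(
            onset_sample = round((stim_ms + rt) * sfreq / 1000),
            code = paste0("resp_", side), condition = cond,
            direction = side, ssd_ms = NA_real_, trial_index = tr$index[i])
      }
      # gross artifact: burst across scalp channels, anchored to the trial's
      # analysis-locking event so it lands inside the stimulus-locked epoch
      if (runif(1) < templates$gross_artifact_p) {
        truth_artifact[i] <- TRUE
        anchor_ms <- if (tr$trial_type[i] == "stop")
          t0 + ons$stop_onset_ms[i] else stim_ms
        a0 <- round((anchor_ms + 100) * sfreq / 1000)
        a1 <- min(n_samp, a0 + round(0.1 * sfreq))
        X[setdiff(EEG_CHANNELS, "EOG"), a0:a1] <-
          X[setdiff(EEG_CHANNELS, "EOG"), a0:a1] +
          templates$gross_artifact_uv
      }
    }
    # background noise, independent per channel
    if (templates$noise_rms_uv > 0)
      for (ch in seq_len(nch))
        X[ch, ] <- X[ch, ] + pink_noise(n_samp, templates$noise_rms_uv,
                                        templates$noise_exponent)
    # blinks
    blink_onsets <- integer(0)
    if (templates$blink_rate_per_min > 0) {
      dur_min <- n_samp / sfreq / 60
      n_blink <- rpois(1, templates$blink_rate_per_min * dur_min)
      bw <- blink_waveform(sfreq) * templates$blink_amp_uv
      blink_w <- c(Fz = 0.4, F3 = 0.35, F4 = 0.35, Cz = 0.12, C3 = 0.1,
                   C4 = 0.1, EOG = -1)[EEG_CHANNELS]
      if (n_blink > 0) {
        blink_onsets <- sort(sample.int(n_samp - length(bw), n_blink))
        for (s in blink_onsets) {
          span <- s:(s + length(bw) - 1)
          X[, span] <- X[, span] + outer(unname(blink_w), bw)
        }
      }
    }
    events <- do.call(rbind, events)
    events <- events[order(events$onset_sample), ]
    rownames(events) <- NULL
    eeg <- structure(list(data = X, labels = EEG_CHANNELS, sfreq = sfreq),
                     class = "eeg_recording")
    structure(list(eeg = eeg, events = events, schedule = schedule,
                   behavior = behavior,
                   truth = list(templates = templates,
                                gross_artifact_trials =
                                  tr$index[truth_artifact],
                                blink_onset_samples = blink_onsets,
                                blink_len_samples =
                                  length(blink_waveform(sfreq)))),
              class = "simulated_session")
  }
  withr::with_seed(as.integer(seed), run())
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording:", nrow(x$data), "channels x", ncol(x$data),
      "samples @", x$sfreq, "Hz\n")
  cat("channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Simulate one subject's full session (behaviour + optional EEG)
#'
#' @param params a [race_params()] list.
#' @param templates an [erp_templates()] list.
#' @param design a [design_params()] list.
#' @param seed integer seed.
#' @param include_eeg set `FALSE` for behaviour-only simulation (much
#'   faster; used when only SSRT-level quantities are needed).
#' @return a `simulated_session` (without `eeg` if `include_eeg = FALSE`).
#' @export
simulate_session <- function(params = race_params(),
                             templates = erp_templates(),
                             design = design_params(), seed = 1L,
                             include_eeg = TRUE) {
  sched <- generate_schedule(design, seed = child_seed(seed, 1))
  beh <- simulate_behavior(sched, params, seed = child_seed(seed, 2))
  if (!include_eeg)
    return(structure(list(schedule = sched, behavior = beh,
                          truth = list(race = params)),
                     class = "simulated_session"))
  ses <- simulate_eeg(sched, beh, templates, seed = child_seed(seed, 3))
  ses$truth$race <- params
  ses
}

#' Simulate a two-group study
#'
#' Draws per-subject race-model and ERP parameters around group-level means
#' (between-subject variation on the go and stop process means and on the
#' component amplitudes) and simulates each subject's session.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param group_effects named list, one entry per group, each with elements
#'   `race` ([race_params()]) and `erp` ([erp_templates()]).
#' @param seed integer seed.
#' @param between_sd list of between-subject SDs: `go_mu`, `stop_mu`,
#'   `erp_amp` (multiplicative log-normal SD on amplitudes).
#' @param include_eeg simulate EEG per subject (heavy) or behaviour only.
#' @param design a [design_params()] list.
#' @return list of class `simulated_study`: `sessions` (list), `subjects`
#'   (data frame with group labels and per-subject truth).
#' @export
simulate_study <- function(n_per_group = 30,
                           group_effects = default_group_effects(),
                           seed = 1L,
                           between_sd = list(go_mu = 40, stop_mu = 25,
                                             erp_amp = 0.15),
                           include_eeg = FALSE,
                           design = design_params()) {
  if (n_per_group < 2) stop("need at least 2 subjects per group",
                            call. = FALSE)
  groups <- names(group_effects)
  sessions <- list()
  subjects <- list()
  k <- 0
  for (g in seq_along(groups)) {
    ge <- group_effects[[g]]
    for (s in seq_len(n_per_group)) {
      k <- k + 1
      sub_seed <- child_seed(seed, k)
      p <- ge$race
      tpl <- ge$erp
      draw <- withr::with_seed(sub_seed + 900L, list(
        dgo = rnorm(1, 0, between_sd$go_mu),
        dstop = rnorm(1, 0, between_sd$stop_mu),
        amp_f = exp(rnorm(1, 0, between_sd$erp_amp))))
      p$go_mu <- p$go_mu + draw$dgo
      p$stop_mu <- p$stop_mu + draw$dstop
      for (cn in names(tpl$components))
        tpl$components[[cn]]$amp <- tpl$components[[cn]]$amp * draw$amp_f
      ses <- simulate_session(p, tpl, design, seed = sub_seed,
                              include_eeg = include_eeg)
      sessions[[k]] <- ses
      subjects[[k]] <- data.frame(subject = sprintf("S%02d", k),
                                  group = groups[g],
                                  go_mu = p$go_mu,
                                  stop_mu_reactive = p$stop_mu[["reactive"]],
                                  stop_mu_proactive = p$stop_mu[["proactive"]])
    }
  }
  structure(list(sessions = sessions, subjects = do.call(rbind, subjects),
                 group_effects = group_effects, seed = as.integer(seed)),
            class = "simulated_study")
}

#' Default per-group generating parameters
#'
#' Qualitatively mirrors the direction of the published group differences:
#' the gaming group responds faster on go trials, shows a longer proactive
#' stop latency and more proactive choice errors, a smaller cue-locked P3
#' and, on proactive stop trials, a smaller N2 and larger stop-P3.
#'
#' @return named list with `vga` and `control` entries (`race` + `erp`).
#' @export
default_group_effects <- function() {
  list(
    vga = list(
      race = race_params(go_mu = 480,
                         stop_mu = c(reactive = 350, proactive = 375),
                         choice_error_p = 0.09),
      erp = erp_templates(p3cue_amp = 2.3,
                          n2stop_amp = c(reactive = -0.7, proactive = -1.2),
                          p3stop_amp = c(reactive = 3.1, proactive = 4.0))),
    control = list(
      race = race_params(go_mu = 560,
                         stop_mu = c(reactive = 350, proactive = 335),
                         choice_error_p = 0.05),
      erp = erp_templates(p3cue_amp = 4.0,
                          n2stop_amp = c(reactive = -0.8, proactive = -2.0),
                          p3stop_amp = c(reactive = 3.1, proactive = 2.9))))
}
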