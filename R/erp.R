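COMPONENT_WINDOWS <- list(
  P3cue  = c(300, 550),
  P3go   = c(280, 500),
  N2stop = c(200, 350),
  P3stop = c(280, 500))

COMPONENT_ELECTRODES <- list(
  P3cue  = c("Fz", "F3", "F4"),
  P3go   = c("Cz", "C3", "C4"),
  N2stop = c("Fz", "F3", "F4"),
  P3stop = c("Cz", "C3", "C4"))

#' Zero-phase band-pass filter for continuous EEG
#'
#' Channel-wise zero-phase Butterworth filtering in the 0.1-45 Hz band used
#' for ERP work: the channel mean is removed, then a high-pass and a
#' low-pass section are each applied forward and backward (`filtfilt`), so
#' the passband is preserved without phase distortion.
#'
#' @param recording an `eeg_recording` (or bare channels x samples matrix
#'   with an `sfreq` attribute).
#' @param low,high band edges in Hz; `high` must be below Nyquist.
#' @return filtered recording of the same form.
#' @export
bandpass <- function(recording, low = 0.1, high = 45) {
  X <- recording$data
  sfreq <- recording$sfreq
  if (high >= sfreq / 2)
    stop("high cutoff ", high, " Hz must be below Nyquist (",
         sfreq / 2, " Hz)", call. = FALSE)
  if (low <= 0 || low >= high) stop("invalid band edges", call. = FALSE)
  hp <- signal::butter(2, low / (sfreq / 2), type = "high")
  lp <- signal::butter(4, high / (sfreq / 2), type = "low")
  for (ch in seq_len(nrow(X))) {
    x <- X[ch, ] - mean(X[ch, ])
    x <- signal::filtfilt(hp, x)
    x <- signal::filtfilt(lp, x)
    X[ch, ] <- x
  }
  recording$data <- X
  recording
}

#' Extract event-locked epochs from a continuous recording
#'
#' Cuts one epoch per matching event and baseline-corrects each channel by
#' subtracting its mean over the baseline window. Events too close to the
#' record edge yield epochs flagged `rejected` with reason `"edge"` rather
#' than an error.
#'
#' @param recording an `eeg_recording`.
#' @param events marker table (`onset_sample`, `code`, `condition`,
#'   `direction`, ...).
#' @param code event code to lock to (`"cue"`, `"go"`, `"stop"`).
#' @param condition,direction optional event filters.
#' @param window epoch window in ms relative to the event, default -200..800.
#' @param baseline baseline window in ms, default -200..0.
#' @return list of class `epoch_set`: `data` (epoch x channel x time array),
#'   `times_ms`, `channels`, `sfreq`, `events` (matching rows), `rejected`
#'   logical vector and `reject_reason`.
#' @export
epoch <- function(recording, events, code, condition = NULL,
                  direction = NULL, window = c(-200, 800),
                  baseline = c(-200, 0)) {
  ev <- events[events$code == code, , drop = FALSE]
  if (!is.null(condition)) ev <- ev[ev$condition == condition, , drop = FALSE]
  if (!is.null(direction)) ev <- ev[ev$direction == direction, , drop = FALSE]
  sfreq <- recording$sfreq
  s_lo <- round(window[1] * sfreq / 1000)
  s_hi <- round(window[2] * sfreq / 1000)
  times_ms <- (s_lo:s_hi) * 1000 / sfreq
  n_t <- length(times_ms)
  nch <- nrow(recording$data)
  n_ep <- nrow(ev)
  arr <- array(NA_real_, dim = c(n_ep, nch, n_t),
               dimnames = list(NULL, recording$labels, NULL))
  rejected <- logical(n_ep)
  reason <- character(n_ep)
  bl_idx <- which(times_ms >= baseline[1] & times_ms <= baseline[2])
  for (i in seq_len(n_ep)) {
    s0 <- ev$onset_sample[i] + s_lo
    s1 <- ev$onset_sample[i] + s_hi
    if (s0 < 1 || s1 > ncol(recording$data)) {
      rejected[i] <- TRUE
      reason[i] <- "edge"
      next
    }
    seg <- recording$data[, s0:s1, drop = FALSE]
    seg <- seg - rowMeans(seg[, bl_idx, drop = FALSE])
    arr[i, , ] <- seg
  }
  structure(list(data = arr, times_ms = times_ms,
                 channels = recording$labels, sfreq = sfreq, events = ev,
                 rejected = rejected, reject_reason = reason,
                 baseline = baseline),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("Epoch set:", dim(x$data)[1], "epochs x", dim(x$data)[2],
      "channels x", dim(x$data)[3], "samples;",
      sum(x$rejected), "rejected\n")
  invisible(x)
}

#' Reject epochs exceeding an absolute-amplitude threshold
#'
#' Flags any epoch whose absolute value exceeds the threshold on any scalp
#' (non-EOG) channel, implementing the standard removal of noisy trials
#' above 100 microvolts. Already-rejected epochs keep their original reason.
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uv rejection threshold in microvolts.
#' @return the `epoch_set` with updated `rejected`/`reject_reason`.
#' @export
reject_amplitude <- function(epochs, threshold_uv = 100) {
  scalp <- which(epochs$channels != "EOG")
  for (i in seq_len(dim(epochs$data)[1])) {
    if (epochs$rejected[i]) next
    if (max(abs(epochs$data[i, scalp, ]), na.rm = TRUE) > threshold_uv) {
      epochs$rejected[i] <- TRUE
      epochs$reject_reason[i] <- "amplitude"
    }
  }
  epochs
}

#' Average retained epochs into a subject ERP, and subjects into a grand
#' average
#'
#' Pointwise arithmetic mean over retained (non-rejected) epochs; at the
#' group level, the pointwise mean over subject ERPs. Subjects with no
#' retained epochs are excluded with a warning.
#'
#' @param x an `epoch_set` (subject level) or a list of subject ERPs
#'   (group level).
#' @return list of class `erp_waveform`: `data` (channel x time), `times_ms`,
#'   `channels`, `sfreq`, `n` (epochs or subjects averaged).
#' @export
grand_average <- function(x) {
  if (inherits(x, "epoch_set")) {
    keep <- which(!x$rejected)
    if (length(keep) == 0)
      stop("all epochs rejected; no average possible", call. = FALSE)
    m <- apply(x$data[keep, , , drop = FALSE], c(2, 3), mean)
    return(structure(list(data = m, times_ms = x$times_ms,
                          channels = x$channels, sfreq = x$sfreq,
                          n = length(keep)),
                     class = "erp_waveform"))
  }
  waves <- Filter(Negate(is.null), x)
  if (length(waves) == 0) stop("no subject ERPs to average", call. = FALSE)
  if (length(waves) < length(x))
    warning(length(x) - length(waves), " subject(s) excluded (no data)")
  m <- Reduce(`+`, lapply(waves, `[[`, "data")) / length(waves)
  w1 <- waves[[1]]
  structure(list(data = m, times_ms = w1$times_ms, channels = w1$channels,
                 sfreq = w1$sfreq, n = length(waves)),
            class = "erp_waveform")
}

# indices of strict-or-plateau local minima of a vector
local_minima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(diff(sign(diff(y))) > 0) + 1L
}

#' Measure an ERP component on one electrode
#'
#' P3 variants (P3-cue 300-550 ms, P3-Go and P3-stop 280-500 ms) are scored
#' as the maximum amplitude and its latency within the search window. The
#' stop-locked N2 (200-350 ms) is scored as the second negative peak: among
#' negative local minima of the post-stimulus waveform ordered by latency,
#' the one of overall rank two is returned when it falls inside the window;
#' when the window holds negative minima but none of rank two, the most
#' negative one is returned flagged `"fallback"`; with no negative minimum
#' in the window the measure is `NA` flagged `"missing"` with a warning.
#'
#' @param erp an `erp_waveform`.
#' @param component one of `"P3cue"`, `"P3go"`, `"N2stop"`, `"P3stop"`.
#' @param electrode channel label; defaults are frontal (Fz/F3/F4) for
#'   P3-cue and N2-stop and central (Cz/C3/C4) for P3-Go and P3-stop.
#' @param window_ms optional override of the search window.
#' @return one-row data frame: `component`, `electrode`, `amplitude_uv`,
#'   `latency_ms`, `window_lo_ms`, `window_hi_ms`, `flag`.
#' @export
measure_component <- function(erp, component, electrode = NULL,
                              window_ms = NULL) {
  component <- match.arg(component, names(COMPONENT_WINDOWS))
  win <- window_ms %||% COMPONENT_WINDOWS[[component]]
  electrode <- electrode %||% COMPONENT_ELECTRODES[[component]][1]
  if (!electrode %in% erp$channels)
    stop("electrode ", electrode, " not in waveform channels", call. = FALSE)
  if (win[1] < min(erp$times_ms) || win[2] > max(erp$times_ms))
    stop("search window [", win[1], ", ", win[2],
         "] ms outside the epoch", call. = FALSE)
  y <- erp$data[match(electrode, erp$channels), ]
  t <- erp$times_ms
  in_win <- which(t >= win[1] & t <= win[2])
  flag <- ""
  if (component == "N2stop") {
    post <- which(t >= 0)
    minima <- post[local_minima(y[post])]
    minima <- minima[y[minima] < 0]              # negative peaks only
    cand <- intersect(minima, in_win)
    if (length(cand) == 0) {
      warning("no negative local minimum in the N2 window: component missing")
      return(data.frame(component = component, electrode = electrode,
                        amplitude_uv = NA_real_, latency_ms = NA_real_,
                        window_lo_ms = win[1], window_hi_ms = win[2],
                        flag = "missing"))
    }
    rank2 <- if (length(minima) >= 2) minima[2] else NA_integer_
    if (!is.na(rank2) && rank2 %in% cand) {
      pk <- rank2
    } else {
      pk <- cand[which.min(y[cand])]
      flag <- "fallback"
    }
  } else {
    pk <- in_win[which.max(y[in_win])]
  }
  data.frame(component = component, electrode = electrode,
             amplitude_uv = y[pk], latency_ms = t[pk],
             window_lo_ms = win[1], window_hi_ms = win[2], flag = flag)
}

#' Re-reference a recording to the mean of selected channels
#'
#' Utility for recordings not already referenced to linked ears; not applied
#' anywhere by default (input is assumed linked-ear referenced).
#'
#' @param recording an `eeg_recording`.
#' @param ref_channels channels whose mean becomes the new reference.
#' @return re-referenced recording.
#' @export
rereference <- function(recording, ref_channels) {
  idx <- match(ref_channels, recording$labels)
  if (anyNA(idx)) stop("unknown reference channel(s)", call. = FALSE)
  ref <- colMeans(recording$data[idx, , drop = FALSE])
  scalp <- recording$labels != "EOG"
  recording$data[scalp, ] <- sweep(recording$data[scalp, , drop = FALSE],
                                   2, ref)
  recording
}

#' Measure all components of one subject's session
#'
#' Runs the full per-subject ERP pipeline on a simulated (or loaded)
#' session: band-pass filter, epoch per event class, amplitude rejection,
#' blink removal (optional), averaging and windowed peak measurement over
#' the component's electrode set.
#'
#' @param session a `simulated_session` with EEG.
#' @param filter band-pass before epoching (default TRUE; turn off for
#'   noiseless template-recovery checks).
#' @param remove_blinks_first run ICA blink zeroing on the continuous record.
#' @param reject_uv amplitude-rejection threshold.
#' @return data frame of component measures: one row per component x
#'   condition x direction x electrode.
#' @export
measure_session <- function(session, filter = TRUE,
                            remove_blinks_first = FALSE, reject_uv = 100) {
  rec <- session$eeg
  if (remove_blinks_first) rec <- remove_blinks(rec)$recording
  if (filter) rec <- bandpass(rec)
  out <- list()
  specs <- list(
    list(comp = "P3cue", code = "cue", by_dir = FALSE),
    list(comp = "P3go", code = "go", by_dir = FALSE),
    list(comp = "N2stop", code = "stop", by_dir = TRUE),
    list(comp = "P3stop", code = "stop", by_dir = TRUE))
  for (cond in unique(session$schedule$trials$condition)) {
    for (sp in specs) {
      dirs <- if (sp$by_dir) c("left", "right") else list(NULL)
      for (d in dirs) {
        ep <- epoch(rec, session$events, sp$code, condition = cond,
                    direction = if (is.null(d)) NULL else d)
        ep <- reject_amplitude(ep, reject_uv)
        if (all(ep$rejected)) next
        avg <- grand_average(ep)
        for (el in COMPONENT_ELECTRODES[[sp$comp]]) {
          m <- measure_component(avg, sp$comp, el)
          m$condition <- cond
          m$direction <- if (is.null(d)) "n/a" else d
          m$n_epochs <- avg$n
          out[[length(out) + 1]] <- m
        }
      }
    }
  }
  do.call(rbind, out)
}
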