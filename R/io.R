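#' Write / read a task schedule as a tab-separated table
#'
#' Columns: index, condition, trial_type, cue_direction, stop_direction,
#' ssd_ms, and the within-trial onsets of cue, fixation gap and stimulus in
#' ms from trial start.
#'
#' @param schedule a `task_schedule`.
#' @param path output file.
#' @export
write_schedule <- function(schedule, path) {
  tr <- schedule$trials
  ons <- trial_onsets(schedule)
  out <- cbind(tr, cue_onset_ms = ons$cue_onset_ms,
               gap_onset_ms = tr$cue_duration_ms,
               stim_onset_ms = ons$stim_onset_ms)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_schedule
#' @param design the [design_params()] the schedule was generated from
#'   (counts are re-validated against it).
#' @return for `read_schedule`, a `task_schedule`.
#' @export
read_schedule <- function(path, design = design_params()) {
  tr <- utils::read.delim(path, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  needed <- c("index", "condition", "trial_type", "cue_direction",
              "stop_direction", "ssd_ms")
  miss <- setdiff(needed, names(tr))
  if (length(miss))
    stop("malformed schedule file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  structure(list(trials = tr[, intersect(
    c(needed, "cue_duration_ms", "gap_duration_ms",
      "stimulus_duration_ms"), names(tr))],
    seed = NA_integer_, design = design),
    class = "task_schedule")
}

#' Write / read an event marker table (tab-separated)
#'
#' Columns: onset_sample, code, condition, direction, ssd_ms, trial_index.
#' The reader sorts by onset and warns when the file was unsorted.
#'
#' @param events marker data frame.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  if (!all(c("onset_sample", "code") %in% names(ev)))
    stop("malformed event file ", path,
         ": needs onset_sample and code columns", call. = FALSE)
  if (is.unsorted(ev$onset_sample)) {
    warning("event onsets were unsorted in ", path, "; sorting")
    ev <- ev[order(ev$onset_sample), ]
    rownames(ev) <- NULL
  }
  ev
}

pad_field <- function(x, width) {
  s <- as.character(x)
  s <- ifelse(nchar(s) > width, substr(s, 1, width), s)
  formatC(s, width = -width)
}

#' Write a recording to European Data Format (EDF)
#'
#' Minimal EDF writer: one physical/digital scaling per channel computed
#' from the data range, 1-second data records, 16-bit little-endian
#' samples. The trailing partial record is zero-padded; the true sample
#' count is recoverable from the event table or the caller.
#'
#' @param recording an `eeg_recording`.
#' @param path output file.
#' @export
write_edf <- function(recording, path) {
  X <- recording$data
  sfreq <- recording$sfreq
  ns <- nrow(X)
  spr <- as.integer(sfreq)                 # samples per 1-s record
  n_rec <- as.integer(ceiling(ncol(X) / spr))
  pad <- n_rec * spr - ncol(X)
  if (pad > 0) X <- cbind(X, matrix(0, ns, pad))
  phys_min <- apply(X, 1, min)
  phys_max <- apply(X, 1, max)
  same <- phys_max - phys_min < 1e-12
  phys_max[same] <- phys_min[same] + 1
  dig_min <- -32768L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con,
                                     nchars = width, eos = NULL)
  header_bytes <- 256L + 256L * ns
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(header_bytes, 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (lab in recording$labels) wr(lab, 16)
  for (i in 1:ns) wr("", 80)                       # transducer
  for (i in 1:ns) wr("uV", 8)
  for (i in 1:ns) wr(signif(phys_min[i], 6), 8)
  for (i in 1:ns) wr(signif(phys_max[i], 6), 8)
  for (i in 1:ns) wr(dig_min, 8)
  for (i in 1:ns) wr(dig_max, 8)
  for (i in 1:ns) wr("", 80)                       # prefiltering
  for (i in 1:ns) wr(spr, 8)
  for (i in 1:ns) wr("", 32)
  # re-read the written physical bounds at header precision so the
  # digitisation uses exactly what a reader will see
  pmin_h <- as.numeric(pad_field(signif(phys_min, 6), 8))
  pmax_h <- as.numeric(pad_field(signif(phys_max, 6), 8))
  scale <- (pmax_h - pmin_h) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in 1:ns) {
      dig <- round((X[ch, idx] - pmin_h[ch]) / scale[ch]) + dig_min
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @return for `read_edf`, an `eeg_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  ver <- rd(8)
  if (ver != "0")
    stop("malformed EDF file ", path, ": bad version field at byte 0",
         call. = FALSE)
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(1:ns, function(i) rd(16), "")
  for (i in 1:ns) rd(80)
  for (i in 1:ns) rd(8)                            # physical dimension
  pmin <- vapply(1:ns, function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(1:ns, function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(1:ns, function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(1:ns, function(i) as.numeric(rd(8)), 0)
  for (i in 1:ns) rd(80)
  spr <- vapply(1:ns, function(i) as.integer(rd(8)), 0L)
  for (i in 1:ns) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed sampling rates not supported", call. = FALSE)
  X <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in 1:ns) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      X[ch, idx] <- (dig - dmin[ch]) * scale[ch] + pmin[ch]
    }
  }
  structure(list(data = X, labels = labels, sfreq = spr[1] / rec_dur),
            class = "eeg_recording")
}

#' Write / read a behavioural trial log as CSV
#'
#' @param behavior a `behavioral_trials` data frame.
#' @param path file path.
#' @export
write_behavior <- function(behavior, path) {
  utils::write.csv(behavior, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("index", "left_rt_ms", "right_rt_ms") %in% names(b)))
    stop("malformed behaviour log ", path,
         ": needs index, left_rt_ms, right_rt_ms", call. = FALSE)
  class(b) <- c("behavioral_trials", "data.frame")
  b
}
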