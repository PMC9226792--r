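sine_rec <- function(freq, sfreq = 500, dur = 20, amp = 1) {
  t <- seq(0, dur, by = 1 / sfreq)
  as_recording(matrix(amp * sin(2 * pi * freq * t), 1), "Fz", sfreq)
}

test_that("band-pass keeps 10 Hz, kills DC, attenuates 60 Hz by > 20 dB", {
  mid <- 1000:9000
  g10 <- max(abs(bandpass(sine_rec(10))$data[1, mid]))
  expect_gte(g10, 0.95)
  dc <- bandpass(as_recording(matrix(50, 1, 10000), "Fz"))
  expect_lt(mean(abs(dc$data[1, mid])), 1)
  g60 <- max(abs(bandpass(sine_rec(60))$data[1, mid]))
  expect_lt(20 * log10(1 / g60), Inf)
  expect_gt(-20 * log10(g60), 20)
  expect_error(bandpass(sine_rec(10), high = 250), "Nyquist")
})

test_that("band-passed white noise is band-limited as the filter response
          predicts", {
  rec <- withr::with_seed(5, as_recording(matrix(rnorm(2e4), 1), "Fz"))
  out <- bandpass(rec)$data[1, ]
  sp_in <- Mod(fft(rec$data[1, ]))^2
  sp_out <- Mod(fft(out))^2
  f <- (seq_along(sp_out) - 1) * 500 / length(sp_out)
  inband <- f > 1 & f < 40
  stopband <- f > 80 & f < 250
  gain_in <- sum(sp_out[inband]) / sum(sp_in[inband])
  gain_stop <- sum(sp_out[stopband]) / sum(sp_in[stopband])
  expect_gt(gain_in, 0.8)
  expect_lt(gain_stop, 0.01)
})

test_that("epoching matches markers, flags edge events, zeroes baselines", {
  tpl <- quiet_templates()
  ses <- simulate_session(race_params(), tpl, design_params(), seed = 20)
  ep <- epoch(ses$eeg, ses$events, "stop", condition = "proactive",
              direction = "right")
  expect_equal(dim(ep$data)[1], 70)
  expect_equal(dim(ep$data)[1],
               sum(ses$events$code == "stop" &
                     ses$events$condition == "proactive" &
                     ses$events$direction == "right"))
  bl <- ep$times_ms >= -200 & ep$times_ms <= 0
  expect_lt(max(abs(apply(ep$data[, , bl], c(1, 2), mean))), 1e-9)
  # event at the very start of the record is edge-flagged, not an error
  ev <- data.frame(onset_sample = 10, code = "cue", condition = "reactive",
                   direction = "none", ssd_ms = NA, trial_index = 0)
  ep2 <- epoch(ses$eeg, ev, "cue")
  expect_true(ep2$rejected[1])
  expect_equal(ep2$reject_reason[1], "edge")
})

test_that("noiseless epochs reproduce the injected template sample for
          sample", {
  tpl <- quiet_templates(p3go_amp = 5, p3go_lat = 350)
  des <- design_params(n_total = 20)
  ses <- simulate_session(race_params(), tpl, des, seed = 21)
  ep <- epoch(ses$eeg, ses$events, "go")
  cz <- match("Cz", ep$channels)
  one <- ep$data[1, cz, ]
  expect_equal(max(one), 5, tolerance = 1e-9)
  expect_equal(ep$times_ms[which.max(one)], 350)
  # every epoch identical to the template
  for (i in 2:dim(ep$data)[1])
    expect_equal(ep$data[i, cz, ], one, tolerance = 1e-12)
})

test_that("amplitude rejection flags threshold crossers and is monotone", {
  tpl <- quiet_templates()
  ses <- simulate_session(race_params(), tpl, design_params(n_total = 20),
                          seed = 22)
  ep <- epoch(ses$eeg, ses$events, "go")
  ep$data[2, 1, 100] <- 120          # above default threshold
  ep$data[3, 1, 100] <- 80           # below
  r <- reject_amplitude(ep)
  expect_true(r$rejected[2])
  expect_equal(r$reject_reason[2], "amplitude")
  expect_false(r$rejected[3])
  # lowering the threshold never retains more epochs
  kept <- sapply(c(150, 100, 60, 30, 1),
                 function(th) sum(!reject_amplitude(ep, th)$rejected))
  expect_true(all(diff(kept) <= 0))
})

test_that("averaging is idempotent, order-invariant and obeys the 1/sqrt(n)
          law", {
  tpl <- quiet_templates()
  ses <- simulate_session(race_params(), tpl, design_params(n_total = 20),
                          seed = 23)
  ep <- epoch(ses$eeg, ses$events, "go")
  avg <- grand_average(ep)
  # identical epochs average to any one of them
  expect_equal(avg$data[match("Cz", avg$channels), ],
               ep$data[1, match("Cz", ep$channels), ], tolerance = 1e-12)
  # permuting epochs leaves the average unchanged
  perm <- ep
  o <- withr::with_seed(1, sample(dim(ep$data)[1]))
  perm$data <- ep$data[o, , , drop = FALSE]
  perm$rejected <- ep$rejected[o]
  expect_equal(grand_average(perm)$data, avg$data, tolerance = 1e-12)
  # noisy epochs: residual of the average shrinks like 1/sqrt(n)
  tpl_n <- erp_templates(noise_rms_uv = 10, blink_rate_per_min = 0,
                         gross_artifact_p = 0, noise_exponent = 0)
  des <- design_params(n_total = 180)
  ses_n <- simulate_session(race_params(), tpl_n, des, seed = 24)
  ses_q <- simulate_session(race_params(), quiet_templates(), des, seed = 24)
  avn <- grand_average(epoch(ses_n$eeg, ses_n$events, "go"))
  avq <- grand_average(epoch(ses_q$eeg, ses_q$events, "go"))
  resid <- avn$data - avq$data
  rms <- sqrt(mean(resid^2))
  expect_equal(rms, 10 / sqrt(avn$n), tolerance = 0.3)
  # group level: average of equal subject ERPs is the subject ERP
  expect_equal(grand_average(list(avq, avq, avq))$data, avq$data)
})

test_that("component measurement scores peaks inside the defined windows", {
  t <- seq(-200, 800, by = 2)
  bump <- function(amp, lat, w = 40) amp * exp(-((t - lat)^2) / (2 * w^2))
  wave <- function(y, ch = "Cz") {
    structure(list(data = matrix(rep(y, 6), 6, byrow = TRUE,
                                 dimnames = list(NULL, NULL)),
                   times_ms = t,
                   channels = c("Fz", "F3", "F4", "Cz", "C3", "C4"),
                   sfreq = 500, n = 1), class = "erp_waveform")
  }
  m <- measure_component(wave(bump(5, 400)), "P3go", "Cz")
  expect_equal(m$amplitude_uv, 5)
  expect_equal(m$latency_ms, 400)
  expect_true(m$latency_ms >= m$window_lo_ms & m$latency_ms <= m$window_hi_ms)
  # two negative troughs at 150 and 250 ms: the 250 ms one is the second
  # negative peak overall and lies in the N2 window
  y2 <- -bump(3, 150, 20) - bump(2, 250, 20)
  m2 <- measure_component(wave(y2), "N2stop", "Fz")
  expect_equal(m2$amplitude_uv, -2, tolerance = 1e-3)
  expect_equal(m2$latency_ms, 250)
  expect_equal(m2$flag, "")
  # single trough: fallback to the most negative minimum in the window
  m3 <- measure_component(wave(-bump(2, 250, 20)), "N2stop", "Fz")
  expect_equal(m3$flag, "fallback")
  expect_equal(m3$latency_ms, 250)
  # flat waveform: missing-component signal
  expect_warning(m4 <- measure_component(wave(rep(0, length(t))),
                                         "N2stop", "Fz"), "missing")
  expect_true(is.na(m4$amplitude_uv))
  # window outside the epoch is a configuration error
  short <- wave(bump(5, 400))
  short$times_ms <- t + 500
  expect_error(measure_component(short, "P3go", "Cz"), "outside")
})

test_that("noiseless pipeline recovers injected amplitudes and latencies on
          all electrodes", {
  tpl <- quiet_templates()
  ses <- simulate_session(race_params(), tpl, design_params(n_total = 40),
                          seed = 26)
  m <- measure_session(ses, filter = FALSE)
  for (i in seq_len(nrow(m))) {
    comp <- m$component[i]
    tplc <- tpl$components[[comp]]
    want_amp <- tplc$amp[[m$condition[i]]] * tplc$weights[[m$electrode[i]]]
    expect_equal(m$amplitude_uv[i], want_amp, tolerance = 1e-6)
    expect_lte(abs(m$latency_ms[i] - tplc$lat), 2)  # one sample at 500 Hz
  }
})
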