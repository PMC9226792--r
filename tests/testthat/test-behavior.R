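mini_sched <- function() {
  # 2 conditions x (3 go + 2 stop) hand-built schedule
  des <- design_params(n_total = 20, go_frac = 0.6)
  generate_schedule(des, seed = 101)
}

test_that("trial classification follows the selective-stopping taxonomy", {
  s <- mini_sched()
  tr <- s$trials
  raw <- data.frame(index = tr$index, left_rt_ms = 600, right_rt_ms = 600)
  stop_r <- which(tr$trial_type == "stop" & tr$stop_direction == "right")
  stop_l <- which(tr$trial_type == "stop" & tr$stop_direction == "left")
  go_i <- which(tr$trial_type == "go")
  # both hands respond on a stop-right trial -> failed stop
  # left hand only -> successful selective stop
  raw$right_rt_ms[stop_r[2]] <- NA
  # right hand only on a stop-right trial -> choice error
  raw$left_rt_ms[stop_r[3]] <- NA
  # no response on a go trial -> omission
  raw$left_rt_ms[go_i[1]] <- NA
  raw$right_rt_ms[go_i[1]] <- NA
  cls <- classify_trials(raw, s)
  expect_equal(cls$classification[stop_r[1]], "stop_failed")
  expect_equal(cls$classification[stop_r[2]], "stop_success")
  expect_equal(cls$classification[stop_r[3]], "stop_choice_error")
  expect_equal(cls$classification[stop_l[1]], "stop_failed")
  expect_equal(cls$classification[go_i[1]], "go_omission")
  expect_equal(cls$classification[go_i[2]], "go_correct")
  # exhaustive and mutually exclusive
  expect_equal(sum(table(cls$classification)), nrow(tr))
  expect_error(classify_trials(raw[-1, ], s), "rows")
})

test_that("go metrics average responded trials and count omissions", {
  s <- generate_schedule(design_params(n_total = 20, go_frac = 0.6),
                         seed = 3)
  tr <- s$trials
  raw <- data.frame(index = tr$index, left_rt_ms = NA_real_,
                    right_rt_ms = NA_real_)
  go_i <- which(tr$trial_type == "go")
  raw$left_rt_ms[go_i] <- 500
  raw$right_rt_ms[go_i] <- 700
  raw$left_rt_ms[go_i[1:2]] <- NA
  raw$right_rt_ms[go_i[1:2]] <- NA
  st_i <- which(tr$trial_type == "stop")
  raw$left_rt_ms[st_i] <- 600; raw$right_rt_ms[st_i] <- 600
  cls <- classify_trials(raw, s)
  gm <- go_metrics(cls)
  expect_equal(gm$mean_rt_ms, 600)      # mean of the two hands
  expect_equal(gm$omission_count, 2)
  expect_equal(gm$n_go, 12)
  expect_error(go_metrics(cls[cls$trial_type == "stop", ]), "no go trials")
})

test_that("simulated go RTs have the ex-Gaussian mean mu + tau", {
  s <- generate_schedule(seed = 12)
  p <- race_params(go_mu = 500, go_tau = 100, proactive_slowing_ms = 0,
                   go_omission_p = 0)
  b <- simulate_behavior(s, p, seed = 13)
  cls <- classify_trials(b, s)
  expect_equal(go_metrics(cls)$mean_rt_ms, 600, tolerance = 10 / 600)
})

test_that("integration SSRT matches hand-computed cases", {
  est <- estimate_ssrt_integration(seq(400, 580, by = 20), 0.5, 200)
  expect_equal(est$n_rank, 5)
  expect_equal(est$value_ms, 280)
  # degenerate distribution: every quantile is the common value
  for (p in c(0.01, 0.4, 1))
    expect_equal(estimate_ssrt_integration(rep(500, 30), p, 300)$value_ms,
                 200)
  expect_warning(est0 <- estimate_ssrt_integration(1:10, 0, 100),
                 "undefined")
  expect_true(is.na(est0$value_ms))
  expect_error(estimate_ssrt_integration(numeric(0), 0.5, 100), "empty")
})

test_that("integration SSRT equals the sort-and-index oracle on random
          inputs", {
  withr::with_seed(21, {
    for (i in 1:200) {
      n <- sample(5:200, 1)
      rts <- round(runif(n, 300, 900), 1)
      p <- runif(1, 0.05, 1)
      ssd <- runif(1, 100, 400)
      om <- sample(0:5, 1)
      expect_equal(estimate_ssrt_integration(rts, p, ssd, om)$value_ms,
                   oracle_ssrt(rts, p, ssd, om))
    }
  })
})

test_that("SSRT estimator is translation-equivariant and SSD-monotone", {
  withr::with_seed(31, {
    rts <- runif(80, 400, 800)
    base <- estimate_ssrt_integration(rts, 0.37, 250)$value_ms
    expect_equal(estimate_ssrt_integration(rts + 33, 0.37, 250)$value_ms,
                 base + 33)
    expect_equal(estimate_ssrt_integration(rts, 0.37, 250 + 40)$value_ms,
                 base - 40)
  })
})

test_that("omission padding never lowers the estimate", {
  rts <- seq(400, 600, by = 10)
  e0 <- estimate_ssrt_integration(rts, 0.6, 200, omission_count = 0)$value_ms
  e5 <- estimate_ssrt_integration(rts, 0.6, 200, omission_count = 5)$value_ms
  expect_gte(e5, e0)
})

test_that("recovery is monotone over the stop-latency grid and unbiased at
          the calibration point", {
  # With uniform random SSDs (no staircase) the integration estimate is
  # attenuated toward the centre of its range, so point recovery is asserted
  # at the 250 ms calibration condition and ordering over the grid.
  recover <- function(stop_mu, seeds) {
    mean(sapply(seeds, function(sd) {
      s <- generate_schedule(seed = sd)
      b <- simulate_behavior(s, race_params(stop_mu = stop_mu),
                             seed = sd + 100)
      m <- behavior_metrics(classify_trials(b, s))
      mean(c(m$ssrt_right_ms, m$ssrt_left_ms))
    }))
  }
  est <- sapply(c(200, 250, 300), recover, seeds = 1:6)
  expect_true(all(diff(est) > 0))
  expect_lt(abs(est[2] - 250), 15)
})

test_that("session scorecard has the expected shape and strata", {
  s <- generate_schedule(seed = 14)
  b <- simulate_behavior(s, race_params(), seed = 15)
  m <- behavior_metrics(classify_trials(b, s))
  expect_equal(nrow(m), 2)
  expect_setequal(m$condition, c("reactive", "proactive"))
  expect_true(all(c("rt_go_ms", "om_go", "ssrt_right_ms", "ssrt_left_ms",
                    "che_stopr", "che_stopl") %in% names(m)))
  expect_true(all(is.finite(m$ssrt_right_ms)))
})
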