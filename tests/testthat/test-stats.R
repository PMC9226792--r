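test_that("pooled t-test matches hand computation and handles degeneracy", {
  tt <- independent_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(tt$t, 3), -3.674)
  expect_equal(tt$df, 4)
  same <- independent_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  ident <- independent_t_test(c(1, 5, 9), c(1, 5, 9))
  expect_equal(ident$t, 0, tolerance = 1e-12)
  expect_equal(ident$p, 1, tolerance = 1e-12)
  expect_error(independent_t_test(1, c(1, 2)), "at least 2")
  # Welch flag reproduces R's Welch df
  w <- independent_t_test(c(1, 2, 3, 9), c(4, 5, 6), welch = TRUE)
  expect_equal(w$df, unname(t.test(c(1, 2, 3, 9), c(4, 5, 6))$parameter))
})

test_that("t-test type-I error is calibrated under the null", {
  p <- withr::with_seed(41, replicate(1000, {
    independent_t_test(rnorm(8), rnorm(8))$p
  }))
  expect_gte(mean(p < 0.05), 0.035)
  expect_lte(mean(p < 0.05), 0.065)
})

test_that("mixed RM-ANOVA equals the brute-force SS decomposition", {
  d <- expand.grid(subject = paste0("s", 1:6), trial = c("a", "b"),
                   electrode = c("e1", "e2", "e3"))
  d$group <- ifelse(d$subject %in% paste0("s", 1:3), "g1", "g2")
  d$y <- withr::with_seed(7, as.numeric(sample(1:50, nrow(d), replace = TRUE)))
  res <- mixed_rm_anova(d, "y", "subject", "group", c("trial", "electrode"))
  ss <- oracle_mixed_ss(d, "y", "subject", "group", "trial", "electrode")
  get <- function(eff) res[res$effect == eff, ]
  rel <- function(x, y) abs(x - y) / max(1, abs(y))
  expect_lt(rel(get("group")$ss, ss$G), 1e-9)
  expect_lt(rel(get("group")$ss_error, ss$subj_err), 1e-9)
  expect_lt(rel(get("trial")$ss, ss$A), 1e-9)
  expect_lt(rel(get("group x trial")$ss, ss$GA), 1e-9)
  expect_lt(rel(get("trial")$ss_error, ss$A_err), 1e-9)
  expect_lt(rel(get("electrode")$ss, ss$B), 1e-9)
  expect_lt(rel(get("group x electrode")$ss, ss$GB), 1e-9)
  expect_lt(rel(get("electrode")$ss_error, ss$B_err), 1e-9)
  expect_lt(rel(get("trial x electrode")$ss, ss$AB), 1e-9)
  expect_lt(rel(get("group x trial x electrode")$ss, ss$GAB), 1e-9)
  expect_lt(rel(get("trial x electrode")$ss_error, ss$AB_err), 1e-9)
  # F from SS ratio matches reported F
  expect_equal(get("trial")$F,
               (ss$A / get("trial")$df_num) /
                 (ss$A_err / get("trial")$df_den), tolerance = 1e-9)
})

test_that("identical groups give a zero group effect", {
  d <- expand.grid(subject = paste0("s", 1:4), trial = c("a", "b"))
  d$group <- ifelse(d$subject %in% c("s1", "s2"), "g1", "g2")
  vals <- c(a = 3, b = 7)
  d$y <- vals[as.character(d$trial)]          # same for every subject
  res <- mixed_rm_anova(d, "y", "subject", "group", "trial")
  expect_equal(res$F[res$effect == "group"], 0)
})

test_that("incomplete designs raise explicit missing-cell errors", {
  d <- expand.grid(subject = paste0("s", 1:4), trial = c("a", "b"))
  d$group <- ifelse(d$subject %in% c("s1", "s2"), "g1", "g2")
  d$y <- rnorm(nrow(d))
  expect_error(mixed_rm_anova(d[-1, ], "y", "subject", "group", "trial"),
               "unbalanced")
  d2 <- d
  d2$group[d2$subject == "s1"][1] <- "g2"
  expect_error(mixed_rm_anova(d2, "y", "subject", "group", "trial"),
               "more than one group")
})

test_that("partial eta squared obeys its F-statistic identity", {
  d <- expand.grid(subject = paste0("s", 1:8), trial = c("a", "b"),
                   electrode = c("e1", "e2"))
  d$group <- ifelse(d$subject %in% paste0("s", 1:4), "g1", "g2")
  d$y <- withr::with_seed(9, rnorm(nrow(d), ave(seq_len(nrow(d)),
                                                d$subject)))
  res <- mixed_rm_anova(d, "y", "subject", "group", c("trial", "electrode"))
  expect_equal(res$partial_eta_sq,
               partial_eta_sq(res$F, res$df_num, res$df_den),
               tolerance = 1e-12)
  expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))
  expect_true(all(res$F >= 0))
})

test_that("Greenhouse-Geisser leaves 2-level effects alone and shrinks
          others' significance no more than warranted", {
  d <- expand.grid(subject = paste0("s", 1:10), trial = c("a", "b", "c"))
  d$group <- ifelse(d$subject %in% paste0("s", 1:5), "g1", "g2")
  eff <- c(a = 0, b = 1.5, c = 3)
  d$y <- withr::with_seed(11, eff[as.character(d$trial)] + rnorm(nrow(d)))
  plain <- mixed_rm_anova(d, "y", "subject", "group", "trial")
  gg <- mixed_rm_anova(d, "y", "subject", "group", "trial", gg = TRUE)
  i <- which(gg$effect == "trial")
  expect_equal(gg$F[i], plain$F[i])            # F unchanged, dfs rescaled
  expect_gte(gg$p[i], plain$p[i])              # correction is conservative
  expect_equal(gg$correction[i], "greenhouse_geisser")
  expect_equal(gg$correction[gg$effect == "group"], "none")
})

test_that("Bonferroni adjustment multiplies, caps at one, preserves order", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_equal(bonferroni_adjust(c(0.04, 0.04), 2), c(0.08, 0.08))
  p <- c(0.001, 0.02, 0.04, 0.3)
  expect_equal(order(bonferroni_adjust(p, 6)), order(p))
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), "family_size")
})

test_that("participant screening applies the addiction-score cutoffs", {
  tab <- data.frame(subject = c("a", "b", "c"), vat = c(2.82, 1.05, 2.0))
  out <- screen_participants(tab)
  expect_equal(out$vga_eligible, c(TRUE, FALSE, FALSE))
  expect_equal(out$control_eligible, c(FALSE, TRUE, FALSE))
  expect_error(screen_participants(data.frame(subject = "x", vat = 5.4)),
               "range")
})
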