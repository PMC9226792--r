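# Independent oracles used across tests. These stay deliberately naive:
# explicit enumeration and marginal-mean arithmetic, no shared code with the
# implementation.

# Integration-method SSRT by explicit sort-and-index enumeration.
oracle_ssrt <- function(go_rts, p_respond, mean_ssd, omissions = 0) {
  padded <- c(go_rts, rep(max(go_rts), omissions))
  sorted <- sort(padded)
  n <- length(sorted)
  idx <- ceiling(p_respond * n)
  idx <- max(1, min(n, idx))
  sorted[idx] - mean_ssd
}

# Brute-force sums-of-squares for a balanced 1-between (G) x 2-within (A, B)
# repeated-measures design with one observation per subject x A x B cell.
# Returns every effect and error SS via explicit marginal means.
oracle_mixed_ss <- function(d, dv, subject, between, w1, w2) {
  y <- d[[dv]]
  S <- factor(d[[subject]]); G <- factor(d[[between]])
  A <- factor(d[[w1]]); B <- factor(d[[w2]])
  m <- mean(y)
  mg <- tapply(y, G, mean); ma <- tapply(y, A, mean); mb <- tapply(y, B, mean)
  ms <- tapply(y, S, mean)
  gofs <- tapply(as.character(G), S, `[`, 1)   # group of each subject
  mga <- tapply(y, list(G, A), mean); mgb <- tapply(y, list(G, B), mean)
  mab <- tapply(y, list(A, B), mean)
  mgab <- tapply(y, list(G, A, B), mean)
  msa <- tapply(y, list(S, A), mean); msb <- tapply(y, list(S, B), mean)
  a <- nlevels(A); b <- nlevels(B); g <- nlevels(G)
  n_subj <- nlevels(S); n_per <- n_subj / g

  ss <- list()
  ss$G <- n_per * a * b * sum((mg - m)^2)
  ss$subj_err <- a * b * sum((ms - mg[gofs])^2)
  ss$A <- n_subj * b * sum((ma - m)^2)
  ss$GA <- n_per * b * sum((mga - outer(mg, ma, `+`) + m)^2)
  ss$A_err <- 0
  for (s in levels(S)) for (ai in levels(A))
    ss$A_err <- ss$A_err +
      b * (msa[s, ai] - ms[s] - mga[gofs[s], ai] + mg[gofs[s]])^2
  ss$B <- n_subj * a * sum((mb - m)^2)
  ss$GB <- n_per * a * sum((mgb - outer(mg, mb, `+`) + m)^2)
  ss$B_err <- 0
  for (s in levels(S)) for (bi in levels(B))
    ss$B_err <- ss$B_err +
      a * (msb[s, bi] - ms[s] - mgb[gofs[s], bi] + mg[gofs[s]])^2
  ss$AB <- n_subj * sum((mab - outer(ma, mb, `+`) + m)^2)
  gab_dev <- mgab
  for (gi in dimnames(mgab)[[1]]) for (ai in dimnames(mgab)[[2]])
    for (bi in dimnames(mgab)[[3]])
      gab_dev[gi, ai, bi] <- mgab[gi, ai, bi] - mga[gi, ai] - mgb[gi, bi] -
        mab[ai, bi] + mg[gi] + ma[ai] + mb[bi] - m
  ss$GAB <- n_per * sum(gab_dev^2)
  ss_total <- sum((y - m)^2)
  ss$AB_err <- ss_total - Reduce(`+`, ss)
  lapply(ss, as.numeric)
}

# tiny helper: an eeg_recording from a channels x samples matrix
as_recording <- function(X, labels = paste0("ch", seq_len(nrow(X))),
                         sfreq = 500) {
  structure(list(data = X, labels = labels, sfreq = sfreq),
            class = "eeg_recording")
}

# noiseless template set: no noise, no blinks, no gross artifacts
quiet_templates <- function(...) {
  erp_templates(noise_rms_uv = 0, blink_rate_per_min = 0,
                gross_artifact_p = 0, ...)
}
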