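#' Independent-samples t-test with group summaries
#'
#' Classical two-sided pooled-variance Student's t-test (Welch's unequal
#' variance form available via `welch = TRUE`). With zero pooled variance
#' and equal means the conventional `t = 0, p = 1` is returned rather than
#' an error.
#'
#' @param x,y numeric vectors for the two groups (each n >= 2).
#' @param welch use the Welch-Satterthwaite form.
#' @return list of class `t_test_result`: `t`, `df`, `p`, `mean_x`, `sd_x`,
#'   `mean_y`, `sd_y`.
#' @export
independent_t_test <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  degenerate <- sd(x) == 0 && sd(y) == 0
  if (degenerate && mean(x) == mean(y)) {
    res <- list(t = 0, df = length(x) + length(y) - 2, p = 1)
  } else if (degenerate) {
    res <- list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0)
  } else {
    tt <- t.test(x, y, var.equal = !welch)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  out <- c(res, list(mean_x = mean(x), sd_x = sd(x),
                     mean_y = mean(y), sd_y = sd(y)))
  class(out) <- "t_test_result"
  out
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t(%.2f) = %.3f, p = %.4g  [%.2f +/- %.2f vs %.2f +/- %.2f]\n",
              x$df, x$t, x$p, x$mean_x, x$sd_x, x$mean_y, x$sd_y))
  invisible(x)
}

#' Bonferroni adjustment over an explicit family
#'
#' Multiplies each p-value by the family size and caps at 1. The family
#' size may exceed the number of p-values supplied (comparisons planned but
#' not all carried out).
#'
#' @param p_values numeric vector of raw p-values.
#' @param family_size number of comparisons in the family (defaults to
#'   `length(p_values)`).
#' @return adjusted p-values, order-preserving.
#' @export
bonferroni_adjust <- function(p_values, family_size = length(p_values)) {
  if (family_size < length(p_values))
    stop("family_size must be at least the number of p-values",
         call. = FALSE)
  pmin(1, p_values * family_size)
}

#' Mixed repeated-measures ANOVA (between group x within factors)
#'
#' Univariate sums-of-squares decomposition with subject as the blocking
#' unit: each within effect (and its interaction with group) is tested
#' against the corresponding subject-by-effect error stratum; the group main
#' effect is tested against between-subject variation. Requires a complete
#' balanced design (every subject measured in every within cell). Partial
#' eta squared is reported per effect as SS_effect / (SS_effect +
#' SS_error-of-its-stratum). An optional Greenhouse-Geisser correction
#' rescales the dfs of within effects (off by default).
#'
#' @param data long-format data frame.
#' @param dv name of the dependent-variable column.
#' @param subject name of the subject-identifier column.
#' @param between name of the between-subjects factor column (or NULL).
#' @param within character vector of within-subject factor columns.
#' @param gg apply the Greenhouse-Geisser sphericity correction to within
#'   effects.
#' @return data frame of class `anova_result`: one row per effect with
#'   `effect`, `ss`, `ss_error`, `df_num`, `df_den`, `F`, `p`,
#'   `partial_eta_sq`, `correction`.
#' @export
mixed_rm_anova <- function(data, dv, subject, between = NULL, within,
                           gg = FALSE) {
  d <- data
  d$.y <- d[[dv]]
  d$.subj <- factor(d[[subject]])
  if (anyNA(d$.y)) {
    bad <- unique(as.character(d$.subj)[is.na(d$.y)])
    stop("missing '", dv, "' measurement(s) for subject(s) ",
         paste(bad, collapse = ", "),
         "; complete or drop these subjects (no imputation is applied)",
         call. = FALSE)
  }
  for (w in within) d[[w]] <- factor(d[[w]])
  if (!is.null(between)) d[[between]] <- factor(d[[between]])

  # balance check: every subject must hold every within-cell exactly once
  cell <- interaction(d[, within, drop = FALSE], drop = FALSE)
  tab <- table(d$.subj, cell)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    stop("unbalanced design: subject ", rownames(tab)[bad[1, 1]],
         " has ", tab[bad[1, , drop = FALSE]], " observations in cell ",
         colnames(tab)[bad[1, 2]], call. = FALSE)
  }
  if (!is.null(between)) {
    g_per_subj <- tapply(as.character(d[[between]]), d$.subj,
                         function(x) length(unique(x)))
    if (any(g_per_subj != 1))
      stop("a subject appears in more than one group", call. = FALSE)
    if (length(unique(tapply(d[[between]], d$.subj, `[`, 1))) < 2 ||
        min(table(tapply(d[[between]], d$.subj, `[`, 1))) < 2)
      stop("need at least 2 subjects per group", call. = FALSE)
  }

  wterm <- paste(within, collapse = "*")
  rhs <- if (is.null(between)) wterm else
    paste0(between, "*", wterm)
  form <- stats::as.formula(
    paste0(".y ~ ", rhs, " + Error(.subj/(", wterm, "))"))
  fit <- aov(form, data = d)
  sm <- summary(fit)

  rows <- list()
  ss_tot <- sum((d$.y - mean(d$.y))^2)
  tiny <- 1e-12 * (ss_tot + 1)      # guard: exact-zero effects, not 0/0 noise
  for (stratum in names(sm)) {
    tabs <- sm[[stratum]][[1]]
    terms <- trimws(rownames(tabs))
    resid_i <- which(terms == "Residuals")
    if (length(resid_i) == 0) next
    ss_err <- tabs[resid_i, "Sum Sq"]
    df_err <- tabs[resid_i, "Df"]
    for (i in setdiff(seq_along(terms), resid_i)) {
      ss <- tabs[i, "Sum Sq"]
      dfn <- tabs[i, "Df"]
      Fv <- if (ss < tiny) 0 else (ss / dfn) / (ss_err / df_err)
      rows[[length(rows) + 1]] <- data.frame(
        effect = gsub(":", " x ", terms[i]),
        ss = ss, ss_error = ss_err, df_num = dfn, df_den = df_err,
        F = Fv, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$correction <- "none"
  res$eps <- 1

  if (gg) {
    for (i in seq_len(nrow(res))) {
      wf <- strsplit(res$effect[i], " x ", fixed = TRUE)[[1]]
      wf <- intersect(wf, within)
      if (length(wf) == 0) next
      eps <- gg_epsilon(d, within_effect = wf, within_all = within)
      res$eps[i] <- eps
      res$correction[i] <- "greenhouse_geisser"
    }
  }
  res$p <- stats::pf(res$F, res$df_num * res$eps, res$df_den * res$eps,
                     lower.tail = FALSE)
  res$partial_eta_sq <- res$ss / (res$ss + res$ss_error)
  res$eps <- NULL
  res <- res[, c("effect", "ss", "ss_error", "df_num", "df_den", "F", "p",
                 "partial_eta_sq", "correction")]
  class(res) <- c("anova_result", "data.frame")
  res
}

# Greenhouse-Geisser epsilon for a within effect, from the covariance of
# the subject x within-cell score matrix projected on the effect contrasts.
gg_epsilon <- function(d, within_effect, within_all) {
  # subject x cell matrix of scores, cells ordered consistently
  cell <- interaction(d[, within_all, drop = FALSE], drop = FALSE)
  M <- tapply(d$.y, list(d$.subj, cell), mean)
  cells <- do.call(expand.grid,
                   lapply(d[, within_all, drop = FALSE], levels))
  names(cells) <- within_all
  ord <- match(colnames(M), interaction(cells, drop = FALSE))
  cells <- cells[ord, , drop = FALSE]
  # contrast matrix of the effect: kronecker over per-factor contrasts
  # (averaging matrix for factors not in the effect)
  mats <- lapply(within_all, function(w) {
    k <- nlevels(factor(cells[[w]]))
    if (w %in% within_effect) stats::contr.helmert(k) else
      matrix(1, k, 1)
  })
  # cells vary fastest in the first factor (expand.grid convention)
  Cm <- Reduce(function(a, b) kronecker(b, a), mats)
  S <- cov(M)
  V <- t(Cm) %*% S %*% Cm
  k <- ncol(V)
  (sum(diag(V))^2) / (k * sum(V^2))
}

#' Partial eta squared from an F statistic
#'
#' The algebraic identity `F * df_num / (F * df_num + df_den)`.
#'
#' @param F_value,df_num,df_den ANOVA F statistic and its dfs.
#' @return partial eta squared in \[0, 1\].
#' @export
partial_eta_sq <- function(F_value, df_num, df_den) {
  (F_value * df_num) / (F_value * df_num + df_den)
}

#' Screen participants by video-game-addiction score
#'
#' Eligibility follows the instrument cutoffs: addicted-group eligible at a
#' mean-item score of 2.5 or higher, control-group eligible at 1.5 or
#' less; scores between the cutoffs are eligible for neither group.
#'
#' @param table data frame with columns `subject` and `vat` (mean-item
#'   score on the 0-5 scale).
#' @return the table with logical columns `vga_eligible`,
#'   `control_eligible`.
#' @export
screen_participants <- function(table) {
  v <- table$vat
  if (any(is.na(v)) || any(v < 0 | v > 5))
    stop("VAT scores must lie within the instrument range [0, 5]",
         call. = FALSE)
  table$vga_eligible <- v >= 2.5
  table$control_eligible <- v <= 1.5
  table
}
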