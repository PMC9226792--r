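#' Study configuration
#'
#' Bundles every tunable of the pipeline: task design, per-group race-model
#' and ERP generating parameters, the number of subjects per group, ERP
#' processing settings and statistics settings. A configuration
#' round-trips load -> save -> load to an identical structure.
#'
#' @param n_per_group subjects per group.
#' @param seed master seed; all stage seeds derive from it.
#' @param design [design_params()].
#' @param group_effects per-group `race` + `erp` parameter list.
#' @param include_eeg simulate and analyse EEG (behaviour-only otherwise).
#' @param reject_uv amplitude-rejection threshold in microvolts.
#' @param alpha significance level for the reports.
#' @param gg use the Greenhouse-Geisser correction in the RM-ANOVA.
#' @param welch use Welch t-tests for group comparisons.
#' @return list of class `study_config`.
#' @export
study_config <- function(n_per_group = 30, seed = 1L,
                         design = design_params(),
                         group_effects = default_group_effects(),
                         include_eeg = FALSE, reject_uv = 100,
                         alpha = 0.05, gg = FALSE, welch = FALSE) {
  cfg <- list(n_per_group = n_per_group, seed = as.integer(seed),
              design = design, group_effects = group_effects,
              include_eeg = include_eeg, reject_uv = reject_uv,
              alpha = alpha, gg = gg, welch = welch)
  class(cfg) <- "study_config"
  cfg
}

#' Save / load a study configuration (YAML)
#'
#' @param cfg a `study_config`.
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass_deep(cfg), path)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep)
  else if (!is.null(names(x))) lapply(as.list(x), unclass_deep)
  else unclass(x)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ge <- lapply(raw$group_effects, function(g) {
    race <- g$race
    list(race = race_params(go_mu = race$go_mu, go_sigma = race$go_sigma,
                            go_tau = race$go_tau,
                            stop_mu = unlist(race$stop_mu),
                            stop_sigma = unlist(race$stop_sigma),
                            proactive_slowing_ms = race$proactive_slowing_ms,
                            trigger_failure_p = race$trigger_failure_p,
                            choice_error_p = race$choice_error_p,
                            go_omission_p = race$go_omission_p),
         erp = rebuild_templates(g$erp))
  })
  dp <- raw$design
  study_config(n_per_group = raw$n_per_group, seed = raw$seed,
               design = design_params(
                 n_total = dp$n_total, go_frac = dp$go_frac,
                 conditions = unlist(dp$conditions),
                 ssd_grid_ms = unlist(dp$ssd_grid_ms),
                 cue_ms = dp$cue_ms, gap_ms = dp$gap_ms,
                 stim_ms = dp$stim_ms, stop_ms = dp$stop_ms,
                 max_consecutive_stop = dp$max_consecutive_stop),
               group_effects = ge, include_eeg = raw$include_eeg,
               reject_uv = raw$reject_uv, alpha = raw$alpha, gg = raw$gg,
               welch = raw$welch)
}

rebuild_templates <- function(e) {
  cmp <- e$components
  amp <- function(x) unlist(x$amp)
  erp_templates(p3cue_amp = amp(cmp$P3cue), p3cue_lat = cmp$P3cue$lat,
                p3go_amp = amp(cmp$P3go), p3go_lat = cmp$P3go$lat,
                n2stop_amp = amp(cmp$N2stop), n2stop_lat = cmp$N2stop$lat,
                p3stop_amp = amp(cmp$P3stop), p3stop_lat = cmp$P3stop$lat,
                width_ms = cmp$P3cue$width,
                noise_rms_uv = e$noise_rms_uv,
                noise_exponent = e$noise_exponent,
                blink_rate_per_min = e$blink_rate_per_min,
                blink_amp_uv = e$blink_amp_uv,
                gross_artifact_p = e$gross_artifact_p,
                gross_artifact_uv = e$gross_artifact_uv)
}

#' Behavioural group comparison table
#'
#' Independent t-tests per condition for go RT, omissions, SSRT (right and
#' left) and choice errors (right and left), mirroring the standard
#' behavioural results table of a two-group stop-signal study.
#'
#' @param metrics per-subject metrics: data frame with `subject`, `group`,
#'   `condition` and the [behavior_metrics()] columns.
#' @param welch use Welch t-tests.
#' @return data frame: one row per condition x measure with group means,
#'   SDs, t, df, p.
#' @export
behavior_group_stats <- function(metrics, welch = FALSE) {
  groups <- sort(unique(metrics$group))
  stopifnot(length(groups) == 2)
  measures <- c("rt_go_ms", "om_go", "ssrt_right_ms", "ssrt_left_ms",
                "che_stopr", "che_stopl")
  rows <- list()
  for (cond in unique(metrics$condition)) {
    sub <- metrics[metrics$condition == cond, ]
    for (m in measures) {
      x <- na.omit(sub[[m]][sub$group == groups[1]])
      y <- na.omit(sub[[m]][sub$group == groups[2]])
      if (length(x) < 2 || length(y) < 2) {
        # stratum too sparse (e.g. undefined SSRT at tiny trial counts)
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, measure = m,
          mean_1 = mean(x), sd_1 = sd(x), mean_2 = mean(y), sd_2 = sd(y),
          t = NA_real_, df = NA_real_, p = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      tt <- independent_t_test(x, y, welch = welch)
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, measure = m,
        mean_1 = tt$mean_x, sd_1 = tt$sd_x,
        mean_2 = tt$mean_y, sd_2 = tt$sd_y,
        t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "groups") <- groups
  out
}

#' Mixed RM-ANOVA tables for ERP component measures
#'
#' Reproduces the ERP statistical design: for the cue- and go-locked P3, a
#' group x trial-condition x electrode ANOVA; for the stop-locked N2 and
#' P3, a group x stop-direction x electrode ANOVA within each condition.
#' Run separately for amplitude and latency.
#'
#' @param measures tidy measures with columns `subject`, `group`,
#'   `component`, `condition`, `direction`, `electrode`, `amplitude_uv`,
#'   `latency_ms`.
#' @param dv `"amplitude_uv"` or `"latency_ms"`.
#' @param gg Greenhouse-Geisser correction switch.
#' @return named list of `anova_result` tables.
#' @export
erp_group_stats <- function(measures, dv = "amplitude_uv", gg = FALSE) {
  out <- list()
  try_table <- function(name, d, within) {
    res <- tryCatch(
      mixed_rm_anova(d, dv = dv, subject = "subject", between = "group",
                     within = within, gg = gg),
      error = function(e) {
        warning("skipping ANOVA for ", name, ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) out[[name]] <<- res
  }
  for (comp in c("P3cue", "P3go")) {
    d <- measures[measures$component == comp, ]
    if (nrow(d)) try_table(comp, d, c("condition", "electrode"))
  }
  for (comp in c("N2stop", "P3stop")) {
    for (cond in unique(measures$condition)) {
      d <- measures[measures$component == comp &
                      measures$condition == cond, ]
      if (nrow(d)) try_table(paste(comp, cond, sep = "_"), d,
                             c("direction", "electrode"))
    }
  }
  out
}

#' Run the full simulation-and-analysis pipeline
#'
#' Simulates the study, scores behaviour per subject, measures ERP
#' components when EEG is enabled, runs the group statistics, and writes
#' per-stage artifacts (CSV/JSON) plus a run log carrying the seed and a
#' configuration hash for provenance. Deterministic: identical
#' configuration and seed give byte-identical numeric outputs.
#'
#' @param config a [study_config()].
#' @param out_dir writable output directory (created if absent).
#' @return list of class `study_report`: `behavior_metrics`,
#'   `behavior_stats`, `erp_measures`, `erp_stats`, `seed`, `config_hash`.
#' @export
run_pipeline <- function(config = study_config(), out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg_hash <- config_hash(config)
  log_path <- file.path(out_dir, "run_log.txt")
  logline <- function(...) cat(..., "\n", sep = "", file = log_path,
                               append = TRUE)
  cat("", file = log_path)
  logline("selstopsig pipeline, seed=", config$seed, ", config=", cfg_hash)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed [config ", cfg_hash, "]: ",
           conditionMessage(e), call. = FALSE))
  }
  study <- stage("simulate", simulate_study(
    n_per_group = config$n_per_group, group_effects = config$group_effects,
    seed = config$seed, include_eeg = config$include_eeg,
    design = config$design))
  logline("simulated ", length(study$sessions), " sessions")

  metrics <- stage("behavior", {
    rows <- lapply(seq_along(study$sessions), function(i) {
      ses <- study$sessions[[i]]
      cls <- classify_trials(ses$behavior, ses$schedule)
      m <- behavior_metrics(cls)
      m$subject <- study$subjects$subject[i]
      m$group <- study$subjects$group[i]
      m
    })
    do.call(rbind, rows)
  })
  write_provenanced_csv(metrics, file.path(out_dir, "behavior_metrics.csv"),
                        config$seed, cfg_hash)
  beh_stats <- stage("behavior_stats",
                     behavior_group_stats(metrics, welch = config$welch))
  write_provenanced_csv(beh_stats, file.path(out_dir, "behavior_stats.csv"),
                        config$seed, cfg_hash)

  erp_measures <- NULL
  erp_stats <- NULL
  if (config$include_eeg) {
    erp_measures <- stage("erp", {
      rows <- lapply(seq_along(study$sessions), function(i) {
        m <- measure_session(study$sessions[[i]],
                             reject_uv = config$reject_uv)
        m$subject <- study$subjects$subject[i]
        m$group <- study$subjects$group[i]
        m
      })
      do.call(rbind, rows)
    })
    write_provenanced_csv(erp_measures,
                          file.path(out_dir, "erp_measures.csv"),
                          config$seed, cfg_hash)
    erp_stats <- stage("erp_stats",
                       erp_group_stats(erp_measures, gg = config$gg))
    jsonlite::write_json(erp_stats, file.path(out_dir, "erp_stats.json"),
                         dataframe = "rows", digits = NA)
  }
  logline("done")
  structure(list(behavior_metrics = metrics, behavior_stats = beh_stats,
                 erp_measures = erp_measures, erp_stats = erp_stats,
                 seed = config$seed, config_hash = cfg_hash),
            class = "study_report")
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA)
  # small polynomial rolling hash over the serialized config (provenance
  # fingerprint, not cryptographic)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

write_provenanced_csv <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config=%s", seed, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a provenanced CSV written by the pipeline
#'
#' @param path file path.
#' @return data frame (the provenance comment line is skipped).
#' @export
read_provenanced_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
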