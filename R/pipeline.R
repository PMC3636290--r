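#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: the design, per-arm
#' behavioral parameters, the kappa chance model, the testing levels and an
#' optional coded-acts input for the thematic stage.
#'
#' @param seed integer root seed for the run.
#' @param design design list from [study_design()].
#' @param params_hc,params_ic behavioral parameters per arm; defaults are
#'   [default_behavior_params()] for both.
#' @param chance_model kappa chance model, see [group_agreement()].
#' @param alpha family-wise alpha in (0, 1].
#' @param m_outcomes outcomes per scenario for the Bonferroni adjustment.
#' @param coded_acts optional path to a coded dialogue-act CSV.
#' @param theme_scheme coding scheme for the thematic stage.
#' @return Validated configuration list of class `consensim_config`.
#' @export
run_config <- function(seed = 1L, design = study_design(),
                       params_hc = default_behavior_params(design$scenarios),
                       params_ic = default_behavior_params(design$scenarios),
                       chance_model = "free_marginal", alpha = 0.05,
                       m_outcomes = 2L, coded_acts = NULL,
                       theme_scheme = default_theme_scheme()) {
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 1) {
    cs_error("alpha must be in (0, 1]", "consensim_validation_error")
  }
  if (!is_scalar_number(m_outcomes) || m_outcomes < 1) {
    cs_error("m_outcomes must be >= 1", "consensim_validation_error")
  }
  structure(list(seed = seed, design = design, params_hc = params_hc,
                 params_ic = params_ic, chance_model = chance_model,
                 alpha = alpha, m_outcomes = m_outcomes,
                 coded_acts = coded_acts, theme_scheme = theme_scheme),
            class = "consensim_config")
}

#' Default thematic coding scheme
#'
#' A reconstruction of the argument categories used to code the informal
#' groups' discussions (the published material names only some of them);
#' flagged as synthetic where it is one.
#'
#' @return Character vector of theme codes.
#' @export
default_theme_scheme <- function() {
  c("clinical_judgment", "pro_evidence", "contra_evidence", "uncertainty",
    "own_experience", "other_guidelines", "procedural", "other")
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[consensim] ", fmt), ...))
}

#' Run the full simulate - score - analyze - report pipeline
#'
#' Simulates the trial, computes the outcome series, runs the inferential
#' layer, and assembles the report bundle: a baseline table (round-1 mean
#' and 95% CI per arm, scenario and outcome), round-wise trajectory tables,
#' the effect-size/test table, an optional thematic tally, and run
#' metadata. All intermediates are persisted to `out_dir` (when given) so
#' every reported number can be recomputed from the written score table.
#'
#' @param config configuration from [run_config()].
#' @param out_dir output directory for the persisted tables (created if
#'   needed); NULL keeps everything in memory.
#' @param verbose log stage progress and record counts to standard error.
#' @return List of class `consensim_report`: `baseline`, `trajectories`,
#'   `effects`, `thematic` (or NULL), `scores`, `trial`, `meta`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "consensim_config"))
  t0 <- Sys.time()
  trial <- simulate_trial(config$design, config$params_hc, config$params_ic,
                          seed = config$seed)
  log_stage(verbose, "simulate: %d answer records, %d groups",
            nrow(trial$answers), length(unique(trial$groups$group_id)))
  report <- validate_trial(trial$answers, config$design$scenarios,
                           trial$groups, config$design$group_size)
  if (nrow(report)) {
    cs_error(sprintf("simulate stage produced an inconsistent trial (%d findings)",
                     nrow(report)), "consensim_internal_error")
  }
  scores <- compute_outcome_series(trial$answers, config$design$scenarios,
                                   config$chance_model)
  log_stage(verbose, "score: %d group x scenario x round cells", nrow(scores))
  effects <- analyze_outcomes(scores, config$alpha, config$m_outcomes)
  log_stage(verbose, "analyze: %d scenario x outcome rows", nrow(effects))

  baseline <- summarize_round(scores, round = 1L)
  trajectories <- trajectory_table(scores)

  thematic <- NULL
  if (!is.null(config$coded_acts)) {
    acts <- read_coded_acts(config$coded_acts, config$theme_scheme)
    thematic <- tally_themes(acts, config$theme_scheme)
    log_stage(verbose, "thematic: %d acts tallied", attr(thematic, "total"))
  }

  meta <- list(seed = config$seed,
               package_version = as.character(utils::packageVersion("consensim")),
               chance_model = config$chance_model, alpha = config$alpha,
               m_outcomes = config$m_outcomes,
               alpha_adjusted = bonferroni_alpha(config$alpha,
                                                config$m_outcomes),
               n_hc_groups = sum(table(unique(trial$groups[,
                 c("group_id", "arm")])$arm)["HC"]),
               n_ic_groups = sum(table(unique(trial$groups[,
                 c("group_id", "arm")])$arm)["IC"]),
               n_unassigned = length(trial$unassigned),
               elapsed_seconds = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))

  bundle <- structure(list(baseline = baseline, trajectories = trajectories,
                           effects = effects, thematic = thematic,
                           scores = scores, trial = trial, meta = meta),
                      class = "consensim_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_answers(trial$answers, file.path(out_dir, "answers.csv"))
    utils::write.csv(trial$groups, file.path(out_dir, "groups.csv"),
                     row.names = FALSE)
    utils::write.csv(trial$transcripts, file.path(out_dir, "transcripts.csv"),
                     row.names = FALSE)
    utils::write.csv(trial$rankings, file.path(out_dir, "rankings.csv"),
                     row.names = FALSE)
    utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    utils::write.csv(effects, file.path(out_dir, "effects.csv"),
                     row.names = FALSE)
    utils::write.csv(baseline, file.path(out_dir, "baseline.csv"),
                     row.names = FALSE)
    utils::write.csv(trajectories, file.path(out_dir, "trajectories.csv"),
                     row.names = FALSE)
    if (!is.null(thematic)) {
      utils::write.csv(thematic, file.path(out_dir, "thematic.csv"),
                       row.names = FALSE)
    }
    meta_out <- meta
    meta_out$elapsed_seconds <- NULL  # keep reruns byte-identical
    jsonlite::write_json(meta_out, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    log_stage(verbose, "report: bundle written to %s", out_dir)
  }
  bundle
}

# per arm x scenario x outcome mean and 95% CI at one round
summarize_round <- function(scores, round = 1L) {
  sub <- scores[scores$round == round, ]
  rows <- list()
  for (arm in unique(sub$arm)) {
    for (sid in unique(sub$scenario_id)) {
      cell <- sub[sub$arm == arm & sub$scenario_id == sid, ]
      for (outcome in c("evidence_score", "kappa")) {
        v <- cell[[outcome]]
        if (all(is.na(v)) || length(v) < 2L) next
        ci <- mean_ci95(v)
        rows[[length(rows) + 1L]] <- data.frame(
          arm = arm, scenario_id = sid, outcome = outcome, round = round,
          n_groups = length(v), mean = ci[["mean"]], ci_lower = ci[["lower"]],
          ci_upper = ci[["upper"]], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per arm x scenario x round mean outcomes (the figures' plotted quantity)
trajectory_table <- function(scores) {
  rows <- list()
  for (arm in unique(scores$arm)) {
    for (sid in unique(scores$scenario_id)) {
      for (r in sort(unique(scores$round))) {
        cell <- scores[scores$arm == arm & scores$scenario_id == sid &
                         scores$round == r, ]
        rows[[length(rows) + 1L]] <- data.frame(
          arm = arm, scenario_id = sid, round = r, n_groups = nrow(cell),
          mean_evidence_score = if (all(is.na(cell$evidence_score)))
            NA_real_ else mean(cell$evidence_score),
          mean_kappa = mean(cell$kappa), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# fast per-group evidence scores straight off an answer table (no kappa);
# used by the replicated power loop
group_evidence_table <- function(answers, scenarios) {
  has_ev <- scenario_has_evidence(scenarios)
  ev_sids <- names(has_ev)[has_ev]
  sub <- answers[answers$scenario_id %in% ev_sids, ]
  pt_key <- paste(scenarios$scenario_id, scenarios$option_id)
  pts <- scenarios$points[match(paste(sub$scenario_id, sub$option_id), pt_key)]
  maxpts <- vapply(ev_sids, function(s)
    max(scenarios$points[scenarios$scenario_id == s]), numeric(1L))
  key <- paste(sub$group_id, sub$arm, sub$scenario_id, sub$round, sep = "\r")
  sums <- rowsum(pts, key)
  ns <- rowsum(rep(1L, nrow(sub)), key)
  parts <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
  out <- data.frame(group_id = parts[, 1L], arm = parts[, 2L],
                    scenario_id = parts[, 3L],
                    round = as.integer(parts[, 4L]),
                    evidence_score = as.numeric(sums) /
                      (as.numeric(ns) * maxpts[parts[, 3L]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Monte-Carlo power / calibration comparison of the two protocols
#'
#' Replicates the whole pipeline over a grid of behavioral conditions and
#' reports, per grid cell, the fraction of between-arm Mann-Whitney tests
#' on the evidence-score change (round 3 minus round 1, one test per
#' evidence-bearing scenario) that reject at the Bonferroni-adjusted level,
#' with a binomial Monte-Carlo standard error. With equal parameters across
#' arms this measures the pipeline's type-I error; with `eps_hc > eps_ic`
#' it traces a power curve the original proof-of-concept trial lacked.
#'
#' @param grid data frame with columns `eps_hc`, `eps_ic`, `gamma`.
#' @param n_replicates replicate trials per grid cell.
#' @param design design list from [study_design()].
#' @param alpha,m_outcomes testing levels (rejection at `alpha / m_outcomes`).
#' @param seed integer root seed; each replicate draws from its own derived
#'   stream.
#' @return Data frame: the grid plus `n_tests`, `rejections`, `reject_rate`,
#'   `mc_se` (NA when `n_replicates` is 1).
#' @export
compare_protocols <- function(grid, n_replicates = 100L,
                              design = study_design(), alpha = 0.05,
                              m_outcomes = 2L, seed = 1L) {
  if (n_replicates < 1L) {
    cs_error("n_replicates must be >= 1", "consensim_validation_error")
  }
  a_adj <- bonferroni_alpha(alpha, m_outcomes)
  scen <- design$scenarios
  ev_sids <- names(which(scenario_has_evidence(scen)))
  out <- grid
  out$n_tests <- 0L; out$rejections <- 0L
  out$reject_rate <- NA_real_; out$mc_se <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p_hc <- default_behavior_params(scen, epsilon = grid$eps_hc[i],
                                    gamma = grid$gamma[i])
    p_ic <- default_behavior_params(scen, epsilon = grid$eps_ic[i],
                                    gamma = grid$gamma[i])
    rej <- 0L; n_tests <- 0L
    for (r in seq_len(n_replicates)) {
      rseed <- derive_seed(seed, sprintf("cell%d_rep%d", i, r))
      trial <- simulate_trial(design, p_hc, p_ic, seed = rseed)
      ev <- group_evidence_table(trial$answers, scen)
      for (sid in ev_sids) {
        sub <- ev[ev$scenario_id == sid, ]
        wide <- merge(sub[sub$round == 1L, c("group_id", "arm", "evidence_score")],
                      sub[sub$round == 3L, c("group_id", "evidence_score")],
                      by = "group_id", suffixes = c("_r1", "_r3"))
        chg <- wide$evidence_score_r3 - wide$evidence_score_r1
        hc <- wide$arm == "HC"
        p <- mann_whitney_u_exact(chg[hc], chg[!hc])$p.value
        n_tests <- n_tests + 1L
        if (p <= a_adj) rej <- rej + 1L
      }
    }
    out$n_tests[i] <- n_tests
    out$rejections[i] <- rej
    out$reject_rate[i] <- rej / n_tests
    out$mc_se[i] <- if (n_replicates > 1L) {
      sqrt(out$reject_rate[i] * (1 - out$reject_rate[i]) / n_tests)
    } else NA_real_
  }
  out
}
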