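#' Behavioral parameters of the opinion-dynamics model
#'
#' The simulator models each participant's choice as a categorical draw.
#' `baseline` gives the pre-discussion propensity weights per scenario;
#' once the evidence is revealed, propensities are tilted multiplicatively
#' by `exp(epsilon * points)` (a softmax pull toward better-evidenced
#' options, with no effect on evidence-free scenarios whose points are all
#' zero); `gamma` is the probability of a conforming move — toward the
#' partner's answer at a team's second attempt, toward the group's modal
#' round-2 answer at round 3. Response times are log-normal; a team's
#' elapsed time per scenario is the sum of its members' per-attempt draws,
#' compared against `time_limit`.
#'
#' @param baseline named list, one element per scenario_id: a named
#'   non-negative weight vector over that scenario's option_ids with at
#'   least one positive entry.
#' @param epsilon evidence-attraction strength, >= 0.
#' @param gamma conformity probability in `[0, 1]`.
#' @param rt_meanlog,rt_sdlog log-normal response-time parameters
#'   (seconds scale).
#' @param time_limit per-scenario team time limit in seconds.
#' @return A validated parameter list of class `consensim_params`.
#' @seealso [default_behavior_params()] for the study-condition defaults.
#' @export
behavior_params <- function(baseline, epsilon = 1, gamma = 0.4,
                            rt_meanlog = log(20), rt_sdlog = 0.5,
                            time_limit = 120) {
  if (!is.list(baseline) || is.null(names(baseline))) {
    cs_error("baseline must be a named list of weight vectors",
             "consensim_validation_error")
  }
  for (sid in names(baseline)) {
    w <- baseline[[sid]]
    if (is.null(names(w)) || any(w < 0) || !any(w > 0)) {
      cs_error(sprintf(
        "baseline['%s'] must be named, non-negative, with a positive entry",
        sid), "consensim_validation_error")
    }
  }
  if (!is_scalar_number(epsilon) || epsilon < 0) {
    cs_error("epsilon must be >= 0", "consensim_validation_error")
  }
  if (!is_scalar_number(gamma) || gamma < 0 || gamma > 1) {
    cs_error("gamma must be in [0, 1]", "consensim_validation_error")
  }
  if (!is_scalar_number(time_limit) || time_limit <= 0) {
    cs_error("time_limit must be positive", "consensim_validation_error")
  }
  structure(list(baseline = baseline, epsilon = epsilon, gamma = gamma,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 time_limit = time_limit),
            class = "consensim_params")
}

# baseline propensities emulating the trial's round-1 behavior on the
# bundled lower-back-pain scenarios: a mildly contra-evidence imaging habit,
# a strongly evidence-concordant therapy preference, a mixed drug profile,
# and a moderate sick-leave consensus
.default_weights <- list(
  imaging = c(no_routine_imaging = 0.27, plain_xray = 0.29, mri_scan = 0.19,
              ct_scan = 0.15, bone_scan = 0.10),
  therapy = c(stay_active = 0.55, exercise_therapy = 0.25,
              spinal_manipulation = 0.10, bed_rest = 0.10),
  drugs = c(paracetamol = 0.30, nsaid = 0.28, muscle_relaxant = 0.12,
            weak_opioid = 0.18, antidepressant = 0.12),
  sick_leave = c(no_sick_leave = 0.15, few_days = 0.60, one_week = 0.17,
                 until_painfree = 0.08))

#' Default behavioral parameters for a scenario set
#'
#' Returns [behavior_params()] with the package's calibrated baseline
#' propensities for the bundled lower-back-pain scenarios, and uniform
#' propensities for any other scenario in the set.
#'
#' @param scenarios scenario table.
#' @param ... overrides passed on to [behavior_params()]
#'   (`epsilon`, `gamma`, ...).
#' @export
default_behavior_params <- function(scenarios, ...) {
  baseline <- list()
  for (sid in unique(scenarios$scenario_id)) {
    opts <- scenarios$option_id[scenarios$scenario_id == sid]
    w <- .default_weights[[sid]]
    if (is.null(w) || !setequal(names(w), opts)) {
      w <- stats::setNames(rep(1 / length(opts), length(opts)), opts)
    }
    baseline[[sid]] <- w[opts]
  }
  behavior_params(baseline = baseline, ...)
}

# per-scenario lookup tables used in the inner simulation loops
prep_scenario <- function(scenarios, params, scenario_id) {
  opts <- scenario_options(scenarios, scenario_id)
  w <- params$baseline[[scenario_id]]
  if (is.null(w)) {
    cs_error(sprintf("no baseline propensity for scenario '%s'", scenario_id),
             "consensim_validation_error")
  }
  missing_opts <- setdiff(opts$option_id, names(w))
  if (length(missing_opts)) {
    cs_error(sprintf("baseline['%s'] missing option(s): %s", scenario_id,
                     paste(missing_opts, collapse = ", ")),
             "consensim_validation_error")
  }
  w0 <- w[opts$option_id] / sum(w[opts$option_id])
  tilt <- w0 * exp(params$epsilon * opts$points)
  list(ids = opts$option_id, points = opts$points,
       index = opts$option_index, w0 = as.numeric(w0),
       w_eps = as.numeric(tilt / sum(tilt)))
}

# between two (possibly equal) answers: higher evidence points, then lower
# declared option index
canonical_choice <- function(prep, a, b) {
  if (a == b) return(a)
  ia <- match(a, prep$ids); ib <- match(b, prep$ids)
  if (prep$points[ia] != prep$points[ib]) {
    return(if (prep$points[ia] > prep$points[ib]) a else b)
  }
  if (prep$index[ia] <= prep$index[ib]) a else b
}

# modal answer; ties broken by lower declared option index
modal_choice <- function(prep, answers) {
  counts <- table(factor(answers, levels = prep$ids))
  winners <- which(counts == max(counts))
  prep$ids[min(winners)]
}

#' Randomize participants to arms, groups and teams
#'
#' Simple randomization to the HC (human computation) and IC (informal
#' consensus) arms followed by assignment to consensus groups of
#' `group_size` and — via the trial's envelope procedure — to within-group
#' teams of 2. By default the realized arm totals are forced (the study's
#' realized 64/56 split); `arm_counts = NULL` instead performs true 1:1
#' per-participant randomization. Participants left over after forming
#' full groups become unassigned observers.
#'
#' @param n_participants total number of participants.
#' @param group_size participants per group (default 8; must be even when
#'   `pair_teams` is TRUE).
#' @param arm_counts named vector `c(HC = ..., IC = ...)` of forced arm
#'   totals, or NULL for true simple randomization.
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @param pair_teams assign envelope-pair teams within every group
#'   (default TRUE; both arms pair for the round-2 discussion step).
#' @return Data frame with columns `participant_id`, `group_id`, `arm`,
#'   `team_id`; unassigned participant ids in the `unassigned` attribute.
#' @examples
#' g <- randomize_participants(120, arm_counts = c(HC = 64, IC = 56), seed = 1)
#' table(unique(g[, c("group_id", "arm")])$arm)  # 8 HC, 7 IC groups
#' @export
randomize_participants <- function(n_participants, group_size = 8L,
                                   arm_counts = c(HC = 64L, IC = 56L),
                                   seed = 1L, pair_teams = TRUE) {
  if (n_participants < group_size) {
    cs_error("need at least one group's worth of participants",
             "consensim_validation_error")
  }
  if (pair_teams && group_size %% 2L != 0L) {
    cs_error("group_size must be even to pair teams of 2",
             "consensim_validation_error")
  }
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(n_participants))
  shuffled <- sample(ids)
  if (is.null(arm_counts)) {
    coin <- stats::runif(n_participants) < 0.5
    pools <- list(HC = shuffled[coin], IC = shuffled[!coin])
  } else {
    if (!all(c("HC", "IC") %in% names(arm_counts))) {
      cs_error("arm_counts needs named entries HC and IC",
               "consensim_validation_error")
    }
    if (sum(arm_counts) > n_participants) {
      cs_error("arm_counts exceed n_participants", "consensim_validation_error")
    }
    pools <- list(HC = shuffled[seq_len(arm_counts[["HC"]])],
                  IC = shuffled[arm_counts[["HC"]] + seq_len(arm_counts[["IC"]])])
  }
  rows <- list()
  unassigned <- setdiff(shuffled, unlist(pools))
  for (arm in c("HC", "IC")) {
    pool <- pools[[arm]]
    n_groups <- length(pool) %/% group_size
    if (n_groups * group_size < length(pool)) {
      unassigned <- c(unassigned, pool[(n_groups * group_size + 1L):length(pool)])
    }
    for (g in seq_len(n_groups)) {
      members <- pool[(g - 1L) * group_size + seq_len(group_size)]
      gid <- sprintf("%s%d", arm, g)
      team <- if (pair_teams) {
        sprintf("%s_t%d", gid, rep(seq_len(group_size / 2L), each = 2L))
      } else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = members, group_id = gid, arm = arm, team_id = team,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "unassigned") <- sort(unassigned)
  out
}

#' Simulate one HC team answering one scenario
#'
#' Both teammates first answer independently from the baseline propensity
#' (their round-1 answers). If they disagree, the evidence and the
#' teammate's answer are revealed and each gets one chance to change: with
#' probability `gamma` a participant conforms to the pair's canonical
#' answer (the better-evidenced of the two, then the lower-indexed),
#' otherwise re-draws from the evidence-tilted propensity. The transcript
#' records both attempts, consensus flags, the summed response-time draws
#' and whether the time limit was exceeded; the final attempt's answers are
#' the round-2 answers.
#'
#' @param team character vector of the 2 teammates' participant ids.
#' @param scenarios scenario table.
#' @param scenario_id scenario being answered.
#' @param params [behavior_params()] object.
#' @return List with `transcript` (one-row data frame) and `answers`
#'   (data frame of the two participants' round-1 and round-2 choices).
#'   Consumes the R RNG stream; seed via [set.seed()] for reproducibility.
#' @export
simulate_hc_scenario <- function(team, scenarios, scenario_id, params) {
  if (length(team) != 2L) {
    cs_error("a team has exactly 2 participants", "consensim_validation_error")
  }
  prep <- prep_scenario(scenarios, params, scenario_id)
  sim_team_scenario(team, prep, params, team_id = paste(team, collapse = "+"),
                    scenario_id = scenario_id)
}

# inner team-scenario simulation working on prepped lookup tables
sim_team_scenario <- function(team, prep, params, team_id, scenario_id) {
  a1 <- prep$ids[sample.int(length(prep$ids), 2L, replace = TRUE,
                            prob = prep$w0)]
  elapsed <- sum(stats::rlnorm(2L, params$rt_meanlog, params$rt_sdlog))
  cons1 <- a1[1L] == a1[2L]
  if (cons1) {
    a2 <- c(NA_character_, NA_character_)
    cons_final <- TRUE
    final <- a1
  } else {
    canon <- canonical_choice(prep, a1[1L], a1[2L])
    a2 <- character(2L)
    for (i in 1:2) {
      a2[i] <- if (stats::runif(1L) < params$gamma) canon else
        prep$ids[sample.int(length(prep$ids), 1L, prob = prep$w_eps)]
    }
    elapsed <- elapsed + sum(stats::rlnorm(2L, params$rt_meanlog,
                                           params$rt_sdlog))
    cons_final <- a2[1L] == a2[2L]
    final <- a2
  }
  transcript <- data.frame(
    team_id = team_id, scenario_id = scenario_id,
    participant_1 = team[1L], participant_2 = team[2L],
    attempt1_1 = a1[1L], attempt1_2 = a1[2L],
    consensus_after_attempt1 = cons1,
    attempt2_1 = a2[1L], attempt2_2 = a2[2L],
    consensus_final = cons_final, elapsed_seconds = elapsed,
    limit_exceeded = elapsed > params$time_limit,
    stringsAsFactors = FALSE)
  answers <- data.frame(
    participant_id = rep(team, 2L),
    scenario_id = scenario_id,
    round = rep(1:2, each = 2L),
    option_id = c(a1, final),
    stringsAsFactors = FALSE)
  list(transcript = transcript, answers = answers)
}

# a post-feedback individual re-rating round: conform to the group's modal
# previous answer with probability gamma, otherwise redraw under the
# evidence tilt
sim_reflection_round <- function(prev_answers, prep, params) {
  mode_opt <- modal_choice(prep, prev_answers)
  n <- length(prev_answers)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (stats::runif(1L) < params$gamma) mode_opt else
      prep$ids[sample.int(length(prep$ids), 1L, prob = prep$w_eps)]
  }
  out
}

#' Simulate an IC group's three rating rounds for one scenario
#'
#' Round 1: independent baseline draws. Round 2: after the evidence is
#' handed out and the envelope pairs discuss, each participant conforms to
#' their pair's canonical answer with probability `gamma`, otherwise
#' re-draws from the evidence-tilted propensity. Round 3: after the
#' moderated full-group meeting, conformity pulls toward the group's modal
#' round-2 answer (ties to the lower-indexed option), again with an
#' evidence-tilted re-draw otherwise.
#'
#' @param group data frame of the group's members with `participant_id`
#'   and `team_id` columns (8 rows).
#' @param scenarios scenario table.
#' @param scenario_id scenario being answered.
#' @param params [behavior_params()] object.
#' @return Data frame of answer records (`participant_id`, `scenario_id`,
#'   `round`, `option_id`) for rounds 1-3. Consumes the R RNG stream.
#' @export
simulate_ic_rounds <- function(group, scenarios, scenario_id, params) {
  prep <- prep_scenario(scenarios, params, scenario_id)
  sim_ic_scenario(group, prep, params, scenario_id)
}

sim_ic_scenario <- function(group, prep, params, scenario_id) {
  n <- nrow(group)
  r1 <- prep$ids[sample.int(length(prep$ids), n, replace = TRUE,
                            prob = prep$w0)]
  # partner lookup within envelope pairs
  partner <- vapply(seq_len(n), function(i) {
    same <- which(group$team_id == group$team_id[i])
    setdiff(same, i)[1L]
  }, integer(1L))
  r2 <- character(n)
  for (i in seq_len(n)) {
    r2[i] <- if (stats::runif(1L) < params$gamma) {
      canonical_choice(prep, r1[i], r1[partner[i]])
    } else {
      prep$ids[sample.int(length(prep$ids), 1L, prob = prep$w_eps)]
    }
  }
  r3 <- sim_reflection_round(r2, prep, params)
  data.frame(participant_id = rep(group$participant_id, 3L),
             scenario_id = scenario_id,
             round = rep(1:3, each = n),
             option_id = c(r1, r2, r3),
             stringsAsFactors = FALSE)
}

#' Rank the teams of an HC group
#'
#' The game's competition element: teams are ordered by consensus count
#' (descending), then times the limit was exceeded (ascending), then total
#' elapsed time (ascending), with exact ties broken by team id.
#'
#' @param transcripts transcript rows of one group's teams, one row per
#'   team x scenario (as produced by [simulate_hc_scenario()]).
#' @return Data frame ordered by rank with columns `rank`, `team_id`,
#'   `consensus_count`, `exceed_count`, `total_time`.
#' @export
rank_teams <- function(transcripts) {
  teams <- unique(transcripts$team_id)
  per_team <- table(transcripts$team_id)
  scen <- unique(transcripts$scenario_id)
  if (any(per_team != length(scen))) {
    cs_error("every team needs a transcript for every scenario",
             "consensim_validation_error")
  }
  agg <- do.call(rbind, lapply(teams, function(tid) {
    rows <- transcripts[transcripts$team_id == tid, ]
    data.frame(team_id = tid,
               consensus_count = sum(rows$consensus_final),
               exceed_count = sum(rows$limit_exceeded),
               total_time = sum(rows$elapsed_seconds),
               stringsAsFactors = FALSE)
  }))
  ord <- order(-agg$consensus_count, agg$exceed_count, agg$total_time,
               agg$team_id)
  agg <- agg[ord, ]
  agg <- cbind(rank = seq_len(nrow(agg)), agg)
  rownames(agg) <- NULL
  agg
}

# one HC group: 4 teams play all scenarios, ranking is computed, and only
# then does the individual third round happen (the game's competition
# element must not touch the final answers)
sim_hc_group <- function(group, preps, params) {
  transcripts <- list(); answers <- list()
  teams <- unique(group$team_id)
  for (tid in teams) {
    members <- group$participant_id[group$team_id == tid]
    for (sid in names(preps)) {
      res <- sim_team_scenario(members, preps[[sid]], params, tid, sid)
      transcripts[[length(transcripts) + 1L]] <- res$transcript
      answers[[length(answers) + 1L]] <- res$answers
    }
  }
  transcripts <- do.call(rbind, transcripts)
  answers <- do.call(rbind, answers)
  ranking <- rank_teams(transcripts)
  r3 <- list()
  for (sid in names(preps)) {
    sub <- answers[answers$scenario_id == sid & answers$round == 2L, ]
    sub <- sub[match(group$participant_id, sub$participant_id), ]
    r3[[length(r3) + 1L]] <- data.frame(
      participant_id = group$participant_id, scenario_id = sid, round = 3L,
      option_id = sim_reflection_round(sub$option_id, preps[[sid]], params),
      stringsAsFactors = FALSE)
  }
  list(transcripts = transcripts, ranking = ranking,
       answers = rbind(answers, do.call(rbind, r3)))
}

#' Study-shaped design specification
#'
#' The trial's realized design: 120 participants, forced arm totals of 64
#' (HC) and 56 (IC), groups of 8, and the bundled four lower-back-pain
#' scenarios unless another set is given.
#'
#' @param scenarios scenario table; default loads the bundled set.
#' @param n_participants,group_size,arm_counts design numbers; see
#'   [randomize_participants()].
#' @return Design list consumed by [simulate_trial()].
#' @export
study_design <- function(scenarios = NULL, n_participants = 120L,
                         group_size = 8L, arm_counts = c(HC = 64L, IC = 56L)) {
  if (is.null(scenarios)) {
    scenarios <- read_scenarios(system.file("extdata", "scenarios_lbp.yaml",
                                            package = "consensim"))
  }
  list(scenarios = scenarios, n_participants = n_participants,
       group_size = group_size, arm_counts = arm_counts)
}

#' Simulate the full randomized trial
#'
#' Randomizes participants, then simulates every HC group's game (team
#' attempts, evidence reveal, ranking, post-ranking individual round 3) and
#' every IC group's three-round meeting protocol. Each group draws from its
#' own RNG stream derived by stable hashing of the group id from the root
#' seed, so changing the number of groups does not reshuffle the others;
#' the whole output is reproducible given the seed.
#'
#' @param design design list from [study_design()].
#' @param params_hc behavioral parameters for the HC arm.
#' @param params_ic behavioral parameters for the IC arm; defaults to
#'   `params_hc` (equal-arm null).
#' @param seed integer root seed.
#' @return List of class `consensim_trial` with elements `answers` (full
#'   long answer table), `groups`, `transcripts` (HC teams), `rankings`
#'   (per HC group), `unassigned`, `seed`.
#' @examples
#' \donttest{
#' design <- study_design()
#' trial <- simulate_trial(design, default_behavior_params(design$scenarios),
#'                         seed = 42)
#' nrow(trial$answers)  # 120 * 4 * 3 = 1440
#' }
#' @export
simulate_trial <- function(design, params_hc, params_ic = params_hc,
                           seed = 1L) {
  groups <- randomize_participants(design$n_participants, design$group_size,
                                   design$arm_counts, seed = seed)
  sids <- unique(design$scenarios$scenario_id)
  preps <- list(
    HC = stats::setNames(lapply(sids, function(s)
      prep_scenario(design$scenarios, params_hc, s)), sids),
    IC = stats::setNames(lapply(sids, function(s)
      prep_scenario(design$scenarios, params_ic, s)), sids))
  answers <- list(); transcripts <- list(); rankings <- list()
  for (gid in unique(groups$group_id)) {
    members <- groups[groups$group_id == gid, ]
    arm <- members$arm[1L]
    params <- if (arm == "HC") params_hc else params_ic
    set.seed(derive_seed(seed, gid))
    if (arm == "HC") {
      res <- sim_hc_group(members, preps$HC, params)
      res$transcripts$group_id <- gid
      res$ranking$group_id <- gid
      transcripts[[length(transcripts) + 1L]] <- res$transcripts
      rankings[[length(rankings) + 1L]] <- res$ranking
      ans <- res$answers
    } else {
      ans <- do.call(rbind, lapply(sids, function(s)
        sim_ic_scenario(members, preps$IC[[s]], params, s)))
    }
    ans$group_id <- gid
    ans$arm <- arm
    answers[[length(answers) + 1L]] <- ans
  }
  answers <- do.call(rbind, answers)
  cols <- c("participant_id", "group_id", "arm", "scenario_id", "round",
            "option_id")
  answers <- answers[order(answers$group_id, answers$participant_id,
                           answers$scenario_id, answers$round), cols]
  rownames(answers) <- NULL
  structure(list(answers = answers, groups = groups,
                 transcripts = do.call(rbind, transcripts),
                 rankings = do.call(rbind, rankings),
                 unassigned = attr(groups, "unassigned"), seed = seed),
            class = "consensim_trial")
}
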