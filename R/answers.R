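#' Read an answer table
#'
#' Answer tables are the trial's long-format data: one row per participant,
#' scenario and round, with the chosen option. Columns (exactly):
#' `participant_id,group_id,arm,scenario_id,round,option_id`; UTF-8 CSV with
#' a header row; `round` an integer in 1..3. Referential integrity against
#' the scenario set (and, when given, the group table) is checked on load;
#' structural completeness is the job of [validate_trial()].
#'
#' @param path path to the CSV file.
#' @param scenarios a `consensim_scenarios` table to validate against.
#' @param groups optional group table (as from [randomize_participants()])
#'   to validate group membership and arms against.
#' @return Data frame of answer records.
#' @export
read_answers <- function(path, scenarios, groups = NULL) {
  if (!file.exists(path)) {
    cs_error(sprintf("answer file not found: %s", path),
             "consensim_format_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  validate_answer_records(df, scenarios, groups)
}

#' @rdname read_answers
#' @param answers an answer table to write.
#' @export
write_answers <- function(answers, path) {
  cols <- c("participant_id", "group_id", "arm", "scenario_id", "round",
            "option_id")
  utils::write.csv(answers[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# shared referential checks for in-memory or freshly read records
validate_answer_records <- function(df, scenarios, groups = NULL) {
  required <- c("participant_id", "group_id", "arm", "scenario_id", "round",
                "option_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    cs_error(paste("answer table missing column(s):",
                   paste(missing_cols, collapse = ", ")),
             "consensim_format_error")
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$round <- suppressWarnings(as.integer(df$round))
  bad_round <- which(is.na(df$round) | !(df$round %in% 1:3))
  if (length(bad_round)) {
    cs_error(sprintf("round must be an integer in 1..3; offending row(s): %s",
                     paste(utils::head(bad_round, 10L), collapse = ", ")),
             "consensim_validation_error")
  }
  bad_arm <- which(!(df$arm %in% c("HC", "IC")))
  if (length(bad_arm)) {
    cs_error(sprintf("arm must be 'HC' or 'IC'; offending row(s): %s",
                     paste(utils::head(bad_arm, 10L), collapse = ", ")),
             "consensim_validation_error")
  }
  bad_sc <- which(!(df$scenario_id %in% unique(scenarios$scenario_id)))
  if (length(bad_sc)) {
    cs_error(sprintf("unknown scenario_id; offending row(s): %s",
                     paste(utils::head(bad_sc, 10L), collapse = ", ")),
             "consensim_validation_error")
  }
  opt_key <- paste(scenarios$scenario_id, scenarios$option_id)
  bad_opt <- which(!(paste(df$scenario_id, df$option_id) %in% opt_key))
  if (length(bad_opt)) {
    cs_error(sprintf("option_id not in its scenario; offending row(s): %s",
                     paste(utils::head(bad_opt, 10L), collapse = ", ")),
             "consensim_validation_error")
  }
  key <- paste(df$participant_id, df$scenario_id, df$round)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    cs_error(sprintf(
      "duplicate (participant, scenario, round) record: %s", dup),
      "consensim_validation_error")
  }
  if (!is.null(groups)) {
    known <- paste(groups$participant_id, groups$group_id, groups$arm)
    bad_mem <- which(!(paste(df$participant_id, df$group_id, df$arm) %in% known))
    if (length(bad_mem)) {
      cs_error(sprintf(
        "participant/group/arm not in the group table; offending row(s): %s",
        paste(utils::head(bad_mem, 10L), collapse = ", ")),
        "consensim_validation_error")
    }
  }
  rownames(df) <- NULL
  df
}

#' Structural validation report for a trial
#'
#' Checks the design-level invariants that [read_answers()] does not enforce
#' row-wise: every (participant, scenario) cell covered at all three rounds,
#' groups of exactly the design size, and — for groups that carry teams — a
#' partition of the group into disjoint pairs. Findings are returned as a
#' report, never as errors: the trial's own data had shifting denominators
#' (dropouts), and the analysis layer must see missingness, not have it
#' hidden.
#'
#' @param answers answer table (validated records).
#' @param scenarios scenario table.
#' @param groups group table with columns `participant_id`, `group_id`,
#'   `arm`, and optionally `team_id`.
#' @param group_size required number of participants per group (default 8).
#' @return Data frame with columns `code`, `group_id`, `detail`; zero rows
#'   when the trial is fully consistent.
#' @export
validate_trial <- function(answers, scenarios, groups, group_size = 8L) {
  findings <- list()
  add <- function(code, group_id, detail) {
    findings[[length(findings) + 1L]] <<- data.frame(
      code = code, group_id = group_id, detail = detail,
      stringsAsFactors = FALSE)
  }
  # group sizes
  sizes <- table(groups$group_id)
  for (g in names(sizes)) {
    if (sizes[[g]] != group_size) {
      add("group_size", g,
          sprintf("group size %d != %d", sizes[[g]], group_size))
    }
  }
  # team partition: every member in exactly one team, every team exactly 2
  if ("team_id" %in% names(groups)) {
    for (g in unique(groups$group_id)) {
      mem <- groups[groups$group_id == g, ]
      teams <- mem$team_id[!is.na(mem$team_id) & mem$team_id != ""]
      if (!length(teams)) next
      if (length(teams) != nrow(mem)) {
        add("team_partition", g, "some members without a team")
        next
      }
      tsz <- table(teams)
      if (any(tsz != 2L)) {
        add("team_partition", g,
            sprintf("team(s) not of size 2: %s",
                    paste(names(tsz)[tsz != 2L], collapse = ", ")))
      }
    }
  }
  # completeness: all three rounds for every participant x scenario
  sid <- unique(scenarios$scenario_id)
  expected <- expand.grid(participant_id = unique(groups$participant_id),
                          scenario_id = sid, round = 1:3,
                          stringsAsFactors = FALSE)
  have <- paste(answers$participant_id, answers$scenario_id, answers$round)
  want <- paste(expected$participant_id, expected$scenario_id, expected$round)
  miss <- expected[!(want %in% have), , drop = FALSE]
  if (nrow(miss)) {
    gid <- groups$group_id[match(miss$participant_id, groups$participant_id)]
    for (i in seq_len(nrow(miss))) {
      add("missing_cell", gid[i],
          sprintf("participant %s scenario %s round %d missing",
                  miss$participant_id[i], miss$scenario_id[i], miss$round[i]))
    }
  }
  if (!length(findings)) {
    return(data.frame(code = character(), group_id = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}
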