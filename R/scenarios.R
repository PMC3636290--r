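#' Evidence grades and directions
#'
#' Clinical evidence attached to an answer option is described by a GRADE-style
#' quality level (`high`, `moderate`, `low`, `very_low`, or `absent` when no
#' evidence exists for the option) and a direction (`pro` when the evidence
#' supports the option, `contra` when it argues against it, `none` when there
#' is no evidence). `absent` and `none` imply each other.
#'
#' @name evidence-marks
#' @keywords internal
NULL

EVIDENCE_GRADES <- c("high", "moderate", "low", "very_low", "absent")
EVIDENCE_DIRECTIONS <- c("pro", "contra", "none")
GRADE_POINTS <- c(high = 4, moderate = 3, low = 2, very_low = 1, absent = 0)

#' Signed evidence points of an answer option
#'
#' Maps a GRADE quality level to points (high = 4, moderate = 3, low = 2,
#' very low = 1) and negates them when the evidence argues against the
#' option. Options without evidence carry 0 points.
#'
#' @param grade character vector of evidence grades
#'   (`"high"`, `"moderate"`, `"low"`, `"very_low"`, `"absent"`).
#' @param direction character vector of evidence directions
#'   (`"pro"`, `"contra"`, `"none"`); recycled against `grade`.
#' @return Integer vector of signed points in -4..4.
#' @examples
#' evidence_points("high", "pro")     # 4
#' evidence_points("high", "contra")  # -4
#' evidence_points("absent", "none")  # 0
#' @export
evidence_points <- function(grade, direction) {
  if (length(grade) != length(direction)) {
    n <- max(length(grade), length(direction))
    grade <- rep_len(grade, n)
    direction <- rep_len(direction, n)
  }
  if (!all(grade %in% EVIDENCE_GRADES)) {
    cs_error(sprintf("unknown evidence grade(s): %s",
                     paste(setdiff(grade, EVIDENCE_GRADES), collapse = ", ")),
             "consensim_validation_error")
  }
  if (!all(direction %in% EVIDENCE_DIRECTIONS)) {
    cs_error(sprintf("unknown evidence direction(s): %s",
                     paste(setdiff(direction, EVIDENCE_DIRECTIONS), collapse = ", ")),
             "consensim_validation_error")
  }
  bad <- (grade == "absent") != (direction == "none")
  if (any(bad)) {
    cs_error("grade 'absent' and direction 'none' must occur together",
             "consensim_validation_error")
  }
  sign <- ifelse(direction == "contra", -1L, 1L)
  as.integer(sign * GRADE_POINTS[grade])
}

#' Construct a validated scenario table
#'
#' A scenario set is a long data frame with one row per answer option of each
#' multiple-choice clinical scenario. Required columns: `scenario_id`,
#' `topic`, `option_id`, `label`, `grade`, `direction`. An `option_index`
#' column (1-based position within the scenario) and a signed `points` column
#' are derived. Whether a scenario carries evidence is derived, never stored:
#' see [scenario_has_evidence()].
#'
#' @param df data frame with the required columns.
#' @return The validated scenario table, classed `consensim_scenarios`.
#' @seealso [read_scenarios()] to load the bundled YAML format.
#' @export
as_scenarios <- function(df) {
  required <- c("scenario_id", "topic", "option_id", "label", "grade", "direction")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    cs_error(paste("scenario table missing column(s):",
                   paste(missing_cols, collapse = ", ")),
             "consensim_format_error")
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cc in required) df[[cc]] <- as.character(df[[cc]])
  # per-scenario checks
  for (sid in unique(df$scenario_id)) {
    rows <- df[df$scenario_id == sid, ]
    if (nrow(rows) < 2L) {
      cs_error(sprintf("scenario '%s' needs >=2 options", sid),
               "consensim_validation_error")
    }
    if (anyDuplicated(rows$option_id)) {
      dup <- rows$option_id[duplicated(rows$option_id)][1L]
      cs_error(sprintf("scenario '%s' has duplicate option_id '%s'", sid, dup),
               "consensim_validation_error")
    }
    if (length(unique(rows$topic)) != 1L) {
      cs_error(sprintf("scenario '%s' has inconsistent topic text", sid),
               "consensim_validation_error")
    }
  }
  df$points <- evidence_points(df$grade, df$direction)
  df$option_index <- stats::ave(seq_len(nrow(df)), df$scenario_id,
                                FUN = seq_along)
  class(df) <- c("consensim_scenarios", "data.frame")
  df
}

#' Read a scenario configuration file
#'
#' Scenario sets are declared in YAML: a top-level `scenarios` list whose
#' entries carry `scenario_id`, `topic` and an ordered `options` list with
#' `option_id`, `label`, `grade` and `direction` per option. The bundled
#' lower-back-pain set used throughout the package lives at
#' `system.file("extdata", "scenarios_lbp.yaml", package = "consensim")`.
#'
#' @param path path to a YAML scenario file.
#' @return A validated `consensim_scenarios` table (see [as_scenarios()]).
#' @examples
#' sc <- read_scenarios(system.file("extdata", "scenarios_lbp.yaml",
#'                                  package = "consensim"))
#' scenario_has_evidence(sc)
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) {
    cs_error(sprintf("scenario file not found: %s", path),
             "consensim_format_error")
  }
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    cs_error(sprintf("cannot parse scenario file %s: %s", path,
                     conditionMessage(e)),
             "consensim_format_error")
  })
  if (is.null(doc$scenarios) || !length(doc$scenarios)) {
    cs_error("scenario file has no 'scenarios' entry", "consensim_format_error")
  }
  rows <- lapply(doc$scenarios, function(sc) {
    for (f in c("scenario_id", "topic", "options")) {
      if (is.null(sc[[f]])) {
        cs_error(sprintf("scenario entry missing field '%s'", f),
                 "consensim_format_error")
      }
    }
    opt <- lapply(sc$options, function(o) {
      for (f in c("option_id", "label", "grade", "direction")) {
        if (is.null(o[[f]])) {
          cs_error(sprintf("scenario '%s': option missing field '%s'",
                           sc$scenario_id, f),
                   "consensim_format_error")
        }
      }
      data.frame(scenario_id = sc$scenario_id, topic = sc$topic,
                 option_id = o$option_id, label = o$label,
                 grade = o$grade, direction = o$direction,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, opt)
  })
  as_scenarios(do.call(rbind, rows))
}

#' Which scenarios carry clinical evidence?
#'
#' A scenario has evidence iff at least one of its options has a grade other
#' than `absent`. The flag is derived from the option table, never stored.
#'
#' @param scenarios a `consensim_scenarios` table.
#' @return Named logical vector, one element per scenario in table order.
#' @export
scenario_has_evidence <- function(scenarios) {
  sid <- unique(scenarios$scenario_id)
  out <- vapply(sid, function(s) {
    any(scenarios$grade[scenarios$scenario_id == s] != "absent")
  }, logical(1L))
  names(out) <- sid
  out
}

#' Option rows of one scenario
#'
#' @param scenarios a `consensim_scenarios` table.
#' @param scenario_id scenario to extract.
#' @return Data frame of the scenario's options in declared order.
#' @export
scenario_options <- function(scenarios, scenario_id) {
  rows <- scenarios[scenarios$scenario_id == scenario_id, , drop = FALSE]
  if (!nrow(rows)) {
    cs_error(sprintf("unknown scenario_id '%s'", scenario_id),
             "consensim_validation_error")
  }
  rows <- as.data.frame(rows)
  rownames(rows) <- NULL
  rows
}
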