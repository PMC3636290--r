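#' Signed normalized group evidence score
#'
#' The group-level concordance-with-evidence statistic: each chosen option
#' contributes its signed evidence points (4/3/2/1 for high/moderate/low/very
#' low, negated when the evidence argues against the option, 0 when the
#' option carries no evidence); the member sum is divided by the highest
#' attainable group score, i.e. the number of members times the maximum
#' positive option points of the scenario. A score of 1 means every member
#' chose the best-evidenced option; unanimous choice of a `(high, contra)`
#' option scores -1 when the maximum is 4.
#'
#' @param choices character vector of chosen `option_id`s, one per group
#'   member at one round.
#' @param options option rows of the scenario answered (see
#'   [scenario_options()]), with `option_id` and `points` columns.
#' @return The evidence score, a number in `[-1, 1]`.
#' @examples
#' sc <- read_scenarios(system.file("extdata", "scenarios_lbp.yaml",
#'                                  package = "consensim"))
#' opts <- scenario_options(sc, "therapy")
#' group_evidence_score(rep("stay_active", 8), opts)  # 1
#' @export
group_evidence_score <- function(choices, options) {
  if (all(options$grade == "absent")) {
    cs_error("evidence score undefined for an evidence-free scenario",
             "consensim_undefined_error")
  }
  unknown <- setdiff(choices, options$option_id)
  if (length(unknown)) {
    cs_error(sprintf("choice(s) not among the scenario's options: %s",
                     paste(unknown, collapse = ", ")),
             "consensim_validation_error")
  }
  max_points <- max(options$points)
  if (max_points <= 0) {
    cs_error("normalization undefined: no option has positive evidence points",
             "consensim_undefined_error")
  }
  pts <- options$points[match(choices, options$option_id)]
  sum(pts) / (length(choices) * max_points)
}

#' Within-group agreement kappa for one item
#'
#' Chance-corrected agreement of `n` raters each choosing one of `k`
#' categories for a single item. Observed agreement is the fraction of
#' concordant rater pairs among all `n(n-1)/2` pairs. Chance agreement is
#' `1/k` under the free-marginal model (the default: raters are not
#' constrained to any marginal distribution, the natural model for a single
#' multiple-choice item) or the Fleiss-style sum of squared category shares
#' under the fixed-marginal model. Kappa is `(Po - Pe) / (1 - Pe)`; it is 1
#' exactly when all raters agree (by convention also under the fixed-marginal
#' model, whose chance term degenerates to 1 at unanimity on one item).
#'
#' @param choices character vector of the raters' chosen categories.
#' @param n_categories number of available categories `k` (>= 2); for a
#'   scenario this is its number of options.
#' @param chance_model `"free_marginal"` (default) or `"fixed_marginal"`.
#' @return Kappa, a number `<= 1`.
#' @examples
#' group_agreement(rep("a", 8), n_categories = 4)            # 1
#' group_agreement(rep(c("a", "b", "c", "d"), 2), 4)         # -1/7
#' group_agreement(c(rep("a", 7), "b"), 2)                   # 0.5
#' @export
group_agreement <- function(choices, n_categories,
                            chance_model = c("free_marginal", "fixed_marginal")) {
  chance_model <- match.arg(chance_model)
  n <- length(choices)
  if (n < 2L) cs_error("agreement needs >= 2 raters", "consensim_validation_error")
  if (n_categories < 2L) {
    cs_error("agreement needs >= 2 categories", "consensim_validation_error")
  }
  counts <- table(choices)
  if (length(counts) > n_categories) {
    cs_error("more distinct choices than categories", "consensim_validation_error")
  }
  po <- sum(counts * (counts - 1)) / (n * (n - 1))
  if (po == 1) return(1)
  pe <- switch(chance_model,
               free_marginal = 1 / n_categories,
               fixed_marginal = sum((counts / n)^2))
  (po - pe) / (1 - pe)
}

#' Per-group outcome series over rounds
#'
#' Computes the two group-level outcomes — evidence score and agreement
#' kappa — for every group x scenario x round cell of an answer table.
#' Evidence scores are computed only for scenarios that carry evidence;
#' agreement is computed for all scenarios. The kappa chance model is
#' recorded in the result's `chance_model` attribute.
#'
#' @param answers validated answer table.
#' @param scenarios scenario table.
#' @param chance_model kappa chance model, see [group_agreement()].
#' @return Data frame with columns `group_id`, `arm`, `scenario_id`,
#'   `round`, `n_members`, `evidence_score` (NA for evidence-free
#'   scenarios), `kappa`.
#' @export
compute_outcome_series <- function(answers, scenarios,
                                   chance_model = c("free_marginal",
                                                    "fixed_marginal")) {
  chance_model <- match.arg(chance_model)
  has_ev <- scenario_has_evidence(scenarios)
  cells <- unique(answers[, c("group_id", "arm", "scenario_id", "round")])
  cells <- cells[order(cells$group_id, cells$scenario_id, cells$round), ]
  key_all <- paste(answers$group_id, answers$scenario_id, answers$round)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    rows <- answers[key_all == paste(cell$group_id, cell$scenario_id,
                                     cell$round), ]
    opts <- scenario_options(scenarios, cell$scenario_id)
    ev <- if (has_ev[[cell$scenario_id]]) {
      group_evidence_score(rows$option_id, opts)
    } else NA_real_
    kap <- group_agreement(rows$option_id, nrow(opts), chance_model)
    out[[i]] <- data.frame(group_id = cell$group_id, arm = cell$arm,
                           scenario_id = cell$scenario_id, round = cell$round,
                           n_members = nrow(rows), evidence_score = ev,
                           kappa = kap, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "chance_model") <- chance_model
  res
}
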