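# fixtures built in code, shared across test files

bundled_scenarios <- function() {
  read_scenarios(system.file("extdata", "scenarios_lbp.yaml",
                             package = "consensim"))
}

# minimal two-scenario set: one graded (max points 4), one evidence-free
tiny_scenarios <- function() {
  as_scenarios(data.frame(
    scenario_id = c(rep("s1", 3), rep("s2", 2)),
    topic = c(rep("graded question", 3), rep("ungraded question", 2)),
    option_id = c("a", "b", "c", "x", "y"),
    label = c("best", "middling", "against", "either", "or"),
    grade = c("high", "low", "moderate", "absent", "absent"),
    direction = c("pro", "pro", "contra", "none", "none"),
    stringsAsFactors = FALSE))
}

# a complete, hand-built 1-group answer table on tiny_scenarios()
tiny_answers <- function(option = "a") {
  grid <- expand.grid(participant_id = sprintf("P%03d", 1:8),
                      scenario_id = c("s1", "s2"), round = 1:3,
                      stringsAsFactors = FALSE)
  grid$group_id <- "HC1"
  grid$arm <- "HC"
  grid$option_id <- ifelse(grid$scenario_id == "s1", option, "x")
  grid[, c("participant_id", "group_id", "arm", "scenario_id", "round",
           "option_id")]
}

tiny_groups <- function() {
  data.frame(participant_id = sprintf("P%03d", 1:8), group_id = "HC1",
             arm = "HC", team_id = rep(sprintf("HC1_t%d", 1:4), each = 2),
             stringsAsFactors = FALSE)
}

# brute-force multirater kappa by explicit pair enumeration
oracle_pair_kappa <- function(choices, k, chance_model = "free_marginal") {
  n <- length(choices)
  pairs <- utils::combn(n, 2)
  po <- mean(choices[pairs[1, ]] == choices[pairs[2, ]])
  pe <- if (chance_model == "free_marginal") 1 / k else
    sum((table(choices) / n)^2)
  if (po == 1) 1 else (po - pe) / (1 - pe)
}

# brute-force exact signed-rank p: all 2^n sign assignments
oracle_signed_rank_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}

# brute-force exact Mann-Whitney p: all choose(n+m, n) labelings, U by
# direct pair comparison
oracle_mw <- function(a, b) {
  u_stat <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u <- u_stat(a, b)
  pooled <- c(a, b)
  n <- length(a)
  combs <- utils::combn(length(pooled), n)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  list(u = u,
       p = min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9))))
}
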