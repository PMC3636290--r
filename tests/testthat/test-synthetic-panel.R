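test_that("randomization reproduces the trial's realized design", {
  g <- randomize_participants(120, arm_counts = c(HC = 64, IC = 56), seed = 5)
  arms <- unique(g[, c("group_id", "arm")])
  expect_equal(sum(arms$arm == "HC"), 8)
  expect_equal(sum(arms$arm == "IC"), 7)
  expect_length(attr(g, "unassigned"), 0)
  expect_true(all(table(g$group_id) == 8))
  # every group partitions into 4 teams of 2
  for (gid in unique(g$group_id)) {
    expect_true(all(table(g$team_id[g$group_id == gid]) == 2))
  }

  # 123 invitees with forced 64/56 totals leave 3 observers
  g2 <- randomize_participants(123, arm_counts = c(HC = 64, IC = 56), seed = 5)
  expect_length(attr(g2, "unassigned"), 3)

  # deterministic given the seed
  g3 <- randomize_participants(120, arm_counts = c(HC = 64, IC = 56), seed = 5)
  expect_identical(g, g3)
  # odd group size cannot be paired into teams
  expect_error(randomize_participants(21, group_size = 7, arm_counts =
                                        c(HC = 14, IC = 7), seed = 1),
               class = "consensim_validation_error")
})

test_that("team consensus dynamics honor the conformity and evidence limits", {
  sc <- tiny_scenarios()
  # gamma = 1: on disagreement both adopt the pair's canonical answer
  p_conform <- default_behavior_params(sc, epsilon = 0, gamma = 1)
  set.seed(1)
  saw_disagreement <- FALSE
  for (i in 1:50) {
    res <- simulate_hc_scenario(c("P001", "P002"), sc, "s1", p_conform)
    tr <- res$transcript
    if (!tr$consensus_after_attempt1) {
      saw_disagreement <- TRUE
      expect_true(tr$consensus_final)
      expect_identical(tr$attempt2_1, tr$attempt2_2)
    }
  }
  expect_true(saw_disagreement)

  # degenerate propensity: always instant consensus, no second attempt
  p_degen <- behavior_params(
    baseline = list(s1 = c(a = 1, b = 0, c = 0), s2 = c(x = 1, y = 0)))
  set.seed(2)
  for (i in 1:20) {
    tr <- simulate_hc_scenario(c("P001", "P002"), sc, "s1", p_degen)$transcript
    expect_true(tr$consensus_after_attempt1)
    expect_true(is.na(tr$attempt2_1))
  }

  # strong evidence attraction: second attempts land on the unique
  # max-evidence option almost surely
  p_strong <- default_behavior_params(sc, epsilon = 8, gamma = 0)
  set.seed(3)
  hits <- 0L; n_second <- 0L
  for (i in 1:1000) {
    tr <- simulate_hc_scenario(c("P001", "P002"), sc, "s1", p_strong)$transcript
    if (!tr$consensus_after_attempt1) {
      n_second <- n_second + 2L
      hits <- hits + sum(c(tr$attempt2_1, tr$attempt2_2) == "a")
    }
  }
  expect_gt(n_second, 100)
  expect_gte(hits / n_second, 0.99)
})

test_that("IC rounds follow the baseline / pair / majority structure", {
  sc <- tiny_scenarios()
  grp <- tiny_groups()

  # gamma = 1: whenever round 2 has a unique majority, round 3 is unanimous
  # on it
  p1 <- default_behavior_params(sc, epsilon = 0.5, gamma = 1)
  set.seed(4)
  checked <- 0L
  for (i in 1:20) {
    ans <- simulate_ic_rounds(grp, sc, "s1", p1)
    r2 <- ans$option_id[ans$round == 2]
    counts <- table(r2)
    if (sum(counts == max(counts)) == 1L) {
      checked <- checked + 1L
      expect_true(all(ans$option_id[ans$round == 3] ==
                        names(which.max(counts))))
    }
  }
  expect_gt(checked, 0)

  # gamma = eps = 0: every round is a fresh baseline draw; round-3 option
  # shares match the baseline propensity distributionally
  p0 <- default_behavior_params(sc, epsilon = 0, gamma = 0)
  set.seed(5)
  draws <- character(0)
  for (i in 1:150) {
    ans <- simulate_ic_rounds(grp, sc, "s2", p0)
    draws <- c(draws, ans$option_id[ans$round == 3])
  }
  share_x <- mean(draws == "x")
  expect_lt(abs(share_x - 0.5), 3 * sqrt(0.25 / length(draws)))
})

test_that("team ranking key is consensus desc, exceed asc, time asc, id", {
  tr_row <- function(team, sid, cons, exceed, secs) {
    data.frame(team_id = team, scenario_id = sid, consensus_final = cons,
               limit_exceeded = exceed, elapsed_seconds = secs)
  }
  # A: 2 consensus in 300 s; B: 1 consensus in 200 s -> A first
  t1 <- rbind(tr_row("A", "s1", TRUE, FALSE, 150),
              tr_row("A", "s2", TRUE, FALSE, 150),
              tr_row("B", "s1", TRUE, FALSE, 100),
              tr_row("B", "s2", FALSE, FALSE, 100))
  expect_equal(rank_teams(t1)$team_id, c("A", "B"))

  # equal consensus/exceed: faster total time first
  t2 <- rbind(tr_row("A", "s1", TRUE, FALSE, 300),
              tr_row("B", "s1", TRUE, FALSE, 200))
  expect_equal(rank_teams(t2)$team_id, c("B", "A"))

  # fewer limit violations beat time
  t3 <- rbind(tr_row("A", "s1", TRUE, TRUE, 100),
              tr_row("B", "s1", TRUE, FALSE, 400))
  expect_equal(rank_teams(t3)$team_id, c("B", "A"))

  # exact tie: team id order
  t4 <- rbind(tr_row("B", "s1", TRUE, FALSE, 100),
              tr_row("A", "s1", TRUE, FALSE, 100))
  expect_equal(rank_teams(t4)$team_id, c("A", "B"))

  # missing transcript is an error
  t5 <- rbind(tr_row("A", "s1", TRUE, FALSE, 100),
              tr_row("A", "s2", TRUE, FALSE, 100),
              tr_row("B", "s1", TRUE, FALSE, 100))
  expect_error(rank_teams(t5), class = "consensim_validation_error")
})

test_that("a study-shaped trial has the right shape and is reproducible", {
  d <- study_design()
  p <- default_behavior_params(d$scenarios)
  tr1 <- simulate_trial(d, p, seed = 9)
  expect_equal(nrow(tr1$answers), 120 * 4 * 3)
  expect_equal(nrow(tr1$transcripts), 8 * 4 * 4)  # groups x teams x scenarios
  expect_equal(nrow(tr1$rankings), 8 * 4)

  tr2 <- simulate_trial(d, p, seed = 9)
  expect_identical(tr1$answers, tr2$answers)
  expect_identical(tr1$transcripts, tr2$transcripts)

  # final team consensus implies identical round-2 records
  r2 <- tr1$answers[tr1$answers$round == 2, ]
  key <- paste(r2$participant_id, r2$scenario_id)
  for (i in which(tr1$transcripts$consensus_final)) {
    row <- tr1$transcripts[i, ]
    o1 <- r2$option_id[key == paste(row$participant_1, row$scenario_id)]
    o2 <- r2$option_id[key == paste(row$participant_2, row$scenario_id)]
    expect_identical(o1, o2)
  }
})

test_that("group streams are stable under changes in group count", {
  sc <- tiny_scenarios()
  p <- default_behavior_params(sc)
  # same invitee pool and seed, so the shuffle and the HC pool coincide;
  # only the number of IC groups differs
  d_small <- study_design(sc, n_participants = 48,
                          arm_counts = c(HC = 16, IC = 16))
  d_large <- study_design(sc, n_participants = 48,
                          arm_counts = c(HC = 16, IC = 32))
  tr_s <- simulate_trial(d_small, p, seed = 7)
  tr_l <- simulate_trial(d_large, p, seed = 7)
  # HC arm totals agree, so the same participants form the same HC groups
  # and adding IC groups must not reshuffle their answers
  hc_s <- tr_s$answers[tr_s$answers$arm == "HC", ]
  hc_l <- tr_l$answers[tr_l$answers$arm == "HC", ]
  expect_identical(hc_s, hc_l)
})
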