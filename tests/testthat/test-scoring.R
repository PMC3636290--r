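test_that("evidence points follow the 4/3/2/1 scheme with sign reversal", {
  expect_equal(evidence_points("high", "pro"), 4L)
  expect_equal(evidence_points("moderate", "pro"), 3L)
  expect_equal(evidence_points("low", "pro"), 2L)
  expect_equal(evidence_points("very_low", "pro"), 1L)
  expect_equal(evidence_points("high", "contra"), -4L)
  expect_equal(evidence_points("very_low", "contra"), -1L)
  expect_equal(evidence_points("absent", "none"), 0L)
  expect_error(evidence_points("high", "none"),
               class = "consensim_validation_error")
  expect_error(evidence_points("absent", "pro"),
               class = "consensim_validation_error")
})

test_that("group evidence score hits its defining anchor points", {
  sc <- bundled_scenarios()
  opts <- scenario_options(sc, "imaging")
  # unanimity on the unique best-evidenced option defines score 1
  expect_equal(group_evidence_score(rep("no_routine_imaging", 8), opts), 1)
  # unanimity against: sign symmetry (moderate contra = -3 of max 4)
  expect_equal(group_evidence_score(rep("plain_xray", 8), opts), -3 / 4)

  # hand-built scenario with a (high, contra) option against max 4
  opts2 <- scenario_options(as_scenarios(data.frame(
    scenario_id = "s", topic = "t", option_id = c("pro4", "con4"),
    label = c("for", "against"), grade = c("high", "high"),
    direction = c("pro", "contra"))), "s")
  expect_equal(group_evidence_score(rep("con4", 8), opts2), -1)

  # mixed choices: (4*4 + 4*2) / (8*4) = 0.75
  opts3 <- scenario_options(tiny_scenarios(), "s1")
  expect_equal(group_evidence_score(rep(c("a", "b"), each = 4), opts3), 0.75)

  # evidence-free scenario: undefined
  expect_error(group_evidence_score(rep("x", 8),
                                    scenario_options(tiny_scenarios(), "s2")),
               class = "consensim_undefined_error")
  # no positively graded option: normalization undefined
  opts4 <- scenario_options(as_scenarios(data.frame(
    scenario_id = "s", topic = "t", option_id = c("c1", "c2"),
    label = c("u", "v"), grade = c("low", "high"),
    direction = c("contra", "contra"))), "s")
  expect_error(group_evidence_score(rep("c1", 8), opts4),
               class = "consensim_undefined_error")
})

test_that("evidence score is permutation-invariant and member-linear", {
  opts <- scenario_options(tiny_scenarios(), "s1")
  set.seed(11)
  for (i in 1:20) {
    ch <- sample(opts$option_id, 8, replace = TRUE)
    base <- group_evidence_score(ch, opts)
    expect_equal(group_evidence_score(sample(ch), opts), base)
    expect_gte(base, -1); expect_lte(base, 1)
    # move member 1 from its option to another: exact score shift
    to <- sample(opts$option_id, 1)
    shifted <- ch; shifted[1] <- to
    delta <- (opts$points[match(to, opts$option_id)] -
                opts$points[match(ch[1], opts$option_id)]) / (8 * 4)
    expect_equal(group_evidence_score(shifted, opts), base + delta)
  }
})

test_that("multirater kappa matches hand-enumerated pair counts", {
  # unanimity is 1 under either chance model
  expect_equal(group_agreement(rep("a", 8), 4, "free_marginal"), 1)
  expect_equal(group_agreement(rep("a", 8), 4, "fixed_marginal"), 1)
  # 2/2/2/2 over 4 options: Po = 1/7, Pe = 1/4 -> -1/7
  expect_equal(group_agreement(rep(c("a", "b", "c", "d"), 2), 4), -1 / 7)
  # 7 vs 1 over 2 options: Po = 0.75, Pe = 0.5 -> 0.5
  expect_equal(group_agreement(c(rep("a", 7), "b"), 2), 0.5)
  expect_error(group_agreement("a", 4), class = "consensim_validation_error")
})

test_that("kappa agrees with the brute-force pair-counting oracle", {
  set.seed(21)
  cats <- letters[1:4]
  for (i in 1:400) {
    ch <- sample(cats, 8, replace = TRUE)
    for (model in c("free_marginal", "fixed_marginal")) {
      expect_equal(group_agreement(ch, 4, model),
                   oracle_pair_kappa(ch, 4, model))
    }
    expect_lte(group_agreement(ch, 4), 1)
  }
})

test_that("outcome series covers the design and skips ungraded scenarios", {
  d <- study_design()
  p <- default_behavior_params(d$scenarios)
  tr <- simulate_trial(d, p, seed = 13)
  s <- compute_outcome_series(tr$answers, d$scenarios)
  expect_equal(nrow(s), 15 * 4 * 3)
  expect_equal(sum(!is.na(s$evidence_score)), 15 * 3 * 3)
  expect_true(all(is.na(s$evidence_score[s$scenario_id == "sick_leave"])))
  expect_true(all(!is.na(s$kappa)))
  expect_equal(attr(s, "chance_model"), "free_marginal")

  # unanimity everywhere: all kappas 1, score = chosen option's share
  sc <- tiny_scenarios()
  s2 <- compute_outcome_series(tiny_answers(option = "b"), sc)
  expect_true(all(s2$kappa == 1))
  expect_true(all(s2$evidence_score[s2$scenario_id == "s1"] == 0.5))
})
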