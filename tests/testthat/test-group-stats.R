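test_that("within-group d matches hand computations and flags degeneracy", {
  expect_equal(within_group_d(c(0.1, 0.5, 0.3), c(0.1, 0.5, 0.3)), 0)
  # means 0.3 / 0.7, both SDs sqrt(0.02) -> d = 0.4 / 0.1414...
  expect_equal(within_group_d(c(0.2, 0.4), c(0.6, 0.8)),
               0.4 / sqrt(0.02), tolerance = 1e-12)
  expect_error(within_group_d(c(0.5, 0.5), c(0.7, 0.7)),
               class = "consensim_undefined_error")
  expect_error(within_group_d(c(1, 2), c(1, 2, 3)),
               class = "consensim_validation_error")
})

test_that("between-group d is signed by default with (n-1)-weighted pooling", {
  expect_equal(between_group_d(c(0.1, 0.2), c(0.1, 0.2)), 0)
  expect_equal(between_group_d(c(0.4, 0.6), c(0.1, 0.3)),
               0.3 / sqrt(0.02), tolerance = 1e-12)
  # IC improving more gives a negative d unless the absolute form is asked
  d_neg <- between_group_d(c(0.1, 0.3), c(0.4, 0.6))
  expect_lt(d_neg, 0)
  expect_equal(between_group_d(c(0.1, 0.3), c(0.4, 0.6), signed = FALSE),
               abs(d_neg))
  expect_error(between_group_d(c(1, 1), c(2, 2)),
               class = "consensim_undefined_error")
})

test_that("Cohen's d is location and scale invariant", {
  set.seed(31)
  for (i in 1:20) {
    r1 <- rnorm(8); r3 <- rnorm(8)
    a <- rnorm(8); b <- rnorm(7)
    shift <- runif(1, -5, 5); scale <- runif(1, 0.1, 10)
    expect_equal(within_group_d(r1, r3),
                 within_group_d(scale * r1 + shift, scale * r3 + shift))
    expect_equal(between_group_d(a, b),
                 between_group_d(scale * a + shift, scale * b + shift))
  }
})

test_that("exact signed-rank test reproduces closed cases", {
  res <- wilcoxon_signed_rank_exact(c(1, 2, 3))
  expect_equal(res$statistic, 6)
  expect_equal(res$p.value, 0.25)
  expect_true(res$exact)

  # point-symmetric configuration: p = 1 at the null's center
  expect_equal(wilcoxon_signed_rank_exact(c(-1, 1))$p.value, 1)

  zero <- wilcoxon_signed_rank_exact(c(0, 0, 0))
  expect_equal(zero$p.value, 1)
  expect_true(zero$no_information)
})

test_that("exact signed-rank matches sign-flip enumeration, ties included", {
  set.seed(41)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    # half the fixtures carry ties and zeros to exercise mid-ranks
    d <- if (i %% 2) round(runif(n, -3, 3), 0) else rnorm(n)
    if (all(d == 0)) d[1] <- 1
    res <- wilcoxon_signed_rank_exact(d)
    expect_equal(res$p.value, oracle_signed_rank_p(d))
    expect_gte(res$p.value, 0); expect_lte(res$p.value, 1)
  }
  # tie-free case cross-checked against the standard exact implementation
  d <- c(1.3, -0.4, 2.2, 0.7, -1.8, 0.2, 3.1, -2.6)
  expect_equal(wilcoxon_signed_rank_exact(d)$p.value,
               stats::wilcox.test(d, exact = TRUE)$p.value)
})

test_that("exact Mann-Whitney reproduces closed cases and the oracle", {
  res <- mann_whitney_u_exact(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1 / 3, tolerance = 1e-12)
  expect_equal(mann_whitney_u_exact(c(1, 2, 5), c(1, 2, 5))$p.value, 1)

  set.seed(51)
  for (i in 1:25) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    vals <- if (i %% 2) sample(1:4, n + m, TRUE) else rnorm(n + m)
    a <- vals[seq_len(n)]; b <- vals[-seq_len(n)]
    or <- oracle_mw(a, b)
    res <- mann_whitney_u_exact(a, b)
    expect_equal(res$statistic, or$u)
    expect_equal(res$p.value, or$p)
  }
  # the study's arm sizes, 8 vs 7 groups, against the C(15,8) enumeration
  set.seed(52)
  a <- rnorm(8); b <- rnorm(7)
  expect_equal(mann_whitney_u_exact(a, b)$p.value, oracle_mw(a, b)$p)
  # and against the standard exact implementation on tie-free data
  expect_equal(mann_whitney_u_exact(a, b)$p.value,
               stats::wilcox.test(a, b, exact = TRUE)$p.value)
})

test_that("large-sample Mann-Whitney approximation is sane", {
  set.seed(61)
  a <- rnorm(15); b <- rnorm(15, 1)
  res <- mann_whitney_u_exact(a, b)
  expect_false(res$exact)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("Bonferroni arithmetic and t-intervals are exact", {
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 5), 0.002)
  expect_error(bonferroni_alpha(0.05, 0), class = "consensim_validation_error")

  expect_equal(mean_ci95(rep(0.5, 8)), c(mean = 0.5, lower = 0.5, upper = 0.5))
  ci <- mean_ci95(c(0, 1))
  half <- stats::qt(0.975, 1) * stats::sd(c(0, 1)) / sqrt(2)
  expect_equal(ci, c(mean = 0.5, lower = 0.5 - half, upper = 0.5 + half))
  expect_equal(unname(ci["upper"]), 6.853102, tolerance = 1e-6)
  # symmetric about the mean by construction
  set.seed(71)
  v <- rnorm(10)
  ci2 <- mean_ci95(v)
  expect_equal(ci2[["upper"]] - ci2[["mean"]], ci2[["mean"]] - ci2[["lower"]])
  expect_error(mean_ci95(1), class = "consensim_validation_error")
})

test_that("analyze_outcomes assembles the inferential table", {
  d <- study_design(tiny_scenarios(), n_participants = 48,
                    arm_counts = c(HC = 24, IC = 24))
  p <- default_behavior_params(d$scenarios, epsilon = 1.5, gamma = 0.5)
  tr <- simulate_trial(d, p, seed = 17)
  s <- compute_outcome_series(tr$answers, d$scenarios)
  eff <- analyze_outcomes(s)
  # graded scenario contributes both outcomes, ungraded only kappa
  expect_setequal(paste(eff$scenario_id, eff$outcome),
                  c("s1 evidence_score", "s1 kappa", "s2 kappa"))
  expect_equal(attr(eff, "alpha_adjusted"), 0.025)
  expect_true(all(eff$p_between >= 0 & eff$p_between <= 1))
  expect_true(all(eff$n_hc == 3 & eff$n_ic == 3))
})
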