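# package-local cache for Mann-Whitney labeling enumerations
.mw_cache <- new.env(parent = emptyenv())

#' Within-group Cohen's d on round-wise change
#'
#' Standardized magnitude of the round 1 -> round 3 change of a group-level
#' outcome within one arm: the absolute difference of the round means divided
#' by the pooled standard deviation `sqrt((s1^2 + s3^2) / 2)` (sample SDs,
#' n-1 denominator; the two rounds have the same groups, so pooling weights
#' are equal).
#'
#' @param values_r1,values_r3 per-group outcome values at rounds 1 and 3,
#'   paired by group, length >= 2.
#' @return Cohen's d (non-negative).
#' @export
within_group_d <- function(values_r1, values_r3) {
  if (length(values_r1) != length(values_r3)) {
    cs_error("round-1 and round-3 vectors must be paired (equal length)",
             "consensim_validation_error")
  }
  if (length(values_r1) < 2L) {
    cs_error("need >= 2 groups", "consensim_validation_error")
  }
  s_pooled <- sqrt((stats::var(values_r1) + stats::var(values_r3)) / 2)
  num <- abs(mean(values_r3) - mean(values_r1))
  if (s_pooled == 0) {
    if (num == 0) return(0)
    cs_error("pooled SD is zero: effect size undefined",
             "consensim_undefined_error")
  }
  num / s_pooled
}

#' Between-group Cohen's d on changes
#'
#' Standardized difference between the arms' mean round-wise changes: the
#' HC mean change minus the IC mean change, divided by the pooled standard
#' deviation with Bessel-corrected variances weighted by `n - 1`. The
#' numerator is signed by default (negative when IC improves more), with
#' `signed = FALSE` giving the absolute form.
#'
#' @param hc_changes per-HC-group round 3 minus round 1 changes.
#' @param ic_changes per-IC-group changes.
#' @param signed keep the sign of the difference (default TRUE).
#' @return Cohen's d.
#' @export
between_group_d <- function(hc_changes, ic_changes, signed = TRUE) {
  n1 <- length(hc_changes); n2 <- length(ic_changes)
  if (n1 < 2L || n2 < 2L) {
    cs_error("need >= 2 groups per arm", "consensim_validation_error")
  }
  sp <- sqrt(((n1 - 1) * stats::var(hc_changes) +
              (n2 - 1) * stats::var(ic_changes)) / (n1 + n2 - 2))
  num <- mean(hc_changes) - mean(ic_changes)
  if (sp == 0) {
    if (num == 0) return(0)
    cs_error("pooled SD is zero: effect size undefined",
             "consensim_undefined_error")
  }
  if (signed) num / sp else abs(num) / sp
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided one-sample signed-rank test on paired differences, exact for
#' small samples: zeros are dropped (Wilcoxon's original treatment), absolute
#' differences receive mid-ranks under ties, and the null distribution of
#' `W+` is obtained from the generating function over all `2^n` sign
#' assignments of the ranks. The two-sided p is `min(1, 2 * min(P(W <= w),
#' P(W >= w)))`. Beyond `exact_max_n` non-zero differences a normal
#' approximation with the exact sign-flip variance of the mid-ranks is used.
#'
#' @param diffs numeric vector of paired differences.
#' @param exact_max_n largest n for the exact enumeration (default 20).
#' @return List with `statistic` (W+), `p.value`, `n` (non-zero
#'   differences), `exact`, and `no_information` (TRUE when every
#'   difference is zero, in which case p = 1).
#' @examples
#' wilcoxon_signed_rank_exact(c(1, 2, 3))$p.value  # 0.25
#' @export
wilcoxon_signed_rank_exact <- function(diffs, exact_max_n = 20L) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p.value = 1, n = 0L, exact = TRUE,
                no_information = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max_n) {
    # doubled ranks are integers even under mid-rank ties
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)
    f[1L] <- 1
    for (ri in r2) {
      g <- f
      idx <- (ri + 1L):(total + 1L)
      g[idx] <- g[idx] + f[seq_len(total + 1L - ri)]
      f <- g
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (w - mu) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  list(statistic = w, p.value = p, n = n, exact = exact,
       no_information = FALSE)
}

#' Exact Mann-Whitney U test
#'
#' Two-sided two-sample test on the Mann-Whitney statistic
#' `U = #(a > b) + 0.5 * #(a == b)` over all cross-arm pairs. For pooled
#' sample sizes up to `exact_max_n` the exact permutation distribution is
#' obtained by enumerating all `choose(n + m, n)` labelings of the pooled
#' (mid-ranked) values; beyond that a normal approximation with tie
#' correction and continuity correction is used. The study's arm sizes
#' (8 and 7 groups) always take the exact path.
#'
#' @param a,b numeric samples to compare.
#' @param exact_max_n largest pooled size for exact enumeration (default 20).
#' @return List with `statistic` (U for sample `a`), `p.value`, `exact`.
#' @examples
#' mann_whitney_u_exact(c(1, 2), c(3, 4))$p.value  # 1/3
#' @export
mann_whitney_u_exact <- function(a, b, exact_max_n = 20L) {
  n <- length(a); m <- length(b)
  if (!n || !m) cs_error("both samples must be non-empty",
                         "consensim_validation_error")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  big <- n + m
  if (big <= exact_max_n) {
    key <- paste0(big, "_", n)
    combs <- .mw_cache[[key]]
    if (is.null(combs)) {
      combs <- utils::combn(big, n)
      .mw_cache[[key]] <- combs
    }
    sums <- colSums(matrix(r[combs], nrow = n))
    us <- sums - n * (n + 1) / 2
    eps <- 1e-9
    p_le <- mean(us <= u + eps)
    p_ge <- mean(us >= u - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * m / 2
    ties <- table(r)
    sigma2 <- n * m / 12 * (big + 1 - sum(ties^3 - ties) / (big * (big - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  list(statistic = u, p.value = p, exact = exact)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level in (0, 1].
#' @param m number of outcome measures tested per scenario (>= 1).
#' @return `alpha / m`; the trial's two outcomes at alpha 0.05 give 0.025.
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 1) {
    cs_error("alpha must be in (0, 1]", "consensim_validation_error")
  }
  if (!is_scalar_number(m) || m < 1) {
    cs_error("m must be >= 1", "consensim_validation_error")
  }
  alpha / m
}

#' Mean with 95% t-interval
#'
#' @param values numeric vector, length >= 2.
#' @return Named numeric vector `c(mean, lower, upper)` using the
#'   t-distribution interval `mean +/- t(0.975, n-1) * s / sqrt(n)`.
#' @export
mean_ci95 <- function(values) {
  n <- length(values)
  if (n < 2L) cs_error("need >= 2 values for a CI", "consensim_validation_error")
  m <- mean(values)
  half <- stats::qt(0.975, n - 1) * stats::sd(values) / sqrt(n)
  c(mean = m, lower = m - half, upper = m + half)
}

#' Effect-size and test table for an outcome series
#'
#' The trial's inferential layer applied to a [compute_outcome_series()]
#' result: per scenario and outcome, within-arm Cohen's d on the round
#' 1 -> 3 change with an exact Wilcoxon signed-rank p, and the between-arm
#' Cohen's d on the changes with an exact Mann-Whitney p, flagged
#' significant at the Bonferroni-adjusted level. Degenerate cells (zero
#' pooled SD) yield NA effect sizes rather than errors.
#'
#' @param series outcome series from [compute_outcome_series()].
#' @param alpha family-wise alpha (default 0.05).
#' @param m_outcomes outcomes per scenario for the Bonferroni adjustment
#'   (default 2: evidence score and agreement).
#' @param signed_between sign convention for the between-arm d, see
#'   [between_group_d()].
#' @return Data frame, one row per scenario x outcome, with columns for the
#'   within-arm and between-arm effect sizes, p-values and significance
#'   flags; the adjusted alpha is stored in the `alpha_adjusted` attribute.
#' @export
analyze_outcomes <- function(series, alpha = 0.05, m_outcomes = 2L,
                             signed_between = TRUE) {
  a_adj <- bonferroni_alpha(alpha, m_outcomes)
  safe_d <- function(expr) tryCatch(expr, consensim_undefined_error =
                                      function(e) NA_real_)
  rows <- list()
  for (sid in unique(series$scenario_id)) {
    for (outcome in c("evidence_score", "kappa")) {
      sub <- series[series$scenario_id == sid, ]
      if (all(is.na(sub[[outcome]]))) next
      wide <- stats::reshape(
        sub[, c("group_id", "arm", "round", outcome)],
        idvar = c("group_id", "arm"), timevar = "round", direction = "wide")
      v1 <- wide[[paste0(outcome, ".1")]]
      v3 <- wide[[paste0(outcome, ".3")]]
      ok <- !is.na(v1) & !is.na(v3)
      wide <- wide[ok, ]; v1 <- v1[ok]; v3 <- v3[ok]
      hc <- wide$arm == "HC"
      chg <- v3 - v1
      row <- data.frame(scenario_id = sid, outcome = outcome,
                        n_hc = sum(hc), n_ic = sum(!hc),
                        stringsAsFactors = FALSE)
      for (arm in c("HC", "IC")) {
        sel <- wide$arm == arm
        d <- if (sum(sel) >= 2L) safe_d(within_group_d(v1[sel], v3[sel])) else NA_real_
        p <- if (sum(sel) >= 1L) wilcoxon_signed_rank_exact(chg[sel])$p.value else NA_real_
        row[[paste0("d_within_", tolower(arm))]] <- d
        row[[paste0("p_within_", tolower(arm))]] <- p
      }
      if (sum(hc) >= 2L && sum(!hc) >= 2L) {
        row$d_between <- safe_d(between_group_d(chg[hc], chg[!hc],
                                                signed = signed_between))
        row$p_between <- mann_whitney_u_exact(chg[hc], chg[!hc])$p.value
      } else {
        row$d_between <- NA_real_
        row$p_between <- NA_real_
      }
      row$sig_within_hc <- !is.na(row$p_within_hc) & row$p_within_hc <= a_adj
      row$sig_within_ic <- !is.na(row$p_within_ic) & row$p_within_ic <= a_adj
      row$sig_between <- !is.na(row$p_between) & row$p_between <= a_adj
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "alpha_adjusted") <- a_adj
  res
}
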