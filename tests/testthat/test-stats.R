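# Statistical stage: pooled t, Pearson r, permutation agreement, CV,
# MFI contrasts, noise propagation.

test_that("identical samples give t = 0, p = 1, and echo their summaries", {
  r <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3), labels = c("x", "y"),
                        variable = "BT")
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)
  expect_equal(c(r$n1, r$n2), c(3, 3))
  expect_equal(c(r$mean1, r$mean2), c(2, 2))
  expect_equal(c(r$sd1, r$sd2), c(1, 1))
})

test_that("pooled t matches the closed form on the worked example", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  # independent closed-form computation
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  r <- two_sample_ttest(a, b)
  expect_equal(r$t_statistic, t_hand, tolerance = 1e-10)
  expect_equal(round(r$t_statistic, 4), -1.2247)
  expect_equal(r$p_value, p_hand, tolerance = 1e-10)
  expect_equal(r$df, 4)
})

test_that("degenerate zero-variance samples behave per contract", {
  expect_equal(two_sample_ttest(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  expect_error(two_sample_ttest(c(2, 2, 2), c(3, 3, 3)), "degenerate")
  expect_error(two_sample_ttest(1, c(1, 2)), ">= 2")
})

test_that("t-test p agrees with a brute-force permutation null", {
  set.seed(42)
  a <- rnorm(6); b <- rnorm(6) + 0.5
  p_perm <- perm_ttest_p(a, b, n_perm = 1e5)
  p_t <- two_sample_ttest(a, b)$p_value
  expect_lt(abs(p_t - p_perm), 0.01)
})

test_that("perfect linear relations give |r| = 1 with vanishing p", {
  x <- 1:10
  r <- pearson_correlation(x, 2 * x + 1)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_lt(r$p_value, 1e-12)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  neg <- pearson_correlation(c(1, 2, 3), c(6, 4, 2))
  expect_equal(neg$r, -1, tolerance = 1e-12)
})

test_that("correlation p agrees with a permutation null", {
  set.seed(7)
  x <- rnorm(12); y <- 0.5 * x + rnorm(12)
  p_perm <- perm_cor_p(x, y, n_perm = 1e5)
  p_r <- pearson_correlation(x, y)$p_value
  expect_lt(abs(p_r - p_perm), 0.01)
})

test_that("constant inputs raise an undefined-correlation error", {
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")
  expect_error(pearson_correlation(1:5, rep(2, 5)), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "n >= 3")
})

test_that("coefficient of variation follows sd over mean", {
  expect_equal(unname(reproducibility_stats(c(2, 2, 2))), 0)
  expect_equal(unname(reproducibility_stats(c(9, 10, 11))), 0.1)
  expect_equal(reproducibility_stats(list(BT = c(9, 10, 11) * 3))[["BT"]],
               0.1)  # scale invariance
  expect_error(reproducibility_stats(c(-1, 1)), "mean is zero")
  expect_error(reproducibility_stats(c(1)), ">= 2")
})

test_that("MFI contrasts cover adjacent classes within sex and sexes within class", {
  set.seed(8)
  n <- 30
  tab <- data.frame(
    sex = rep(c("F", "M"), each = 3 * n),
    mfi_class = rep(rep(c("normal", "mild", "moderate"), each = n), 2),
    BT = rnorm(6 * n, 2.5, 0.5))
  res <- mfi_group_analysis(tab, variables = "BT")
  expect_setequal(unique(res$contrast),
                  c("within-F", "within-M", "between-sex|normal",
                    "between-sex|mild", "between-sex|moderate"))
  expect_equal(nrow(res), 7)
  # single-class cohort: only the between-sex contrast remains
  one <- tab[tab$mfi_class == "mild", ]
  res1 <- mfi_group_analysis(one, variables = "BT")
  expect_equal(res1$contrast, "between-sex|mild")
})

test_that("MFI contrasts hold the type-I rate under the null and detect a shift", {
  n_runs <- 100
  null_fp <- power_hit <- logical(n_runs)
  for (k in seq_len(n_runs)) {
    set.seed(1000 + k)
    n <- 30
    tab <- data.frame(
      sex = rep(c("F", "M"), each = 3 * n),
      mfi_class = rep(rep(c("normal", "mild", "moderate"), each = n), 2),
      MPI = rnorm(6 * n, 0.13, 0.05))
    res <- mfi_group_analysis(tab, variables = "MPI")
    null_fp[k] <- all(res$p_value > 0.05)
    n2 <- 25
    tab2 <- data.frame(
      sex = "F",
      mfi_class = rep(c("normal", "mild", "moderate"), each = n2),
      MPI = rnorm(3 * n2, 0.13, 0.05) +
        rep(c(0, 0, 0.05), each = n2))
    res2 <- suppressMessages(mfi_group_analysis(tab2, variables = "MPI"))
    sig <- res2[res2$group1 == "mild" & res2$group2 == "moderate", ]
    power_hit[k] <- isTRUE(sig$significant)
  }
  expect_gte(mean(null_fp), 0.60)   # 7 raw tests at alpha 0.05
  expect_gte(mean(power_hit), 0.80) # d = 1 at n = 25/class
})

test_that("zero noise reproduces the baseline p in every execution", {
  set.seed(9)
  tab <- data.frame(age = rnorm(40, 60, 10))
  tab$BT <- 3 - 0.02 * tab$age + rnorm(40, 0, 0.3)
  nr <- noise_perturbation_analysis(tab, "BT", "age", noise_fraction = 0,
                                    n_executions = 10)
  expect_true(all(nr$p_values == nr$baseline_p))
  expect_equal(nr$mean_p, nr$baseline_p)
})

test_that("strong correlations survive segmentation-scale noise", {
  set.seed(10)
  x <- rnorm(100)
  y <- 0.8 * x + rnorm(100, 0, sqrt(1 - 0.8^2))  # r ~ 0.8
  tab <- data.frame(age = x, BT = abs(y) + 3)
  tab$BT <- 3 + 0.5 * x + rnorm(100, 0, 0.375)
  nr <- noise_perturbation_analysis(tab, "BT", "age", noise_fraction = 0.025,
                                    n_executions = 10, seed = 2)
  expect_true(nr$significance_preserved)
  expect_lt(nr$mean_p, 0.001)
})

test_that("null correlations yield uniform noisy p-values across seeds", {
  mean_ps <- vapply(seq_len(200), function(s) {
    set.seed(30000 + s)
    tab <- data.frame(age = rnorm(100), BT = rnorm(100) + 5)
    noise_perturbation_analysis(tab, "BT", "age", noise_fraction = 0.025,
                                n_executions = 3, seed = s)$mean_p
  }, numeric(1))
  expect_gt(mean(mean_ps), 0.4)
  expect_lt(mean(mean_ps), 0.6)
})

test_that("implausible noise fractions are refused", {
  tab <- data.frame(age = 1:10, BT = rnorm(10))
  expect_error(noise_perturbation_analysis(tab, "BT", "age", 0.6), "implausible")
  expect_error(noise_perturbation_analysis(tab, "BT", "age", -0.1), ">= 0")
  expect_error(noise_perturbation_analysis(tab, "XX", "age", 0.02), "missing")
})
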