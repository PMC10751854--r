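# Descriptive summaries, omnibus tests, post-hoc Bonferroni, ANCOVA.

test_that("describe reports median/IQR and mean/SD per the normality gate", {
  g <- factor(rep("a", 5))
  d <- describe_metric(c(1, 2, 3, 4, 5), g, force = FALSE)
  expect_equal(d$stats$median, 3)
  expect_equal(d$stats$q1, 2)
  expect_equal(d$stats$q3, 4)
  dn <- describe_metric(c(1, 2, 3, 4, 5), g, force = TRUE)
  expect_match(unname(dn$formatted["a"]), "±")
  # constant group: SD exactly 0, no Shapiro crash
  dc <- describe_metric(rep(2, 5), g, force = NA)
  expect_equal(dc$stats$sd, 0)
  expect_error(describe_metric(1, factor("a")), "at least 2")
})

test_that("log-normal samples are flagged non-normal as n grows", {
  set.seed(12)
  x <- rlnorm(2000, 0, 1)
  d <- describe_metric(x, factor(rep("a", 2000)))
  expect_false(d$normal)
  y <- rnorm(2000)
  expect_true(describe_metric(y, factor(rep("a", 2000)))$normal)
})

test_that("Kruskal-Wallis H matches the rank-formula oracle", {
  gl <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  H <- kw_rank_oracle(gl)
  expect_equal(H, 7.2)                     # frozen from the rank formula
  res <- omnibus_test(unlist(gl), factor(rep(1:3, each = 3)), "kruskal_wallis")
  expect_equal(res$statistic, H)
  # invariance under strictly monotone transforms
  res2 <- omnibus_test(exp(unlist(gl)), factor(rep(1:3, each = 3)),
                       "kruskal_wallis")
  expect_equal(res2$statistic, res$statistic)
})

test_that("identical groups give F near 0 and p near 1; extreme tables reject", {
  x <- rep(c(1, 2, 3, 4, 5), 3)
  g <- factor(rep(1:3, each = 5))
  res <- omnibus_test(x, g, "anova")
  expect_lt(res$statistic, 1e-20)
  expect_gt(res$p.value, 0.999)
  tab <- factor(rep(c("x", "y"), times = c(10, 10)))
  grp <- factor(rep(c("a", "b"), times = c(10, 10)))
  chi <- omnibus_test(tab, grp, "chi_squared")
  expect_lt(chi$p.value, 0.05)
  expect_error(omnibus_test(rnorm(10), factor(rep(1:2, 5)), "chi_squared"),
               "categorical")
})

test_that("Bonferroni arithmetic: adjusted = min(1, 3 x raw)", {
  set.seed(5)
  x <- c(rnorm(15), rnorm(15, 1), rnorm(15, 0.1))
  g <- factor(rep(1:3, each = 15))
  for (fam in c("anova", "kruskal_wallis")) {
    ph <- posthoc_pairwise(x, g, fam)
    expect_equal(nrow(ph), 3L)
    expect_equal(ph$p_adj, pmin(1, 3 * ph$p_raw))
  }
  expect_equal(min(1, 0.02 * 3), 0.06)
  # capping at 1 on indistinguishable groups
  xn <- rep(c(1, 2, 3, 4, 5, 6), 3) + rnorm(18, sd = 1e-3)
  phn <- posthoc_pairwise(xn, factor(rep(1:3, each = 6)), "kruskal_wallis")
  expect_true(any(phn$p_adj == 1))
})

test_that("ANCOVA matches the normal-equations oracle on a 6-row dataset", {
  df <- data.frame(y = c(3.1, 4.0, 5.2, 6.3, 7.1, 8.4),
                   group = factor(rep(c("a", "b"), each = 3)),
                   bmi = c(21, 24, 27, 22, 25, 29))
  res <- ancova_group_test(df, "y", "group", "bmi")
  oracle <- ancova_f_oracle(df$y, df$group, df$bmi)
  expect_equal(res$F, oracle$F, tolerance = 1e-10)
  expect_equal(res$p.value, oracle$p, tolerance = 1e-10)
})

test_that("ANCOVA reduces to one-way ANOVA for a constant covariate", {
  set.seed(8)
  df <- data.frame(y = rnorm(30), group = factor(rep(1:3, each = 10)),
                   bmi = rep(25, 30))
  res <- ancova_group_test(df, "y", "group", "bmi")
  aovp <- omnibus_test(df$y, df$group, "anova")
  expect_equal(res$p.value, aovp$p.value, tolerance = 1e-12)
  expect_length(res$covariates, 0)
  # covariate collinear with the group factor is rejected
  df$bad <- as.numeric(df$group)
  expect_error(ancova_group_test(df, "y", "group", "bad"), "collinear")
})

test_that("a group effect mediated by BMI loses significance under ANCOVA", {
  set.seed(21)
  n <- 60
  g <- factor(rep(c("control", "paroxysmal", "persistent"), each = n))
  bmi <- rnorm(3 * n, mean = rep(c(24, 27, 28), each = n), sd = 1.5)
  y <- 0.05 * bmi + rnorm(3 * n, sd = 0.05)   # effect entirely through BMI
  df <- data.frame(y = y, group = g, bmi = bmi)
  raw <- omnibus_test(y, g, "anova")$p.value
  adj <- ancova_group_test(df, "y", "group", "bmi")$p.value
  expect_lt(raw, 1e-6)
  expect_gt(adj, 100 * raw)
})

test_that("compare_groups assembles the full battery", {
  co <- make_cohort(seed = 3)
  cmp <- compare_groups(co, metrics = c("sex", "bmi", "infat_ml", "dense_ml"))
  expect_setequal(cmp$summary$metric, c("sex", "bmi", "infat_ml", "dense_ml"))
  expect_identical(cmp$summary$family[cmp$summary$metric == "sex"],
                   "chi_squared")
  expect_true(all(cmp$summary$p >= 0 & cmp$summary$p <= 1))
  expect_equal(nrow(cmp$pairwise), 3 * 3)     # 3 continuous metrics x 3 pairs
  expect_true(all(c("control", "paroxysmal", "persistent") %in%
                  names(cmp$summary)))
  expect_false("bmi" %in% cmp$ancova$metric)  # covariate not self-adjusted
})
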