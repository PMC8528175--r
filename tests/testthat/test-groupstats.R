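test_that("group summaries use a tie-to-low median split and exact moments", {
  cohort <- tibble::tibble(
    observer_id = c("a", "b", "c", "d"),
    aq = c(8L, 13L, 14L, 22L)
  )
  fits <- tidyr::expand_grid(
    observer_id = cohort$observer_id,
    task = "single", condition = "connected",
    reference_numerosity = c(15, 100)
  )
  fits <- dplyr::arrange(fits, observer_id, reference_numerosity)
  fits$bias_percent <- c(-20, -12, -20, -12, -18, -10, -18, -10)
  fits$weber_fraction <- 0.2
  s <- summarize_group_biases(fits, cohort)
  # median of {8,13,14,22} is 13.5; a,b low; c,d high
  low_low <- s[s$band == "low" & s$aq_group == "low_aq", ]
  expect_identical(low_low$n, 2L)
  expect_equal(low_low$mean_bias, -20)
  expect_equal(low_low$sd_bias, 0)
  high_high <- s[s$band == "high" & s$aq_group == "high_aq", ]
  expect_equal(high_high$mean_bias, -10)
  # unmatched fits are dropped with a warning
  fits2 <- fits
  fits2$observer_id[1:2] <- "zz"
  expect_warning(summarize_group_biases(fits2, cohort), "no matching observer")
})

test_that("correlation Bayes factors reproduce independently computed values", {
  # frozen oracle values from numerical integration of the JZS correlation
  # Bayes factor (independent implementation)
  expect_equal(bf_pearson(0.59, 18), 0.6840989, tolerance = 1e-5)
  expect_equal(bf_pearson(0.30, 18), -0.4303078, tolerance = 1e-5)
  expect_equal(bf_pearson(-0.25, 18), -0.5302381, tolerance = 1e-5)
  expect_equal(bf_pearson(0.45, 12), -0.1963379, tolerance = 1e-5)
  expect_equal(bf_pearson(0.80, 10), 1.0358004, tolerance = 1e-5)
  # stretched-beta variant against the closed-form oracle values
  expect_equal(bf_pearson(0.59, 18, "stretched_beta"), 0.8014104, tolerance = 1e-5)
  expect_equal(bf_pearson(0.30, 18, "stretched_beta"), -0.2399609, tolerance = 1e-5)
})

test_that("correlation Bayes factors are sign-symmetric and null-shrinking", {
  for (m in c("jzs", "stretched_beta")) {
    expect_equal(bf_pearson(0.59, 18, m), bf_pearson(-0.59, 18, m),
                 tolerance = 1e-9)
    for (n in c(3, 5, 10, 18, 50))
      expect_lt(bf_pearson(0, n, m), 0)  # BF10 < 1 at r = 0
  }
})

test_that("pearson_with_bf matches the classical test and flags degeneracies", {
  withr::local_seed(8)
  x <- stats::rnorm(18)
  y <- 0.5 * x + stats::rnorm(18)
  res <- pearson_with_bf(x, y)
  ct <- stats::cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_error(pearson_with_bf(x, rep(1, 18)), "zero variance")
  expect_warning(res1 <- pearson_with_bf(x, 2 * x + 3), "capped")
  expect_equal(res1$log10_bf, 1e6)
  expect_equal(res1$p, 0)
})

test_that("the repeated-measures ANOVA matches a hand-prepared worked example", {
  # 3 subjects x A(2) x B(2); F values computed independently beforehand
  vals <- rbind(c(3.0, 5.0, 2.0, 7.0),
                c(4.0, 6.5, 2.5, 8.0),
                c(2.5, 5.5, 3.0, 6.0))
  d <- expand.grid(B = 1:2, A = 1:2, subj = 1:3)[, 3:1]
  d$y <- as.vector(t(vals))
  res <- rm_anova_within(d, dv = "y", subject = "subj", factors = c("A", "B"))
  expect_equal(res$F[res$effect == "A"], 4, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "B"], 147, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "A:B"], 4, tolerance = 1e-8)
  expect_identical(res$df1, c(1, 1, 1))
  expect_identical(res$df2, c(2, 2, 2))
  expect_equal(res$p[res$effect == "B"], 0.0067340833, tolerance = 1e-8)
  # partial eta squared from F and dfs agrees with the SS-based value
  expect_equal(res$eta_p2, res$F * res$df1 / (res$F * res$df1 + res$df2),
               tolerance = 1e-10)
})

test_that("the ANOVA decomposition agrees with aov() error strata", {
  withr::local_seed(77)
  d <- expand.grid(subj = factor(1:8), task = factor(c("s", "d")),
                   num = factor(c(15, 25, 100)))
  d$y <- stats::rnorm(nrow(d)) + 2 * (d$task == "d") + as.numeric(d$num)
  res <- rm_anova_within(d, "y", "subj", c("task", "num"))
  av <- summary(stats::aov(y ~ task * num + Error(subj / (task * num)), data = d))
  get_f <- function(stratum, row) av[[stratum]][[1]][row, "F value"]
  expect_equal(res$F[res$effect == "task"], get_f("Error: subj:task", "task"),
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "num"], get_f("Error: subj:num", "num"),
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "task:num"],
               get_f("Error: subj:task:num", "task:num"), tolerance = 1e-8)
})

test_that("blocking is honoured: relabelling subjects within cells keeps F", {
  withr::local_seed(3)
  d <- expand.grid(subj = 1:6, task = c("s", "d"))
  d$y <- stats::rnorm(12) + 3 * (d$subj %% 3)
  res1 <- rm_anova_within(d, "y", "subj", "task")
  d2 <- d
  relab <- c(4, 6, 1, 3, 2, 5)
  d2$subj <- relab[d2$subj]
  res2 <- rm_anova_within(d2, "y", "subj", "task")
  expect_equal(res1$F, res2$F, tolerance = 1e-10)
})

test_that("null and strong effects behave as constructed", {
  # zero marginal task effect by construction, with nonzero subject x task
  # interaction so the error stratum is well defined
  d0 <- expand.grid(subj = 1:5, task = c("s", "d"))
  base <- c(1, 3, 5, 2, 4)
  delta <- c(1, -1, 2, -2, 0)
  d0$y <- base[d0$subj] + delta[d0$subj] * (d0$task == "d")
  res0 <- rm_anova_within(d0, "y", "subj", "task")
  expect_equal(res0$F[1], 0, tolerance = 1e-10)
  expect_gte(res0$p[1], 0.99)
  # a large within-subject effect at n = 12 is detected essentially always
  withr::local_seed(12)
  ps <- replicate(25, {
    d <- expand.grid(subj = 1:12, task = c("s", "d"))
    d$y <- stats::rnorm(24, sd = 1) + 3 * (d$task == "d") + rep(stats::rnorm(12), 2)
    rm_anova_within(d, "y", "subj", "task")$p[1]
  })
  expect_gte(mean(ps < 0.001), 0.95)
  # BIC Bayes factors point the right way
  dbig <- expand.grid(subj = 1:12, task = c("s", "d"))
  withr::local_seed(13)
  dbig$y <- stats::rnorm(24, sd = 0.5) + 4 * (dbig$task == "d")
  expect_gt(rm_anova_within(dbig, "y", "subj", "task")$log10_bf_bic[1], 0.5)
  expect_lt(res0$log10_bf_bic[1], 0)
})

test_that("unbalanced or undersized designs are rejected", {
  d <- expand.grid(subj = 1:4, task = c("s", "d"))
  d$y <- stats::rnorm(8)
  expect_error(rm_anova_within(d[-1, ], "y", "subj", "task"), "unbalanced")
  d1 <- d[d$subj == 1, ]
  expect_error(rm_anova_within(d1, "y", "subj", "task"), "2 subjects")
})

test_that("the Jarque-Bera statistic matches its definition and references", {
  x <- c(1.2, -0.4, 0.3, 2.1, -1.7, 0.8, 0.05, -0.9, 1.5, -2.2, 0.6, 0.1)
  res <- jarque_bera(x)
  # frozen from an independent implementation of n/6 (S^2 + (K-3)^2/4)
  expect_equal(res$jb, 0.4603460386, tolerance = 1e-9)
  expect_equal(res$p, 0.7943961447, tolerance = 1e-9)
  expect_error(jarque_bera(rep(1, 20)), "zero variance")
  expect_error(jarque_bera(1:5), "at least 8")
})

test_that("Jarque-Bera holds its nominal size and catches heavy tails", {
  withr::local_seed(2)
  xs <- matrix(stats::rnorm(1000 * 4000), nrow = 1000)
  ps <- apply(xs, 2, function(v) jarque_bera(v)$p)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.015)
  heavy <- stats::rt(1000, df = 2)
  expect_lt(jarque_bera(heavy)$p, 1e-6)
  expect_gt(jarque_bera(heavy)$jb, 50)
})
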