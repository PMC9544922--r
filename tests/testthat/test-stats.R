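test_that("one-way ANOVA matches its sums-of-squares definition", {
  # fixed 3 x 5 fixture against an independently coded SS decomposition
  g <- list(a = c(5.1, 4.8, 6.0, 5.5, 5.2),
            b = c(6.3, 6.8, 5.9, 7.1, 6.5),
            c = c(4.2, 4.9, 4.4, 5.0, 4.6))
  res <- one_way_anova(g)
  y <- unlist(g); lab <- rep(names(g), lengths(g))
  gm <- mean(y)
  ssb <- sum(tapply(y, lab, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum((y - ave(y, lab))^2)
  F_oracle <- (ssb / 2) / (ssw / 12)
  expect_equal(res$statistic, F_oracle, tolerance = 1e-10)
  expect_equal(res$df, c(2, 12))
  expect_equal(res$p, pf(F_oracle, 2, 12, lower.tail = FALSE), tolerance = 1e-12)
  # cross-check against the built-in linear-model route
  expect_equal(res$statistic,
               unname(summary(aov(y ~ lab))[[1]]$`F value`[1]),
               tolerance = 1e-8)
  # identical group means with spread: F = 0, p = 1
  eq <- one_way_anova(list(c(1, 2, 3), c(2, 1, 3)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  # two groups: F equals the squared pooled-variance t statistic
  x <- c(3.1, 2.8, 3.6, 3.3); yv <- c(4.0, 4.4, 3.8, 4.1)
  tt <- t.test(x, yv, var.equal = TRUE)
  expect_equal(one_way_anova(list(x, yv))$statistic,
               unname(tt$statistic)^2, tolerance = 1e-10)
  expect_error(one_way_anova(list(c(1, 2))), "two groups")
  expect_error(one_way_anova(list(1, c(1, 2))), "two values")
})

test_that("one-way ANOVA p-values are uniform under the Gaussian null", {
  set.seed(314)
  ps <- replicate(2000, {
    one_way_anova(list(rnorm(5), rnorm(5), rnorm(5)))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("post-hoc adjustments match reference implementations", {
  g <- list(a = c(24, 28, 37, 30), b = c(37, 44, 31, 35),
            c = c(42, 47, 52, 38))
  df <- data.frame(v = unlist(g), gl = factor(rep(names(g), lengths(g))))
  tk <- pairwise_posthoc(g, "tukey")
  ref <- TukeyHSD(aov(v ~ gl, df))$gl[, "p adj"]
  expect_equal(tk$p_adj, unname(ref[c("b-a", "c-a", "c-b")]),
               tolerance = 1e-8)
  # one comparison: bonferroni equals the raw pooled t-test p
  two <- list(x = c(1.2, 1.9, 1.4), y = c(2.3, 2.9, 2.6))
  bf <- pairwise_posthoc(two, "bonferroni")
  raw <- t.test(two$x, two$y, var.equal = TRUE)$p.value
  expect_equal(bf$p_adj, raw, tolerance = 1e-10)
  # identical groups: every adjusted p is 1
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_true(all(pairwise_posthoc(same, "tukey")$p_adj == 1))
  expect_true(all(pairwise_posthoc(same, "bonferroni")$p_adj == 1))
  expect_error(pairwise_posthoc(g, "holm"))
})

test_that("Monte-Carlo Dunnett agrees with the multivariate-t reference", {
  skip_if_not_installed("multcomp")
  g <- list(ctrl = c(24, 28, 37, 30), t1 = c(37, 44, 31, 35),
            t2 = c(42, 47, 52, 38))
  dn <- pairwise_posthoc(g, "dunnett_mc", control = 1, nsim = 2e5, seed = 1)
  df <- data.frame(v = unlist(g), gl = factor(rep(names(g), lengths(g))))
  ref <- summary(multcomp::glht(aov(v ~ gl, df),
                                linfct = multcomp::mcp(gl = "Dunnett")))
  expect_equal(dn$p_adj, as.numeric(ref$test$pvalues), tolerance = 0.01)
})

test_that("split-plot RM ANOVA matches an independent decomposition", {
  tab <- make_panel(group_eff = 0.5, week_eff = 0.2, seed = 5)
  res <- rm_anova_split_plot(tab, gg_correction = FALSE)
  # oracle: base R aov with an explicit error stratum
  tab$week_f <- factor(tab$week)
  tab$animal_f <- factor(tab$animal_id)
  or <- summary(aov(value ~ group * week_f + Error(animal_f / week_f),
                    data = tab))
  F_group <- or[["Error: animal_f"]][[1]]$`F value`[1]
  F_time <- or[["Error: animal_f:week_f"]][[1]]$`F value`[1]
  F_int <- or[["Error: animal_f:week_f"]][[1]]$`F value`[2]
  expect_equal(res$effect_terms$Treatment$statistic, F_group, tolerance = 1e-8)
  expect_equal(res$effect_terms$Time$statistic, F_time, tolerance = 1e-8)
  expect_equal(res$effect_terms$Interaction$statistic, F_int, tolerance = 1e-8)
  expect_error(rm_anova_split_plot(tab[-1, ]), "unbalanced")
})

test_that("Greenhouse-Geisser epsilon is bounded and matches the oracle", {
  for (sd in 1:10) {
    k <- sample(3:6, 1)
    tab <- make_panel(weeks = seq_len(k), seed = sd)
    res <- rm_anova_split_plot(tab)
    expect_gte(res$epsilon, 1 / (k - 1) - 1e-12)
    expect_lte(res$epsilon, 1 + 1e-12)
    # independent covariance-moment formula
    an <- unique(tab$animal_id)
    Y <- matrix(NA_real_, length(an), k)
    Y[cbind(match(tab$animal_id, an), tab$week)] <- tab$value
    grp <- tapply(tab$group, tab$animal_id, `[`, 1)[an]
    eps_o <- gg_epsilon_oracle(Y, grp)
    expect_equal(res$epsilon, min(1, max(1 / (k - 1), eps_o)),
                 tolerance = 1e-10)
    # corrected dfs are epsilon * uncorrected
    expect_equal(res$effect_terms$Time$df[1], res$epsilon * (k - 1))
  }
})

test_that("epsilon approaches 1 under compound symmetry as n grows", {
  # exchangeable within-subject covariance is spherical, so GG epsilon
  # should be near its upper bound with many subjects
  set.seed(77)
  k <- 5; n <- 200
  subj <- rnorm(n, 0, 2)
  tab <- expand.grid(animal_id = paste0("s", 1:n), week = 1:k,
                     stringsAsFactors = FALSE)
  tab$group <- ifelse(as.integer(sub("s", "", tab$animal_id)) <= n / 2,
                      "A", "B")
  tab$value <- subj[as.integer(sub("s", "", tab$animal_id))] +
    rnorm(nrow(tab))
  expect_gt(rm_anova_split_plot(tab)$epsilon, 0.95)
})

test_that("exact Mann-Whitney reproduces enumeration on small samples", {
  # 5 vs 3 fixture whose exact two-tailed p is 44/56
  x <- c(29, 9, 58, 18, 2); y <- c(11, 38, 25)
  res <- mann_whitney_exact(x, y)
  expect_equal(res$p, 44 / 56, tolerance = 1e-12)
  expect_equal(res$n_assignments, 56)
  expect_equal(mann_whitney_exact(c(1, 2), c(3, 4))$p, 2 / 6,
               tolerance = 1e-12)
  # symmetry in the two samples
  expect_equal(mann_whitney_exact(y, x)$p, res$p)
  expect_error(mann_whitney_exact(numeric(), y), "non-empty")
  expect_error(mann_whitney_exact(rnorm(15), rnorm(15)), "enumerate")
})

test_that("exact Mann-Whitney equals a brute-force oracle, ties included", {
  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:min(6, 10 - n1), 1)
    # integer draws so ties occur often
    x <- sample(1:6, n1, replace = TRUE)
    y <- sample(1:6, n2, replace = TRUE)
    res <- mann_whitney_exact(x, y)
    or <- mw_oracle(x, y)
    expect_equal(res$statistic, or$U)
    expect_equal(res$p, or$p, tolerance = 1e-12)
  }
})

test_that("exact Mann-Whitney is conservative under the null", {
  set.seed(2024)
  n_rep <- 2000
  rej <- 0L
  for (i in seq_len(n_rep)) {
    if (mann_whitney_exact(rnorm(4), rnorm(4))$p < 0.05) rej <- rej + 1L
  }
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(rej / n_rep, 0.05 + 2 * se)
})
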