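test_that("mixed ANOVA nulls out absent effects in constructed data", {
  # identical social/nonsocial values per participant; groups differ by a
  # constant: stimulus and interaction F are zero, group F is positive
  set.seed(1)
  base <- rnorm(12, 50, 5)
  long <- data.frame(
    participant_id = rep(sprintf("p%02d", 1:12), 2),
    group = rep(rep(c("NT", "AUT"), each = 6), 2),
    stimulus_type = rep(c("social", "nonsocial"), each = 12),
    value = rep(base + rep(c(0, 10), each = 6), 2))
  an <- mixed_anova_2x2(long)
  expect_equal(an$F[an$effect == "stimulus_type"], 0)
  expect_equal(an$F[an$effect == "group:stimulus_type"], 0)
  expect_gt(an$F[an$effect == "group"], 0)
  expect_equal(an$df1, rep(1, 3))
  expect_equal(an$df2, rep(10, 3))  # (1, N - 2) for every effect
})

test_that("mixed ANOVA matches the projection oracle on random datasets", {
  for (seed in 1:10) {
    long <- random_long(sample(4:8, 1), sample(4:8, 1), seed = seed)
    an <- mixed_anova_2x2(long)
    orc <- oracle_mixed_anova(long)
    expect_equal(an$F, orc$F, tolerance = 1e-10)
    expect_equal(an$p, orc$p, tolerance = 1e-10)
    expect_equal(an$eta_p2, orc$eta_p2, tolerance = 1e-10)
    # partial eta squared identity
    expect_equal(an$eta_p2,
                 an$F * an$df1 / (an$F * an$df1 + an$df2),
                 tolerance = 1e-12)
  }
})

test_that("mixed ANOVA rejects unbalanced within-measurements", {
  long <- random_long(4, 4, seed = 2)
  expect_error(mixed_anova_2x2(long[-1, ]), "p01")
})

test_that("Wilcoxon signed-rank matches exact enumeration", {
  # all differences positive, n = 5: two-sided p = 2/2^5
  w <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(w$p, 0.0625)
  expect_equal(w$r, 1)
  # identical pairs: degenerate
  w0 <- wilcoxon_signed_rank(1:6, 1:6)
  expect_equal(w0$p, 1)
  expect_equal(w0$r, 0)
  # random tie-free pairs up to n = 8 against the 2^n enumeration oracle
  set.seed(42)
  for (rep_i in 1:20) {
    n <- sample(5:8, 1)
    x <- rnorm(n); y <- rnorm(n)
    w <- wilcoxon_signed_rank(x, y)
    expect_equal(w$p, oracle_wilcoxon_exact(x, y))
  }
})

test_that("Mann-Whitney matches exact enumeration and handles ties", {
  m <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(m$statistic, 0)
  expect_equal(m$p, 0.1)
  expect_equal(m$r, 1)
  # fully tied samples carry no ordering information
  m0 <- mann_whitney_u(rep(3, 5), rep(3, 5))
  expect_equal(m0$r, 0)
  expect_equal(m0$p, 1)
  # random tie-free samples against the rank-assignment enumeration oracle
  set.seed(7)
  for (rep_i in 1:20) {
    na <- sample(3:5, 1); nb <- sample(3:5, 1)
    a <- rnorm(na); b <- rnorm(nb)
    m <- mann_whitney_u(a, b)
    expect_equal(m$p, oracle_mwu_exact(a, b))
  }
})

test_that("exact and approximate p agree near the enumeration cutoff", {
  set.seed(9)
  for (rep_i in 1:10) {
    a <- rnorm(7); b <- rnorm(7)   # just above the n = 12 exact cutoff
    pe <- mann_whitney_u(a, b, exact = TRUE)$p
    pa <- mann_whitney_u(a, b, exact = FALSE)$p
    expect_lt(abs(pe - pa), 0.05)
    x <- rnorm(20); y <- x + rnorm(20, 0.2)
    pe <- wilcoxon_signed_rank(x, y, exact = TRUE)$p
    pa <- wilcoxon_signed_rank(x, y, exact = FALSE)$p
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("rank-biserial r hits +/-1 exactly under complete separation", {
  expect_equal(mann_whitney_u(1:5, 6:10)$r, 1)
  expect_equal(mann_whitney_u(6:10, 1:5)$r, -1)
  expect_equal(wilcoxon_signed_rank(2:9, (2:9) - 1)$r, 1)
  expect_equal(wilcoxon_signed_rank((2:9) - 1, 2:9)$r, -1)
})

test_that("ANCOVA matches the nested-model oracle and limits", {
  set.seed(15)
  n <- 40
  group <- rep(c("NT", "AUT"), each = n / 2)
  age <- rnorm(n, 24, 4)
  value <- 50 + 2 * (group == "AUT") + rnorm(n)
  a <- ancova_group(value, group, age)
  # explicit two-model residual-sum-of-squares oracle
  rss0 <- sum(resid(lm(value ~ age))^2)
  rss1 <- sum(resid(lm(value ~ age + factor(group)))^2)
  f_orc <- ((rss0 - rss1) / 1) / (rss1 / (n - 3))
  expect_equal(a$F, f_orc, tolerance = 1e-10)
  expect_equal(a$p, pf(f_orc, 1, n - 3, lower.tail = FALSE),
               tolerance = 1e-10)
  # value fully explained by a shared age slope: group F collapses
  v2 <- 3 * age
  a2 <- ancova_group(v2, group, age)
  expect_lt(a2$F, 0.1)
  # constant covariate warns and reduces to one-way ANOVA
  expect_warning(a3 <- ancova_group(value, group, rep(5, n)), "constant")
  f_aov <- summary(aov(value ~ factor(group)))[[1]][1, "F value"]
  expect_equal(a3$F, f_aov, tolerance = 1e-10)
})

test_that("ANCOVA approaches the unadjusted ANOVA when age is irrelevant", {
  set.seed(16)
  n <- 600
  group <- rep(c("NT", "AUT"), each = n / 2)
  age <- rnorm(n)                       # independent of value and group
  value <- 10 + (group == "AUT") + rnorm(n)
  f_adj <- ancova_group(value, group, age)$F
  f_raw <- summary(aov(value ~ factor(group)))[[1]][1, "F value"]
  expect_lt(abs(f_adj - f_raw) / f_raw, 0.1)
})

test_that("per-movie comparisons cover the expected movies and measures", {
  cfg <- cohort_config(n_per_group = c(NT = 10, AUT = 8), seed = 33)
  res <- simulate_and_extract(cfg)
  tab <- per_movie_comparisons(res$cohort)
  # 9 non-mixed movies x 2 measures + 2 mixed movies x TFF
  expect_equal(nrow(tab), 20)
  expect_equal(sum(tab$measure == "br"), 9)
  expect_true(all(tab$n_nt == 10 & tab$n_aut == 8))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(abs(tab$r) <= 1))
})

test_that("sensitivity subset filters on mean TFF across analyzed movies", {
  co <- data.frame(participant_id = c("a", "b", "c"), group = "NT",
                   mean_tff_social = c(95, 70, 85),
                   mean_tff_nonsocial = c(90, 60, 88))
  # no per-movie columns: falls back to aggregate endpoints
  kept <- sensitivity_subset(co, 80)
  expect_equal(kept$participant_id, c("a", "c"))
  expect_equal(nrow(sensitivity_subset(co, 0)), 3)
  expect_error(sensitivity_subset(co, 100), "floor")
})

test_that("clinical correlations recover hand-computable cases", {
  co <- data.frame(group = "AUT", mean_tff_social = c(0, 1, 2),
                   ados_sa = c(1, 3, 5))
  tab <- clinical_correlations(co, "mean_tff_social", "ados_sa")
  expect_equal(tab$r, 1)
  co2 <- data.frame(group = "AUT", mean_tff_social = c(0, 1, 2),
                    ados_sa = c(0, 1, 0))
  tab2 <- clinical_correlations(co2, "mean_tff_social", "ados_sa")
  expect_equal(tab2$r, 0)
  co3 <- data.frame(group = "AUT", mean_tff_social = c(0, 1, 2),
                    ados_sa = rep(4, 3))
  expect_warning(tab3 <- clinical_correlations(co3, "mean_tff_social",
                                               "ados_sa"),
                 "not estimable")
  expect_true(is.na(tab3$r))
})

test_that("demographic tests reproduce hand-computed statistics", {
  # sex split of the screening cohort: chi-square from the printed counts
  manifest <- data.frame(
    group = rep(c("NT", "AUT"), c(416, 43)),
    sex = c(rep(c("boy", "girl"), c(209, 207)),
            rep(c("boy", "girl"), c(32, 11))),
    age_months = 20)
  tab <- demographics_tests(manifest)
  obs <- rbind(c(209, 207), c(32, 11))
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  chi_hand <- sum((obs - expected)^2 / expected)
  expect_equal(tab$statistic[tab$variable == "sex"], chi_hand,
               tolerance = 1e-10)
  # identical compositions give chi-square zero
  m2 <- data.frame(group = rep(c("NT", "AUT"), each = 20),
                   sex = rep(c("boy", "girl"), 20),
                   age_months = rnorm(40, 22, 3))
  t2 <- demographics_tests(m2)
  expect_equal(t2$statistic[t2$variable == "sex"], 0)
  expect_true(t2$p[t2$variable == "age_months"] >= 0)
})
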