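test_that("exact Mann-Whitney matches full enumeration and known worked examples", {
  # complete separation at n = 5 per group: p = 2/252
  res <- exact_mann_whitney(1:5, 6:10)
  expect_equal(res$p_value, 2 / 252)
  expect_equal(round(res$p_value, 3), 0.008)
  expect_equal(res$statistic, 25)
  # single observations: p = 1
  expect_equal(exact_mann_whitney(1, 2)$p_value, 1)
  # interleaved: all 6 assignments enumerated by hand give 2/3
  expect_equal(exact_mann_whitney(c(1, 3), c(2, 4))$p_value, 2 / 3)
  # random instances vs the enumeration oracle (with and without ties)
  set.seed(5)
  for (i in 1:12) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- sample(1:8, n1, replace = TRUE)
    b <- sample(1:8, n2, replace = TRUE)
    expect_equal(exact_mann_whitney(a, b)$p_value, enum_mwu_p(a, b),
                 info = sprintf("instance %d", i))
  }
  expect_error(exact_mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("U and W null distributions match enumeration and sum to 1", {
  for (n1 in 1:5) for (n2 in 1:5) {
    counts <- mwu_null_counts(n1, n2)
    expect_equal(unname(counts), enum_mwu_counts(n1, n2))
    expect_equal(sum(counts), choose(n1 + n2, n1))
  }
  # larger sizes still sum correctly (convolution vs closed-form total)
  for (n in c(10, 12)) {
    expect_equal(sum(mwu_null_counts(n / 2, n / 2)), choose(n, n / 2))
  }
  for (n in c(3, 5, 8, 12)) {
    counts <- renaldce:::signed_rank_null_counts(seq_len(n))
    expect_equal(unname(counts), enum_signed_rank_counts(n))
    expect_equal(sum(counts), 2^n)
  }
})

test_that("exact signed-rank test reproduces the printed paired p-values", {
  # all-positive differences: p = 2 / 2^n
  expect_equal(exact_wilcoxon_signed_rank(c(1, 2, 3, 4))$p_value, 0.125)
  expect_equal(exact_wilcoxon_signed_rank(c(1, 2, 3))$p_value, 0.25)
  # rank-3 magnitude negative among five: p = 10/32
  res <- exact_wilcoxon_signed_rank(c(1, 2, -3, 4, 5))
  expect_equal(res$p_value, 10 / 32)
  expect_equal(res$statistic, 3)  # W = min(W+, W-)
  # zeros are dropped
  res0 <- exact_wilcoxon_signed_rank(c(0, 1, 2, 3, 4))
  expect_equal(res0$p_value, 0.125)
  expect_equal(res0$n_zero, 1)
  expect_error(exact_wilcoxon_signed_rank(c(0, 0)), "zero")
  # random instances vs sign-enumeration oracle
  set.seed(9)
  for (i in 1:10) {
    d <- round(rnorm(sample(3:8, 1)), 2)
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(exact_wilcoxon_signed_rank(d)$p_value, enum_wilcoxon_p(d))
  }
})

test_that("exact tests agree with wilcox.test on untied data", {
  set.seed(31)
  for (i in 1:8) {
    a <- rnorm(5); b <- rnorm(5)
    expect_equal(exact_mann_whitney(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value)
    d <- rnorm(6)
    expect_equal(exact_wilcoxon_signed_rank(d)$p_value,
                 wilcox.test(d, exact = TRUE)$p.value)
  }
})

test_that("rank-biserial effect sizes match their pair-counting definitions", {
  expect_equal(rank_biserial_unpaired(6:10, 1:5), 1)
  expect_equal(rank_biserial_unpaired(c(1, 2, 3, 4, 10), 5:9), -0.6)
  expect_equal(rank_biserial_unpaired(1:4, 1:4), 0)
  expect_equal(rank_biserial_paired(c(1, 2, 3, 4)), 1)
  expect_equal(rank_biserial_paired(c(1, 2, -3, 4, 5)), 0.6)
  # relationship r = 1 - 2 U_b / (n1 n2) without ties, and |r| <= 1 always
  set.seed(13)
  for (i in 1:20) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
    r <- rank_biserial_unpaired(a, b)
    u_b <- sum(outer(a, b, "<"))
    expect_equal(r, 1 - 2 * u_b / (length(a) * length(b)))
    expect_lte(abs(r), 1)
    d <- rnorm(sample(2:8, 1))
    expect_lte(abs(rank_biserial_paired(d)), 1)
  }
})

test_that("exact p-values are valid (conservative) under the null at n1 = n2 = 5", {
  # full enumeration: distribution of the p-value over all 252 assignments
  pool <- 1:10
  combos <- utils::combn(10, 5)
  ps <- apply(combos, 2, function(idx)
    exact_mann_whitney(pool[idx], pool[-idx])$p_value)
  for (alpha in unique(ps)) {
    expect_lte(mean(ps <= alpha), alpha + 1e-12)
  }
})

test_that("Hodges-Lehmann estimate and CI match brute-force enumeration", {
  expect_equal(hodges_lehmann(c(2, 3, 4), c(1, 2, 3))$estimate, 1)
  # pure shift: b = a + c
  a <- c(1.2, 2.4, 3.1, 4.8)
  hl <- hodges_lehmann(a + 2.5, a)
  expect_equal(hl$estimate, 2.5)
  # n1 = n2 = 5: k = 3 from the exact U cdf
  hl5 <- hodges_lehmann(rnorm(5), rnorm(5))
  expect_equal(hl5$k, 3)
  set.seed(17)
  for (i in 1:15) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
    hl <- hodges_lehmann(a, b)
    expect_equal(hl$estimate, brute_hl_estimate(a, b))
    d <- sort(as.vector(outer(a, b, "-")))
    expect_equal(hl$ci_low, d[hl$k])
    expect_equal(hl$ci_high, d[length(d) + 1 - hl$k])
    expect_lte(hl$ci_low, hl$estimate)
    expect_gte(hl$ci_high, hl$estimate)
  }
  # equivariance: shifting sample a shifts estimate and both CI ends
  a <- rnorm(6); b <- rnorm(5)
  h0 <- hodges_lehmann(a, b)
  h1 <- hodges_lehmann(a + 3, b)
  expect_equal(h1$estimate, h0$estimate + 3)
  expect_equal(h1$ci_low, h0$ci_low + 3)
  expect_equal(h1$ci_high, h0$ci_high + 3)
  # coverage unattainable at tiny n
  expect_equal(hodges_lehmann(1:2, 3:4)$flag, "coverage_unattainable")
})

test_that("paired Hodges-Lehmann agrees with the Walsh-average definition", {
  set.seed(23)
  for (i in 1:10) {
    d <- rnorm(sample(6:9, 1))
    hl <- hodges_lehmann_paired(d)
    w <- outer(d, d, "+") / 2
    walsh <- sort(w[upper.tri(w, diag = TRUE)])
    expect_equal(hl$estimate, median(walsh))
    expect_equal(hl$ci_low, walsh[hl$k])
    # cross-check against wilcox.test's exact HL interval
    wt <- wilcox.test(d, conf.int = TRUE, exact = TRUE)
    expect_equal(hl$estimate, unname(wt$estimate))
    expect_equal(hl$ci_low, wt$conf.int[1])
    expect_equal(hl$ci_high, wt$conf.int[2])
  }
  # below the attainable 95% coverage the widest interval is returned
  small <- hodges_lehmann_paired(c(1, 2, 3, 4))
  expect_equal(small$flag, "coverage_unattainable")
  expect_equal(small$ci_low, 1)
  expect_equal(small$ci_high, 4)
})

test_that("compare_groups assembles unpaired and paired reports correctly", {
  tab <- data.frame(
    animal_id = rep(sprintf("a%02d", 1:10), each = 3),
    group = rep(c("16h", "30min"), each = 15),
    roi_label = rep(c("transplant", "left_native", "right_native"), 10),
    median_ktrans = c(rbind(6:10, matrix(runif(20, 0.5, 1), 2))),
    median_vp = runif(30, 20, 35))
  tab$median_ktrans[tab$group == "30min" & tab$roi_label == "transplant"] <- 1:5
  cmp <- compare_groups(tab, "ktrans", "unpaired", arm1 = "16h",
                        arm2 = "30min")
  expect_equal(cmp$p_value, 2 / 252)
  expect_equal(cmp$effect_size, 1)
  expect_true(cmp$significant)
  expect_equal(cmp$n1, 5)
  # paired: transplant vs left within 16h (all transplant values larger)
  cmp2 <- compare_groups(tab, "ktrans", "paired", arm1 = "transplant",
                         arm2 = "left_native", group = "16h")
  expect_equal(cmp2$p_value, 2 / 32)
  expect_equal(cmp2$effect_size, 1)
  # dropping an incomplete animal reduces n and is reported
  tab2 <- tab[!(tab$animal_id == "a01" & tab$roi_label == "left_native"), ]
  cmp3 <- compare_groups(tab2, "ktrans", "paired", arm1 = "transplant",
                         arm2 = "left_native", group = "16h")
  expect_equal(cmp3$n1, 4)
  expect_equal(cmp3$n_dropped, 1)
  expect_equal(cmp3$p_value, 2 / 16)
  # identical groups: p = 1, effect 0
  tab3 <- tab
  tab3$median_ktrans[tab3$roi_label == "transplant"] <- rep(1:5, 2)
  cmp4 <- compare_groups(tab3, "ktrans", "unpaired", arm1 = "16h",
                         arm2 = "30min")
  expect_equal(cmp4$p_value, 1)
  expect_equal(cmp4$effect_size, 0)
  expect_error(compare_groups(tab[tab$animal_id == "a01", ], "ktrans",
                              "unpaired", arm1 = "16h", arm2 = "30min"),
               "at least 2")
})

test_that("stats_report covers the full study layout", {
  set.seed(41)
  tab <- data.frame(
    animal_id = rep(sprintf("a%02d", 1:10), each = 3),
    group = rep(c("16h", "30min"), each = 15),
    roi_label = rep(c("transplant", "left_native", "right_native"), 10),
    median_ktrans = runif(30, 0.5, 3),
    median_vp = runif(30, 20, 35))
  rep_ <- stats_report(tab)
  # 2 parameters x (1 intergroup + 2 groups x 2 native rois)
  expect_equal(nrow(rep_), 10)
  expect_setequal(unique(rep_$design), c("unpaired", "paired"))
  expect_true(all(rep_$p_value > 0 & rep_$p_value <= 1))
  expect_true(all(abs(rep_$effect_size) <= 1))
  # single-group table: intergroup rows absent, intragroup still present
  rep1 <- stats_report(tab[tab$group == "16h", ])
  expect_equal(nrow(rep1), 4)
  expect_true(all(rep1$design == "paired"))
})
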