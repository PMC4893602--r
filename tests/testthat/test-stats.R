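# rank statistics: Wilcoxon, van Elteren, Bonferroni, star tables

test_that("rank-sum test: degenerate, separated and oracle-checked cases", {
  # identical samples -> p = 1
  expect_equal(wilcoxonRankSum(c(1, 1, 2), c(1, 2, 1))$p, 1)
  # complete separation: rank sum of a is the minimum possible
  w <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$statistic, 6)
  # exact path matches complete enumeration to numerical precision
  set.seed(21)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(5) + i / 4
    expect_equal(wilcoxonRankSum(a, b)$p, exactRankSumP(a, b),
                 tolerance = 1e-3)
  }
  # normal path agrees with the base oracle on large samples
  set.seed(22)
  a <- rnorm(60); b <- rnorm(55) + 0.3
  expect_equal(wilcoxonRankSum(a, b)$p,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-12)
  # tie correction agrees with the base oracle too
  a2 <- round(rnorm(40), 1); b2 <- round(rnorm(40) + 0.4, 1)
  expect_equal(wilcoxonRankSum(a2, b2)$p,
               wilcox.test(a2, b2, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("van Elteren reduces exactly to Wilcoxon for one stratum", {
  set.seed(31)
  a <- rnorm(30); b <- rnorm(32) + 0.4
  v <- vanElteren(c(a, b), rep(c("A", "B"), c(30, 32)), rep(1, 62), "A", "B")
  w <- wilcoxonRankSum(a, b)
  expect_lt(abs(v$p - w$p), 1e-12)
  expect_equal(v$nStrata, 1L)
})

test_that("van Elteren handles missing strata and invariances", {
  set.seed(32)
  val <- rnorm(90)
  grp <- rep(c("A", "B", "A"), each = 30)
  st <- rep(c("s1", "s1", "s2"), each = 30)   # s2 has no B
  expect_warning(v <- vanElteren(val, grp, st, "A", "B"), "dropping")
  expect_error(vanElteren(val[1:30], grp[1:30], st[1:30], "A", "B"),
               "no stratum")
  # invariance to monotone stratum relabeling and value translation
  val2 <- rnorm(120); grp2 <- rep(rep(c("A", "B"), each = 15), 4)
  st2 <- rep(1:4, each = 30)
  v1 <- vanElteren(val2, grp2, st2, "A", "B")
  v2 <- vanElteren(val2, grp2, c(10, 20, 30, 40)[st2], "A", "B")
  v3 <- vanElteren(val2 + 100, grp2, st2, "A", "B")
  expect_equal(v1$p, v2$p)
  expect_equal(v1$p, v3$p)
})

test_that("stratified shifts pool evidence across strata", {
  # consistent shift in both strata: combined p beats each single-stratum p
  a1 <- c(1, 2, 3, 4); b1 <- c(3.5, 4.5, 5, 6)
  a2 <- c(11, 12, 13, 14); b2 <- c(13.5, 14.5, 15, 16)
  val <- c(a1, b1, a2, b2)
  grp <- rep(rep(c("A", "B"), each = 4), 2)
  st <- rep(1:2, each = 8)
  pBoth <- vanElteren(val, grp, st, "A", "B")$p
  p1 <- vanElteren(val[1:8], grp[1:8], st[1:8], "A", "B")$p
  p2 <- vanElteren(val[9:16], grp[9:16], st[9:16], "A", "B")$p
  expect_lt(pBoth, p1)
  expect_lt(pBoth, p2)
})

test_that("type-I error is calibrated under the stratified null", {
  set.seed(1)
  rej <- mean(replicate(500, {
    v <- rnorm(240)
    vanElteren(v, rep(rep(c("A", "B"), each = 15), 8),
               rep(1:8, each = 30), "A", "B")$p < 0.05
  }))
  expect_gt(rej, 0.025)
  expect_lt(rej, 0.075)
})

test_that("Bonferroni correction caps, scales, preserves order", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 6), 1.0)
  expect_equal(bonferroni(c(0.2, 0.4)), c(0.4, 0.8))
  expect_equal(bonferroni(0.37, m = 1), 0.37)
  p <- c(0.001, 0.01, 0.04)
  expect_equal(order(bonferroni(p, m = 10)), order(p))
  expect_error(bonferroni(1.2), "0, 1")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "family size")
})

test_that("star coding and the significance grid", {
  expect_equal(significanceStars(c(0.04, 0.0005, 0.2, 0.009)),
               c("*", "***", "ns", "**"))
  res <- data.frame(assay = rep(c("MSD", "AFM"), each = 2),
                    comparison = rep(c("X vs C", "Y vs C"), 2),
                    p_adj = c(0.04, 0.2, 0.0005, 0.009))
  g <- significanceTable(res)
  expect_equal(g$`X vs C`[g$assay == "MSD"], "*")
  expect_equal(g$`Y vs C`[g$assay == "MSD"], "ns")
  expect_equal(g$`X vs C`[g$assay == "AFM"], "***")
  expect_equal(g$`Y vs C`[g$assay == "AFM"], "**")
})

test_that("compareToControl assembles corrected comparisons", {
  set.seed(41)
  val <- c(rnorm(40), rnorm(40) + 2, rnorm(40))
  grp <- rep(c("CC", "X", "Y"), each = 40)
  st <- rep(rep(1:4, each = 10), 3)
  res <- compareToControl(val, grp, st, control = "CC", assay = "MSD")
  expect_equal(nrow(res), 2)
  expect_equal(res$p_adj, pmin(1, 2 * res$p_raw))
  expect_lt(res$p_adj[res$comparison == "X vs CC"], 0.001)
  expect_gt(res$p_adj[res$comparison == "Y vs CC"], 0.05)
})
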