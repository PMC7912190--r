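# Region/cluster comparison battery.

test_that("the normality gate routes by Shapiro-Wilk on residuals", {
  g <- rep(c("a", "b"), each = 25)
  exact_norm <- c(qnorm(ppoints(25)), qnorm(ppoints(25)) + 5)
  expect_equal(normality_gate(exact_norm, g)$decision, "normal")
  # heavy right skew is caught in nearly every replicate
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    normality_gate(rlnorm(32, sdlog = 1.5), rep(1:4, each = 8))$decision ==
      "non-normal"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_error(normality_gate(c(1, 2), c("a", "b")), "at least 3")
  expect_equal(normality_gate(rep(1, 10), rep(1:2, 5))$decision, "non-normal")
})

test_that("two-group ANOVA equals the equal-variance t-test", {
  set.seed(1)
  x <- rnorm(20); g <- rep(c("a", "b"), each = 10)
  a <- anova_tukey(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)
  expect_equal(a$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("widely separated groups earn all-distinct letters", {
  set.seed(2)
  g <- rep(letters[1:4], each = 8)
  x <- rnorm(32, sd = 1) + rep(c(0, 10, 20, 30), each = 8)
  a <- anova_tukey(x, g)
  expect_equal(length(unique(a$letters)), 4)
  # letter display is invariant to group-label permutation
  perm <- sample(seq_along(x))
  a2 <- anova_tukey(x[perm], g[perm])
  expect_equal(a2$letters[names(a$letters)], a$letters)
})

test_that("ANOVA F matches the sum-of-squares oracle on a 4x8 fixture", {
  set.seed(3)
  g <- rep(c("SL", "SH", "NL", "NH"), each = 8)
  x <- rnorm(32) + rep(c(2, 0, 2.5, 0.3), each = 8)
  a <- anova_tukey(x, g)
  expect_equal(a$statistic, oracle_anova_F(x, g), tolerance = 1e-10)
  expect_warning(anova_tukey(c(x, 99), c(g, "tiny")), "excluding groups")
})

test_that("Kruskal-Wallis matches oracles and the two-group identity", {
  set.seed(4)
  g <- rep(c("a", "b", "c"), each = 7)
  x <- round(rnorm(21), 1)  # force ties
  k <- kruskal_dunn(x, g)
  expect_equal(k$statistic, oracle_kw_H(x, g), tolerance = 1e-10)
  # two groups: KW p equals the tie-corrected normal-approximation
  # Mann-Whitney p without continuity correction
  g2 <- rep(c("a", "b"), c(9, 12))
  x2 <- round(rnorm(21), 1)
  k2 <- kruskal_dunn(x2, g2)
  w <- suppressWarnings(wilcox.test(x2 ~ g2, exact = FALSE, correct = FALSE))
  expect_equal(k2$p, w$p.value, tolerance = 1e-10)
  # all-identical values: H = 0, p = 1
  k0 <- kruskal_dunn(rep(2, 12), rep(1:3, each = 4))
  expect_equal(k0$statistic, 0)
  expect_equal(k0$p, 1)
})

test_that("permuted labels rarely reach significance", {
  set.seed(5)
  base <- rnorm(32)
  hits <- vapply(1:200, function(i) {
    kruskal_dunn(sample(base), rep(1:4, each = 8))$p > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.94)
})

test_that("Dunn z tests use pooled ranks with Holm adjustment", {
  set.seed(6)
  g <- rep(c("a", "b", "c"), each = 10)
  x <- rnorm(30) + rep(c(0, 0, 3), each = 10)
  dn <- dunn_test(x, g)
  expect_equal(dn$p_adjusted, p.adjust(dn$p, "holm"))
  # symmetric in group order: z flips sign
  dn_ba <- dunn_test(x, factor(g, levels = c("c", "b", "a")))
  expect_equal(sort(abs(dn$z)), sort(abs(dn_ba$z)), tolerance = 1e-12)
})

test_that("Fisher battery matches enumeration and handles edge tables", {
  f <- fisher_battery(matrix(c(8, 0, 0, 8), 2, byrow = TRUE))
  expect_equal(f$p, 2 / 12870, tolerance = 1e-10)
  expect_equal(f$method, "exact")
  f1 <- fisher_battery(matrix(c(5, 3, 5, 3), 2, byrow = TRUE))
  expect_equal(f1$p, 1)
  expect_error(fisher_battery(matrix(c(1.5, 2, 3, 4), 2)), "integers")
  expect_warning(fisher_battery(matrix(c(4, 2, 0, 0, 3, 1), 3, byrow = TRUE)),
                 "empty")
})

test_that("the loose-housing region table is overwhelmingly non-random", {
  # region counts of loose vs tie-up housing across the four regions
  tab <- cbind(loose = c(0, 8, 3, 8), tieup = c(8, 0, 5, 0))
  rownames(tab) <- c("SL", "SH", "NL", "NH")
  f <- fisher_battery(tab)
  expect_lt(f$p, 0.001)
  # pairwise letters separate the all-loose from the all-tie-up regions
  expect_false(f$letters["SL"] == f$letters["SH"])
})

test_that("2x2 exact p equals the hypergeometric closed form broadly", {
  for (r1 in c(2, 5, 8)) for (r2 in c(3, 8)) for (c1 in 1:(r1 + r2 - 1)) {
    a_max <- min(r1, c1)
    for (a in max(0, c1 - r2):a_max) {
      tab <- matrix(c(a, r1 - a, c1 - a, r2 - (c1 - a)), 2)
      if (any(tab < 0)) next
      expect_equal(fisher_battery(tab)$p, oracle_fisher_2x2(tab),
                   tolerance = 1e-9)
    }
  }
})

test_that("cluster two-way ANOVA adjusts for altitude and latitude", {
  set.seed(7)
  n <- 32
  cl <- rep(c("C1", "C2", "C3", "tiny"), c(12, 10, 8, 2))
  alt <- c(rnorm(22, 900, 80), rnorm(10, 40, 10))
  lat <- rep(c("north", "south"), 16)
  # response driven entirely by altitude: cluster effect not significant
  y <- 30 - 0.004 * alt + rnorm(n, sd = 0.2)
  res <- cluster_twoway_anova(y, cl, alt, lat)
  expect_false("tiny" %in% res$clusters)
  expect_gt(res$p, 0.05)
  # injected cluster effect of many sds is detected
  y2 <- y + 5 * (cl == "C2")
  res2 <- cluster_twoway_anova(y2, cl, alt, lat)
  expect_lt(res2$p, 0.05)
  expect_error(cluster_twoway_anova(y[1:4], cl[c(1, 2, 13, 23)],
                                    alt[1:4], lat[1:4]), "fewer than 2")
})

test_that("cluster ANOVA null p-values are close to uniform", {
  set.seed(8)
  ps <- vapply(1:200, function(i) {
    cl <- sample(rep(c("A", "B", "C"), c(12, 10, 10)))
    alt <- rnorm(32, 500, 200)
    lat <- sample(c("north", "south"), 32, TRUE)
    y <- 25 - 0.004 * alt + rnorm(32)
    cluster_twoway_anova(y, cl, alt, lat)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("compare_regions picks the test family by variable type", {
  cfg <- generator_config(seed = 21)
  farms <- generate_farms(cfg)
  res_alt <- compare_regions(farms, "altitude")
  expect_true(res_alt$test %in% c("one-way ANOVA + Tukey-Kramer",
                                  "Kruskal-Wallis + Dunn"))
  expect_lt(res_alt$p, 0.001)  # altitude separates highland from lowland
  res_house <- compare_regions(farms, "Housing")
  expect_match(res_house$test, "Fisher")
})
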