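# Ward clustering, k-means consolidation and V-tests.

make_clouds <- function(n_per = 10, sep = 20, seed = 1) {
  set.seed(seed)
  rbind(matrix(rnorm(2 * n_per), ncol = 2),
        matrix(rnorm(2 * n_per) + sep, ncol = 2))
}

test_that("two well-separated clouds suggest two clusters", {
  X <- make_clouds()
  hw <- hcluster_ward(X, m = 2)
  expect_equal(hw$suggested_k, 2L)
  expect_true(all(diff(hw$dendrogram$height) >= -1e-10))
})

test_that("identical points degrade to a single suggested cluster", {
  X <- matrix(1, nrow = 6, ncol = 2)
  expect_warning(hw <- hcluster_ward(X, m = 2), "identical")
  expect_equal(hw$suggested_k, 1L)
})

test_that("the archetype fixture yields seven clusters", {
  af <- archetype_farms(seed = 8)
  dec <- famd_decompose(famd_encode(af))
  m <- retain_components(dec$explained, 0.70)
  hw <- hcluster_ward(dec$scores, m)
  expect_equal(hw$suggested_k, 7L)
  km <- kmeans_consolidate(dec$scores, m, 7,
                           init = cutree(hw$dendrogram, 7))
  expect_equal(oracle_ari(km$labels, af$archetype), 1)
})

test_that("k-means consolidation is a fixed point on optimal input", {
  X <- make_clouds()
  init <- rep(1:2, each = 10)
  km <- kmeans_consolidate(X, 2, 2, init = init)
  expect_equal(unname(km$labels), init)
  # agreement with the reference Lloyd implementation
  ref <- suppressWarnings(stats::kmeans(X, centers = km$centroids,
                                        algorithm = "Lloyd", iter.max = 100))
  expect_equal(unname(km$inertia), ref$tot.withinss, tolerance = 1e-8)
})

test_that("k = n gives singleton clusters with zero inertia", {
  X <- matrix(rnorm(12), ncol = 2)
  km <- kmeans_consolidate(X, 2, k = nrow(X), init = seq_len(nrow(X)))
  expect_equal(km$inertia, 0)
  expect_equal(length(unique(km$labels)), nrow(X))
  expect_error(kmeans_consolidate(X, 2, k = 1), "k must lie")
})

test_that("consolidation never increases within-cluster inertia", {
  for (s in 1:5) {
    af <- archetype_farms(seed = s, noise_frac = 0.4)
    dec <- famd_decompose(famd_encode(af))
    m <- retain_components(dec$explained, 0.70)
    hc <- hclust(dist(dec$scores[, 1:m]), method = "ward.D2")
    for (k in c(3, 5, 7)) {
      init <- cutree(hc, k)
      W0 <- shedclim:::.within_inertia(dec$scores[, 1:m, drop = FALSE], init)
      km <- kmeans_consolidate(dec$scores, m, k, init = init)
      expect_lte(km$inertia, W0 + 1e-9)
    }
  }
})

test_that("quantitative V-test matches its formula and conventions", {
  # reconstructed dataset with the printed cluster summaries:
  # N = 32, cluster of 4 at mean 2.88, overall mean 1.17, population
  # sd 1.09 -> v = 3.3014 by direct formula evaluation
  delta <- sqrt((32 * 1.09^2 - 4 * (2.88 - 1.17)^2 -
                   28 * ((32 * 1.17 - 4 * 2.88) / 28 - 1.17)^2) / 28)
  rest_mean <- (32 * 1.17 - 4 * 2.88) / 28
  x <- c(rep(2.88, 4), rest_mean + rep(c(delta, -delta), 14))
  labels <- rep(c("C1", "rest"), c(4, 28))
  vt <- vtest_quantitative(labels, x)
  row <- vt[vt$cluster == "C1", ]
  expect_equal(row$group_mean, 2.88)
  expect_equal(row$overall_mean, 1.17, tolerance = 1e-12)
  expect_equal(row$overall_sd, 1.09, tolerance = 1e-12)
  expect_equal(row$v, 3.301425, tolerance = 1e-5)
  expect_equal(row$p, 2 * pnorm(-3.301425), tolerance = 1e-5)
})

test_that("V-test handles equal means, singletons and zero variance", {
  x <- rep(c(1, 2), 8)
  labels <- rep(c("a", "b"), each = 8)
  # both clusters hold the overall mean exactly
  vt <- vtest_quantitative(labels, rep(c(1, 2), times = 8))
  expect_equal(vt$v, c(0, 0))
  expect_equal(vt$p, c(1, 1))
  # singleton cluster: finite v with n_k = 1
  vt1 <- vtest_quantitative(c("s", rep("r", 9)), c(5, rnorm(9)))
  expect_true(is.finite(vt1$v[vt1$cluster == "s"]))
  # zero overall variance: not applicable
  vt0 <- vtest_quantitative(labels, rep(3, 16))
  expect_true(all(is.na(vt0$v)))
})

test_that("categorical V-test matches hypergeometric enumeration", {
  # cluster of 5 farms all sharing a category held by 7 of 32
  f <- rep(c("yes", "no"), c(7, 25))
  labels <- c(rep("C", 5), rep("R", 27))  # the 5 cluster farms all "yes"
  vt <- vtest_categorical(labels, f, "yes")
  row <- vt[vt$cluster == "C", ]
  tail_p <- oracle_hyper_upper(5, K = 7, N = 32, n = 5)
  expect_equal(row$p, min(1, 2 * tail_p), tolerance = 1e-12)
  expect_equal(row$v, qnorm(tail_p, lower.tail = FALSE), tolerance = 1e-12)
  expect_gt(row$v, 0)
})

test_that("categorical V-test signs are symmetric under complement", {
  set.seed(3)
  f <- sample(c("a", "b"), 32, replace = TRUE, prob = c(0.6, 0.4))
  labels <- rep(1:4, each = 8)
  va <- vtest_categorical(labels, f, "a")
  vb <- vtest_categorical(labels, f, "b")
  expect_equal(va$v, -vb$v, tolerance = 1e-10)
  # strong under-representation carries a negative sign
  f2 <- c(rep("x", 27), rep("y", 5))
  lab2 <- rep(c("c", "r"), c(5, 27))
  f2[lab2 == "c"] <- "y"  # cluster has none of the near-universal "x"
  vx <- vtest_categorical(lab2, f2, "x")
  expect_lt(vx$v[vx$cluster == "c"], 0)
  expect_error(vtest_categorical(labels, f, "zzz"), "not present")
})

test_that("archetype membership is recovered across seeds", {
  aris <- vapply(1:5, function(s) {
    af <- archetype_farms(seed = s)
    cl <- cluster_housing(af)
    oracle_ari(cl$labels, af$archetype)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("cluster_housing is robust to constant columns", {
  af <- archetype_farms(seed = 1)
  af$HoseCoFlo <- 2  # constant
  expect_warning(cl <- cluster_housing(af), "constant")
  expect_equal(length(cl$labels), nrow(af))
  expect_true(all(cl$vtest_quantitative$variable != "HoseCoFlo"))
})
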