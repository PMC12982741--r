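test_that("far-apart blobs are separated by any linkage at k = 2", {
  set.seed(91)
  pts <- rbind(matrix(rnorm(40, 0, 0.5), 20),
               matrix(rnorm(40, 50, 0.5), 20))
  rownames(pts) <- paste0("L", 1:40)
  blob <- rep(1:2, each = 20)
  for (lk in c("ward", "complete", "average", "single")) {
    part <- agglomerativeCluster(pts, k = 2, linkage = lk)
    expect_equal(adjustedRandIndex(part, blob), 1)
  }
  expect_equal(names(part), rownames(pts))
})

test_that("k = n yields all singletons; invalid combinations error", {
  set.seed(92)
  pts <- matrix(rnorm(20), 10)
  part <- agglomerativeCluster(pts, k = 10, linkage = "complete")
  expect_equal(nlevels(part), 10)
  expect_error(agglomerativeCluster(pts, k = 2, linkage = "ward",
                                    metric = "manhattan"), "euclidean")
  expect_error(agglomerativeCluster(pts, k = 11, linkage = "complete"), "k must")
})

test_that("small instances match a quadratic naive agglomeration oracle", {
  set.seed(93)
  for (rep in 1:100) {
    n <- sample(4:8, 1)
    k <- sample(2:(n - 1), 1)
    lk <- sample(c("complete", "average", "single"), 1)
    pts <- matrix(runif(n * 2), n)
    part <- agglomerativeCluster(pts, k, linkage = lk)
    ref <- oracleAgglomerate(pts, k, linkage = lk)
    expect_equal(adjustedRandIndex(part, ref), 1)
  }
})

test_that("optimization with budget 1 returns the single evaluated configuration", {
  set.seed(94)
  pts <- matrix(rnorm(60), 30)
  rownames(pts) <- paste0("L", 1:30)
  gt <- list(env = sample(letters[1:3], 30, replace = TRUE))
  space <- clusteringSearchSpace(k_range = c(2, 2), linkages = "complete",
                                 budget = 1)
  res <- optimizeClustering(pts, gt, space)
  expect_equal(nrow(res$trace), 1)
  expect_equal(res$best_params$k, 2)
  expect_equal(res$objective, res$trace$objective[1])
})

test_that("three separated blobs select k = 3, agreeing with exhaustive search", {
  set.seed(95)
  blob <- rep(1:3, each = 20)
  pts <- matrix(rnorm(120, sd = 0.4), 60) + cbind(c(0, 10, 20)[blob],
                                                  c(0, 0, 10)[blob])
  rownames(pts) <- paste0("L", 1:60)
  gt <- list(blob = blob)
  space <- clusteringSearchSpace(k_range = c(2, 6), linkages = c("ward", "complete"),
                                 budget = 100) # covers the grid: exhaustive
  res <- optimizeClustering(pts, gt, space)
  expect_equal(res$best_params$k, 3)
  expect_equal(adjustedRandIndex(res$partition, blob), 1)
  # exhaustive-search oracle: recompute every cell independently
  best <- -Inf
  for (k in 2:6) for (lk in c("ward", "complete")) {
    p <- agglomerativeCluster(pts, k, lk)
    obj <- 0.5 * silhouetteScore(pts, p) + 0.5 * adjustedRandIndex(p, blob)
    best <- max(best, obj)
  }
  expect_equal(res$objective, best, tolerance = 1e-12)
})

test_that("every trace row satisfies the equal-weight objective identity", {
  set.seed(96)
  pts <- matrix(rnorm(80), 40)
  rownames(pts) <- paste0("L", 1:40)
  gt <- list(a = sample(1:2, 40, TRUE), b = sample(1:3, 40, TRUE))
  res <- optimizeClustering(pts, gt, clusteringSearchSpace(k_range = c(2, 5),
    linkages = c("ward", "average"), budget = 20))
  for (r in seq_len(nrow(res$trace))) {
    p <- agglomerativeCluster(pts, res$trace$k[r], res$trace$linkage[r])
    sil <- silhouetteScore(pts, p)
    ari <- mean(c(adjustedRandIndex(p, gt$a), adjustedRandIndex(p, gt$b)))
    expect_equal(res$trace$objective[r], 0.5 * sil + 0.5 * ari, tolerance = 1e-12)
  }
  # and the reported optimum is consistent with its own partition
  silBest <- silhouetteScore(pts, res$partition)
  ariBest <- mean(c(adjustedRandIndex(res$partition, gt$a),
                    adjustedRandIndex(res$partition, gt$b)))
  expect_equal(res$objective, 0.5 * silBest + 0.5 * ariBest, tolerance = 1e-12)
})

test_that("under-budget search stays within budget and finds the evaluated optimum", {
  set.seed(97)
  blob <- rep(1:3, each = 15)
  pts <- matrix(rnorm(90, sd = 0.5), 45) + cbind(c(0, 8, 16)[blob], 0)
  rownames(pts) <- paste0("L", 1:45)
  space <- clusteringSearchSpace(k_range = c(2, 12), linkages = c("ward",
    "complete", "average"), budget = 12, seed = 5)
  res <- optimizeClustering(pts, list(blob = blob), space)
  expect_equal(nrow(res$trace), 12) # 33 candidates, budget 12
  expect_equal(res$objective, max(res$trace$objective))
  res2 <- optimizeClustering(pts, list(blob = blob), space)
  expect_identical(res$trace, res2$trace) # seeded: same search path
})

test_that("row-permutation yields the same partition up to relabeling", {
  set.seed(98)
  pts <- matrix(rnorm(100, sd = 0.3), 50) + rep(c(0, 6), each = 25)
  rownames(pts) <- paste0("L", 1:50)
  gt <- rep(1:2, each = 25)
  perm <- sample(50)
  p1 <- agglomerativeCluster(pts, 4, "average")
  p2 <- agglomerativeCluster(pts[perm, ], 4, "average")
  expect_equal(adjustedRandIndex(p1[perm], p2), 1)
})

test_that("raw-feature clustering recovers exact duplicate groups", {
  set.seed(99)
  proto <- matrix(rnorm(10 * 2), 2)
  m <- proto[rep(1:2, each = 12), ] + 0 # 24 lesions, two exact groups
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(m)),
    rowData = S4Vectors::DataFrame(feature_class = rep("intensity", 10),
                                   family = rep("firstorder", 10)),
    colData = S4Vectors::DataFrame(lesion_id = paste0("L", 1:24),
      patient_id = "P", tumor_type = rep(c("a", "b"), each = 12),
      environment = rep(c("x", "y"), each = 12),
      lesion_class = "solid_organ_met", row.names = paste0("L", 1:24)))
  res <- clusterRawFeatures(se, space = clusteringSearchSpace(k_range = c(2, 4),
    linkages = "complete", budget = 10))
  expect_equal(adjustedRandIndex(res$partition, rep(1:2, each = 12)), 1)
  res2 <- clusterRawFeatures(se, space = clusteringSearchSpace(k_range = c(2, 4),
    linkages = "complete", budget = 10))
  expect_identical(res$partition, res2$partition)
})
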