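test_that("two points merge at a height equal to their distance", {
  X <- rbind(a = c(0, 0), b = c(3, 4))
  tree <- ward_linkage(X)
  expect_equal(nrow(tree$merges), 1)
  expect_equal(tree$merges$height, 5)
  expect_equal(tree$merges$size, 2L)
})

test_that("duplicated points merge at height zero", {
  X <- matrix(rep(c(1, 2), each = 6), nrow = 6)
  rownames(X) <- paste0("p", 1:6)
  tree <- ward_linkage(X)
  expect_true(all(tree$merges$height == 0))
})

test_that("Ward linkage equals brute-force greedy agglomeration on small sets", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- 4L + (seed %% 5L)     # 4..8 points
    X <- matrix(rnorm(n * 2), nrow = n)
    rownames(X) <- paste0("p", seq_len(n))
    tree <- ward_linkage(X)
    oracle <- brute_ward(X)
    expect_equal(sort(tree$merges$height), sort(oracle$heights),
                 tolerance = 1e-8)
    for (k in 1:n) {
      expect_equal(canonical_partition(cut_clusters(tree, k)[paste0("p", 1:n)]),
                   canonical_partition(oracle$partitions[[k]]),
                   info = sprintf("seed %d, k %d", seed, k))
    }
  }
})

test_that("merge heights are non-decreasing (Ward monotonicity)", {
  fx <- shared_kv_ensemble()
  tree <- ward_linkage(fx$space$scores)
  expect_true(all(diff(tree$merges$height) >= -1e-12))
})

test_that("cuts are nested and cover the degenerate levels", {
  set.seed(2)
  X <- matrix(rnorm(16), nrow = 8)
  rownames(X) <- paste0("p", 1:8)
  tree <- ward_linkage(X)
  expect_equal(length(unique(cut_clusters(tree, 1))), 1)
  expect_equal(length(unique(cut_clusters(tree, 8))), 8)
  expect_error(cut_clusters(tree, 0), "k must be")
  expect_error(cut_clusters(tree, 9), "k must be")
  for (k in 2:8) {
    fine <- cut_clusters(tree, k)
    coarse <- cut_clusters(tree, k - 1L)
    # every fine cluster sits inside exactly one coarse cluster
    expect_true(all(tapply(coarse, fine,
                           function(x) length(unique(x))) == 1))
  }
})

test_that("two well-separated blobs are recovered exactly at k = 2", {
  set.seed(3)
  X <- rbind(matrix(rnorm(8, mean = 0, sd = 0.1), ncol = 2),
             matrix(rnorm(8, mean = 10, sd = 0.1), ncol = 2))
  rownames(X) <- paste0("p", 1:8)
  lab <- cut_clusters(ward_linkage(X), 2)
  expect_equal(canonical_partition(lab), rep(1:2, each = 4))
})

test_that("validity indexes match direct formula evaluation on a worked set", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1),
             c(8, 8), c(9, 8), c(10, 10))
  rownames(X) <- paste0("p", 1:6)
  labels <- c(1, 1, 1, 2, 2, 2)
  names(labels) <- rownames(X)
  vi <- validity_indexes(X, labels)
  oracle <- direct_indexes(X, labels)
  expect_equal(vi$silhouette, oracle$silhouette, tolerance = 1e-12)
  expect_equal(vi$dunn, oracle$dunn, tolerance = 1e-12)
  expect_equal(vi$davies_bouldin, oracle$davies_bouldin, tolerance = 1e-12)
  expect_equal(vi$calinski_harabasz, oracle$calinski_harabasz,
               tolerance = 1e-12)
  expect_equal(vi$singleton_count, 0L)
  # with a singleton present
  labels2 <- c(1, 1, 3, 2, 2, 2)
  names(labels2) <- rownames(X)
  vi2 <- validity_indexes(X, labels2)
  oracle2 <- direct_indexes(X, labels2)
  expect_equal(vi2$silhouette, oracle2$silhouette, tolerance = 1e-12)
  expect_equal(vi2$davies_bouldin, oracle2$davies_bouldin, tolerance = 1e-12)
  expect_equal(vi2$singleton_count, 1L)
})

test_that("zero within-cluster scatter gives Davies-Bouldin 0 and silhouette 1", {
  X <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  rownames(X) <- paste0("p", 1:4)
  labels <- c(1, 1, 2, 2)
  names(labels) <- rownames(X)
  vi <- validity_indexes(X, labels)
  expect_equal(vi$davies_bouldin, 0)
  expect_equal(vi$silhouette, 1)
})

test_that("inner distance follows its defining formula", {
  mkfeat <- function(vals) list(activation = make_fv("activation", vals))
  # two clusters of two vectors each, small integers
  feats <- list(a = mkfeat(c(0, 0, 0, 0)), b = mkfeat(c(2, 2, 2, 2)),
                c = mkfeat(c(10, 10, 10, 10)), d = mkfeat(c(14, 10, 10, 10)))
  labels <- c(a = 1, b = 1, c = 2, d = 2)
  di <- inner_distance(feats, labels)
  # cluster 1: mean (1,1,1,1); each member's mean |dev| = 1
  # cluster 2: mean (12,10,10,10); member deviations (2,0,0,0) -> 0.5
  expect_equal(unname(di["activation"]), (1 + 0.5) / 2)
  # all-singleton cut: zero for every protocol
  singletons <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(unname(inner_distance(feats, singletons)["activation"]), 0)
  # a cluster of identical vectors contributes zero scatter
  twins <- list(a = mkfeat(c(3, 3)), b = mkfeat(c(3, 3)))
  expect_equal(unname(inner_distance(twins, c(a = 1, b = 1))["activation"]), 0)
})

test_that("reference models minimize the distance to the cluster mean", {
  X <- rbind(a = c(0, 0), b = c(2, 0), c = c(1, 1), d = c(1, -1),
             e = c(0.9, 0))
  labels <- stats::setNames(rep(1, 5), rownames(X))
  ref <- reference_models(X, labels)
  # oracle: exhaustive scan
  ctr <- colMeans(X)
  d <- apply(X, 1, function(r) sqrt(sum((r - ctr)^2)))
  expect_equal(unname(ref["1"]), names(which.min(d)))
  # singleton cluster returns its only member
  labs2 <- c(a = 1, b = 2, c = 2, d = 2, e = 2)
  expect_equal(unname(reference_models(X, labs2)["1"]), "a")
  # symmetric pair equidistant from the mean: lexicographically first id
  Y <- rbind(q = c(-1, 0), p = c(1, 0))
  expect_equal(unname(reference_models(Y, c(q = 1, p = 1))["1"]), "p")
})

test_that("scan_k reports index profiles and the silhouette peaks at the true k", {
  fx <- shared_kv_ensemble()
  tree <- ward_linkage(fx$space$scores)
  tab <- scan_k(tree, fx$space$scores, features = fx$features,
                k_range = 2:10)
  expect_equal(tab$k, 2:10)
  expect_true(all(c("silhouette", "dunn", "davies_bouldin",
                    "calinski_harabasz", "singleton_count",
                    "inner_activation") %in% names(tab)))
  # singleton count never increases as k decreases
  expect_true(all(diff(tab$singleton_count) >= 0))
  # the ensemble was generated from 5 templates
  expect_equal(tab$k[which.max(tab$silhouette)], 5)
})

test_that("an all-singleton cut has zero inner distance for every protocol", {
  fx <- shared_kv_ensemble()
  n <- length(fx$features)
  singles <- stats::setNames(seq_len(n), names(fx$features))
  di <- inner_distance(fx$features, singles)
  expect_true(all(di == 0))
  expect_length(di, 5)
})

test_that("clusters are named by dominant subtype labels", {
  labels <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2, g = 2)
  subtypes <- c(a = "A", b = "A", c = "dr", d = "m", e = "HH", f = "IR",
                g = "SK")
  nm <- name_clusters(labels, subtypes)
  expect_equal(unname(nm["1"]), "A/dr")     # 2/3 and 1/3 both >= 30%
  expect_equal(unname(nm["2"]), "mixed")    # all shares at 25%
})
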