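# Independent oracles used across test files. These deliberately re-derive
# quantities from first principles (brute-force agglomeration, direct formula
# evaluation) rather than calling the package's implementations.

# Greedy Ward agglomeration, recomputing all pairwise merge costs at each
# step. Cost of merging clusters A, B is the within-cluster variance increase
# |A||B|/(|A|+|B|) * ||mean_A - mean_B||^2; reported heights are sqrt(2*cost),
# the same scale as hclust's "ward.D2".
brute_ward <- function(X) {
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  partitions <- vector("list", n)
  partitions[[n]] <- seq_len(n)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- NULL
    best_cost <- Inf
    for (i in 1:(m - 1L)) {
      for (j in (i + 1L):m) {
        A <- clusters[[i]]
        B <- clusters[[j]]
        mA <- colMeans(X[A, , drop = FALSE])
        mB <- colMeans(X[B, , drop = FALSE])
        cost <- length(A) * length(B) / (length(A) + length(B)) *
          sum((mA - mB)^2)
        if (cost < best_cost) {
          best_cost <- cost
          best <- c(i, j)
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    heights <- c(heights, sqrt(2 * best_cost))
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions[[length(clusters)]] <- lab
  }
  list(partitions = partitions, heights = heights)
}

# Canonical form of a partition: relabel clusters by first appearance, so two
# labelings describe the same partition iff their canonical forms are equal.
canonical_partition <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

# Direct-formula cluster validity indexes (silhouette with the singleton = 0
# convention; Dunn; Davies-Bouldin; Calinski-Harabasz).
direct_indexes <- function(X, labels) {
  n <- nrow(X)
  dm <- as.matrix(dist(X))
  f <- factor(labels)
  k <- nlevels(f)
  idx <- split(seq_len(n), f)
  sil <- vapply(seq_len(n), function(i) {
    own <- setdiff(idx[[as.integer(f[i])]], i)
    if (length(own) == 0L) return(0)
    a <- mean(dm[i, own])
    b <- min(vapply(setdiff(seq_len(k), as.integer(f[i])), function(cl) {
      mean(dm[i, idx[[cl]]])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  diam <- vapply(idx, function(m) if (length(m) < 2) 0 else max(dm[m, m]),
                 numeric(1))
  inter <- Inf
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) inter <- min(inter, min(dm[idx[[i]], idx[[j]]]))
  }
  cent <- t(vapply(idx, function(m) colMeans(X[m, , drop = FALSE]),
                   numeric(ncol(X))))
  sig <- vapply(seq_len(k), function(i) {
    mean(apply(X[idx[[i]], , drop = FALSE], 1,
               function(r) sqrt(sum((r - cent[i, ])^2))))
  }, numeric(1))
  db <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (sig[i] + sig[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }, numeric(1)))
  }, numeric(1)))
  grand <- colMeans(X)
  B <- sum(lengths(idx) *
             apply(cent, 1, function(r) sum((r - grand)^2)))
  W <- sum(vapply(seq_len(k), function(i) {
    sum(apply(X[idx[[i]], , drop = FALSE], 1,
              function(r) sum((r - cent[i, ])^2)))
  }, numeric(1)))
  list(silhouette = mean(sil), dunn = inter / max(diam),
       davies_bouldin = db,
       calinski_harabasz = (B / (k - 1)) / (W / (n - k)))
}

# Minimal feature_vector constructor for synthetic featureization tests.
make_fv <- function(protocol, values) {
  structure(list(protocol_name = protocol, values = values,
                 n_conditions = 1L, all_zero = FALSE, flipped = FALSE),
            class = "feature_vector")
}
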