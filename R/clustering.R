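#' Ward hierarchical clustering of kinetic scores
#'
#' Agglomerative clustering with Ward's minimal-variance linkage on the
#' Euclidean distances between total scores (`stats::hclust`, method
#' `"ward.D2"`, whose merge heights are monotone in the within-cluster
#' variance increase; for two singletons the merge height equals their
#' Euclidean distance).
#'
#' @param scores `N x D` numeric matrix of total scores with channel ids as
#'   row names (e.g. `space$scores` from [fit_score_space()]).
#' @return An object of class `linkage_tree` wrapping the `hclust` result,
#'   with `$ids` and a `$merges` table (`a`, `b`, `height`, `size`; negative
#'   entries denote leaves, positive entries earlier merges).
#' @export
ward_linkage <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop_invalid("need at least 2 channels to cluster")
  if (!all(is.finite(scores))) stop_invalid("scores must be finite")
  if (is.null(rownames(scores))) {
    rownames(scores) <- paste0("ch", seq_len(nrow(scores)))
  }
  hc <- hclust(dist(scores), method = "ward.D2")
  size <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    sz <- function(j) if (j < 0) 1L else size[j]
    size[i] <- sz(hc$merge[i, 1]) + sz(hc$merge[i, 2])
  }
  structure(
    list(hclust = hc, ids = rownames(scores),
         merges = data.frame(a = hc$merge[, 1], b = hc$merge[, 2],
                             height = hc$height, size = size)),
    class = "linkage_tree"
  )
}

#' Cut a linkage tree into k clusters
#'
#' @param tree a [ward_linkage()] result.
#' @param k number of clusters, `1 <= k <= N`.
#' @return Named integer vector (channel id -> cluster id in `1..k`). Cuts
#'   are nested: the cut at `k` refines the cut at `k - 1`.
#' @export
cut_clusters <- function(tree, k) {
  stopifnot(inherits(tree, "linkage_tree"))
  n <- length(tree$ids)
  if (k < 1L || k > n) stop_invalid("k must be in 1..%d", n)
  cutree(tree$hclust, k = k)
}

check_labels <- function(scores, labels) {
  scores <- as.matrix(scores)
  if (is.null(names(labels))) {
    if (length(labels) != nrow(scores)) {
      stop_invalid("labels must be named by channel id or match scores rows")
    }
    names(labels) <- rownames(scores)
  }
  if (!setequal(names(labels), rownames(scores))) {
    stop_invalid("labels and scores cover different channel ids")
  }
  labels[rownames(scores)]
}

#' Internal cluster-validity indexes
#'
#' Computes, from a labeled score matrix: mean silhouette width (via
#' \pkg{cluster}; singletons contribute width 0), the Dunn index (minimum
#' between-cluster point distance over maximum within-cluster diameter),
#' the Davies-Bouldin index (mean over clusters of the worst pairwise
#' `(sigma_i + sigma_j) / d_ij`, with `sigma` the mean member-to-centroid
#' distance and `d` the centroid distance), the Calinski-Harabasz variance
#' ratio `[B/(k-1)] / [W/(n-k)]`, and the number of singleton clusters.
#' Silhouette, Dunn and Calinski-Harabasz indicate compact well-separated
#' clusters when high; Davies-Bouldin when low.
#'
#' @param scores `N x D` score matrix with channel ids as row names.
#' @param labels cluster labels named by channel id; at least 2 nonempty
#'   clusters.
#' @return Named list: `silhouette`, `dunn`, `davies_bouldin`,
#'   `calinski_harabasz`, `singleton_count`.
#' @export
validity_indexes <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- check_labels(scores, labels)
  f <- factor(labels)
  k <- nlevels(f)
  n <- nrow(scores)
  if (k < 2L) stop_invalid("validity indexes need at least 2 clusters")
  dm <- as.matrix(dist(scores))
  sil <- cluster::silhouette(as.integer(f), dmatrix = dm)
  sil_mean <- mean(sil[, "sil_width"])
  # Dunn: min inter-cluster distance / max intra-cluster diameter
  idx <- split(seq_len(n), f)
  diam <- vapply(idx, function(i) {
    if (length(i) < 2L) 0 else max(dm[i, i])
  }, numeric(1))
  min_inter <- Inf
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      min_inter <- min(min_inter, min(dm[idx[[i]], idx[[j]]]))
    }
  }
  dunn <- min_inter / max(diam)   # Inf if every cluster is a singleton
  centroids <- t(vapply(idx, function(i) {
    colMeans(scores[i, , drop = FALSE])
  }, numeric(ncol(scores))))
  sigma <- vapply(seq_len(k), function(i) {
    mean(sqrt(colSums((t(scores[idx[[i]], , drop = FALSE]) -
                         centroids[i, ])^2)))
  }, numeric(1))
  db_terms <- vapply(seq_len(k), function(i) {
    r <- vapply(setdiff(seq_len(k), i), function(j) {
      dij <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
      (sigma[i] + sigma[j]) / dij
    }, numeric(1))
    max(r)
  }, numeric(1))
  grand <- colMeans(scores)
  B <- sum(lengths(idx) * rowSums((centroids - rep(grand, each = k))^2))
  W <- sum(vapply(seq_len(k), function(i) {
    sum((t(t(scores[idx[[i]], , drop = FALSE]) - centroids[i, ]))^2)
  }, numeric(1)))
  ch <- if (W == 0) Inf else (B / (k - 1)) / (W / (n - k))
  list(silhouette = sil_mean, dunn = dunn, davies_bouldin = mean(db_terms),
       calinski_harabasz = ch,
       singleton_count = sum(lengths(idx) == 1L))
}

#' Per-protocol inner distance of a clustering
#'
#' A trace-level heterogeneity measure: for each protocol, let `s_j` be
#' channel `j`'s appended feature trace and `c_k` the mean trace of cluster
#' `k`; then
#' `d_inner = (1/n_clusters) * sum_k (1/|C_k|) * sum_{j in C_k} ||s_j - c_k||`
#' with the norm defined as the mean absolute value over all entries of the
#' appended trace. All-singleton cuts give 0 for every protocol.
#'
#' @param features named list (channel id -> per-protocol feature vectors),
#'   as passed to [fit_score_space()].
#' @param labels cluster labels named by channel id, covering all channels.
#' @return Named numeric vector, one inner distance per protocol.
#' @export
inner_distance <- function(features, labels) {
  if (is.null(names(labels)) || !setequal(names(labels), names(features))) {
    stop_invalid("labels must be named and cover exactly the feature ids")
  }
  protos <- names(features[[1]])
  out <- numeric(length(protos))
  names(out) <- protos
  f <- factor(labels[names(features)])
  for (p in protos) {
    X <- feature_matrix(features, p)
    d_k <- vapply(levels(f), function(lv) {
      rows <- which(f == lv)
      ck <- colMeans(X[rows, , drop = FALSE])
      mean(vapply(rows, function(j) mean(abs(X[j, ] - ck)), numeric(1)))
    }, numeric(1))
    out[p] <- mean(d_k)
  }
  out
}

#' Reference model of each cluster
#'
#' The member whose total score is closest (Euclidean) to the cluster's mean
#' score coordinate; ties are broken by lexicographically smallest channel
#' id.
#'
#' @param scores `N x D` score matrix with channel ids as row names.
#' @param labels cluster labels named by channel id.
#' @return Named character vector (cluster id -> channel id).
#' @export
reference_models <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- check_labels(scores, labels)
  f <- factor(labels)
  vapply(levels(f), function(lv) {
    ids <- names(labels)[f == lv]
    sub <- scores[ids, , drop = FALSE]
    ctr <- colMeans(sub)
    d <- sqrt(colSums((t(sub) - ctr)^2))
    ids[order(d, ids)][1]
  }, character(1))
}

#' Scan validity indexes across cut levels
#'
#' Evaluates [validity_indexes()] (and, if features are given,
#' [inner_distance()]) for every `k` in `k_range`. No cut is selected
#' automatically: the appropriate number of clusters is chosen by the user
#' from the index profiles (knees, local extrema), as is standard for
#' internal validity criteria.
#'
#' @param tree a [ward_linkage()] result.
#' @param scores the score matrix the tree was built from.
#' @param features optional per-channel feature lists for inner distances.
#' @param k_range integer vector of cut levels (default `2:(N-1)`).
#' @return Data frame with one row per `k`.
#' @export
scan_k <- function(tree, scores, features = NULL,
                   k_range = 2:(length(tree$ids) - 1L)) {
  scores <- as.matrix(scores)
  rows <- lapply(k_range, function(k) {
    labels <- cut_clusters(tree, k)
    vi <- validity_indexes(scores, labels)
    row <- data.frame(k = k, silhouette = vi$silhouette, dunn = vi$dunn,
                      davies_bouldin = vi$davies_bouldin,
                      calinski_harabasz = vi$calinski_harabasz,
                      singleton_count = vi$singleton_count)
    if (!is.null(features)) {
      di <- inner_distance(features, labels)
      row <- cbind(row, as.data.frame(as.list(
        stats::setNames(di, paste0("inner_", names(di))))))
    }
    row
  })
  do.call(rbind, rows)
}

#' Name clusters by dominant subtype labels
#'
#' Each cluster is named by the subtype labels contributing at least
#' `threshold` (30% by default) of its members, joined by `"/"` in
#' decreasing share; clusters with no label reaching the threshold are named
#' `"mixed"`.
#'
#' @param labels cluster labels named by channel id.
#' @param subtypes subtype labels named by channel id.
#' @param threshold minimum share for a subtype to contribute to the name.
#' @return Named character vector (cluster id -> name).
#' @export
name_clusters <- function(labels, subtypes, threshold = 0.3) {
  f <- factor(labels)
  vapply(levels(f), function(lv) {
    st <- subtypes[names(labels)[f == lv]]
    tab <- sort(table(st) / length(st), decreasing = TRUE)
    keep <- tab[tab >= threshold]
    if (length(keep) == 0L) "mixed" else paste(names(keep), collapse = "/")
  }, character(1))
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree: %d leaves, %d merges (Ward)>\n",
              length(x$ids), nrow(x$merges)))
  invisible(x)
}

#' @export
plot.linkage_tree <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}
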