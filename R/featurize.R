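#' Reduce a trace set to a normalized feature vector
#'
#' Standard preprocessing of voltage-clamp current responses:
#'
#' 1. If the trace set is inward-dominated (the absolute minimum over the
#'    whole set exceeds the absolute maximum), multiply all traces by -1 so
#'    currents deflect positively.
#' 2. Divide all traces by the maximum value of the whole (flipped) set,
#'    removing the dependence on the maximal conductance.
#' 3. Restrict each trace to the protocol's analysis window \[TA, TB\].
#' 4. Uniformly subsample each restricted trace to exactly 512 points
#'    (endpoints included).
#' 5. Concatenate across graded steps in ascending voltage order; for
#'    calcium-gated channels, across calcium levels in descending
#'    concentration outermost.
#'
#' Flipping and normalization act on the set as a whole (not per trace), so
#' the relative amplitudes across steps — the activation curve — are
#' preserved. An all-zero trace set returns a zero vector with
#' `all_zero = TRUE` and a warning instead of dividing by zero.
#'
#' @param traces a `trace_set` from [run_clamp()].
#' @return An object of class `feature_vector`: list with `protocol_name`,
#'   `values` (length `512 * n_conditions`, all in \[-1, 1\]), `n_conditions`
#'   and `all_zero`.
#' @examples
#' ch <- template_library()[["kv_dr"]]
#' ts <- run_clamp(ch, build_protocol("Kv", "activation"))
#' length(preprocess_traces(ts)$values)   # 512 * 16 = 8192
#' @export
preprocess_traces <- function(traces) {
  stopifnot(inherits(traces, "trace_set"))
  M <- traces$traces
  if (!all(is.finite(M))) stop_invalid("trace set contains non-finite values")
  flipped <- abs(min(M)) > abs(max(M))
  if (flipped) M <- -M
  mx <- max(M)
  all_zero <- mx == 0 && min(M) == 0
  if (all_zero) {
    warning(sprintf("all-zero trace set for %s/%s; returning zero features",
                    traces$channel_id, traces$protocol_name))
  } else {
    M <- M / mx
  }
  dt <- traces$dt
  w <- traces$protocol$window
  i0 <- round(w[1] / dt) + 1L
  i1 <- round(w[2] / dt) + 1L
  cols <- i0:i1
  pick <- cols[round(seq(1, length(cols), length.out = 512L))]
  sub <- M[, pick, drop = FALSE]
  structure(
    list(protocol_name = traces$protocol_name, values = as.vector(t(sub)),
         n_conditions = nrow(sub), all_zero = all_zero,
         flipped = flipped),
    class = "feature_vector"
  )
}

#' Simulate and featurize one channel under all five protocols
#'
#' @param channel a [channel_model()].
#' @param dt integration timestep, ms.
#' @param table protocol parameter table.
#' @return Named list of `feature_vector`, one per protocol.
#' @export
channel_features <- function(channel, dt = 0.05, table = protocol_table()) {
  lapply(run_all_protocols(channel, dt = dt, table = table),
         preprocess_traces)
}

#' Simulate and featurize an ensemble of channels
#'
#' Runs [channel_features()] for every channel, discarding raw traces as it
#' goes (features are roughly 40x smaller than the traces they summarize).
#'
#' @param channels named list of [channel_model()] objects sharing one ion
#'   class.
#' @param dt integration timestep, ms.
#' @return Named list (by channel id) of per-protocol feature lists, the
#'   input container for [fit_score_space()].
#' @export
ensemble_features <- function(channels, dt = 0.05) {
  ids <- vapply(channels, function(ch) ch$id, character(1))
  names(channels) <- ids
  cls <- unique(vapply(channels, function(ch) ch$ion_class, character(1)))
  if (length(cls) != 1L) {
    stop_invalid("all channels must share one ion class (got %s)",
                 paste(cls, collapse = ", "))
  }
  lapply(channels, channel_features, dt = dt)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

col_pop_stats <- function(X) {
  cm <- colMeans(X)
  cv <- colMeans(X^2) - cm^2
  cv[cv < 0 | !is.finite(cv)] <- 0   # guard against cancellation error
  list(mean = cm, sd = sqrt(cv))
}

# PCA by SVD of an already column-centered matrix; retains the smallest
# dimensionality whose cumulative explained variance reaches `threshold`.
# Axis signs are fixed by making each axis's largest-|loading| positive.
fit_pca <- function(Z, threshold) {
  sv <- svd(Z)
  var_i <- sv$d^2
  total <- sum(var_i)
  if (total == 0) {
    m <- 1L
    explained <- 1
  } else {
    cum <- cumsum(var_i) / total
    m <- which(cum >= threshold)[1]
    explained <- cum[m]
  }
  rot <- sv$v[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    i_star <- which.max(abs(rot[, j]))
    if (rot[i_star, j] < 0) rot[, j] <- -rot[, j]
  }
  list(rotation = rot, ndim = m, explained = explained)
}

feature_matrix <- function(features, protocol) {
  rows <- lapply(features, function(f) {
    fv <- f[[protocol]]
    if (is.null(fv)) stop_invalid("missing protocol '%s' features", protocol)
    fv$values
  })
  L <- unique(lengths(rows))
  if (length(L) != 1L) {
    stop_invalid("protocol '%s': inconsistent feature lengths", protocol)
  }
  matrix(unlist(rows, use.names = FALSE), nrow = length(rows), byrow = TRUE,
         dimnames = list(names(features), NULL))
}

#' Fit the two-stage PCA kinetic score space over an ensemble
#'
#' For each protocol, the per-channel feature vectors are stacked into an
#' `N x L` matrix, each column is Z-scored (population standard deviation;
#' zero-variance columns map to 0), and the matrix is reduced by PCA keeping
#' the smallest dimensionality that captures at least `variance_threshold`
#' (99% by default) of the variance. Each protocol's score block — the
#' *condition scores* — is then divided by the standard deviation of all its
#' entries to equalize ranges across protocols while keeping covariance
#' structure. The five normalized blocks are concatenated and reduced again
#' by PCA (same variance criterion) to a final `D`-dimensional *total score*
#' per channel. All transforms are stored so new channels or recorded traces
#' can be projected later with [project_scores()].
#'
#' @param features named list (channel id -> named list of per-protocol
#'   `feature_vector`s), e.g. from [ensemble_features()]; at least 2
#'   channels.
#' @param variance_threshold fraction of variance each PCA stage must retain
#'   (default 0.99).
#' @param center_final logical; re-center the concatenated condition scores
#'   before the final PCA (default `TRUE`).
#' @return An object of class `score_space` with the fitted transforms, the
#'   ensemble's total scores (`$scores`, an `N x D` matrix), per-protocol
#'   condition scores (`$condition_scores`), and the variance captured at
#'   each stage (`$explained`).
#' @export
fit_score_space <- function(features, variance_threshold = 0.99,
                            center_final = TRUE) {
  n <- length(features)
  if (n < 2L) stop_invalid("need at least 2 channels to fit a score space")
  if (is.null(names(features)) || anyDuplicated(names(features))) {
    stop_invalid("features must be uniquely named by channel id")
  }
  protos <- names(features[[1]])
  per_protocol <- list()
  blocks <- list()
  for (p in protos) {
    X <- feature_matrix(features, p)
    st <- col_pop_stats(X)
    Z <- sweep(X, 2, st$mean, "-")
    nz <- st$sd > 0
    Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2, st$sd[nz], "/")
    Z[, !nz] <- 0
    pca <- fit_pca(Z, variance_threshold)
    S <- Z %*% pca$rotation
    score_sd <- pop_sd(as.vector(S))
    if (score_sd == 0) score_sd <- 1   # degenerate (identical) ensemble
    per_protocol[[p]] <- list(mean = st$mean, sd = st$sd,
                              rotation = pca$rotation, ndim = pca$ndim,
                              explained = pca$explained,
                              score_sd = score_sd, length = ncol(X))
    blocks[[p]] <- S / score_sd
  }
  C <- do.call(cbind, blocks)
  final_center <- if (center_final) colMeans(C) else rep(0, ncol(C))
  Cc <- sweep(C, 2, final_center, "-")
  fpca <- fit_pca(Cc, variance_threshold)
  scores <- Cc %*% fpca$rotation
  rownames(scores) <- names(features)
  colnames(scores) <- paste0("dim_", seq_len(ncol(scores)))
  structure(
    list(ids = names(features), protocols = per_protocol,
         final = list(center = final_center, rotation = fpca$rotation,
                      ndim = fpca$ndim),
         variance_threshold = variance_threshold,
         explained = list(
           per_protocol = vapply(per_protocol, function(x) x$explained,
                                 numeric(1)),
           final = fpca$explained),
         condition_scores = blocks, scores = scores),
    class = "score_space"
  )
}

space_fingerprint <- function(space) {
  c(length(space$ids), space$final$ndim,
    round(sum(abs(space$final$rotation)), 10))
}

#' Project per-protocol features into a fitted score space
#'
#' Applies the stored Z-scoring, per-protocol PCA, scale normalizers and
#' final PCA of a fitted [fit_score_space()] to a new channel's features.
#' Projecting a member of the fitted ensemble reproduces its stored score.
#'
#' @param space a fitted `score_space`.
#' @param features named list of per-protocol `feature_vector`s for one
#'   channel (e.g. from [channel_features()]), or a `trace_set`-derived
#'   equivalent for recorded data.
#' @param channel_id optional label for the resulting score.
#' @return An object of class `score_vector`: list with `channel_id`,
#'   `total` (length-D numeric) and `conditions` (per-protocol normalized
#'   condition scores).
#' @export
project_scores <- function(space, features, channel_id = "query") {
  stopifnot(inherits(space, "score_space"))
  conds <- list()
  for (p in names(space$protocols)) {
    sp <- space$protocols[[p]]
    fv <- features[[p]]
    if (is.null(fv)) stop_invalid("missing features for protocol '%s'", p)
    x <- if (inherits(fv, "feature_vector")) fv$values else as.numeric(fv)
    if (length(x) != sp$length) {
      stop_invalid("protocol '%s': feature length %d, space expects %d",
                   p, length(x), sp$length)
    }
    z <- x - sp$mean
    nz <- sp$sd > 0
    z[nz] <- z[nz] / sp$sd[nz]
    z[!nz] <- 0
    conds[[p]] <- as.vector(z %*% sp$rotation) / sp$score_sd
  }
  total <- as.vector(
    (unlist(conds, use.names = FALSE) - space$final$center) %*%
      space$final$rotation)
  structure(
    list(channel_id = channel_id, total = total, conditions = conds,
         space = space_fingerprint(space)),
    class = "score_vector"
  )
}

#' Kinetic similarity: Euclidean distance between total scores
#'
#' @param a,b `score_vector`s projected into the same score space.
#' @return Nonnegative distance (0 for identical kinetics).
#' @export
similarity <- function(a, b) {
  stopifnot(inherits(a, "score_vector"), inherits(b, "score_vector"))
  if (!isTRUE(all.equal(a$space, b$space))) {
    stop_invalid("score vectors come from different score spaces")
  }
  sqrt(sum((a$total - b$total)^2))
}

#' Stored score of an ensemble member as a score_vector
#'
#' @param space a fitted `score_space`.
#' @param id channel id of a fitted ensemble member.
#' @return A `score_vector`.
#' @export
ensemble_score <- function(space, id) {
  if (!id %in% space$ids) stop_invalid("'%s' is not in the fitted ensemble", id)
  conds <- lapply(space$condition_scores, function(b) b[id, ])
  structure(
    list(channel_id = id, total = as.vector(space$scores[id, ]),
         conditions = conds, space = space_fingerprint(space)),
    class = "score_vector"
  )
}

#' Nearest ensemble members to a projected score
#'
#' @param space a fitted `score_space`.
#' @param score a `score_vector` from [project_scores()].
#' @param n number of neighbours to report.
#' @return Data frame with `channel_id` and `distance`, ascending.
#' @export
nearest_members <- function(space, score, n = 5L) {
  d <- sqrt(colSums((t(space$scores) - score$total)^2))
  ord <- order(d, names(d))
  out <- data.frame(channel_id = space$ids[ord], distance = d[ord],
                    row.names = NULL)
  utils::head(out, n)
}

#' @export
print.score_space <- function(x, ...) {
  cat(sprintf(
    "<score_space: %d channels, %d protocols -> D = %d (>= %.0f%% variance)>\n",
    length(x$ids), length(x$protocols), x$final$ndim,
    100 * x$variance_threshold))
  invisible(x)
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector %s: D = %d>\n", x$channel_id, length(x$total)))
  invisible(x)
}
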