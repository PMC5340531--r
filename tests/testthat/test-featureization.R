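test_that("feature vector lengths follow 512 x steps (x calcium levels)", {
  tl <- template_library()
  ts_kv <- run_clamp(tl[["kv_dr"]], build_protocol("Kv", "activation"))
  expect_length(preprocess_traces(ts_kv)$values, 8192)      # 512 * 16
  ts_kca <- run_clamp(tl[["kca_sk"]], build_protocol("KCa", "activation"))
  expect_length(preprocess_traces(ts_kca)$values, 57344)    # 512 * 16 * 7
  fv <- preprocess_traces(ts_kv)
  expect_true(all(is.finite(fv$values)))
  expect_lte(max(abs(fv$values)), 1)
})

test_that("preprocessing is invariant to positive scaling of the trace set", {
  tl <- template_library()
  ts <- run_clamp(tl[["kv_a"]], build_protocol("Kv", "activation"))
  fv1 <- preprocess_traces(ts)
  ts$traces <- 4 * ts$traces
  fv2 <- preprocess_traces(ts)
  expect_identical(fv1$values, fv2$values)
})

test_that("inward-dominated trace sets are flipped before normalization", {
  ch <- template_library()[["nav_hh"]]
  ts <- run_clamp(ch, build_protocol("Nav", "activation"))
  expect_lt(min(ts$traces), 0)                    # inward Na current
  expect_gt(abs(min(ts$traces)), abs(max(ts$traces)))
  fv <- preprocess_traces(ts)
  expect_true(fv$flipped)
  # the set maximum maps to +1 (the subsample grid may narrowly miss the
  # exact peak sample, so check the normalized peak from just below)
  expect_lte(max(fv$values), 1)
  expect_gt(max(fv$values), 0.9)
})

test_that("an all-zero trace set yields a flagged zero vector with a warning", {
  ts <- run_clamp(template_library()[["kv_dr"]],
                  build_protocol("Kv", "activation"))
  ts$traces[] <- 0
  expect_warning(fv <- preprocess_traces(ts), "all-zero")
  expect_true(fv$all_zero)
  expect_true(all(fv$values == 0))
  expect_length(fv$values, 8192)
})

test_that("Z-scored columns have mean 0 and population sd 1 in the fitted space", {
  set.seed(11)
  protos <- c("activation", "inactivation", "deactivation", "ramp",
              "action_potential")
  feats <- lapply(1:6, function(i) {
    fv <- lapply(protos, function(p) make_fv(p, runif(40, -1, 1)))
    names(fv) <- protos
    fv
  })
  names(feats) <- paste0("ch", 1:6)
  space <- fit_score_space(feats)
  for (p in protos) {
    X <- t(vapply(feats, function(f) f[[p]]$values, numeric(40)))
    sp <- space$protocols[[p]]
    Z <- sweep(X, 2, sp$mean, "-")
    nz <- sp$sd > 0
    Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2, sp$sd[nz], "/")
    expect_lt(max(abs(colMeans(Z))), 1e-10)
    pop_sd_cols <- sqrt(colMeans(Z[, nz, drop = FALSE]^2))
    expect_lt(max(abs(pop_sd_cols - 1)), 1e-10)
  }
})

test_that("both PCA stages retain at least 99% of the variance", {
  fx <- shared_kv_ensemble()
  expect_true(all(fx$space$explained$per_protocol >= 0.99))
  expect_gte(fx$space$explained$final, 0.99)
})

test_that("principal axes and scores match a brute-force covariance eigensolve", {
  set.seed(5)
  protos <- "activation"
  L <- 7
  feats <- lapply(1:3, function(i) {
    list(activation = make_fv("activation", rnorm(L)))
  })
  names(feats) <- paste0("ch", 1:3)
  space <- fit_score_space(feats, variance_threshold = 0.99)
  X <- t(vapply(feats, function(f) f$activation$values, numeric(L)))
  cm <- colMeans(X)
  csd <- sqrt(colMeans(X^2) - cm^2)
  Z <- sweep(sweep(X, 2, cm, "-"), 2, csd, "/")
  # oracle: eigendecomposition of the (population) covariance of Z
  ev <- eigen(crossprod(Z) / nrow(Z), symmetric = TRUE)
  frac <- cumsum(ev$values) / sum(ev$values)
  m_oracle <- which(frac >= 0.99)[1]
  sp <- space$protocols$activation
  expect_equal(sp$ndim, m_oracle)
  for (j in seq_len(m_oracle)) {
    # axes agree up to sign
    dot <- abs(sum(sp$rotation[, j] * ev$vectors[, j]))
    expect_equal(dot, 1, tolerance = 1e-8)
    # scores along each axis agree up to the same sign
    s_pkg <- (Z %*% sp$rotation[, j])
    s_orc <- (Z %*% ev$vectors[, j])
    expect_equal(abs(as.vector(crossprod(s_pkg, s_orc))) /
                   (sqrt(sum(s_pkg^2)) * sqrt(sum(s_orc^2))), 1,
                 tolerance = 1e-8)
  }
})

test_that("projecting fitted ensemble members reproduces their stored scores", {
  fx <- shared_kv_ensemble()
  err <- vapply(names(fx$features), function(id) {
    sv <- project_scores(fx$space, fx$features[[id]], channel_id = id)
    max(abs(sv$total - fx$space$scores[id, ]))
  }, numeric(1))
  expect_lt(max(err), 1e-9)
})

test_that("scores are invariant to the maximal conductance end to end", {
  tl <- template_library()
  fx <- shared_kv_ensemble()
  ch <- tl[["kv_dr"]]
  ch2 <- ch
  ch2$gbar <- 16 * ch$gbar
  f1 <- channel_features(ch)
  f2 <- channel_features(ch2)
  s1 <- project_scores(fx$space, f1)
  s2 <- project_scores(fx$space, f2)
  expect_identical(s1$total, s2$total)
  ch3 <- ch
  ch3$gbar <- 3.7 * ch$gbar     # non-dyadic factor: equal to rounding
  s3 <- project_scores(fx$space, channel_features(ch3))
  expect_equal(s3$total, s1$total, tolerance = 1e-10)
})

test_that("a perturbed template projects nearest to its parent's members", {
  fx <- shared_kv_ensemble()
  probe_ens <- generate_ensemble(
    ensemble_spec(fx$templates["kv_a"], n_per_template = 1,
                  jitter_fraction = 0.005, seed = 77))
  probe <- probe_ens$channels[[1]]
  sv <- project_scores(fx$space, channel_features(probe), "probe")
  nn <- nearest_members(fx$space, sv, n = 1)
  expect_equal(unname(fx$ensemble$labels[nn$channel_id]), "kv_a")
  # oracle: exhaustive distance scan over all stored scores
  d_all <- apply(fx$space$scores, 1, function(r) sqrt(sum((r - sv$total)^2)))
  expect_equal(nn$channel_id, names(which.min(d_all)))
  expect_equal(nn$distance, min(d_all))
})

test_that("similarity is a metric on score vectors from one space", {
  fx <- shared_kv_ensemble()
  fp <- ionclamp:::space_fingerprint(fx$space)
  mk <- function(total) structure(list(channel_id = "x", total = total,
                                       space = fp), class = "score_vector")
  d <- ncol(fx$space$scores)
  set.seed(99)
  for (i in 1:100) {
    a <- mk(rnorm(d)); b <- mk(rnorm(d)); c <- mk(rnorm(d))
    expect_equal(similarity(a, a), 0)
    expect_equal(similarity(a, b), similarity(b, a))
    expect_lte(similarity(a, c), similarity(a, b) + similarity(b, c) + 1e-12)
  }
  sv <- ensemble_score(fx$space, fx$space$ids[1])
  other <- fx$space
  other$final$rotation <- other$final$rotation * 2
  sv2 <- ensemble_score(other, other$ids[1])
  expect_error(similarity(sv, sv2), "different score spaces")
})
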