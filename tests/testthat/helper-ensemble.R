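# Shared synthetic ensemble: 5 Kv templates x 10 members at 1% jitter,
# simulated once per test run and reused by the featureization, clustering
# and acceptance tests (simulation of all five protocols for 50 channels is
# the dominant cost of the suite).
.shared_env <- new.env(parent = emptyenv())

shared_kv_ensemble <- function() {
  if (is.null(.shared_env$fixture)) {
    tl <- template_library()
    kv <- tl[c("kv_hh", "kv_dr", "kv_a", "kv_m", "kv_ir")]
    ens <- generate_ensemble(
      ensemble_spec(kv, n_per_template = 10, jitter_fraction = 0.01,
                    seed = 42))
    feats <- ensemble_features(ens$channels)
    space <- fit_score_space(feats)
    .shared_env$fixture <- list(ensemble = ens, features = feats,
                                space = space, templates = kv)
  }
  .shared_env$fixture
}
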