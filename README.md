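# ionclamp

Quantitative, model-free comparison of voltage- and calcium-gated ion
channel kinetics.

Thousands of Hodgkin–Huxley-style ion channel models have been published,
with heterogeneous naming, provenance and implementation — yet many of them
describe nearly identical currents, and nominally same-named channels can
behave very differently. `ionclamp` characterizes any such model purely by
its *behavior*: it clamps the channel through a standardized battery of
voltage protocols, reduces the recorded current traces to a low-dimensional
kinetic *score*, and compares, clusters and queries channels by distance in
score space. The package is aimed at computational neuroscientists who need
to deduplicate channel model collections, pick a representative model for a
kinetic phenotype, or match a newly recorded current against a reference
ensemble.

## The method

A channel model is a set of gating variables $x_i \in [0,1]$ with
first-order kinetics

$$\dot x_i = \frac{x_{i,\infty}(V) - x_i}{\tau_i(V)}, \qquad
I(t) = \bar g \prod_i x_i(t)^{p_i}\,(V(t) - E_\mathrm{rev}),$$

where $E_\mathrm{rev}$ is fixed or computed by the Nernst equation
$E = \frac{RT}{zF}\ln([ion]_\mathrm{out}/[ion]_\mathrm{in})$ at 37 °C.
Five voltage-clamp protocols (activation, inactivation, deactivation, ramp,
action potential), parameterized per ion class (Kv, Nav, Cav, KCa, Ih),
are integrated at $dt = 0.05$ ms with per-gate exponential-Euler updates
(exact for piecewise-constant clamp voltage). Calcium-gated channels are
run at seven calcium levels, $10^{-x}$ mM for $x = 2.0, 2.5, \dots, 5.0$.

Each trace set is flipped positive if inward-dominated, normalized by its
set maximum (removing $\bar g$), restricted to a protocol-specific analysis
window, subsampled to 512 points per trace and appended across graded steps
— e.g. $512 \times 16 = 8192$ values for Kv activation. Per protocol, the
ensemble's feature matrix is Z-scored by column and reduced by PCA keeping
99% of the variance (the *condition scores*); the five blocks are rescaled
by their score standard deviation, concatenated, and reduced once more by
PCA (99%) to a $D$-dimensional *total score* per channel. Kinetic
similarity is the Euclidean distance between total scores. Channels are
grouped by Ward's minimal-variance hierarchical clustering, with silhouette,
Dunn, Davies–Bouldin and Calinski–Harabasz indexes plus a trace-level
per-protocol *inner distance* (mean absolute deviation from the
cluster-mean trace, averaged over clusters) to guide the choice of cut. The
fitted transforms form a reusable score space: new simulated channels, or
experimentally recorded traces ingested from CSV, are projected into it and
matched to their nearest ensemble members.

## Worked example

Build a synthetic ensemble from three built-in Kv templates (Hodgkin–Huxley
delayed rectifier, A-type, m-type), score it, cluster it, and project a new
channel:

```r
library(ionclamp)
tl <- template_library()
ens <- generate_ensemble(ensemble_spec(tl[c("kv_hh", "kv_a", "kv_m")],
                                       n_per_template = 4,
                                       jitter_fraction = 0.02, seed = 7))
feats <- ensemble_features(ens$channels)   # 5 protocols x 12 channels
space <- fit_score_space(feats)
space
#> <score_space: 12 channels, 5 protocols -> D = 2 (>= 99% variance)>

tree <- ward_linkage(space$scores)
scan_k(tree, space$scores, k_range = 2:5)[, 1:5]
#>   k silhouette       dunn davies_bouldin calinski_harabasz
#> 1 2  0.6942324  0.9932679     0.40354448          21.98187
#> 2 3  0.9777753 16.7583301     0.03105270        7250.99491
#> 3 4  0.8481412  0.7977768     0.07685314        8174.07942
#> 4 5  0.6477785  1.1576987     0.16747902       16451.66036
```

The silhouette peak, Dunn peak and Davies–Bouldin minimum all point at
`k = 3` — the number of templates the ensemble was generated from. Cutting
there recovers the template partition exactly and names each cluster by its
dominant subtype:

```r
labels <- cut_clusters(tree, k = 3)
table(labels, ens$labels)
#> labels kv_a kv_hh kv_m
#>      1    0     4    0
#>      2    4     0    0
#>      3    0     0    4
reference_models(space$scores, labels)
#>           1           2           3
#> "kv_hh_j03"  "kv_a_j03"  "kv_m_j01"

probe <- generate_ensemble(ensemble_spec(tl["kv_a"], 1, 0.02,
                                         seed = 99))$channels[[1]]
sv <- project_scores(space, channel_features(probe), "new_channel")
nearest_members(space, sv, n = 3)
#>   channel_id    distance
#> 1   kv_a_j03 0.001377561
#> 2   kv_a_j02 0.015048528
#> 3   kv_a_j01 0.027789313
```

The unseen A-type variant lands next to the A-type members, far from the
other clusters — the projection workflow used to compare new models (or
recorded traces read with `read_trace_csv()`) against a reference ensemble.

A command-line driver wrapping the same functions ships at
`inst/cli/ionclamp.R`, with subcommands `fixtures`, `simulate`, `score`,
`cluster`, `project` and `protocol` (waveform dump); see the header of that
file for usage.

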