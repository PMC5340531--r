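---
title: "Model-free kinetic scoring of ion channel models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-free kinetic scoring of ion channel models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionclamp)
```

This vignette documents the scientific model behind `ionclamp`, the
numerical and design choices that were genuinely open, and what the
package's synthetic tests do and do not demonstrate about real data.

## The channel model and its assumptions

Channels are Hodgkin–Huxley style: independent gating variables
$x_i \in [0,1]$ relaxing as $\dot x_i = (x_{i,\infty} - x_i)/\tau_i$, with
the open fraction a product of integer powers and current density
$I = \bar g \prod_i x_i^{p_i} (V - E_\mathrm{rev})$ in mA/cm². This
deliberately excludes Markov-state schemes and ligand- or light-gated
channels: the method targets the voltage- and calcium-gated families (Kv,
Nav, Cav, KCa, Ih) that dominate published neuron models.

Published models express their rate functions in many ad-hoc forms. Rather
than emulating arbitrary code, `ionclamp` fixes a declarative closed-form
family that covers classical models and serializes cleanly to YAML:

* `alpha_beta` gates: $\alpha(V)$ and $\beta(V)$ are sums of exponential
  ($A e^{(V - V_h)/k}$), sigmoid ($A/(1 + e^{(V_h - V)/k})$) and linoid
  ($A (V - V_h)/(e^{(V - V_h)/k} - 1)$) terms, converted by
  $x_\infty = \alpha/(\alpha+\beta)$, $\tau = 1/(\alpha+\beta)$.
* `inf_tau` gates: a Boltzmann steady state and a bell-shaped (or fixed)
  time constant
  $\tau(V) = \tau_\mathrm{min} + A/(e^{(V - V_m)/k_1} + e^{-(V - V_m)/k_2})$.
* calcium-dependent gates (KCa only) multiply the voltage part of
  $x_\infty$ by a Hill saturation $(c/K_d)^h/(1 + (c/K_d)^h)$.

Rates are taken as already valid at the 37 °C simulation temperature
(`q10_factor = 1` by default); per-model temperature idiosyncrasies are out
of scope. Linoid terms have a removable singularity at $V = V_h$; within
$10^{-6}$ mV of it they are evaluated by the analytic limit $A \cdot k$,
avoiding catastrophic cancellation while keeping the function continuous
(verified on a fine grid in the tests).

Reversal potentials either come from the Nernst equation with
$R = 8.314462618$ J/(mol·K), $F = 96485.33212$ C/mol,
$T(\mathrm{K}) = {}^\circ\mathrm{C} + 273.15$, or are fixed (Ih, a mixed
cation current, uses −45 mV). The standard per-class concentrations shipped
in `inst/extdata/ion_defaults.csv` reproduce the class reversal potentials
(K⁺ −86.7, Na⁺ +50.0, Ca²⁺ +135.0 mV) to within 0.1 mV.

## Protocols

The 25 protocol parameterizations (5 classes × 5 protocols) ship as a
plain-text table (`inst/extdata/protocol_table.csv`) so the geometry is
inspectable and replaceable. Conventions that the table alone does not fix:

* **Step ranges include both endpoints** — validated by the 16-step Kv
  activation family (−80 to +70 mV in 10 mV increments).
* **Segments are left-closed**: the sample at a boundary time belongs to
  the incoming segment; voltage changes instantaneously.
* **Ramp geometry**: after the initial hold, eight linear segments
  alternate between the holding and peak voltage starting upward — four
  up/down pairs whose differing durations give four distinct slopes. Both
  the starting direction and the full-range assumption are conventions;
  because the whole table is replaceable, alternative geometries need no
  code change.
* **Action-potential waveform**: the protocol calls for a somatic
  recording of a regular-spiking neuron, which cannot be bundled. The
  package synthesizes a deterministic surrogate — a −65 mV baseline with
  stereotyped spikes (0.6 ms half-cosine rise to +30 mV, 1.4 ms
  repolarization to a −75 mV afterhyperpolarization, 6 ms exponential
  recovery) at 10 Hz from 100 ms on, with seeded 1 ms timing jitter. It is
  labelled synthetic throughout; a recorded waveform can be passed via
  `build_protocol(..., ap_waveform = )`.

## Clamp integration

Under ideal voltage clamp the gate ODEs are decoupled and linear in time
within any constant-voltage span, so each gate is advanced by the
exponential-Euler update $x \leftarrow x_\infty + (x - x_\infty)
e^{-dt/\tau}$ with $(x_\infty, \tau)$ evaluated at the clamped voltage of
the left sample. This is *exact* for piecewise-constant waveforms (the
dominant case) and unconditionally stable for the stiff Nav gates
($\tau \sim 0.1$ ms); on ramps at $dt = 0.05$ ms halving the step changes
currents by far less than 0.1% RMS (tested). The scan itself is a two-line
Rcpp kernel; rate evaluation stays vectorized in R. Gates are initialized
at steady state for the holding potential, which removes onset transients
and makes every run bit-reproducible. The recorded current is the
channel's own (no leak conductance): under ideal clamp a linear leak would
in any case be largely removed by the normalization step.

## Preprocessing and scoring

Decisions where the procedure was underdetermined:

* **Flip rule.** Inward currents must be flipped positive, but the
  detection rule is a choice: a trace *set* is flipped when its absolute
  minimum exceeds its absolute maximum. Set-level (not per-trace) flipping
  preserves the relative structure across graded steps.
* **Normalization denominator** is the maximum over the whole flipped set.
  Per-trace normalization would destroy the activation curve — the growth
  of peak current across steps — which is precisely the kinetic signature
  the scores should retain. An all-zero set returns a flagged zero vector
  with a warning instead of dividing by zero.
* **Subsampling** picks 512 uniformly spaced sample indexes of the
  analysis window, first and last included, with no anti-alias filtering
  (simulated traces are smooth). Windows range from ~1000 to ~42000
  samples, so 512 points always subsample, never interpolate.
* **Concatenation order** is ascending step voltage, and for KCa calcium
  levels outermost in descending concentration. Any fixed order yields
  identical distances; this one is simply documented and frozen.
* **Z-scoring** uses the population (divide-by-N) standard deviation;
  zero-variance columns map to 0. With N ensemble members per class the
  N vs N−1 choice only rescales columns uniformly and is invisible after
  the per-protocol score normalization; population form keeps the "unit
  variance" property exact in-sample.
* **PCA stages** retain the smallest dimensionality reaching 99%
  cumulative variance (`variance_threshold`, configurable). The final PCA
  re-centers the concatenated condition scores (`center_final = TRUE` by
  default; configurable, since an uncentered second stage is also
  defensible). Principal-axis signs are fixed by making each axis's
  largest-magnitude loading positive, so results are reproducible across
  linear-algebra backends.
* **Degenerate ensembles** (identical members) give zero-variance score
  blocks; the per-protocol scale normalizer then divides by 1 instead of
  0, and all pairwise distances are exactly zero.

Because normalization removes $\bar g$ before any statistics, scores are
invariant to the maximal conductance end to end — exactly so for dyadic
scale factors, and to rounding error (≤ 1 ulp per division) otherwise.

## Clustering

Ward linkage is computed by `stats::hclust(method = "ward.D2")` on
Euclidean score distances; merge heights are then monotone and, for two
singletons, equal their distance. The test suite checks this agglomeration
against an independently coded brute-force greedy Ward (recomputing all
pair costs each step) on small point sets, and the four validity indexes
(silhouette via the `cluster` package; Dunn, Davies–Bouldin and
Calinski–Harabasz coded here) against direct formula evaluation.
Tie-breaking among equal-cost merges follows `hclust`; ties occur only on
degenerate (duplicated-point) inputs, where all orders give the same
heights.

No cut is selected automatically. The appropriate number of clusters is a
judgment call over several index profiles (silhouette/Dunn/CH peaks,
Davies–Bouldin minima, knees in the inner distance, singleton counts), so
the package exposes the full `scan_k()` table and leaves the choice to the
user.

The per-protocol inner distance uses the norm
$\|s\| = \frac{1}{L}\sum_{i=1}^{L}|s(i)|$ with $L$ the *full* appended
length — for KCa, all $c \cdot 512 \cdot 7$ entries. Dividing per
concentration block instead would change the value by a constant factor
only. It is computed on raw (non-Z-scored) feature traces, matching its
role as a trace-level, transform-free heterogeneity measure.

## Genealogy

Ancestor–descendant relations between models form a directed graph;
*families* are the connected components of its undirected skeleton
(via `igraph`), numbered by decreasing size then smallest member id.
Metadata are free text — there is no controlled vocabulary across
publications — so crosstab matching is exact-string after lowercasing and
trimming.

## The synthetic ensemble generator

`generate_ensemble()` emulates the diversity of a published-model corpus:
each template is replicated with voltage midpoints shifted by
$\mathcal N(0, (100\,\mathrm{mV}) \cdot \mathrm{jitter})$ — 1% jitter ≈
1 mV, a percentage of the ~100 mV physiological range — and rates, slopes,
time constants and calcium affinities scaled log-normally with
$\sigma_{\log} = \mathrm{jitter}$. Members violating the gating
invariants are resampled (bounded retries). This mimics the biological and
fitting variability seen between same-subtype models, but *not* other
axes of real corpus diversity: alternative rate-law shapes, extra gates,
temperature conventions, or implementation bugs. Recovery results (ARI = 1
at 1% jitter for 5 Kv templates × 10 members; test fixture sizes chosen to
exercise all five protocols for ~50 channels) therefore demonstrate the
pipeline's correctness and discriminative power on well-posed kinetic
families — not a corpus-level cluster census, which would require the
real model collections.

## Known limitations

* Single ideal-clamp compartment: no series resistance, space-clamp or
  leak-subtraction artifacts; recorded-data workflows assume such
  corrections were applied upstream (e.g. P/4).
* HH-style kinetics only; calcium acts as a fixed parameter per run, not a
  dynamic variable.
* The action-potential protocol uses a synthetic spike train unless a
  recorded waveform is supplied.
* Scores are ensemble-relative: distances are only comparable within one
  fitted score space, and spaces fitted on different ensembles (or ion
  classes) are deliberately incompatible.
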