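rate_term <- function(type, rate, vhalf, slope) {
  list(type = type, rate = rate, vhalf = vhalf, slope = slope)
}

bell_tau <- function(min, amp, vmax, kleft, kright = kleft) {
  list(min = min, amp = amp, vmax = vmax, kleft = kleft, kright = kright)
}

boltzmann <- function(vhalf, slope) list(vhalf = vhalf, slope = slope)

kv_nernst <- function() list(z = 1, conc_in = 85.0, conc_out = 3.3152396)
nav_nernst <- function() list(z = 1, conc_in = 21.0, conc_out = 136.3753955)
cav_nernst <- function() list(z = 2, conc_in = 8.1929e-5, conc_out = 2.0)

#' Built-in channel model templates
#'
#' A documented library of classical Hodgkin-Huxley style channel models
#' spanning all five ion classes, used as the basis for synthetic ensembles
#' and as worked examples. Subtype labels follow common usage: `A` (A-type,
#' transient inactivating K), `dr` (delayed rectifier, sustained K), `HH`
#' (squid-axon kinetics), `m` (muscarinic slow K), `IR` (inward rectifier),
#' `l.t.` (low-threshold Ca), `SK`/`BK` (small/big conductance Ca-gated K),
#' `HCN` (hyperpolarization-activated cation).
#'
#' All templates use class reversal potentials computed by the Nernst
#' equation from the standard concentrations (see [ion_defaults()]), except
#' Ih, whose mixed-cation reversal is fixed at -45 mV. Every template
#' satisfies the gating invariants (`x_inf` in \[0,1\], `tau > 0` on
#' \[-150, 70\] mV).
#'
#' @return Named list of [channel_model()] objects:
#' \describe{
#'   \item{kv_hh}{squid delayed rectifier, `n^4`, alpha/beta rates.}
#'   \item{kv_dr}{cortical-style delayed rectifier, `n^2`, inf/tau form.}
#'   \item{kv_a}{A-type transient K, `a^3 b` (activation + inactivation).}
#'   \item{kv_m}{m-type slow non-inactivating K.}
#'   \item{kv_ir}{inward rectifier K (opens on hyperpolarization).}
#'   \item{nav_hh}{squid transient Na, `m^3 h`.}
#'   \item{cav_lt}{low-threshold (T-type) Ca, `m^2 h`.}
#'   \item{kca_sk}{SK-type Ca-gated K, purely calcium-dependent Hill gate.}
#'   \item{kca_bk}{BK-type Ca- and voltage-gated K.}
#'   \item{ih_hcn}{HCN hyperpolarization-activated cation current.}
#' }
#' @examples
#' names(template_library())
#' @export
template_library <- function() {
  if (!is.null(.pkg_env$templates)) return(.pkg_env$templates)
  lib <- list(
    # Squid-axon delayed rectifier: alpha_n linoid, beta_n exponential.
    kv_hh = channel_model(
      "kv_hh", "Kv", subtype = "HH", nernst = kv_nernst(),
      gates = list(gate_spec("n", 4L, "alpha_beta", list(
        alpha = list(rate_term("linoid", -0.01, -55, -10)),
        beta = list(rate_term("exponential", 0.125, -65, -80))
      )))
    ),
    kv_dr = channel_model(
      "kv_dr", "Kv", subtype = "dr", nernst = kv_nernst(),
      gates = list(gate_spec("n", 2L, "inf_tau", list(
        inf = boltzmann(-20, 9),
        tau = bell_tau(1, 20, -30, 15)
      )))
    ),
    kv_a = channel_model(
      "kv_a", "Kv", subtype = "A", nernst = kv_nernst(),
      gates = list(
        gate_spec("a", 3L, "inf_tau", list(
          inf = boltzmann(-30, 10),
          tau = bell_tau(0.5, 4, -40, 20)
        )),
        gate_spec("b", 1L, "inf_tau", list(
          inf = boltzmann(-70, -6),
          tau = bell_tau(15, 50, -60, 30)
        ))
      )
    ),
    kv_m = channel_model(
      "kv_m", "Kv", subtype = "m", nernst = kv_nernst(),
      gates = list(gate_spec("m", 1L, "inf_tau", list(
        inf = boltzmann(-35, 10),
        tau = bell_tau(20, 120, -35, 20)
      )))
    ),
    kv_ir = channel_model(
      "kv_ir", "Kv", subtype = "IR", nernst = kv_nernst(),
      gates = list(gate_spec("r", 1L, "inf_tau", list(
        inf = boltzmann(-80, -12),
        tau = bell_tau(2, 8, -80, 20)
      )))
    ),
    nav_hh = channel_model(
      "nav_hh", "Nav", subtype = "HH", nernst = nav_nernst(),
      gates = list(
        gate_spec("m", 3L, "alpha_beta", list(
          alpha = list(rate_term("linoid", -0.1, -40, -10)),
          beta = list(rate_term("exponential", 4, -65, -18))
        )),
        gate_spec("h", 1L, "alpha_beta", list(
          alpha = list(rate_term("exponential", 0.07, -65, -20)),
          beta = list(rate_term("sigmoid", 1, -35, 10))
        ))
      )
    ),
    cav_lt = channel_model(
      "cav_lt", "Cav", subtype = "l.t.", nernst = cav_nernst(),
      gates = list(
        gate_spec("m", 2L, "inf_tau", list(
          inf = boltzmann(-57, 6.2),
          tau = bell_tau(0.6, 6, -75, 15)
        )),
        gate_spec("h", 1L, "inf_tau", list(
          inf = boltzmann(-81, -4),
          tau = bell_tau(10, 80, -80, 15)
        ))
      )
    ),
    kca_sk = channel_model(
      "kca_sk", "KCa", subtype = "SK", nernst = kv_nernst(),
      gates = list(gate_spec("z", 1L, "inf_tau", list(
        ca = list(kd = 3e-4, hill = 4),
        tau = list(fixed = 8)
      ), ca_dependent = TRUE))
    ),
    kca_bk = channel_model(
      "kca_bk", "KCa", subtype = "BK", nernst = kv_nernst(),
      gates = list(gate_spec("o", 1L, "inf_tau", list(
        ca = list(kd = 1e-3, hill = 2),
        inf = boltzmann(-20, 15),
        tau = bell_tau(1, 6, -20, 20)
      ), ca_dependent = TRUE))
    ),
    ih_hcn = channel_model(
      "ih_hcn", "Ih", subtype = "HCN", erev = -45,
      gates = list(gate_spec("q", 1L, "inf_tau", list(
        inf = boltzmann(-80, -8),
        tau = bell_tau(30, 1400, -85, 15.5)
      )))
    )
  )
  for (ch in lib) validate_channel(ch)
  .pkg_env$templates <- lib
  lib
}
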