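# Evaluate (x_inf, tau) along a voltage series, exploiting repeated voltages
# in stepped protocols (holds produce few unique values).
gate_rates_series <- function(gate, V, ca) {
  uv <- unique(V)
  if (length(uv) * 4L < length(V)) {
    st <- gate_steady_state(gate, uv, ca = ca)
    m <- match(V, uv)
    list(inf = st$inf[m], tau = st$tau[m])
  } else {
    gate_steady_state(gate, V, ca = ca)
  }
}

# Integrate one waveform for one channel at one calcium level.
integrate_waveform <- function(channel, V, dt, erev, ca = NULL) {
  open <- rep(1, length(V))
  for (gate in channel$gates) {
    g_ca <- if (gate$ca_dependent) ca else NULL
    st <- gate_rates_series(gate, V, g_ca)
    a <- exp(-dt / st$tau)
    x <- .gate_scan(st$inf, a, st$inf[1])
    if (!all(is.finite(x))) {
      stop_invalid("channel '%s', gate '%s': non-finite gate state",
                   channel$id, gate$name)
    }
    open <- open * x^gate$exponent
  }
  channel$gbar * open * (V - erev)
}

#' Simulate a channel under a voltage-clamp protocol
#'
#' Integrates the channel's gating variables under ideal voltage clamp with
#' per-gate exponential-Euler updates
#' `x <- x_inf + (x - x_inf) * exp(-dt/tau)` at the protocol timestep
#' (default 0.05 ms), with `(x_inf, tau)` evaluated at the clamped voltage.
#' Gates are initialized at steady state for the first sample's voltage (the
#' holding potential), which removes onset transients and makes runs exactly
#' reproducible. The recorded current density is the channel's own current
#' `I(t) = gbar * prod_i x_i(t)^p_i * (V(t) - E_rev)` (no leak), in mA/cm^2
#' for `gbar` in S/cm^2 and voltages in mV.
#'
#' Calcium-gated (KCa) channels are simulated once per calcium level (the
#' seven standard concentrations by default, descending), with calcium held
#' fixed during each run.
#'
#' @param channel a [channel_model()].
#' @param protocol a [build_protocol()] object for the channel's ion class.
#' @param ca_levels calcium concentrations, mM; required to be `NULL` unless
#'   the channel is KCa (default: [default_ca_levels()]).
#' @return An object of class `trace_set`: a list with `channel_id`,
#'   `protocol`, `dt`, `conditions` (data frame with `ca_level` and `step`),
#'   and `traces` (conditions x time matrix of current density, mA/cm^2).
#' @examples
#' ch <- template_library()[["kv_a"]]
#' ts <- run_clamp(ch, build_protocol("Kv", "activation"))
#' dim(ts$traces)   # 16 steps x 14001 samples
#' @export
run_clamp <- function(channel, protocol, ca_levels = NULL) {
  stopifnot(inherits(channel, "channel_model"),
            inherits(protocol, "voltage_protocol"))
  if (protocol$ion_class != channel$ion_class) {
    stop_invalid("protocol is for class %s, channel '%s' is %s",
                 protocol$ion_class, channel$id, channel$ion_class)
  }
  if (channel$ion_class == "KCa") {
    if (is.null(ca_levels)) ca_levels <- default_ca_levels()
  } else if (!is.null(ca_levels)) {
    stop_invalid("ca_levels are only valid for KCa channels")
  }
  erev <- channel_erev(channel)
  n_steps <- length(protocol$segments)
  cas <- if (is.null(ca_levels)) NA_real_ else ca_levels
  conditions <- expand.grid(step = seq_len(n_steps), ca_level = cas,
                            KEEP.OUT.ATTRS = FALSE)
  # calcium outermost (descending as given), steps ascending within a level
  conditions <- conditions[order(match(conditions$ca_level, cas),
                                 conditions$step), c("ca_level", "step")]
  rownames(conditions) <- NULL
  n_t <- round(protocol$total_duration / protocol$dt) + 1L
  traces <- matrix(NA_real_, nrow = nrow(conditions), ncol = n_t)
  waves <- lapply(seq_len(n_steps), function(i) sample_waveform(protocol, i))
  for (i in seq_len(nrow(conditions))) {
    ca <- conditions$ca_level[i]
    traces[i, ] <- integrate_waveform(
      channel, waves[[conditions$step[i]]], protocol$dt, erev,
      ca = if (is.na(ca)) NULL else ca)
  }
  structure(
    list(channel_id = channel$id, ion_class = channel$ion_class,
         protocol_name = protocol$name, protocol = protocol,
         dt = protocol$dt, conditions = conditions,
         ca_levels = if (is.null(ca_levels)) NULL else ca_levels,
         traces = traces),
    class = "trace_set"
  )
}

#' Run all five protocols for a channel
#'
#' Builds the activation, inactivation, deactivation, ramp and
#' action-potential protocols for the channel's ion class and simulates each.
#'
#' @param channel a [channel_model()].
#' @param dt integration timestep, ms.
#' @param table protocol parameter table (default [protocol_table()]).
#' @param ca_levels calcium levels for KCa channels (default the standard 7).
#' @return Named list of `trace_set`, one per protocol.
#' @export
run_all_protocols <- function(channel, dt = 0.05, table = protocol_table(),
                              ca_levels = NULL) {
  protos <- lapply(.PROTOCOL_NAMES, function(nm) {
    build_protocol(channel$ion_class, nm, dt = dt, table = table)
  })
  names(protos) <- .PROTOCOL_NAMES
  lapply(protos, function(p) run_clamp(channel, p, ca_levels = ca_levels))
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set %s/%s: %d trace(s) x %d samples, dt = %g ms>\n",
              x$channel_id, x$protocol_name, nrow(x$traces), ncol(x$traces),
              x$dt))
  invisible(x)
}
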