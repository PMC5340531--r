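#' Gating-variable specification
#'
#' A gate is a dimensionless state variable `x` in \[0, 1\] obeying first-order
#' relaxation `dx/dt = (x_inf(V) - x) / tau(V)`; the channel open fraction is
#' the product of gate states raised to integer powers. Two closed-form rate
#' families are supported:
#'
#' * `"alpha_beta"`: forward/backward rates `alpha(V)`, `beta(V)` given as sums
#'   of exponential, sigmoid and linoid terms; then `x_inf = alpha/(alpha+beta)`
#'   and `tau = 1/(alpha+beta)`.
#' * `"inf_tau"`: a Boltzmann steady state
#'   `x_inf = 1/(1 + exp((vhalf - V)/slope))` and a bell-shaped (or fixed)
#'   time constant
#'   `tau = min + amp / (exp((V - vmax)/kleft) + exp(-(V - vmax)/kright))`.
#'
#' Calcium-dependent gates (`ca_dependent = TRUE`, `inf_tau` form only)
#' multiply the voltage part of `x_inf` (or 1, if no voltage part is given) by
#' a Hill saturation `(ca/kd)^h / (1 + (ca/kd)^h)`.
#'
#' Rate terms for the `alpha_beta` form are lists
#' `list(type, rate, vhalf, slope)` with `rate` in 1/ms and voltages in mV:
#'
#' * exponential: `rate * exp((V - vhalf)/slope)`
#' * sigmoid: `rate / (1 + exp((vhalf - V)/slope))`
#' * linoid: `rate * (V - vhalf) / (exp((V - vhalf)/slope) - 1)`, evaluated by
#'   its analytic limit `rate * slope` within 1e-6 mV of the removable
#'   singularity at `V = vhalf`.
#'
#' @param name gate label (e.g. `"m"`, `"h"`, `"n"`).
#' @param exponent positive integer power `p` in `x^p`.
#' @param rate_form `"alpha_beta"` or `"inf_tau"`.
#' @param rate_params parameter list for the chosen family (see Details).
#' @param ca_dependent logical; gate driven by intracellular calcium.
#' @param q10_factor dimensionless rate scaling (default 1: rates are taken as
#'   already valid at the 37 degree simulation temperature).
#' @return An object of class `gate_spec`.
#' @seealso [gate_steady_state()], [channel_model()]
#' @export
gate_spec <- function(name, exponent = 1L,
                      rate_form = c("alpha_beta", "inf_tau"),
                      rate_params = list(),
                      ca_dependent = FALSE, q10_factor = 1) {
  rate_form <- match.arg(rate_form)
  if (!is.numeric(exponent) || length(exponent) != 1L ||
      exponent < 1 || exponent != round(exponent)) {
    stop_invalid("gate '%s': exponent must be a positive integer", name)
  }
  if (ca_dependent && rate_form != "inf_tau") {
    stop_invalid("gate '%s': calcium-dependent gates use the 'inf_tau' form",
                 name)
  }
  if (ca_dependent && is.null(rate_params$ca)) {
    stop_invalid("gate '%s': ca_dependent gate needs rate_params$ca", name)
  }
  if (rate_form == "alpha_beta" &&
      (is.null(rate_params$alpha) || is.null(rate_params$beta))) {
    stop_invalid("gate '%s': alpha_beta form needs rate_params$alpha/$beta",
                 name)
  }
  if (rate_form == "inf_tau" && is.null(rate_params$tau)) {
    stop_invalid("gate '%s': inf_tau form needs rate_params$tau", name)
  }
  if (q10_factor <= 0) stop_invalid("gate '%s': q10_factor must be > 0", name)
  structure(
    list(name = as.character(name), exponent = as.integer(exponent),
         rate_form = rate_form, rate_params = rate_params,
         ca_dependent = isTRUE(ca_dependent), q10_factor = q10_factor),
    class = "gate_spec"
  )
}

# Evaluate one alpha/beta rate term, vectorized over V.
eval_rate_term <- function(term, V) {
  A <- term$rate
  vh <- term$vhalf
  k <- term$slope
  switch(term$type,
    exponential = A * exp((V - vh) / k),
    sigmoid = A / (1 + exp((vh - V) / k)),
    linoid = {
      dv <- V - vh
      out <- numeric(length(V))
      sing <- abs(dv) < 1e-6
      out[sing] <- A * k
      out[!sing] <- A * dv[!sing] / (exp(dv[!sing] / k) - 1)
      out
    },
    stop_invalid("unknown rate term type '%s'", term$type)
  )
}

eval_rate_sum <- function(terms, V) {
  out <- numeric(length(V))
  for (term in terms) out <- out + eval_rate_term(term, V)
  out
}

eval_bell_tau <- function(tau, V) {
  if (!is.null(tau$fixed)) {
    rep_len(tau$fixed, length(V))
  } else {
    tau$min + tau$amp /
      (exp((V - tau$vmax) / tau$kleft) + exp(-(V - tau$vmax) / tau$kright))
  }
}

#' Steady state and time constant of a gate
#'
#' Evaluates `x_inf(V)` and `tau(V)` for a gate, vectorized over voltage.
#' For `alpha_beta` gates the standard conversion `x_inf = alpha/(alpha+beta)`,
#' `tau = 1/(alpha+beta)` is used; linoid rate terms are evaluated by their
#' analytic limit at the removable singularity. The `q10_factor` scales both
#' rates, i.e. divides `tau`.
#'
#' @param gate a [gate_spec()].
#' @param V membrane voltage, mV (vector allowed).
#' @param ca intracellular calcium concentration, mM. Required if and only if
#'   the gate is calcium-dependent.
#' @return A list with numeric vectors `inf` (in \[0,1\]) and `tau` (ms, > 0).
#' @examples
#' g <- template_library()[["kv_hh"]]$gates[[1]]
#' gate_steady_state(g, V = c(-80, -55, 0))
#' @export
gate_steady_state <- function(gate, V, ca = NULL) {
  stopifnot(inherits(gate, "gate_spec"))
  if (gate$ca_dependent && is.null(ca)) {
    stop_invalid("gate '%s' is calcium-dependent: supply ca (mM)", gate$name)
  }
  if (!gate$ca_dependent && !is.null(ca)) {
    stop_invalid("gate '%s' is not calcium-dependent: ca must be absent",
                 gate$name)
  }
  p <- gate$rate_params
  if (gate$rate_form == "alpha_beta") {
    a <- eval_rate_sum(p$alpha, V)
    b <- eval_rate_sum(p$beta, V)
    inf <- a / (a + b)
    tau <- 1 / (a + b)
  } else {
    if (is.null(p$inf)) {
      inf <- rep_len(1, length(V))
    } else {
      inf <- 1 / (1 + exp((p$inf$vhalf - V) / p$inf$slope))
    }
    tau <- eval_bell_tau(p$tau, V)
    if (gate$ca_dependent) {
      r <- (ca / p$ca$kd)^p$ca$hill
      inf <- inf * (r / (1 + r))
    }
  }
  tau <- tau / gate$q10_factor
  list(inf = inf, tau = tau)
}

#' Check gate invariants over the physiological voltage range
#'
#' Sweeps `V` over \[-150, 70\] mV (and, for calcium-dependent gates, calcium
#' over the seven standard concentrations) and verifies that `x_inf` stays in
#' \[0, 1\] and `tau` stays strictly positive and finite.
#'
#' @param gate a [gate_spec()].
#' @param v_grid voltages to check, mV.
#' @param ca_grid calcium levels to check for calcium-dependent gates, mM.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_gate <- function(gate, v_grid = seq(-150, 70, by = 1),
                          ca_grid = default_ca_levels()) {
  cas <- if (gate$ca_dependent) ca_grid else list(NULL)
  for (ca in cas) {
    st <- gate_steady_state(gate, v_grid, ca = ca)
    if (!all(is.finite(st$inf)) || any(st$inf < 0 | st$inf > 1)) {
      stop_invalid("gate '%s': x_inf leaves [0,1] on [-150, 70] mV",
                   gate$name)
    }
    if (!all(is.finite(st$tau)) || any(st$tau <= 0)) {
      stop_invalid("gate '%s': tau must be finite and > 0 on [-150, 70] mV",
                   gate$name)
    }
  }
  invisible(TRUE)
}

#' @export
print.gate_spec <- function(x, ...) {
  cat(sprintf("<gate %s^%d, %s%s>\n", x$name, x$exponent, x$rate_form,
              if (x$ca_dependent) ", Ca-dependent" else ""))
  invisible(x)
}
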