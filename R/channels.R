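#' Nernst reversal potential
#'
#' Computes the single-ion equilibrium potential
#' `E = (R T / (z F)) ln(c_out / c_in)` with `T` in kelvin
#' (`T = temperature + 273.15`), `R = 8.314462618` J/(mol K) and
#' `F = 96485.33212` C/mol.
#'
#' @param z integer ionic valence (nonzero; +1 for K+/Na+, +2 for Ca2+).
#' @param conc_in,conc_out intra-/extracellular concentrations, mM (> 0).
#' @param temperature temperature in degrees Celsius (default 37).
#' @return Reversal potential in mV.
#' @examples
#' nernst_potential(1, 85.0, 3.3152396)    # K+ at 37 C, about -86.7 mV
#' nernst_potential(2, 8.1929e-5, 2.0)     # Ca2+ at 37 C, about 135 mV
#' @export
nernst_potential <- function(z, conc_in, conc_out, temperature = 37) {
  if (length(z) != 1L || z == 0 || z != round(z)) {
    stop_invalid("z must be a single nonzero integer valence")
  }
  if (!is.numeric(conc_in) || !is.numeric(conc_out) ||
      any(conc_in <= 0) || any(conc_out <= 0)) {
    stop_invalid("concentrations must be positive (mM)")
  }
  tk <- temperature + .ZERO_CELSIUS
  1000 * (.GAS_CONSTANT * tk / (z * .FARADAY)) * log(conc_out / conc_in)
}

#' Per-class simulation defaults
#'
#' Reversal potentials, ionic concentrations, valence, temperature and
#' integration timestep used for each of the five ion channel classes
#' (Kv, Nav, Cav, KCa, Ih). Concentrations are not used for Ih, whose
#' reversal potential is fixed at -45 mV.
#'
#' @param ion_class optional class label; if given, the single matching row.
#' @return A data frame (or one-row data frame) of defaults.
#' @export
ion_defaults <- function(ion_class = NULL) {
  if (is.null(.pkg_env$ion_defaults)) {
    path <- system.file("extdata", "ion_defaults.csv", package = "ionclamp")
    .pkg_env$ion_defaults <- read.csv(path, stringsAsFactors = FALSE)
  }
  tab <- .pkg_env$ion_defaults
  if (is.null(ion_class)) return(tab)
  row <- tab[tab$ion_class == ion_class, , drop = FALSE]
  if (nrow(row) != 1L) stop_invalid("unknown ion class '%s'", ion_class)
  row
}

#' The seven standard intracellular calcium levels (mM)
#'
#' Calcium-gated channels are simulated at concentrations `10^-x` mM with
#' `x = 2.0, 2.5, ..., 5.0` (i.e. 10 uM down to 10 nM), listed in descending
#' concentration order.
#'
#' @return Numeric vector of 7 concentrations, mM.
#' @export
default_ca_levels <- function() {
  10^-seq(2.0, 5.0, by = 0.5)
}

.ION_CLASSES <- c("Kv", "Nav", "Cav", "KCa", "Ih")

#' Ion channel model
#'
#' A channel model is a set of gating variables with an ion class, a maximal
#' conductance and a reversal-potential specification. The simulated current
#' density is `I = gbar * prod_i x_i^p_i * (V - E_rev)` in mA/cm^2.
#'
#' The reversal potential is either fixed (`erev` in mV) or computed by the
#' Nernst equation from `nernst = list(z, conc_in, conc_out)` at the class
#' temperature (see [ion_defaults()]); exactly one of the two must be given.
#'
#' @param id channel identifier (used as label throughout the pipeline).
#' @param ion_class one of `"Kv"`, `"Nav"`, `"Cav"`, `"KCa"`, `"Ih"`.
#' @param gates list of [gate_spec()] objects.
#' @param gbar maximal conductance, S/cm^2 (> 0; scores are invariant to it).
#' @param erev fixed reversal potential, mV (or `NULL`).
#' @param nernst list with `z`, `conc_in`, `conc_out` (mM) for Nernst
#'   computation (or `NULL`).
#' @param inward sign-convention label: does the channel carry a
#'   predominantly inward current under physiological gradients? Defaults by
#'   class (Nav/Cav/Ih inward). Metadata only; current sign follows
#'   `V - E_rev`.
#' @param subtype free-text kinetic subtype label (e.g. `"A"`, `"dr"`,
#'   `"HH"`), used for cluster naming and crosstabs.
#' @return An object of class `channel_model`.
#' @examples
#' ch <- template_library()[["kv_dr"]]
#' channel_erev(ch)
#' @export
channel_model <- function(id, ion_class, gates, gbar = 1.0,
                          erev = NULL, nernst = NULL, inward = NULL,
                          subtype = NA_character_) {
  if (!ion_class %in% .ION_CLASSES) {
    stop_invalid("ion_class must be one of %s",
                 paste(.ION_CLASSES, collapse = ", "))
  }
  if (!is.list(gates) || length(gates) == 0L ||
      !all(vapply(gates, inherits, logical(1), "gate_spec"))) {
    stop_invalid("gates must be a nonempty list of gate_spec objects")
  }
  if (gbar <= 0) stop_invalid("gbar must be > 0 (S/cm^2)")
  if (is.null(erev) == is.null(nernst)) {
    stop_invalid("give exactly one of erev (mV) or nernst (z, conc_in, conc_out)")
  }
  n_ca <- sum(vapply(gates, function(g) g$ca_dependent, logical(1)))
  if (ion_class == "KCa" && n_ca == 0L) {
    stop_invalid("KCa models need at least one calcium-dependent gate")
  }
  if (ion_class != "KCa" && n_ca > 0L) {
    stop_invalid("only KCa models may have calcium-dependent gates")
  }
  if (is.null(inward)) inward <- ion_class %in% c("Nav", "Cav", "Ih")
  names(gates) <- vapply(gates, function(g) g$name, character(1))
  obj <- structure(
    list(id = as.character(id), ion_class = ion_class, gates = gates,
         gbar = gbar,
         erev_spec = if (!is.null(erev)) {
           list(type = "fixed", erev = erev)
         } else {
           list(type = "nernst", z = nernst$z, conc_in = nernst$conc_in,
                conc_out = nernst$conc_out)
         },
         inward = isTRUE(inward), subtype = as.character(subtype)),
    class = "channel_model"
  )
  obj
}

#' Reversal potential of a channel model
#'
#' @param channel a [channel_model()].
#' @param temperature temperature in degrees Celsius for Nernst computation.
#' @return Reversal potential, mV.
#' @export
channel_erev <- function(channel, temperature = 37) {
  es <- channel$erev_spec
  if (es$type == "fixed") es$erev
  else nernst_potential(es$z, es$conc_in, es$conc_out, temperature)
}

#' Validate a channel model against the gating invariants
#'
#' Checks class/gate consistency and sweeps every gate over the physiological
#' voltage (and calcium) range via [validate_gate()].
#'
#' @param channel a [channel_model()].
#' @return `TRUE` invisibly, or an error.
#' @export
validate_channel <- function(channel) {
  stopifnot(inherits(channel, "channel_model"))
  for (g in channel$gates) validate_gate(g)
  invisible(TRUE)
}

#' @export
print.channel_model <- function(x, ...) {
  gs <- vapply(x$gates, function(g) sprintf("%s^%d", g$name, g$exponent),
               character(1))
  cat(sprintf("<channel_model %s [%s%s] %s, gbar = %g S/cm^2, Erev = %.1f mV>\n",
              x$id, x$ion_class,
              if (!is.na(x$subtype)) paste0("/", x$subtype) else "",
              paste(gs, collapse = " "), x$gbar, channel_erev(x)))
  invisible(x)
}
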