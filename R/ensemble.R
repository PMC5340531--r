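#' Specification for a synthetic channel ensemble
#'
#' Synthetic ensembles emulate the parameter diversity found across
#' published channel models: each template is replicated with jittered
#' kinetic parameters, giving an ensemble with known ground-truth structure
#' against which clustering and projection can be validated.
#'
#' The jitter model applies `jitter_fraction` on two natural scales:
#' half-voltages (and other voltage midpoints) are shifted additively by
#' `Normal(0, jitter_fraction * 100 mV)` — i.e. 1% jitter shifts midpoints
#' by about 1 mV, a percentage of the ~100 mV physiological range — while
#' rates, slopes, time constants and calcium affinities are scaled
#' log-normally with `sdlog = jitter_fraction`. Hill coefficients and gate
#' exponents are left untouched.
#'
#' @param templates list of [channel_model()] objects sharing one ion class.
#' @param n_per_template members generated per template (>= 1).
#' @param jitter_fraction relative perturbation scale (>= 0; 0 reproduces
#'   the templates exactly).
#' @param seed integer seed; generation is deterministic given the spec.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(templates, n_per_template, jitter_fraction,
                          seed = 1L) {
  if (length(templates) == 0L ||
      !all(vapply(templates, inherits, logical(1), "channel_model"))) {
    stop_invalid("templates must be channel_model objects")
  }
  cls <- unique(vapply(templates, function(t) t$ion_class, character(1)))
  if (length(cls) != 1L) stop_invalid("templates must share one ion class")
  if (n_per_template < 1L) stop_invalid("n_per_template must be >= 1")
  if (jitter_fraction < 0) stop_invalid("jitter_fraction must be >= 0")
  names(templates) <- vapply(templates, function(t) t$id, character(1))
  structure(
    list(ion_class = cls, templates = templates,
         n_per_template = as.integer(n_per_template),
         jitter_fraction = jitter_fraction, seed = as.integer(seed)),
    class = "ensemble_spec"
  )
}

jitter_value <- function(x, kind, jf) {
  switch(kind,
    voltage = x + rnorm(1, sd = jf * 100),
    scale = x * exp(rnorm(1, sd = jf)),
    x
  )
}

jitter_gate <- function(gate, jf) {
  p <- gate$rate_params
  if (gate$rate_form == "alpha_beta") {
    for (side in c("alpha", "beta")) {
      p[[side]] <- lapply(p[[side]], function(term) {
        term$vhalf <- jitter_value(term$vhalf, "voltage", jf)
        term$rate <- jitter_value(term$rate, "scale", jf)
        term$slope <- jitter_value(term$slope, "scale", jf)
        term
      })
    }
  } else {
    if (!is.null(p$inf)) {
      p$inf$vhalf <- jitter_value(p$inf$vhalf, "voltage", jf)
      p$inf$slope <- jitter_value(p$inf$slope, "scale", jf)
    }
    if (!is.null(p$tau$fixed)) {
      p$tau$fixed <- jitter_value(p$tau$fixed, "scale", jf)
    } else {
      p$tau$min <- jitter_value(p$tau$min, "scale", jf)
      p$tau$amp <- jitter_value(p$tau$amp, "scale", jf)
      p$tau$vmax <- jitter_value(p$tau$vmax, "voltage", jf)
      p$tau$kleft <- jitter_value(p$tau$kleft, "scale", jf)
      p$tau$kright <- jitter_value(p$tau$kright, "scale", jf)
    }
    if (!is.null(p$ca)) p$ca$kd <- jitter_value(p$ca$kd, "scale", jf)
  }
  gate$rate_params <- p
  gate
}

#' Generate a synthetic ensemble with known ground truth
#'
#' Deterministically (given the spec's seed) perturbs each template
#' `n_per_template` times under the jitter model of [ensemble_spec()].
#' Members violating the gating invariants are resampled (up to 25 tries
#' each) so every generated model is a valid channel.
#'
#' @param spec an [ensemble_spec()].
#' @return List with `channels` (named list of [channel_model()]), `labels`
#'   (named character vector: member id -> source template id) and `spec`.
#' @examples
#' tl <- template_library()
#' ens <- generate_ensemble(ensemble_spec(tl[c("kv_a", "kv_dr")],
#'                                        n_per_template = 3,
#'                                        jitter_fraction = 0.01, seed = 42))
#' ens$labels
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  with_seed(spec$seed, {
    channels <- list()
    labels <- character(0)
    for (tmpl in spec$templates) {
      for (i in seq_len(spec$n_per_template)) {
        id <- sprintf("%s_j%02d", tmpl$id, i)
        member <- NULL
        for (try in seq_len(25L)) {
          cand <- tmpl
          cand$id <- id
          cand$gates <- lapply(tmpl$gates, jitter_gate,
                               jf = spec$jitter_fraction)
          names(cand$gates) <- names(tmpl$gates)
          ok <- tryCatch({
            validate_channel(cand)
            TRUE
          }, error = function(e) FALSE)
          if (ok) {
            member <- cand
            break
          }
        }
        if (is.null(member)) {
          stop_invalid(
            "could not generate a valid member of template '%s' in 25 tries",
            tmpl$id)
        }
        channels[[id]] <- member
        labels[id] <- tmpl$id
      }
    }
    list(channels = channels, labels = labels, spec = spec)
  })
}
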