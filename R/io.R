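CHANNEL_SCHEMA_VERSION <- "1.0"

gate_to_list <- function(g) {
  list(name = g$name, exponent = g$exponent, rate_form = g$rate_form,
       rate_params = g$rate_params, ca_dependent = g$ca_dependent,
       q10_factor = g$q10_factor)
}

#' Write a channel definition file
#'
#' Serializes one channel model to a structured YAML document (one channel
#' per file; `schema_version` field included). Round-tripping through
#' [read_channel()] is lossless to full double precision.
#'
#' @param channel a [channel_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_channel <- function(channel, path) {
  stopifnot(inherits(channel, "channel_model"))
  doc <- list(
    schema_version = CHANNEL_SCHEMA_VERSION,
    id = channel$id, ion_class = channel$ion_class,
    subtype = channel$subtype, gbar = channel$gbar,
    inward = channel$inward, erev_spec = channel$erev_spec,
    gates = lapply(unname(channel$gates), gate_to_list)
  )
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' Read a channel definition file
#'
#' @param path a YAML file written by [write_channel()] (schema 1.0).
#' @param validate check gating invariants after reading (default `TRUE`).
#' @return A [channel_model()].
#' @export
read_channel <- function(path, validate = TRUE) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema_version)) {
    stop_invalid("'%s': not a channel definition file (no schema_version)",
                 path)
  }
  gates <- lapply(doc$gates, function(g) {
    gate_spec(g$name, g$exponent, g$rate_form, g$rate_params,
              ca_dependent = isTRUE(g$ca_dependent),
              q10_factor = g$q10_factor)
  })
  es <- doc$erev_spec
  ch <- channel_model(
    doc$id, doc$ion_class, gates, gbar = doc$gbar,
    erev = if (es$type == "fixed") es$erev else NULL,
    nernst = if (es$type == "nernst") {
      list(z = es$z, conc_in = es$conc_in, conc_out = es$conc_out)
    } else NULL,
    inward = doc$inward,
    subtype = if (is.null(doc$subtype)) NA_character_ else doc$subtype
  )
  if (validate) validate_channel(ch)
  ch
}

#' Write a synthetic ensemble to a directory
#'
#' One channel definition file per member plus `ground_truth.csv`
#' (`channel_id`, `template_id`).
#'
#' @param ensemble result of [generate_ensemble()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in ensemble$channels) {
    write_channel(ch, file.path(dir, paste0(ch$id, ".yaml")))
  }
  write.csv(data.frame(channel_id = names(ensemble$labels),
                       template_id = unname(ensemble$labels)),
            file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read all channel definitions in a directory
#'
#' @param dir directory of `.yaml` channel files.
#' @return Named list of [channel_model()] objects.
#' @export
read_ensemble <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE))
  if (length(paths) == 0L) stop_invalid("no channel files in '%s'", dir)
  channels <- lapply(paths, read_channel)
  names(channels) <- vapply(channels, function(ch) ch$id, character(1))
  channels
}

#' Export a trace set as tidy CSV
#'
#' Columns `protocol`, `step`, `ca_level`, `t_ms`, `current`; channel id,
#' ion class, dt and analysis window are embedded as `#`-prefixed header
#' comments so the file is self-describing.
#'
#' @param traces a `trace_set` from [run_clamp()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# channel_id=%s", traces$channel_id),
    sprintf("# ion_class=%s", traces$ion_class),
    sprintf("# protocol=%s", traces$protocol_name),
    sprintf("# dt=%.17g", traces$dt),
    sprintf("# TA=%.17g", traces$protocol$window[1]),
    sprintf("# TB=%.17g", traces$protocol$window[2])
  ), con)
  t_ms <- waveform_times(traces$protocol)
  df <- do.call(rbind, lapply(seq_len(nrow(traces$conditions)), function(i) {
    data.frame(protocol = traces$protocol_name,
               step = traces$conditions$step[i],
               ca_level = traces$conditions$ca_level[i],
               t_ms = t_ms, current = traces$traces[i, ])
  }))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a tidy trace CSV back into a trace set
#'
#' Accepts files written by [write_trace_csv()] as well as externally
#' recorded current traces in the same schema (the embedded `ion_class` and
#' `protocol` headers select the matching analysis window). Recorded data
#' need not share the simulation timestep; `dt` is taken from the header.
#'
#' @param path CSV file path.
#' @param table protocol parameter table used to rebuild the window.
#' @return A `trace_set`.
#' @export
read_trace_csv <- function(path, table = protocol_table()) {
  header <- readLines(path, n = 20L)
  header <- header[startsWith(header, "# ")]
  meta <- list()
  for (h in header) {
    kv <- strsplit(sub("^# ", "", h), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  need <- c("channel_id", "ion_class", "protocol", "dt")
  if (!all(need %in% names(meta))) {
    stop_invalid("'%s': missing header field(s) %s; expected '# key=value' lines",
                 path, paste(setdiff(need, names(meta)), collapse = ", "))
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  cols <- c("protocol", "step", "ca_level", "t_ms", "current")
  if (!all(cols %in% names(df))) {
    stop_invalid("'%s': trace CSV needs columns %s", path,
                 paste(cols, collapse = ", "))
  }
  dt <- as.numeric(meta$dt)
  protocol <- build_protocol(meta$ion_class, meta$protocol, dt = dt,
                             table = table)
  conditions <- unique(df[order(match(df$ca_level, unique(df$ca_level)),
                                df$step), c("ca_level", "step")])
  rownames(conditions) <- NULL
  n_t <- round(protocol$total_duration / dt) + 1L
  traces <- matrix(NA_real_, nrow = nrow(conditions), ncol = n_t)
  for (i in seq_len(nrow(conditions))) {
    sel <- df$step == conditions$step[i]
    if (is.na(conditions$ca_level[i])) {
      sel <- sel & is.na(df$ca_level)
    } else {
      sel <- sel & !is.na(df$ca_level) &
        df$ca_level == conditions$ca_level[i]
    }
    sub <- df[sel, ]
    if (nrow(sub) != n_t) {
      stop_invalid("'%s': step %s has %d samples, protocol needs %d",
                   path, conditions$step[i], nrow(sub), n_t)
    }
    traces[i, ] <- sub$current[order(sub$t_ms)]
  }
  ca <- unique(conditions$ca_level)
  structure(
    list(channel_id = meta$channel_id, ion_class = meta$ion_class,
         protocol_name = meta$protocol, protocol = protocol, dt = dt,
         conditions = conditions,
         ca_levels = if (all(is.na(ca))) NULL else ca,
         traces = traces),
    class = "trace_set"
  )
}

#' Save / load a fitted score space archive
#'
#' The fitted transforms (per-protocol Z-scoring parameters, principal axis
#' matrices, scale normalizers, final PCA) and the ensemble scores are
#' stored in a single-file archive.
#'
#' @param space a fitted `score_space`.
#' @param path archive file path (conventionally `.rds`).
#' @return `path` (or the restored `score_space` for `load_score_space`).
#' @export
save_score_space <- function(space, path) {
  stopifnot(inherits(space, "score_space"))
  saveRDS(space, path)
  invisible(path)
}

#' @rdname save_score_space
#' @export
load_score_space <- function(path) {
  space <- readRDS(path)
  if (!inherits(space, "score_space")) {
    stop_invalid("'%s' is not a score space archive", path)
  }
  space
}

#' Export ensemble total scores as CSV
#'
#' @param space a fitted `score_space`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(space, path) {
  df <- data.frame(channel_id = space$ids, space$scores, row.names = NULL,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
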