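#' Voltage-clamp protocol parameter table
#'
#' The 25 protocol parameterizations (5 ion classes x 5 protocols) as a data
#' frame. Voltages (`V0`..`V3`, `dV`) are in mV, durations (`T1`..`T9`) and
#' the analysis window (`TA`, `TB`) in ms. The table ships as a plain-text
#' CSV (`inst/extdata/protocol_table.csv`) and can be replaced wholesale via
#' `path` to customize protocol geometry.
#'
#' @param path optional path to an alternative table with the same columns.
#' @return Data frame with one row per (ion class, protocol).
#' @export
protocol_table <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.pkg_env$protocol_table)) {
      p <- system.file("extdata", "protocol_table.csv", package = "ionclamp")
      .pkg_env$protocol_table <- read.csv(p, stringsAsFactors = FALSE)
    }
    return(.pkg_env$protocol_table)
  }
  read.csv(path, stringsAsFactors = FALSE)
}

.PROTOCOL_NAMES <- c("activation", "inactivation", "deactivation",
                     "ramp", "action_potential")

hold_seg <- function(v, duration) {
  list(type = "hold", v0 = v, v1 = v, duration = duration)
}
ramp_seg <- function(v0, v1, duration) {
  list(type = "ramp", v0 = v0, v1 = v1, duration = duration)
}

#' Construct a voltage-clamp protocol
#'
#' Builds one of the five standardized waveform families for an ion class
#' from the parameter table:
#'
#' * `activation`: hold `V0` (T1), graded step `V1..V2` by `dV` (T2),
#'   hold `V0` (T3) — one waveform per step level.
#' * `inactivation`: hold `V0` (T1), graded prepulse `V1..V2` (T2), fixed
#'   test step `V3` (T3), hold `V0` (T4).
#' * `deactivation`: hold `V0` (T1), fixed high step `V1` (T2), graded tail
#'   step `V2..V3` (T3), hold `V0` (T4).
#' * `ramp`: hold `V0` (T1), then eight alternating linear ramps between
#'   `V0` and `V1` with durations `T2..T9`, starting upward — four up/down
#'   pairs of differing slope.
#' * `action_potential`: a fixed somatic spike-train waveform of duration
#'   `T1` (see [synthesize_ap_waveform()]); a recorded waveform can be
#'   supplied via `ap_waveform`.
#'
#' Step ranges include both endpoints. Voltage changes instantaneously at
#' segment boundaries; the sample at a boundary time belongs to the new
#' segment (left-closed segments).
#'
#' @param ion_class one of `"Kv"`, `"Nav"`, `"Cav"`, `"KCa"`, `"Ih"`.
#' @param name protocol name (see above).
#' @param dt integration timestep, ms (default 0.05).
#' @param table protocol parameter table (default [protocol_table()]).
#' @param ap_waveform optional numeric voltage series (mV, sampled at `dt`)
#'   replacing the built-in action-potential waveform.
#' @return An object of class `voltage_protocol` with fields `segments` (a
#'   list of per-step segment lists), `step_voltages`, `dt`,
#'   `window = c(TA, TB)` and `total_duration`.
#' @examples
#' p <- build_protocol("Kv", "activation")
#' length(p$segments)   # 16 graded steps
#' p$window             # analysis window [100, 700] ms
#' @export
build_protocol <- function(ion_class, name, dt = 0.05,
                           table = protocol_table(), ap_waveform = NULL) {
  row <- table[table$ion_class == ion_class & table$protocol == name, ,
               drop = FALSE]
  if (nrow(row) != 1L) {
    stop_invalid("no protocol '%s' for ion class '%s'", name, ion_class)
  }
  r <- as.list(row)
  steps <- numeric(0)
  samples <- NULL
  if (name == "activation") {
    steps <- seq(r$V1, r$V2, by = r$dV)
    segments <- lapply(steps, function(v) {
      list(hold_seg(r$V0, r$T1), hold_seg(v, r$T2), hold_seg(r$V0, r$T3))
    })
  } else if (name == "inactivation") {
    steps <- seq(r$V1, r$V2, by = r$dV)
    segments <- lapply(steps, function(v) {
      list(hold_seg(r$V0, r$T1), hold_seg(v, r$T2), hold_seg(r$V3, r$T3),
           hold_seg(r$V0, r$T4))
    })
  } else if (name == "deactivation") {
    steps <- seq(r$V2, r$V3, by = r$dV)
    segments <- lapply(steps, function(v) {
      list(hold_seg(r$V0, r$T1), hold_seg(r$V1, r$T2), hold_seg(v, r$T3),
           hold_seg(r$V0, r$T4))
    })
  } else if (name == "ramp") {
    durs <- unlist(r[paste0("T", 2:9)], use.names = FALSE)
    ends <- rep(c(r$V1, r$V0), 4)   # up, down, up, down, ...
    starts <- c(r$V0, ends[-8])
    segs <- c(list(hold_seg(r$V0, r$T1)),
              mapply(ramp_seg, starts, ends, durs, SIMPLIFY = FALSE))
    segments <- list(segs)
  } else if (name == "action_potential") {
    n <- round(r$T1 / dt) + 1L
    if (is.null(ap_waveform)) {
      samples <- synthesize_ap_waveform(r$T1, spike_rate = 10, seed = 20L,
                                        dt = dt)
    } else {
      if (length(ap_waveform) != n) {
        stop_invalid("ap_waveform must have %d samples (%g ms at dt = %g)",
                     n, r$T1, dt)
      }
      samples <- as.numeric(ap_waveform)
    }
    segments <- list(list(list(type = "samples", duration = r$T1)))
  } else {
    stop_invalid("unknown protocol name '%s'", name)
  }
  total <- sum(vapply(segments[[1]], function(s) s$duration, numeric(1)))
  structure(
    list(ion_class = ion_class, name = name, segments = segments,
         step_voltages = steps, dt = dt, window = c(r$TA, r$TB),
         total_duration = total, ap_samples = samples),
    class = "voltage_protocol"
  )
}

#' Sample times of a protocol waveform
#'
#' @param protocol a [build_protocol()] object.
#' @return Numeric vector of sample times, ms (length
#'   `round(total_duration/dt) + 1`).
#' @export
waveform_times <- function(protocol) {
  n <- round(protocol$total_duration / protocol$dt)
  (0:n) * protocol$dt
}

#' Sample one waveform of a protocol as a voltage time series
#'
#' Holds are constant; ramp segments are linearly interpolated. Segments are
#' left-closed: the sample exactly at a boundary takes the new segment's
#' value. The final sample (at the total duration) takes the last segment's
#' end value.
#'
#' @param protocol a [build_protocol()] object.
#' @param step_index 1-based waveform index (1 for ramp/action potential).
#' @return Numeric voltage series, mV, of length
#'   `round(total_duration/dt) + 1`.
#' @examples
#' p <- build_protocol("Kv", "activation")
#' v <- sample_waveform(p, 16)
#' range(v)   # -80 (hold) to 70 (largest step)
#' @export
sample_waveform <- function(protocol, step_index) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  if (step_index < 1L || step_index > length(protocol$segments)) {
    stop_invalid("step_index %d out of range (1..%d)", step_index,
                 length(protocol$segments))
  }
  if (protocol$name == "action_potential") return(protocol$ap_samples)
  t <- waveform_times(protocol)
  segs <- protocol$segments[[step_index]]
  bounds <- cumsum(c(0, vapply(segs, function(s) s$duration, numeric(1))))
  idx <- findInterval(t, bounds)          # left-closed segments
  idx[idx > length(segs)] <- length(segs) # final sample: last segment's end
  v <- numeric(length(t))
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    in_seg <- idx == i
    if (!any(in_seg)) next
    if (s$type == "hold") {
      v[in_seg] <- s$v0
    } else {
      frac <- (t[in_seg] - bounds[i]) / s$duration
      v[in_seg] <- s$v0 + frac * (s$v1 - s$v0)
    }
  }
  v
}

#' Synthetic regular-spiking action-potential waveform
#'
#' Generates a deterministic somatic voltage waveform emulating a
#' regular-spiking neuron: a -65 mV resting baseline with stereotyped spikes
#' (fast half-cosine depolarization to +30 mV over 0.6 ms, repolarization to
#' a -75 mV afterhyperpolarization over 1.4 ms, exponential recovery with a
#' 6 ms time constant). Spikes begin at 100 ms and recur at the mean
#' inter-spike interval `1000/spike_rate` ms with a small seeded Gaussian
#' timing jitter (sd 1 ms).
#'
#' @param duration total duration, ms (default 1800).
#' @param spike_rate mean firing rate, Hz; 0 yields the constant baseline.
#' @param seed integer seed controlling the timing jitter; the waveform is a
#'   pure function of `(duration, spike_rate, seed, dt)`.
#' @param dt sampling interval, ms.
#' @return Numeric voltage series, mV, length `round(duration/dt) + 1`.
#' @examples
#' v <- synthesize_ap_waveform(1800, 10, seed = 1)
#' sum(diff(v > 0) == 1)   # number of spikes
#' @export
synthesize_ap_waveform <- function(duration = 1800, spike_rate = 10,
                                   seed = 1L, dt = 0.05) {
  if (duration <= 0) stop_invalid("duration must be > 0")
  n <- round(duration / dt) + 1L
  v <- rep(-65, n)
  if (spike_rate <= 0) return(v)
  isi <- 1000 / spike_rate
  spike_times <- with_seed(seed, {
    st <- seq(100, duration - 5, by = isi)
    st + rnorm(length(st), sd = 1)
  })
  spike_times <- spike_times[spike_times > 0 & spike_times < duration - 5]
  # stereotyped spike shape, evaluated on the dt grid relative to onset
  kern_t <- seq(0, 30, by = dt)
  rise <- kern_t <= 0.6
  fall <- kern_t > 0.6 & kern_t <= 2.0
  ahp <- kern_t > 2.0
  kern <- numeric(length(kern_t))
  kern[rise] <- -65 + 95 * (1 - cos(pi * kern_t[rise] / 0.6)) / 2
  kern[fall] <- 30 - 105 * (kern_t[fall] - 0.6) / 1.4
  kern[ahp] <- -65 - 10 * exp(-(kern_t[ahp] - 2.0) / 6)
  for (st in spike_times) {
    i0 <- round(st / dt) + 1L
    i1 <- min(n, i0 + length(kern) - 1L)
    v[i0:i1] <- kern[seq_len(i1 - i0 + 1L)]
  }
  v
}

#' Dump a protocol waveform as a (t, V) table
#'
#' @param protocol a [build_protocol()] object.
#' @param step_index waveform index.
#' @return Data frame with columns `t_ms`, `v_mV`.
#' @export
protocol_as_table <- function(protocol, step_index = 1L) {
  data.frame(t_ms = waveform_times(protocol),
             v_mV = sample_waveform(protocol, step_index))
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf(
    "<voltage_protocol %s/%s: %d waveform(s), %g ms, dt = %g ms, window [%g, %g] ms>\n",
    x$ion_class, x$name, length(x$segments), x$total_duration, x$dt,
    x$window[1], x$window[2]))
  invisible(x)
}
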