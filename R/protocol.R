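#' Declarative voltage-clamp protocol
#'
#' A protocol is a holding potential plus a list of sweeps; each sweep is an
#' ordered table of piecewise-constant segments `(V, dur, label)`.  Labels
#' mark analysis windows ("1P", "interval", "2P", "step", ...).  Sampling is
#' per segment: `dt_seg = min(dt, dur/10)`, so short pulses are always
#' resolved by at least 10 samples while multi-second intervals stay cheap.
#'
#' @param sweeps list of data.frames with columns `V`, `dur`, `label`.
#' @param holding holding potential (mV), prepended/appended around sweeps.
#' @param dt base sampling interval (ms).  Default: 0.1 ms for sweeps up to
#'   2 s total, 1 ms beyond.
#' @param sweep_info optional data.frame of per-sweep covariates (step
#'   voltage, inter-pulse interval, ...), one row per sweep.
#' @param id protocol identifier.
#' @return object of class `kv_protocol`.
#' @export
kv_protocol <- function(sweeps, holding = -80, dt = NULL, sweep_info = NULL,
                        id = "protocol") {
  stopifnot(is.list(sweeps), length(sweeps) >= 1)
  sweeps <- lapply(sweeps, function(sw) {
    sw <- as.data.frame(sw)
    if (is.null(sw$label)) sw$label <- paste0("seg", seq_len(nrow(sw)))
    if (any(sw$dur <= 0)) stop("segment durations must be > 0")
    sw[, c("V", "dur", "label")]
  })
  if (is.null(dt)) {
    total <- max(vapply(sweeps, function(sw) sum(sw$dur), numeric(1)))
    dt <- if (total > 2000) 1 else 0.1
  }
  if (!is.null(sweep_info)) stopifnot(nrow(sweep_info) == length(sweeps))
  structure(list(sweeps = sweeps, holding = holding, dt = dt,
                 sweep_info = sweep_info, id = id),
            class = "kv_protocol")
}

#' @export
print.kv_protocol <- function(x, ...) {
  cat(sprintf("<kv_protocol '%s'> %d sweep(s), holding %g mV, dt %g ms\n",
              x$id, length(x$sweeps), x$holding, x$dt))
  invisible(x)
}

#' Family of step depolarizations
#'
#' One sweep per step potential from `V_from` to `V_to` in `dV` increments,
#' each held for `duration` ms, from and back to the holding potential.
#'
#' @param V_from,V_to,dV step range and increment (mV), `dV > 0`.
#' @param duration step duration (ms).
#' @param holding holding potential (mV).
#' @param prehold,posthold baseline segments (ms) around the step.
#' @return a [kv_protocol()] with `sweep_info$V_step`.
#' @export
make_step_family <- function(V_from, V_to, dV = 10, duration = 1000,
                             holding = -80, prehold = 5, posthold = 100) {
  if (dV <= 0) stop("dV must be > 0")
  steps <- seq(V_from, V_to, by = dV)
  if (!length(steps)) stop("empty step range")
  sweeps <- lapply(steps, function(V)
    data.frame(V = c(holding, V, holding),
               dur = c(prehold, duration, posthold),
               label = c("hold", "step", "post")))
  kv_protocol(sweeps, holding = holding,
              sweep_info = data.frame(V_step = steps),
              id = sprintf("step_%gms", duration))
}

#' Two-pulse (prepulse/test) protocol family
#'
#' Conventional recovery / cumulative-inactivation protocol: a prepulse
#' (1P) is followed, after a variable interval at `inter_V`, by a test pulse
#' (2P).  One sweep per interval.
#'
#' @param prepulse_ms prepulse duration (ms).
#' @param intervals inter-pulse intervals (ms), nonempty, positive.
#' @param inter_V potential during the interval (mV).
#' @param test_ms test-pulse duration (ms).
#' @param V_pulse pulse potential (mV) for both pulses.
#' @param holding holding potential (mV).
#' @param prehold,posthold baseline segments (ms).
#' @return a [kv_protocol()] with `sweep_info$interval`.
#' @export
make_two_pulse <- function(prepulse_ms, intervals, inter_V = -80,
                           test_ms = 20, V_pulse = 40, holding = -80,
                           prehold = 5, posthold = 20) {
  if (!length(intervals) || any(intervals <= 0))
    stop("intervals must be nonempty and positive")
  sweeps <- lapply(intervals, function(iv)
    data.frame(V = c(holding, V_pulse, inter_V, V_pulse, holding),
               dur = c(prehold, prepulse_ms, iv, test_ms, posthold),
               label = c("hold", "1P", "interval", "2P", "post")))
  kv_protocol(sweeps, holding = holding,
              sweep_info = data.frame(interval = intervals),
              id = sprintf("two_pulse_%gms", prepulse_ms))
}

# time grid and segment table of one sweep; t = 0 at sweep start.
# Pulse segments (those whose peak currents are measured) are sampled at
# 0.25 ms or finer regardless of the base dt so peak location is resolved.
.sweep_grid <- function(sw, dt, gating = FALSE) {
  t0 <- cumsum(c(0, sw$dur))
  segs <- data.frame(start = t0[-length(t0)], end = t0[-1],
                     V = sw$V, label = sw$label)
  pulse_labels <- c("step", "1P", "2P")
  grids <- lapply(seq_len(nrow(sw)), function(i) {
    dur <- sw$dur[i]
    dts <- min(dt, dur / 10)
    if (sw$label[i] %in% pulse_labels) dts <- min(dts, 0.25)
    n <- max(2L, ceiling(dur / dts))
    g <- seq(0, dur, length.out = n + 1L)[-1L]
    if (gating) {
      # gating transients relax orders of magnitude faster than the command
      # sampling; prepend a dense head so trapezoidal charge integrals
      # capture the stiff ON/OFF spikes
      head <- c(seq(0.005, min(1, dur), by = 0.005),
                if (dur > 1) seq(1.05, min(5, dur), by = 0.05))
      g <- sort(unique(c(head, g)))
    }
    segs$start[i] + g
  })
  list(segs = segs, grids = grids)
}
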