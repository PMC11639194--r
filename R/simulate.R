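#' Simulate ionic currents for a protocol
#'
#' Deterministic two-electrode-voltage-clamp forward model: each sweep starts
#' from the stationary occupancy at the holding potential (sweeps are
#' independent, emulating the long inter-sweep rest used experimentally),
#' occupancy is propagated segment by segment under the piecewise-constant
#' command, and the current is
#' `I(t) = g * (p_O(t) + p_P(t)) * (V(t) - E_K)` with `E_K` from the Nernst
#' equation.  Currents are per channel times unit conductance.
#'
#' @param params a [kv_rate_params()] (or calibrated preset, see
#'   [kv_preset()]).
#' @param cond a [kv_condition()]; its `V` is overridden by the command.
#' @param protocol a [kv_protocol()].
#' @param scheme a [kv_scheme()]; defaults to the scheme attached to
#'   `params` by [kv_preset()], else the full scheme.
#' @return object of class `kv_sweep_family`: a list of `kv_trace`
#'   data.frames (`time_ms`, `current`, `voltage_mV`) with segment markers,
#'   plus the protocol and condition.
#' @export
simulate_ionic <- function(params, cond, protocol, scheme = NULL) {
  scheme <- scheme %||% attr(params, "scheme") %||% kv_scheme_full()
  .simulate_family(params, cond, protocol, scheme, kind = "ionic")
}

#' Simulate gating currents for a protocol
#'
#' Non-conducting (W-to-F pore mutant analogue) simulation: kinetics are
#' unchanged but ionic conductance is forced to zero and the recorded signal
#' is the gating current from [gating_flux()] (e0/ms per channel).  A
#' conducting preset is accepted with a warning.
#'
#' @inheritParams simulate_ionic
#' @return a `kv_sweep_family` of gating-current traces.
#' @export
simulate_gating <- function(params, cond, protocol, scheme = NULL) {
  scheme <- scheme %||% attr(params, "scheme") %||% kv_scheme_full()
  if (!isTRUE(attr(params, "nonconducting")) && params$g > 0)
    warning("conducting preset passed to simulate_gating; proceeding with g = 0")
  .simulate_family(params, cond, protocol, scheme, kind = "gating")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stationary occupancy of the communicating component containing the first
# (resting closed) state; states cut off by zero rates get no mass
.holding_state <- function(Q) {
  comp <- .components(Q)
  p <- numeric(nrow(Q))
  idx <- which(comp == comp[1])
  p[idx] <- .solve_stationary(Q[idx, idx, drop = FALSE])
  names(p) <- rownames(Q)
  p
}

.simulate_family <- function(params, cond, protocol, scheme, kind) {
  E_K <- nernst_potential(cond$K_out, cond$K_in)
  cond_hold <- cond; cond_hold$V <- protocol$holding
  Qh <- build_generator(scheme, params, cond_hold)
  p_hold <- .holding_state(Qh)
  traces <- vector("list", length(protocol$sweeps))
  for (k in seq_along(protocol$sweeps)) {
    sw <- protocol$sweeps[[k]]
    sg <- .sweep_grid(sw, protocol$dt, gating = kind == "gating")
    p <- p_hold
    tt <- 0
    PP <- matrix(p, nrow = 1)
    vv <- sw$V[1]
    ig <- if (kind == "gating") {
      cv <- cond; cv$V <- sw$V[1]
      gating_flux(matrix(p, 1, dimnames = list(NULL, scheme$states)),
                  scheme, params, cv)
    } else NULL
    for (i in seq_len(nrow(sw))) {
      cv <- cond; cv$V <- sw$V[i]
      Qi <- build_generator(scheme, params, cv)
      grid_local <- sg$grids[[i]] - sg$segs$start[i]
      Pi <- propagate(Qi, p, grid_local)
      p <- Pi[nrow(Pi), ]
      tt <- c(tt, sg$grids[[i]])
      PP <- rbind(PP, Pi)
      vv <- c(vv, rep(sw$V[i], length(grid_local)))
      if (kind == "gating") ig <- c(ig, gating_flux(Pi, scheme, params, cv))
    }
    colnames(PP) <- scheme$states
    cur <- if (kind == "ionic") {
      pc <- rowSums(PP[, scheme$conducting, drop = FALSE])
      params$g * pc * (vv - E_K)
    } else ig
    tr <- data.frame(time_ms = tt, current = cur, voltage_mV = vv)
    attr(tr, "segments") <- sg$segs
    attr(tr, "occupancy") <- PP
    attr(tr, "meta") <- list(kind = kind, sweep = k, protocol = protocol$id,
                             E_K = E_K,
                             info = if (!is.null(protocol$sweep_info))
                               protocol$sweep_info[k, , drop = FALSE] else NULL)
    class(tr) <- c("kv_trace", "data.frame")
    traces[[k]] <- tr
  }
  structure(list(traces = traces, protocol = protocol, cond = cond,
                 params = params, scheme = scheme, kind = kind),
            class = "kv_sweep_family")
}

#' @export
print.kv_sweep_family <- function(x, ...) {
  cat(sprintf("<kv_sweep_family> %d %s sweep(s) of protocol '%s'\n",
              length(x$traces), x$kind, x$protocol$id))
  invisible(x)
}

# samples of one labelled segment of a trace
.trace_window <- function(trace, label, which_occurrence = 1L) {
  segs <- attr(trace, "segments")
  idx <- which(segs$label == label)
  if (!length(idx)) stop("no segment labelled '", label, "' in trace")
  i <- idx[which_occurrence]
  sel <- trace$time_ms >= segs$start[i] & trace$time_ms <= segs$end[i]
  trace[sel, , drop = FALSE]
}

#' Leak subtraction by the P/n protocol
#'
#' Emulates the classical P/n correction used for gating-current recordings:
#' `n` scaled subtraction pulses (1/n of the main command excursion) are
#' delivered from a hyperpolarized subtraction holding potential where
#' little gating charge moves; their summed, baseline-corrected response is
#' subtracted from the baseline-corrected main sweep.  Linear leak and any
#' artifact linear in the voltage excursion cancel exactly; the nonlinear
#' gating component is preserved up to the (computed, reported) charge moved
#' within the subtraction range.
#'
#' @param raw a `kv_sweep_family` produced with a leak component (see
#'   [generate_dataset()]), or a noiseless family (then subtraction only
#'   removes what the sub-pulses themselves contain).
#' @param n number of subtraction pulses (4 or 6 classically).
#' @param sub_holding holding potential for the subtraction pulses (mV).
#' @return a `kv_sweep_family` of subtracted traces; each trace carries the
#'   attribute `sub_charge` (gating charge moved by one subtraction sweep,
#'   e0, a measure of the correction's error term).
#' @export
p_over_n_subtract <- function(raw, n = 4, sub_holding = -140) {
  if (n <= 0) stop("n must be positive")
  art <- attr(raw, "artifacts") %||% list(g_leak = 0, E_leak = 0,
                                          cap_A = 0, cap_tau = 1)
  out <- raw
  for (k in seq_along(raw$traces)) {
    tr <- raw$traces[[k]]
    segs <- attr(tr, "segments")
    sw <- raw$protocol$sweeps[[k]]
    # scaled command from the subtraction holding potential
    sub_sw <- sw
    sub_sw$V <- sub_holding + (sw$V - raw$protocol$holding) / n
    sub_proto <- kv_protocol(list(sub_sw), holding = sub_holding,
                             dt = raw$protocol$dt, id = "sub")
    fam_sub <- .simulate_family(raw$params, raw$cond, sub_proto, raw$scheme,
                                kind = raw$kind)
    sub_tr <- fam_sub$traces[[1]]
    sub_sig <- .add_linear_artifacts(sub_tr, art)
    # baselines: mean over the initial holding segment
    base_main <- mean(tr$current[tr$time_ms <= segs$end[1]])
    sseg <- attr(sub_tr, "segments")
    base_sub <- mean(sub_sig[sub_tr$time_ms <= sseg$end[1]])
    corrected <- (tr$current - base_main) - n * (sub_sig - base_sub)
    qsub <- .charge_moved(sub_tr, raw$scheme)
    tr$current <- corrected
    attr(tr, "sub_charge") <- qsub
    out$traces[[k]] <- tr
  }
  attr(out, "artifacts") <- NULL
  out
}

# total gating charge moved over a whole sweep trace (e0)
.charge_moved <- function(trace, scheme) {
  occ <- attr(trace, "occupancy")
  if (is.null(occ)) return(NA_real_)
  de <- .directed_edges(scheme)
  q <- numeric(ncol(occ))
  names(q) <- colnames(occ)
  # cumulative charge per state along forward edges from the first state
  e <- scheme$edges[scheme$edges$z != 0, ]
  # breadth-first assignment of cumulative charge
  done <- scheme$states[1]
  repeat {
    grew <- FALSE
    for (i in seq_len(nrow(scheme$edges))) {
      f <- scheme$edges$from[i]; tt <- scheme$edges$to[i]
      z <- scheme$edges$z[i]
      if (f %in% done && !(tt %in% done)) {
        q[tt] <- q[f] + z; done <- c(done, tt); grew <- TRUE
      } else if (tt %in% done && !(f %in% done)) {
        q[f] <- q[tt] - z; done <- c(done, f); grew <- TRUE
      }
    }
    if (!grew) break
  }
  sum(q * (occ[nrow(occ), ] - occ[1, ]))
}

# linear leak + capacitive transients added to a trace's current samples
.add_linear_artifacts <- function(trace, art) {
  cur <- trace$current
  if (art$g_leak != 0)
    cur <- cur + art$g_leak * (trace$voltage_mV - art$E_leak)
  if (art$cap_A != 0) {
    segs <- attr(trace, "segments")
    Vprev <- c(segs$V[1], segs$V[-nrow(segs)])
    for (i in seq_len(nrow(segs))) {
      dV <- segs$V[i] - Vprev[i]
      if (dV == 0) next
      sel <- trace$time_ms > segs$start[i] & trace$time_ms <= segs$end[i]
      tloc <- trace$time_ms[sel] - segs$start[i]
      cur[sel] <- cur[sel] + art$cap_A * dV *
        (0.7 * exp(-tloc / (0.3 * art$cap_tau)) +
           0.3 * exp(-tloc / art$cap_tau))
    }
  }
  cur
}
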