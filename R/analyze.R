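#' Decay analysis of a depolarizing-pulse current
#'
#' Locates the peak current within the pulse segment, fits the decay from
#' the peak sample to the end of the pulse with one and two exponentials,
#' and selects the number of components by a deterministic rule: two
#' components are reported iff the two-exponential fit improves the residual
#' sum of squares by more than 10%, both amplitudes exceed 2% of the peak,
#' and the time-constant ratio exceeds 3.  Traces whose total relaxation is
#' below 2% of the peak are reported as non-inactivating (`n_comp = 0`).
#' `st_peak` is the current at the final pulse sample divided by the peak.
#'
#' @param trace a `kv_trace` (one sweep).
#' @param pulse label of the pulse segment (default `"step"`; use `"1P"` for
#'   two-pulse sweeps).
#' @param n_comp optional forced number of components (1 or 2), bypassing
#'   the selection rule.
#' @return list of class `kv_decay`: `fit` (a `kv_expfit` or NULL),
#'   `n_comp`, `st_peak`, `peak`, `taus`, `A2_frac`.
#' @export
analyze_decay <- function(trace, pulse = "step", n_comp = NULL) {
  w <- .trace_window(trace, pulse)
  ipk <- which.max(w$current)
  peak <- w$current[ipk]
  if (peak <= 0) stop("no detectable peak in pulse segment")
  yend <- w$current[nrow(w)]
  st_peak <- yend / peak
  dec <- w[ipk:nrow(w), ]
  if ((peak - min(dec$current)) < 0.02 * peak && is.null(n_comp)) {
    return(structure(list(fit = NULL, n_comp = 0L, st_peak = st_peak,
                          peak = peak, taus = numeric(0),
                          A2_frac = NA_real_),
                     class = "kv_decay"))
  }
  tt <- dec$time_ms - dec$time_ms[1]
  if (!is.null(n_comp)) {
    fit <- fit_exponential(tt, dec$current, n_comp = n_comp)
    nc <- n_comp
  } else {
    f1 <- fit_exponential(tt, dec$current, n_comp = 1)
    f2 <- tryCatch(fit_exponential(tt, dec$current, n_comp = 2),
                   error = function(e) NULL)
    use2 <- !is.null(f2) && f2$sse < 0.9 * f1$sse &&
      all(abs(f2$components$A) > 0.02 * peak) && !f2$degenerate
    fit <- if (use2) f2 else f1
    nc <- if (use2) 2L else 1L
  }
  structure(list(fit = fit, n_comp = nc, st_peak = st_peak, peak = peak,
                 taus = fit$components$tau, A2_frac = fit$A2_frac),
            class = "kv_decay")
}

#' @export
print.kv_decay <- function(x, ...) {
  if (x$n_comp == 0) {
    cat(sprintf("<kv_decay> non-inactivating, st/peak=%.3f\n", x$st_peak))
  } else {
    cat(sprintf("<kv_decay> %d component(s): tau=%s ms, st/peak=%.3f\n",
                x$n_comp, paste(signif(x$taus, 4), collapse = ", "),
                x$st_peak))
    if (!is.na(x$A2_frac)) cat(sprintf("  A2/(A1+A2)=%.3f\n", x$A2_frac))
  }
  invisible(x)
}

# peak current of a labelled pulse
.peak_of <- function(trace, label) {
  w <- .trace_window(trace, label)
  max(w$current)
}

#' Two-pulse recovery analysis
#'
#' For each sweep of a two-pulse family, measures the peak currents of the
#' prepulse (1P) and test pulse (2P), plots their ratio against the
#' inter-pulse interval, fits the time course with one or two exponentials
#' (amplitudes are negative for recoveries), and normalizes the ratios by
#' the fitted plateau `Y0`.  The initial activatable fraction is
#' `init = 1 - sum(|A_i|)` of the normalized fit.
#'
#' @param family a `kv_sweep_family` from a [make_two_pulse()] protocol.
#' @param n_comp optional forced number of exponential components.
#' @return list of class `kv_recovery`: `interval`, `ratio` (raw),
#'   `ratio_norm`, `fit` (normalized-scale `kv_expfit`), `n_comp`, `init`,
#'   `taus`, `A2_frac`.
#' @export
analyze_recovery <- function(family, n_comp = NULL) {
  iv <- family$protocol$sweep_info$interval
  ratio <- vapply(family$traces, function(tr) {
    p1 <- .peak_of(tr, "1P")
    if (p1 <= .Machine$double.eps) stop("prepulse peak is ~0; cannot form ratio")
    .peak_of(tr, "2P") / p1
  }, numeric(1))
  res <- .fit_recovery_curve(iv, ratio, n_comp)
  structure(c(res, list(interval = iv, ratio = ratio)),
            class = "kv_recovery")
}

# shared by ionic recovery, cumulative and charge recovery
.fit_recovery_curve <- function(iv, ratio, n_comp = NULL) {
  span <- max(ratio) - min(ratio)
  if (span < 0.02 * max(ratio)) {
    # already recovered: no fittable relaxation
    return(list(fit = NULL, n_comp = 0L, init = mean(ratio),
                ratio_norm = ratio / mean(ratio), taus = numeric(0),
                A2_frac = NA_real_, Y0 = mean(ratio)))
  }
  if (!is.null(n_comp)) {
    fit <- fit_exponential(iv, ratio, n_comp = n_comp, origin = "zero")
    nc <- n_comp
  } else {
    f1 <- fit_exponential(iv, ratio, n_comp = 1, origin = "zero")
    f2 <- if (length(iv) >= 6)
      tryCatch(fit_exponential(iv, ratio, n_comp = 2, origin = "zero"),
               error = function(e) NULL) else NULL
    use2 <- !is.null(f2) && f2$sse < 0.9 * f1$sse &&
      all(abs(f2$components$A) > 0.02 * abs(f2$Y0)) && !f2$degenerate
    fit <- if (use2) f2 else f1
    nc <- if (use2) 2L else 1L
  }
  Y0 <- fit$Y0
  ratio_norm <- ratio / Y0
  init <- 1 - sum(abs(fit$components$A)) / Y0
  list(fit = fit, n_comp = nc, init = init, ratio_norm = ratio_norm,
       taus = fit$components$tau, A2_frac = fit$A2_frac, Y0 = Y0)
}

#' @export
print.kv_recovery <- function(x, ...) {
  cat(sprintf("<kv_recovery> %d interval(s), %d component(s): tau=%s ms, init=%.3f\n",
              length(x$interval), x$n_comp,
              paste(signif(x$taus, 4), collapse = ", "), x$init))
  invisible(x)
}

#' Cumulative-inactivation (tandem-pulse) analysis
#'
#' Ratio of the second to the first peak current of two identical short
#' pulses versus the inter-pulse interval, with an exponential fit of the
#' relationship and the ratio extrapolated to 1 ms after the first pulse
#' (reported both from the fit and as the raw ratio at the shortest
#' interval).
#'
#' @inheritParams analyze_recovery
#' @return list of class `kv_cumulative`: `interval`, `ratio`, `fit`,
#'   `n_comp`, `ratio_at_1ms` (fit-based), `ratio_shortest` (raw).
#' @export
analyze_cumulative <- function(family, n_comp = NULL) {
  iv <- family$protocol$sweep_info$interval
  ratio <- vapply(family$traces, function(tr)
    .peak_of(tr, "2P") / .peak_of(tr, "1P"), numeric(1))
  res <- .fit_recovery_curve(iv, ratio, n_comp)
  at1 <- if (is.null(res$fit)) mean(ratio)
  else stats::predict(res$fit, 1)
  structure(list(interval = iv, ratio = ratio, fit = res$fit,
                 n_comp = res$n_comp, ratio_at_1ms = at1,
                 ratio_shortest = ratio[which.min(iv)]),
            class = "kv_cumulative")
}

#' ON gating charge by trapezoidal integration
#'
#' @param trace a gating-current `kv_trace`.
#' @param pulse label of the pulse segment to integrate over.
#' @param which_occurrence which occurrence of the label (1 = first).
#' @return Q_on (e0 per channel).
#' @export
integrate_qon <- function(trace, pulse = "step", which_occurrence = 1L) {
  w <- .trace_window(trace, pulse, which_occurrence)
  pracma::trapz(w$time_ms, w$current)
}

#' Charge-voltage (Q-V) analysis of a gating family
#'
#' Integrates the ON gating charge of each step sweep, normalizes by the
#' maximum, and fits a Boltzmann function.
#'
#' @param family a gating `kv_sweep_family` from [make_step_family()].
#' @return list of class `kv_qv`: `V`, `Q_on`, `Qnorm`, `fit`
#'   (a `kv_boltzmann`).
#' @export
analyze_qv <- function(family) {
  V <- family$protocol$sweep_info$V_step
  if (length(V) < 5) stop("need at least 5 step voltages for Q-V analysis")
  Q <- vapply(family$traces, integrate_qon, numeric(1), pulse = "step")
  Qn <- Q / max(Q)
  structure(list(V = V, Q_on = Q, Qnorm = Qn, fit = fit_boltzmann(V, Qn)),
            class = "kv_qv")
}

#' @export
print.kv_qv <- function(x, ...) {
  cat(sprintf("<kv_qv> %d steps, V_half=%.3g mV, k=%.3g mV\n",
              length(x$V), x$fit$V_half, x$fit$k))
  invisible(x)
}

#' Gating-charge recovery (charge immobilization) analysis
#'
#' For a two-pulse gating family, integrates Q_on during the first (Q1) and
#' second (Q2) pulses, fits the ratio `Q2/Q1` versus interval with a single
#' exponential, and normalizes plateau and amplitude by the first-pulse
#' charge.  The immobilized fraction is `1 - plateau`.
#'
#' @param family a gating `kv_sweep_family` from [make_two_pulse()].
#' @return list of class `kv_charge_recovery`: `interval`, `Q1`, `Q2`,
#'   `ratio`, `fit`, `plateau`, `immobilized`, `tau`.
#' @export
analyze_charge_recovery <- function(family) {
  iv <- family$protocol$sweep_info$interval
  Q1 <- vapply(family$traces, integrate_qon, numeric(1), pulse = "1P")
  Q2 <- vapply(family$traces, integrate_qon, numeric(1), pulse = "2P")
  if (any(Q1 <= 0)) stop("first-pulse charge must be positive")
  ratio <- Q2 / Q1
  res <- .fit_recovery_curve(iv, ratio, n_comp = if (length(iv) >= 4) 1 else NULL)
  plateau <- res$Y0
  structure(list(interval = iv, Q1 = Q1, Q2 = Q2, ratio = ratio,
                 fit = res$fit, plateau = plateau,
                 immobilized = 1 - plateau,
                 tau = if (length(res$taus)) res$taus[1] else NA_real_),
            class = "kv_charge_recovery")
}

#' @export
print.kv_charge_recovery <- function(x, ...) {
  cat(sprintf("<kv_charge_recovery> plateau=%.3f (immobilized %.1f%%), tau=%.3g ms\n",
              x$plateau, 100 * x$immobilized, x$tau))
  invisible(x)
}

# component with the largest |A| ("dominant") or the slowest tau
.dominant_tau <- function(fit) {
  comp <- fit$components
  comp$tau[which.max(abs(comp$A))]
}
.slow_tau <- function(fit, min_frac = 0.05) {
  comp <- fit$components
  keep <- abs(comp$A) >= min_frac * sum(abs(comp$A))
  max(comp$tau[keep])
}
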