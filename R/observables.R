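#' Published table-level observables used for calibration
#'
#' The channel variants studied here (wild-type AKv1, the amino-terminal
#' point mutant I8Q, and the amino-terminal deletion dN) were characterized
#' by table-level observables: fast/slow inactivation time constants and
#' amplitude fractions of the 1-s (10-s for dN) depolarizing-pulse decay,
#' the steady/peak current ratio, two-pulse recovery time constants and the
#' initial activatable fraction, and Boltzmann parameters of activation and
#' Q-V curves.  No rate constants were published; [calibrate_preset()]
#' inverts these observables into rates at run time, so this table is the
#' sole numeric input of every preset.
#'
#' Units: time constants in ms, potentials in mV, fractions dimensionless.
#'
#' @param channel "AKv1", "I8Q" or "dN" (NULL returns the full list).
#' @return nested list of observables per channel and solution.
#' @export
kv_observables <- function(channel = NULL) {
  obs <- list(
    AKv1 = list(
      decay_ND96 = list(tau1 = 21.9, st = 0.078, n_comp = 1),
      decay_highK = list(tau1 = 23.2, st = 0.135, n_comp = 1),
      recovery_ND96 = list(tau = 3454.2, init = 0.043, n_comp = 1),
      recovery_highK = list(tau = 216.0, init = 0.132, n_comp = 1),
      activation = list(V_half = 0.9, k = -6.3),
      qv = list(V_half = -0.5, k = -9.4),
      pulse_ms = 1000),
    I8Q = list(
      decay_ND96 = list(tau1 = 24.2, tau2 = 964.2, A2_frac = 0.398,
                        st = 0.232, n_comp = 2),
      decay_highK = list(tau1 = 27.8, st = 0.512, n_comp = 1),
      recovery_ND96 = list(tau1 = 48.1, tau2 = 2038.4, A2_frac = 0.735,
                           init = 0.219, n_comp = 2),
      recovery_highK = list(tau1 = 22.6, tau2 = 1957.7, A2_frac = 0.13,
                            init = 0.517, n_comp = 2),
      activation = list(V_half = 4.6, k = -5.4),
      qv = list(V_half = 8.1, k = -8.3),
      pulse_ms = 1000),
    dN = list(
      decay_ND96 = list(tau1 = 531, tau2 = 3522, A2_frac = 0.943,
                        st = 0.245, n_comp = 2),
      decay_highK = list(tau2 = 7513, st = 0.448, n_comp = 1),
      recovery_ND96 = list(tau = 3491, init = 0.325, n_comp = 1),
      recovery_highK = list(tau = 1781, init = 0.61, n_comp = 1),
      activation = list(V_half = 6.7, k = -6.0),
      pulse_ms = 10000))
  if (is.null(channel)) return(obs)
  ch <- match.arg(channel, names(obs))
  obs[[ch]]
}

#' Standard inter-pulse interval lists of the recovery protocols
#'
#' `"long"` is the sparse list reaching 30 s used for slowly recovering
#' channels; `"dense"` starts at 2 ms and resolves fast recovery
#' components; `"gating"` is the 5-ms-increment list used for gating-charge
#' recovery after 10-ms pulses; `"tandem"` is the short-pulse
#' cumulative-inactivation list.
#'
#' @param which one of "long", "dense", "gating", "tandem", "dn".
#' @return numeric vector of intervals (ms).
#' @export
recovery_intervals <- function(which = c("long", "dense", "gating",
                                         "tandem", "dn")) {
  switch(match.arg(which),
         long = c(10, 100, 500, 1000, 2000, 5000, 10000, 20000, 30000),
         dense = c(2, 5, 10, 20, 50, 100, 200, 500, 1000, 2000, 5000,
                   10000, 20000),
         gating = seq(1, 96, by = 5),
         tandem = c(5, 10, 25, 50, 100, 200, 500),
         dn = c(200, 500, 1000, 2000, 5000, 10000, 20000))
}
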