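#' Recording condition
#'
#' Membrane potential and external solution for evaluating the rate matrix.
#' `preset = "ND96"` is the standard low-potassium frog Ringer (2 mM K+);
#' `preset = "highK"` is the 98 mM KCl solution.  TEA is accepted for
#' interface completeness but has no kinetic effect on this channel.
#'
#' @param V membrane potential (mV).
#' @param K_out external K+ (mM).
#' @param Zn external Zn2+ (uM).
#' @param TEA external TEA (mM); accepted, no effect.
#' @param K_in internal K+ (mM), used for the Nernst reversal potential.
#' @param preset optional name ("ND96" or "highK") supplying `K_out`.
#' @return object of class `kv_condition`.
#' @export
kv_condition <- function(V = -80, K_out = 2, Zn = 0, TEA = 0, K_in = 100,
                         preset = NULL) {
  if (!is.null(preset)) {
    K_out <- switch(match.arg(preset, c("ND96", "highK")),
                    ND96 = 2, highK = 98)
  }
  if (any(c(K_out, Zn, TEA, K_in) < 0)) stop("concentrations must be >= 0")
  structure(list(V = V, K_out = K_out, Zn = Zn, TEA = TEA, K_in = K_in),
            class = "kv_condition")
}

#' @export
print.kv_condition <- function(x, ...) {
  cat(sprintf("<kv_condition> V=%g mV, K_out=%g mM, Zn=%g uM, TEA=%g mM, K_in=%g mM\n",
              x$V, x$K_out, x$Zn, x$TEA, x$K_in))
  invisible(x)
}

#' Nernst reversal potential for K+
#'
#' `E_K = kT * log(K_out / K_in)` with the thermal voltage `kT = 25.7` mV
#' (room temperature).  External K+ below 0.01 mM is floored to keep the
#' potential finite.
#'
#' @param K_out,K_in external / internal K+ (mM).
#' @return reversal potential (mV).
#' @export
nernst_potential <- function(K_out, K_in = 100) {
  25.7 * log(max(K_out, 0.01) / K_in)
}

#' Rate constants and modulator constants of the kinetic scheme
#'
#' Rates are in 1/ms, voltages in mV, charges in elementary charges.
#' Voltage dependence is exponential: sensor steps move at
#' `a0 * exp((V - Vshift)/Va)` forward and `b0 * exp(-(V - Vshift)/Vb)`
#' backward; the concerted opening uses `ko`/`kc` prefactors with e-fold
#' voltages `Voa`/`Vob`.  Dock/undock (`kd`/`ku`), block/unblock
#' (`kb`/`kub`) and C-type entry (`kci`, `kci0`) are voltage independent;
#' C-type recovery (`kcr`, `kcr0`, values defined at -80 mV) may carry a
#' mild voltage dependence with e-fold voltage `Vcr` (`Inf` = flat).
#'
#' External modulators: C-type entry is multiplied by
#' `m_K = 1/(1 + K_out/K_K)` (or its reciprocal form `1 + K_out/K_K` when
#' `u_type = TRUE`) and by `m_Zn = 1 + eta_Zn * Zn/(K_Zn + Zn)`; the unblock
#' rate is multiplied by the K+ "push-off" factor
#' `1 + theta_push * K_out/(K_out + K_K)`.
#'
#' @param ... named overrides of the defaults listed above; unknown names
#'   are kept in `$extra` and resolved as constant rates, which lets ad-hoc
#'   schemes (e.g. a bare two-state block) use custom rate names.
#' @return object of class `kv_rate_params` (a named list).
#' @export
kv_rate_params <- function(...) {
  p <- list(
    a0 = 0.8, Va = 2 * 25.7 / 3, b0 = 0.8, Vb = 2 * 25.7 / 3,
    Vshift = 0,
    ko = 0.6, kc = 0.12, Voa = 2 * 25.7 / 4, Vob = 2 * 25.7 / 4,
    kd = 0.5, ku = 0.125,
    kb = 0.05, kub = 3e-3,
    kci = 1.5e-2, kcr = 7e-4,
    kci0 = 0, kcr0 = 0, Vcr = Inf,
    K_K = 0.5, theta_push = 0.5, K_Zn = 100, eta_Zn = 1.3,
    u_type = FALSE, g = 1)
  dots <- list(...)
  extra <- dots[!(names(dots) %in% names(p))]
  for (nm in intersect(names(dots), names(p))) p[[nm]] <- dots[[nm]]
  p$extra <- if (length(extra)) extra else list()
  rates <- c("a0", "b0", "ko", "kc", "kd", "ku", "kb", "kub",
             "kci", "kcr", "kci0", "kcr0")
  if (any(unlist(p[rates]) < 0)) stop("rate constants must be >= 0")
  if (p$Va <= 0 || p$Vb <= 0) stop("Va and Vb must be > 0")
  if (p$K_K <= 0 || p$K_Zn <= 0 || p$theta_push < 0 || p$eta_Zn < 0)
    stop("modulator constants must be positive")
  class(p) <- "kv_rate_params"
  p
}

#' @export
print.kv_rate_params <- function(x, ...) {
  cat("<kv_rate_params> (1/ms unless noted)\n")
  show <- c("a0", "Va", "b0", "Vb", "Vshift", "ko", "kc", "kd", "ku",
            "kb", "kub", "kci", "kcr", "kci0", "kcr0", "Vcr",
            "K_K", "theta_push", "K_Zn", "eta_Zn", "u_type", "g")
  for (nm in show) cat(sprintf("  %-10s %s\n", nm, format(x[[nm]], digits = 4)))
  if (length(x$extra))
    cat("  extra:", paste(names(x$extra), unlist(x$extra), sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

# K+ modulation of C-type entry
.m_K <- function(params, K_out) {
  if (isTRUE(params$u_type)) 1 + K_out / params$K_K
  else 1 / (1 + K_out / params$K_K)
}

# Zn2+ acceleration of C-type entry
.m_Zn <- function(params, Zn) 1 + params$eta_Zn * Zn / (params$K_Zn + Zn)

# K+ push-off on the unblock rate
.m_push <- function(params, K_out) {
  1 + params$theta_push * K_out / (K_out + params$K_K)
}

# evaluate a named rate at (V, condition); errors on unknown names
.rate_value <- function(name, params, cond) {
  V <- cond$V
  r <- switch(
    name,
    a    = params$a0 * exp((V - params$Vshift) / params$Va),
    b    = params$b0 * exp(-(V - params$Vshift) / params$Vb),
    ko   = params$ko * exp((V - params$Vshift) / params$Voa),
    kc   = params$kc * exp(-(V - params$Vshift) / params$Vob),
    kd   = params$kd,
    ku   = params$ku,
    kb   = params$kb,
    kub  = params$kub * .m_push(params, cond$K_out),
    kci  = params$kci * .m_K(params, cond$K_out) * .m_Zn(params, cond$Zn),
    kci0 = params$kci0 * .m_K(params, cond$K_out) * .m_Zn(params, cond$Zn),
    kcr  = params$kcr * .kcr_vfac(params, V),
    kcr0 = params$kcr0 * .kcr_vfac(params, V),
    {
      if (!is.null(params$extra[[name]])) params$extra[[name]]
      else stop("unknown transition rate name: ", name)
    })
  if (!is.finite(r) || r < 0)
    stop("rate '", name, "' evaluated to an invalid value: ", r)
  r
}

.kcr_vfac <- function(params, V) {
  if (is.infinite(params$Vcr)) 1 else exp(-(V + 80) / params$Vcr)
}
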