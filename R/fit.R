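#' Boltzmann fit of an activation / inactivation / Q-V curve
#'
#' Least-squares fit of `Y = Ymax / (1 + exp((V - V_half)/k))`.  The slope
#' factor `k` is signed: negative for curves rising with depolarization
#' (activation, Q-V), positive for steady-state inactivation curves.
#'
#' @param V potentials (mV), at least 4 points spanning the transition.
#' @param Y observed values.
#' @return object of class `kv_boltzmann` with `Ymax`, `V_half`, `k`,
#'   `sse`, `n_points`, and `converged`.
#' @export
fit_boltzmann <- function(V, Y) {
  stopifnot(length(V) == length(Y))
  if (length(V) < 4) stop("need at least 4 points for a Boltzmann fit")
  ymax0 <- max(Y)
  vh0 <- V[which.min(abs(Y - ymax0 / 2))]
  rising <- stats::coef(stats::lm(Y ~ V))[2] > 0
  k0 <- if (rising) -8 else 8
  dat <- data.frame(V = V, Y = Y)
  best <- NULL
  for (kstart in c(k0, k0 / 2, k0 * 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(Y ~ Ymax / (1 + exp((V - Vh) / k)),
                        data = dat,
                        start = list(Ymax = ymax0, Vh = vh0, k = kstart),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    warning("Boltzmann fit failed to converge; returning grid-search best")
    gr <- .boltz_grid(V, Y, ymax0)
    return(structure(list(Ymax = gr$Ymax, V_half = gr$Vh, k = gr$k,
                          sse = gr$sse, n_points = length(V),
                          converged = FALSE),
                     class = "kv_boltzmann"))
  }
  cf <- stats::coef(best$fit)
  structure(list(Ymax = unname(cf["Ymax"]), V_half = unname(cf["Vh"]),
                 k = unname(cf["k"]), sse = best$sse,
                 n_points = length(V), converged = TRUE),
            class = "kv_boltzmann")
}

.boltz_grid <- function(V, Y, ymax0) {
  grid <- expand.grid(Vh = seq(min(V), max(V), length.out = 81),
                      k = c(-seq(1, 30, by = 0.5), seq(1, 30, by = 0.5)))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    x <- 1 / (1 + exp((V - grid$Vh[i]) / grid$k[i]))
    ym <- sum(x * Y) / sum(x * x)
    sse <- sum((Y - ym * x)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(Vh = grid$Vh[i], k = grid$k[i], Ymax = ym, sse = sse)
  }
  best
}

#' @export
print.kv_boltzmann <- function(x, ...) {
  cat(sprintf("<kv_boltzmann> Ymax=%.4g, V_half=%.3g mV, k=%.3g mV (n=%d, sse=%.3g)\n",
              x$Ymax, x$V_half, x$k, x$n_points, x$sse))
  invisible(x)
}

#' Predict from a Boltzmann fit
#' @param object a `kv_boltzmann`.
#' @param V potentials (mV).
#' @param ... unused.
#' @export
predict.kv_boltzmann <- function(object, V, ...) {
  object$Ymax / (1 + exp((V - object$V_half) / object$k))
}

#' Single or double exponential fit
#'
#' Fits `Y = Y0 + A1 exp(-t/tau1)` or
#' `Y = Y0 + A1 exp(-t/tau1) + A2 exp(-t/tau2)` by Levenberg-Marquardt least
#' squares with a multi-start initialization ladder on the time constants
#' (seeds spread around the crude 1/e crossing; amplitudes solved linearly
#' for each seed).  Components are returned sorted by ascending tau; for
#' two components a `degenerate` flag marks `tau2/tau1 <= 3`.
#'
#' @param t times (ms), measured from the start of the fit window.
#' @param y observed values.
#' @param n_comp 1 or 2 exponential components.
#' @param window optional `c(lo, hi)` restricting the fit to `t` in range.
#' @param restarts number of multi-start seeds for `n_comp = 2`.
#' @param origin `"window"` (default) re-references times to the first
#'   fitted sample, as appropriate for decays measured from the peak;
#'   `"zero"` keeps the given time axis, as required for recovery curves
#'   whose amplitudes are extrapolations to interval zero.
#' @return object of class `kv_expfit`: `Y0`, `components` (data.frame
#'   `A`, `tau`), `A2_frac` (`A2/(A1+A2)` on absolute amplitudes), `sse`,
#'   `n_points`, `degenerate`.
#' @export
fit_exponential <- function(t, y, n_comp = 1, window = NULL, restarts = 5,
                            origin = c("window", "zero")) {
  stopifnot(length(t) == length(y), n_comp %in% c(1, 2))
  origin <- match.arg(origin)
  if (!is.null(window)) {
    sel <- t >= window[1] & t <= window[2]
    t <- t[sel]; y <- y[sel]
  }
  if (origin == "window") t <- t - t[1]
  if (length(t) < 2 + 2 * n_comp)
    stop("fewer points than parameters in exponential fit")
  tau_c <- .crude_tau(t, y)
  seeds <- if (n_comp == 1) {
    lapply(c(0.3, 1, 3), function(f) tau_c * f)
  } else {
    base <- list(c(1 / 3, 3), c(1 / 10, 1), c(1, 10), c(1 / 30, 1 / 2),
                 c(1, 30))
    lapply(base[seq_len(min(restarts, length(base)))],
           function(f) tau_c * f)
  }
  best <- NULL
  for (taus in seeds) {
    fit <- .fit_exp_one(t, y, taus)
    if (is.null(fit)) next
    better <- is.null(best) || fit$sse < best$sse * (1 - 1e-9) ||
      (abs(fit$sse - best$sse) <= best$sse * 1e-9 &&
         n_comp == 2 && fit$ratio < best$ratio)
    if (better) best <- fit
  }
  if (is.null(best)) stop("exponential fit failed for all starts")
  comp <- data.frame(A = best$A, tau = best$tau)
  comp <- comp[order(comp$tau), , drop = FALSE]
  rownames(comp) <- NULL
  a_abs <- abs(comp$A)
  structure(list(Y0 = best$Y0, components = comp,
                 A2_frac = if (n_comp == 2) a_abs[2] / sum(a_abs) else NA_real_,
                 sse = best$sse, n_points = length(t),
                 degenerate = n_comp == 2 && comp$tau[2] / comp$tau[1] <= 3),
            class = "kv_expfit")
}

.crude_tau <- function(t, y) {
  y0 <- y[1]; yend <- y[length(y)]
  if (abs(y0 - yend) < .Machine$double.eps) return(max(t[length(t)] / 3, 1e-6))
  target <- yend + (y0 - yend) * exp(-1)
  idx <- if (y0 > yend) which(y <= target) else which(y >= target)
  if (!length(idx)) return(max(t[length(t)] / 3, 1e-6))
  max(t[idx[1]], t[2])
}

# linear amplitude solve for given taus, then nlsLM polish
.fit_exp_one <- function(t, y, taus) {
  taus <- pmax(taus, 1e-9)
  X <- cbind(1, vapply(taus, function(tau) exp(-t / tau),
                       numeric(length(t))))
  ab <- tryCatch(qr.solve(qr(X), y), error = function(e) NULL)
  if (is.null(ab)) return(NULL)
  n_comp <- length(taus)
  st <- c(list(Y0 = ab[1]),
          stats::setNames(as.list(ab[-1]), paste0("A", seq_len(n_comp))),
          stats::setNames(as.list(taus), paste0("tau", seq_len(n_comp))))
  form <- if (n_comp == 1)
    y ~ Y0 + A1 * exp(-t / tau1)
  else
    y ~ Y0 + A1 * exp(-t / tau1) + A2 * exp(-t / tau2)
  lower <- rep(-Inf, length(st))
  names(lower) <- names(st)
  lower[grep("^tau", names(st))] <- 1e-9
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(t = t, y = y), start = st,
                      lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to the linear solve at the seed taus
    res <- y - X %*% ab
    return(list(Y0 = ab[1], A = ab[-1], tau = taus, sse = sum(res^2),
                ratio = if (n_comp == 2) max(taus) / min(taus) else 1))
  }
  cf <- stats::coef(fit)
  tau <- cf[grep("^tau", names(cf))]
  list(Y0 = unname(cf["Y0"]), A = unname(cf[paste0("A", seq_len(n_comp))]),
       tau = unname(tau), sse = sum(stats::resid(fit)^2),
       ratio = if (n_comp == 2) max(tau) / min(tau) else 1)
}

#' @export
print.kv_expfit <- function(x, ...) {
  cat(sprintf("<kv_expfit> Y0=%.4g, %d component(s), sse=%.3g\n",
              x$Y0, nrow(x$components), x$sse))
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  A%d=%.4g  tau%d=%.4g ms\n", i, x$components$A[i],
                i, x$components$tau[i]))
  if (!is.na(x$A2_frac)) cat(sprintf("  A2/(A1+A2)=%.3f%s\n", x$A2_frac,
                                     if (x$degenerate) " (near-degenerate)" else ""))
  invisible(x)
}

#' Predict from an exponential fit
#' @param object a `kv_expfit`.
#' @param t times (ms, same origin as the fit window).
#' @param ... unused.
#' @export
predict.kv_expfit <- function(object, t, ...) {
  out <- rep(object$Y0, length(t))
  for (i in seq_len(nrow(object$components)))
    out <- out + object$components$A[i] * exp(-t / object$components$tau[i])
  out
}
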