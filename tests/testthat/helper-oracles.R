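# Independent oracles used to cross-check the package's fitting and
# propagation routines.  These deliberately use different algorithms from
# the implementation paths they check.

# variable-projection fit of Y0 + sum A_i exp(-t/tau_i) over a log-spaced
# tau grid: amplitudes solved linearly, taus by exhaustive grid search
varpro_exp_oracle <- function(t, y, n_comp, tau_lo, tau_hi, n_grid = 60) {
  taus <- exp(seq(log(tau_lo), log(tau_hi), length.out = n_grid))
  best <- NULL
  combos <- if (n_comp == 1) matrix(seq_along(taus), ncol = 1)
  else t(utils::combn(seq_along(taus), 2))
  for (r in seq_len(nrow(combos))) {
    tu <- taus[combos[r, ]]
    X <- cbind(1, vapply(tu, function(tau) exp(-t / tau), numeric(length(t))))
    ab <- tryCatch(qr.solve(qr(X), y), error = function(e) NULL)
    if (is.null(ab)) next
    sse <- sum((y - X %*% ab)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(tau = tu, Y0 = ab[1], A = ab[-1], sse = sse)
  }
  best
}

# exhaustive SSE grid search for the Boltzmann fit (Ymax solved linearly)
boltzmann_grid_oracle <- function(V, Y, Vh_range, k_range, n = 201) {
  grid <- expand.grid(Vh = seq(Vh_range[1], Vh_range[2], length.out = n),
                      k = seq(k_range[1], k_range[2], length.out = n))
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

# ODE-solver route for dp/dt = pQ (independent of the matrix-exponential
# implementation inside propagate)
ode_propagate_oracle <- function(Q, p0, t_grid) {
  rhs <- function(t, p, parms) list(as.vector(p %*% parms))
  out <- deSolve::lsoda(p0, c(0, t_grid), rhs, Q,
                        rtol = 1e-11, atol = 1e-12)
  unname(out[-1, -1, drop = FALSE])
}

# a small 4-state inactivation chain (open/pre-block/blocked/C-type) with
# voltage-independent rates, used across propagation tests
chain4 <- function() {
  list(
    scheme = kv_scheme(c("O", "P", "N", "NC"), c("O", "P"),
                       data.frame(from = c("O", "P", "N"),
                                  to = c("P", "N", "NC"),
                                  fwd = c("kd", "kb", "kci"),
                                  bwd = c("ku", "kub", "kcr"),
                                  z = c(0, 0, 0))),
    params = kv_rate_params(kd = 0.05, ku = 0.0125, kb = 0.05, kub = 0.005,
                            kci = 0.01, kcr = 0.002, theta_push = 0,
                            K_K = 1e6),
    cond = kv_condition(V = 40, K_out = 0))
}

rel_err <- function(x, ref) abs(x / ref - 1)
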