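#' Gating current from an occupancy trajectory
#'
#' The gating current is the net charge flux through every charge-carrying
#' transition: `I_g(t) = sum_edges z * (p_from * k_fwd - p_to * k_bwd)`, in
#' elementary charges per ms per channel.  Its time integral over a pulse is
#' the net gating charge moved, and over any closed voltage cycle returning
#' to equilibrium the integral is zero.
#'
#' @param P occupancy matrix (`time x states`, columns named as
#'   `scheme$states`), e.g. from [propagate()].
#' @param scheme a [kv_scheme()].
#' @param params a [kv_rate_params()].
#' @param cond a [kv_condition()] (evaluation potential for the rates).
#' @return numeric vector of gating current samples (e0/ms per channel).
#' @export
gating_flux <- function(P, scheme, params, cond) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1,
                                   dimnames = list(NULL, scheme$states))
  e <- scheme$edges
  Ig <- numeric(nrow(P))
  for (i in seq_len(nrow(e))) {
    if (e$z[i] == 0) next
    kf <- .rate_value(e$fwd[i], params, cond)
    kb <- .rate_value(e$bwd[i], params, cond)
    Ig <- Ig + e$z[i] * (P[, e$from[i]] * kf - P[, e$to[i]] * kb)
  }
  Ig
}

#' Equilibrium charge-voltage relation of the activation path
#'
#' Closed-form equilibrium gating charge as a function of voltage, computed
#' from the per-step equilibrium constants of the activation chain.  States
#' beyond the open state (pre-block, N- and C-type inactivated) carry the
#' full activation charge, so the equilibrium Q-V depends only on the
#' sensor/opening steps.  Used to shift-calibrate a gating preset to a
#' printed Q-V midpoint.
#'
#' @param params a [kv_rate_params()].
#' @param V_grid voltages (mV).
#' @param scheme scheme whose activation path is used (default full scheme).
#' @param cond condition for rate evaluation (K+/Zn do not enter the charged
#'   steps; default ND96).
#' @return data.frame with `V`, `Q` (e0 per channel) and `Qnorm`.
#' @export
qv_equilibrium <- function(params, V_grid = seq(-80, 60, by = 5),
                           scheme = kv_scheme_full(),
                           cond = kv_condition(preset = "ND96")) {
  e <- scheme$edges
  chain <- e[e$z > 0, ]
  Q <- vapply(V_grid, function(V) {
    cv <- cond; cv$V <- V
    K <- vapply(seq_len(nrow(chain)), function(i)
      .rate_value(chain$fwd[i], params, cv) /
        .rate_value(chain$bwd[i], params, cv), numeric(1))
    w <- c(1, cumprod(K))          # relative occupancy along the path
    q <- c(0, cumsum(chain$z))     # cumulative charge at each node
    sum(w * q) / sum(w)
  }, numeric(1))
  data.frame(V = V_grid, Q = Q, Qnorm = Q / max(Q))
}
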