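# fabricate a minimal two-pulse family whose 2P/1P peak ratios follow a
# prescribed curve; used to test the recovery analysis arithmetic in
# isolation from the simulator
fake_recovery_family <- function(iv, ratio, gating = FALSE) {
  traces <- lapply(seq_along(iv), function(k) {
    seg <- data.frame(
      start = c(0, 5, 25, 25 + iv[k], 45 + iv[k]),
      end = c(5, 25, 25 + iv[k], 45 + iv[k], 50 + iv[k]),
      V = c(-80, 40, -80, 40, -80),
      label = c("hold", "1P", "interval", "2P", "post"))
    mk <- function(s, e, n, val) {
      tt <- seq(s, e, length.out = n + 1)[-1]
      data.frame(time_ms = tt, current = val, voltage_mV = 0)
    }
    tr <- rbind(mk(0, 5, 4, 0), mk(5, 25, 20, 1),
                mk(25, 25 + iv[k], 10, 0),
                mk(25 + iv[k], 45 + iv[k], 20, ratio[k]),
                mk(45 + iv[k], 50 + iv[k], 4, 0))
    attr(tr, "segments") <- seg
    class(tr) <- c("kv_trace", "data.frame")
    tr
  })
  structure(list(traces = traces,
                 protocol = list(sweep_info = data.frame(interval = iv),
                                 id = "fake"),
                 kind = if (gating) "gating" else "ionic"),
            class = "kv_sweep_family")
}

test_that("analyze_decay: degenerate and closed-form cases", {
  # non-inactivating trace -> st/peak = 1, no components
  p <- kv_rate_params(kb = 0, kci0 = 0)
  fam <- simulate_ionic(p, kv_condition(preset = "ND96"),
                        make_step_family(40, 40, 10, 200))
  d <- analyze_decay(fam$traces[[1]])
  expect_identical(d$n_comp, 0L)
  expect_equal(d$st_peak, 1, tolerance = 1e-3)

  # two-state block with f = 0.1, tau = 20 ms: st/peak -> 0.1 at t >> tau
  ab <- two_state_block(20, 0.1)
  p2 <- kv_rate_params(kb = ab[["alpha"]] / (0.5 / 0.625), kub = ab[["beta"]],
                       kd = 0.5, ku = 0.125, kci = 0, theta_push = 0,
                       K_K = 1e6)
  fam2 <- simulate_ionic(p2, kv_condition(preset = "ND96"),
                         make_step_family(40, 40, 10, 1000))
  d2 <- analyze_decay(fam2$traces[[1]])
  expect_equal(d2$st_peak, 0.1, tolerance = 0.02)
  expect_equal(d2$taus[1], 20, tolerance = 0.05 * 20)

  # the model-selection rule is deterministic
  d3 <- analyze_decay(fam2$traces[[1]])
  expect_identical(d2$n_comp, d3$n_comp)
  expect_identical(d2$taus, d3$taus)
})

test_that("recovery analysis: init arithmetic and normalization invariance", {
  iv <- c(10, 100, 500, 1000, 2000, 5000, 10000, 20000, 30000)
  # single-exponential recovery with A1 = -0.948: init = 0.052
  ratio <- 1 - 0.948 * exp(-iv / 3200)
  fam <- fake_recovery_family(iv, ratio)
  r <- analyze_recovery(fam)
  expect_equal(r$init, 0.052, tolerance = 1e-4)
  expect_equal(r$taus[1], 3200, tolerance = 1)
  # init is invariant to rescaling the raw ratios
  fam2 <- fake_recovery_family(iv, 0.37 * ratio)
  r2 <- analyze_recovery(fam2)
  expect_equal(r2$init, r$init, tolerance = 1e-6)
  expect_equal(r2$ratio_norm, r$ratio_norm, tolerance = 1e-6)

  # already-recovered input: init = 1, no components
  rflat <- analyze_recovery(fake_recovery_family(iv, rep(1, length(iv))))
  expect_equal(rflat$init, 1, tolerance = 1e-9)
  expect_identical(rflat$n_comp, 0L)

  # double-exponential recovery: all four parameters back within 1%
  iv2 <- c(2, 5, 10, 20, 50, 100, 200, 500, 1000, 2000, 5000, 10000, 20000)
  ratio2 <- 1 - 0.43 * exp(-iv2 / 55) - 0.35 * exp(-iv2 / 2100)
  rd <- analyze_recovery(fake_recovery_family(iv2, ratio2))
  expect_identical(rd$n_comp, 2L)
  expect_lt(max(rel_err(rd$taus, c(55, 2100))), 0.01)
  expect_lt(max(rel_err(abs(rd$fit$components$A), c(0.43, 0.35))), 0.01)
  expect_equal(rd$init, 1 - 0.43 - 0.35, tolerance = 1e-3)
})

test_that("cumulative-inactivation ratios behave and dip at -40 mV", {
  # non-inactivating channel: ratio 1 at every interval
  p0 <- kv_rate_params(kb = 0, kci0 = 0)
  proto <- make_two_pulse(20, c(5, 25, 100), inter_V = -80, test_ms = 20)
  fam0 <- simulate_ionic(p0, kv_condition(preset = "ND96"), proto)
  c0 <- analyze_cumulative(fam0)
  expect_equal(c0$ratio, rep(1, 3), tolerance = 1e-6)

  # wild-type-like preset: non-monotone ratio at -40 mV inter-pulse
  # potential (initial depression from pre-block -> block conversion)
  p <- kv_preset("AKv1")
  proto2 <- make_two_pulse(20, recovery_intervals("tandem"), inter_V = -40,
                           test_ms = 20)
  cc <- analyze_cumulative(simulate_ionic(p, kv_condition(preset = "ND96"),
                                          proto2))
  expect_lt(min(cc$ratio), cc$ratio[1])          # dips below the first point
  expect_gt(cc$ratio[length(cc$ratio)], min(cc$ratio))  # then recovers
  expect_true(is.finite(cc$ratio_at_1ms) && is.finite(cc$ratio_shortest))

  # occupancy-level ratio agrees with the trace-level measurement
  tr <- simulate_ionic(p, kv_condition(preset = "ND96"),
                       make_two_pulse(20, 100, -80, 20))$traces[[1]]
  occ <- attr(tr, "occupancy")
  cond_frac <- occ[, "O"] + occ[, "P"]
  segs <- attr(tr, "segments")
  in1 <- tr$time_ms > segs$start[2] & tr$time_ms <= segs$end[2]
  in2 <- tr$time_ms > segs$start[4] & tr$time_ms <= segs$end[4]
  r_occ <- max(cond_frac[in2]) / max(cond_frac[in1])
  r_tr <- kvinact:::.peak_of(tr, "2P") / kvinact:::.peak_of(tr, "1P")
  expect_equal(r_tr, r_occ, tolerance = 5e-3)
})

test_that("Q_on integration: trivial integrals and equilibrium Q-V oracle", {
  # rectangular pulse of height h and width w integrates to h * w
  tt <- seq(0, 30, by = 0.5)
  rect <- data.frame(time_ms = tt,
                     current = ifelse(tt >= 5 & tt <= 25, 2, 0),
                     voltage_mV = 0)
  attr(rect, "segments") <- data.frame(start = c(0, 5, 25),
                                       end = c(5, 25, 30),
                                       V = c(-80, 40, -80),
                                       label = c("hold", "step", "post"))
  class(rect) <- c("kv_trace", "data.frame")
  expect_equal(integrate_qon(rect, "step"), 2 * 20, tolerance = 1e-12)
  zero <- rect
  zero$current <- 0
  expect_equal(integrate_qon(zero, "step"), 0)

  # single-step two-state sensor: equilibrium Q-V is exactly Boltzmann with
  # k = -25.7 / z
  sens_params <- kv_rate_params(a0 = 1, b0 = 1, Va = 2 * 25.7 / 2,
                                Vb = 2 * 25.7 / 2, ko = 0, kci0 = 0)
  sens <- kv_scheme(c("C", "A"), character(0),
                    data.frame(from = "C", to = "A", fwd = "a", bwd = "b",
                               z = 2))
  qv <- qv_equilibrium(sens_params, seq(-60, 60, by = 5), scheme = sens)
  f <- fit_boltzmann(qv$V, qv$Q)
  expect_equal(f$k, -25.7 / 2, tolerance = 1e-3)
  expect_equal(f$V_half, 0, tolerance = 1e-3)

  # multi-step chain: closed-form equilibrium Q-V equals the brute-force
  # stationary-occupancy charge sum on the activation path
  p <- kv_rate_params()
  chain <- kv_scheme(c("C0", "C1", "C2", "C3", "O"), "O",
                     data.frame(from = c("C0", "C1", "C2", "C3"),
                                to = c("C1", "C2", "C3", "O"),
                                fwd = c("a", "a", "a", "ko"),
                                bwd = c("b", "b", "b", "kc"),
                                z = c(3, 3, 3, 4)))
  qv2 <- qv_equilibrium(p, seq(-60, 60, by = 10), scheme = chain)
  qstate <- c(C0 = 0, C1 = 3, C2 = 6, C3 = 9, O = 13)
  brute <- vapply(qv2$V, function(V) {
    Q <- build_generator(chain, p, kv_condition(V = V, K_out = 2))
    sum(steady_state(Q) * qstate[chain$states])
  }, numeric(1))
  expect_lt(max(abs(qv2$Q - brute)), 1e-8)
})

test_that("charge-recovery analysis recovers a known exponential time course", {
  iv <- seq(1, 96, by = 5)
  ratio <- 0.97 - 0.55 * exp(-iv / 30)
  fam <- fake_recovery_family(iv, ratio, gating = TRUE)
  # Q1 constant by construction; Q2/Q1 follows the prescribed curve
  cr <- analyze_charge_recovery(fam)
  expect_equal(cr$tau, 30, tolerance = 0.3)
  expect_equal(cr$plateau, 0.97, tolerance = 1e-3)
  expect_equal(cr$immobilized, 0.03, tolerance = 1e-3)
})
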