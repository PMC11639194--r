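test_that("scheme constructors enforce the structural invariants", {
  full <- kv_scheme_full()
  expect_true(all(full$conducting %in% full$states))
  expect_identical(full$conducting, c("O", "P"))
  expect_gt(sum(full$edges$z), 0)          # net forward charge positive
  expect_equal(sum(full$edges$z), 13)

  dn <- kv_scheme_dn()
  expect_false(any(c("P", "N", "NC") %in% dn$states))
  expect_identical(dn$conducting, "O")

  expect_error(kv_scheme(c("A", "B"), "C",
                         data.frame(from = "A", to = "B", fwd = "kb",
                                    bwd = "kub", z = 0)),
               "conducting")
  expect_error(kv_scheme(c("A", "B"), "A",
                         data.frame(from = "A", to = "A", fwd = "kb",
                                    bwd = "kub", z = 0)),
               "self-transitions")
})

test_that("generator matrix: forced identities and modulator neutral point", {
  two <- kv_scheme(c("O", "N"), "O",
                   data.frame(from = "O", to = "N", fwd = "kb", bwd = "kub",
                              z = 0))
  # all rates zero -> zero matrix
  p0 <- kv_rate_params(kb = 0, kub = 0)
  expect_equal(build_generator(two, p0, kv_condition(V = 0, K_out = 0)),
               matrix(0, 2, 2, dimnames = list(c("O", "N"), c("O", "N"))))
  # two-state block: [[-a, a], [b, -b]] at any V
  p <- kv_rate_params(kb = 0.045, kub = 0.005)
  for (V in c(-120, 0, 60)) {
    Q <- build_generator(two, p, kv_condition(V = V, K_out = 0))
    expect_equal(unname(Q),
                 matrix(c(-0.045, 0.005, 0.045, -0.005), 2, 2))
  }
  # Zn = 0, K_out = 0 -> C-entry multiplier exactly 1
  cimod <- kv_scheme(c("N", "NC"), character(0),
                     data.frame(from = "N", to = "NC", fwd = "kci",
                                bwd = "kcr", z = 0))
  Q <- build_generator(cimod, kv_rate_params(kci = 0.37, kcr = 0),
                       kv_condition(V = 40, K_out = 0, Zn = 0))
  expect_identical(Q["N", "NC"], 0.37)
  # unknown rate name errors
  bad <- kv_scheme(c("A", "B"), "A",
                   data.frame(from = "A", to = "B", fwd = "nonsense",
                              bwd = "kub", z = 0))
  expect_error(build_generator(bad, p, kv_condition()), "unknown transition")
})

test_that("generator rows sum to zero for the full scheme at many conditions", {
  p <- kv_rate_params(kci0 = 1e-4, kcr0 = 1e-4)
  for (V in c(-140, -80, 0, 40, 60)) {
    for (K in c(0, 2, 98)) {
      Q <- build_generator(kv_scheme_full(), p,
                           kv_condition(V = V, K_out = K, Zn = 100))
      expect_lt(max(abs(rowSums(Q))), 1e-12 * max(abs(Q)))
      expect_true(all(Q[row(Q) != col(Q)] >= 0))
    }
  }
})

test_that("two_state_block inverts the pore-block relations exactly", {
  ab <- two_state_block(20, 0.5)
  expect_equal(unname(ab), c(0.025, 0.025))
  # round trip through steady state + decay tau
  ab2 <- two_state_block(24.2, 0.512)
  expect_equal(sum(ab2), 1 / 24.2)
  two <- kv_scheme(c("O", "N"), "O",
                   data.frame(from = "O", to = "N", fwd = "kb", bwd = "kub",
                              z = 0))
  Q <- build_generator(two, kv_rate_params(kb = ab2[["alpha"]],
                                           kub = ab2[["beta"]]),
                       kv_condition(K_out = 0))
  ss <- steady_state(Q)
  expect_equal(ss[["O"]], 0.512, tolerance = 1e-12)
  expect_equal(1 / (Q["O", "N"] + Q["N", "O"]), 24.2, tolerance = 1e-12)
  expect_error(two_state_block(-1, 0.5), "tau_inacti")
  expect_error(two_state_block(20, 1), "steady_frac")
})

test_that("steady_state: analytic cases and propagation oracle", {
  two <- kv_scheme(c("O", "N"), "O",
                   data.frame(from = "O", to = "N", fwd = "kb", bwd = "kub",
                              z = 0))
  Qs <- build_generator(two, kv_rate_params(kb = 0.03, kub = 0.03),
                        kv_condition(K_out = 0))
  expect_equal(unname(steady_state(Qs)), c(0.5, 0.5))
  Qa <- build_generator(two, kv_rate_params(kb = 0.045, kub = 0.005),
                        kv_condition(K_out = 0))
  expect_equal(steady_state(Qa)[["O"]], 0.1, tolerance = 1e-12)

  # random 5-state generator: stationary vector vs long-time propagation
  set.seed(11)
  R <- matrix(stats::runif(25, 0.001, 0.05), 5, 5)
  diag(R) <- 0
  diag(R) <- -rowSums(R)
  pi_hat <- steady_state(R)
  P <- propagate(R, c(1, 0, 0, 0, 0), 1e6)
  expect_lt(max(abs(P[1, ] - pi_hat)), 1e-6)

  # reducible generator warns and still returns a distribution
  Qr <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  Qr[1, 2] <- 0.1; Qr[2, 1] <- 0.2
  diag(Qr) <- -rowSums(Qr)
  expect_warning(ssr <- steady_state(Qr), "reducible")
  expect_equal(sum(ssr), 1)
})

test_that("K+, Zn2+ and u-type modulators move C-type entry the right way", {
  p <- kv_rate_params(kci = 0.01, K_K = 0.5, K_Zn = 100, eta_Zn = 1.3)
  sch <- kv_scheme(c("N", "NC"), character(0),
                   data.frame(from = "N", to = "NC", fwd = "kci",
                              bwd = "kcr", z = 0))
  entry <- function(p, K, Zn = 0)
    build_generator(sch, p, kv_condition(V = 40, K_out = K, Zn = Zn))["N", "NC"]
  # K+ suppresses (non-u-type), monotonically
  expect_true(entry(p, 0) > entry(p, 2) && entry(p, 2) > entry(p, 98))
  # Zn2+ accelerates, monotonically
  expect_true(entry(p, 2, 300) > entry(p, 2, 100) &&
                entry(p, 2, 100) > entry(p, 2, 0))
  # u-type flag inverts the K+ dependence
  pu <- kv_rate_params(kci = 0.01, K_K = 0.5, u_type = TRUE)
  expect_true(entry(pu, 98) > entry(pu, 2))
  # kd = 0 never populates the pre-block/blocked branch
  pfull <- kv_rate_params(kd = 0)
  Q <- build_generator(kv_scheme_full(), pfull, kv_condition(V = 40))
  P <- propagate(Q, c(1, rep(0, 8)), c(100, 1000))
  expect_equal(max(P[, c("P", "N", "NC")]), 0)
})
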