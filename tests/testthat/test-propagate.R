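test_that("propagate: identity, closed form, and conservation", {
  # Q = 0 keeps p0
  Q0 <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  P <- propagate(Q0, c(0.2, 0.3, 0.5), c(0, 10, 1000))
  expect_equal(P, matrix(rep(c(0.2, 0.3, 0.5), each = 3), 3,
                         dimnames = list(NULL, c("A", "B", "C"))))
  # symmetric two-state: blocked fraction 0.5 (1 - exp(-0.1 t))
  two <- kv_scheme(c("O", "N"), "O",
                   data.frame(from = "O", to = "N", fwd = "kb", bwd = "kub",
                              z = 0))
  Q <- build_generator(two, kv_rate_params(kb = 0.05, kub = 0.05),
                       kv_condition(K_out = 0))
  tg <- c(0, 1, 5, 10, 20, 50)
  P <- propagate(Q, c(1, 0), tg)
  expect_equal(P[, "N"], 0.5 * (1 - exp(-0.1 * tg)), tolerance = 1e-12)
  # conservation everywhere
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  expect_true(all(P >= 0 & P <= 1))
  # input validation
  expect_error(propagate(matrix(c(1, 0, 0, 1), 2), c(1, 0), 1),
               "non-conservative")
  expect_error(propagate(Q, c(0.5, 0.1), 1), "probability")
  expect_error(propagate(Q, c(1, 0), c(2, 1)), "nondecreasing")
})

test_that("propagate matches an independent ODE solver to 1e-8", {
  skip_if_not_installed("deSolve")
  ch <- chain4()
  Q <- build_generator(ch$scheme, ch$params, ch$cond)
  tg <- c(1, 5, 20, 100, 500)
  P <- propagate(Q, c(1, 0, 0, 0), tg)
  ref <- ode_propagate_oracle(Q, c(1, 0, 0, 0), tg)
  expect_lt(max(abs(P - ref)), 1e-8)
  # full 9-state scheme at a depolarized potential
  p <- kv_rate_params(kci0 = 2e-4, kcr0 = 3e-4)
  Qf <- build_generator(kv_scheme_full(), p, kv_condition(V = 40, K_out = 2))
  p0 <- c(1, rep(0, 8))
  Pf <- propagate(Qf, p0, c(0.5, 2, 10, 200))
  reff <- ode_propagate_oracle(Qf, p0, c(0.5, 2, 10, 200))
  expect_lt(max(abs(Pf - reff)), 1e-8)
})

test_that("Gillespie ensemble agrees with deterministic propagation", {
  ch <- chain4()
  Q <- build_generator(ch$scheme, ch$params, ch$cond)
  tg <- c(50, 100)
  n <- 1e4
  gs <- gillespie_sample(ch$scheme, ch$params, ch$cond, n_traj = n,
                         t_grid = tg, seed = 101)
  P <- propagate(Q, c(1, 0, 0, 0), tg)
  se <- sqrt(P * (1 - P) / n)
  expect_true(all(abs(gs$occupancy - P) <= 3 * pmax(se, 1e-4)))
})

test_that("Gillespie sampler: determinism and degenerate cases", {
  ch <- chain4()
  g1 <- gillespie_sample(ch$scheme, ch$params, ch$cond, 50, c(10, 50),
                         seed = 7, keep_paths = TRUE)
  g2 <- gillespie_sample(ch$scheme, ch$params, ch$cond, 50, c(10, 50),
                         seed = 7, keep_paths = TRUE)
  expect_identical(g1$paths, g2$paths)
  expect_error(gillespie_sample(ch$scheme, ch$params, ch$cond, 10, c(1)),
               "seed")
  # all rates zero: trajectory constant at the initial state
  p0 <- kv_rate_params(kd = 0, kb = 0, kci = 0, ku = 0, kub = 0, kcr = 0)
  gz <- gillespie_sample(ch$scheme, p0, ch$cond, 1, c(1, 100), seed = 3)
  expect_equal(gz$occupancy[, "O"], c(1, 1))
})

test_that("gating flux: zero-charge schemes, single-step charge, closed cycle", {
  ch <- chain4()   # all z = 0
  Q <- build_generator(ch$scheme, ch$params, ch$cond)
  P <- propagate(Q, c(1, 0, 0, 0), seq(0, 50, by = 1))
  expect_equal(gating_flux(P, ch$scheme, ch$params, ch$cond),
               rep(0, nrow(P)))

  # single activation step with z = 2: the flux integral equals the charge
  # implied by the occupancy change, and a saturating step moves ~all of z
  sens <- kv_scheme(c("C", "A"), character(0),
                    data.frame(from = "C", to = "A", fwd = "a", bwd = "b",
                               z = 2))
  p <- kv_rate_params(a0 = 1, b0 = 1, Va = 25.7, Vb = 25.7)
  cond <- kv_condition(V = 60)
  Qs <- build_generator(sens, p, cond)
  tg <- seq(0.005, 40, by = 0.005)
  Ps <- propagate(Qs, c(1, 0), tg)
  Ig <- gating_flux(Ps, sens, p, cond)
  q_int <- unname(pracma::trapz(c(0, tg), c(gating_flux(matrix(c(1, 0), 1,
    dimnames = list(NULL, c("C", "A"))), sens, p, cond), Ig)))
  expect_equal(q_int, 2 * unname(Ps[nrow(Ps), "A"]), tolerance = 1e-3)
  expect_gt(q_int, 2 * 0.9)

  # full scheme: ON pulse + complete OFF recovery moves zero net charge
  gp <- kv_gating_preset("AKv1")
  fam <- simulate_gating(gp, kv_condition(preset = "ND96"),
                         make_step_family(40, 40, 10, 10, posthold = 20000))
  tr <- fam$traces[[1]]
  qon <- integrate_qon(tr, "step")
  net <- pracma::trapz(tr$time_ms, tr$current)
  expect_gt(qon, 10)                  # most of the 13 e0 moves
  expect_lt(abs(net), 0.01 * qon)     # and returns over the closed cycle
})
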