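#' Exact stochastic simulation of the gating jump process
#'
#' Gillespie (stochastic simulation algorithm) sampler for the continuous
#' time Markov chain defined by a scheme, parameter set and condition.  It is
#' the stochastic counterpart of [propagate()]: the ensemble occupancy of a
#' large sample is an unbiased estimate of the deterministic solution, which
#' makes this the independent cross-check for the matrix-exponential
#' propagator.
#'
#' @param scheme a [kv_scheme()].
#' @param params a [kv_rate_params()].
#' @param cond a [kv_condition()].
#' @param n_traj number of independent trajectories (>= 1).
#' @param t_grid report times (ms, nondecreasing, starting at or after 0).
#' @param seed mandatory RNG seed (the jump process is stochastic).
#' @param p0 initial occupancy; defaults to all mass in the first state.
#' @param keep_paths if TRUE (and `n_traj <= 100`) also return the raw jump
#'   trajectories.
#' @return list with `occupancy` (matrix `length(t_grid) x nstates` of
#'   ensemble state fractions), `n_traj`, and optionally `paths`.
#' @export
gillespie_sample <- function(scheme, params, cond, n_traj, t_grid, seed,
                             p0 = NULL, keep_paths = FALSE) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  if (n_traj < 1) stop("n_traj must be >= 1")
  if (is.unsorted(t_grid)) stop("t_grid must be nondecreasing")
  s <- length(scheme$states)
  Q <- build_generator(scheme, params, cond)
  rates_out <- -diag(Q)
  # per-state jump distribution
  jump_to <- vector("list", s)
  jump_p <- vector("list", s)
  for (i in seq_len(s)) {
    tgt <- which(Q[i, ] > 0)
    jump_to[[i]] <- tgt
    jump_p[[i]] <- if (length(tgt)) cumsum(Q[i, tgt]) / sum(Q[i, tgt]) else numeric(0)
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  if (is.null(p0)) p0 <- c(1, rep(0, s - 1))
  state <- sample.int(s, n_traj, replace = TRUE, prob = p0)
  t_now <- numeric(n_traj)
  occ <- matrix(0, length(t_grid), s,
                dimnames = list(NULL, scheme$states))
  paths <- if (keep_paths && n_traj <= 100)
    lapply(seq_len(n_traj), function(i) list(t = 0, s = state[i])) else NULL

  # next jump time per trajectory (absorbing states never jump)
  draw_wait <- function(st) {
    w <- rep(Inf, length(st))
    act <- rates_out[st] > 0
    if (any(act)) w[act] <- stats::rexp(sum(act), rate = rates_out[st[act]])
    w
  }
  t_jump <- t_now + draw_wait(state)

  for (k in seq_along(t_grid)) {
    tk <- t_grid[k]
    repeat {
      due <- which(t_jump <= tk)
      if (!length(due)) break
      # advance every due trajectory by one jump (vectorized per state)
      st <- state[due]
      u <- stats::runif(length(due))
      new_state <- integer(length(due))
      for (i in unique(st)) {
        sel <- st == i
        new_state[sel] <- jump_to[[i]][findInterval(u[sel], jump_p[[i]],
                                                    left.open = TRUE) + 1L]
      }
      if (!is.null(paths)) {
        for (j in seq_along(due)) {
          tr <- due[j]
          paths[[tr]]$t <- c(paths[[tr]]$t, t_jump[tr])
          paths[[tr]]$s <- c(paths[[tr]]$s, new_state[j])
        }
      }
      t_now[due] <- t_jump[due]
      state[due] <- new_state
      t_jump[due] <- t_now[due] + draw_wait(new_state)
    }
    occ[k, ] <- tabulate(state, nbins = s) / n_traj
  }
  out <- list(occupancy = occ, n_traj = n_traj, t_grid = t_grid, seed = seed)
  if (!is.null(paths)) out$paths <- paths
  out
}
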