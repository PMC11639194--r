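#' Build the rate (generator) matrix of a scheme
#'
#' Evaluates every transition rate of `scheme` at the membrane potential and
#' solution given by `cond` and assembles the infinitesimal generator `Q`:
#' `Q[i, j]` is the rate from state `i` to state `j` and each diagonal entry
#' is minus its row sum, so occupancy evolves as `dp/dt = p Q`.
#'
#' @param scheme a [kv_scheme()].
#' @param params a [kv_rate_params()].
#' @param cond a [kv_condition()] (its `V` is the evaluation potential).
#' @return square matrix with dimnames `scheme$states`.
#' @export
build_generator <- function(scheme, params, cond) {
  s <- scheme$states
  Q <- matrix(0, length(s), length(s), dimnames = list(s, s))
  de <- .directed_edges(scheme)
  for (i in seq_len(nrow(de))) {
    Q[de$from[i], de$to[i]] <- Q[de$from[i], de$to[i]] +
      .rate_value(de$rate[i], params, cond)
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Deterministic propagation of state occupancies
#'
#' Solves `dp/dt = p Q` for a constant generator on a nondecreasing time
#' grid.  The solver is the matrix exponential: an eigendecomposition fast
#' path evaluates all grid times at once and falls back to
#' scaling-and-squaring stepping (`Matrix::expm`) when the eigenbasis is
#' ill-conditioned.  Occupancies are conservative to better than 1e-9 at
#' every sample.
#'
#' @param Q generator matrix (rows sum to zero).
#' @param p0 initial occupancy vector (non-negative, sums to 1).
#' @param t_grid nondecreasing times (ms); occupancy is reported at each.
#' @return matrix `length(t_grid) x nstates` of occupancies.
#' @export
propagate <- function(Q, p0, t_grid) {
  s <- nrow(Q)
  scale <- max(abs(Q), 1)
  if (max(abs(rowSums(Q))) > 1e-9 * scale)
    stop("non-conservative generator: row sums differ from zero")
  if (any(p0 < -1e-12) || abs(sum(p0) - 1) > 1e-9)
    stop("p0 must be a probability vector")
  if (is.unsorted(t_grid)) stop("t_grid must be nondecreasing")
  p0 <- pmax(p0, 0); p0 <- p0 / sum(p0)

  P <- .propagate_eigen(Q, p0, t_grid)
  if (is.null(P)) P <- .propagate_step(Q, p0, t_grid)
  colnames(P) <- rownames(Q)
  P
}

.propagate_eigen <- function(Q, p0, t_grid) {
  e <- tryCatch(eigen(Q), error = function(err) NULL)
  if (is.null(e)) return(NULL)
  Vm <- e$vectors
  W <- tryCatch(solve(Vm), error = function(err) NULL)
  if (is.null(W)) return(NULL)
  C <- as.vector(p0 %*% Vm)
  # p(t)_j = sum_k C_k exp(lambda_k t) W_kj, evaluated for all t at once
  E <- exp(outer(t_grid, e$values))           # T x s
  P <- Re(sweep(E, 2, C, `*`) %*% W)
  drift <- max(abs(rowSums(P) - 1))
  if (!is.finite(drift) || drift > 1e-9) return(NULL)
  P[P < 0 & P > -1e-9] <- 0
  if (any(P < 0)) return(NULL)
  P
}

.propagate_step <- function(Q, p0, t_grid) {
  P <- matrix(NA_real_, length(t_grid), nrow(Q))
  dts <- diff(c(0, t_grid))
  cache <- list()
  p <- p0
  for (i in seq_along(t_grid)) {
    dt <- dts[i]
    if (dt > 0) {
      key <- format(dt, digits = 15)
      if (is.null(cache[[key]]))
        cache[[key]] <- as.matrix(Matrix::expm(Q * dt))
      p <- as.vector(p %*% cache[[key]])
      p <- pmax(p, 0); p <- p / sum(p)
    }
    P[i, ] <- p
  }
  P
}

#' Stationary occupancy of a generator
#'
#' Solves `pi Q = 0`, `sum(pi) = 1`.  For a reducible generator (states that
#' do not communicate) a warning is issued and the stationary distribution is
#' computed per communicating component, components weighted equally.
#'
#' @param Q generator matrix.
#' @return stationary occupancy vector.
#' @export
steady_state <- function(Q) {
  s <- nrow(Q)
  comp <- .components(Q)
  if (max(comp) > 1L) {
    warning("reducible generator: returning component-wise stationary solution")
    pi_out <- numeric(s)
    for (k in seq_len(max(comp))) {
      idx <- which(comp == k)
      pi_out[idx] <- .solve_stationary(Q[idx, idx, drop = FALSE]) / max(comp)
    }
    names(pi_out) <- rownames(Q)
    return(pi_out)
  }
  pi_out <- .solve_stationary(Q)
  names(pi_out) <- rownames(Q)
  pi_out
}

.solve_stationary <- function(Q) {
  s <- nrow(Q)
  if (s == 1L) return(1)
  A <- rbind(t(Q), rep(1, s))
  b <- c(rep(0, s), 1)
  pi_out <- qr.solve(A, b)
  pi_out <- pmax(pi_out, 0)
  pi_out / sum(pi_out)
}

# undirected connectivity components over nonzero off-diagonal entries
.components <- function(Q) {
  s <- nrow(Q)
  adj <- (abs(Q) + t(abs(Q))) > 0
  diag(adj) <- FALSE
  comp <- integer(s)
  k <- 0L
  for (i in seq_len(s)) {
    if (comp[i] > 0L) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Invert decay time constant and steady fraction into block rates
#'
#' For a single-step open-channel block `O <-> N` with association rate
#' `alpha` and dissociation rate `beta`, the macroscopic decay time constant
#' is `1/(alpha + beta)` and the stationary conducting fraction is
#' `beta/(alpha + beta)`.  This helper inverts those relations.
#'
#' @param tau_inacti decay time constant (ms), > 0.
#' @param steady_frac stationary conducting fraction in `[0, 1)`.
#' @return named vector `c(alpha =, beta =)` (1/ms).
#' @export
two_state_block <- function(tau_inacti, steady_frac) {
  if (tau_inacti <= 0) stop("tau_inacti must be > 0")
  if (steady_frac < 0 || steady_frac >= 1)
    stop("steady_frac must be in [0, 1)")
  c(alpha = (1 - steady_frac) / tau_inacti,
    beta = steady_frac / tau_inacti)
}
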