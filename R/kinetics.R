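#' Assemble the rate matrix Q at a given agonist concentration
#'
#' `Q[i, j]` is the transition rate from state j to state i (ms^-1); rates of
#' ligand order 1 are multiplied by the concentration (mM).  Diagonal entries
#' are set to the negative column sums, so every column of Q sums to zero.
#'
#' @param scheme A [kinetic_scheme()].
#' @param params A [channel_params()] supplying every rate name the scheme
#'   declares.
#' @param concentration Agonist concentration (mM), non-negative.
#' @return A `rate_matrix`: the Q matrix with the concentration it was
#'   assembled at attached as attribute `concentration`.
#' @export
assemble_rate_matrix <- function(scheme, params, concentration = 0) {
  if (concentration < 0)
    stop("concentration must be non-negative", call. = FALSE)
  missing <- setdiff(scheme$transitions$rate, names(params$rates))
  if (length(missing))
    stop("parameter vector lacks rate(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ns <- scheme$n_states
  Q <- matrix(0, ns, ns, dimnames = list(scheme$states, scheme$states))
  tr <- scheme$transitions
  if (nrow(tr)) {
    idx <- cbind(match(tr$to, scheme$states), match(tr$from, scheme$states))
    vals <- tr$multiplier * unname(params$rates[tr$rate]) *
      concentration^tr$ligand_order
    for (k in seq_len(nrow(tr)))      # += (duplicated entries may exist)
      Q[idx[k, 1], idx[k, 2]] <- Q[idx[k, 1], idx[k, 2]] + vals[k]
  }
  diag(Q) <- diag(Q) - colSums(Q)
  structure(Q, concentration = concentration, class = c("rate_matrix", "matrix"))
}

#' Spectral decomposition of a rate matrix
#'
#' Diagonalises Q as `U diag(lambda) U^-1`.  Q is generally non-symmetric, so
#' eigenvalues and eigenvectors may be complex; all downstream observable
#' quantities are checked to have negligible imaginary residue before being
#' cast to real.  A (numerically) degenerate spectrum is rejected: the
#' factorised covariance algebra assumes distinct eigenvalues.
#'
#' @param Q A rate matrix (from [assemble_rate_matrix()]).
#' @param degeneracy_tol Relative tolerance below which two eigenvalues are
#'   considered degenerate.
#' @return A list with `values` (complex), `U`, `U_inv`.
#' @export
spectral_decompose <- function(Q, degeneracy_tol = 1e-8) {
  e <- eigen(unclass(Q))
  lam <- e$values
  scale <- max(Mod(lam), 1)
  if (length(lam) > 1) {
    d <- Mod(outer(lam, lam, "-"))
    diag(d) <- Inf
    if (min(d) < degeneracy_tol * scale)
      stop("degenerate eigenvalue spectrum (two eigenvalues closer than ",
           "tolerance); perturb the rate constants slightly", call. = FALSE)
  }
  U <- e$vectors
  U_inv <- solve(U)
  structure(list(values = lam, U = U, U_inv = U_inv),
            class = "spectral_decomposition")
}

## propagate p across `times` via the spectral factors; returns Ns x Nt complex
.propagate <- function(sd, p0, times) {
  w <- sd$U_inv %*% p0                      # Ns x 1
  ph <- exp(outer(sd$values, times))        # Ns x Nt
  sd$U %*% (ph * as.vector(w))
}

.cast_real <- function(x, tol = 1e-9, what = "quantity") {
  if (is.complex(x)) {
    resid <- max(abs(Im(x)))
    if (resid > tol * max(1, max(abs(Re(x)))))
      stop("imaginary residue ", signif(resid, 3), " in ", what, call. = FALSE)
    x <- Re(x)
  }
  x
}

#' Initial state occupancy p(0)
#'
#' Under the instantaneous-binding idealisation, a delta distribution on the
#' scheme's fully liganded state.  Otherwise the channels are equilibrated at
#' the first pre-equilibration concentration, propagated through the remaining
#' epochs and through the agonist pulse; p(0) refers to the end of the pulse.
#'
#' @param scheme A [kinetic_scheme()].
#' @param params A [channel_params()].
#' @param proto A [protocol()].
#' @return Probability vector over states (sums to 1).
#' @export
initial_state <- function(scheme, params, proto) {
  if (isTRUE(proto$instantaneous_binding)) {
    if (is.null(scheme$liganded_state))
      stop("scheme has no liganded_state for the instantaneous-binding ",
           "idealisation", call. = FALSE)
    p <- as.numeric(scheme$states == scheme$liganded_state)
    return(stats::setNames(p, scheme$states))
  }
  epochs <- proto$pre_equilibration
  if (is.null(epochs) || !nrow(epochs))
    stop("pre_equilibration epochs required when instantaneous_binding is ",
         "FALSE", call. = FALSE)
  # equilibrium at the first epoch's concentration: null vector of Q
  Q1 <- assemble_rate_matrix(scheme, params, epochs$concentration[1])
  ns <- scheme$n_states
  A <- rbind(unclass(Q1), rep(1, ns))
  p <- qr.solve(A, c(rep(0, ns), 1))
  p[p < 0 & p > -1e-12] <- 0
  for (j in seq_len(nrow(epochs))[-1]) {
    Qj <- assemble_rate_matrix(scheme, params, epochs$concentration[j])
    p <- as.vector(Matrix::expm(unclass(Qj) * epochs$duration[j]) %*% p)
  }
  Qp <- assemble_rate_matrix(scheme, params, proto$pulse_concentration)
  p <- as.vector(Matrix::expm(unclass(Qp) * proto$pulse_duration) %*% p)
  p <- pmax(p, 0)
  stats::setNames(p / sum(p), scheme$states)
}

#' State occupancy probabilities over time
#'
#' Columns are `exp(Q t) p0` for each requested time (concentration fixed at
#' `concentration`, i.e. after the pulse).
#'
#' @inheritParams initial_state
#' @param p0 Initial probability vector.
#' @param times Numeric vector of times (ms).
#' @param concentration Agonist concentration during the propagation (mM).
#' @return `n_states` x `length(times)` matrix of probabilities.
#' @export
occupancy <- function(scheme, params, p0, times, concentration = 0) {
  Q <- assemble_rate_matrix(scheme, params, concentration)
  sd <- spectral_decompose(Q)
  P <- .cast_real(.propagate(sd, p0, times), what = "occupancy")
  rownames(P) <- scheme$states
  P
}

#' Mean single-channel current
#'
#' `mu(t) = i' exp(Q t) p(0)` with `i` the per-state unitary-current vector.
#' @inheritParams occupancy
#' @return Numeric vector of mean currents (pA) at `times`.
#' @export
mean_single_channel_current <- function(scheme, params, p0, times,
                                        concentration = 0) {
  i <- state_currents(scheme, params)
  as.vector(i %*% occupancy(scheme, params, p0, times, concentration))
}

#' Single-channel covariance matrix on a time grid
#'
#' Dense evaluation of the covariance of the current of one channel,
#' `c(t, t') = i' exp(Q (t'-t)) (p(t) * i) - mu(t) mu(t')` for `t <= t'`,
#' extended symmetrically.  This is the direct (quadratic-cost) evaluation
#' used as reference; the likelihood machinery uses the semiseparable
#' factorisation instead.
#'
#' @inheritParams occupancy
#' @return `length(times)` square covariance matrix (pA^2).
#' @export
single_channel_covariance <- function(scheme, params, p0, times,
                                      concentration = 0) {
  Q <- assemble_rate_matrix(scheme, params, concentration)
  sd <- spectral_decompose(Q)
  i <- state_currents(scheme, params)
  P <- .propagate(sd, p0, times)               # complex Ns x Nt
  mu <- as.vector(crossprod(i, P))             # complex
  nt <- length(times)
  u <- as.vector(crossprod(i, sd$U))           # i'U, length Ns
  G <- sd$U_inv %*% (P * i)                    # gamma: Ns x Nt
  C <- matrix(0 + 0i, nt, nt)
  for (j in seq_len(nt)) {
    dtv <- times[j:nt] - times[j]
    # c(t_j, t_k) for k >= j
    C[j, j:nt] <- colSums(u * exp(outer(sd$values, dtv)) * G[, j]) -
      mu[j] * mu[j:nt]
  }
  C[lower.tri(C)] <- t(C)[lower.tri(C)]
  .cast_real(C, what = "single-channel covariance")
}

#' Peak open probability
#'
#' Maximum over time of the summed open-state occupancy, given that the
#' channel starts from `p0` (by default the fully liganded state at the end of
#' the agonist pulse).
#'
#' @inheritParams occupancy
#' @return A single probability in `[0, 1]`.
#' @export
peak_open_probability <- function(scheme, params, p0, times,
                                  concentration = 0) {
  P <- occupancy(scheme, params, p0, times, concentration)
  if (!scheme$n_open) return(0)
  po <- colSums(P[names(scheme$open_states), , drop = FALSE])
  min(max(po), 1)
}
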