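# Independent oracles used across the test suite.  These deliberately avoid
# the package's spectral/semiseparable code paths: dense covariances are
# evaluated with scaling-and-squaring matrix exponentials and single-channel
# ensembles with a per-channel continuous-time (Gillespie) path simulator.

expm_oracle <- function(M) as.matrix(Matrix::expm(M))

# dense single-channel mean/covariance via expm only (uniform grid)
dense_moments_oracle <- function(scheme, params, p0, times) {
  Q <- unclass(assemble_rate_matrix(scheme, params, 0))
  i <- state_currents(scheme, params)
  nt <- length(times)
  h <- if (nt > 1) times[2] - times[1] else 1
  Eh <- expm_oracle(Q * h)
  P <- matrix(0, nrow(Q), nt)
  P[, 1] <- expm_oracle(Q * times[1]) %*% p0
  if (nt > 1) for (k in 2:nt) P[, k] <- Eh %*% P[, k - 1]
  mu <- as.vector(i %*% P)
  lagmats <- vector("list", nt)
  lagmats[[1]] <- diag(nrow(Q))
  if (nt > 1) for (l in 2:nt) lagmats[[l]] <- Eh %*% lagmats[[l - 1]]
  C <- matrix(0, nt, nt)
  for (j in seq_len(nt)) {
    pj_i <- P[, j] * i
    for (k in j:nt) {
      C[j, k] <- sum(i * (lagmats[[k - j + 1]] %*% pj_i)) - mu[j] * mu[k]
      C[k, j] <- C[j, k]
    }
  }
  list(mu = mu, C = C, P = P)
}

# dense multivariate-Gaussian log-density oracle (constant term omitted to
# match the likelihood convention)
dense_gauss_loglik <- function(traces, mu, C, nch) {
  R <- chol(C)
  ld <- 2 * sum(log(diag(R)))
  ll <- 0
  for (k in seq_len(ncol(traces))) {
    r <- traces[, k] - nch[k] * mu
    z <- forwardsolve(t(R), r)
    ll <- ll - 0.5 * (sum(z^2) / nch[k] + length(mu) * log(nch[k]))
  }
  ll - ncol(traces) / 2 * ld
}

# per-channel continuous-time path simulation (independent of the
# multinomial aggregate engine); returns state index at each grid time
gillespie_channels <- function(scheme, params, start_state, times,
                               n_channels) {
  Q <- unclass(assemble_rate_matrix(scheme, params, 0))
  ns <- nrow(Q)
  out_rate <- -diag(Q)
  jump <- Q
  diag(jump) <- 0
  jump <- sweep(jump, 2, pmax(colSums(jump), 1e-300), "/")  # P(dest | leave j)
  tmax <- max(times)
  states <- matrix(0L, length(times), n_channels)
  for (ch in seq_len(n_channels)) {
    s <- start_state
    t <- 0
    path_t <- 0
    path_s <- s
    while (t < tmax) {
      r <- out_rate[s]
      if (r <= 0) break
      t <- t + stats::rexp(1, r)
      if (t >= tmax) break
      s <- sample.int(ns, 1, prob = jump[, s])
      path_t <- c(path_t, t)
      path_s <- c(path_s, s)
    }
    states[, ch] <- path_s[findInterval(times, path_t)]
  }
  states
}
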