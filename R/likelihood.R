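#' Semiseparable factors of the single-channel covariance
#'
#' On a uniform grid the single-channel covariance matrix `c_m1` has
#' lower-triangle rank `N_s + 1`: `c[i, j] = sum_k A[i, k] B[k, j]` for
#' `i >= j`.  This builds the spectral generators of that factorisation
#' (eigenvalues, `u = i'U`, `gamma_j = U^-1 (p(t_j) * i)`, and the mean
#' vector), from which Cholesky factorisation, solves, log-determinants and
#' noise-trace corrections all run in time linear in the grid size.
#'
#' @param scheme A [kinetic_scheme()].
#' @param params A [channel_params()].
#' @param p0 Initial state probability vector (at the end of the pulse).
#' @param times Uniform time grid (ms after pulse end).
#' @param concentration Post-pulse agonist concentration (mM).
#' @return An object of class `ss_factors`.
#' @export
ss_factors <- function(scheme, params, p0, times, concentration = 0) {
  nt <- length(times)
  if (nt >= 2) {
    h <- diff(times)
    if (max(abs(h - h[1])) > 1e-8 * max(h))
      stop("`times` must be a uniform grid", call. = FALSE)
    h <- h[1]
  } else h <- 1
  Q <- assemble_rate_matrix(scheme, params, concentration)
  sd <- spectral_decompose(Q)
  i <- state_currents(scheme, params)
  P <- .propagate(sd, p0, times)                    # Ns x Nt complex
  mu <- .cast_real(as.vector(crossprod(i, P)), what = "mean current")
  u <- as.vector(crossprod(i, sd$U))                # i'U
  gam <- sd$U_inv %*% (P * i)                       # U^-1 (p(t) * i)
  structure(list(lambda = sd$values, u = as.complex(u),
                 gamma = gam, mu = mu, times = times, h = h,
                 n_states = scheme$n_states, chol = NULL),
            class = "ss_factors")
}

#' @exportS3Method base::print
print.ss_factors <- function(x, ...) {
  cat("<ss_factors> grid of ", length(x$times), " points (h = ", x$h,
      " ms), ", x$n_states, "-state scheme\n", sep = "")
  invisible(x)
}

#' Dense A and B factor matrices
#'
#' Materialises the `N_T x (N_s + 1)` and `(N_s + 1) x N_T` factor matrices
#' whose product reproduces the lower triangle of `c_m1`.  The exponentials
#' are referenced to the segment end time so both factors stay bounded on
#' short grids; this dense form exists for inspection and testing — the
#' solver works directly on the per-step transfer form and never builds it.
#'
#' @param factors An [ss_factors()].
#' @return List with matrices `A` and `B` (complex).
#' @export
dense_factors <- function(factors) {
  ts_end <- factors$times[length(factors$times)]
  ns <- length(factors$lambda)
  A <- cbind(t(exp(outer(factors$lambda, factors$times - ts_end)) *
                 factors$u), factors$mu)
  B <- rbind(exp(outer(factors$lambda, ts_end - factors$times)) *
               factors$gamma, -factors$mu)
  list(A = A, B = B)
}

#' Reconstruct the dense covariance from the factors
#'
#' Symmetrised `A B` reconstruction (lower triangle from the factors,
#' mirrored).  For testing on small grids.
#' @param factors An [ss_factors()].
#' @return Real symmetric matrix.
#' @export
ss_reconstruct <- function(factors) {
  f <- dense_factors(factors)
  C <- f$A %*% f$B
  C[upper.tri(C)] <- t(C)[upper.tri(C)]
  .cast_real(C, tol = 1e-7, what = "covariance reconstruction")
}

.ss_chol <- function(factors, jitter = -1) {
  f <- cpp_ss_chol(factors$u, factors$lambda * factors$h, factors$gamma,
                   factors$mu, jitter)
  if (!isTRUE(f$ok))
    stop("single-channel covariance is not positive definite on this grid ",
         "(pivot failure even with diagonal jitter); trim the window or ",
         "increase jitter", call. = FALSE)
  if (f$jitter > 0)
    message("added diagonal jitter ", signif(f$jitter, 3),
            " to factorise c_m1")
  f
}

.with_chol <- function(factors) {
  if (is.null(factors$chol)) factors$chol <- .ss_chol(factors)
  factors
}

#' Solve linear systems in the single-channel covariance
#'
#' Computes `c_m1^-1 rhs` through the structured Cholesky factorisation
#' (cost linear in the grid size per right-hand side).
#'
#' @param factors An [ss_factors()].
#' @param rhs Numeric vector or matrix of right-hand sides (rows = grid).
#' @return Matrix of solutions (same shape as `rhs`).
#' @export
ss_solve <- function(factors, rhs) {
  rhs <- as.matrix(rhs)
  factors <- .with_chol(factors)
  s <- cpp_ss_solve(factors$u, factors$lambda * factors$h, factors$mu,
                    factors$chol$w, factors$chol$d, rhs)
  s$x
}

#' Log-determinant of the single-channel covariance
#' @param factors An [ss_factors()].
#' @return `log |c_m1|`.
#' @export
ss_logdet <- function(factors) {
  factors <- .with_chol(factors)
  factors$chol$logdet
}

#' Noise trace correction term
#'
#' Exact `tr(c_m1^-1 c_noise)` for an AR(1)-sum noise covariance, computed by
#' a linear-time recursion over the quasiseparable inverse (no dense matrix
#' is formed).  Enters the noise-corrected log-likelihood as
#' `+ (1/2) tr(c_m1^-1 c_noise) N <1/N_ch>`.
#'
#' @param factors An [ss_factors()].
#' @param noise A [noise_model()], or `NULL` for 0.
#' @param stride Grid stride in acquisition samples (the AR coefficients are
#'   per acquisition sample).
#' @return Scalar trace value.
#' @export
noise_trace_term <- function(factors, noise, stride = 1) {
  if (is.null(noise)) return(0)
  factors <- .with_chol(factors)
  cpp_ss_trace(factors$u, factors$lambda * factors$h, factors$mu,
               factors$chol$w, factors$chol$d,
               noise$phi^stride, noise$stat_sd^2)
}

#' Window indices for the per-trace channel-number estimator
#'
#' From the peak of the model mean current down to `frac` of the peak
#' (contiguous high signal-to-noise region of the decay).
#' @param mu Mean current on the grid.
#' @param frac Fraction of the peak at which the window ends.
#' @return Integer vector `c(first, last)` (1-based).
#' @export
nch_window <- function(mu, frac = 0.3) {
  i0 <- which.max(mu)
  below <- which(mu < frac * mu[i0])
  i1 <- if (any(below > i0)) min(below[below > i0]) - 1L else length(mu)
  c(i0, max(i1, min(i0 + 1L, length(mu))))
}

#' Per-trace liganded-channel-number estimate
#'
#' Closed-form maximiser of the single-trace likelihood over the channel
#' number: `N_chi = (-n + sqrt(n^2 + 4 (c'c_m1^-1 c)(mu'c_m1^-1 mu))) /
#' (2 mu'c_m1^-1 mu)` evaluated on the windowed sub-grid (`n` = window
#' length).  The window restricts to high signal-to-noise samples so the
#' neglected noise quadratic form stays small.
#'
#' @param traces Numeric matrix (grid x traces) or vector.
#' @param factors An [ss_factors()] on the same grid.
#' @param window Integer `c(first, last)` window (default from
#'   [nch_window()]).
#' @return Numeric vector of per-trace channel numbers.
#' @export
estimate_nch <- function(traces, factors, window = NULL) {
  traces <- as.matrix(traces)
  if (is.null(window)) window <- nch_window(factors$mu)
  idx <- window[1]:window[2]
  if (length(idx) < 1) stop("empty channel-number window", call. = FALSE)
  sub <- ss_subset(factors, idx)
  sub <- .with_chol(sub)
  muw <- sub$mu
  qmu <- drop(crossprod(muw, ss_solve(sub, muw)))
  if (qmu <= 0) stop("mu' c_m1^-1 mu is not positive: channel-number scale ",
                     "undefined", call. = FALSE)
  xc <- ss_solve(sub, traces[idx, , drop = FALSE])
  qc <- colSums(traces[idx, , drop = FALSE] * xc)
  n <- length(idx)
  (-n + sqrt(n^2 + 4 * qc * qmu)) / (2 * qmu)
}

#' Restrict factors to a sub-grid
#'
#' The factor quantities are pointwise in time, so a contiguous or uniformly
#' strided subset of the grid is just the corresponding subset of columns.
#' @param factors An [ss_factors()].
#' @param idx Indices into the grid (must be uniformly spaced).
#' @return An [ss_factors()] on the sub-grid.
#' @export
ss_subset <- function(factors, idx) {
  st <- if (length(idx) >= 2) unique(diff(idx)) else 1
  if (length(st) > 1) stop("sub-grid must be uniformly spaced", call. = FALSE)
  structure(list(lambda = factors$lambda, u = factors$u,
                 gamma = factors$gamma[, idx, drop = FALSE],
                 mu = factors$mu[idx], times = factors$times[idx],
                 h = factors$h * st, n_states = factors$n_states,
                 chol = NULL),
            class = "ss_factors")
}

#' Noise-corrected log-likelihood of a trace set
#'
#' Evaluates the log-likelihood of the parameter point given the traces,
#' with the per-trace channel numbers profiled out by their closed-form
#' estimates (unless supplied) and the coloured-noise correction
#' `+ (1/2) tr(c_m1^-1 c_noise) N <1/N_ch>` applied.  The additive constant
#' `N N_T log(2 pi) / 2` is omitted.
#'
#' @param traces A [trace_set()] or a numeric matrix (grid x traces).
#' @param scheme A [kinetic_scheme()].
#' @param params A [channel_params()].
#' @param noise A [noise_model()] or `NULL`.
#' @param p0 Initial state vector; defaults to the delta on the scheme's
#'   fully liganded state.
#' @param times Grid times; defaults to the trace set's grid.
#' @param nch Optional fixed per-trace channel numbers (otherwise estimated).
#' @param window_frac Peak fraction ending the channel-number window.
#' @param stride Acquisition-sample stride of the grid (for the AR noise
#'   coefficients).
#' @param nch_bounds Length-2 bounds applied to the profiled per-trace
#'   channel numbers (the fitting protocol bounds every parameter, the
#'   channel number included; an unbounded profile admits a degenerate
#'   many-channels/low-open-probability ridge).
#' @param nch_noise_sub Subtract the expected noise quadratic form from the
#'   windowed trace quadratic form when profiling the channel numbers (the
#'   exact profile retains this term; the closed-form approximation neglects
#'   it, which biases the profile upward where the gating covariance is
#'   small).
#' @return An object of class `nsfa_loglik`: list with `loglik`,
#'   `loglik_uncorrected`, `per_trace_nch`, `quad_forms`, `logdet_cm1`,
#'   `noise_trace_term`.
#' @export
nsfa_loglik <- function(traces, scheme, params, noise = NULL, p0 = NULL,
                        times = NULL, nch = NULL, window_frac = 0.3,
                        stride = 1, nch_bounds = c(1e-12, Inf),
                        nch_noise_sub = FALSE) {
  if (inherits(traces, "trace_set")) {
    if (is.null(times)) times <- trace_times(traces)
    traces <- traces$currents
  }
  traces <- as.matrix(traces)
  if (is.null(times)) stop("`times` required for matrix input", call. = FALSE)
  if (is.null(p0)) {
    p0 <- as.numeric(scheme$states == scheme$liganded_state)
  }
  fac <- ss_factors(scheme, params, p0, times)
  win <- nch_window(fac$mu, window_frac)
  phi <- if (is.null(noise)) numeric(0) else noise$phi^stride
  nu <- if (is.null(noise)) numeric(0) else noise$stat_sd^2
  res <- cpp_ss_loglik(fac$u, fac$lambda * fac$h, fac$gamma, fac$mu,
                       traces, win[1] - 1L, win[2] - 1L, phi, nu,
                       if (is.null(nch)) numeric(0) else as.numeric(nch),
                       nch_bounds[1], nch_bounds[2], isTRUE(nch_noise_sub))
  if (!isTRUE(res$ok))
    stop("covariance factorisation failed at this parameter point",
         call. = FALSE)
  structure(list(loglik = res$loglik,
                 loglik_uncorrected = res$loglik_uncorrected,
                 per_trace_nch = as.vector(res$nch),
                 quad_forms = as.vector(res$quad),
                 logdet_cm1 = res$logdet,
                 noise_trace_term = res$trace_term,
                 mu_quad = res$qmu,
                 window = win,
                 n_traces = ncol(traces),
                 n_points = nrow(traces)),
            class = "nsfa_loglik")
}

#' @exportS3Method base::print
print.nsfa_loglik <- function(x, ...) {
  cat("<nsfa_loglik> logL = ", format(x$loglik, digits = 8), " (",
      x$n_traces, " traces x ", x$n_points, " points)\n", sep = "")
  cat("  per-trace N_ch: ", paste(round(range(x$per_trace_nch)),
                                  collapse = " - "),
      "; noise trace term = ", signif(x$noise_trace_term, 4), "\n", sep = "")
  invisible(x)
}
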