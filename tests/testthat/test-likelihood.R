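test_that("factor reconstruction equals the direct covariance (dense oracle)", {
  # 3-state, 25-point grid
  sch <- scheme_3state(); par <- params_3state("R")
  tt <- seq(1, 5.8, by = 0.2)
  fac <- ss_factors(sch, par, c(0, 1, 0), tt)
  Cd <- dense_moments_oracle(sch, par, c(0, 1, 0), tt)$C
  expect_lt(max(abs(ss_reconstruct(fac) - Cd)), 1e-8 * max(abs(Cd)))
  # dense A, B factors reproduce the lower triangle
  f <- dense_factors(fac)
  AB <- Re(f$A %*% f$B)
  lower <- lower.tri(Cd, diag = TRUE)
  expect_lt(max(abs(AB[lower] - Cd[lower])), 1e-8 * max(abs(Cd)))

  # 7-state, 40-point grid
  sch7 <- scheme_gabaa7(); par7 <- params_gabaa7()
  p07 <- as.numeric(sch7$states == "RG2")
  tt7 <- seq(1, 8.8, by = 0.2)
  fac7 <- ss_factors(sch7, par7, p07, tt7)
  Cd7 <- dense_moments_oracle(sch7, par7, p07, tt7)$C
  expect_lt(max(abs(ss_reconstruct(fac7) - Cd7)), 1e-8 * max(abs(Cd7)))
})

test_that("zero unitary currents collapse the covariance factors", {
  sch <- scheme_3state(); par <- params_3state("R")
  par$unitary <- 0
  fac <- ss_factors(sch, par, c(0, 1, 0), seq(1, 5, by = 0.5))
  expect_equal(max(abs(ss_reconstruct(fac))), 0)
  expect_equal(max(Mod(dense_factors(fac)$A[, 1:3])), 0)  # i-weighted columns
})

test_that("sub-grid factors equal pointwise subsets", {
  sch <- scheme_gabaa7(); par <- params_gabaa7()
  p0 <- as.numeric(sch$states == "RG2")
  tt <- seq(1, 20, by = 0.2)
  fac <- ss_factors(sch, par, p0, tt)
  idx <- seq(3, 90, by = 3)
  sub <- ss_subset(fac, idx)
  direct <- ss_factors(sch, par, p0, tt[idx])
  expect_equal(sub$mu, direct$mu, tolerance = 1e-12)
  expect_equal(sub$gamma, direct$gamma, tolerance = 1e-12)
  expect_equal(sub$h, direct$h, tolerance = 1e-12)
})

test_that("structured solve and log-determinant match dense Cholesky", {
  sch <- scheme_gabaa7(); par <- params_gabaa7()
  p0 <- as.numeric(sch$states == "RG2")
  tt <- seq(1, 8.8, by = 0.2)                  # 40 points
  fac <- ss_factors(sch, par, p0, tt)
  Cd <- single_channel_covariance(sch, par, p0, tt)
  R <- chol(Cd)
  rhs <- withr::with_seed(21, matrix(rnorm(length(tt) * 3), ncol = 3))
  xd <- backsolve(R, forwardsolve(t(R), rhs))
  xs <- ss_solve(fac, rhs)
  expect_lt(max(abs(xs - xd)) / max(abs(xd)), 1e-6)
  expect_equal(ss_logdet(fac), 2 * sum(log(diag(R))), tolerance = 1e-9)

  # positive-definiteness property over random parameter draws
  sch3 <- scheme_3state()
  withr::with_seed(22, {
    for (k in 1:100) {
      p <- params_3state("R")
      p$rates[] <- p$rates * exp(stats::runif(4, -1, 1))
      f <- ss_factors(sch3, p, c(0, 1, 0), seq(1, 15, by = 0.5))
      q <- drop(crossprod(f$mu, ss_solve(f, f$mu)))
      expect_gte(q, 0)
    }
  })
})

test_that("noise trace term matches the dense trace and scales linearly", {
  sch <- scheme_gabaa7(); par <- params_gabaa7()
  p0 <- as.numeric(sch$states == "RG2")
  tt <- seq(1, 8.8, by = 0.2)
  fac <- ss_factors(sch, par, p0, tt)
  nm <- default_noise_model(3)
  Cd <- single_channel_covariance(sch, par, p0, tt)
  Cn <- noise_covariance(nm, length(tt))
  tr_dense <- sum(diag(solve(Cd, Cn)))
  tr_ss <- noise_trace_term(fac, nm)
  expect_equal(tr_ss, tr_dense, tolerance = 1e-6)
  # doubling the noise covariance doubles the term
  nm2 <- nm; nm2$stat_sd <- nm$stat_sd * sqrt(2)
  expect_equal(noise_trace_term(fac, nm2), 2 * tr_ss, tolerance = 1e-10)
  expect_equal(noise_trace_term(fac, NULL), 0)
  # strided grids use the stride-adjusted AR coefficients
  idx <- seq(1, length(tt), by = 2)
  fac2 <- ss_subset(fac, idx)
  Cd2 <- Cd[idx, idx]
  Cn2 <- noise_covariance(nm, length(idx), stride = 2)
  expect_equal(noise_trace_term(fac2, nm, stride = 2),
               sum(diag(solve(Cd2, Cn2))), tolerance = 1e-6)
})

test_that("channel-number estimator: collapse at zero, scaling limit, windowing", {
  sch <- scheme_gabaa7(); par <- params_gabaa7()
  p0 <- as.numeric(sch$states == "RG2")
  tt <- seq(1, 50, by = 0.2)
  fac <- ss_factors(sch, par, p0, tt)
  expect_equal(estimate_nch(matrix(0, length(tt), 1), fac)[1], 0)
  # for c = K mu the estimator is K - n/(2 mu'C^-1 mu) + O(1/K): the
  # absolute bias is K-independent, so the relative error vanishes as K grows
  est <- vapply(c(3e2, 3e3, 3e4), function(K)
    estimate_nch(matrix(K * fac$mu, ncol = 1), fac)[1], numeric(1))
  rel <- abs(est - c(3e2, 3e3, 3e4)) / c(3e2, 3e3, 3e4)
  expect_true(all(diff(rel) < 0))
  expect_lt(rel[3], 0.005)
  # the absolute bias stabilises (O(1/K) correction dies out)
  expect_lt(abs((3e4 - est[3]) - (3e3 - est[2])), 0.2)
  # default window runs from the mean-current peak to 0.3 of the peak
  w <- nch_window(fac$mu, 0.3)
  expect_equal(w[1], which.max(fac$mu))
  expect_true(all(fac$mu[w[1]:w[2]] >= 0.3 * max(fac$mu) - 1e-12))
})

test_that("log-likelihood equals a dense Gaussian oracle and behaves under noise", {
  sch <- scheme_3state(); par <- params_3state("R")
  pr <- protocol(dt = 0.2, pulse_duration = 0.2, record_duration = 7,
                 analysis_start_offset = 1)        # 31 points
  ts <- quiet_sim(sch, par, pr, 8, noise = NULL, seed = 31)
  nch <- rep(400, 8)
  ll <- nsfa_loglik(ts, sch, par, nch = nch)
  mo <- dense_moments_oracle(sch, par, c(0, 1, 0), trace_times(ts))
  expect_equal(ll$loglik, dense_gauss_loglik(ts$currents, mo$mu, mo$C, nch),
               tolerance = 1e-6)
  # a noise model with zero amplitude leaves the value unchanged
  nm0 <- noise_model(c(0.5), c(0), target_sd = NULL)
  expect_equal(nsfa_loglik(ts, sch, par, noise = nm0, nch = nch)$loglik,
               ll$loglik)
})

test_that("the true parameters dominate a mis-scaled unitary current", {
  fx <- fx_fig4R_small()
  ts <- trim_traces(fx$traces, 1)[1:20]   # decaying phase (t = 0 has zero
                                          # model variance by construction)
  ll_true <- nsfa_loglik(ts, fx$scheme, fx$params, noise = fx$noise)
  par2 <- fx$params; par2$unitary <- 2 * par2$unitary
  ll_wrong <- nsfa_loglik(ts, fx$scheme, par2, noise = fx$noise)
  expect_gt(ll_true$loglik, ll_wrong$loglik)
})

test_that("the dropped noise-signal cross term is small relative to the retained term", {
  # simulate signal and noise separately so the cross term is computable
  sch <- scheme_3state(); par <- params_3state("R")
  pr <- default_protocol("3state")
  N <- 30
  sig <- quiet_sim(sch, par, pr, N, noise = NULL, seed = 41)
  nm <- default_noise_model(3)
  nmat <- withr::with_seed(42,
    generate_colored_noise(nm, nrow(sig$currents), N))
  cur <- sig$currents + nmat
  tt <- trace_times(sig)
  fac <- ss_factors(sch, par, c(0, 1, 0), tt)
  nch <- sig$nch_true                 # decomposition holds at the true counts
  mu <- fac$mu
  xn <- ss_solve(fac, nmat)
  retained <- 0.5 * sum(colSums(nmat * xn) / nch)
  cross <- sum(vapply(seq_len(N), function(i) {
    r <- cur[, i] - nmat[, i] - nch[i] * mu
    sum(xn[, i] * r) / nch[i]
  }, numeric(1)))
  expect_lt(abs(cross), 0.05 * retained)
})

test_that("profile-likelihood curvature in the unitary current grows with sample size", {
  fx <- fx_fig4R_small()
  curv <- function(n) {
    ts <- trim_traces(fx$traces, 1)[seq_len(n)]
    f <- function(i1) {
      p <- fx$params; p$unitary <- i1
      nsfa_loglik(ts, fx$scheme, p, noise = fx$noise)$loglik
    }
    d <- 0.05
    -(f(1 + d) - 2 * f(1) + f(1 - d)) / d^2
  }
  c5 <- curv(5); c20 <- curv(20); c80 <- curv(80)
  expect_gt(c20, c5)
  expect_gt(c80, c20)
})
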