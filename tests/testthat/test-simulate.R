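test_that("channel-number sampling is rounded, truncated Gaussian", {
  withr::with_seed(1, {
    expect_equal(sample_channel_numbers(250, 0, 5), rep(250L, 5))
    x <- sample_channel_numbers(250, 50, 1e4)
    expect_lt(abs(mean(x) - 250), 3 * 50 / sqrt(1e4))
    expect_true(all(sample_channel_numbers(2, 50, 500) >= 1))
  })
})

test_that("a single channel produces a two-level trace and counts are conserved", {
  sch <- scheme_3state(); par <- params_3state("R")
  pr <- default_protocol("3state")
  ts <- quiet_sim(sch, par, pr, 3, noise = NULL, seed = 2)
  # force a one-channel trace set
  par1 <- par; par1$nch_mean <- 1; par1$nch_sd <- 0
  ts1 <- quiet_sim(sch, par1, pr, 4, noise = NULL, seed = 3)
  expect_true(all(ts1$currents %in% c(0, 1)))

  K <- pmax(as.matrix(Matrix::expm(unclass(
    assemble_rate_matrix(sch, par, 0)) * 0.1)), 0)
  cnt <- withr::with_seed(4, cpp_sim_ensemble_counts(K, c(0, 1, 0), 500, 200))
  expect_equal(colSums(cnt), rep(500, 201))
})

test_that("large-N noiseless traces follow the deterministic mean", {
  sch <- scheme_3state(); par <- params_3state("R")
  par$nch_mean <- 1e5; par$nch_sd <- 0
  pr <- default_protocol("3state")
  ts <- quiet_sim(sch, par, pr, 1, noise = NULL, seed = 7)
  tt <- trace_times(ts)
  mu <- mean_single_channel_current(sch, par, c(0, 1, 0), tt)
  hi <- mu > 0.5 * max(mu)
  expect_lt(max(abs(ts$currents[hi, 1] - 1e5 * mu[hi]) / (1e5 * mu[hi])), 0.05)
})

test_that("ensemble mean and variance of aggregate simulations match theory", {
  sch <- scheme_3state(); par <- params_3state("R")
  par$nch_mean <- 200; par$nch_sd <- 0
  pr <- protocol(dt = 0.1, pulse_duration = 0.2, record_duration = 20,
                 analysis_start_offset = 0.5)
  ts <- quiet_sim(sch, par, pr, 2000, noise = NULL, seed = 8)
  tt <- trace_times(ts)
  mu <- mean_single_channel_current(sch, par, c(0, 1, 0), tt)
  v_th <- 200 * diag(single_channel_covariance(sch, par, c(0, 1, 0), tt))
  m_emp <- rowMeans(ts$currents)
  v_emp <- apply(ts$currents, 1, stats::var)
  expect_true(all(abs(m_emp - 200 * mu) <= 4 * sqrt(v_th / 2000) + 1e-8))
  # variance of a sample variance ~ 2 v^2 / n for near-Gaussian sums
  expect_true(all(abs(v_emp - v_th) <= 5 * sqrt(2 * v_th^2 / 2000) + 0.05))
})

test_that("coloured-noise generator: stationary SD, autocorrelation, reproducibility", {
  withr::with_seed(10, {
    w <- generate_colored_noise(noise_model(0, 1), 1e5, 10)
    expect_lt(abs(stats::sd(w) - 1), 0.01)
  })
  withr::with_seed(11, {
    nm <- default_noise_model(3)
    x <- generate_colored_noise(nm, 4000, 300)
    expect_lt(abs(stats::sd(x) - 3), 0.02 * 3)
  })
  withr::with_seed(12, {
    x <- generate_colored_noise(noise_model(0.9, 1), 5e4, 4)
    r1 <- mean(vapply(1:4, function(j)
      stats::cor(x[-1, j], x[-nrow(x), j]), numeric(1)))
    expect_lt(abs(r1 - 0.9), 0.02)
  })
  a <- withr::with_seed(13, generate_colored_noise(default_noise_model(3), 100, 5))
  b <- withr::with_seed(13, generate_colored_noise(default_noise_model(3), 100, 5))
  expect_identical(a, b)
})

test_that("noise covariance matches its definition and simulated noise", {
  nm0 <- noise_model(0, 2)
  expect_equal(unclass(noise_covariance(nm0, 5)), 4 * diag(5),
               ignore_attr = TRUE)
  nm <- default_noise_model(3)
  C <- noise_covariance(nm, 30)
  # Toeplitz stationarity
  expect_equal(C[1:29, 1:29], C[2:30, 2:30], ignore_attr = TRUE)
  expect_equal(C[1, 1], 9, tolerance = 1e-12)
  emp <- withr::with_seed(14, {
    x <- generate_colored_noise(nm, 30, 2e4)
    tcrossprod(x) / (2e4)
  })
  mc_sd <- sqrt((diag(C) %o% diag(C) + C^2) / 2e4)
  expect_true(all(abs(emp - C) <= 4 * mc_sd))
})

test_that("a noise model can be re-estimated from baseline segments", {
  truth <- noise_model(c(0.2, 0.95), c(1, 0.8), target_sd = 2.5)
  base <- withr::with_seed(19, generate_colored_noise(truth, 4000, 30))
  est <- estimate_noise_model(base, n_components = 2, max_lag = 150)
  # total stationary SD and the covariance at short lags are recovered
  expect_lt(abs(sqrt(sum(est$stat_sd^2)) - 2.5), 0.25)
  C_true <- noise_covariance(truth, 20)
  C_est <- noise_covariance(est, 20)
  expect_lt(max(abs(C_est - C_true)), 0.15 * C_true[1, 1])
})

test_that("trace statistics: exact exponential recovery and degenerate input", {
  tt <- seq(0, 60, by = 0.2)
  y <- 50 * exp(-tt / 17)
  ts <- trace_set(cbind(y, 0 * y), dt = 0.2, t0 = 0)
  st <- trace_statistics(ts)
  expect_equal(st$decay_tau[1], 17, tolerance = 1e-6)
  expect_equal(st$peak[1], 50)
  expect_equal(st$peak[2], 0)
})

test_that("trace sets trim, subset and tidy consistently", {
  fx <- fx_fig4R_small()
  ts <- fx$traces
  tr <- trim_traces(ts, 5)
  expect_equal(trace_times(tr)[1], 5, tolerance = 1e-9)
  sub <- ts[c(2, 2, 5)]
  expect_equal(sub$currents[, 1], sub$currents[, 2])
  tb <- tibble::as_tibble(ts[1:3])
  expect_equal(nrow(tb), 3 * nrow(ts$currents))
  expect_named(tb, c("trace", "time", "current"))
})
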