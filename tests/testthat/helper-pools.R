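# Shared simulated pools for the validation-scale tests (built once).

pool_fig1 <- function() fx_fig1_pool()   # 1000-trace 7-state reference pool

pool_fig3 <- function() fx_cached("fig3_pool", function()
  suppressWarnings(nsfa_fixture("fig3", n_traces = 600, seed = 404)))

pool_het <- function() fx_cached("het_pool", function()
  suppressWarnings(nsfa_fixture("fig5_het", n_traces = 600, seed = 505)))

pool_model <- function(model) fx_cached(paste0("pool_", model), function()
  suppressWarnings(nsfa_fixture(paste0("fig4_", model), n_traces = 400,
                                seed = 606)))

# decaying-phase windows used by the ML analyses
ml_window <- function(ts) trim_traces(ts, 1, 51)
ml_window3 <- function(ts) thin_traces(trim_traces(ts, 1, 51), 2L)

cfg_accept <- function(seed, maxit = 60) {
  fit_config(n_restarts = 2, maxit = maxit, seed = seed)
}

boot_estimates <- function(report, term) {
  report$replicates$estimate[report$replicates$term == term]
}

rms_pct <- function(est, true) 100 * sqrt(mean((est - true)^2)) / true
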