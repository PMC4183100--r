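# Lazily built shared fixtures (computed once per test run).

.fx_cache <- new.env(parent = emptyenv())

fx_cached <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder()
  .fx_cache[[name]]
}

fx_fig1_pool <- function() fx_cached("fig1_pool", function()
  suppressWarnings(nsfa_fixture("fig1", n_traces = 1000, seed = 101)))

fx_fig4R_small <- function() fx_cached("fig4R_small", function()
  suppressWarnings(nsfa_fixture("fig4_R", n_traces = 120, seed = 202)))

# decaying-phase, coarsened view of the 3-state pool used by the fitting
# tests: [1, 51] ms at an effective 0.2 ms grid
fx_fig4R_ml <- function() fx_cached("fig4R_ml", function()
  thin_traces(trim_traces(fx_fig4R_small()$traces, 1, 51), 2L))

quiet_sim <- function(...) suppressWarnings(simulate_traces(...))
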