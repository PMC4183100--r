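#' Bundled simulation fixtures
#'
#' Regenerates, at configurable scale, the simulated ensembles used
#' throughout the package's validation experiments:
#'
#' * `fig1` — 7-state GABA-A receptor, equal unitary currents (1 pA),
#'   N_ch ~ 250 +/- 50, coloured noise SD 3 pA.
#' * `fig3` — two-conductance 7-state variant (i1 = 2, i2 = 1 pA, modified
#'   gating rates), N_ch ~ 500 +/- 50.
#' * `fig4_R`, `fig4_A`, `fig4_N` — 3-state abstract receptor: reference
#'   model, halved closing rate, doubled channel number.
#' * `fig5_het` — as `fig1` but with `koff`, `d2`, `r2` varying uniformly
#'   within +/-20 percent from trace to trace.
#'
#' @param id Fixture identifier.
#' @param n_traces Number of traces (default 1000, the full-scale pool).
#' @param seed Integer seed.
#' @param scale Scale factor applied to `n_traces`; 0 returns the
#'   configuration (scheme, parameters, protocol, noise) without traces.
#' @return A list with `id`, `scheme`, `params`, `protocol`, `noise`,
#'   `rate_jitter` and (when `scale > 0`) `traces`.
#' @export
nsfa_fixture <- function(id = c("fig1", "fig3", "fig4_R", "fig4_A",
                                "fig4_N", "fig5_het"),
                         n_traces = 1000, seed = 1L, scale = 1) {
  id <- match.arg(id)
  noise <- default_noise_model(3)
  # fixtures keep the full post-pulse record (offset 0): amplitude/decay
  # statistics and peak scaling need the true peak, which precedes the 1 ms
  # start of the likelihood window; analyses trim with trim_traces()
  full_record <- function(p) { p$analysis_start_offset <- 0; p }
  if (id %in% c("fig1", "fig5_het")) {
    scheme <- scheme_gabaa7(); params <- params_gabaa7()
    proto <- default_protocol("gabaa7")
    jit <- if (id == "fig5_het") list(koff = 0.2, d2 = 0.2, r2 = 0.2)
           else NULL
  } else if (id == "fig3") {
    scheme <- scheme_gabaa7(two_conductance = TRUE)
    params <- params_gabaa7(two_conductance = TRUE)
    proto <- default_protocol("gabaa7")
    jit <- NULL
  } else {
    scheme <- scheme_3state()
    params <- params_3state(sub("fig4_", "", id))
    proto <- default_protocol("3state")
    jit <- NULL
  }
  out <- list(id = id, scheme = scheme, params = params, protocol = proto,
              noise = noise, rate_jitter = jit)
  n <- round(n_traces * scale)
  if (n > 0)
    out$traces <- simulate_traces(scheme, params, full_record(proto), n,
                                  noise = noise, rate_jitter = jit,
                                  seed = seed)
  out
}

#' Full-scale study design for a fixture
#'
#' The replicate counts of the full validation protocol (suitable for an
#' overnight run on one CPU), alongside the reduced desk-scale counts used
#' by the bundled checks.
#'
#' @param id Fixture identifier as in [nsfa_fixture()].
#' @return Tibble with one row per analysis run on that fixture.
#' @export
study_design <- function(id = c("fig1", "fig3", "fig4_R", "fig4_A",
                                "fig4_N", "fig5_het")) {
  id <- match.arg(id)
  switch(id,
    fig1 = tibble::tibble(
      analysis = c("ml_bootstrap", "ps_bootstrap"),
      sample_sizes = list(c(5, 10, 20, 30, 40, 100), c(5, 10, 20, 30, 40, 100)),
      n_bootstrap = c(60, 1000), n_restarts = c(10, NA),
      desk_n_bootstrap = c(12, 200), desk_n_restarts = c(2, NA)),
    fig3 = tibble::tibble(
      analysis = c("ml_bootstrap", "ps_bootstrap"),
      sample_sizes = list(50, 50),
      n_bootstrap = c(15, 250), n_restarts = c(10, NA),
      desk_n_bootstrap = c(5, 100), desk_n_restarts = c(2, NA)),
    fig5_het = tibble::tibble(
      analysis = c("mcmc", "ps_bootstrap"),
      sample_sizes = list(1, 250),
      n_bootstrap = c(50, 50), n_restarts = c(NA, NA),
      desk_n_bootstrap = c(25, 50), desk_n_restarts = c(NA, NA)),
    tibble::tibble(
      analysis = "ml_bootstrap", sample_sizes = list(100),
      n_bootstrap = 20, n_restarts = 5,
      desk_n_bootstrap = 6, desk_n_restarts = 2))
}

#' Write / read a scheme + parameter configuration
#'
#' Plain-text (YAML) serialisation of a kinetic scheme, its parameters, and
#' optionally protocol and noise model.
#'
#' @param fixture List with `scheme`, `params` and optionally `protocol`,
#'   `noise` (as returned by [nsfa_fixture()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_scheme_config <- function(fixture, path) {
  sc <- fixture$scheme; pa <- fixture$params
  cfg <- list(
    states = sc$states,
    transitions = lapply(seq_len(nrow(sc$transitions)), function(k)
      as.list(sc$transitions[k, ])),
    open_states = as.list(sc$open_states),
    liganded_state = sc$liganded_state,
    rates = as.list(pa$rates),
    unitary = pa$unitary,
    nch_mean = pa$nch_mean, nch_sd = pa$nch_sd)
  if (!is.null(fixture$protocol))
    cfg$protocol <- unclass(fixture$protocol)[
      c("dt", "pulse_duration", "pulse_concentration", "record_duration",
        "analysis_start_offset", "instantaneous_binding")]
  if (!is.null(fixture$noise))
    cfg$noise <- list(phi = fixture$noise$phi,
                      sigma = fixture$noise$sigma,
                      target_sd = fixture$noise$target_sd)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_scheme_config
#' @export
read_scheme_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  req <- c("states", "transitions", "open_states", "rates", "unitary")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop("malformed scheme config: missing key(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  tr <- dplyr::bind_rows(lapply(cfg$transitions, tibble::as_tibble))
  scheme <- kinetic_scheme(
    states = unlist(cfg$states),
    transitions = tr,
    open_states = unlist(cfg$open_states),
    liganded_state = cfg$liganded_state)
  params <- channel_params(unlist(cfg$rates), unlist(cfg$unitary),
                           nch_mean = cfg$nch_mean %||% 250,
                           nch_sd = cfg$nch_sd %||% 0)
  out <- list(scheme = scheme, params = params)
  if (!is.null(cfg$protocol))
    out$protocol <- do.call(protocol, cfg$protocol)
  if (!is.null(cfg$noise))
    out$noise <- noise_model(unlist(cfg$noise$phi), unlist(cfg$noise$sigma),
                             target_sd = cfg$noise$target_sd)
  out
}

#' Write / read a trace set as CSV
#'
#' Plain-text interchange: first column `time_ms`, one column per trace
#' (pA).  The grid offset and interval are recovered from the time column.
#'
#' @param ts A [trace_set()].
#' @param path File path.
#' @return `path` (write) or a [trace_set()] (read).
#' @export
write_traces_csv <- function(ts, path) {
  df <- data.frame(time_ms = trace_times(ts), ts$currents)
  names(df) <- c("time_ms", paste0("trace", seq_len(ncol(ts$currents))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path)
  if (names(df)[1] != "time_ms")
    stop("malformed trace CSV: first column must be time_ms", call. = FALSE)
  tt <- df[[1]]
  trace_set(as.matrix(df[, -1, drop = FALSE]),
            dt = if (length(tt) > 1) tt[2] - tt[1] else 1, t0 = tt[1])
}

#' Write an analysis report as JSON
#'
#' Serialises a result object (fit, accuracy report, PS NSFA fit, ...)
#' together with provenance: package version, seed and a hash of the
#' configuration.
#'
#' @param x Result object with a `tidy()` method, or a plain list.
#' @param path Output path.
#' @param seed Seed used to produce the result.
#' @param config Configuration list included (and hashed) for provenance.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, seed = NULL, config = NULL) {
  body <- if (is.list(x) && !is.object(x)) x else
    list(class = class(x)[1], estimates = tidy(x))
  rep <- list(package = "mlnsfa",
              version = as.character(utils::packageVersion("mlnsfa")),
              seed = seed,
              config_hash = if (!is.null(config))
                sum(utf8ToInt(paste(deparse(config), collapse = ""))) else NULL,
              config = config,
              result = body)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
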