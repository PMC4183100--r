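#' Sample per-trial channel numbers
#'
#' Trial-to-trial quantal variability: rounded Gaussian draws, truncated from
#' below at 1.
#'
#' @param mean,sd Gaussian mean and SD of the channel-number distribution.
#' @param n Number of trials.
#' @return Integer vector of length `n`.
#' @export
sample_channel_numbers <- function(mean, sd, n) {
  pmax(1L, as.integer(round(stats::rnorm(n, mean, sd))))
}

#' A set of macroscopic current traces
#'
#' Container for simulated (or recorded) macroscopic currents on the analysis
#' grid.  Currents are stored as a time x trace matrix in pA; `t0` is the
#' offset of the first sample after the end of the agonist pulse.
#'
#' @param currents Numeric matrix, time points in rows, traces in columns.
#' @param dt Sampling interval (ms).
#' @param t0 Time of the first sample (ms after pulse end).
#' @param nch_true Optional per-trace true channel numbers.
#' @param seed Optional seed recorded for provenance.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(currents, dt, t0 = 0, nch_true = NULL, seed = NULL) {
  currents <- as.matrix(currents)
  stopifnot(dt > 0, ncol(currents) >= 1)
  if (!is.null(nch_true)) stopifnot(length(nch_true) == ncol(currents))
  structure(list(currents = currents, dt = dt, t0 = t0,
                 nch_true = nch_true, seed = seed),
            class = "trace_set")
}

#' @exportS3Method base::print
print.trace_set <- function(x, ...) {
  cat("<trace_set> ", ncol(x$currents), " traces x ", nrow(x$currents),
      " points, dt = ", x$dt, " ms, t0 = ", x$t0, " ms\n", sep = "")
  invisible(x)
}

#' @export
dim.trace_set <- function(x) dim(x$currents)

#' Times of a trace set's samples
#' @param ts A [trace_set()].
#' @return Numeric vector (ms after pulse end).
#' @export
trace_times <- function(ts) ts$t0 + (seq_len(nrow(ts$currents)) - 1) * ts$dt

#' @importFrom tibble as_tibble
#' @export
as_tibble.trace_set <- function(x, ...) {
  tt <- trace_times(x)
  tibble::tibble(
    trace = rep(seq_len(ncol(x$currents)), each = nrow(x$currents)),
    time = rep(tt, ncol(x$currents)),
    current = as.vector(x$currents))
}

#' Subset traces of a trace set
#' @param x A [trace_set()]; `i` trace indices.
#' @param i Trace indices to keep (with repetition allowed, e.g. bootstrap
#'   resampling).
#' @param ... Unused.
#' @export
`[.trace_set` <- function(x, i, ...) {
  out <- trace_set(x$currents[, i, drop = FALSE], dt = x$dt, t0 = x$t0,
                   nch_true = x$nch_true[i], seed = x$seed)
  attr(out, "stride") <- attr(x, "stride")
  out
}

#' Simulate macroscopic synaptic currents
#'
#' Each trial draws a channel number from the Gaussian quantal-variability
#' distribution and propagates aggregate state counts with multinomial
#' transitions under the discrete-time kernel `exp(Q dt)` (exact in
#' distribution at the sample times).  The trace is the unitary-current
#' weighted open-state count; coloured background noise is added if a noise
#' model is supplied.  Only the analysis window (from `analysis_start_offset`
#' after the pulse end) is returned.
#'
#' @param scheme A [kinetic_scheme()].
#' @param params A [channel_params()].
#' @param proto A [protocol()].
#' @param n_traces Number of traces.
#' @param noise A [noise_model()] or `NULL`.
#' @param rate_jitter Optional named list of relative half-widths: each listed
#'   rate is multiplied, per trace, by `runif(1 - w, 1 + w)` (receptor
#'   heterogeneity between trials).
#' @param seed Optional integer seed (applied via [withr::with_seed()]).
#' @return A [trace_set()].
#' @export
simulate_traces <- function(scheme, params, proto, n_traces,
                            noise = NULL, rate_jitter = NULL, seed = NULL) {
  run <- function() {
    nch <- sample_channel_numbers(params$nch_mean, params$nch_sd, n_traces)
    istate <- state_currents(scheme, params)
    n_steps <- round(proto$record_duration / proto$dt)
    stiff <- max(abs(diag(assemble_rate_matrix(
      scheme, params, proto$pulse_concentration))))
    if (proto$dt > 1 / stiff)
      warning("dt exceeds the fastest relaxation time 1/max|q_ii| = ",
              signif(1 / stiff, 3), " ms", call. = FALSE)
    p0 <- initial_state(scheme, params, proto)

    kern_of <- function(pp, conc) {
      K <- as.matrix(Matrix::expm(unclass(
        assemble_rate_matrix(scheme, pp, conc)) * proto$dt))
      pmax(K, 0)
    }
    if (is.null(rate_jitter)) {
      kerns <- array(kern_of(params, 0),
                     dim = c(scheme$n_states, scheme$n_states, 1))
      per_trace <- FALSE
    } else {
      kerns <- array(0, dim = c(scheme$n_states, scheme$n_states, n_traces))
      for (i in seq_len(n_traces)) {
        pp <- params
        for (r in names(rate_jitter))
          pp$rates[[r]] <- pp$rates[[r]] *
            stats::runif(1, 1 - rate_jitter[[r]], 1 + rate_jitter[[r]])
        kerns[, , i] <- kern_of(pp, 0)
      }
      per_trace <- TRUE
    }
    cur <- cpp_sim_macroscopic(kerns, as.integer(n_steps), as.numeric(p0),
                               as.integer(nch), istate, per_trace)
    if (!is.null(noise))
      cur <- cur + generate_colored_noise(noise, nrow(cur), n_traces)
    keep <- which(round(seq(0, proto$record_duration, by = proto$dt), 10) >=
                    proto$analysis_start_offset)
    trace_set(cur[keep, , drop = FALSE], dt = proto$dt,
              t0 = proto$analysis_start_offset, nch_true = nch, seed = seed)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Trim a trace set to an analysis window
#'
#' Keeps samples with times in `[t_start, t_end]` (ms after pulse end), e.g.
#' to move from the full recorded response (used for amplitude/decay
#' statistics and peak scaling) to the decaying-phase window used for
#' likelihood inference.
#' @param ts A [trace_set()].
#' @param t_start New first-sample time (ms).
#' @param t_end Last time retained (ms).
#' @return A [trace_set()].
#' @export
trim_traces <- function(ts, t_start, t_end = Inf) {
  tt <- trace_times(ts)
  keep <- which(tt >= t_start - 1e-9 & tt <= t_end + 1e-9)
  out <- trace_set(ts$currents[keep, , drop = FALSE], dt = ts$dt,
                   t0 = tt[keep[1]], nch_true = ts$nch_true,
                   seed = ts$seed)
  attr(out, "stride") <- attr(ts, "stride")
  out
}

#' Thin a trace set to a coarser uniform grid
#'
#' Keeps every `stride`-th sample.  Useful when the likelihood grid can be
#' coarser than the acquisition grid without losing kinetic information.
#' @param ts A [trace_set()].
#' @param stride Positive integer subsampling stride.
#' @return A [trace_set()]; the acquisition stride is recorded in attribute
#'   `stride` so noise models can be adjusted.
#' @export
thin_traces <- function(ts, stride) {
  stride <- as.integer(stride)
  stopifnot(stride >= 1)
  keep <- seq(1L, nrow(ts$currents), by = stride)
  out <- trace_set(ts$currents[keep, , drop = FALSE], dt = ts$dt * stride,
                   t0 = ts$t0, nch_true = ts$nch_true, seed = ts$seed)
  attr(out, "stride") <- stride * (attr(ts, "stride") %||% 1L)
  out
}

#' Per-trace peak amplitude and mono-exponential decay time
#'
#' The peak is the raw maximum over the analysis window (no smoothing, to
#' match the peak-scaling convention).  The decay time is the time constant
#' of a least-squares mono-exponential `A exp(-t / tau)` fitted from the
#' trace's peak over `fit_span` milliseconds, with the amplitude profiled
#' out.  The decay of these schemes is multi-exponential (fast
#' desensitisation, slow resensitisation-limited deactivation); a single
#' time constant only summarises its first e-fold or so, so by default the
#' fit spans the 50 ms after the peak rather than the whole record.
#'
#' @param ts A [trace_set()].
#' @param fit_span Length (ms) of the decay segment fitted, measured from
#'   each trace's peak; `Inf` fits to the end of the window.
#' @return A tibble with one row per trace: `trace`, `peak` (pA), `t_peak`
#'   (ms), `decay_tau` (ms).
#' @export
trace_statistics <- function(ts, fit_span = 50) {
  tt <- trace_times(ts)
  stats <- purrr::map_dfr(seq_len(ncol(ts$currents)), function(i) {
    y <- ts$currents[, i]
    ipk <- which.max(y)
    iend <- max(which(tt <= tt[ipk] + fit_span))
    tf <- tt[ipk:iend] - tt[ipk]
    yf <- y[ipk:iend]
    sse <- function(tau) {
      b <- exp(-tf / tau)
      A <- sum(yf * b) / sum(b * b)
      sum((yf - A * b)^2)
    }
    tau <- if (length(tf) < 3 || all(yf == 0)) NA_real_ else
      stats::optimize(sse, c(ts$dt / 2, 50 * max(tt)))$minimum
    tibble::tibble(trace = i, peak = y[ipk], t_peak = tt[ipk],
                   decay_tau = tau)
  })
  stats
}

#' Ensemble summary of trace statistics
#'
#' @param ts A [trace_set()].
#' @param fit_span Decay-fit span (ms), see [trace_statistics()].
#' @return One-row tibble with ensemble mean and SD of the per-trace peak and
#'   decay time.
#' @export
ensemble_statistics <- function(ts, fit_span = 50) {
  st <- trace_statistics(ts, fit_span = fit_span)
  tibble::tibble(
    n = nrow(st),
    peak_mean = mean(st$peak), peak_sd = stats::sd(st$peak),
    decay_mean = mean(st$decay_tau, na.rm = TRUE),
    decay_sd = stats::sd(st$decay_tau, na.rm = TRUE))
}

#' Plot a trace set
#'
#' @param object A [trace_set()].
#' @param n_max Maximum number of traces drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trace_set <- function(object, n_max = 30, ...) {
  idx <- seq_len(min(ncol(object$currents), n_max))
  df <- as_tibble(object[idx])
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$current,
                                   group = .data$trace)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::labs(x = "time after pulse (ms)", y = "current (pA)")
}
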