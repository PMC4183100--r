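#' Univariate-update slice sampler
#'
#' Coordinate-wise slice sampling with stepping-out and shrinkage, targeting
#' an arbitrary (unnormalised) log density.  Used here to sample parameter
#' likelihood surfaces, which are typically skewed for single traces, so
#' posterior means rather than modes are reported.
#'
#' @param logf Function taking a parameter vector and returning the log
#'   density (may return `-Inf`).
#' @param x0 Numeric start vector.
#' @param n_samples Number of samples to draw (after the start point).
#' @param w Step-out widths (scalar or per-coordinate).
#' @param max_steps Maximum step-out expansions per side.
#' @return Matrix `n_samples` x `length(x0)` of samples.
#' @export
slice_sampler <- function(logf, x0, n_samples, w = 1, max_steps = 20) {
  d <- length(x0)
  w <- rep_len(w, d)
  out <- matrix(NA_real_, n_samples, d)
  x <- x0
  fx <- logf(x)
  if (!is.finite(fx)) stop("log density not finite at the start point",
                           call. = FALSE)
  for (s in seq_len(n_samples)) {
    for (j in seq_len(d)) {
      z <- fx - stats::rexp(1)
      lo <- x[j] - stats::runif(1) * w[j]
      hi <- lo + w[j]
      f_at <- function(v) { xx <- x; xx[j] <- v; logf(xx) }
      k <- max_steps
      while (k > 0 && f_at(lo) > z) { lo <- lo - w[j]; k <- k - 1 }
      k <- max_steps
      while (k > 0 && f_at(hi) > z) { hi <- hi + w[j]; k <- k - 1 }
      repeat {
        v <- stats::runif(1, lo, hi)
        fv <- f_at(v)
        if (fv > z) { x[j] <- v; fx <- fv; break }
        if (v < x[j]) lo <- v else hi <- v
        if (hi - lo < 1e-12) { break }  # pathological shrinkage
      }
    }
    out[s, ] <- x
  }
  out
}

#' Slice-sampling MCMC over a single-trace likelihood
#'
#' Samples the noise-corrected likelihood of one macroscopic current as a
#' distribution over the free parameters (in log space), with the per-trace
#' channel number profiled out by its closed-form estimate at every
#' parameter point.  The single-trace likelihood is typically right-skewed
#' in the unitary current, so its mean is the recommended point summary.
#'
#' @param trace Numeric vector (one current on the analysis grid) or a
#'   one-trace [trace_set()].
#' @param scheme A [kinetic_scheme()].
#' @param params_ref A [channel_params()]: start point and non-sampled
#'   parameters.
#' @param noise A [noise_model()] or `NULL`.
#' @param free Parameter names to sample (default: unitary currents plus the
#'   doubly-liganded gating rates for the 7-state scheme, all
#'   concentration-independent rates otherwise).
#' @param times Grid times (required for vector input).
#' @param n_samples Chain length (excluding burn-in).
#' @param burn_in Fraction of the chain discarded.
#' @param w Slice step width in log-parameter space.
#' @param stride Point stride applied to the grid before evaluating the
#'   likelihood (the chain is over one trace; a coarser grid loses little
#'   information and speeds the chain up).
#' @param seed Integer seed.
#' @return Tibble of post-burn-in samples (one column per free parameter,
#'   plus the profiled `nch`).
#' @export
slice_sample_trace <- function(trace, scheme, params_ref, noise = NULL,
                               free = NULL, times = NULL, n_samples = 1000,
                               burn_in = 0.2, w = 0.4, stride = 1L,
                               seed = 1L) {
  stride0 <- 1L
  if (inherits(trace, "trace_set")) {
    stride0 <- attr(trace, "stride") %||% 1L
    times <- trace_times(trace)
    trace <- trace$currents[, 1]
  }
  if (is.null(times)) stop("`times` required for vector input", call. = FALSE)
  idx <- seq(1L, length(times), by = stride)
  trace <- trace[idx]; times <- times[idx]
  stride <- stride * stride0                  # acquisition-sample stride
  free <- free %||% default_free_parameters(scheme)
  p0 <- as.numeric(scheme$states == scheme$liganded_state)
  theta0 <- .theta_get(params_ref, free)
  cur <- matrix(trace, ncol = 1)
  nch_last <- NA_real_
  logf <- function(ltheta) {
    par <- .theta_set(params_ref, free, exp(ltheta))
    res <- tryCatch(
      nsfa_loglik(cur, scheme, par, noise = noise, p0 = p0, times = times,
                  stride = stride),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$loglik) ||
        abs(res$loglik) > 1e12) return(-Inf)
    nch_last <<- res$per_trace_nch[1]
    res$loglik
  }
  n_total <- ceiling(n_samples / (1 - burn_in))
  run <- function() {
    raw <- matrix(NA_real_, n_total, length(free))
    nchv <- numeric(n_total)
    x <- log(theta0)
    for (s in seq_len(n_total)) {
      # one sweep at a time so the profiled channel number of the accepted
      # point (the last accepted evaluation in the sweep) can be recorded
      x <- slice_sampler(logf, x, 1, w = w)[1, ]
      raw[s, ] <- x
      nchv[s] <- nch_last
    }
    keep <- seq(n_total - n_samples + 1L, n_total)
    samp <- exp(raw[keep, , drop = FALSE])
    colnames(samp) <- free
    moved <- apply(raw[keep, , drop = FALSE], 2, stats::sd)
    if (any(moved < 1e-10))
      warning("slice chain appears stuck in coordinate(s) ",
              paste(free[moved < 1e-10], collapse = ", "),
              " (zero post-burn-in movement); consider a different step ",
              "width `w` or start point", call. = FALSE)
    smp <- tibble::as_tibble(samp)
    smp$nch <- nchv[keep]
    smp
  }
  withr::with_seed(seed, run())
}
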