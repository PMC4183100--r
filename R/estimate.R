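#' Default free parameters of a scheme
#'
#' All concentration-independent rate constants plus one unitary current per
#' conductance class (`i1`, `i2`, ...).  Ligand-order-1 rates are excluded:
#' with the instantaneous-binding initial condition the post-pulse
#' concentration is zero, so binding rates never enter the likelihood.
#'
#' @param scheme A [kinetic_scheme()].
#' @return Character vector of parameter names.
#' @export
default_free_parameters <- function(scheme) {
  tr <- scheme$transitions
  c(unique(tr$rate[tr$ligand_order == 0]),
    paste0("i", seq_len(max(scheme$n_classes, 1))))
}

.theta_get <- function(params, names) {
  vapply(names, function(nm) {
    if (grepl("^i[0-9]+$", nm)) {
      params$unitary[as.integer(sub("^i", "", nm))]
    } else params$rates[[nm]]
  }, numeric(1))
}

.theta_set <- function(params, names, values) {
  for (k in seq_along(names)) {
    nm <- names[k]
    if (grepl("^i[0-9]+$", nm)) {
      params$unitary[as.integer(sub("^i", "", nm))] <- values[k]
    } else params$rates[[nm]] <- values[k]
  }
  params
}

#' Configuration of the graduated maximum-likelihood fit
#'
#' Initial points are drawn log-uniformly in
#' `[theta_ref / init_range_factor, theta_ref * init_range_factor]` and the
#' search is bounded within `[theta_ref / bound_factor, theta_ref *
#' bound_factor]`.  The minimisation is graduated: the first stage uses a few
#' traces sampled at few points, and each following stage doubles both until
#' the full data set is used, warm-starting from the previous optimum.
#'
#' @param free_parameters Parameter names to fit (default: all
#'   concentration-independent rates plus the unitary currents).
#' @param init_range_factor,bound_factor Multiplicative ranges around the
#'   reference values.
#' @param n_restarts Number of optimisation restarts; the first starts at
#'   `theta_ref`, the rest at random initial points.
#' @param schedule Optional list of `c(n_traces, n_points)` stages; built
#'   automatically when `NULL`.
#' @param maxit Iteration cap per stage for the bounded quasi-Newton
#'   (L-BFGS-B) minimiser.
#' @param factr Relative-tolerance control of L-BFGS-B.
#' @param window_frac Peak fraction ending the channel-number window.
#' @param nch_noise_sub Use the noise-subtracted channel-number profile
#'   (see [nsfa_loglik()]) when updating the per-trace channel numbers
#'   between stages; the default keeps the closed-form estimator as printed.
#' @param seed Integer seed making the whole fit deterministic.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(free_parameters = NULL, init_range_factor = 10,
                       bound_factor = 50, n_restarts = 5, schedule = NULL,
                       maxit = 500, factr = 4.5e7, window_frac = 0.3,
                       nch_noise_sub = FALSE, seed = 1L) {
  stopifnot(bound_factor >= init_range_factor, n_restarts >= 1)
  structure(list(free_parameters = free_parameters,
                 init_range_factor = init_range_factor,
                 bound_factor = bound_factor,
                 n_restarts = n_restarts, schedule = schedule,
                 maxit = maxit, factr = factr,
                 window_frac = window_frac,
                 nch_noise_sub = nch_noise_sub,
                 seed = as.integer(seed)),
            class = "fit_config")
}

.build_schedule <- function(n_traces, n_points) {
  stages <- list()
  nt <- min(3L, n_traces); np <- min(50L, n_points)
  repeat {
    stages[[length(stages) + 1L]] <- c(nt, np)
    if (nt >= n_traces && np >= n_points) break
    nt <- min(nt * 2L, n_traces); np <- min(np * 2L, n_points)
  }
  stages
}

.stage_grid <- function(n_points, np) {
  stride <- max(1L, floor(n_points / np))
  seq(1L, n_points, by = stride)
}

#' Graduated multi-start maximum-likelihood fit
#'
#' Maximises the noise-corrected log-likelihood over the free parameters in
#' log space with a bounded quasi-Newton minimiser, using a graduated
#' schedule (growing numbers of traces and sample points, warm starts) and
#' multiple restarts.  `theta_ref` centres the initial-value and bound
#' ranges: in simulation studies it is the generating parameter vector; for
#' real data the user supplies a plausible reference.
#'
#' @param traces A [trace_set()].
#' @param scheme A [kinetic_scheme()].
#' @param params_ref A [channel_params()] providing `theta_ref` and all
#'   non-fitted parameters.
#' @param noise A [noise_model()] or `NULL`.
#' @param config A [fit_config()].
#' @return An object of class `ml_fit`.
#' @export
ml_fit <- function(traces, scheme, params_ref, noise = NULL,
                   config = fit_config()) {
  stopifnot(inherits(traces, "trace_set"), ncol(traces$currents) >= 2)
  free <- config$free_parameters %||% default_free_parameters(scheme)
  theta_ref <- .theta_get(params_ref, free)
  lo <- log(theta_ref / config$bound_factor)
  hi <- log(theta_ref * config$bound_factor)
  p0 <- as.numeric(scheme$states == scheme$liganded_state)
  nt_all <- ncol(traces$currents); np_all <- nrow(traces$currents)
  schedule <- config$schedule %||% .build_schedule(nt_all, np_all)
  times_all <- trace_times(traces)

  nch_bounds <- c(params_ref$nch_mean / config$bound_factor,
                  params_ref$nch_mean * config$bound_factor)
  stride0 <- attr(traces, "stride") %||% 1L     # acquisition-grid stride
  # closed-form per-trace channel numbers at a parameter point (full grid)
  profile_nch <- function(ltheta) {
    par <- .theta_set(params_ref, free, exp(ltheta))
    tryCatch(
      nsfa_loglik(traces$currents, scheme, par, noise = noise, p0 = p0,
                  times = times_all, window_frac = config$window_frac,
                  stride = stride0, nch_bounds = nch_bounds,
                  nch_noise_sub = config$nch_noise_sub)$per_trace_nch,
      error = function(e) NULL)
  }
  # the channel numbers are estimated first and held fixed while the
  # rate/current parameters are optimised (re-profiling N_chi inside the
  # objective admits a degenerate many-channels/low-P(open) ridge)
  objective <- function(ltheta, cur, times, stride, nch) {
    par <- .theta_set(params_ref, free, exp(ltheta))
    ll <- tryCatch(
      nsfa_loglik(cur, scheme, par, noise = noise, p0 = p0, times = times,
                  window_frac = config$window_frac,
                  stride = stride * stride0, nch = nch)$loglik,
      error = function(e) NA_real_)
    # implausibly large magnitudes signal numerical breakdown, not fit quality
    if (!is.finite(ll) || abs(ll) > 1e12) 1e12 else -ll
  }
  # channel numbers are estimated once, at the reference parameter point,
  # and shared by every restart; the reported per-trace numbers are
  # re-evaluated at the optimum
  nch_ref <- profile_nch(log(theta_ref))
  if (is.null(nch_ref))
    stop("channel-number profiling failed at the reference parameters",
         call. = FALSE)

  run <- function() {
    restart_ll <- numeric(config$n_restarts)
    restart_conv <- logical(config$n_restarts)
    best <- NULL
    for (r in seq_len(config$n_restarts)) {
      start <- if (r == 1) log(theta_ref) else
        stats::runif(length(free),
                     log(theta_ref / config$init_range_factor),
                     log(theta_ref * config$init_range_factor))
      cur <- pmin(pmax(start, lo), hi)
      nch_cur <- nch_ref
      obj_full <- objective(cur, traces$currents, times_all, 1L, nch_cur)
      conv <- TRUE
      for (st in schedule) {
        idx_tr <- seq_len(st[1])
        idx_tp <- .stage_grid(np_all, st[2])
        stride <- if (length(idx_tp) > 1) diff(idx_tp[1:2]) else 1L
        opt <- stats::optim(cur, objective, method = "L-BFGS-B",
                            lower = lo, upper = hi,
                            cur = traces$currents[idx_tp, idx_tr,
                                                  drop = FALSE],
                            times = times_all[idx_tp], stride = stride,
                            nch = nch_cur[idx_tr],
                            control = list(maxit = config$maxit,
                                           factr = config$factr))
        conv <- conv && (opt$convergence == 0)
        # monotone safeguard: accept the stage optimum only if it improves
        # the full-data objective (coarse stages can wander)
        cand_full <- objective(opt$par, traces$currents, times_all, 1L,
                               nch_cur)
        if (cand_full <= obj_full) {
          cur <- opt$par
          obj_full <- cand_full
        }
      }
      ll_full <- -obj_full
      restart_ll[r] <- ll_full
      restart_conv[r] <- conv
      if (is.null(best) || ll_full > best$ll)
        best <- list(par = cur, ll = ll_full, conv = conv)
    }
    params_ml <- .theta_set(params_ref, free, exp(best$par))
    final <- nsfa_loglik(traces, scheme, params_ml, noise = noise, p0 = p0,
                         window_frac = config$window_frac, stride = stride0,
                         nch_bounds = nch_bounds)
    grid_po <- seq(0, max(times_all), by = traces$dt)
    po <- peak_open_probability(scheme, params_ml, p0, grid_po)
    structure(list(params = params_ml, free = free,
                   theta = stats::setNames(exp(best$par), free),
                   theta_ref = stats::setNames(theta_ref, free),
                   loglik = best$ll,
                   per_trace_nch = final$per_trace_nch,
                   nch_mean = mean(final$per_trace_nch),
                   p_open_peak = po,
                   restart_logliks = restart_ll,
                   converged = any(restart_conv[restart_ll == max(restart_ll)]),
                   config = config, scheme = scheme),
              class = "ml_fit")
  }
  withr::with_seed(config$seed, run())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.ml_fit <- function(x, ...) {
  cat("<ml_fit> logL = ", format(x$loglik, digits = 8),
      if (!x$converged) "  (not converged)", "\n", sep = "")
  cat("  ", paste(sprintf("%s = %.4g", names(x$theta), x$theta),
                  collapse = ", "), "\n", sep = "")
  cat("  mean N_ch = ", round(x$nch_mean, 1), ", P(o,peak) = ",
      signif(x$p_open_peak, 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ml_fit <- function(x, ...) {
  tibble::tibble(term = c(names(x$theta), "nch", "p_open_peak"),
                 estimate = c(unname(x$theta), x$nch_mean, x$p_open_peak),
                 reference = c(unname(x$theta_ref), NA_real_, NA_real_))
}

#' @export
glance.ml_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, nch_mean = x$nch_mean,
                 p_open_peak = x$p_open_peak,
                 n_restarts = length(x$restart_logliks),
                 converged = x$converged)
}

#' Bootstrap accuracy of the maximum-likelihood estimates
#'
#' Resamples `n_traces` currents with replacement from a generated pool,
#' runs the graduated fit on each bootstrap sample, and summarises the
#' deviation of each parameter estimate from its generating value as the
#' relative error: root-mean-square deviation divided by the true value, in
#' percent.
#'
#' @param pool A [trace_set()] pool of simulated currents.
#' @param n_traces Sample size per bootstrap replicate.
#' @param n_bootstrap Number of replicates.
#' @param scheme,params_ref,noise,config As in [ml_fit()] (`params_ref` is
#'   the generating parameter vector).
#' @return An object of class `accuracy_report` with per-replicate estimates
#'   and the relative-error table.
#' @export
bootstrap_accuracy <- function(pool, n_traces, n_bootstrap, scheme,
                               params_ref, noise = NULL,
                               config = fit_config()) {
  p0 <- as.numeric(scheme$states == scheme$liganded_state)
  grid_po <- seq(0, max(trace_times(pool)), by = pool$dt)
  true <- c(.theta_get(params_ref,
                       config$free_parameters %||%
                         default_free_parameters(scheme)),
            nch = params_ref$nch_mean,
            p_open_peak = peak_open_probability(scheme, params_ref, p0,
                                                grid_po))
  run <- function() {
    reps <- purrr::map_dfr(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(ncol(pool$currents), n_traces, replace = TRUE)
      cfg <- config; cfg$seed <- config$seed + 1000L * b
      fit <- ml_fit(pool[idx], scheme, params_ref, noise = noise,
                    config = cfg)
      dplyr::mutate(tidy(fit), replicate = b)
    })
    reps
  }
  reps <- withr::with_seed(config$seed, run())
  errors <- reps |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(mean = mean(.data$estimate),
                     sd = stats::sd(.data$estimate),
                     se = stats::sd(.data$estimate) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(true = unname(true[.data$term]))
  errors$rel_error_pct <- vapply(seq_len(nrow(errors)), function(k) {
    est <- reps$estimate[reps$term == errors$term[k]]
    100 * sqrt(mean((est - errors$true[k])^2)) / errors$true[k]
  }, numeric(1))
  structure(list(replicates = reps, errors = errors,
                 n_traces = n_traces, n_bootstrap = n_bootstrap),
            class = "accuracy_report")
}

#' @exportS3Method base::print
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report> ", x$n_bootstrap, " bootstrap samples of ",
      x$n_traces, " traces\n", sep = "")
  print(as.data.frame(x$errors), digits = 3)
  invisible(x)
}

#' @export
tidy.accuracy_report <- function(x, ...) x$errors

#' @export
glance.accuracy_report <- function(x, ...) {
  tibble::tibble(n_traces = x$n_traces, n_bootstrap = x$n_bootstrap)
}

#' Plot bootstrap estimate distributions
#' @param object An `accuracy_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accuracy_report <- function(object, ...) {
  df <- dplyr::left_join(object$replicates,
                         object$errors[, c("term", "true")], by = "term")
  ggplot2::ggplot(df, ggplot2::aes(.data$term, .data$estimate)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point(ggplot2::aes(y = .data$true), colour = "green4",
                        shape = 3, size = 3) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = NULL, y = "estimate")
}

#' Compare parameter estimates between two conditions
#'
#' For every parameter estimated in both reports, computes the relative
#' difference of the bootstrap means, `Delta = 100 |mean_a - mean_b| /
#' mean_a` (percent), together with the per-condition estimate scatter
#' (replicate SD, in percent of `mean_a` — the scale on which single
#' estimates from the two conditions differ).  A parameter is flagged as
#' changed when `Delta` exceeds twice the combined scatter — the standard
#' two-sample criterion at roughly 2 sigma.
#'
#' @param report_a,report_b `accuracy_report` objects (condition A is the
#'   reference).
#' @return Tibble with `term`, `delta_pct`, `sd_a_pct`, `sd_b_pct`,
#'   `changed`.
#' @export
compare_models <- function(report_a, report_b) {
  ea <- report_a$errors; eb <- report_b$errors
  shared <- intersect(ea$term, eb$term)
  purrr::map_dfr(shared, function(tm) {
    a <- ea[ea$term == tm, ]; b <- eb[eb$term == tm, ]
    delta <- 100 * abs(a$mean - b$mean) / a$mean
    sd_a <- 100 * a$sd / a$mean
    sd_b <- 100 * b$sd / a$mean
    tibble::tibble(term = tm, delta_pct = delta, sd_a_pct = sd_a,
                   sd_b_pct = sd_b,
                   changed = delta > 2 * sqrt(sd_a^2 + sd_b^2))
  })
}
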