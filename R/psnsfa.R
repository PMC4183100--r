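#' Peak-scaled difference traces
#'
#' Scales the ensemble mean waveform to each trace's peak amplitude and
#' subtracts: `d_i = I_i - <I> max(I_i) / max(<I>)`.  The scaling removes the
#' variance contributed by trial-to-trial (quantal) amplitude variability,
#' leaving fluctuations attributable to stochastic channel gating.  Peaks are
#' raw maxima over the analysis window (no smoothing).
#'
#' @param ts A [trace_set()] or numeric matrix (grid x traces).
#' @return List with `diffs` (matrix of scaled differences), `mean_current`
#'   (ensemble mean vector) and `scale` (per-trace scale factors).
#' @export
peak_scale <- function(ts) {
  cur <- if (inherits(ts, "trace_set")) ts$currents else as.matrix(ts)
  m <- rowMeans(cur)
  pk <- apply(cur, 2, max)
  scale <- pk / max(m)
  diffs <- cur - outer(m, scale)
  list(diffs = diffs, mean_current = m, scale = scale)
}

#' Peak-scaled non-stationary fluctuation analysis
#'
#' Builds the per-timepoint ensemble variance of the peak-scaled differences
#' against the ensemble mean current and fits the rising limb of that
#' variance-mean relation with the parabola
#' `sigma^2 = i_ch <I> - <I>^2 / N_ch + sigma0^2`
#' by weighted least squares.  Weights are `1 / var(sigma^2_t)` with
#' `var(sigma^2) = 2 sigma^4 / (N - 1)` evaluated at the model-predicted
#' variance and refined by iterative reweighting: weights taken from the raw
#' (or locally smoothed) empirical curve systematically chase downward
#' fluctuations and bias the fit at the ensemble sizes this method is used
#' with.  The rising limb is every mean-current value up to the mean current
#' at which the smoothed variance-mean curve attains its maximum.
#'
#' When the background-noise SD is known (simulations; baseline estimates
#' for recordings) pass `noise_sd`: the noise floor `sigma0^2` is then fixed
#' rather than fitted, which conditions the parabola markedly better.
#'
#' @param ts A [trace_set()] or numeric matrix (grid x traces).
#' @param noise_sd Optional known background-noise SD (pA); fixes
#'   `sigma0^2 = noise_sd^2`.
#' @param smooth_k Width (points) of the running-mean smoother used only to
#'   locate the variance maximum.
#' @param peak_smooth Width (points) of the box smoother applied to each
#'   trace before reading off its peak amplitude for scaling (1 = raw max).
#' @return An object of class `psnsfa_fit` with elements `i_ch` (pA), `nch`,
#'   `sigma0_sq` (pA^2), `vcov` (fit covariance on the parabola
#'   coefficients), and `curve` (tibble of the variance-mean points with the
#'   fitted mask).
#' @export
psnsfa_fit <- function(ts, noise_sd = NULL, smooth_k = 25, peak_smooth = 5) {
  cur <- if (inherits(ts, "trace_set")) ts$currents else as.matrix(ts)
  n <- ncol(cur)
  if (n < 3) stop("need at least 3 traces", call. = FALSE)
  m <- rowMeans(cur)
  pk <- if (peak_smooth > 1) {
    sm <- apply(cur, 2, function(y)
      as.vector(stats::filter(y, rep(1 / peak_smooth, peak_smooth),
                              sides = 2)))
    apply(sm, 2, max, na.rm = TRUE)
  } else apply(cur, 2, max)
  d <- cur - outer(m, pk / max(m))
  v <- rowSums(d^2) / (n - 1)                 # variance about the scaled mean
  if (all(v == 0)) stop("degenerate input: zero variance", call. = FALSE)
  # rising limb: points with <I> below the smoothed variance maximum
  ord <- order(m)
  vs_s <- v
  vs_s[ord] <- as.vector(stats::filter(v[ord], rep(1 / smooth_k, smooth_k),
                                       sides = 2))
  vs_s[is.na(vs_s)] <- v[is.na(vs_s)]
  imax <- which.max(vs_s[ord])
  if (is.na(imax) || !length(imax)) imax <- which.max(v[ord])
  mask <- m <= m[ord][imax]
  if (sum(mask) < 4) mask <- rep(TRUE, length(m))

  s0_fixed <- !is.null(noise_sd)
  s0 <- if (s0_fixed) noise_sd^2 else 0
  vfloor <- max(1e-6 * max(v), 0.05 * s0)
  if (s0_fixed) {
    y <- v - s0
    fit <- stats::lm(y ~ 0 + m + I(m^2), subset = mask)
    for (it in 1:3) {
      pred <- pmax(stats::coef(fit)[1] * m + stats::coef(fit)[2] * m^2, 0) + s0
      w <- (n - 1) / (2 * pmax(pred, vfloor)^2)
      fit <- stats::lm(y ~ 0 + m + I(m^2), weights = w, subset = mask)
    }
    cf <- stats::coef(fit)
    out_s0 <- s0
    curv <- unname(cf["I(m^2)"])
    i_ch <- unname(cf["m"])
  } else {
    fit <- stats::lm(v ~ m + I(m^2), subset = mask)
    for (it in 1:3) {
      cf <- stats::coef(fit)
      pred <- pmax(cf["(Intercept)"] + cf["m"] * m + cf["I(m^2)"] * m^2,
                   vfloor)
      w <- (n - 1) / (2 * pred^2)
      fit <- stats::lm(v ~ m + I(m^2), weights = w, subset = mask)
    }
    cf <- stats::coef(fit)
    out_s0 <- unname(cf["(Intercept)"])
    curv <- unname(cf["I(m^2)"])
    i_ch <- unname(cf["m"])
  }
  w_all <- rep(NA_real_, length(m))
  w_all[mask] <- stats::weights(fit) %||% 1
  structure(list(i_ch = i_ch,
                 nch = -1 / curv,
                 sigma0_sq = out_s0,
                 sigma0_fixed = s0_fixed,
                 vcov = stats::vcov(fit),
                 curve = tibble::tibble(mean_current = m, variance = v,
                                        weight = w_all, rising = mask),
                 n_traces = n),
            class = "psnsfa_fit")
}

#' @exportS3Method base::print
print.psnsfa_fit <- function(x, ...) {
  cat("<psnsfa_fit> (", x$n_traces, " traces)\n",
      "  i_ch = ", signif(x$i_ch, 4), " pA;  N_ch = ", signif(x$nch, 4),
      ";  sigma0^2 = ", signif(x$sigma0_sq, 4), " pA^2\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.psnsfa_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  s0_se <- if ("(Intercept)" %in% names(se)) se[["(Intercept)"]] else NA_real_
  tibble::tibble(
    term = c("i_ch", "nch", "sigma0_sq"),
    estimate = c(x$i_ch, x$nch, x$sigma0_sq),
    std.error = c(se[["m"]],
                  abs(x$nch^2 * se[["I(m^2)"]]),  # delta method for -1/beta2
                  s0_se))
}

#' @export
glance.psnsfa_fit <- function(x, ...) {
  tibble::tibble(i_ch = x$i_ch, nch = x$nch, sigma0_sq = x$sigma0_sq,
                 n_traces = x$n_traces, n_points = nrow(x$curve),
                 n_rising = sum(x$curve$rising))
}

#' Variance-mean plot of a peak-scaled NSFA fit
#' @param object A `psnsfa_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psnsfa_fit <- function(object, ...) {
  cv <- object$curve
  grid <- tibble::tibble(
    mean_current = seq(0, max(cv$mean_current), length.out = 200))
  grid$variance <- object$sigma0_sq + object$i_ch * grid$mean_current -
    grid$mean_current^2 / object$nch
  ggplot2::ggplot(cv, ggplot2::aes(.data$mean_current, .data$variance)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$rising), size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "mean current (pA)",
                  y = expression(variance ~ (pA^2)))
}
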