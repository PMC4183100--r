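#' Define a kinetic scheme for a ligand-gated channel
#'
#' A kinetic scheme is the topology of an aggregated Markov model: its states,
#' the allowed directed transitions with named rate constants, and the map from
#' open states to conductance classes.  Rates themselves live in a separate
#' parameter vector (see [channel_params()]) so that one scheme can be fitted
#' or simulated under many parameterisations.
#'
#' @param states Character vector of state labels.
#' @param transitions Data frame with columns `from`, `to`, `rate`
#'   (rate-constant name) and `ligand_order` (0 for concentration-independent
#'   rates, 1 for rates multiplied by the agonist concentration in mM).  An
#'   optional `multiplier` column carries fixed statistical factors (e.g. a
#'   doubly-liganded state unbinds at twice the single-site rate), so one
#'   rate constant can parameterise several transitions.
#' @param open_states Named integer vector mapping open-state labels to
#'   conductance-class indices (1-based).  States not listed are closed.
#' @param liganded_state Label of the state into which channels are driven by a
#'   saturating agonist pulse under the instantaneous-binding idealisation.
#'
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(states, transitions, open_states,
                           liganded_state = NULL) {
  stopifnot(is.character(states), length(states) >= 1, !anyDuplicated(states))
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  req <- c("from", "to", "rate", "ligand_order")
  if (!all(req %in% names(transitions)))
    stop("`transitions` must have columns from, to, rate, ligand_order",
         call. = FALSE)
  if (is.null(transitions$multiplier))
    transitions$multiplier <- rep(1, nrow(transitions))
  bad <- setdiff(unique(c(transitions$from, transitions$to)), states)
  if (length(bad))
    stop("transition references undeclared state(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(paste(transitions$from, transitions$to)))
    stop("duplicate directed transition", call. = FALSE)
  if (any(transitions$multiplier <= 0))
    stop("transition multipliers must be positive", call. = FALSE)
  if (any(transitions$ligand_order < 0))
    stop("ligand_order must be a non-negative integer", call. = FALSE)
  if (length(open_states)) {
    stopifnot(!is.null(names(open_states)))
    if (!all(names(open_states) %in% states))
      stop("open state not among declared states", call. = FALSE)
  }
  # connectivity of the undirected transition graph
  adj <- matrix(FALSE, length(states), length(states),
                dimnames = list(states, states))
  for (k in seq_len(nrow(transitions))) {
    adj[transitions$from[k], transitions$to[k]] <- TRUE
    adj[transitions$to[k], transitions$from[k]] <- TRUE
  }
  reach <- rep(FALSE, length(states)); reach[1] <- TRUE
  repeat {
    new <- reach | apply(adj[, reach, drop = FALSE], 1, any)
    if (identical(new, reach)) break
    reach <- new
  }
  if (!all(reach))
    stop("transition graph is not connected", call. = FALSE)
  if (!is.null(liganded_state)) stopifnot(liganded_state %in% states)
  structure(
    list(states = states,
         transitions = transitions,
         open_states = vapply(open_states, as.integer, integer(1)),
         liganded_state = liganded_state,
         n_states = length(states),
         n_open = length(open_states),
         n_classes = if (length(open_states)) max(open_states) else 0L),
    class = "kinetic_scheme")
}

#' @exportS3Method base::print
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> ", x$n_states, " states (",
      paste(x$states, collapse = ", "), ")\n", sep = "")
  cat("  open states: ",
      paste(sprintf("%s[class %d]", names(x$open_states), x$open_states),
            collapse = ", "), "\n", sep = "")
  cat("  ", nrow(x$transitions), " directed transitions\n", sep = "")
  invisible(x)
}

#' Parameter vector for a kinetic scheme
#'
#' Bundles the rate constants (ms^-1, or mM^-1 ms^-1 for ligand-order-1
#' rates), the unitary current of each conductance class (pA, positive
#' magnitudes) and the trial-to-trial channel-number distribution
#' (Gaussian mean/SD, truncated at 1 when sampled).
#'
#' @param rates Named numeric vector of positive rate constants.
#' @param unitary Numeric vector of unitary currents, one per conductance
#'   class.
#' @param nch_mean,nch_sd Mean and standard deviation of the per-trial number
#'   of liganded channels.
#' @return An object of class `channel_params`.
#' @export
channel_params <- function(rates, unitary, nch_mean = 250, nch_sd = 50) {
  stopifnot(is.numeric(rates), !is.null(names(rates)), all(rates > 0),
            is.numeric(unitary), all(is.finite(unitary)),
            nch_mean > 0, nch_sd >= 0)
  structure(list(rates = rates, unitary = unitary,
                 nch_mean = nch_mean, nch_sd = nch_sd),
            class = "channel_params")
}

#' @exportS3Method base::print
print.channel_params <- function(x, ...) {
  cat("<channel_params>\n  rates (ms^-1): ",
      paste(sprintf("%s=%g", names(x$rates), x$rates), collapse = ", "), "\n",
      "  unitary currents (pA): ", paste(x$unitary, collapse = ", "), "\n",
      "  N_ch ~ round(N(", x$nch_mean, ", ", x$nch_sd, "^2)), floor 1\n",
      sep = "")
  invisible(x)
}

#' Per-state unitary current vector
#'
#' Expands the per-conductance-class unitary currents into a per-state vector
#' (0 for closed states), in the state order of the scheme.
#' @param scheme A [kinetic_scheme()].
#' @param params A [channel_params()].
#' @return Numeric vector of length `n_states`.
#' @export
state_currents <- function(scheme, params) {
  if (length(params$unitary) < scheme$n_classes)
    stop("need one unitary current per conductance class", call. = FALSE)
  i <- stats::setNames(numeric(scheme$n_states), scheme$states)
  if (scheme$n_open)
    i[names(scheme$open_states)] <- params$unitary[scheme$open_states]
  unname(i)
}

#' Seven-state GABA-A receptor scheme
#'
#' The experimentally derived scheme with an unbound state R, singly- and
#' doubly-liganded closed states (RG, RG2) and their open (O1, O2) and
#' desensitized (D1, D2) states.  Unbinding uses statistical factors: RG loses
#' its ligand at `k_off`, RG2 at `2 k_off`.
#'
#' @param two_conductance If `TRUE`, O1 and O2 get separate conductance
#'   classes (so their unitary currents can differ); otherwise they share one.
#' @return A [kinetic_scheme()].
#' @export
scheme_gabaa7 <- function(two_conductance = FALSE) {
  tr <- data.frame(
    from = c("R",  "RG",  "RG", "RG2", "RG", "O1", "RG", "D1",
             "RG2", "O2", "RG2", "D2"),
    to   = c("RG", "R",   "RG2", "RG", "O1", "RG", "D1", "RG",
             "O2",  "RG2", "D2", "RG2"),
    rate = c("kon1", "koff", "kon2", "koff", "b1", "a1", "d1", "r1",
             "b2", "a2", "d2", "r2"),
    ligand_order = c(1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    multiplier = c(1, 1, 1, 2, 1, 1, 1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
  open <- if (two_conductance) c(O1 = 1L, O2 = 2L) else c(O1 = 1L, O2 = 1L)
  kinetic_scheme(states = c("R", "RG", "RG2", "O1", "O2", "D1", "D2"),
                 transitions = tr, open_states = open,
                 liganded_state = "RG2")
}

#' Default GABA-A receptor rate constants
#'
#' Rate constants of the 7-state scheme adapted from fast-application
#' experiments on GABA-A receptors; the doubly-liganded state unbinds at
#' `2 * k_off` (statistical factor, carried by the transition multiplier).
#'
#' @param two_conductance Use the two-conductance parameterisation (modified
#'   gating rates, i1 = 2 pA for O1 and i2 = 1 pA for O2)?
#' @param nch_mean,nch_sd Channel-number distribution (defaults 250/50 for the
#'   standard model, 500/50 for the two-conductance one).
#' @return A [channel_params()].
#' @export
params_gabaa7 <- function(two_conductance = FALSE,
                          nch_mean = if (two_conductance) 500 else 250,
                          nch_sd = 50) {
  rates <- c(koff = 0.13, d1 = 0.14, d2 = 1.5, r1 = 0.02,
             r2 = 0.12, a1 = 1.5, a2 = 1, b1 = 0.15, b2 = 8,
             kon1 = 4, kon2 = 8)
  if (two_conductance) {
    rates[c("b2", "b1", "d1", "r1", "d2", "r2")] <-
      c(4, 1.2, 1, 1, 0.15, 1)
    unitary <- c(2, 1)
  } else {
    unitary <- 1
  }
  channel_params(rates, unitary, nch_mean = nch_mean, nch_sd = nch_sd)
}

#' Three-state abstract receptor scheme
#'
#' Unbound state R, singly-liganded closed state RL and a single open state O.
#' @return A [kinetic_scheme()].
#' @export
scheme_3state <- function() {
  tr <- data.frame(
    from = c("R", "RL", "RL", "O"),
    to   = c("RL", "R", "O", "RL"),
    rate = c("kon", "koff", "b", "a"),
    ligand_order = c(1L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
  kinetic_scheme(states = c("R", "RL", "O"), transitions = tr,
                 open_states = c(O = 1L), liganded_state = "RL")
}

#' Three-state model parameterisations
#'
#' Model "R" is the reference (closing rate a = 2.5 ms^-1, N_ch 400 +/- 50);
#' model "A" halves the closing rate (a = 1.25 ms^-1) and model "N" doubles
#' the channel number (800 +/- 71) at reference gating.
#'
#' @param model One of "R", "A", "N".
#' @return A [channel_params()].
#' @export
params_3state <- function(model = c("R", "A", "N")) {
  model <- match.arg(model)
  a <- if (model == "A") 1.25 else 2.5
  nch <- if (model == "N") c(800, 71) else c(400, 50)
  channel_params(c(kon = 6, koff = 0.025, b = 0.25, a = a),
                 unitary = 1, nch_mean = nch[1], nch_sd = nch[2])
}

#' Stimulation protocol
#'
#' Describes the agonist concentration time course and the sampling of the
#' recorded current.  Under the instantaneous-binding idealisation (the
#' default used throughout the bundled fixtures) a brief saturating pulse is
#' assumed to place every available channel in the scheme's fully liganded
#' state at the end of the pulse, and the recording is analysed from
#' `analysis_start_offset` after the pulse end.
#'
#' @param dt Sampling interval (ms).
#' @param pulse_duration Agonist pulse duration (ms); must be an integer
#'   multiple of `dt`.
#' @param pulse_concentration Pulse concentration (mM).
#' @param record_duration Recorded duration after the pulse end (ms).
#' @param analysis_start_offset Start of the analysis window, measured from
#'   the pulse end (ms).
#' @param pre_equilibration Data frame of (concentration, duration) epochs the
#'   channels experience before the pulse; used only when
#'   `instantaneous_binding = FALSE`.
#' @param instantaneous_binding Use the delta initial condition on the fully
#'   liganded state?
#' @return An object of class `protocol`.
#' @export
protocol <- function(dt, pulse_duration = dt, pulse_concentration = 1,
                     record_duration, analysis_start_offset = 0,
                     pre_equilibration = NULL,
                     instantaneous_binding = TRUE) {
  stopifnot(dt > 0, pulse_duration > 0, record_duration > pulse_duration,
            pulse_concentration >= 0, analysis_start_offset >= 0)
  if (abs(pulse_duration / dt - round(pulse_duration / dt)) > 1e-8)
    stop("pulse_duration must be an integer multiple of dt", call. = FALSE)
  if (!is.null(pre_equilibration)) {
    pre_equilibration <- as.data.frame(pre_equilibration)
    stopifnot(all(c("concentration", "duration") %in%
                    names(pre_equilibration)))
  }
  structure(list(dt = dt, pulse_duration = pulse_duration,
                 pulse_concentration = pulse_concentration,
                 record_duration = record_duration,
                 analysis_start_offset = analysis_start_offset,
                 pre_equilibration = pre_equilibration,
                 instantaneous_binding = instantaneous_binding),
            class = "protocol")
}

#' Protocols used by the bundled simulations
#'
#' The 7-state fixtures use dt = 0.2 ms, a 0.2 ms saturating pulse and a
#' 200 ms recording analysed from 1 ms after the pulse end; the 3-state
#' fixtures use dt = 0.1 ms and a 0.2 ms pulse.  The record is long enough
#' for the mean current to decay to a few percent of its peak, which the
#' peak-scaled variance-mean analysis needs.
#' @param which `"gabaa7"` or `"3state"`.
#' @return A [protocol()].
#' @export
default_protocol <- function(which = c("gabaa7", "3state")) {
  which <- match.arg(which)
  if (which == "gabaa7")
    protocol(dt = 0.2, pulse_duration = 0.2, pulse_concentration = 1,
             record_duration = 200, analysis_start_offset = 1)
  else
    protocol(dt = 0.1, pulse_duration = 0.2, pulse_concentration = 1,
             record_duration = 200, analysis_start_offset = 1)
}

#' Analysis time grid of a protocol
#'
#' Uniform, closed grid starting at the analysis-window start (times are
#' measured from the end of the agonist pulse).
#' @param proto A [protocol()].
#' @return Numeric vector of times (ms).
#' @export
protocol_times <- function(proto) {
  seq(proto$analysis_start_offset, proto$record_duration, by = proto$dt)
}
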