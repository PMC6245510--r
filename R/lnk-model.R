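#' Temporal filter
#'
#' A causal discrete-time filter stored as taps per lag sample. Taps have
#' units of 1/s so that convolution with a dimensionless stimulus,
#' `g(t) = sum_tau F(tau) s(t - tau) dt`, is dimensionless.
#'
#' @param taps Numeric vector of filter taps (lag 0 first), units 1/s.
#' @param dt Sample interval (s).
#' @return An object of class `temporal_filter`.
#' @export
temporal_filter <- function(taps, dt) {
  if (!all(is.finite(taps))) stop_invalid("filter taps must be finite")
  check_positive(dt, "dt")
  structure(list(taps = as.numeric(taps), dt = dt,
                 window_length = length(taps) * dt),
            class = "temporal_filter")
}

#' @export
print.temporal_filter <- function(x, ...) {
  cat(sprintf("<temporal_filter> %d taps over %g s (dt = %g s), peak %.3g at %g s\n",
              length(x$taps), x$window_length, x$dt,
              x$taps[which.max(abs(x$taps))],
              (which.max(abs(x$taps)) - 1L) * x$dt))
  invisible(x)
}

#' Sigmoid synaptic nonlinearity
#'
#' The static nonlinearity of an LNK pathway:
#' `u(x) = clamp(((erf(kappa * x + b1) + 1)/2)^a + b2, 0, 1)`.
#' `u` scales the activation (and optionally slow-recovery) rate of the
#' kinetics block between zero and its maximal value, so the pre-offset
#' maximum is normalized to exactly 1. The alternative literal reading in
#' which the activation rate constant itself appears in the denominator is
#' available as `dialect = "ka_denominator"` (see [eval_nonlinearity()]).
#'
#' @param a Exponent, dimensionless, in `[0, 20]`. Larger `a` sharpens
#'   rectification.
#' @param b1 Horizontal offset (threshold position), dimensionless.
#' @param b2 Vertical offset, dimensionless.
#' @param kappa Input scale (1 / SD of the filtered stimulus), dimensionless.
#' @return An object of class `sigmoid_nonlinearity`.
#' @export
sigmoid_nonlinearity <- function(a = 1, b1 = 0, b2 = 0, kappa = 1) {
  if (!is.finite(a) || a < 0 || a > 20) stop_invalid("a must be in [0, 20]")
  if (!all(is.finite(c(b1, b2, kappa)))) stop_invalid("parameters must be finite")
  structure(list(a = a, b1 = b1, b2 = b2, kappa = kappa),
            class = "sigmoid_nonlinearity")
}

#' Canonical threshold nonlinearity N0
#'
#' Half-wave rectification `u(x) = max(x, 0)` (not clamped above), used to
#' probe kinetics blocks with an input whose mean and SD grow linearly with
#' contrast.
#'
#' @return An object of class `threshold_nonlinearity`.
#' @export
canonical_nonlinearity <- function() {
  structure(list(), class = "threshold_nonlinearity")
}

#' Kinetics parameters of the four-state release model
#'
#' Rates (1/s) of the first-order Markov scheme
#' Resting -> Active -> Inactivated1 -> (Resting | Inactivated2 -> Resting),
#' with transitions: activation `u(t)*k_a` (R->A), fast inactivation `k_fi`
#' (A->I1), fast recovery `k_fr` (I1->R), slow inactivation `k_si` (I1->I2)
#' and slow recovery `u(t)*k_sr` (I2->R). The nonlinearity output `u(t)`
#' scales the activation rate and, by default, also the slow recovery rate.
#'
#' @param k_a,k_fi,k_fr,k_si,k_sr Non-negative rate constants (1/s).
#' @param u_scaled_rates Character subset of
#'   `c("activation", "slow_recovery")`; which rates `u(t)` multiplies.
#' @return An object of class `lnk_kinetics`.
#' @export
lnk_kinetics <- function(k_a, k_fi, k_fr, k_si, k_sr,
                         u_scaled_rates = c("activation", "slow_recovery")) {
  for (nm in c("k_a", "k_fi", "k_fr", "k_si", "k_sr")) {
    check_nonneg(get(nm), nm)
  }
  u_scaled_rates <- match.arg(u_scaled_rates,
                              c("activation", "slow_recovery"),
                              several.ok = TRUE)
  if (!"activation" %in% u_scaled_rates) {
    stop_invalid("u must scale at least the activation rate")
  }
  structure(list(k_a = k_a, k_fi = k_fi, k_fr = k_fr, k_si = k_si, k_sr = k_sr,
                 u_scaled_rates = u_scaled_rates),
            class = "lnk_kinetics")
}

#' One LNK pathway
#'
#' @param filter A [temporal_filter()] (`F_LNK`).
#' @param nonlinearity A [sigmoid_nonlinearity()].
#' @param kinetics An [lnk_kinetics()].
#' @param weight Dimensionless pathway weight applied at summation.
#' @param polarity_label `"On"` or `"Off"`.
#' @return An object of class `lnk_pathway`.
#' @export
lnk_pathway <- function(filter, nonlinearity, kinetics, weight = 1,
                        polarity_label = c("Off", "On")) {
  polarity_label <- match.arg(polarity_label)
  if (!is.finite(weight)) stop_invalid("weight must be finite")
  structure(list(filter = filter, nonlinearity = nonlinearity,
                 kinetics = kinetics, weight = weight,
                 polarity_label = polarity_label),
            class = "lnk_pathway")
}

#' An LNK cell: one or two weighted pathways plus output scaling
#'
#' The cell output is
#' `r(t) = output_scale * sum_p weight_p * A_p(t) + output_offset`,
#' where `A_p(t)` is the active-state occupancy of pathway `p`.
#'
#' @param pathways List of 1 or 2 [lnk_pathway()] objects with distinct labels.
#' @param output_scale Scale to millivolts.
#' @param output_offset Offset (mV), e.g. the resting potential.
#' @return An object of class `lnk_cell`.
#' @export
lnk_cell <- function(pathways, output_scale = 1, output_offset = 0) {
  if (inherits(pathways, "lnk_pathway")) pathways <- list(pathways)
  if (length(pathways) < 1L || length(pathways) > 2L) {
    stop_invalid("an lnk_cell has 1 or 2 pathways")
  }
  labels <- vapply(pathways, `[[`, "", "polarity_label")
  if (anyDuplicated(labels)) stop_invalid("pathway labels must be distinct")
  names(pathways) <- labels
  structure(list(pathways = pathways, output_scale = output_scale,
                 output_offset = output_offset),
            class = "lnk_cell")
}

#' @export
print.lnk_cell <- function(x, ...) {
  cat(sprintf("<lnk_cell> %d pathway(s): %s; scale %.3g mV, offset %.3g mV\n",
              length(x$pathways), paste(names(x$pathways), collapse = " + "),
              x$output_scale, x$output_offset))
  for (p in x$pathways) {
    cat(sprintf("  %-3s w = %.3g, filter %d taps, a = %.3g, b1 = %.3g, rates (/s): ka %.3g kfi %.3g kfr %.3g ksi %.3g ksr %.3g\n",
                p$polarity_label, p$weight, length(p$filter$taps),
                p$nonlinearity$a, p$nonlinearity$b1, p$kinetics$k_a,
                p$kinetics$k_fi, p$kinetics$k_fr, p$kinetics$k_si,
                p$kinetics$k_sr))
  }
  invisible(x)
}

#' Apply a temporal filter to a stimulus
#'
#' Causal discrete convolution `g(t) = sum_tau F(tau) s(t - tau) dt`. The
#' output has the length of the input; the first `window_length` of the output
#' is convolution burn-in and carries an attribute `burn_in_samples`.
#'
#' @param filter A [temporal_filter()].
#' @param stim Normalized (dimensionless) stimulus vector.
#' @param dt Sample interval of the stimulus (s); must equal `filter$dt`.
#' @return Numeric vector `g` with attribute `burn_in_samples`.
#' @export
apply_filter <- function(filter, stim, dt = filter$dt) {
  if (abs(dt - filter$dt) > 1e-12) {
    stop_invalid("stimulus dt (%g) does not match filter dt (%g)", dt, filter$dt)
  }
  g <- causal_convolve(stim, filter$taps * filter$dt)
  attr(g, "burn_in_samples") <- length(filter$taps)
  g
}

#' Evaluate a synaptic nonlinearity
#'
#' For a [sigmoid_nonlinearity()], the default dialect returns
#' `clamp(((erf(kappa*x + b1) + 1)/2)^a + b2, 0, 1)`, i.e. the pre-offset
#' maximum is normalized to 1 so that `u(t)` scales the activation rate of
#' the kinetics block between 0 and `k_a`. `dialect = "ka_denominator"`
#' instead normalizes by the activation rate constant supplied via `k_a`
#' (the literal printed form). For the canonical threshold nonlinearity,
#' returns `pmax(x, 0)`.
#'
#' @param nl A nonlinearity object.
#' @param x Numeric input (the filtered stimulus `g`).
#' @param dialect `"normalized"` (default) or `"ka_denominator"`.
#' @param k_a Activation rate, used only by the `ka_denominator` dialect.
#' @return `u`, clamped to `[0, 1]` for sigmoid nonlinearities so that the
#'   kinetics rate matrix stays valid.
#' @export
eval_nonlinearity <- function(nl, x, dialect = c("normalized", "ka_denominator"),
                              k_a = NULL) {
  if (inherits(nl, "threshold_nonlinearity")) return(pmax(x, 0))
  dialect <- match.arg(dialect)
  base <- erf(nl$kappa * x + nl$b1) + 1
  u <- if (dialect == "normalized") {
    (base / 2)^nl$a + nl$b2
  } else {
    if (is.null(k_a)) stop_invalid("ka_denominator dialect needs k_a")
    base^nl$a / k_a + nl$b2
  }
  pmin(pmax(u, 0), 1)
}

# Build the 4x4 generator Q(u) (rows sum to zero; occupancy row vector P
# evolves as dP/dt = P Q).
kinetics_Q <- function(kin, u) {
  scale_sr <- if ("slow_recovery" %in% kin$u_scaled_rates) u else 1
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- u * kin$k_a
  Q[2, 3] <- kin$k_fi
  Q[3, 1] <- kin$k_fr
  Q[3, 4] <- kin$k_si
  Q[4, 1] <- scale_sr * kin$k_sr
  diag(Q) <- -rowSums(Q)
  Q
}

#' Simulate the four-state kinetics block
#'
#' Integrates `dP/dt = P Q(u(t))` for the four fractional occupancies
#' (Resting, Active, Inactivated1, Inactivated2). `u` is treated as piecewise
#' constant over each sample, so each step is propagated exactly with the
#' matrix exponential `exp(Q dt)`; exponentials are cached per distinct value
#' of `u`, which keeps the simulation exact and fast for frame-held stimuli.
#'
#' @param kin An [lnk_kinetics()].
#' @param u Numeric vector of nonlinearity outputs in `[0, 1]`.
#' @param dt Time step (s).
#' @param initial Initial occupancy vector (length 4, non-negative, sums to 1).
#' @param u_bins If positive, quantize `u` to this many levels before
#'   propagation so the exponential cache stays small even when `u` varies
#'   every sample (used by the fitting objective); 0 (default) propagates
#'   each exact value.
#' @return An `occupancy_trajectory`: a list with `occupancies`
#'   (`n x 4` matrix, columns R, A, I1, I2) and `dt`.
#' @export
simulate_kinetics <- function(kin, u, dt, initial = c(1, 0, 0, 0),
                              u_bins = 0) {
  if (length(initial) != 4L || any(initial < -1e-12)) {
    stop_invalid("initial must be 4 non-negative occupancies")
  }
  if (abs(sum(initial) - 1) > 1e-9) stop_invalid("initial must sum to 1")
  if (any(u < -1e-12) || any(u > 1 + 1e-12)) {
    stop_invalid("u must lie within [0, 1]")
  }
  check_positive(dt, "dt")
  occ <- simulate_kinetics_cpp(
    kin$k_a, kin$k_fi, kin$k_fr, kin$k_si, kin$k_sr,
    "slow_recovery" %in% kin$u_scaled_rates,
    pmin(pmax(u, 0), 1), dt, initial, as.integer(u_bins))
  structure(list(occupancies = occ, dt = dt), class = "occupancy_trajectory")
}

#' Steady-state occupancy at constant drive
#'
#' The unique probability vector `p` with `p Q(u) = 0` for constant
#' `u > 0`. At `u = 0` both the resting and the slow-inactivated state are
#' absorbing and no unique stationary vector exists.
#'
#' @param kin An [lnk_kinetics()].
#' @param u_const Constant drive in `(0, 1]`.
#' @return Numeric vector of length 4 (R, A, I1, I2) summing to 1.
#' @export
steady_state_occupancy <- function(kin, u_const) {
  if (u_const <= 0 || u_const > 1) {
    stop_invalid("u_const must lie in (0, 1]: at u = 0 the stationary vector is not unique")
  }
  Q <- kinetics_Q(kin, u_const)
  # p Q = 0 and sum(p) = 1: replace one balance equation by normalization
  A <- rbind(t(Q)[1:3, ], rep(1, 4))
  p <- solve(A, c(0, 0, 0, 1))
  pmax(p, 0) / sum(pmax(p, 0))
}

# internal: run filter -> nonlinearity -> kinetics for one pathway,
# returning the active-state series. Initial condition: steady state at the
# mean u over the first `init_window` seconds.
pathway_active_state <- function(path, stim, dt, init_window = 2) {
  g <- apply_filter(path$filter, stim, dt)
  u <- eval_nonlinearity(path$nonlinearity, g)
  n0 <- min(length(u), max(1L, round(init_window / dt)))
  u0 <- max(mean(u[seq_len(n0)]), 1e-6)
  p0 <- steady_state_occupancy(path$kinetics, u0)
  traj <- simulate_kinetics(path$kinetics, u, dt, initial = p0)
  traj$occupancies[, 2L]
}

#' Simulate one LNK pathway
#'
#' Runs the full cascade filter -> sigmoid nonlinearity -> kinetics and
#' returns the active-state occupancy `A(t)`, the pathway's output signal.
#' The pathway weight is *not* applied here; weights enter only at the
#' cell-level summation. The kinetics start from the steady state implied by
#' the mean drive over the first 2 s, and callers should treat the first 2 s
#' as burn-in.
#'
#' @param path An [lnk_pathway()].
#' @param stim Normalized stimulus vector.
#' @param dt Sample interval (s).
#' @return Numeric vector `A(t)` in `[0, 1]`.
#' @export
simulate_pathway <- function(path, stim, dt = path$filter$dt) {
  pathway_active_state(path, stim, dt)
}

#' Simulate an LNK cell
#'
#' `r(t) = output_scale * sum_p weight_p * A_p(t) + output_offset` (mV).
#'
#' @param cell An [lnk_cell()].
#' @param stim Normalized stimulus vector.
#' @param dt Sample interval (s).
#' @param return_pathways If `TRUE`, attach the per-pathway weighted
#'   contributions (in mV, offset excluded) as attribute `pathway_outputs`.
#' @return Numeric vector of membrane potential (mV).
#' @export
simulate_cell <- function(cell, stim, dt = cell$pathways[[1L]]$filter$dt,
                          return_pathways = FALSE) {
  contribs <- lapply(cell$pathways, function(p) {
    cell$output_scale * p$weight * pathway_active_state(p, stim, dt)
  })
  out <- Reduce(`+`, contribs) + cell$output_offset
  if (return_pathways) attr(out, "pathway_outputs") <- contribs
  out
}

#' Silence a pathway (in-silico APB)
#'
#' Returns a cell in which the named pathway's weight is zero, emulating the
#' pharmacological block of one pathway while leaving every other parameter
#' untouched. Because pathway outputs sum, the silenced cell's output plus the
#' silenced pathway's weighted contribution reconstructs the control output.
#'
#' @param cell An [lnk_cell()].
#' @param label `"On"` or `"Off"`.
#' @return An [lnk_cell()].
#' @export
silence_pathway <- function(cell, label) {
  if (!label %in% names(cell$pathways)) {
    stop_invalid("no pathway labelled '%s'", label)
  }
  cell$pathways[[label]]$weight <- 0
  cell
}

#' Burn-in duration used by all simulation-based analyses
#'
#' The kinetics are initialized at a steady state estimated from the first 2 s
#' of drive; the same 2 s are excluded from all downstream statistics.
#'
#' @return Burn-in duration (s).
#' @export
lnk_burn_in <- function() 2
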