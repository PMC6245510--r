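# Ground-truth cells and synthetic recordings.
#
# The reference cell encodes the qualitative physiology of an On-Off cell:
# the Off pathway has a low-threshold, steep nonlinearity and an early
# negative filter lobe; the On pathway has a higher threshold, shallower
# slope and a delayed positive biphasic filter; the kinetics blocks are
# similar across pathways, with rates in the 1-100 /s range typical of
# bipolar-cell synaptic release.

# difference-of-gamma filter taps, unit L2 norm, units 1/s
gamma_bump <- function(t, peak, order = 5) {
  theta <- peak / (order - 1)
  h <- (t / theta)^(order - 1) * exp(-(t - peak) / theta)
  h / max(h)
}

reference_filter <- function(polarity, dt, window_length = 0.6) {
  t <- seq(0, window_length - dt, by = dt)
  taps <- if (polarity == "Off") {
    # early negative trough near 70 ms with a weak positive rebound:
    # nearly monophasic, so low-contrast (Off-dominated) responses integrate
    -(gamma_bump(t, 0.068) - 0.25 * gamma_bump(t, 0.135))
  } else {
    # sharper positive peak, delayed to ~140 ms, with a negative rebound;
    # recruiting it at high contrast makes the summed response differentiate
    gamma_bump(t, 0.14, order = 8) - 0.55 * gamma_bump(t, 0.266, order = 8)
  }
  temporal_filter(taps / sqrt(sum(taps^2)) / dt, dt)
}

#' Construct the reference two-pathway LNK cell
#'
#' A deterministic (given `seed`) ground-truth On-Off cell satisfying the
#' qualitative orderings that define the biology: the On threshold exceeds
#' the Off threshold, the On slope is shallower, the On filter's positive
#' first peak is later than the Off filter's negative first peak, and the
#' two kinetics blocks are similar. The seed applies a small multiplicative
#' jitter (within +/-8%) to the kinetic rates so independent draws are
#' distinct cells of the same family; the orderings always hold.
#'
#' @param seed Integer seed.
#' @param dt Sample interval (s).
#' @return An [lnk_cell()] with attribute `generator` recording the
#'   generating parameters.
#' @export
make_reference_cell <- function(seed = 1, dt = 0.001) {
  jit <- with_seed(derive_seed(seed, 600L), exp(runif(10, -0.08, 0.08)))
  # Off: low threshold (activates near contrast 0.05), steep
  nl_off <- sigmoid_nonlinearity(a = 1.6, b1 = -0.75, b2 = 0, kappa = 3)
  # On: higher threshold (activates near contrast 0.15), shallower
  nl_on <- sigmoid_nonlinearity(a = 1.0, b1 = -2.4, b2 = 0, kappa = 1.5)
  # u scales activation only, so higher contrast slowly depletes the
  # reserve pool: contrast steps give a transient response peak followed by
  # slow depression, and the baseline potential sags at high contrast
  kin_off <- lnk_kinetics(k_a = 60 * jit[1L], k_fi = 22 * jit[2L],
                          k_fr = 9 * jit[3L], k_si = 2.0 * jit[4L],
                          k_sr = 1.2 * jit[5L], u_scaled_rates = "activation")
  kin_on <- lnk_kinetics(k_a = 60 * jit[6L], k_fi = 20 * jit[7L],
                         k_fr = 10 * jit[8L], k_si = 1.8 * jit[9L],
                         k_sr = 1.1 * jit[10L], u_scaled_rates = "activation")
  cell <- lnk_cell(list(
    lnk_pathway(reference_filter("Off", dt), nl_off, kin_off,
                weight = 1, polarity_label = "Off"),
    lnk_pathway(reference_filter("On", dt), nl_on, kin_on,
                weight = 0.65, polarity_label = "On")),
    output_scale = 40, output_offset = -65)
  attr(cell, "generator") <- list(seed = seed, dt = dt,
                             threshold_off = -nl_off$b1 / nl_off$kappa,
                             threshold_on = -nl_on$b1 / nl_on$kappa)
  cell
}

#' Synthetic noisy recording from a ground-truth cell
#'
#' Simulates the cell's membrane potential and adds low-pass-filtered
#' Gaussian noise (2nd-order Butterworth, default cutoff 50 Hz), emulating
#' recording noise. The noise is rescaled after filtering so its SD is
#' exactly `noise_sd`. Full provenance (seeds and parameters) is stored so
#' every recording is regenerable bit-identically.
#'
#' @param cell An [lnk_cell()].
#' @param stim A `flicker_stimulus`.
#' @param noise_sd Noise SD (mV); 0 gives a clean recording.
#' @param noise_cutoff Low-pass cutoff (Hz).
#' @param seed Integer seed for the noise draw.
#' @param condition `"control"` or `"apb"` provenance label.
#' @return A list of class `synthetic_recording`: `stimulus`, `clean`,
#'   `noisy`, `dt`, `condition`, `provenance`.
#' @export
synth_recording <- function(cell, stim, noise_sd = 0, noise_cutoff = 50,
                            seed = 1, condition = "control") {
  check_nonneg(noise_sd, "noise_sd")
  s <- normalize_stimulus(stim)
  clean <- simulate_cell(cell, s, stim$dt)
  noise <- if (noise_sd > 0) {
    raw <- with_seed(derive_seed(seed, 700L), rnorm(length(clean)))
    bf <- signal::butter(2, noise_cutoff * 2 * stim$dt, type = "low")
    filtered <- signal::filtfilt(bf, raw)
    filtered / sd(filtered) * noise_sd
  } else numeric(length(clean))
  structure(list(stimulus = stim, clean = clean, noisy = clean + noise,
                 dt = stim$dt, condition = condition,
                 provenance = list(seed = seed, noise_sd = noise_sd,
                                   noise_cutoff = noise_cutoff)),
            class = "synthetic_recording")
}

#' Matched control/On-blocked recording pair
#'
#' The control recording comes from the full two-pathway cell and the blocked
#' recording from the same cell with the On pathway silenced, driven by the
#' identical stimulus with independent noise draws: the in-silico analogue of
#' a pharmacological On-pathway block.
#'
#' @inheritParams synth_recording
#' @return A list with elements `control` and `apb`, each a
#'   `synthetic_recording`.
#' @export
synth_apb_pair <- function(cell, stim, noise_sd = 0, seed = 1) {
  if (length(cell$pathways) != 2L) stop_invalid("need a two-pathway cell")
  list(control = synth_recording(cell, stim, noise_sd,
                                 seed = derive_seed(seed, 1L),
                                 condition = "control"),
       apb = synth_recording(silence_pathway(cell, "On"), stim, noise_sd,
                             seed = derive_seed(seed, 2L),
                             condition = "apb"))
}

#' Synthetic inhomogeneous-Poisson spike train
#'
#' Converts the cell's membrane potential into a firing rate through a
#' rectified-linear function, `rate(t) = rate_scale * max(r(t) -
#' rate_threshold, 0)`, and draws Poisson spikes per sample. For spatial
#' stimuli the stimulus is first projected onto `spatial_profile`, so the
#' spike train carries a spatial receptive field recoverable by
#' spike-triggered averaging.
#'
#' @param cell An [lnk_cell()].
#' @param stim A `flicker_stimulus` (spatial allowed).
#' @param rate_scale Hz per mV above threshold.
#' @param rate_threshold Threshold (mV).
#' @param spatial_profile Optional weight per bar for spatial stimuli.
#' @param seed Integer seed.
#' @return A [spike_train()]; the rate series is attached as attribute
#'   `rate`.
#' @export
synth_spike_train <- function(cell, stim, rate_scale = 2, rate_threshold = -65,
                              spatial_profile = NULL, seed = 1) {
  check_positive(rate_scale, "rate_scale")
  s <- normalize_stimulus(stim)
  if (is.matrix(s)) {
    if (is.null(spatial_profile) || length(spatial_profile) != nrow(s)) {
      stop_invalid("spatial stimuli need a spatial_profile of length n_space")
    }
    s <- drop(crossprod(s, spatial_profile))
    s <- s / sd(s) * mean(stim$schedule$contrast)
  }
  r <- simulate_cell(cell, s, stim$dt)
  rate <- rate_scale * pmax(r - rate_threshold, 0)
  counts <- with_seed(derive_seed(seed, 800L), rpois(length(rate), rate * stim$dt))
  times <- rep((seq_along(counts) - 0.5) * stim$dt, counts)
  out <- spike_train(times, duration = length(counts) * stim$dt)
  attr(out, "rate") <- rate
  out
}

#' Ground truth for the parameter-recovery benchmark
#'
#' Generates a noiseless 300 s recording from a one-pathway LNK cell drawn
#' from the same model family the fitter assumes: an Off-type
#' gamma-difference filter, a sigmoid nonlinearity whose `kappa` is the
#' reciprocal SD of the filtered stimulus on this record (the package's
#' standardization convention), and the four-state kinetics with both the
#' activation and slow-recovery rates scaled by `u(t)`. The stimulus follows
#' the standard protocol: 15 contrast segments of 20 s drawn uniformly from
#' 0.05-0.35.
#'
#' @param seed Integer seed for the stimulus.
#' @param dt Sample interval (s); 5 ms keeps the experiment desk-scale.
#' @return A list with `cell` (the generating [lnk_cell()]), `stim` (the
#'   normalized stimulus) and `resp` (the noiseless response, mV).
#' @export
synth_recovery_experiment <- function(seed = 1, dt = 0.005) {
  sched <- make_contrast_schedule(15, 20, 0.05, 0.35,
                                  rng_seed = derive_seed(seed, 900L))
  stim <- generate_flicker(sched, dt = dt,
                           rng_seed = derive_seed(seed, 901L))
  s <- normalize_stimulus(stim)
  filt <- reference_filter("Off", dt)
  g <- apply_filter(filt, s)
  kappa <- 1 / sd(g[-seq_len(length(filt$taps))])
  cell <- lnk_cell(list(lnk_pathway(
    filt,
    sigmoid_nonlinearity(a = 1.6, b1 = -0.75, b2 = 0, kappa = kappa),
    lnk_kinetics(k_a = 60, k_fi = 22, k_fr = 9, k_si = 1.4, k_sr = 2.4),
    weight = 1, polarity_label = "Off")),
    output_scale = 40, output_offset = -65)
  list(cell = cell, stim = s, resp = simulate_cell(cell, s, dt))
}
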