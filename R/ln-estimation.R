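#' Remove spikes from an intracellular trace
#'
#' Detects action potentials as samples whose derivative exceeds
#' `deriv_thresh` (mV/ms) *and* whose amplitude exceeds `amp_thresh` (mV)
#' above a running median, then replaces each detection and a +/- 3 ms
#' neighbourhood by linear interpolation, leaving the subthreshold membrane
#' potential. Thresholds are exposed because the appropriate values depend on
#' recording quality.
#'
#' @param trace Membrane potential (mV).
#' @param dt Sample interval (s); must be <= 2 ms so spikes are resolvable.
#' @param deriv_thresh Derivative criterion (mV/ms).
#' @param amp_thresh Amplitude criterion above the running median (mV).
#' @param median_window Running-median window (s).
#' @param pad Half-width of the interpolation window (s).
#' @return The de-spiked trace (same length).
#' @export
remove_spikes <- function(trace, dt, deriv_thresh = 5, amp_thresh = 15,
                          median_window = 0.05, pad = 0.003) {
  if (dt > 0.002) stop_invalid("dt must be <= 2 ms to resolve spikes")
  n <- length(trace)
  k <- max(3L, round(median_window / dt))
  if (k %% 2L == 0L) k <- k + 1L
  baseline <- runmed(trace, k, endrule = "median")
  deriv <- c(0, diff(trace)) / (dt * 1000)  # mV per ms
  hit <- abs(deriv) > deriv_thresh & (trace - baseline) > amp_thresh
  if (!any(hit)) return(trace)
  if (mean(hit) > 0.5) stop_invalid("spike criterion fires on > 50%% of samples")
  npad <- round(pad / dt)
  bad <- rep(FALSE, n)
  for (i in which(hit)) {
    bad[max(1L, i - npad):min(n, i + npad)] <- TRUE
  }
  if (all(bad)) stop_invalid("spike removal would discard the whole trace")
  idx <- seq_len(n)
  out <- trace
  out[bad] <- approx(idx[!bad], trace[!bad], xout = idx[bad], rule = 2)$y
  out
}

#' Estimate an LN temporal filter by spectral reverse correlation
#'
#' The filter's Fourier transform is the ratio of the averaged stimulus-
#' response cross-spectrum to the averaged stimulus auto-spectrum, estimated
#' over overlapping Hann-tapered segments (1 s long, stepped every 0.1 s by
#' default). The auto-spectrum denominator corrects for deviations of the
#' stimulus from white noise and carries a small ridge (1% of its mean power)
#' for numerical stability. The time-domain filter is truncated to
#' `window_length` and amplitude-normalized so the variance of the linear
#' prediction equals the variance of the stimulus.
#'
#' @param stim Normalized stimulus vector.
#' @param resp Response vector (same length and dt).
#' @param dt Sample interval (s).
#' @param window_length Filter window (s); default 0.6 s.
#' @param segment_length Spectral segment length (s); default 1 s.
#' @param segment_step Segment step (s); default 0.1 s.
#' @param ridge Ridge fraction added to the denominator; default 0.01.
#' @return A [temporal_filter()] satisfying `var(g) = var(s)`.
#' @export
estimate_filter <- function(stim, resp, dt, window_length = 0.6,
                            segment_length = 1, segment_step = 0.1,
                            ridge = 0.01) {
  if (length(stim) != length(resp)) stop_invalid("stim and resp lengths differ")
  nseg <- n_samples_of(segment_length, dt)
  step <- n_samples_of(segment_step, dt)
  n <- length(stim)
  if (nseg > n) stop_invalid("segment_length exceeds record length")
  starts <- seq(1L, n - nseg + 1L, by = step)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  cross <- numeric(nseg)
  auto <- numeric(nseg)
  s_mean <- mean(stim); r_mean <- mean(resp)
  for (s0 in starts) {
    idx <- s0:(s0 + nseg - 1L)
    sf <- fft((stim[idx] - s_mean) * taper)
    rf <- fft((resp[idx] - r_mean) * taper)
    cross <- cross + Conj(sf) * rf
    auto <- auto + Re(Conj(sf) * sf)
  }
  auto <- auto / length(starts)
  cross <- cross / length(starts)
  denom <- auto + ridge * mean(auto)
  Ff <- cross / denom
  f_time <- Re(fft(Ff, inverse = TRUE)) / nseg
  nw <- min(nseg, n_samples_of(window_length, dt))
  taps <- f_time[seq_len(nw)] / dt  # taps in 1/s units
  filt <- temporal_filter(taps, dt)
  # normalize amplitude so var(g) = var(s)
  g <- apply_filter(filt, stim)
  b <- length(filt$taps)
  vg <- var(g[-seq_len(b)])
  vs <- var(stim[-seq_len(b)])
  if (vg <= 0) stop_invalid("linear prediction has zero variance")
  temporal_filter(taps * sqrt(vs / vg), dt)
}

#' Linear prediction of an LN model
#'
#' Convolves the estimated filter with the stimulus; after
#' [estimate_filter()]'s normalization, `var(g) = var(s)`.
#'
#' @inheritParams apply_filter
#' @return Numeric vector `g` with attribute `burn_in_samples`.
#' @export
linear_prediction <- function(filter, stim, dt = filter$dt) {
  apply_filter(filter, stim, dt)
}

#' Estimate a static nonlinearity by equal-population binning
#'
#' Bins the linear prediction `g` into `n_bins` equal-population bins and
#' computes the mean response per bin. Equal-population binning keeps the
#' tails stable where `g` is sparsely sampled.
#'
#' @param g Linear prediction (burn-in removed by the caller).
#' @param resp Response aligned with `g`.
#' @param n_bins Number of bins (default 40).
#' @return A data frame of class `binned_nonlinearity` with columns
#'   `g` (bin centers, mean of g in bin), `response` (mean response) and
#'   `count` (bin occupancy).
#' @export
estimate_nonlinearity <- function(g, resp, n_bins = 40) {
  if (length(g) != length(resp)) stop_invalid("g and resp lengths differ")
  if (n_bins > length(g)) stop_invalid("n_bins exceeds the sample count")
  qs <- quantile(g, probs = seq(0, 1, length.out = n_bins + 1L),
                 names = FALSE, type = 7)
  qs[1L] <- -Inf; qs[n_bins + 1L] <- Inf
  bin <- cut(g, breaks = unique(qs), labels = FALSE, include.lowest = TRUE)
  centers <- tapply(g, bin, mean)
  means <- tapply(resp, bin, mean)
  counts <- tapply(resp, bin, length)
  out <- data.frame(g = as.numeric(centers), response = as.numeric(means),
                    count = as.integer(counts))
  out <- out[order(out$g), ]
  rownames(out) <- NULL
  class(out) <- c("binned_nonlinearity", "data.frame")
  out
}

#' Spike train container
#'
#' @param spike_times Spike times (s), non-decreasing, within `[0, duration]`.
#' @param duration Record duration (s).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(spike_times, duration) {
  spike_times <- sort(as.numeric(spike_times))
  if (length(spike_times) &&
      (spike_times[1L] < 0 || spike_times[length(spike_times)] > duration)) {
    stop_invalid("spike times must lie within [0, duration]")
  }
  structure(list(spike_times = spike_times, duration = duration),
            class = "spike_train")
}

#' Spike-triggered average stimulus
#'
#' Averages the stimulus patch preceding each spike over the lag window and
#' subtracts the stimulus mean, yielding the spatiotemporal receptive-field
#' estimate used for spiking responses.
#'
#' @param stim A `flicker_stimulus` (spatial or uniform-field).
#' @param spikes A [spike_train()].
#' @param window_length Lag window (s); default 0.6 s.
#' @return An object of class `spatiotemporal_filter`: list with `map`
#'   (`n_space x n_lags`, lag 0 first), `dt`.
#' @export
spike_triggered_average <- function(stim, spikes, window_length = 0.6) {
  if (length(spikes$spike_times) == 0L) stop_invalid("no spikes")
  if (length(spikes$spike_times) < 100L) {
    warning("fewer than 100 spikes; STA will be noisy")
  }
  vals <- stim$values
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = 1L)
  n <- ncol(vals)
  nlag <- n_samples_of(window_length, stim$dt)
  idx_spk <- round(spikes$spike_times / stim$dt) + 1L
  idx_spk <- idx_spk[idx_spk >= nlag & idx_spk <= n]
  if (length(idx_spk) == 0L) stop_invalid("no usable spikes in the window")
  acc <- matrix(0, nrow(vals), nlag)
  for (i in idx_spk) {
    acc <- acc + vals[, i:(i - nlag + 1L), drop = FALSE]
  }
  map <- acc / length(idx_spk) - rowMeans(vals)
  structure(list(map = map, dt = stim$dt), class = "spatiotemporal_filter")
}

#' Temporal course of a spatiotemporal filter (first principal component)
#'
#' The leading right-singular vector of the space x time map, i.e. the
#' dominant temporal waveform shared across space. The sign is fixed so the
#' vector's largest-magnitude lobe matches the sign of the map's
#' largest-magnitude entry, making the convention deterministic.
#'
#' @param stf A `spatiotemporal_filter`.
#' @return A [temporal_filter()] with unit-norm taps (scaled by `1/dt` so
#'   units remain 1/s).
#' @export
temporal_course_pc1 <- function(stf) {
  if (all(stf$map == 0)) stop_invalid("degenerate (all-zero) map")
  sv <- svd(stf$map)
  v <- sv$v[, 1L]
  peak <- which.max(abs(stf$map))
  peak_t <- ((peak - 1L) %/% nrow(stf$map)) + 1L
  if (sign(v[which.max(abs(v))]) != sign(stf$map[peak])) v <- -v
  temporal_filter(v / stf$dt, stf$dt)
}
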