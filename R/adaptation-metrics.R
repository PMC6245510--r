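#' Power spectrum of a temporal filter
#'
#' One-sided power spectral density of the (zero-padded) filter taps up to the
#' Nyquist frequency. Zero-padding to `n_pad` points fixes the frequency grid
#' independently of the filter length, so median frequencies are comparable
#' across filters. The density satisfies Parseval's identity:
#' `sum(power) * df = sum(taps^2) * dt`.
#'
#' @param filter A [temporal_filter()] or a numeric vector of taps (then `dt`
#'   must be given).
#' @param dt Sample interval (s), taken from the filter if available.
#' @param n_pad FFT length (default 4096).
#' @return A data frame with columns `frequency` (Hz) and `power`.
#' @export
power_spectrum <- function(filter, dt = NULL, n_pad = 4096) {
  if (inherits(filter, "temporal_filter")) {
    taps <- filter$taps; dt <- filter$dt
  } else {
    taps <- as.numeric(filter)
    if (is.null(dt)) stop_invalid("dt required for raw taps")
  }
  if (length(taps) == 0L) stop_invalid("empty filter")
  n_pad <- max(n_pad, length(taps))
  X <- fft(c(taps, numeric(n_pad - length(taps))))
  half <- seq_len(n_pad %/% 2 + 1L)
  pw <- Mod(X[half])^2 * dt^2
  # double the interior bins for the one-sided density
  interior <- half > 1L & half < (n_pad %/% 2 + 1L)
  pw[interior] <- 2 * pw[interior]
  freq <- (half - 1L) / (n_pad * dt)
  data.frame(frequency = freq, power = pw)
}

#' Power spectrum of a raw response trace
#'
#' Welch-style averaged periodogram over Hann-tapered segments, for
#' inspecting response bandwidth directly rather than through a fitted filter.
#'
#' @param trace Response vector.
#' @param dt Sample interval (s).
#' @param segment_length Segment length (s).
#' @return A data frame with columns `frequency` (Hz) and `power`.
#' @export
response_spectrum <- function(trace, dt, segment_length = 1) {
  nseg <- n_samples_of(segment_length, dt)
  if (nseg > length(trace)) stop_invalid("segment longer than record")
  starts <- seq(1L, length(trace) - nseg + 1L, by = nseg %/% 2)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  acc <- numeric(nseg %/% 2 + 1L)
  for (s0 in starts) {
    x <- trace[s0:(s0 + nseg - 1L)]
    X <- fft((x - mean(x)) * taper)
    acc <- acc + Mod(X[seq_along(acc)])^2
  }
  data.frame(frequency = (seq_along(acc) - 1L) / (nseg * dt),
             power = acc / length(starts))
}

#' Median frequency of a power spectrum
#'
#' The frequency at which the cumulative normalized power first reaches one
#' half, linearly interpolated between grid points: a robust scalar summary of
#' temporal bandwidth. Invariant to overall spectrum scaling.
#'
#' @param spectrum A data frame with columns `frequency` and `power`.
#' @return Median frequency (Hz).
#' @export
median_frequency <- function(spectrum) {
  pw <- spectrum$power
  f <- spectrum$frequency
  tot <- sum(pw)
  if (tot <= 0) stop_invalid("zero total power")
  cdf <- cumsum(pw) / tot
  k <- which(cdf >= 0.5)[1L]
  if (k == 1L) return(f[1L])
  # linear interpolation of the first 0.5 crossing
  c0 <- cdf[k - 1L]; c1 <- cdf[k]
  f[k - 1L] + (0.5 - c0) / (c1 - c0) * (f[k] - f[k - 1L])
}

#' Slope of median frequency versus contrast
#'
#' Ordinary least-squares fit of median frequency (Hz) against contrast
#' (dimensionless sigma units); the slope, in Hz per unit contrast, is the
#' temporal-bandwidth adaptation index.
#'
#' @param contrasts Contrast values (>= 3).
#' @param medians Median frequencies (Hz), same length.
#' @return A list with `slope` (Hz/sigma), `se`, `intercept`.
#' @export
frequency_shift_slope <- function(contrasts, medians) {
  if (length(contrasts) < 3L) stop_invalid("need at least 3 contrast levels")
  if (length(contrasts) != length(medians)) stop_invalid("length mismatch")
  fit <- lm(medians ~ contrasts)
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(coef(fit)[2L]), se = unname(sm[2L, 2L]),
       intercept = unname(coef(fit)[1L]))
}

#' Gain of a binned nonlinearity
#'
#' Average slope of the static nonlinearity: the occupancy-weighted mean of
#' adjacent-bin finite differences. Weighting by bin occupancy makes the
#' measure reflect the stimulus distribution actually explored.
#'
#' @param nl A `binned_nonlinearity` from [estimate_nonlinearity()], or a
#'   data frame with columns `g`, `response` and optionally `count`.
#' @return Average slope (response units per unit `g`).
#' @export
nonlinearity_gain <- function(nl) {
  if (nrow(nl) < 2L) stop_invalid("need at least 2 bins")
  dg <- diff(nl$g)
  if (any(dg <= 0)) stop_invalid("degenerate bins (non-increasing centers)")
  slopes <- diff(nl$response) / dg
  w <- if (!is.null(nl$count)) nl$count[-1L] + nl$count[-nrow(nl)] else
    rep(1, length(slopes))
  sum(slopes * w) / sum(w)
}

#' Response delay from a temporal filter
#'
#' Time to the first strictly negative local minimum of the filter (the
#' hyperpolarizing lobe), refined by three-point parabolic interpolation.
#' Filters without a negative lobe (pure On filters) have no defined delay.
#'
#' @param filter A [temporal_filter()].
#' @return Delay (s).
#' @export
response_delay <- function(filter) {
  x <- filter$taps
  n <- length(x)
  if (n < 3L) stop_invalid("filter too short")
  is_min <- c(FALSE, x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n], FALSE)
  k <- which(is_min & x < 0)[1L]
  if (is.na(k)) stop_invalid("filter has no negative local minimum")
  # parabolic refinement around (k-1, k, k+1)
  y0 <- x[k - 1L]; y1 <- x[k]; y2 <- x[k + 1L]
  denom <- y0 - 2 * y1 + y2
  shift <- if (abs(denom) > 0) 0.5 * (y0 - y2) / denom else 0
  (k - 1L + shift) * filter$dt
}

#' Normalized per-segment response offset
#'
#' Mean of the trace in non-overlapping segments (default 4 s), each divided
#' by the whole-record standard deviation: tracks slow changes in baseline
#' membrane potential across contrast epochs.
#'
#' @param trace Response vector.
#' @param dt Sample interval (s).
#' @param segment_length Segment duration (s); default 4 s.
#' @return Numeric vector of normalized segment means.
#' @export
response_offset <- function(trace, dt, segment_length = 4) {
  nseg <- n_samples_of(segment_length, dt)
  if (length(trace) < nseg) stop_invalid("record shorter than one segment")
  s <- sd(trace)
  if (s == 0) stop_invalid("zero whole-record SD")
  nfull <- length(trace) %/% nseg
  m <- colMeans(matrix(trace[seq_len(nfull * nseg)], nrow = nseg))
  m / s
}

#' On/Off response ratio from a PSTH
#'
#' Baseline-subtracted mean firing rate in a window after flash onset divided
#' by the same after flash offset. Classifies cells along the On-Off axis:
#' 0 for pure Off cells, larger for stronger On input.
#'
#' @param time,rate PSTH time base (s) and firing rate (Hz).
#' @param flash_onset,flash_offset Flash edge times (s).
#' @param window Response window after each edge (s); default 0.4 s.
#' @param baseline_window Pre-onset baseline window (s); default 0.2 s.
#' @return Dimensionless ratio, floored at 0.
#' @export
on_off_ratio <- function(time, rate, flash_onset, flash_offset,
                         window = 0.4, baseline_window = 0.2) {
  base <- mean(rate[time >= flash_onset - baseline_window & time < flash_onset])
  on_r <- mean(rate[time >= flash_onset & time < flash_onset + window]) - base
  off_r <- mean(rate[time >= flash_offset & time < flash_offset + window]) - base
  if (!is.finite(off_r) || off_r <= 0) stop_invalid("zero or undefined Off response")
  max(on_r, 0) / off_r
}

#' Slow firing-rate change within a contrast epoch
#'
#' Least-squares slope of rate versus time over the epoch, multiplied by the
#' epoch duration and normalized by the epoch's maximum measured rate: the
#' fractional rate change across the epoch. Positive values during low
#' contrast indicate slow adaptation (rate recovering upward).
#'
#' @param time,rate Time (s) and firing rate (Hz) within one epoch.
#' @return Dimensionless normalized slope.
#' @export
slow_rate_change <- function(time, rate) {
  if (max(time) - min(time) < 2) stop_invalid("epoch must be at least 2 s")
  rmax <- max(rate)
  if (rmax <= 0) stop_invalid("zero maximum rate")
  fit <- lm(rate ~ time)
  unname(coef(fit)[2L]) * (max(time) - min(time)) / rmax
}

#' Per-contrast adaptation summary of a simulated cell
#'
#' Fits an LN model (filter + binned nonlinearity) to the cell's output at
#' each contrast and collects gain, delay, median frequency and the
#' frequency-shift slope: the full descriptive characterization used to
#' quantify contrast adaptation.
#'
#' @param cell An [lnk_cell()].
#' @param contrasts Contrast levels.
#' @param epoch_length Simulated epoch per contrast (s).
#' @param dt Sample interval (s).
#' @param rng_seed Integer seed.
#' @param n_bins Bins for the nonlinearity.
#' @return A list of class `adaptation_summary`: `per_contrast` data frame
#'   (contrast, gain, delay, median_frequency), `frequency_shift` (slope fit),
#'   and `models` (the per-contrast LN models).
#' @export
adaptation_summary <- function(cell, contrasts, epoch_length = 60,
                               dt = 0.001, rng_seed = 1, n_bins = 40) {
  stopifnot(length(contrasts) >= 3L)
  models <- vector("list", length(contrasts))
  rows <- vector("list", length(contrasts))
  for (i in seq_along(contrasts)) {
    sched <- contrast_schedule(0, epoch_length, contrasts[i])
    stim <- generate_flicker(sched, dt = dt,
                             rng_seed = derive_seed(rng_seed, 100L + i))
    s <- normalize_stimulus(stim)
    r <- simulate_cell(cell, s, dt)
    burn <- round(lnk_burn_in() / dt)
    filt <- estimate_filter(s[-seq_len(burn)], r[-seq_len(burn)], dt)
    g <- linear_prediction(filt, s[-seq_len(burn)])
    gb <- attr(g, "burn_in_samples")
    nlc <- estimate_nonlinearity(g[-seq_len(gb)], r[-seq_len(burn)][-seq_len(gb)],
                                 n_bins = n_bins)
    spec <- power_spectrum(filt)
    delay <- tryCatch(response_delay(filt), error = function(e) NA_real_)
    models[[i]] <- list(filter = filt, nonlinearity = nlc,
                        contrast = contrasts[i])
    rows[[i]] <- data.frame(contrast = contrasts[i],
                            gain = nonlinearity_gain(nlc),
                            delay = delay,
                            median_frequency = median_frequency(spec))
  }
  per_contrast <- do.call(rbind, rows)
  structure(list(per_contrast = per_contrast,
                 frequency_shift = frequency_shift_slope(
                   per_contrast$contrast, per_contrast$median_frequency),
                 models = models),
            class = "adaptation_summary")
}

#' @export
print.adaptation_summary <- function(x, ...) {
  cat("<adaptation_summary>\n")
  print(x$per_contrast, row.names = FALSE)
  cat(sprintf("  frequency-shift slope: %.3g +/- %.3g Hz/sigma\n",
              x$frequency_shift$slope, x$frequency_shift$se))
  invisible(x)
}
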