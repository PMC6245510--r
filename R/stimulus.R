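#' Contrast schedule for a flicker stimulus
#'
#' A contrast schedule is an ordered set of contiguous time segments, each with
#' its own temporal contrast. Contrast is the dimensionless ratio `W/M` of the
#' standard deviation to the mean of the stimulus intensity distribution.
#'
#' @param start Segment start times (s), strictly increasing, contiguous.
#' @param duration Segment durations (s), all positive.
#' @param contrast Segment contrasts (dimensionless), all positive
#'   (zero is tolerated only for degenerate test stimuli).
#' @return An object of class `contrast_schedule`: a data frame with columns
#'   `start`, `duration`, `contrast`.
#' @export
contrast_schedule <- function(start, duration, contrast) {
  if (length(start) != length(duration) || length(start) != length(contrast)) {
    stop_invalid("start, duration and contrast must have equal length")
  }
  if (any(duration <= 0)) stop_invalid("all segment durations must be > 0")
  if (any(contrast < 0)) stop_invalid("contrasts must be >= 0")
  if (length(start) > 1L) {
    gaps <- start[-1L] - (start[-length(start)] + duration[-length(duration)])
    if (any(abs(gaps) > 1e-9)) {
      stop_invalid("segments must be contiguous and non-overlapping")
    }
  }
  structure(data.frame(start = start, duration = duration, contrast = contrast),
            class = c("contrast_schedule", "data.frame"))
}

#' Random uniform contrast schedule
#'
#' Draws one contrast per segment i.i.d. from a uniform distribution, matching
#' the experimental protocol in which the contrast of a Gaussian flicker
#' stimulus is redrawn every `segment_duration` seconds.
#'
#' @param n_segments Number of contiguous segments (>= 1).
#' @param segment_duration Duration of each segment (s).
#' @param contrast_low,contrast_high Bounds of the uniform contrast
#'   distribution, `0 < contrast_low <= contrast_high`.
#' @param rng_seed Integer seed; the schedule is deterministic given the seed.
#' @return A [contrast_schedule()].
#' @examples
#' sched <- make_contrast_schedule(15, 20, 0.05, 0.35, rng_seed = 1)
#' sum(sched$duration)  # 300 s
#' @export
make_contrast_schedule <- function(n_segments, segment_duration,
                                   contrast_low, contrast_high, rng_seed) {
  if (n_segments < 1L) stop_invalid("n_segments must be >= 1")
  check_positive(segment_duration, "segment_duration")
  check_positive(contrast_low, "contrast_low")
  check_positive(contrast_high, "contrast_high")
  if (contrast_low > contrast_high) {
    stop_invalid("contrast_low must not exceed contrast_high")
  }
  contrasts <- with_seed(derive_seed(rng_seed, 1L),
                         runif(n_segments, contrast_low, contrast_high))
  contrast_schedule(start = (seq_len(n_segments) - 1L) * segment_duration,
                    duration = rep(segment_duration, n_segments),
                    contrast = contrasts)
}

new_flicker_stimulus <- function(values, dt, frame_duration, mean_intensity,
                                 schedule, n_space = 1L) {
  structure(list(values = values, dt = dt, frame_duration = frame_duration,
                 mean_intensity = mean_intensity, schedule = schedule,
                 n_space = as.integer(n_space)),
            class = "flicker_stimulus")
}

#' @export
print.flicker_stimulus <- function(x, ...) {
  n <- if (is.matrix(x$values)) ncol(x$values) else length(x$values)
  cat(sprintf(
    "<flicker_stimulus> %g s at dt = %g s (%d frames of %g s), %d spatial unit(s)\n",
    n * x$dt, x$dt, n * x$dt / x$frame_duration, x$frame_duration, x$n_space))
  if (!is.null(x$schedule)) {
    cat(sprintf("  %d contrast segment(s), contrast %.3g-%.3g\n",
                nrow(x$schedule), min(x$schedule$contrast),
                max(x$schedule$contrast)))
  }
  invisible(x)
}

# Frame-held Gaussian draws: one value per frame, repeated frame_len times.
frame_held_gaussian <- function(n_frames, frame_len, mean, sd_per_frame) {
  draws <- rnorm(n_frames, mean = mean, sd = sd_per_frame)
  rep(draws, each = frame_len)
}

#' Generate a uniform-field Gaussian flicker stimulus
#'
#' The stimulus intensity is redrawn once per frame from a Gaussian with mean
#' `mean_intensity` and standard deviation `contrast * mean_intensity`, and
#' held constant within the frame. Contrast segment boundaries are snapped to
#' the nearest frame boundary so every frame has a single contrast.
#'
#' @param schedule A [contrast_schedule()].
#' @param frame_duration Frame hold time (s); must be an integer multiple of `dt`.
#' @param dt Sample interval (s).
#' @param mean_intensity Mean luminance `M` (> 0), arbitrary units.
#' @param rng_seed Integer seed.
#' @return A `flicker_stimulus` whose `values` are intensities per sample.
#' @export
generate_flicker <- function(schedule, frame_duration = 0.030, dt = 0.001,
                             mean_intensity = 1, rng_seed = 1) {
  check_positive(mean_intensity, "mean_intensity")
  frame_len <- n_samples_of(frame_duration, dt)
  total <- sum(schedule$duration)
  n_frames_total <- round(total / frame_duration)
  # contrast per frame: segment boundaries snapped to frame boundaries
  frame_mid <- (seq_len(n_frames_total) - 0.5) * frame_duration +
    schedule$start[1L]
  seg_end <- schedule$start + schedule$duration
  seg_of_frame <- findInterval(frame_mid, schedule$start,
                               rightmost.closed = TRUE)
  seg_of_frame[seg_of_frame < 1L] <- 1L
  seg_of_frame[seg_of_frame > nrow(schedule)] <- nrow(schedule)
  frame_contrast <- schedule$contrast[seg_of_frame]
  values <- with_seed(derive_seed(rng_seed, 2L), {
    draws <- rnorm(n_frames_total, mean = mean_intensity,
                   sd = frame_contrast * mean_intensity)
    rep(draws, each = frame_len)
  })
  new_flicker_stimulus(values, dt, frame_duration, mean_intensity, schedule)
}

#' Normalize a stimulus to dimensionless contrast units
#'
#' Returns `(I - M)/M`, a zero-mean series whose per-segment standard
#' deviation equals that segment's contrast in expectation. This is the series
#' all models in the package consume.
#'
#' @param stim A `flicker_stimulus`.
#' @return A numeric vector (or matrix for spatial stimuli) of normalized
#'   intensities.
#' @export
normalize_stimulus <- function(stim) {
  if (!inherits(stim, "flicker_stimulus")) stop_invalid("not a flicker_stimulus")
  if (stim$mean_intensity == 0) stop_invalid("mean_intensity is zero")
  (stim$values - stim$mean_intensity) / stim$mean_intensity
}

#' Generate a uniform-field flash stimulus
#'
#' A constant pre-period, a step of amplitude `amplitude` above the mean for
#' `flash_duration`, and a constant post-period; used to classify On and Off
#' responses and compute On/Off ratios.
#'
#' @param pre_duration,flash_duration,post_duration Durations (s), all > 0.
#' @param amplitude Flash amplitude above the mean (luminance units).
#' @param dt Sample interval (s).
#' @param mean_intensity Baseline luminance.
#' @return A `flicker_stimulus` (schedule `NULL`); attributes `onset` and
#'   `offset` hold the flash edge times (s).
#' @export
generate_flash <- function(pre_duration, flash_duration, post_duration,
                           amplitude, dt = 0.001, mean_intensity = 1) {
  check_positive(pre_duration, "pre_duration")
  check_positive(flash_duration, "flash_duration")
  check_positive(post_duration, "post_duration")
  n_pre <- n_samples_of(pre_duration, dt)
  n_fl <- n_samples_of(flash_duration, dt)
  n_post <- n_samples_of(post_duration, dt)
  values <- c(rep(mean_intensity, n_pre),
              rep(mean_intensity + amplitude, n_fl),
              rep(mean_intensity, n_post))
  out <- new_flicker_stimulus(values, dt, frame_duration = dt,
                              mean_intensity = mean_intensity, schedule = NULL)
  attr(out, "onset") <- pre_duration
  attr(out, "offset") <- pre_duration + flash_duration
  out
}

#' Generate a one-dimensional bar-flicker stimulus
#'
#' `n_bars` bars flicker independently (one Gaussian draw per bar per frame)
#' while the contrast of all bars alternates between a high and a low value,
#' emulating the periodic contrast-switching protocol used for spiking
#' receptive-field analyses.
#'
#' @param n_bars Number of bars (>= 1).
#' @param high_contrast,low_contrast Contrasts of the two epochs.
#' @param high_duration,low_duration Epoch durations (s).
#' @param n_cycles Number of high+low cycles.
#' @param frame_duration,dt Temporal structure (s).
#' @param mean_intensity Mean luminance.
#' @param rng_seed Integer seed.
#' @return A `flicker_stimulus` whose `values` is an `n_bars x n_samples`
#'   matrix and whose schedule alternates the two contrasts.
#' @export
generate_bar_flicker <- function(n_bars, high_contrast = 0.35,
                                 low_contrast = 0.05, high_duration = 4,
                                 low_duration = 16, n_cycles = 1,
                                 frame_duration = 0.030, dt = 0.001,
                                 mean_intensity = 1, rng_seed = 1) {
  if (n_bars < 1L) stop_invalid("n_bars must be >= 1")
  check_positive(high_contrast, "high_contrast")
  check_positive(low_contrast, "low_contrast")
  frame_len <- n_samples_of(frame_duration, dt)
  sched <- contrast_schedule(
    start = cumsum(c(0, head(rep(c(high_duration, low_duration), n_cycles), -1L))),
    duration = rep(c(high_duration, low_duration), n_cycles),
    contrast = rep(c(high_contrast, low_contrast), n_cycles))
  total <- sum(sched$duration)
  n_frames <- round(total / frame_duration)
  frame_mid <- (seq_len(n_frames) - 0.5) * frame_duration
  seg <- findInterval(frame_mid, sched$start, rightmost.closed = TRUE)
  seg[seg < 1L] <- 1L; seg[seg > nrow(sched)] <- nrow(sched)
  frame_sd <- sched$contrast[seg] * mean_intensity
  values <- with_seed(derive_seed(rng_seed, 3L), {
    draws <- matrix(rnorm(n_bars * n_frames, mean = mean_intensity,
                          sd = rep(frame_sd, each = n_bars)),
                    nrow = n_bars)
    draws[, rep(seq_len(n_frames), each = frame_len), drop = FALSE]
  })
  new_flicker_stimulus(values, dt, frame_duration, mean_intensity, sched,
                       n_space = n_bars)
}
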