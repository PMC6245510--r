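test_that("filter power spectra satisfy Parseval and match direct DFT", {
  set.seed(10)
  dt <- 0.001
  filt <- temporal_filter(rnorm(64), dt)
  sp <- power_spectrum(filt, n_pad = 256)
  df <- sp$frequency[2L] - sp$frequency[1L]
  expect_equal(sum(sp$power) * df, sum(filt$taps^2) * dt, tolerance = 1e-9)
  # direct DFT-by-summation oracle at a few frequencies
  x <- c(filt$taps, numeric(256 - 64))
  for (k in c(2L, 17L, 101L)) {
    Xk <- sum(x * exp(-2i * pi * (k - 1L) * (seq_along(x) - 1L) / 256))
    doubling <- if (k == 1L || k == 129L) 1 else 2
    expect_equal(sp$power[k], doubling * Mod(Xk)^2 * dt^2, tolerance = 1e-9)
  }
  # a pure cosine tap pattern peaks at its own frequency
  f0 <- 25
  cosine <- temporal_filter(cos(2 * pi * f0 * seq(0, 0.511, by = dt)), dt)
  spc <- power_spectrum(cosine, n_pad = 4096)
  expect_equal(spc$frequency[which.max(spc$power)], f0, tolerance = 1)
})

test_that("median frequency follows the cumulative-power convention", {
  # all power in one bin: within one grid step of that bin under the
  # first-crossing interpolation convention
  sp1 <- data.frame(frequency = c(0, 5, 10), power = c(0, 1, 0))
  expect_lt(abs(median_frequency(sp1) - 5), 5 + 1e-12)
  expect_equal(median_frequency(data.frame(frequency = 5, power = 1)), 5)
  # uniform spectrum on [0, F] -> about F/2
  spu <- data.frame(frequency = seq(0, 40, by = 0.01),
                    power = rep(1, 4001))
  expect_equal(median_frequency(spu), 20, tolerance = 0.05)
  # two equal point masses: first-crossing at the lower frequency
  sp2 <- data.frame(frequency = c(1, 2, 3, 4), power = c(0, 1, 0, 1))
  expect_equal(median_frequency(sp2), 2)
  # invariant to amplitude scaling
  sp3 <- data.frame(frequency = seq(0, 30, by = 0.1),
                    power = stats::dgamma(seq(0, 30, by = 0.1), 3, 0.5))
  expect_equal(median_frequency(sp3),
               median_frequency(transform(sp3, power = 7.3 * power)))
  expect_error(median_frequency(data.frame(frequency = 1:3, power = c(0, 0, 0))),
               "zero total power")
})

test_that("frequency-shift slope matches the closed-form least-squares oracle", {
  contrasts <- c(0.05, 0.15, 0.25, 0.35)
  expect_equal(frequency_shift_slope(contrasts, rep(4, 4))$slope, 0)
  expect_equal(frequency_shift_slope(contrasts, 2 + 6 * contrasts)$slope, 6,
               tolerance = 1e-12)
  set.seed(11)
  med <- 3 + 5 * contrasts + rnorm(4, sd = 0.2)
  fit <- frequency_shift_slope(contrasts, med)
  # closed forms
  sxx <- sum((contrasts - mean(contrasts))^2)
  b <- sum((contrasts - mean(contrasts)) * (med - mean(med))) / sxx
  res <- med - mean(med) - b * (contrasts - mean(contrasts))
  se <- sqrt(sum(res^2) / 2 / sxx)
  expect_equal(fit$slope, b, tolerance = 1e-12)
  expect_equal(fit$se, se, tolerance = 1e-12)
  expect_error(frequency_shift_slope(contrasts[1:2], med[1:2]), "3 contrast")
})

test_that("nonlinearity gain is the occupancy-weighted mean slope", {
  nl_lin <- data.frame(g = 1:5, response = 2.5 * (1:5) + 1,
                       count = c(5, 10, 20, 10, 5))
  expect_equal(nonlinearity_gain(nl_lin), 2.5)
  nl_const <- data.frame(g = 1:4, response = rep(3, 4), count = rep(1, 4))
  expect_equal(nonlinearity_gain(nl_const), 0)
  set.seed(12)
  nl_rand <- data.frame(g = sort(rnorm(10)), response = rnorm(10),
                        count = rpois(10, 20) + 1L)
  slopes <- diff(nl_rand$response) / diff(nl_rand$g)
  w <- nl_rand$count[-1L] + nl_rand$count[-10L]
  expect_equal(nonlinearity_gain(nl_rand), sum(slopes * w) / sum(w))
})

test_that("response delay finds the first negative trough to sub-sample accuracy", {
  dt <- 0.001
  t_lag <- seq(0, 0.3, by = dt)
  bump <- temporal_filter(-exp(-(t_lag - 0.060)^2 / (2 * 0.01^2)), dt)
  expect_equal(response_delay(bump), 0.060, tolerance = 1e-4)
  # biphasic: trough precedes the late positive peak
  biph <- temporal_filter(-exp(-(t_lag - 0.055)^2 / 2e-4) +
                            0.6 * exp(-(t_lag - 0.120)^2 / 2e-4), dt)
  dense <- seq(0, 0.3, by = 1e-5)
  oracle <- dense[which.min(stats::approx(t_lag, biph$taps, dense)$y)]
  expect_lt(abs(response_delay(biph) - oracle), dt / 2)
  expect_error(response_delay(temporal_filter(exp(-t_lag / 0.05), dt)),
               "negative local minimum")
})

test_that("response offset normalizes 4 s segment means by the whole-record SD", {
  dt <- 0.01
  trace <- c(rep(2, 400), rep(6, 400))  # two 4 s plateaus
  off <- response_offset(trace, dt)
  expect_equal(length(off), 2L)
  expect_equal(off, c(2, 6) / sd(trace))
  set.seed(13)
  white <- rnorm(1200)
  offw <- response_offset(white, dt)
  expect_lt(max(abs(offw)), 3 / sqrt(400))
  expect_error(response_offset(rep(1, 800), dt), "zero")
})

test_that("On/Off ratio reflects baseline-subtracted response strengths", {
  tm <- seq(0, 3, by = 0.01)
  base <- 5
  rate <- rep(base, length(tm))
  on_win <- tm >= 1 & tm < 1.4
  off_win <- tm >= 2 & tm < 2.4
  rate[on_win] <- base + 20
  rate[off_win] <- base + 10
  expect_equal(on_off_ratio(tm, rate, 1, 2), 2)
  # no On response -> ratio 0 (an Off cell)
  rate2 <- rep(base, length(tm)); rate2[off_win] <- base + 10
  expect_equal(on_off_ratio(tm, rate2, 1, 2), 0)
  # equal responses -> 1
  rate3 <- rep(base, length(tm)); rate3[on_win | off_win] <- base + 8
  expect_equal(on_off_ratio(tm, rate3, 1, 2), 1)
  expect_error(on_off_ratio(tm, rep(base, length(tm)), 1, 2), "Off response")
})

test_that("slow rate change is the normalized within-epoch rate trend", {
  tm <- seq(0, 4, by = 0.05)
  expect_equal(slow_rate_change(tm, rep(7, length(tm))), 0)
  # rate rising linearly from r to 2r over the epoch -> 0.5
  expect_equal(slow_rate_change(tm, 10 * (1 + tm / 4)), 0.5, tolerance = 1e-10)
  # rising during low contrast is positive by convention
  expect_gt(slow_rate_change(tm, 5 + tm), 0)
  expect_error(slow_rate_change(tm[1:10], rep(1, 10)), "2 s")
})
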