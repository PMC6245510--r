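test_that("spike removal restores the subthreshold trace and is idempotent", {
  set.seed(3)
  dt <- 0.001
  n <- 20000
  clean <- 5 * sin(2 * pi * 2 * seq_len(n) * dt) + rnorm(n, sd = 0.5) - 60
  # insert 2 ms, 40 mV triangular spike templates
  spk_at <- seq(1000, n - 100, by = 950)
  spiky <- clean
  tmpl <- 40 * c(0.5, 1, 0.5)
  for (i in spk_at) spiky[i:(i + 2L)] <- spiky[i:(i + 2L)] + tmpl
  out <- remove_spikes(spiky, dt)
  expect_lt(sqrt(mean((out - clean)^2)), 1)
  # spike-free traces come back unchanged; repeat application is stable
  expect_identical(remove_spikes(clean, dt), clean)
  expect_equal(remove_spikes(out, dt), out, tolerance = 1e-9)
  expect_error(remove_spikes(clean, dt = 0.005), "2 ms")
})

test_that("reverse correlation recovers a known filter and satisfies the
           variance-matching normalization", {
  set.seed(4)
  dt <- 0.001
  s <- quick_stim(duration = 120, contrast = 0.2, seed = 10)
  t_lag <- seq(0, 0.599, by = dt)
  true_taps <- -(dgamma(t_lag, 5, scale = 0.016) -
                   0.5 * dgamma(t_lag, 5, scale = 0.032))
  truth <- temporal_filter(true_taps / sqrt(sum(true_taps^2)) / dt, dt)
  resp <- apply_filter(truth, s)
  resp <- resp + rnorm(length(resp), sd = 0.1 * sd(resp))
  est <- estimate_filter(s, resp, dt)
  expect_gt(cor(est$taps, truth$taps), 0.99)
  # normalization: var(g) = var(s) on the post-burn-in region
  g <- linear_prediction(est, s)
  b <- attr(g, "burn_in_samples")
  expect_equal(var(g[-seq_len(b)]), var(s[-seq_len(b)]), tolerance = 1e-6)
})

test_that("a stimulus-independent response yields an uninformative filter", {
  set.seed(5)
  dt <- 0.001
  s <- quick_stim(duration = 120, contrast = 0.2, seed = 11)
  resp <- rnorm(length(s))
  half <- seq_len(length(s) %/% 2)
  est_null <- estimate_filter(s[half], resp[half], dt)
  # out of sample, the filter fit to a shuffled response predicts nothing
  # (the in-sample correlation reflects only the ~600 fitted taps)
  g <- linear_prediction(est_null, s[-half])
  keep <- -seq_len(attr(g, "burn_in_samples"))
  expect_lt(abs(cor(g[keep], resp[-half][keep])), 0.03)
  # whereas a genuine linear response is predicted almost perfectly
  resp2 <- apply_filter(temporal_filter(rep(1, 300), dt), s)
  est_sig <- estimate_filter(s[half], resp2[half], dt)
  g2 <- linear_prediction(est_sig, s[-half])
  expect_gt(cor(g2[keep], resp2[-half][keep]), 0.98)
})

test_that("binned nonlinearity estimation reproduces known response maps", {
  set.seed(6)
  g <- rnorm(50000)
  # linear response: per-bin means on the line
  nl_lin <- estimate_nonlinearity(g, 2 * g, n_bins = 40)
  expect_equal(nl_lin$response, 2 * nl_lin$g, tolerance = 1e-8)
  expect_equal(sum(nl_lin$count), 50000L)
  # sigmoid response matches the analytic curve at bin centers
  sig <- sigmoid_nonlinearity(a = 2, b1 = -0.5, b2 = 0, kappa = 1)
  nl_sig <- estimate_nonlinearity(g, eval_nonlinearity(sig, g), n_bins = 40)
  expect_lt(max(abs(nl_sig$response - eval_nonlinearity(sig, nl_sig$g))), 0.01)
  # shuffled response: flat at the mean
  resp <- eval_nonlinearity(sig, g)
  nl_shuf <- estimate_nonlinearity(g, sample(resp), n_bins = 20)
  expect_lt(diff(range(nl_shuf$response)), 4 * sd(resp) / sqrt(50000 / 20))
  expect_error(estimate_nonlinearity(g[1:10], g[1:10], n_bins = 40), "exceeds")
})

test_that("spike-triggered averages localize the generating bar", {
  set.seed(7)
  stim <- generate_bar_flicker(6, high_contrast = 0.3, low_contrast = 0.3,
                               high_duration = 30, low_duration = 30,
                               n_cycles = 1, rng_seed = 13)
  norm <- normalize_stimulus(stim)
  # spikes locked to positive excursions of bar 3, lagged by 40 ms
  drive <- norm[3L, ]
  lag <- 40L
  p_spk <- pmax(drive, 0) * 0.05
  spk_idx <- which(stats::runif(length(drive)) < c(rep(0, lag), head(p_spk, -lag)))
  spikes <- spike_train(spk_idx * stim$dt, duration = ncol(norm) * stim$dt)
  sta <- spike_triggered_average(stim, spikes, window_length = 0.3)
  energy <- rowSums(sta$map^2)
  expect_equal(which.max(energy), 3L)
  peak_lag <- which.max(abs(sta$map[3L, ]))
  expect_lt(abs(peak_lag - lag), 35L)  # smeared by the 30 ms frame hold
  expect_error(spike_triggered_average(stim, spike_train(numeric(0), 60)),
               "no spikes")
})

test_that("independent Poisson spikes give a vanishing STA", {
  set.seed(8)
  stim <- generate_bar_flicker(4, 0.3, 0.3, 10, 10, 1, rng_seed = 14)
  dur <- ncol(stim$values) * stim$dt
  spikes <- spike_train(sort(stats::runif(4000, 0.4, dur)), dur)
  suppressWarnings(sta <- spike_triggered_average(stim, spikes, 0.3))
  # each STA entry is a mean of n draws of sd = contrast * M
  expect_lt(max(abs(sta$map)), 5 * 0.3 / sqrt(4000 / 30))
})

test_that("temporal PC1 recovers the time course of a rank-1 map", {
  t_lag <- seq(0, 0.3, by = 0.001)
  v <- sin(2 * pi * 5 * t_lag) * exp(-t_lag / 0.1)
  space <- c(0.2, 1, 0.4, -0.1)
  stf <- structure(list(map = outer(space, v), dt = 0.001),
                   class = "spatiotemporal_filter")
  pc1 <- temporal_course_pc1(stf)
  cc <- cor(pc1$taps, v)
  expect_gt(abs(cc), 1 - 1e-10)
  # sign convention: largest lobe matches the map's largest entry, and the
  # result is deterministic across calls
  expect_gt(cc, 0)
  expect_identical(pc1, temporal_course_pc1(stf))
  # small perturbations move the component by O(noise)
  set.seed(9)
  stf2 <- stf
  stf2$map <- stf$map + matrix(rnorm(length(stf$map), sd = 1e-3),
                               nrow(stf$map))
  pc2 <- temporal_course_pc1(stf2)
  expect_gt(cor(pc2$taps, pc1$taps), 0.999)
  stf0 <- structure(list(map = matrix(0, 2, 5), dt = 0.001),
                    class = "spatiotemporal_filter")
  expect_error(temporal_course_pc1(stf0), "degenerate")
})
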