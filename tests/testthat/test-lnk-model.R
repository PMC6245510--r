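test_that("filter application equals the brute-force convolution oracle", {
  set.seed(1)
  dt <- 0.001
  filt <- temporal_filter(rnorm(50), dt)
  x <- rnorm(1000)
  g <- apply_filter(filt, x)
  expect_equal(as.numeric(g), convolve_oracle(x, filt$taps, dt),
               tolerance = 1e-12)
  expect_equal(attr(g, "burn_in_samples"), 50L)
  # identity kernel and zero stimulus
  delta <- temporal_filter(c(1 / dt, rep(0, 9)), dt)
  expect_equal(as.numeric(apply_filter(delta, x)), x, tolerance = 1e-12)
  expect_equal(max(abs(apply_filter(filt, rep(0, 100)))), 0)
  expect_error(apply_filter(filt, x, dt = 0.002), "match")
})

test_that("sigmoid nonlinearity saturates, is monotone, and hits 1/2 at zero", {
  nl <- sigmoid_nonlinearity(a = 1, b1 = 0, b2 = 0, kappa = 1)
  expect_equal(eval_nonlinearity(nl, 0), 0.5)
  expect_equal(eval_nonlinearity(nl, 50), 1)
  expect_equal(eval_nonlinearity(nl, -50), 0)
  # monotone non-decreasing on a dense grid for a spread of parameters
  x <- seq(-5, 5, by = 0.01)
  for (a in c(0.5, 1, 4, 20)) {
    u <- eval_nonlinearity(sigmoid_nonlinearity(a, -0.7, 0.05, 2), x)
    expect_true(all(diff(u) >= 0))
    expect_true(all(u >= 0 & u <= 1))
  }
  # the ka-denominator dialect reproduces the normalized form when
  # k_a = 2^a (the two parameterizations then coincide)
  a <- 3
  nl2 <- sigmoid_nonlinearity(a, 0.3, 0, 1.5)
  expect_equal(eval_nonlinearity(nl2, x),
               eval_nonlinearity(nl2, x, dialect = "ka_denominator", k_a = 2^a))
  expect_error(sigmoid_nonlinearity(a = 25), "\\[0, 20\\]")
})

test_that("kinetics simulation matches matrix-exponential propagation", {
  skip_if_not_installed("Matrix")
  kin <- test_kinetics()
  set.seed(2)
  u <- rep(runif(40), each = 25)  # piecewise-constant drive
  tr <- simulate_kinetics(kin, u, 0.001, initial = c(0.7, 0.1, 0.1, 0.1))
  oracle <- kinetics_oracle(kin, u, 0.001, c(0.7, 0.1, 0.1, 0.1))
  expect_lt(max(abs(tr$occupancies - oracle)), 1e-8)
  # occupancies conserved and within [0, 1]
  expect_lt(max(abs(rowSums(tr$occupancies) - 1)), 1e-9)
  expect_true(all(tr$occupancies >= -1e-12 & tr$occupancies <= 1 + 1e-12))
})

test_that("u = 0 freezes the resting state and bad inputs are rejected", {
  kin <- test_kinetics()
  tr <- simulate_kinetics(kin, rep(0, 100), 0.001)
  expect_true(all(tr$occupancies[, 1L] == 1))
  expect_error(simulate_kinetics(kin, rep(0.5, 5), 0.001,
                                 initial = c(2, 0, 0, 0)), "sum")
  expect_error(simulate_kinetics(kin, rep(1.5, 5), 0.001), "within")
})

test_that("quantized propagation approximates the exact path", {
  kin <- test_kinetics()
  set.seed(5)
  u <- runif(2000)
  exact <- simulate_kinetics(kin, u, 0.001)$occupancies
  quant <- simulate_kinetics(kin, u, 0.001, u_bins = 4096)$occupancies
  expect_lt(max(abs(exact - quant)), 1e-3)
})

test_that("steady state solves pQ = 0 and agrees with long simulations", {
  kin <- test_kinetics()
  for (u0 in c(0.1, 0.5, 1)) {
    p <- steady_state_occupancy(kin, u0)
    Q <- lnkadapt:::kinetics_Q(kin, u0)
    expect_lt(max(abs(p %*% Q)), 1e-10)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    # nullspace of t(Q) via singular decomposition (independent route)
    v <- svd(t(Q))$v[, 4L]
    expect_equal(p, v / sum(v), tolerance = 1e-8)
  }
  # long-horizon simulation converges to the fixed point
  rates <- c(kin$k_a, kin$k_fi, kin$k_fr, kin$k_si, kin$k_sr)
  t_end <- 100 / min(rates)
  tr <- simulate_kinetics(kin, rep(0.5, round(t_end / 0.001)), 0.001)
  expect_equal(as.numeric(tr$occupancies[nrow(tr$occupancies), ]),
               steady_state_occupancy(kin, 0.5), tolerance = 1e-6)
  expect_error(steady_state_occupancy(kin, 0), "unique")
})

test_that("cell output is additive over pathways and affine in scale/offset", {
  cell <- make_reference_cell(3)
  s <- quick_stim(duration = 8, contrast = 0.3, seed = 6)
  r <- simulate_cell(cell, s, 0.001, return_pathways = TRUE)
  contribs <- attr(r, "pathway_outputs")
  expect_equal(as.numeric(r),
               contribs$Off + contribs$On + cell$output_offset,
               tolerance = 1e-12)
  # pathway weight enters only at summation: simulate_pathway is unweighted
  A_on <- simulate_pathway(cell$pathways$On, s)
  expect_equal(contribs$On, cell$output_scale * cell$pathways$On$weight * A_on,
               tolerance = 1e-12)
  # affine in (scale, offset)
  cell2 <- cell
  cell2$output_scale <- 2 * cell$output_scale
  cell2$output_offset <- cell$output_offset + 7
  r2 <- simulate_cell(cell2, s, 0.001)
  expect_equal(r2, 2 * (as.numeric(r) - cell$output_offset) +
                 cell$output_offset + 7, tolerance = 1e-10)
  # zero weights -> constant offset
  cell0 <- cell
  cell0$pathways$On$weight <- 0
  cell0$pathways$Off$weight <- 0
  expect_equal(unique(round(simulate_cell(cell0, s, 0.001), 12)),
               cell$output_offset)
})

test_that("constant stimulus settles at the steady-state prediction", {
  cell <- make_reference_cell(1)
  p1 <- cell$pathways$Off
  u0 <- eval_nonlinearity(p1$nonlinearity, 0)
  dur <- 10 / min(unlist(p1$kinetics[c("k_si", "k_sr")]))
  A <- simulate_pathway(p1, rep(0, round(dur / 0.001)))
  expect_equal(A[length(A)], steady_state_occupancy(p1$kinetics, u0)[2L],
               tolerance = 1e-6)
})

test_that("silencing a pathway zeroes its weight and preserves additivity", {
  cell <- make_reference_cell(2)
  s <- quick_stim(duration = 6, contrast = 0.25, seed = 8)
  r_full <- simulate_cell(cell, s, 0.001, return_pathways = TRUE)
  r_off <- simulate_cell(silence_pathway(cell, "On"), s, 0.001)
  on_contrib <- attr(r_full, "pathway_outputs")$On
  expect_equal(as.numeric(r_full), r_off + on_contrib, tolerance = 1e-10)
  # silencing a zero-weight pathway is a no-op
  c0 <- silence_pathway(cell, "On")
  expect_identical(silence_pathway(c0, "On"), c0)
  expect_error(silence_pathway(lnk_cell(list(cell$pathways$Off)), "On"),
               "no pathway")
})

test_that("contrast steps produce the adaptation signature in the active state", {
  # the slow pool depletes after a step to high contrast, so the active
  # state transiently overshoots its adapted level and then declines; the
  # effect is averaged over stimulus realizations because single-trial
  # windows are noisy
  cell <- make_reference_cell(1)
  early <- late <- numeric(0)
  for (i in 1:20) {
    sched <- contrast_schedule(c(0, 16), c(16, 14), c(0.05, 0.35))
    s <- normalize_stimulus(generate_flicker(sched, rng_seed = 300 + i))
    A <- simulate_pathway(cell$pathways$Off, s)
    early <- c(early, mean(A[16020:16820]))  # first 0.8 s after the step
    late <- c(late, mean(A[20000:29900]))    # adapted plateau
  }
  expect_gt(mean(early), mean(late) * 1.02)
})
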