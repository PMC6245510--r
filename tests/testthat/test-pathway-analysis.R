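test_that("pathway decomposition is exact under additivity and robust to noise", {
  cell <- make_reference_cell(4)
  sched <- contrast_schedule(0, 12, 0.3)
  stim <- generate_flicker(sched, rng_seed = 20)
  pair <- synth_apb_pair(cell, stim, noise_sd = 0, seed = 1)
  dec <- decompose_pathways(pair$control$clean, pair$apb$clean)
  truth_on <- attr(simulate_cell(cell, normalize_stimulus(stim), stim$dt,
                                 return_pathways = TRUE), "pathway_outputs")$On
  expect_equal(dec$on, truth_on - mean(truth_on), tolerance = 1e-9)
  expect_equal(dec$off, pair$apb$clean - mean(pair$apb$clean))
  # control == blocked -> zero On contribution
  z <- decompose_pathways(pair$apb$clean, pair$apb$clean)
  expect_true(all(z$on == 0))
  # 5% noise: recovered On correlates > 0.99 with the true contribution
  sig_sd <- sd(pair$control$clean)
  pairn <- synth_apb_pair(cell, stim, noise_sd = 0.05 * sig_sd, seed = 2)
  decn <- decompose_pathways(pairn$control$noisy, pairn$apb$noisy)
  keep <- -(1:2000)
  expect_gt(cor(decn$on[keep], truth_on[keep]), 0.99)
  expect_error(decompose_pathways(1:5, 1:4), "length")
})

test_that("component exchange is an involution that preserves components", {
  cell <- make_reference_cell(5)
  for (which in c("nonlinearity", "kinetics")) {
    sw <- exchange_components(cell, which)
    expect_identical(sw$pathways$Off[[which]], cell$pathways$On[[which]])
    expect_identical(sw$pathways$On[[which]], cell$pathways$Off[[which]])
    expect_identical(exchange_components(sw, which), cell)
  }
  # identical components -> identical output
  cell_same <- cell
  cell_same$pathways$On$nonlinearity <- cell$pathways$Off$nonlinearity
  s <- quick_stim(6, 0.25, seed = 21)
  expect_equal(simulate_cell(exchange_components(cell_same, "nonlinearity"),
                             s, 0.001),
               simulate_cell(cell_same, s, 0.001))
  expect_error(exchange_components(lnk_cell(list(cell$pathways$Off)),
                                   "kinetics"), "two-pathway")
})

test_that("alpha/beta fits recover known magnitude curves", {
  contrasts <- seq(0.05, 0.35, by = 0.05)
  # sigma proportional to contrast: slope one, the non-adapting reference
  ab_lin <- fit_alpha_beta(contrasts, contrasts)
  expect_equal(ab_lin$alpha, 1, tolerance = 1e-12)
  # constant sigma: slope zero
  expect_equal(fit_alpha_beta(contrasts, rep(0.4, 7))$alpha, 0,
               tolerance = 1e-12)
  # saturating exponential self-consistency
  sig <- 0.8 * (1 - exp(-contrasts / 0.1))
  ab <- fit_alpha_beta(contrasts, sig)
  expect_equal(ab$beta, 0.1, tolerance = 1e-6)
  expect_equal(ab$sigma_inf, 0.8, tolerance = 1e-6)
  expect_lt(ab$residual, 1e-8)
  expect_error(fit_alpha_beta(contrasts[1:3], sig[1:3]), "4 contrast")
})

test_that("pathway magnitude curves follow the normalization conventions", {
  cell <- make_reference_cell(6)
  contrasts <- c(0.05, 0.2, 0.35)
  curves <- pathway_sigma_vs_contrast(cell, contrasts, epoch_length = 14,
                                      rng_seed = 22)
  full <- curves[curves$pathway == "full", ]
  expect_equal(mean(full$sigma), 1)
  expect_true(all(curves$sigma >= 0))
  # single-pathway cell: its curve and the full curve coincide
  solo <- lnk_cell(list(cell$pathways$Off), cell$output_scale)
  sc <- pathway_sigma_vs_contrast(solo, contrasts, epoch_length = 14,
                                  rng_seed = 22)
  expect_equal(sc$sigma[sc$pathway == "Off"], sc$sigma[sc$pathway == "full"])
  # doubling a pathway weight doubles its unnormalized sigma
  r1 <- simulate_cell(cell, quick_stim(10, 0.2, seed = 23), 0.001,
                      return_pathways = TRUE)
  cell2 <- cell
  cell2$pathways$On$weight <- 2 * cell$pathways$On$weight
  r2 <- simulate_cell(cell2, quick_stim(10, 0.2, seed = 23), 0.001,
                      return_pathways = TRUE)
  expect_equal(sd(attr(r2, "pathway_outputs")$On),
               2 * sd(attr(r1, "pathway_outputs")$On), tolerance = 1e-10)
})

test_that("kinetics response curves are flat at zero drive and converge", {
  kin <- test_kinetics()
  kc <- kinetics_response_curve(kin, c(1e-9, 0.1, 0.3), epoch_length = 12,
                                rng_seed = 24)
  expect_lt(kc$sd_A[1L], 1e-6)
  # longer simulation reproduces the curve within sampling error
  kc_long <- kinetics_response_curve(kin, c(1e-9, 0.1, 0.3),
                                     epoch_length = 48, rng_seed = 25)
  expect_equal(kc$sd_A, kc_long$sd_A, tolerance = 0.15)
})

test_that("a single-point kinetics grid reproduces the control cell", {
  cell <- make_reference_cell(7)
  g1 <- bandwidth_grid_search(cell, grid_factor = 5, n_grid = 1,
                              epoch_length = 12, rng_seed = 26,
                              include_single_pathway = FALSE)
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$k_fi, cell$pathways$Off$kinetics$k_fi)
  expect_equal(g1$k_fr, cell$pathways$Off$kinetics$k_fr)
  # control frequencies match a direct simulation of the unmodified cell
  s <- normalize_stimulus(generate_flicker(contrast_schedule(0, 12, 0.05),
                                           rng_seed = lnkadapt:::derive_seed(26, 401L)))
  r <- simulate_cell(cell, s, 0.001)
  filt <- estimate_filter(s[-(1:2000)], r[-(1:2000)], 0.001)
  expect_equal(g1$median_f_low, median_frequency(power_spectrum(filt)),
               tolerance = 1e-9)
})

test_that("convex hull areas follow the shoelace formula", {
  # unit square plus interior points
  x <- c(0, 1, 1, 0, 0.5, 0.2)
  y <- c(0, 0, 1, 1, 0.5, 0.7)
  expect_equal(convex_hull_area(x, y), 1)
  expect_equal(convex_hull_area(c(0, 1), c(0, 1)), 0)  # degenerate
  expect_equal(convex_hull_area(c(0, 2, 0), c(0, 0, 3)), 3)
})
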