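#' Decompose control and pathway-blocked responses into On and Off parts
#'
#' Under the additive two-pathway model, the response with the On pathway
#' blocked is the Off contribution, and the On contribution is the control
#' response minus the blocked response. Both series are mean-subtracted
#' before subtraction so slow offsets do not leak into the decomposition.
#'
#' @param control Response under control conditions (mV).
#' @param blocked Response with the On pathway blocked (mV).
#' @return A list with `on` and `off` (mean-subtracted series).
#' @export
decompose_pathways <- function(control, blocked) {
  if (length(control) != length(blocked)) {
    stop_invalid("control and blocked traces differ in length")
  }
  control <- control - mean(control)
  blocked <- blocked - mean(blocked)
  list(on = control - blocked, off = blocked)
}

#' Pathway output magnitude versus contrast
#'
#' Simulates the cell at each contrast (steady state, burn-in excluded) and
#' records the standard deviation of each weighted pathway contribution and
#' of the full output. Curves are normalized so the full-cell output SD
#' averaged over contrasts equals one; pathway SDs need not sum to the full
#' SD because the pathway signals partially cancel.
#'
#' @param cell An [lnk_cell()].
#' @param contrasts Contrast levels (>= 2).
#' @param epoch_length Epoch per contrast (s); >= 10 s after burn-in.
#' @param dt Sample interval (s).
#' @param rng_seed Integer seed.
#' @return A data frame of class `pathway_magnitude` with columns
#'   `contrast`, `pathway` (label or "full"), `sigma`.
#' @export
pathway_sigma_vs_contrast <- function(cell, contrasts, epoch_length = 40,
                                      dt = 0.001, rng_seed = 1) {
  if (length(contrasts) < 2L) stop_invalid("need >= 2 contrasts")
  if (epoch_length < lnk_burn_in() + 10) {
    stop_invalid("epoch_length must leave >= 10 s after burn-in")
  }
  burn <- round(lnk_burn_in() / dt)
  rows <- list()
  for (i in seq_along(contrasts)) {
    sched <- contrast_schedule(0, epoch_length, contrasts[i])
    stim <- generate_flicker(sched, dt = dt,
                             rng_seed = derive_seed(rng_seed, 200L + i))
    s <- normalize_stimulus(stim)
    r <- simulate_cell(cell, s, dt, return_pathways = TRUE)
    keep <- -seq_len(burn)
    sig_full <- sd(r[keep])
    contribs <- attr(r, "pathway_outputs")
    for (lab in names(contribs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = contrasts[i], pathway = lab, sigma = sd(contribs[[lab]][keep]))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = contrasts[i], pathway = "full", sigma = sig_full)
  }
  out <- do.call(rbind, rows)
  norm <- mean(out$sigma[out$pathway == "full"])
  out$sigma <- out$sigma / norm
  class(out) <- c("pathway_magnitude", "data.frame")
  out
}

#' Exchange components between the two pathways
#'
#' Swaps either the nonlinearities or the kinetics blocks of a two-pathway
#' cell while leaving filters, weights and everything else unchanged: the
#' in-silico manipulation that tests whether thresholds or release kinetics
#' drive differential pathway adaptation. Exchanging twice restores the
#' original cell.
#'
#' @param cell A two-pathway [lnk_cell()].
#' @param which `"nonlinearity"` or `"kinetics"`.
#' @return An [lnk_cell()].
#' @export
exchange_components <- function(cell, which = c("nonlinearity", "kinetics")) {
  which <- match.arg(which)
  if (length(cell$pathways) != 2L) {
    stop_invalid("component exchange needs a two-pathway cell")
  }
  tmp <- cell$pathways[[1L]][[which]]
  cell$pathways[[1L]][[which]] <- cell$pathways[[2L]][[which]]
  cell$pathways[[2L]][[which]] <- tmp
  cell
}

#' Fit the adaptation summary statistics alpha and beta to sigma(c)
#'
#' `alpha` is the ordinary least-squares average slope of the pathway output
#' SD versus contrast: a non-adapting pathway whose output SD is proportional
#' to contrast has `alpha = 1` (when sigma is expressed in the same units as
#' contrast), while adaptation flattens the curve and lowers `alpha`.
#' `beta` is the decay constant of the saturating exponential
#' `sigma(c) = sigma_inf * (1 - exp(-c/beta))` fit by least squares
#' (profiled: for each `beta`, `sigma_inf` has a closed form; `beta` is then
#' found by one-dimensional minimization). Small `beta` means the pathway's
#' output saturates - i.e. adapts - at low contrast.
#'
#' @param contrasts Contrast values (>= 4).
#' @param sigma Pathway output SD at each contrast.
#' @return A list with `alpha`, `alpha_se`, `beta`, `sigma_inf`, `residual`
#'   (RMS of the exponential fit).
#' @export
fit_alpha_beta <- function(contrasts, sigma) {
  if (length(contrasts) < 4L) stop_invalid("need >= 4 contrast points")
  if (length(contrasts) != length(sigma)) stop_invalid("length mismatch")
  fit <- lm(sigma ~ contrasts)
  alpha <- unname(coef(fit)[2L])
  alpha_se <- suppressWarnings(summary(fit))$coefficients[2L, 2L]
  sse_of <- function(beta) {
    basis <- 1 - exp(-contrasts / beta)
    s_inf <- sum(basis * sigma) / sum(basis^2)
    sum((sigma - s_inf * basis)^2)
  }
  opt <- optimize(sse_of, interval = c(1e-4, 10), tol = 1e-10)
  beta <- opt$minimum
  basis <- 1 - exp(-contrasts / beta)
  s_inf <- sum(basis * sigma) / sum(basis^2)
  if (!is.finite(opt$objective)) {
    stop_invalid("exponential fit failed to converge")
  }
  list(alpha = alpha, alpha_se = alpha_se, beta = beta, sigma_inf = s_inf,
       residual = sqrt(opt$objective / length(sigma)))
}

#' Component-exchange analysis
#'
#' Computes per-pathway output-magnitude curves sigma(c) and their alpha/beta
#' statistics for the control cell and for the cells with nonlinearities or
#' kinetics blocks exchanged between pathways. Comparing how much each
#' exchange moves alpha and beta identifies which component carries the
#' differential adaptation.
#'
#' @inheritParams pathway_sigma_vs_contrast
#' @return A data frame of class `exchange_result` with columns `condition`
#'   (`control`, `swap_nonlinearity`, `swap_kinetics`), `pathway`, `alpha`,
#'   `beta`, `residual`.
#' @export
exchange_analysis <- function(cell, contrasts = seq(0.05, 0.35, by = 0.05),
                              epoch_length = 40, dt = 0.001, rng_seed = 1) {
  cells <- list(control = cell,
                swap_nonlinearity = exchange_components(cell, "nonlinearity"),
                swap_kinetics = exchange_components(cell, "kinetics"))
  rows <- list()
  for (cond in names(cells)) {
    curves <- pathway_sigma_vs_contrast(cells[[cond]], contrasts,
                                        epoch_length, dt, rng_seed)
    for (lab in setdiff(unique(curves$pathway), "full")) {
      sub <- curves[curves$pathway == lab, ]
      ab <- fit_alpha_beta(sub$contrast, sub$sigma)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, pathway = lab, alpha = ab$alpha, beta = ab$beta,
        residual = ab$residual)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("exchange_result", "data.frame")
  out
}

#' Kinetics-block response curve under the canonical nonlinearity
#'
#' Drives a kinetics block with `u(t) = max(g(t), 0)` where `g(t)` is
#' frame-held Gaussian noise with SD equal to the contrast, so both the mean
#' and SD of `u(t)` grow linearly with contrast. Records the SD of the active
#' state `A(t)` against the mean drive `<u>`: the signature of kinetic
#' adaptation is that `sd(A)` rises quickly at low `<u>` and then with a
#' decreasing rate.
#'
#' One unit-variance frame-noise realization is drawn per curve and rescaled
#' by each contrast (common random numbers), so differences between adjacent
#' grid points reflect the kinetics, not independent sampling noise.
#'
#' @param kin An [lnk_kinetics()].
#' @param contrasts Contrast grid.
#' @param epoch_length Epoch per contrast (s).
#' @param dt Sample interval (s).
#' @param frame_duration Frame hold (s).
#' @param rng_seed Integer seed.
#' @return A data frame of class `kinetics_response_curve` with columns
#'   `contrast`, `mean_u`, `sd_A`.
#' @export
kinetics_response_curve <- function(kin, contrasts, epoch_length = 40,
                                    dt = 0.001, frame_duration = 0.030,
                                    rng_seed = 1) {
  frame_len <- n_samples_of(frame_duration, dt)
  n_frames <- round(epoch_length / frame_duration)
  burn <- round(lnk_burn_in() / dt)
  rows <- list()
  nl0 <- canonical_nonlinearity()
  z <- with_seed(derive_seed(rng_seed, 300L),
                 frame_held_gaussian(n_frames, frame_len, 0, 1))
  for (i in seq_along(contrasts)) {
    u <- pmin(eval_nonlinearity(nl0, contrasts[i] * z), 1)
    u0 <- max(mean(u), 1e-6)
    p0 <- steady_state_occupancy(kin, u0)
    traj <- simulate_kinetics(kin, u, dt, initial = p0)
    A <- traj$occupancies[-seq_len(burn), 2L]
    rows[[i]] <- data.frame(contrast = contrasts[i],
                            mean_u = mean(u[-seq_len(burn)]), sd_A = sd(A))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_u), ]
  rownames(out) <- NULL
  class(out) <- c("kinetics_response_curve", "data.frame")
  out
}

#' Grid search over Off-pathway fast kinetics rates
#'
#' Varies the fast inactivation and fast recovery rates of the Off pathway on
#' a log-spaced grid spanning `[value/grid_factor, value*grid_factor]`,
#' simulates at a low and a high contrast, fits LN filters to the model
#' output at each contrast, and records the median frequencies. Run for the
#' Off pathway alone and (optionally) for the intact two-pathway cell, the
#' comparison shows how much more bandwidth-adaptation territory two pathways
#' can span than one.
#'
#' @param cell A two-pathway [lnk_cell()]; On-pathway parameters are never
#'   varied.
#' @param grid_factor Span factor (> 1); default 5, i.e. a factor of 25 total.
#' @param n_grid Grid points per axis; default 9.
#' @param contrast_low,contrast_high The probe contrasts; defaults 0.05, 0.35.
#' @param epoch_length Epoch per contrast per grid point (s).
#' @param dt Sample interval (s).
#' @param include_single_pathway Also run the Off-alone configuration.
#' @param rng_seed Integer seed (same stimuli across grid points).
#' @return A data frame of class `bandwidth_grid` with columns
#'   `configuration` (`off_alone`, `two_pathway`), `k_fi`, `k_fr`,
#'   `median_f_low`, `median_f_high`.
#' @export
bandwidth_grid_search <- function(cell, grid_factor = 5, n_grid = 9,
                                  contrast_low = 0.05, contrast_high = 0.35,
                                  epoch_length = 30, dt = 0.001,
                                  include_single_pathway = TRUE,
                                  rng_seed = 1) {
  if (length(cell$pathways) != 2L) stop_invalid("need a two-pathway cell")
  if (grid_factor < 1) stop_invalid("grid_factor must be >= 1")
  off <- cell$pathways[["Off"]]
  grid_of <- function(v) {
    if (n_grid == 1L) v else exp(seq(log(v / grid_factor), log(v * grid_factor),
                                     length.out = n_grid))
  }
  kfi_grid <- grid_of(off$kinetics$k_fi)
  kfr_grid <- grid_of(off$kinetics$k_fr)
  # shared stimuli across grid points so differences reflect parameters only
  probe <- c(contrast_low, contrast_high)
  stims <- lapply(seq_along(probe), function(i) {
    sched <- contrast_schedule(0, epoch_length, probe[i])
    normalize_stimulus(generate_flicker(sched, dt = dt,
                                        rng_seed = derive_seed(rng_seed, 400L + i)))
  })
  burn <- round(lnk_burn_in() / dt)
  configs <- if (include_single_pathway) c("off_alone", "two_pathway") else
    "two_pathway"
  rows <- list()
  for (config in configs) {
    for (kfi in kfi_grid) for (kfr in kfr_grid) {
      mod <- cell
      mod$pathways[["Off"]]$kinetics$k_fi <- kfi
      mod$pathways[["Off"]]$kinetics$k_fr <- kfr
      if (config == "off_alone") mod <- silence_pathway(mod, "On")
      med <- vapply(stims, function(s) {
        r <- simulate_cell(mod, s, dt)
        filt <- estimate_filter(s[-seq_len(burn)], r[-seq_len(burn)], dt)
        median_frequency(power_spectrum(filt))
      }, numeric(1L))
      rows[[length(rows) + 1L]] <- data.frame(
        configuration = config, k_fi = kfi, k_fr = kfr,
        median_f_low = med[1L], median_f_high = med[2L])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bandwidth_grid", "data.frame")
  out
}

#' Convex-hull area of a set of 2-D points
#'
#' Shoelace area of the convex hull; used to compare the span of
#' (low-contrast, high-contrast) median-frequency behaviors across model
#' configurations.
#'
#' @param x,y Point coordinates.
#' @return Hull area (product of the axis units).
#' @export
convex_hull_area <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(0)
  h <- grDevices::chull(x, y)
  xs <- x[h]; ys <- y[h]
  n <- length(h)
  abs(sum(xs * ys[c(2:n, 1L)] - xs[c(2:n, 1L)] * ys)) / 2
}
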