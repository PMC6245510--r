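#' Raised-cosine temporal basis
#'
#' Log-spaced raised-cosine bumps over a causal window: a standard smooth,
#' low-dimensional parameterization for neural temporal filters. Earlier
#' bumps are narrow (fast structure), later bumps wide (slow structure).
#'
#' @param n_basis Number of basis functions (default 12).
#' @param window_length Filter window (s); default 0.6 s.
#' @param dt Sample interval (s).
#' @param log_offset Warping offset (s) controlling how strongly bump widths
#'   grow with lag.
#' @return An `n_samples x n_basis` matrix; columns have unit L2 norm.
#' @export
raised_cosine_basis <- function(n_basis = 12, window_length = 0.6, dt = 0.001,
                                log_offset = 0.02) {
  t <- seq(0, window_length - dt, by = dt)
  wt <- log(t + log_offset)
  centers <- seq(min(wt), max(wt), length.out = n_basis)
  width <- (centers[2L] - centers[1L]) * 2
  B <- sapply(centers, function(ct) {
    arg <- pmin(pmax((wt - ct) * pi / width, -pi), pi)
    (cos(arg) + 1) / 2
  })
  sweep(B, 2L, sqrt(colSums(B^2)), "/")
}

#' Interleaved k-fold segment assignment
#'
#' Divides a record into consecutive blocks (default 300 ms) assigned
#' round-robin to folds, so every fold samples the whole recording and all
#' contrast epochs. Any incomplete trailing block is dropped.
#'
#' @param n_samples Record length in samples.
#' @param dt Sample interval (s).
#' @param n_folds Number of folds (default 5).
#' @param segment_length Block duration (s); default 0.3 s.
#' @return A list of `n_folds` integer index vectors (disjoint, jointly
#'   covering all complete blocks).
#' @export
kfold_segments <- function(n_samples, dt, n_folds = 5, segment_length = 0.3) {
  if (n_folds < 2L) stop_invalid("n_folds must be >= 2")
  blk <- n_samples_of(segment_length, dt)
  n_blocks <- n_samples %/% blk
  if (n_blocks < n_folds) stop_invalid("record shorter than n_folds segments")
  folds <- vector("list", n_folds)
  for (b in seq_len(n_blocks)) {
    f <- ((b - 1L) %% n_folds) + 1L
    folds[[f]] <- c(folds[[f]], ((b - 1L) * blk + 1L):(b * blk))
  }
  folds
}

#' Pearson correlation on a sample mask
#'
#' @param model_out,data Series of equal length.
#' @param mask Integer indices to evaluate on (burn-in excluded by caller).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
masked_correlation <- function(model_out, data, mask = seq_along(data)) {
  if (length(mask) == 0L) stop_invalid("empty mask")
  a <- model_out[mask]; b <- data[mask]
  if (sd(a) == 0 || sd(b) == 0) stop_invalid("zero variance on mask")
  cor(a, b)
}

#' Response reliability (noise ceiling)
#'
#' From two repeats of the identical stimulus, each modelled as signal plus
#' independent noise, the repeat-to-repeat correlation is
#' `var(signal)/var(total)`, so the maximum correlation any model of the
#' signal can reach against a single repeat is its square root:
#' `ceiling = sqrt(max(cor(repeat_a, repeat_b), 0))`.
#'
#' @param repeat_a,repeat_b Responses to the identical stimulus sequence.
#' @return The ceiling correlation in `[0, 1]`.
#' @export
noise_ceiling <- function(repeat_a, repeat_b) {
  sqrt(max(cor(repeat_a, repeat_b), 0))
}

#' Fit configuration
#'
#' @param n_basis Raised-cosine basis functions for `F_LNK` (default 12).
#' @param window_length Filter window (s).
#' @param n_restarts Random multi-start restarts (default 8).
#' @param maxit_search,maxit_polish Optimizer iteration budgets for the
#'   restart phase and the final polish.
#' @param n_folds Cross-validation folds (default 5).
#' @param fold_segment_length Interleaved block length (s); default 0.3.
#' @param rate_bounds Log10 bounds for all rate constants (1/s).
#' @param a_bounds Bounds for the nonlinearity exponent.
#' @param b1_bounds,b2_bounds Bounds for the nonlinearity offsets.
#' @param ridge Ridge penalty on basis weights.
#' @param rng_seed Master seed; restart seeds derive from it.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_basis = 12, window_length = 0.6, n_restarts = 8,
                       maxit_search = 150, maxit_polish = 400,
                       n_folds = 5, fold_segment_length = 0.3,
                       rate_bounds = c(-1, 2.7), a_bounds = c(0.2, 20),
                       b1_bounds = c(-4, 2), b2_bounds = c(0, 0.3),
                       ridge = 1e-4, rng_seed = 1) {
  if (n_folds < 2L) stop_invalid("n_folds must be >= 2")
  structure(as.list(environment()), class = "fit_config")
}

# ---- internal fitting machinery ------------------------------------------

# parameter vector layout per pathway:
#   n_basis filter weights, a, b1, b2, log10 rates (ka, kfi, kfr, ksi, ksr)
n_par_pathway <- function(cfg) cfg$n_basis + 3L + 5L

unpack_pathway <- function(theta, cfg, label) {
  nb <- cfg$n_basis
  w <- theta[seq_len(nb)]
  a <- theta[nb + 1L]; b1 <- theta[nb + 2L]; b2 <- theta[nb + 3L]
  rates <- 10^theta[nb + 3L + 1:5]
  list(w = w, a = a, b1 = b1, b2 = b2,
       kin = lnk_kinetics(rates[1L], rates[2L], rates[3L], rates[4L], rates[5L]),
       label = label)
}

# active state of one pathway from precomputed basis-convolved stimulus X;
# u_bins > 0 quantizes u inside the optimizer for speed (exact otherwise)
pathway_A_from_X <- function(X, par, dt, burn, u_bins = 0) {
  g <- drop(X %*% par$w)
  sg <- sd(g)
  if (sg < 1e-12) return(NULL)
  kappa <- 1 / sg
  if (u_bins > 0) {
    A <- lnk_pathway_active_cpp(g, par$a, par$b1, par$b2, kappa,
                                par$kin$k_a, par$kin$k_fi, par$kin$k_fr,
                                par$kin$k_si, par$kin$k_sr,
                                "slow_recovery" %in% par$kin$u_scaled_rates,
                                dt, as.integer(burn), as.integer(u_bins))
    return(list(A = A, kappa = kappa))
  }
  nl <- sigmoid_nonlinearity(par$a, par$b1, par$b2, kappa)
  u <- eval_nonlinearity(nl, g)
  u0 <- max(mean(u[seq_len(burn)]), 1e-6)
  p0 <- steady_state_occupancy(par$kin, u0)
  traj <- simulate_kinetics(par$kin, u, dt, initial = p0, u_bins = u_bins)
  list(A = traj$occupancies[, 2L], kappa = kappa)
}

# objective: 1 - correlation achieved by the affine-profiled pathway sum,
# plus a small ridge on the basis weights. scale/offset/weights are solved in
# closed form by regressing resp on the pathway active states.
lnk_objective <- function(theta, X, resp, dt, burn, cfg, n_pathways, mask,
                          u_bins = 4096) {
  npp <- n_par_pathway(cfg)
  Amat <- matrix(NA_real_, length(resp), n_pathways)
  for (p in seq_len(n_pathways)) {
    par <- unpack_pathway(theta[(p - 1L) * npp + seq_len(npp)], cfg, p)
    res <- tryCatch(pathway_A_from_X(X, par, dt, burn, u_bins),
                    error = function(e) NULL)
    if (is.null(res)) return(2)
    Amat[, p] <- res$A
  }
  Am <- Amat[mask, , drop = FALSE]
  if (any(apply(Am, 2L, sd) < 1e-12)) return(2)
  r <- if (n_pathways == 1L) {
    abs(cor(Am[, 1L], resp[mask]))
  } else {
    pred <- lm.fit(cbind(1, Am), resp[mask])$fitted.values
    if (sd(pred) < 1e-12) return(2)
    cor(pred, resp[mask])
  }
  1 - r + cfg$ridge * sum(theta[rep(seq_len(cfg$n_basis), n_pathways) +
                                  rep((seq_len(n_pathways) - 1L) * npp,
                                      each = cfg$n_basis)]^2)
}

random_start <- function(cfg, n_pathways, polarity_hint) {
  npp <- n_par_pathway(cfg)
  theta <- numeric(npp * n_pathways)
  for (p in seq_len(n_pathways)) {
    w <- rnorm(cfg$n_basis, 0, 0.5)
    # bias the early bumps toward the hinted polarity so restarts explore
    # both On-like and Off-like filters
    w[1:4] <- w[1:4] + polarity_hint[p] * abs(rnorm(4, 1, 0.3))
    w <- w / sqrt(sum(w^2))
    a <- runif(1, 0.5, 4)
    b1 <- runif(1, -2, 0)
    b2 <- 0
    logrates <- c(runif(1, 1, 2.3),   # k_a
                  runif(1, 0.8, 1.8), # k_fi
                  runif(1, 0.5, 1.5), # k_fr
                  runif(1, -0.5, 0.7), # k_si
                  runif(1, -0.5, 0.7)) # k_sr
    theta[(p - 1L) * npp + seq_len(npp)] <- c(w, a, b1, b2, logrates)
  }
  theta
}

theta_bounds <- function(cfg, n_pathways) {
  npp <- n_par_pathway(cfg)
  lo_p <- c(rep(-5, cfg$n_basis), cfg$a_bounds[1L], cfg$b1_bounds[1L],
            cfg$b2_bounds[1L], rep(cfg$rate_bounds[1L], 5L))
  hi_p <- c(rep(5, cfg$n_basis), cfg$a_bounds[2L], cfg$b1_bounds[2L],
            cfg$b2_bounds[2L], rep(cfg$rate_bounds[2L], 5L))
  list(lower = rep(lo_p, n_pathways), upper = rep(hi_p, n_pathways))
}

# assemble an lnk_cell from an optimized parameter vector; scale/offset and
# weights come from the closed-form affine profile on the training mask.
build_cell_from_theta <- function(theta, X, resp, dt, burn, cfg, n_pathways,
                                  mask, basis) {
  npp <- n_par_pathway(cfg)
  pars <- lapply(seq_len(n_pathways), function(p) {
    unpack_pathway(theta[(p - 1L) * npp + seq_len(npp)], cfg, p)
  })
  As <- lapply(pars, function(par) pathway_A_from_X(X, par, dt, burn))
  Amat <- do.call(cbind, lapply(As, `[[`, "A"))
  cf <- lm.fit(cbind(1, Amat[mask, , drop = FALSE]), resp[mask])$coefficients
  offset <- cf[1L]; coefs <- cf[-1L]
  scale <- max(abs(coefs))
  weights <- coefs / scale
  pathways <- vector("list", n_pathways)
  used <- character(0)
  for (p in seq_len(n_pathways)) {
    taps <- drop(basis %*% pars[[p]]$w) / dt
    # labels by filter polarity: first extremum negative -> Off
    ext <- taps[which.max(abs(taps))]
    lab <- if (ext < 0) "Off" else "On"
    if (lab %in% used) lab <- setdiff(c("On", "Off"), used)[1L]
    used <- c(used, lab)
    nl <- sigmoid_nonlinearity(pars[[p]]$a, pars[[p]]$b1, pars[[p]]$b2,
                               As[[p]]$kappa)
    pathways[[p]] <- lnk_pathway(temporal_filter(taps, dt), nl,
                                 pars[[p]]$kin, weight = weights[p],
                                 polarity_label = lab)
  }
  lnk_cell(pathways, output_scale = scale, output_offset = offset)
}

#' Fit an LNK model by constrained multi-start optimization
#'
#' Fits one- or two-pathway LNK models to a stimulus/response record. The
#' filter of each pathway is expressed in a raised-cosine basis; nonlinearity
#' parameters and log-rate constants are optimized by bound-constrained
#' quasi-Newton (L-BFGS-B). Optimization is staged: the filter is initialized
#' from the reverse-correlation LN filter (its basis projection; sign-split
#' for two pathways), the nonlinearity and kinetics parameters are
#' multi-started with the filter held fixed, and the best solution is then
#' polished jointly over all parameters. The output scale, offset and pathway
#' weights are profiled in closed form at every objective evaluation (the
#' objective is one minus the correlation achieved by the best affine
#' combination of pathway active states, plus a small ridge on basis
#' weights), and `kappa` is the reciprocal SD of the current filtered
#' stimulus, so the filter amplitude is not a free direction.
#' Cross-validation uses interleaved 300 ms blocks: the staged search runs on
#' the first training set and the remaining folds are warm-started from its
#' solution.
#'
#' @param stim Normalized stimulus vector.
#' @param resp Response vector (de-spiked membrane potential, mV).
#' @param dt Sample interval (s).
#' @param n_pathways 1 or 2.
#' @param config A [fit_config()].
#' @return A list of class `lnk_fit`: `cell` (the fitted [lnk_cell()] from
#'   the full-data refit), `fold_table` (per-fold train/test correlation),
#'   `test_correlation` (mean across folds), `objective`, `seeds`.
#' @export
fit_lnk <- function(stim, resp, dt, n_pathways = 1, config = fit_config()) {
  if (length(stim) != length(resp)) stop_invalid("stim/resp length mismatch")
  if (length(stim) * dt < 100) {
    warning("record shorter than 100 s; fits may be poorly constrained")
  }
  cfg <- config
  basis <- raised_cosine_basis(cfg$n_basis, cfg$window_length, dt)
  X <- sapply(seq_len(ncol(basis)), function(j) {
    causal_convolve(stim, basis[, j] * dt)
  })
  burn <- round(lnk_burn_in() / dt)
  folds <- kfold_segments(length(stim), dt, cfg$n_folds,
                          cfg$fold_segment_length)
  usable <- setdiff(seq_along(stim), seq_len(burn))
  bounds <- theta_bounds(cfg, n_pathways)
  npp <- n_par_pathway(cfg)

  # filter initialization from the reverse-correlation LN filter
  f_ln <- estimate_filter(stim, resp, dt, window_length = cfg$window_length)
  w_ln <- drop(qr.solve(basis, f_ln$taps * dt))
  w_ln <- w_ln / sqrt(sum(w_ln^2))
  w_init <- if (n_pathways == 2L) {
    # split by polarity: one pathway starts at the LN filter, the other at
    # its negation, so the two explore opposite-polarity basins
    list(w_ln, -w_ln)
  } else list(w_ln)

  idx_w <- unlist(lapply(seq_len(n_pathways), function(p) {
    (p - 1L) * npp + seq_len(cfg$n_basis)
  }))
  idx_nl <- setdiff(seq_len(npp * n_pathways), idx_w)

  run_opt <- function(theta0, mask, maxit, free = seq_along(theta0)) {
    obj <- function(th_free) {
      th <- theta0
      th[free] <- th_free
      lnk_objective(th, X, resp, dt, burn, cfg, n_pathways, mask)
    }
    res <- optim(theta0[free], obj, method = "L-BFGS-B",
                 lower = bounds$lower[free], upper = bounds$upper[free],
                 control = list(maxit = maxit, factr = 1e9))
    theta <- theta0
    theta[free] <- res$par
    list(par = theta, value = res$value)
  }

  train1 <- intersect(unlist(folds[-1L]), usable)
  seeds <- vapply(seq_len(cfg$n_restarts), function(i) {
    derive_seed(cfg$rng_seed, 500L + i)
  }, numeric(1L))

  # stage A: multi-start over nonlinearity + kinetics, filter fixed at init
  best <- NULL
  trace <- numeric(cfg$n_restarts)
  for (i in seq_len(cfg$n_restarts)) {
    theta0 <- with_seed(seeds[i], {
      th <- random_start(cfg, n_pathways, rep(0, n_pathways))
      for (p in seq_len(n_pathways)) {
        th[(p - 1L) * npp + seq_len(cfg$n_basis)] <- w_init[[p]]
      }
      th
    })
    res <- run_opt(theta0, train1, cfg$maxit_search, free = idx_nl)
    trace[i] <- res$value
    if (is.null(best) || res$value < best$value) best <- res
  }
  # stage B: joint polish over all parameters
  best <- run_opt(best$par, train1, cfg$maxit_polish)

  # per-fold warm-started refits and test scores
  fold_rows <- vector("list", cfg$n_folds)
  for (f in seq_len(cfg$n_folds)) {
    train <- intersect(unlist(folds[-f]), usable)
    test <- intersect(folds[[f]], usable)
    res_f <- if (f == 1L) best else
      run_opt(best$par, train, max(30L, cfg$maxit_polish %/% 8L))
    cell_f <- build_cell_from_theta(res_f$par, X, resp, dt, burn, cfg,
                                    n_pathways, train, basis)
    pred <- simulate_cell_from_X(cell_f, X, basis, dt)
    fold_rows[[f]] <- data.frame(
      fold = f,
      train_correlation = masked_correlation(pred, resp, train),
      test_correlation = masked_correlation(pred, resp, test))
  }
  fold_table <- do.call(rbind, fold_rows)

  # final cell refit on all usable data from the best parameters
  res_all <- run_opt(best$par, usable, cfg$maxit_polish %/% 2L)
  cell <- build_cell_from_theta(res_all$par, X, resp, dt, burn, cfg,
                                n_pathways, usable, basis)
  structure(list(cell = cell, fold_table = fold_table,
                 test_correlation = mean(fold_table$test_correlation),
                 objective = res_all$value, restart_objectives = trace,
                 seeds = seeds, config = cfg),
            class = "lnk_fit")
}

# simulate a fitted cell reusing the precomputed basis convolution (the
# fitted taps are exact basis combinations, so this equals simulate_cell)
simulate_cell_from_X <- function(cell, X, basis, dt) {
  burn <- round(lnk_burn_in() / dt)
  out <- rep(cell$output_offset, nrow(X))
  for (p in cell$pathways) {
    w_basis <- drop(qr.solve(basis, p$filter$taps * dt))
    g <- drop(X %*% w_basis)
    u <- eval_nonlinearity(p$nonlinearity, g)
    u0 <- max(mean(u[seq_len(burn)]), 1e-6)
    p0 <- steady_state_occupancy(p$kinetics, u0)
    traj <- simulate_kinetics(p$kinetics, u, dt, initial = p0)
    out <- out + cell$output_scale * p$weight * traj$occupancies[, 2L]
  }
  out
}

#' @export
print.lnk_fit <- function(x, ...) {
  cat(sprintf("<lnk_fit> %d pathway(s), mean test correlation %.4f\n",
              length(x$cell$pathways), x$test_correlation))
  print(x$fold_table, row.names = FALSE)
  invisible(x)
}
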