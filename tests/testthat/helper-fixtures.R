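# Shared fixtures: small deterministic objects rebuilt in code at test time.

test_kinetics <- function() lnk_kinetics(k_a = 60, k_fi = 22, k_fr = 9,
                                         k_si = 1.4, k_sr = 2.4)

# brute-force O(n*k) causal convolution oracle
convolve_oracle <- function(x, taps, dt) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    for (k in seq_len(min(t, length(taps)))) {
      out[t] <- out[t] + taps[k] * x[t - k + 1L] * dt
    }
  }
  out
}

# per-interval matrix-exponential propagation oracle for the kinetics block
kinetics_oracle <- function(kin, u, dt, initial = c(1, 0, 0, 0)) {
  Qof <- function(uu) {
    Q <- matrix(0, 4, 4)
    Q[1, 2] <- uu * kin$k_a
    Q[2, 3] <- kin$k_fi
    Q[3, 1] <- kin$k_fr
    Q[3, 4] <- kin$k_si
    Q[4, 1] <- uu * kin$k_sr
    diag(Q) <- -rowSums(Q)
    Q
  }
  P <- initial
  occ <- matrix(NA_real_, length(u), 4L)
  for (t in seq_along(u)) {
    P <- as.numeric(P %*% as.matrix(Matrix::expm(Qof(u[t]) * dt)))
    occ[t, ] <- P
  }
  occ
}

# a quick single-contrast normalized stimulus
quick_stim <- function(duration = 20, contrast = 0.2, dt = 0.001, seed = 1) {
  sched <- contrast_schedule(0, duration, contrast)
  normalize_stimulus(generate_flicker(sched, dt = dt, rng_seed = seed))
}
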