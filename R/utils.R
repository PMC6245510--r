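#' @useDynLib lnkadapt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef cor fft lm lm.fit median nextn optim optimize
#'   pnorm quantile rnorm rpois runif runmed sd var
#' @importFrom utils head
NULL

# Error function via the Gaussian CDF (erf(x) = 2*Phi(x*sqrt(2)) - 1).
erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid("`%s` must be a single positive finite number", name)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop_invalid("`%s` must be a single non-negative finite number", name)
  }
  invisible(x)
}

# Integer number of samples in a duration, guarding against fp fuzz.
n_samples_of <- function(duration, dt) {
  n <- duration / dt
  ni <- round(n)
  if (abs(n - ni) > 1e-8) {
    stop_invalid("duration %g s is not an integer multiple of dt = %g s",
                 duration, dt)
  }
  as.integer(ni)
}

# Draw a sub-seed from a master seed without disturbing the caller's RNG
# stream more than once; keeps derived seeds below 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483562)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# FFT-based causal convolution of a signal with a kernel (lag 0 first);
# output has the length of the signal.
causal_convolve <- function(x, kernel) {
  n <- length(x)
  k <- length(kernel)
  m <- nextn(n + k - 1L, 2L)
  xf <- fft(c(x, numeric(m - n)))
  kf <- fft(c(kernel, numeric(m - k)))
  Re(fft(xf * kf, inverse = TRUE) / m)[seq_len(n)]
}
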