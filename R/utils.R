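# Internal helpers.

# Evaluate `code` under a given seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Flatten region x epoch x sample array to a sample x (region*epoch) matrix
# (columns ordered region-fastest), and back.
.asSampleMatrix <- function(a) {
  d <- dim(a)
  m <- matrix(aperm(a, c(3L, 1L, 2L)), nrow = d[3L], ncol = d[1L] * d[2L])
  attr(m, "reDim") <- d
  m
}

.fromSampleMatrix <- function(m, d) {
  aperm(array(m, dim = c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
}

# Magnitude of the analytic signal of each column (FFT Hilbert transform).
hilbertEnvelope <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2L)] <- 2
  }
  z <- stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
  Mod(z)
}

# Low-pass each column below `cutoff` Hz with an ideal FFT mask.
.fftLowpass <- function(x, fs, cutoff) {
  x <- as.matrix(x)
  n <- nrow(x)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  keep <- as.numeric(f <= cutoff)
  Re(stats::mvfft(stats::mvfft(x) * keep, inverse = TRUE) / n)
}

.stopIfNot <- function(ok, msg, ...) {
  if (!ok) stop(sprintf(msg, ...), call. = FALSE)
}
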