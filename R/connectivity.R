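# Leakage-corrected amplitude envelope correlation (AEC-c).

#' Pairwise zero-lag orthogonalization
#'
#' Removes from `y` its zero-lag least-squares projection onto `x`
#' (regression with intercept), returning a centered residual whose Pearson
#' correlation with `x` is zero to machine precision. This is the pairwise
#' leakage-correction step applied before envelope correlation: any signal
#' component shared instantaneously between two sources (as produced by
#' field spread / source leakage) is eliminated.
#'
#' @param y,x numeric vectors of equal length (at least 2 samples).
#' @return The residual vector `y - proj_x(y)` (centered).
#' @examples
#' x <- sin(seq(0, 10, by = 0.01))
#' y <- 0.7 * x + rnorm(length(x))
#' abs(cor(orthogonalize(y, x), x)) < 1e-10
#' @export
orthogonalize <- function(y, x) {
  .stopIfNot(length(x) == length(y), "'x' and 'y' must have equal length")
  .stopIfNot(length(x) >= 2L, "signals must have at least 2 samples")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  .stopIfNot(sxx > 0, "degenerate regressor: 'x' has zero variance")
  yc <- y - mean(y)
  yc - (sum(xc * yc) / sxx) * xc
}

# Correlation of the Hilbert envelopes of two (centered) signals.
.envCor <- function(a, b) {
  ea <- hilbertEnvelope(a)
  eb <- hilbertEnvelope(b)
  if (stats::sd(ea) == 0 || stats::sd(eb) == 0) return(NA_real_)
  stats::cor(ea, eb)[1L]
}

#' Uncorrected amplitude envelope correlation
#'
#' Pearson correlation of the analytic envelopes of two band-limited
#' signals, without leakage correction. Kept mainly as the contrast arm for
#' leakage-rejection checks: for `y = x + noise` the uncorrected AEC is
#' close to 1 while [aecCorrected()] is close to 0.
#'
#' @param x,y band-limited numeric vectors of equal length.
#' @return Correlation value in `[-1, 1]`.
#' @export
envelopeCorrelation <- function(x, y) {
  .stopIfNot(length(x) == length(y), "'x' and 'y' must have equal length")
  r <- .envCor(x - mean(x), y - mean(y))
  if (is.na(r)) 0 else r
}

#' Leakage-corrected amplitude envelope correlation (AEC-c)
#'
#' The symmetric pairwise leakage-corrected envelope correlation: each
#' signal is orthogonalized with respect to the other at zero lag, and the
#' two directed envelope correlations
#' `cor(env(orth(y|x)), env(x))` and `cor(env(orth(x|y)), env(y))`
#' are averaged arithmetically (signed; no absolute value is taken).
#' Collinear inputs, for which an orthogonalized residual is identically
#' zero, yield 0 by convention with a warning, so degenerate pairs cannot
#' abort a batch run.
#'
#' @param x,y band-limited numeric vectors of equal length.
#' @return AEC-c value in `[-1, 1]`.
#' @examples
#' t <- seq(0, 20, by = 1/250)[-1]
#' x <- sin(2 * pi * 10 * t) * (1 + 0.4 * sin(2 * pi * t))
#' aecCorrected(x, x + 0.01 * rnorm(length(t)))  # ~0: shared signal removed
#' @export
aecCorrected <- function(x, y) {
  .stopIfNot(length(x) == length(y), "'x' and 'y' must have equal length")
  xc <- x - mean(x)
  yc <- y - mean(y)
  if (stats::sd(xc) == 0 || stats::sd(yc) == 0) {
    warning("degenerate signal with zero variance; AEC-c set to 0")
    return(0)
  }
  ryx <- orthogonalize(y, x)          # y with x's contribution removed
  rxy <- orthogonalize(x, y)
  tol <- 1e-12 * max(stats::sd(xc), stats::sd(yc))
  if (stats::sd(ryx) <= tol || stats::sd(rxy) <= tol) {
    warning("collinear signals; AEC-c set to 0 by convention")
    return(0)
  }
  c1 <- .envCor(ryx, xc)
  c2 <- .envCor(rxy, yc)
  if (is.na(c1) || is.na(c2)) {
    warning("constant envelope encountered; AEC-c set to 0 by convention")
    return(0)
  }
  (c1 + c2) / 2
}

#' Per-epoch AEC-c connectivity matrices
#'
#' Computes the full `region x region` AEC-c adjacency matrix for every
#' epoch of a recording in one frequency band. The input is band-pass
#' filtered first (unless `filter = FALSE`, for data already limited to the
#' requested band), then for each epoch every ordered pair of regions is
#' orthogonalized, enveloped and correlated; the two directions are
#' averaged into a symmetric matrix with zero diagonal.
#'
#' The per-epoch computation is vectorized: all pairwise residuals of an
#' epoch are enveloped in a single FFT batch. Results are identical to
#' calling [aecCorrected()] pair by pair.
#'
#' @param ts an [EpochedTimeSeries-class] with at least 2 regions.
#' @param band a [BandSpec-class].
#' @param filter band-pass filter the input first? (default `TRUE`).
#' @param order,padSamples,method passed to [bandpassFilter()].
#' @return A [ConnectivityStack-class] with one matrix per epoch.
#' @export
connectivityStack <- function(ts, band, filter = TRUE, order = 450,
                              padSamples = 2000, method = "fft") {
  stopifnot(is(ts, "EpochedTimeSeries"), is(band, "BandSpec"))
  .stopIfNot(nRegions(ts) >= 2L, "at least 2 regions are required")
  if (filter)
    ts <- bandpassFilter(ts, band, order = order, padSamples = padSamples,
                         method = method)
  R <- nRegions(ts); E <- nEpochs(ts); n <- nSamples(ts)
  pairs <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)  # i < j
  out <- array(0, dim = c(R, R, E))
  degenerate <- FALSE
  for (e in seq_len(E)) {
    M <- t(ts@data[, e, ])                       # samples x regions
    M <- sweep(M, 2L, colMeans(M))
    cp <- crossprod(M)                           # zero-lag cross products
    v <- diag(cp)
    if (any(v <= 0)) {
      degenerate <- TRUE
      v[v <= 0] <- NA_real_
    }
    env0 <- hilbertEnvelope(M)                   # env(x) per region
    # residual of column b regressed on column a, all ordered pairs (a, b)
    a <- c(pairs[, 1L], pairs[, 2L])
    b <- c(pairs[, 2L], pairs[, 1L])
    beta <- cp[cbind(a, b)] / v[a]
    res <- M[, b, drop = FALSE] - M[, a, drop = FALSE] *
      rep(beta, each = n)
    sdr <- sqrt(pmax(colSums(res^2) / (n - 1L), 0))
    tol <- 1e-12 * sqrt(max(v, na.rm = TRUE) / (n - 1L))
    enr <- hilbertEnvelope(res)
    # cor(env(res_{b|a}), env0[, a]) for each ordered pair
    ce <- sweep(enr, 2L, colMeans(enr))
    c0 <- sweep(env0, 2L, colMeans(env0))
    num <- colSums(ce * c0[, a, drop = FALSE])
    den <- sqrt(colSums(ce^2)) * sqrt(colSums(c0[, a, drop = FALSE]^2))
    r <- ifelse(den > 0 & sdr > tol & is.finite(beta), num / den, NA_real_)
    np <- nrow(pairs)
    val <- (r[seq_len(np)] + r[np + seq_len(np)]) / 2
    if (anyNA(val)) {
      degenerate <- TRUE
      val[is.na(val)] <- 0
    }
    m <- matrix(0, R, R)
    m[pairs] <- val
    out[, , e] <- m + t(m)
  }
  if (degenerate)
    warning("collinear or degenerate region pairs; AEC-c entries set to 0")
  new("ConnectivityStack", values = out, band = band,
      regionLabels = ts@regionLabels)
}
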