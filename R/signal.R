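# Band-pass filtering and analytic envelopes.

#' Design the band-pass FIR filter
#'
#' A linear-phase FIR band-pass designed with [signal::fir1()] and a Hann
#' window. The default order of 450 is the convention used for source-level
#' MEG filtering at 1000 Hz; the filter is always applied twice
#' (forward-backward) by [bandpassFilter()], so its effective magnitude
#' response is squared and its phase response cancels.
#'
#' @param band a [BandSpec-class].
#' @param fs sampling rate in Hz; band must lie below `fs/2`.
#' @param order filter order (number of taps minus one).
#' @return Numeric vector of `order + 1` filter taps.
#' @export
designBandpassFir <- function(band, fs, order = 450) {
  stopifnot(is(band, "BandSpec"))
  .stopIfNot(band@high < fs / 2,
             "band '%s' (%g-%g Hz) exceeds the Nyquist frequency %g Hz",
             band@name, band@low, band@high, fs / 2)
  w <- c(band@low, band@high) * 2 / fs
  as.numeric(signal::fir1(order, w, type = "pass",
                          window = signal::hanning(order + 1)))
}

#' Zero-phase band-pass filtering of epoched signals
#'
#' Applies the Hann-window FIR of [designBandpassFir()] in a two-pass
#' (forward-backward) scheme, so the output is exactly zero-phase and the
#' effective magnitude response is the squared single-pass response. Each
#' epoch is mirror-padded with up to `padSamples` samples on both sides
#' before filtering to suppress edge transients; when an epoch is shorter
#' than the requested padding, the padding is truncated to the available
#' samples and a message is emitted.
#'
#' Two numerically equivalent implementations are available:
#' `method = "fft"` (default) multiplies the padded epoch's spectrum by the
#' squared FIR magnitude response, which is the exact frequency-domain form
#' of the forward-backward pass and vectorizes across all regions and
#' epochs; `method = "conv"` runs the literal time-domain forward-backward
#' convolution and requires padding of at least `2 * order` samples.
#'
#' @param ts an [EpochedTimeSeries-class].
#' @param band a [BandSpec-class].
#' @param order FIR filter order (default 450).
#' @param padSamples mirror padding per side (default 2000 samples).
#' @param method `"fft"` or `"conv"` (see Details).
#' @return A band-limited [EpochedTimeSeries-class] of the same shape, with
#'   `bandOf()` set to the band name.
#' @examples
#' t <- seq(0, 2, by = 1/250)[-1]
#' x <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 40 * t))
#' ts <- epochedTimeSeries(x, fs = 250)
#' flt <- bandpassFilter(ts, bandSpec("alpha", 8, 13))
#' @export
bandpassFilter <- function(ts, band, order = 450, padSamples = 2000,
                           method = c("fft", "conv")) {
  stopifnot(is(ts, "EpochedTimeSeries"), is(band, "BandSpec"))
  method <- match.arg(method)
  taps <- designBandpassFir(band, ts@fs, order = order)
  x <- .asSampleMatrix(ts@data)
  n <- nrow(x)
  need <- if (method == "fft") order else 2L * order
  p <- min(padSamples, n - 1L)
  if (p < need) {
    if (method == "conv")
      stop(sprintf(paste0("epochs of %d samples are too short for time-",
                          "domain two-pass filtering at order %d ",
                          "(need padding >= %d)"), n, order, need),
           call. = FALSE)
    message(sprintf(
      "bandpassFilter: padding truncated to %d samples (epoch length %d)",
      p, n))
  } else if (p < padSamples) {
    message(sprintf(
      "bandpassFilter: padding truncated to %d samples (epoch length %d)",
      p, n))
  }
  xp <- rbind(x[(p + 1L):2L, , drop = FALSE],
              x,
              x[(n - 1L):(n - p), , drop = FALSE])
  y <- if (method == "fft") .filterFft(xp, taps) else .filterConv(xp, taps)
  y <- y[(p + 1L):(p + n), , drop = FALSE]
  epochedTimeSeries(.fromSampleMatrix(y, dim(ts@data)), fs = ts@fs,
                    regionLabels = ts@regionLabels, band = band@name,
                    truth = ts@truth)
}

# Frequency-domain two-pass: multiply by |H|^2 (zero phase by construction).
.filterFft <- function(xp, taps) {
  L <- nrow(xp)
  H2 <- Mod(stats::fft(c(taps, numeric(L - length(taps)))))^2
  Re(stats::mvfft(stats::mvfft(xp) * H2, inverse = TRUE) / L)
}

# Literal forward-backward convolution (per column).
.filterConv <- function(xp, taps) {
  one <- function(v) {
    y <- as.numeric(stats::filter(v, taps, method = "convolution", sides = 1))
    rev(as.numeric(stats::filter(rev(y), taps, method = "convolution",
                                 sides = 1)))
  }
  apply(xp, 2L, one)
}

#' Analytic amplitude envelope
#'
#' Magnitude of the analytic signal (FFT-based Hilbert transform), computed
#' independently for every region and epoch. Input is expected to be
#' band-limited already (see [bandpassFilter()]). The envelope is
#' nonnegative everywhere and scale-equivariant:
#' `envelope(c * x) = |c| * envelope(x)`.
#'
#' @param ts an [EpochedTimeSeries-class] (band-limited).
#' @return An [EpochedTimeSeries-class] holding the envelopes.
#' @export
analyticEnvelope <- function(ts) {
  stopifnot(is(ts, "EpochedTimeSeries"))
  x <- .asSampleMatrix(ts@data)
  env <- hilbertEnvelope(x)
  epochedTimeSeries(.fromSampleMatrix(env, dim(ts@data)), fs = ts@fs,
                    regionLabels = ts@regionLabels, band = ts@band,
                    truth = ts@truth)
}
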