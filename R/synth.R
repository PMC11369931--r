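# Synthetic cohort generator: band-limited signals with planted envelope
# coupling, toy trees, random unique-weight matrices, and a biomarker with
# a planted linear link to the coupling.

# Smooth positive envelope process: Gaussian noise low-passed below
# `cutoff` Hz, rectified, smoothed again, standardized to mean 1 / sd 0.35
# and floored at 0.05. Returns a samples x k matrix.
.envelopeProcess <- function(n, k, fs, cutoff) {
  z <- matrix(stats::rnorm(n * k), n, k)
  e <- abs(.fftLowpass(z, fs, cutoff))
  e <- .fftLowpass(e, fs, cutoff)
  mu <- colMeans(e)
  sd <- sqrt(pmax(colMeans(sweep(e, 2L, mu)^2), .Machine$double.eps))
  e <- sweep(sweep(e, 2L, mu), 2L, sd, "/") * 0.35 + 1
  pmax(e, 0.05)
}

# Constant-modulus frequency-modulated carriers confined to `band`.
# The instantaneous frequency wanders slowly inside the band, keeping a
# margin for the envelope sidebands, and each column gets an independent
# random phase trajectory, so zero-lag correlations between carriers are
# negligible while |analytic signal| stays ~1 (the measured Hilbert
# envelope of envelope * carrier then equals the planted envelope).
.fmCarriers <- function(n, k, fs, band, modRate) {
  f0 <- (band@low + band@high) / 2
  halfBw <- (band@high - band@low) / 2
  dev <- max(halfBw - modRate - 0.5, 0.1 * halfBw)
  u <- .fftLowpass(matrix(stats::rnorm(n * k), n, k), fs, modRate)
  sdu <- sqrt(pmax(colMeans(u^2), .Machine$double.eps))
  u <- tanh(sweep(u, 2L, sdu, "/"))
  finst <- f0 + dev * u
  phase <- 2 * pi * apply(finst, 2L, cumsum) / fs
  phase <- sweep(phase, 2L, stats::runif(k, 0, 2 * pi), "+")
  cos(phase)
}

.bandModRate <- function(band) (band@high - band@low) / 4

#' Generate one subject's region-level time series
#'
#' For each band in `spec@bands`, every region's signal is
#' `envelope x carrier`: the envelope is the planted mixture
#' `sqrt(coupling) * E_shared + sqrt(1 - coupling) * E_region` of
#' independent smooth positive processes, and the carrier is a
#' constant-modulus frequency-modulated oscillation confined to the band
#' with an independent random phase trajectory per region. Zero-lag
#' amplitude coupling between any two regions therefore equals `coupling`
#' (up to sampling error) while zero-lag phase coupling is negligible. The
#' band components are summed into one broadband signal per region.
#'
#' The planted envelopes are stored in the returned object's `truth` slot
#' (per band, `region+1 x epoch x sample`, with the shared envelope first)
#' and serve as the ground-truth oracle for connectivity checks.
#'
#' @param spec a [CohortSpec-class] (geometry and bands are taken from it).
#' @param coupling envelope-sharing coefficient in `[0, 1)`.
#' @param seed integer seed for this subject's draw.
#' @param storeTruth keep the planted envelopes in the `truth` slot?
#' @return An [EpochedTimeSeries-class] of
#'   `nRegions x nEpochs x epochSamples`.
#' @export
generateSubjectTimeSeries <- function(spec, coupling, seed = spec@seed,
                                      storeTruth = TRUE) {
  stopifnot(is(spec, "CohortSpec"))
  .stopIfNot(is.numeric(coupling) && length(coupling) == 1L &&
               is.finite(coupling) && coupling >= 0 && coupling < 1,
             "'coupling' must be a single value in [0, 1)")
  R <- spec@nRegions; E <- spec@nEpochs; n <- spec@epochSamples
  fs <- spec@fs
  withSeed(seed, {
    data <- array(0, dim = c(R, E, n))
    truthEnv <- list()
    for (band in spec@bands) {
      modRate <- .bandModRate(band)
      envArr <- array(NA_real_, dim = c(R + 1L, E, n))
      for (e in seq_len(E)) {
        env <- .envelopeProcess(n, R + 1L, fs, modRate)  # col 1 = shared
        mix <- sqrt(coupling) * env[, 1L] +
          sqrt(1 - coupling) * env[, -1L, drop = FALSE]
        car <- .fmCarriers(n, R, fs, band, modRate)
        data[, e, ] <- data[, e, ] + t(mix * car)
        envArr[1L, e, ] <- env[, 1L]
        envArr[-1L, e, ] <- t(mix)
      }
      truthEnv[[band@name]] <- envArr
    }
    truth <- if (storeTruth)
      list(coupling = coupling, envelopes = truthEnv) else list()
    epochedTimeSeries(data, fs = fs, band = NA_character_, truth = truth)
  })
}

#' Generate a synthetic cohort
#'
#' Draws a per-subject coupling `Normal(couplingBase, couplingSd)` truncated
#' to `[0.01, 0.95]`, a biomarker
#' `intercept + effectSize * (coupling_s - couplingBase) + Normal(0, noiseSd)`
#' (floored at 1 pg/ml), labels the first `nFHpos` subjects `FH+`, and
#' (optionally) generates each subject's time series. All draws come from
#' the generator seeded with `spec@seed`, so an identical spec reproduces
#' the cohort exactly.
#'
#' @param spec a [CohortSpec-class].
#' @param timeseries generate the per-subject signals? Set `FALSE` for a
#'   fast cohort-table-only draw (couplings, biomarker and labels), e.g.
#'   in Monte-Carlo studies of the statistics stage.
#' @param storeTruth passed to [generateSubjectTimeSeries()].
#' @return List with elements `cohort` (data.frame with columns
#'   `subject_id`, `group`, `biomarker`, `coupling_true`) and `timeseries`
#'   (list of [EpochedTimeSeries-class], or `NULL`).
#' @examples
#' coh <- generateCohort(scaledCohortSpec(seed = 7), timeseries = FALSE)
#' table(coh$cohort$group)
#' @export
generateCohort <- function(spec, timeseries = TRUE, storeTruth = TRUE) {
  stopifnot(is(spec, "CohortSpec"))
  draws <- withSeed(spec@seed, {
    coupling <- pmin(pmax(
      stats::rnorm(spec@nSubjects, spec@couplingBase, spec@couplingSd),
      0.01), 0.95)
    biomarker <- pmax(
      spec@intercept + spec@effectSize * (coupling - spec@couplingBase) +
        stats::rnorm(spec@nSubjects, 0, spec@noiseSd), 1)
    subjSeeds <- sample.int(.Machine$integer.max - 1L, spec@nSubjects)
    list(coupling = coupling, biomarker = biomarker, subjSeeds = subjSeeds)
  })
  cohort <- data.frame(
    subject_id = sprintf("S%03d", seq_len(spec@nSubjects)),
    group = rep(c("FH+", "FH-"),
                c(spec@nFHpos, spec@nSubjects - spec@nFHpos)),
    biomarker = draws$biomarker,
    coupling_true = draws$coupling,
    stringsAsFactors = FALSE)
  ts <- NULL
  if (timeseries)
    ts <- lapply(seq_len(spec@nSubjects), function(s)
      generateSubjectTimeSeries(spec, draws$coupling[s],
                                seed = draws$subjSeeds[s],
                                storeTruth = storeTruth))
  list(cohort = cohort, timeseries = ts)
}

#' Canonical toy trees
#'
#' Closed-form reference trees: `"star"` (one center adjacent to all other
#' `n - 1` nodes), `"path"` (a chain with exactly two leaves), `"y"` (the
#' fixed 5-node Y-shaped tree with edges 1-2, 2-3, 2-4, 4-5) and
#' `"random"` (a uniformly random labelled tree via a random Pruefer
#' sequence, with distinct random edge weights).
#'
#' @param kind one of `"star"`, `"path"`, `"y"`, `"random"`.
#' @param n number of nodes (`>= 3`; `"y"` requires `n = 5`).
#' @param seed seed for `kind = "random"`.
#' @return A [SpanningTree-class].
#' @examples
#' degreeSequence(makeToyTree("y", 5))  # 1 3 1 2 1
#' @export
makeToyTree <- function(kind = c("star", "path", "y", "random"), n,
                        seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  .stopIfNot(n >= 3L, "toy trees need n >= 3")
  edges <- switch(kind,
    star = cbind(1L, 2:n),
    path = cbind(1:(n - 1L), 2:n),
    y = {
      .stopIfNot(n == 5L, "the Y tree is defined on exactly 5 nodes")
      cbind(c(1L, 2L, 2L, 4L), c(2L, 3L, 4L, 5L))
    },
    random = withSeed(seed, .pruferDecode(
      sample.int(n, n - 2L, replace = TRUE), n)))
  w <- if (kind == "random")
    withSeed(seed + 1L, sample(seq_len(n - 1L)) / n) else rep(1, n - 1L)
  spanningTree(cbind(edges, w), nNodes = n)
}

# Decode a Pruefer sequence into the edge list of its labelled tree.
.pruferDecode <- function(prufer, n) {
  deg <- rep(1L, n)
  for (v in prufer) deg[v] <- deg[v] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (k in seq_along(prufer)) {
    v <- prufer[k]
    leaf <- which(deg == 1L)[1L]
    edges[k, ] <- c(leaf, v)
    deg[leaf] <- 0L
    deg[v] <- deg[v] - 1L
  }
  edges[n - 1L, ] <- which(deg == 1L)
  edges
}

#' Random symmetric matrix with unique weights
#'
#' A symmetric `n x n` matrix whose `n(n-1)/2` off-diagonal weights are all
#' distinct, lie strictly in `(0, 1)`, and are randomly arranged; the
#' diagonal is zero. With unique weights the maximum spanning tree is
#' unique, which makes these matrices convenient MST fixtures.
#'
#' @param n matrix size (`>= 3`).
#' @param seed integer seed.
#' @return Symmetric numeric matrix.
#' @export
makeRandomMatrix <- function(n, seed = 1L) {
  n <- as.integer(n)
  .stopIfNot(n >= 3L, "'n' must be >= 3")
  M <- n * (n - 1L) / 2
  w <- withSeed(seed, (sample.int(M) - 0.5) / M)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- w
  m + t(m)
}
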