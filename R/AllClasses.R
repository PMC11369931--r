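#' @import methods
NULL

# ---------------------------------------------------------------------------
# BandSpec
# ---------------------------------------------------------------------------

#' Frequency band definition
#'
#' An S4 container for a named frequency band. The canonical bands used
#' throughout resting-state electrophysiology are theta (4-8 Hz),
#' alpha (8-13 Hz) and beta (13-30 Hz); see [defaultBands()].
#'
#' @slot name single character label, e.g. `"alpha"`.
#' @slot low lower band edge in Hz; must satisfy `0 < low < high`.
#' @slot high upper band edge in Hz.
#'
#' @seealso [bandSpec()], [bandpassFilter()]
#' @export
setClass("BandSpec",
         representation(name = "character", low = "numeric", high = "numeric"))

setValidity("BandSpec", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("'name' must be a single non-empty string")
  if (length(object@low) != 1L || length(object@high) != 1L)
    return("'low' and 'high' must be single numbers")
  if (!is.finite(object@low) || !is.finite(object@high))
    return("band edges must be finite")
  if (!(object@low > 0 && object@low < object@high))
    return("band edges must satisfy 0 < low < high")
  TRUE
})

#' Construct a BandSpec
#'
#' @param name band label.
#' @param low,high band edges in Hz (`0 < low < high`).
#' @return A [BandSpec-class] object.
#' @examples
#' bandSpec("alpha", 8, 13)
#' @export
bandSpec <- function(name, low, high) {
  new("BandSpec", name = as.character(name),
      low = as.numeric(low), high = as.numeric(high))
}

#' Canonical frequency bands
#'
#' Theta (4-8 Hz), alpha (8-13 Hz) and beta (13-30 Hz).
#'
#' @return Named list of [BandSpec-class] objects.
#' @export
defaultBands <- function() {
  list(theta = bandSpec("theta", 4, 8),
       alpha = bandSpec("alpha", 8, 13),
       beta  = bandSpec("beta", 13, 30))
}

# ---------------------------------------------------------------------------
# EpochedTimeSeries
# ---------------------------------------------------------------------------

#' Epoched multichannel time series
#'
#' Region-level signals cut into equal-length epochs, stored as a
#' `region x epoch x sample` array with sampling-rate metadata. This is the
#' unit the filtering and connectivity stages consume.
#'
#' @slot data numeric array with `dim = c(n_regions, n_epochs, n_samples)`;
#'   no missing values allowed.
#' @slot fs sampling rate in Hz.
#' @slot regionLabels character vector of region names (length `n_regions`).
#' @slot band label of the band the data are limited to, or `NA` for
#'   broadband/synthetic-mixture data.
#' @slot truth list carrying generator ground truth (planted coupling and
#'   envelopes) when produced by [generateSubjectTimeSeries()]; empty
#'   otherwise. Never used by the analysis stages.
#'
#' @seealso [epochedTimeSeries()], [bandpassFilter()], [analyticEnvelope()]
#' @export
setClass("EpochedTimeSeries",
         representation(data = "array", fs = "numeric",
                        regionLabels = "character", band = "character",
                        truth = "list"))

setValidity("EpochedTimeSeries", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("'data' must be a 3-d array (region x epoch x sample)")
  if (anyNA(d) || !all(is.finite(d)))
    return("'data' must be finite with no missing values")
  if (dim(d)[1L] < 2L)
    return("at least 2 regions are required")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("'fs' must be a single positive number")
  if (length(object@regionLabels) != dim(d)[1L])
    return("'regionLabels' length must equal the number of regions")
  if (length(object@band) != 1L)
    return("'band' must be a single string (or NA)")
  TRUE
})

#' Construct an EpochedTimeSeries
#'
#' @param data `region x epoch x sample` numeric array. A `region x sample`
#'   matrix is promoted to a single epoch.
#' @param fs sampling rate in Hz.
#' @param regionLabels optional region names; defaults to `R1, R2, ...`.
#' @param band optional band label.
#' @param truth optional generator ground-truth list.
#' @return An [EpochedTimeSeries-class] object.
#' @export
epochedTimeSeries <- function(data, fs, regionLabels = NULL,
                              band = NA_character_, truth = list()) {
  if (is.matrix(data)) data <- array(data, dim = c(nrow(data), 1L, ncol(data)))
  if (is.null(regionLabels)) regionLabels <- paste0("R", seq_len(dim(data)[1L]))
  new("EpochedTimeSeries", data = data, fs = as.numeric(fs),
      regionLabels = as.character(regionLabels),
      band = as.character(band), truth = truth)
}

# ---------------------------------------------------------------------------
# ConnectivityStack
# ---------------------------------------------------------------------------

#' Per-epoch connectivity matrices for one band
#'
#' A stack of symmetric `region x region` AEC-c adjacency matrices, one per
#' epoch, with the diagonal fixed at zero.
#'
#' @slot values numeric array `region x region x epoch`; each slice
#'   symmetric, zero-diagonal, finite, in `[-1, 1]`.
#' @slot band the [BandSpec-class] the matrices were computed in.
#' @slot regionLabels region names.
#'
#' @seealso [connectivityStack()], [epochMatrix()], [subjectMetrics()]
#' @export
setClass("ConnectivityStack",
         representation(values = "array", band = "BandSpec",
                        regionLabels = "character"))

setValidity("ConnectivityStack", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L || dim(v)[1L] != dim(v)[2L])
    return("'values' must be a region x region x epoch array")
  if (!all(is.finite(v)))
    return("connectivity values must be finite")
  if (max(abs(v)) > 1 + 1e-8)
    return("connectivity values must lie in [-1, 1]")
  for (e in seq_len(dim(v)[3L])) {
    m <- v[, , e]
    if (any(abs(diag(m)) > 1e-12))
      return(sprintf("epoch %d: diagonal must be zero", e))
    if (max(abs(m - t(m))) > 1e-10)
      return(sprintf("epoch %d: matrix must be symmetric", e))
  }
  if (length(object@regionLabels) != dim(v)[1L])
    return("'regionLabels' length must equal the number of regions")
  TRUE
})

# ---------------------------------------------------------------------------
# SpanningTree
# ---------------------------------------------------------------------------

#' Spanning tree of a connectivity matrix
#'
#' A loopless connected subgraph on `N` nodes with exactly `N - 1` weighted
#' edges. Edge weights carry the original connectivity values.
#'
#' @slot nNodes number of nodes `N`.
#' @slot edges numeric matrix with `N - 1` rows and columns
#'   `from`, `to`, `weight` (1-based node indices, `from < to`).
#' @slot nodeLabels node names.
#'
#' @seealso [mstFromMatrix()], [makeToyTree()], [treeMetrics()]
#' @export
setClass("SpanningTree",
         representation(nNodes = "integer", edges = "matrix",
                        nodeLabels = "character"))

setValidity("SpanningTree", function(object) {
  n <- object@nNodes
  e <- object@edges
  if (n < 2L) return("a tree needs at least 2 nodes")
  if (!is.numeric(e) || ncol(e) != 3L)
    return("'edges' must be a numeric matrix with columns from, to, weight")
  if (nrow(e) != n - 1L)
    return("a spanning tree on N nodes must have exactly N - 1 edges")
  idx <- as.integer(e[, 1:2])
  if (any(idx < 1L) || any(idx > n))
    return("edge endpoints out of range")
  if (any(e[, 1L] == e[, 2L])) return("self-loops are not allowed")
  # N - 1 edges + full connectivity <=> acyclic spanning tree
  parent <- seq_len(n)
  find <- function(i) {
    i <- as.integer(i)
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (k in seq_len(nrow(e))) {
    a <- find(e[k, 1L]); b <- find(e[k, 2L])
    if (a == b) return("edges contain a cycle")
    parent[a] <- b
  }
  if (length(unique(vapply(seq_len(n), find, integer(1)))) != 1L)
    return("tree is not connected")
  if (length(object@nodeLabels) != n)
    return("'nodeLabels' length must equal nNodes")
  TRUE
})

#' Construct a SpanningTree
#'
#' @param edges matrix (or data.frame) with columns from, to, weight.
#' @param nNodes number of nodes; defaults to the largest endpoint index.
#' @param nodeLabels optional node names.
#' @return A [SpanningTree-class] object.
#' @export
spanningTree <- function(edges, nNodes = NULL, nodeLabels = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) == 2L) edges <- cbind(edges, 1)
  colnames(edges) <- c("from", "to", "weight")
  swap <- edges[, 1L] > edges[, 2L]
  if (any(swap)) edges[swap, 1:2] <- edges[swap, 2:1]
  if (is.null(nNodes)) nNodes <- max(edges[, 1:2])
  if (is.null(nodeLabels)) nodeLabels <- paste0("N", seq_len(nNodes))
  new("SpanningTree", nNodes = as.integer(nNodes), edges = edges,
      nodeLabels = as.character(nodeLabels))
}

# ---------------------------------------------------------------------------
# TreeMetrics
# ---------------------------------------------------------------------------

#' Global topology metrics of one tree
#'
#' Houses the leaf count `L`, edge count `m`, leaf fraction `LF = L/m`,
#' hop diameter `d`, normalized diameter `D = d/m`, maximum normalized
#' betweenness `BCmax` and tree hierarchy `TH = L / (2 m BCmax)`, together
#' with the per-node degree sequence.
#'
#' @slot L integer leaf count (degree-1 nodes).
#' @slot m integer edge count (`N - 1`).
#' @slot LF leaf fraction.
#' @slot d integer hop diameter.
#' @slot D normalized diameter.
#' @slot BCmax maximum betweenness centrality, normalized to `[0, 1]` by the
#'   number of node pairs excluding the node itself.
#' @slot TH tree hierarchy.
#' @slot degrees integer degree sequence.
#'
#' @seealso [treeMetrics()]
#' @export
setClass("TreeMetrics",
         representation(L = "integer", m = "integer", LF = "numeric",
                        d = "integer", D = "numeric", BCmax = "numeric",
                        TH = "numeric", degrees = "integer"))

# ---------------------------------------------------------------------------
# CohortSpec
# ---------------------------------------------------------------------------

#' Synthetic cohort specification
#'
#' Parameters of the synthetic cohort generator: cohort composition, signal
#' geometry, planted envelope coupling and the linear biomarker link.
#' Subject `s` receives a coupling value drawn as
#' `Normal(couplingBase, couplingSd)` truncated to `[0.01, 0.95]`, and a
#' biomarker value
#' `intercept + effectSize * (coupling_s - couplingBase) + Normal(0, noiseSd)`
#' (floored at 1 pg/ml so the biomarker stays positive). The first `nFHpos`
#' subjects are labelled `FH+`, the rest `FH-`.
#'
#' @slot nSubjects,nFHpos cohort size and number of subjects labelled FH+.
#' @slot nRegions,nEpochs,epochSamples signal geometry (regions, epochs,
#'   samples per epoch).
#' @slot fs sampling rate in Hz.
#' @slot bands list of [BandSpec-class] components summed into each signal.
#' @slot couplingBase mean planted envelope-sharing coefficient in `[0, 1)`.
#' @slot couplingSd between-subject sd of the coupling draw.
#' @slot effectSize biomarker slope (pg/ml per unit coupling deviation).
#' @slot noiseSd biomarker noise sd (pg/ml).
#' @slot intercept biomarker mean at `couplingBase` (pg/ml).
#' @slot seed integer random seed; an identical spec yields a bitwise
#'   identical cohort.
#'
#' @seealso [cohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
         representation(nSubjects = "integer", nFHpos = "integer",
                        nRegions = "integer", nEpochs = "integer",
                        epochSamples = "integer", fs = "numeric",
                        bands = "list", couplingBase = "numeric",
                        couplingSd = "numeric", effectSize = "numeric",
                        noiseSd = "numeric", intercept = "numeric",
                        seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@nSubjects < 1L) return("'nSubjects' must be >= 1")
  if (object@nFHpos > object@nSubjects || object@nFHpos < 0L)
    return("'nFHpos' must satisfy 0 <= nFHpos <= nSubjects")
  if (object@nRegions < 3L) return("'nRegions' must be >= 3")
  if (object@nEpochs < 1L) return("'nEpochs' must be >= 1")
  if (object@epochSamples < 64L) return("'epochSamples' must be >= 64")
  if (!is.finite(object@fs) || object@fs <= 0)
    return("'fs' must be a positive sampling rate in Hz")
  if (!length(object@bands) ||
      !all(vapply(object@bands, is, logical(1), "BandSpec")))
    return("'bands' must be a non-empty list of BandSpec objects")
  for (b in object@bands)
    if (b@high >= object@fs / 2)
      return(sprintf("band '%s' exceeds the Nyquist frequency", b@name))
  if (!is.finite(object@couplingBase) ||
      object@couplingBase < 0 || object@couplingBase >= 1)
    return("'couplingBase' must lie in [0, 1)")
  if (object@couplingSd < 0) return("'couplingSd' must be >= 0")
  if (object@noiseSd < 0) return("'noiseSd' must be >= 0")
  if (object@intercept <= 0) return("'intercept' must be positive (pg/ml)")
  TRUE
})

#' Construct a CohortSpec
#'
#' Defaults describe the full-scale study layout: 76 subjects (54 FH+),
#' 80 regions, 30 epochs of 4096 samples at 1000 Hz, theta/alpha/beta bands,
#' and a biomarker link calibrated so that the planted biomarker-coupling
#' correlation is 0.50 (see [plantedCorrelation()]).
#'
#' @param nSubjects,nFHpos cohort composition.
#' @param nRegions,nEpochs,epochSamples,fs signal geometry.
#' @param bands list of [BandSpec-class].
#' @param couplingBase,couplingSd planted coupling distribution.
#' @param effectSize,noiseSd,intercept biomarker link (pg/ml).
#' @param seed integer random seed.
#' @return A validated [CohortSpec-class].
#' @examples
#' spec <- cohortSpec(nSubjects = 10, nRegions = 6, nEpochs = 2,
#'                    epochSamples = 512, fs = 250, seed = 1)
#' plantedCorrelation(spec)
#' @export
cohortSpec <- function(nSubjects = 76, nFHpos = 54, nRegions = 80,
                       nEpochs = 30, epochSamples = 4096, fs = 1000,
                       bands = defaultBands(), couplingBase = 0.35,
                       couplingSd = 0.12, effectSize = 500,
                       noiseSd = 104, intercept = 381.696, seed = 1L) {
  new("CohortSpec",
      nSubjects = as.integer(nSubjects), nFHpos = as.integer(nFHpos),
      nRegions = as.integer(nRegions), nEpochs = as.integer(nEpochs),
      epochSamples = as.integer(epochSamples), fs = as.numeric(fs),
      bands = bands, couplingBase = as.numeric(couplingBase),
      couplingSd = as.numeric(couplingSd), effectSize = as.numeric(effectSize),
      noiseSd = as.numeric(noiseSd), intercept = as.numeric(intercept),
      seed = as.integer(seed))
}

#' Scaled-down cohort profile
#'
#' A desk-scale profile (20 subjects, 10 regions, 10 epochs of 512 samples
#' at 250 Hz) that keeps full-pipeline runs cheap while preserving every
#' structural feature of the full-scale profile.
#'
#' @param ... overrides passed on to [cohortSpec()].
#' @return A [CohortSpec-class].
#' @export
scaledCohortSpec <- function(...) {
  args <- list(nSubjects = 20, nFHpos = 14, nRegions = 10, nEpochs = 10,
               epochSamples = 512, fs = 250)
  args[names(list(...))] <- list(...)
  do.call(cohortSpec, args)
}

#' Planted biomarker-coupling correlation implied by a CohortSpec
#'
#' The population correlation between the biomarker and the planted coupling
#' under the linear-plus-Gaussian link (ignoring the rare truncation of the
#' coupling draw):
#' `rho = b*s / sqrt((b*s)^2 + noiseSd^2)` with `b = effectSize`,
#' `s = couplingSd`.
#'
#' @param spec a [CohortSpec-class].
#' @return Numeric scalar in `[0, 1)`.
#' @export
plantedCorrelation <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  bs <- spec@effectSize * spec@couplingSd
  bs / sqrt(bs^2 + spec@noiseSd^2)
}
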