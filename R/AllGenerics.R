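# Accessor generics and show methods.

#' @name accessors
#' @title Accessors for megtree objects
#' @description Small accessors exposing object contents without slot access.
#' @param x a megtree S4 object.
#' @param i epoch index.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("tsData", function(x) standardGeneric("tsData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("bandOf", function(x) standardGeneric("bandOf"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("epochMatrix", function(x, i) standardGeneric("epochMatrix"))
#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname accessors
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))
#' @rdname accessors
#' @export
setGeneric("degreeSequence", function(x) standardGeneric("degreeSequence"))

#' @rdname accessors
#' @export
setMethod("tsData", "EpochedTimeSeries", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochedTimeSeries", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("nRegions", "EpochedTimeSeries", function(x) dim(x@data)[1L])
#' @rdname accessors
#' @export
setMethod("nEpochs", "EpochedTimeSeries", function(x) dim(x@data)[2L])
#' @rdname accessors
#' @export
setMethod("nSamples", "EpochedTimeSeries", function(x) dim(x@data)[3L])
#' @rdname accessors
#' @export
setMethod("regionLabels", "EpochedTimeSeries", function(x) x@regionLabels)
#' @rdname accessors
#' @export
setMethod("bandOf", "EpochedTimeSeries", function(x) x@band)
#' @rdname accessors
#' @export
setMethod("groundTruth", "EpochedTimeSeries", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("nRegions", "ConnectivityStack", function(x) dim(x@values)[1L])
#' @rdname accessors
#' @export
setMethod("nEpochs", "ConnectivityStack", function(x) dim(x@values)[3L])
#' @rdname accessors
#' @export
setMethod("regionLabels", "ConnectivityStack", function(x) x@regionLabels)
#' @rdname accessors
#' @export
setMethod("bandOf", "ConnectivityStack", function(x) x@band)
#' @rdname accessors
#' @export
setMethod("epochMatrix", "ConnectivityStack", function(x, i) {
  m <- x@values[, , i]
  dimnames(m) <- list(x@regionLabels, x@regionLabels)
  m
})

#' @rdname accessors
#' @export
setMethod("nNodes", "SpanningTree", function(x) x@nNodes)
#' @rdname accessors
#' @export
setMethod("edgeList", "SpanningTree", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("degreeSequence", "SpanningTree", function(x)
  tabulate(as.integer(x@edges[, 1:2]), nbins = x@nNodes))

setMethod("show", "BandSpec", function(object) {
  cat(sprintf("BandSpec '%s': %g-%g Hz\n",
              object@name, object@low, object@high))
})

setMethod("show", "EpochedTimeSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochedTimeSeries: %d regions x %d epochs x %d samples @ %g Hz (%s)\n",
    d[1L], d[2L], d[3L], object@fs,
    if (is.na(object@band)) "broadband" else object@band))
  if (length(object@truth))
    cat(sprintf("  ground truth attached (coupling = %.3f)\n",
                object@truth$coupling))
})

setMethod("show", "ConnectivityStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("ConnectivityStack: %d x %d AEC-c matrices, %d epochs, band %s\n",
              d[1L], d[2L], d[3L], object@band@name))
})

setMethod("show", "SpanningTree", function(object) {
  cat(sprintf("SpanningTree: %d nodes, %d edges, total weight %.4f\n",
              object@nNodes, nrow(object@edges), sum(object@edges[, 3L])))
})

setMethod("show", "TreeMetrics", function(object) {
  cat(sprintf(
    "TreeMetrics: L=%d m=%d LF=%.4f d=%d D=%.4f BCmax=%.4f TH=%.4f\n",
    object@L, object@m, object@LF, object@d, object@D,
    object@BCmax, object@TH))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    paste0("CohortSpec: %d subjects (%d FH+), %d regions x %d epochs x ",
           "%d samples @ %g Hz\n  coupling %.2f (sd %.2f), planted ",
           "biomarker-coupling correlation %.3f, seed %d\n"),
    object@nSubjects, object@nFHpos, object@nRegions, object@nEpochs,
    object@epochSamples, object@fs, object@couplingBase, object@couplingSd,
    plantedCorrelation(object), object@seed))
})
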