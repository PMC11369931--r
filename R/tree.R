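# Minimum spanning tree extraction and global tree topology metrics.

#' Maximum-connectivity spanning tree of an adjacency matrix
#'
#' Builds the spanning tree of a symmetric connectivity matrix with
#' Kruskal's algorithm, ranking edges by descending connectivity weight —
#' equivalently, ascending reciprocal weight for positive entries — so that
#' the tree retains the strongest backbone of the network. Negative or zero
#' entries are thereby ranked strictly below every positive entry and are
#' only used when needed to complete the tree. Ties are broken
#' deterministically by lexicographic `(i, j)` edge index, so the result is
#' reproducible even when weights are not unique. Edges of the returned
#' tree carry the original connectivity weights.
#'
#' @param m symmetric numeric matrix (`N >= 3`), finite entries; the
#'   diagonal is ignored. May also be a [ConnectivityStack-class] epoch
#'   slice obtained via [epochMatrix()].
#' @param nodeLabels optional node names (defaults to matrix dimnames).
#' @return A [SpanningTree-class] with `N - 1` edges.
#' @examples
#' m <- matrix(0, 3, 3)
#' m[1, 2] <- m[2, 1] <- 0.9
#' m[1, 3] <- m[3, 1] <- 0.5
#' m[2, 3] <- m[3, 2] <- 0.8
#' edgeList(mstFromMatrix(m))  # keeps AB (0.9) and BC (0.8)
#' @export
mstFromMatrix <- function(m, nodeLabels = NULL) {
  m <- as.matrix(m)
  n <- nrow(m)
  .stopIfNot(n >= 3L, "at least 3 nodes are required")
  .stopIfNot(ncol(m) == n, "matrix must be square")
  .stopIfNot(all(is.finite(m)), "matrix entries must be finite")
  .stopIfNot(max(abs(m - t(m))) <= 1e-10, "matrix must be symmetric")
  if (is.null(nodeLabels))
    nodeLabels <- if (!is.null(rownames(m))) rownames(m) else
      paste0("N", seq_len(n))
  idx <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[idx]
  ord <- order(-w, idx[, 1L], idx[, 2L])       # descending, (i, j) tie-break
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  keep <- integer(n - 1L)
  got <- 0L
  for (k in ord) {
    a <- find(idx[k, 1L]); b <- find(idx[k, 2L])
    if (a != b) {
      parent[a] <- b
      got <- got + 1L
      keep[got] <- k
      if (got == n - 1L) break
    }
  }
  edges <- cbind(from = idx[keep, 1L], to = idx[keep, 2L], weight = w[keep])
  spanningTree(edges, nNodes = n, nodeLabels = nodeLabels)
}

# Adjacency list of a tree (list of integer neighbor vectors).
.treeAdjacency <- function(tree) {
  adj <- vector("list", tree@nNodes)
  e <- tree@edges
  for (k in seq_len(nrow(e))) {
    i <- as.integer(e[k, 1L]); j <- as.integer(e[k, 2L])
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Hop distances from `start` by breadth-first search; `blocked` nodes (if
# any) are impassable and keep distance NA.
.bfsDistances <- function(adj, start, blocked = integer(0)) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  if (start %in% blocked) return(dist)
  dist[start] <- 0L
  frontier <- start
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (u in adj[[v]]) {
        if (is.na(dist[u]) && !(u %in% blocked)) {
          dist[u] <- dist[v] + 1L
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

#' Leaf count and leaf fraction
#'
#' A leaf is a node of degree 1. The leaf fraction is `LF = L / m`, the
#' leaf count divided by the number of edges `m = N - 1` (the maximum
#' possible number of leaves). `LF` is 1 for a star and `2/m` for a path.
#'
#' @param tree a [SpanningTree-class] with `N >= 3` nodes.
#' @return Named list with elements `L` and `LF`.
#' @export
leafFraction <- function(tree) {
  stopifnot(is(tree, "SpanningTree"))
  .stopIfNot(tree@nNodes >= 3L, "metrics require at least 3 nodes")
  deg <- degreeSequence(tree)
  L <- sum(deg == 1L)
  list(L = L, LF = L / nrow(tree@edges))
}

#' Hop diameter and normalized diameter
#'
#' The diameter `d` is the largest hop count (number of links) between any
#' two nodes; the normalized diameter is `D = d / m`. Computed with two
#' breadth-first searches (exact on trees). `D` is 1 for a path and `2/m`
#' for a star.
#'
#' @param tree a [SpanningTree-class] with `N >= 3` nodes.
#' @return Named list with elements `d` and `D`.
#' @export
treeDiameter <- function(tree) {
  stopifnot(is(tree, "SpanningTree"))
  .stopIfNot(tree@nNodes >= 3L, "metrics require at least 3 nodes")
  adj <- .treeAdjacency(tree)
  d1 <- .bfsDistances(adj, 1L)
  far <- which.max(d1)
  d2 <- .bfsDistances(adj, far)
  d <- max(d2)
  list(d = as.integer(d), D = d / nrow(tree@edges))
}

#' Normalized tree betweenness centrality
#'
#' For each node `v`, the fraction of unordered node pairs (excluding `v`)
#' whose unique tree path passes through `v`:
#' `BC(v) = pairs through v / ((N-1)(N-2)/2)`, in `[0, 1]`. A star's center
#' scores 1, every leaf scores 0. Computed by removing `v` and counting
#' pairs split across the resulting components.
#'
#' @param tree a [SpanningTree-class] with `N >= 3` nodes.
#' @return Numeric vector of length `N`.
#' @export
treeBetweenness <- function(tree) {
  stopifnot(is(tree, "SpanningTree"))
  n <- tree@nNodes
  .stopIfNot(n >= 3L, "betweenness requires at least 3 nodes")
  adj <- .treeAdjacency(tree)
  totalPairs <- (n - 1) * (n - 2) / 2
  vapply(seq_len(n), function(v) {
    sizes <- integer(0)
    seen <- rep(FALSE, n)
    seen[v] <- TRUE
    for (u in adj[[v]]) {
      if (!seen[u]) {
        comp <- which(!is.na(.bfsDistances(adj, u, blocked = v)))
        seen[comp] <- TRUE
        sizes <- c(sizes, length(comp))
      }
    }
    within <- sum(sizes * (sizes - 1) / 2)
    (totalPairs - within) / totalPairs
  }, numeric(1))
}

#' Tree hierarchy
#'
#' `TH = L / (2 m BCmax)` with `BCmax` the maximum normalized betweenness
#' from [treeBetweenness()]. TH balances network integration against hub
#' overload: it approaches 0 for a long path, equals 0.5 exactly for a
#' star, and larger values indicate configurations that spread load over
#' several well-placed hubs.
#'
#' @param tree a [SpanningTree-class] with `N >= 3` nodes (this guarantees
#'   `BCmax > 0`).
#' @return Numeric scalar `TH`.
#' @export
treeHierarchy <- function(tree) {
  stopifnot(is(tree, "SpanningTree"))
  .stopIfNot(tree@nNodes >= 3L, "tree hierarchy is undefined for N < 3")
  L <- leafFraction(tree)$L
  m <- nrow(tree@edges)
  bcmax <- max(treeBetweenness(tree))
  L / (2 * m * bcmax)
}

#' All global topology metrics of one tree
#'
#' @param tree a [SpanningTree-class] with `N >= 3` nodes.
#' @return A [TreeMetrics-class] object.
#' @examples
#' treeMetrics(makeToyTree("star", 80))  # LF = 1, D = 2/79, TH = 0.5
#' @export
treeMetrics <- function(tree) {
  stopifnot(is(tree, "SpanningTree"))
  lf <- leafFraction(tree)
  di <- treeDiameter(tree)
  bc <- treeBetweenness(tree)
  m <- nrow(tree@edges)
  new("TreeMetrics", L = as.integer(lf$L), m = as.integer(m), LF = lf$LF,
      d = di$d, D = di$D, BCmax = max(bc),
      TH = lf$L / (2 * m * max(bc)),
      degrees = degreeSequence(tree))
}

#' Epoch-averaged tree metrics for one subject and band
#'
#' Builds the maximum-connectivity spanning tree of every per-epoch
#' connectivity matrix, computes the global topology metrics for each tree,
#' and averages them arithmetically across epochs, yielding one value per
#' topological parameter per subject and band.
#'
#' @param x a [ConnectivityStack-class], or a list of symmetric matrices of
#'   identical size (`N >= 3`).
#' @return Named numeric vector with elements `L`, `LF`, `d`, `D`, `BCmax`
#'   and `TH` (epoch means); the per-epoch values are attached as a
#'   data.frame attribute `"perEpoch"`.
#' @export
subjectMetrics <- function(x) {
  mats <- if (is(x, "ConnectivityStack"))
    lapply(seq_len(nEpochs(x)), function(e) epochMatrix(x, e))
  else x
  .stopIfNot(is.list(mats) && length(mats) >= 1L,
             "at least one epoch matrix is required")
  sizes <- vapply(mats, nrow, integer(1))
  .stopIfNot(length(unique(sizes)) == 1L,
             "all epoch matrices must have the same size (got %s)",
             paste(unique(sizes), collapse = ", "))
  rows <- lapply(seq_along(mats), function(e) {
    tm <- treeMetrics(mstFromMatrix(mats[[e]]))
    data.frame(epoch = e, L = tm@L, LF = tm@LF, d = tm@d, D = tm@D,
               BCmax = tm@BCmax, TH = tm@TH)
  })
  perEpoch <- do.call(rbind, rows)
  out <- colMeans(perEpoch[, c("L", "LF", "d", "D", "BCmax", "TH")])
  attr(out, "perEpoch") <- perEpoch
  out
}
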