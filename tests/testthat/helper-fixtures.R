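# Small builders shared across test files.

alphaBand <- function() bandSpec("alpha", 8, 13)
betaBand <- function() bandSpec("beta", 13, 30)

# A tiny cohort spec for fast structural tests.
tinySpec <- function(...) {
  args <- list(nSubjects = 4, nFHpos = 2, nRegions = 4, nEpochs = 2,
               epochSamples = 512, fs = 250,
               bands = list(alphaBand()), seed = 1L)
  args[names(list(...))] <- list(...)
  do.call(cohortSpec, args)
}

# One long-epoch two-region series of band-limited white noise.
noisePair <- function(n, fs, band, seed) {
  set.seed(seed)
  ts <- epochedTimeSeries(rbind(rnorm(n), rnorm(n)), fs = fs)
  suppressMessages(bandpassFilter(ts, band))
}

# Brute-force BH step-up: independent oracle for bhFdr().
bruteForceBH <- function(p, q = 0.1) {
  M <- length(p)
  ord <- order(p)
  adj <- numeric(M)
  for (i in seq_len(M)) {
    ri <- rank(p, ties.method = "first")[i]
    adj[i] <- min(1, min(p[ord][ri:M] * M / (ri:M)))
  }
  s <- p[ord]
  ok <- which(s <= seq_len(M) * q / M)
  thr <- if (length(ok)) s[max(ok)] else 0
  list(adjusted = adj,
       significant = if (length(ok)) p <= thr else rep(FALSE, M),
       threshold = thr)
}

# Total weight of the maximum spanning tree by exhaustive enumeration over
# all N^(N-2) labelled trees (Pruefer sequences).
enumerateMaxTreeWeight <- function(m) {
  n <- nrow(m)
  if (n == 3L) {
    combos <- list(rbind(c(1, 2), c(1, 3)), rbind(c(1, 2), c(2, 3)),
                   rbind(c(1, 3), c(2, 3)))
    return(max(vapply(combos, function(e) sum(m[e]), numeric(1))))
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- -Inf
  for (k in seq_len(nrow(seqs))) {
    e <- megtree:::.pruferDecode(as.integer(seqs[k, ]), n)
    w <- sum(m[e])
    if (w > best) best <- w
  }
  best
}

# Pair-enumeration betweenness oracle: for every unordered pair, walk the
# unique tree path and credit its interior nodes.
enumerateBetweenness <- function(tree) {
  n <- nNodes(tree)
  adj <- megtree:::.treeAdjacency(tree)
  pathBetween <- function(a, b) {
    prev <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[a] <- 0L
    frontier <- a
    while (is.na(dist[b])) {
      nxt <- integer(0)
      for (v in frontier) for (u in adj[[v]])
        if (is.na(dist[u])) { dist[u] <- dist[v] + 1L; prev[u] <- v; nxt <- c(nxt, u) }
      frontier <- nxt
    }
    path <- b
    while (path[1L] != a) path <- c(prev[path[1L]], path)
    path
  }
  counts <- numeric(n)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    inner <- setdiff(pathBetween(a, b), c(a, b))
    counts[inner] <- counts[inner] + 1
  }
  counts / ((n - 1) * (n - 2) / 2)
}
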