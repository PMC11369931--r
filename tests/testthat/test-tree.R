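# Spanning-tree construction and topology metrics.

test_that("closed-form toy trees give their textbook metrics", {
  star <- makeToyTree("star", 80)
  expect_equal(leafFraction(star)$L, 79)
  expect_equal(leafFraction(star)$LF, 1.0)
  expect_equal(treeDiameter(star)$d, 2L)
  expect_equal(treeDiameter(star)$D, 2 / 79)
  bc <- treeBetweenness(star)
  expect_equal(bc[1L], 1.0)               # center routes every pair
  expect_true(all(bc[-1L] == 0))
  expect_equal(treeHierarchy(star), 0.5)

  path <- makeToyTree("path", 80)
  expect_equal(leafFraction(path)$L, 2)
  expect_equal(leafFraction(path)$LF, 2 / 79)
  expect_equal(treeDiameter(path)$d, 79L)
  expect_equal(treeDiameter(path)$D, 1.0)

  path5 <- makeToyTree("path", 5)
  expect_equal(treeBetweenness(path5)[3L], 4 / 6)  # 6 pairs, 4 cross middle
  expect_equal(treeHierarchy(path5), 0.375)

  y <- makeToyTree("y", 5)
  expect_equal(degreeSequence(y), c(1L, 3L, 1L, 2L, 1L))
  m <- treeMetrics(y)
  expect_equal(m@L, 3L)
  expect_equal(m@LF, 0.75)
  expect_equal(m@d, 3L)
  expect_equal(m@D, 0.75)
  expect_equal(m@BCmax, 5 / 6)
  expect_equal(m@TH, 0.45)
})

test_that("Kruskal picks the maximum-connectivity tree", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.9
  m[1, 3] <- m[3, 1] <- 0.5
  m[2, 3] <- m[3, 2] <- 0.8
  e <- edgeList(mstFromMatrix(m))
  expect_equal(sort(e[, "weight"]), c(0.8, 0.9))   # keeps AB and BC

  # a matrix whose only positive entries form a path returns that path
  mp <- matrix(-0.1, 5, 5); diag(mp) <- 0
  for (i in 1:4) mp[i, i + 1] <- mp[i + 1, i] <- 0.5 + i / 10
  ep <- edgeList(mstFromMatrix(mp))
  expect_equal(ep[order(ep[, 1L]), 1:2, drop = FALSE],
               cbind(from = 1:4, to = 2:5))

  # complete unique-weight matrix spans all nodes with N-1 links
  tr <- mstFromMatrix(makeRandomMatrix(80, seed = 4))
  expect_equal(nrow(edgeList(tr)), 79L)
  expect_equal(nNodes(tr), 80L)

  expect_error(mstFromMatrix(matrix(c(0, Inf, 1, Inf, 0, 1, 1, 1, 0), 3)),
               "finite")
})

test_that("MST total weight matches exhaustive enumeration (small N)", {
  cases <- data.frame(n = c(rep(4:6, each = 15), rep(7L, 5)),
                      seed = seq_len(50))
  for (k in seq_len(nrow(cases))) {
    m <- makeRandomMatrix(cases$n[k], seed = 100 + cases$seed[k])
    got <- sum(edgeList(mstFromMatrix(m))[, "weight"])
    expect_equal(got, enumerateMaxTreeWeight(m),
                 info = sprintf("n=%d seed=%d", cases$n[k], cases$seed[k]))
  }
})

test_that("MST edge set is invariant to node relabelling (unique weights)", {
  for (seed in 1:5) {
    n <- 9
    m <- makeRandomMatrix(n, seed = seed)
    perm <- withr::with_seed(seed, sample.int(n))
    mp <- m[perm, perm]
    e1 <- edgeList(mstFromMatrix(m))
    e2 <- edgeList(mstFromMatrix(mp))
    # map permuted tree back to original labels
    back <- cbind(perm[e2[, 1L]], perm[e2[, 2L]])
    back <- t(apply(back, 1L, sort))
    key <- function(e) sort(paste(e[, 1L], e[, 2L]))
    expect_equal(key(back), key(e1[, 1:2, drop = FALSE]))
  }
})

test_that("tree betweenness equals the pair-enumeration oracle", {
  for (seed in 1:12) {
    n <- sample(5:12, 1)
    tr <- makeToyTree("random", n, seed = seed)
    expect_equal(treeBetweenness(tr), enumerateBetweenness(tr),
                 tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("metric bounds and identities hold on random trees", {
  lfs <- ds <- numeric(0)
  for (seed in 1:40) {
    n <- 5 + (seed %% 8)
    tr <- makeToyTree("random", n, seed = 200 + seed)
    m <- treeMetrics(tr)
    expect_true(m@LF >= 2 / m@m && m@LF <= 1)
    expect_true(m@D >= 2 / m@m && m@D <= 1)
    expect_true(m@BCmax > 0 && m@BCmax <= 1)
    expect_true(m@TH > 0)
    expect_equal(sum(m@degrees), 2L * m@m)           # handshake identity
    expect_equal(m@L + sum(m@degrees > 1L), nNodes(tr))
    lfs <- c(lfs, m@LF); ds <- c(ds, m@D)
  }
  # leafier trees are shorter: LF and D anti-correlate across random trees
  expect_lt(cor(lfs, ds), 0)
})

test_that("MST agrees with igraph on reciprocal weights", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    m <- makeRandomMatrix(30, seed = 300 + seed)
    got <- sum(edgeList(mstFromMatrix(m))[, "weight"])
    g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                             weighted = TRUE)
    mst <- igraph::mst(g, weights = 1 / igraph::E(g)$weight)
    expect_equal(got, sum(igraph::E(mst)$weight))
  }
})

test_that("subject metrics average per-epoch tree metrics", {
  m <- makeRandomMatrix(6, seed = 9)
  rep30 <- subjectMetrics(replicate(30, m, simplify = FALSE))
  single <- subjectMetrics(list(m))
  expect_equal(unclass(rep30)[c("LF", "D", "TH")],
               unclass(single)[c("LF", "D", "TH")])

  # epochs forcing a star and a path (N=5) average their LFs
  star <- matrix(0.1, 5, 5); diag(star) <- 0
  star[1, 2:5] <- star[2:5, 1] <- 0.9
  path <- matrix(0.1, 5, 5); diag(path) <- 0
  for (i in 1:4) path[i, i + 1] <- path[i + 1, i] <- 0.8 + i / 100
  avg <- subjectMetrics(list(star, path))
  expect_equal(avg[["LF"]], mean(c(1.0, 0.5)))
  expect_equal(nrow(attr(avg, "perEpoch")), 2L)

  expect_error(subjectMetrics(list(star, makeRandomMatrix(4, 1))), "size")
})
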