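# Leakage-corrected amplitude envelope correlation.

test_that("orthogonalization removes the zero-lag projection exactly", {
  set.seed(61)
  x <- rnorm(500)
  y <- rnorm(500)
  expect_lt(abs(cor(orthogonalize(y, x), x)), 1e-10)
  # already-orthogonal input is returned (centered) unchanged
  yo <- orthogonalize(y, x)
  expect_equal(orthogonalize(yo, x), yo, tolerance = 1e-10)
  # collinear input leaves a zero residual
  expect_lt(max(abs(orthogonalize(2 * x, x))), 1e-10)
  expect_error(orthogonalize(y, numeric(500)), "degenerate")
})

test_that("identical signals give AEC-c 0 by the collinearity convention", {
  t <- seq_len(2000) / 250
  x <- sin(2 * pi * 10 * t) * (1 + 0.3 * sin(2 * pi * t))
  expect_warning(v <- aecCorrected(x, x), "collinear")
  expect_equal(v, 0)
})

test_that("AEC-c is scale invariant", {
  pair <- noisePair(8192, 250, alphaBand(), seed = 62)
  x <- tsData(pair)[1, 1, ]
  y <- tsData(pair)[2, 1, ]
  base <- aecCorrected(x, y)
  expect_equal(aecCorrected(5 * x, -0.2 * y), base, tolerance = 1e-10)
})

test_that("shared zero-lag components are rejected while real envelope
           coupling is kept", {
  # y = x + small independent noise: uncorrected envelope correlation is
  # near 1 but the leakage-corrected value collapses to ~0
  pairA <- noisePair(30000, 250, betaBand(), seed = 63)
  pairB <- noisePair(30000, 250, betaBand(), seed = 64)
  x <- tsData(pairA)[1, 1, ]
  y <- x + 0.05 * tsData(pairB)[1, 1, ]
  expect_gt(envelopeCorrelation(x, y), 0.9)
  expect_lt(abs(aecCorrected(x, y)), 0.1)

  # planted envelope sharing at coupling 0.8 survives the correction:
  # AEC-c within 0.1 of the ground-truth envelope correlation
  spec <- cohortSpec(nSubjects = 2, nFHpos = 1, nRegions = 4, nEpochs = 1,
                     epochSamples = 30000, fs = 250,
                     bands = list(alphaBand()), seed = 65)
  ts <- suppressMessages(generateSubjectTimeSeries(spec, coupling = 0.8,
                                                   seed = 66))
  st <- suppressMessages(connectivityStack(ts, alphaBand()))
  env <- groundTruth(ts)$envelopes$alpha
  prs <- combn(4, 2)
  for (k in seq_len(ncol(prs))) {
    i <- prs[1, k]; j <- prs[2, k]
    oracle <- cor(env[i + 1, 1, ], env[j + 1, 1, ])
    expect_equal(epochMatrix(st, 1)[i, j], oracle, tolerance = 0.1,
                 info = sprintf("pair %d-%d", i, j))
  }
})

test_that("independent generator signals have near-zero AEC-c", {
  spec <- cohortSpec(nSubjects = 2, nFHpos = 1, nRegions = 6, nEpochs = 1,
                     epochSamples = 30000, fs = 250,
                     bands = list(betaBand()), seed = 67)
  ts <- suppressMessages(generateSubjectTimeSeries(spec, coupling = 0,
                                                   seed = 68))
  st <- suppressMessages(connectivityStack(ts, betaBand()))
  prs <- combn(6, 2)
  vals <- apply(prs, 2, function(p) epochMatrix(st, 1)[p[1], p[2]])
  expect_lt(abs(mean(vals)), 0.05)     # 120 s, mean across the 15 pairs
})

test_that("the stack equals pairwise AEC-c and has the declared shape", {
  spec <- tinySpec(nRegions = 4, nEpochs = 3)
  ts <- suppressMessages(generateSubjectTimeSeries(spec, 0.5, seed = 69))
  st <- suppressMessages(connectivityStack(ts, alphaBand()))
  expect_equal(nEpochs(st), 3L)
  expect_equal(dim(epochMatrix(st, 1)), c(4L, 4L))
  flt <- suppressMessages(bandpassFilter(ts, alphaBand()))
  for (e in 1:3) {
    m <- epochMatrix(st, e)
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(0, 4))
    x <- tsData(flt)[2, e, ]
    y <- tsData(flt)[4, e, ]
    expect_equal(m[2, 4], aecCorrected(x, y), tolerance = 1e-10)
  }
})

test_that("a duplicated region yields a zero entry with a warning", {
  spec <- tinySpec(nRegions = 4, nEpochs = 1)
  ts <- suppressMessages(generateSubjectTimeSeries(spec, 0.3, seed = 70))
  d <- tsData(ts)
  d[2, , ] <- d[1, , ]
  dup <- epochedTimeSeries(d, fs = samplingRate(ts))
  expect_warning(st <- suppressMessages(connectivityStack(dup, alphaBand())),
                 "collinear")
  expect_equal(epochMatrix(st, 1)[1, 2], 0)
  expect_gt(abs(epochMatrix(st, 1)[3, 4]), 0)   # other pairs unaffected
})
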