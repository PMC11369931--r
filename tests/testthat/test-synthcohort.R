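# Synthetic cohort generator.

test_that("generation is a pure function of spec and seed", {
  spec <- tinySpec()
  a <- suppressMessages(generateSubjectTimeSeries(spec, 0.4, seed = 7))
  b <- suppressMessages(generateSubjectTimeSeries(spec, 0.4, seed = 7))
  expect_identical(tsData(a), tsData(b))
  c1 <- generateCohort(spec, timeseries = FALSE)
  c2 <- generateCohort(spec, timeseries = FALSE)
  expect_identical(c1$cohort, c2$cohort)
  c3 <- generateCohort(tinySpec(seed = 2), timeseries = FALSE)
  expect_false(identical(c1$cohort$biomarker, c3$cohort$biomarker))
})

test_that("cohort composition and coupling validation follow the spec", {
  spec <- cohortSpec(nSubjects = 76, nFHpos = 54, nRegions = 4,
                     nEpochs = 1, epochSamples = 128, fs = 250,
                     bands = list(alphaBand()), seed = 3)
  coh <- generateCohort(spec, timeseries = FALSE)$cohort
  expect_equal(as.vector(table(coh$group)[c("FH+", "FH-")]), c(54L, 22L))
  expect_true(all(coh$biomarker > 0))
  expect_true(all(coh$coupling_true >= 0 & coh$coupling_true < 1))

  expect_error(generateSubjectTimeSeries(tinySpec(), coupling = 1.2),
               "coupling")
  expect_error(cohortSpec(nSubjects = 5, nFHpos = 9), "nFHpos")
  expect_error(cohortSpec(nRegions = 2), "nRegions")
})

test_that("the biomarker link is exact without noise and null with zero
           effect", {
  noiseless <- tinySpec(nSubjects = 30, nFHpos = 20, noiseSd = 0,
                        effectSize = 400)
  coh <- generateCohort(noiseless, timeseries = FALSE)$cohort
  expect_equal(cor(coh$biomarker, coh$coupling_true, method = "spearman"), 1)

  # effect_size = 0: mean signed correlation over replicate cohorts ~ 0
  rhos <- vapply(1:200, function(r) {
    spec <- cohortSpec(nSubjects = 76, nFHpos = 54, nRegions = 4,
                       nEpochs = 1, epochSamples = 128, fs = 250,
                       bands = list(alphaBand()), effectSize = 0, seed = r)
    coh <- generateCohort(spec, timeseries = FALSE)$cohort
    cor(coh$biomarker, coh$coupling_true)
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("stored ground-truth envelopes reproduce the planted correlation", {
  spec <- cohortSpec(nSubjects = 2, nFHpos = 1, nRegions = 6, nEpochs = 10,
                     epochSamples = 1024, fs = 250,
                     bands = list(alphaBand()), seed = 8)
  ts <- suppressMessages(generateSubjectTimeSeries(spec, coupling = 0.8,
                                                   seed = 9))
  env <- groundTruth(ts)$envelopes$alpha
  prs <- combn(6, 2)
  rs <- apply(prs, 2, function(p)
    cor(as.vector(env[p[1] + 1, , ]), as.vector(env[p[2] + 1, , ])))
  # ~41 s of envelope at ~1.25 Hz modulation: 3 SE is about 0.1 per pair,
  # tighter for the across-pair mean
  expect_lt(abs(mean(rs) - 0.8), 0.05)
  expect_true(all(abs(rs - 0.8) < 0.15))
  expect_true(all(env > 0))
})

test_that("toy trees and random matrices satisfy their contracts", {
  expect_error(makeToyTree("y", 6), "5 nodes")
  expect_equal(degreeSequence(makeToyTree("star", 10))[1L], 9L)
  expect_equal(sum(degreeSequence(makeToyTree("path", 10)) == 1L), 2L)

  m <- makeRandomMatrix(80, seed = 12)
  up <- m[upper.tri(m)]
  expect_equal(length(unique(up)), 3160L)      # 80*79/2 distinct weights
  expect_true(all(up > 0 & up < 1))
  expect_equal(m, t(m))
  expect_identical(m, makeRandomMatrix(80, seed = 12))

  # random trees are valid spanning trees with distinct weights
  for (seed in 1:5) {
    tr <- makeToyTree("random", 8, seed = seed)
    expect_s4_class(tr, "SpanningTree")       # validity enforces tree-ness
    expect_equal(length(unique(edgeList(tr)[, "weight"])), 7L)
  }
})
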