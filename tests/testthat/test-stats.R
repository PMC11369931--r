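# Statistical battery: correlations, FDR, group tests.

test_that("Pearson correlation matches hand computation and null theory", {
  r <- pearsonCorr(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$estimate, 0.6)

  perfect <- pearsonCorr(1:10, 2 * (1:10) + 1)
  expect_equal(perfect$estimate, 1)
  expect_lt(perfect$p_raw, 1e-12)

  expect_error(pearsonCorr(rep(1, 5), rnorm(5)), "variance")

  # null p-values are uniform (KS over 1000 replicates at n = 76)
  set.seed(11)
  p <- replicate(1000, pearsonCorr(rnorm(76), rnorm(76))$p_raw)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH step-up matches the brute-force definition", {
  set.seed(21)
  for (i in 1:1000) {
    M <- sample(1:20, 1)
    p <- round(runif(M), 3)           # rounding provokes ties
    got <- bhFdr(p, q = 0.1)
    ref <- bruteForceBH(p, q = 0.1)
    expect_equal(got$adjusted, ref$adjusted, tolerance = 1e-12)
    expect_equal(got$significant, ref$significant)
    expect_equal(got$threshold, ref$threshold)
  }
})

test_that("BH adjusted values are monotone in raw p and bounded", {
  set.seed(22)
  for (i in 1:50) {
    p <- runif(sample(3:30, 1))
    adj <- bhFdr(p)$adjusted
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-12))
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
  }
  one <- bhFdr(0.05, q = 0.1)
  expect_equal(one$adjusted, 0.05)
  expect_true(one$significant)
  expect_error(bhFdr(numeric(0)), "non-empty")
})

test_that("pooled t-test reproduces the direct formula and t.test", {
  same <- twoSampleT(mean1 = 5, sd1 = 1, n1 = 10, mean2 = 5, sd2 = 1,
                     n2 = 10)
  expect_equal(same$estimate, 0)
  expect_equal(same$p_raw, 1)

  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(sample(5:40, 1), 0.3)
    viaSummary <- twoSampleT(mean1 = mean(x), sd1 = sd(x), n1 = length(x),
                             mean2 = mean(y), sd2 = sd(y), n2 = length(y))
    raw <- twoSampleT(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(viaSummary$estimate, unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(raw$p_raw, ref$p.value, tolerance = 1e-12)
  }
  expect_error(twoSampleT(mean1 = 1, sd1 = 1, n1 = 1, mean2 = 2, sd2 = 1,
                          n2 = 5), "n >= 2")
})

test_that("2x2 chi-square equals the closed-form cross-product formula", {
  even <- chiSquare2x2(matrix(10, 2, 2))
  expect_equal(even$estimate, 0)

  set.seed(41)
  for (i in 1:20) {
    tab <- matrix(sample(5:50, 4), 2)
    got <- chiSquare2x2(tab)$estimate
    N <- sum(tab)
    ref <- N * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
      prod(rowSums(tab), colSums(tab))
    expect_equal(got, ref, tolerance = 1e-12)
  }
  expect_error(chiSquare2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("Fisher r-to-z comparison is one-tailed and group-symmetric", {
  eq <- compareCorrelations(0.4, 30, 0.4, 40)
  expect_equal(eq$estimate, 0)
  expect_equal(eq$p_raw, 0.5)

  a <- compareCorrelations(-0.373, 54, 0.258, 22)
  b <- compareCorrelations(0.258, 22, -0.373, 54)
  expect_equal(a$p_raw, b$p_raw)
  expect_error(compareCorrelations(1, 10, 0.5, 10), "\\|r\\| < 1")
})

test_that("the association battery assembles its two FDR families", {
  set.seed(51)
  n <- 24
  tab <- data.frame(subject_id = seq_len(n),
                    group = rep(c("FH+", "FH-"), c(14, 10)),
                    biomarker = rnorm(n, 380, 150))
  for (b in c("theta", "alpha", "beta"))
    for (m in c("LF", "D", "TH"))
      tab[[paste(b, m, sep = "_")]] <- runif(n)
  res <- runAssociationBattery(tab)
  expect_equal(nrow(res$whole), 9L)       # 3 bands x 3 metrics
  expect_equal(nrow(res$subgroup), 18L)   # both groups pooled in one family
  expect_equal(nrow(res$comparison), 9L)
  expect_equal(res$whole$q_adj, bhFdr(res$whole$p_raw)$adjusted)
  expect_equal(res$subgroup$q_adj, bhFdr(res$subgroup$p_raw)$adjusted)

  # demographic screens appear when covariates are present
  tab$age <- rnorm(n, 61, 6)
  tab$education <- rnorm(n, 18, 5)
  tab$sex <- rep(c("M", "F"), n / 2)
  res2 <- runAssociationBattery(tab)
  expect_setequal(res2$demographics$test,
                  c("biomarker_vs_age", "biomarker_vs_education",
                    "biomarker_by_sex", "sex_by_group"))

  expect_error(runAssociationBattery(tab[, setdiff(names(tab), "biomarker")]),
               "biomarker")
})
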