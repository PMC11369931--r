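# Statistical battery: Pearson correlations under BH FDR control, pooled t,
# chi-square, one-tailed Fisher r-to-z comparison of group correlations.

#' Pearson correlation with t-distributed p-value
#'
#' Two-tailed Pearson correlation test (`stats::cor.test`): p-value from
#' the t distribution with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (`n >= 3`), each with
#'   nonzero variance.
#' @return One-row data.frame with columns `estimate`, `p_raw`, `n`.
#' @examples
#' pearsonCorr(c(1, 2, 3, 4), c(2, 1, 4, 3))  # rho = 0.6
#' @export
pearsonCorr <- function(x, y) {
  .stopIfNot(length(x) == length(y), "'x' and 'y' must have equal length")
  .stopIfNot(length(x) >= 3L, "at least 3 observations are required")
  .stopIfNot(all(is.finite(x)) && all(is.finite(y)),
             "inputs must be finite")
  .stopIfNot(stats::sd(x) > 0 && stats::sd(y) > 0,
             "degenerate input: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(estimate = unname(ct$estimate), p_raw = ct$p.value,
             n = length(x))
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Adjusted values via `stats::p.adjust(method = "BH")`; the rejection set
#' is all p at or below the step-up boundary, the largest sorted `p_(k)`
#' with `p_(k) <= k q / M`. The reported `threshold` is that boundary raw
#' p-value (0 when nothing is rejected), the convention used when quoting
#' a "threshold for significance" alongside FDR-corrected tables.
#'
#' @param pvals vector of raw p-values in `[0, 1]`.
#' @param q FDR level (default 0.1).
#' @return List with `adjusted` (same order as input), `significant`
#'   (logical), and `threshold` (raw-p rejection boundary).
#' @export
bhFdr <- function(pvals, q = 0.1) {
  .stopIfNot(length(pvals) >= 1L, "'pvals' must be non-empty")
  .stopIfNot(all(is.finite(pvals)) && all(pvals >= 0) && all(pvals <= 1),
             "p-values must lie in [0, 1]")
  M <- length(pvals)
  s <- sort(pvals)
  ok <- which(s <= seq_len(M) * q / M)
  threshold <- if (length(ok)) unname(s[max(ok)]) else 0
  list(adjusted = stats::p.adjust(pvals, method = "BH"),
       significant = if (length(ok)) pvals <= threshold
                     else rep(FALSE, M),
       threshold = threshold)
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with `n1 + n2 - 2` degrees of freedom and the pooled
#' variance estimate, two-tailed. Accepts either raw samples (`x`, `y`) or
#' group summaries (`mean1, sd1, n1, mean2, sd2, n2`), so printed summary
#' tables can be re-tested directly.
#'
#' @param x,y optional raw samples.
#' @param mean1,sd1,n1,mean2,sd2,n2 optional group summaries.
#' @return One-row data.frame with `estimate` (t), `p_raw`, `df`,
#'   `n1`, `n2`.
#' @examples
#' twoSampleT(mean1 = 390.706, sd1 = 147.107, n1 = 54,
#'            mean2 = 359.58, sd2 = 174.491, n2 = 22)  # t = 0.792
#' @export
twoSampleT <- function(x = NULL, y = NULL, mean1 = NULL, sd1 = NULL,
                       n1 = NULL, mean2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(x) || !is.null(y)) {
    .stopIfNot(!is.null(x) && !is.null(y),
               "both 'x' and 'y' are required for the raw-sample form")
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  .stopIfNot(!is.null(mean1) && !is.null(sd1) && !is.null(n1) &&
               !is.null(mean2) && !is.null(sd2) && !is.null(n2),
             "supply raw samples or complete summaries")
  .stopIfNot(n1 >= 2 && n2 >= 2, "both groups need n >= 2")
  .stopIfNot(sd1 > 0 || sd2 > 0, "degenerate input: zero variance")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  data.frame(estimate = t, p_raw = 2 * stats::pt(-abs(t), df), df = df,
             n1 = n1, n2 = n2)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square with 1 degree of freedom, without continuity
#' correction.
#'
#' @param counts 2x2 matrix of nonnegative counts; both margins positive.
#' @return One-row data.frame with `estimate` (chi-square), `p_raw`, `df`.
#' @examples
#' chiSquare2x2(matrix(c(17, 10, 37, 12), 2))  # 1.332
#' @export
chiSquare2x2 <- function(counts) {
  counts <- as.matrix(counts)
  .stopIfNot(all(dim(counts) == 2L), "'counts' must be a 2x2 table")
  .stopIfNot(all(counts >= 0), "counts must be nonnegative")
  .stopIfNot(all(rowSums(counts) > 0) && all(colSums(counts) > 0),
             "both margins must be positive")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  data.frame(estimate = unname(ct$statistic), p_raw = ct$p.value, df = 1L)
}

#' One-tailed Fisher r-to-z comparison of two correlations
#'
#' Tests whether two independent Pearson correlations differ using the
#' variance-stabilizing transform `z_k = atanh(r_k)`:
#' `z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`, reported with the
#' one-tailed p-value `1 - Phi(|z|)`. The p-value is symmetric in the two
#' groups.
#'
#' @param r1,n1 correlation and sample size of the first group.
#' @param r2,n2 correlation and sample size of the second group.
#' @return One-row data.frame with `estimate` (z), `p_raw`, `n1`, `n2`.
#' @examples
#' compareCorrelations(-0.373, 54, 0.258, 22)  # p = 0.007
#' @export
compareCorrelations <- function(r1, n1, r2, n2) {
  .stopIfNot(abs(r1) < 1 && abs(r2) < 1,
             "correlations must satisfy |r| < 1")
  .stopIfNot(n1 >= 4 && n2 >= 4, "both groups need n >= 4")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  data.frame(estimate = z, p_raw = 1 - stats::pnorm(abs(z)),
             n1 = n1, n2 = n2)
}

#' The full association battery over a cohort table
#'
#' Runs, over a cohort table carrying epoch-averaged tree metrics per band
#' plus a biomarker and a two-level group label:
#' \enumerate{
#'   \item whole-sample Pearson correlation of every `band x metric` column
#'     against the biomarker, with BH FDR over that family of
#'     `length(bands) * length(metrics)` tests;
#'   \item the same correlations within each group, with BH over the single
#'     pooled family (both groups, all bands and metrics together);
#'   \item a one-tailed Fisher r-to-z comparison of the two group
#'     correlations per `band x metric` cell;
#'   \item the TH-LF Pearson correlation within each group, for bands whose
#'     within-group TH correlation is significant in (2);
#'   \item demographic screens when the columns are present: biomarker vs
#'     `age` and `education` (Pearson), biomarker by `sex` (pooled t), and
#'     `sex` by group (chi-square).
#' }
#'
#' @param table data.frame with columns `biomarker`, `group` (two levels)
#'   and `<band>_<metric>` for every requested band and metric; optional
#'   `age`, `sex`, `education`.
#' @param q FDR level for both families (default 0.1).
#' @param bands,metrics character vectors naming the metric columns.
#' @return List of tidy data.frames: `whole`, `subgroup`, `comparison`,
#'   `thLf`, `demographics`, plus `thresholds` (raw-p rejection boundaries
#'   of the two FDR families).
#' @export
runAssociationBattery <- function(table, q = 0.1,
                                  bands = c("theta", "alpha", "beta"),
                                  metrics = c("LF", "D", "TH")) {
  cells <- expand.grid(band = bands, metric = metrics,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[order(match(cells$band, bands),
                       match(cells$metric, metrics)), ]
  need <- c("biomarker", "group", paste(cells$band, cells$metric, sep = "_"))
  missing <- setdiff(need, names(table))
  .stopIfNot(length(missing) == 0L, "missing columns: %s",
             paste(missing, collapse = ", "))
  groups <- unique(table$group)
  .stopIfNot(length(groups) == 2L, "'group' must have exactly two levels")
  for (g in groups)
    .stopIfNot(sum(table$group == g) >= 4L,
               "group '%s' needs at least 4 subjects", g)

  one <- function(df, band, metric) {
    res <- pearsonCorr(df[[paste(band, metric, sep = "_")]], df$biomarker)
    cbind(data.frame(band = band, metric = metric), res)
  }
  # (1) whole-sample family
  whole <- do.call(rbind, Map(one, list(table), cells$band, cells$metric))
  fw <- bhFdr(whole$p_raw, q = q)
  whole$q_adj <- fw$adjusted
  whole$significant <- fw$significant
  whole <- cbind(family = "whole", whole)
  # (2) pooled subgroup family
  sub <- do.call(rbind, lapply(groups, function(g) {
    df <- table[table$group == g, ]
    cbind(group = g,
          do.call(rbind, Map(one, list(df), cells$band, cells$metric)))
  }))
  fs <- bhFdr(sub$p_raw, q = q)
  sub$q_adj <- fs$adjusted
  sub$significant <- fs$significant
  sub <- cbind(family = "subgroup", sub)
  # (3) per-cell group comparison
  comparison <- do.call(rbind, Map(function(band, metric) {
    a <- sub[sub$group == groups[1L] & sub$band == band &
               sub$metric == metric, ]
    b <- sub[sub$group == groups[2L] & sub$band == band &
               sub$metric == metric, ]
    cbind(data.frame(band = band, metric = metric),
          compareCorrelations(a$estimate, a$n, b$estimate, b$n))
  }, cells$band, cells$metric))
  rownames(comparison) <- NULL
  # (4) TH-LF interpretation aid for significant within-group TH results
  sigTH <- sub[sub$metric == "TH" & sub$significant, c("group", "band")]
  thLf <- if (nrow(sigTH)) do.call(rbind, lapply(seq_len(nrow(sigTH)),
    function(k) {
      g <- sigTH$group[k]; band <- sigTH$band[k]
      df <- table[table$group == g, ]
      cbind(data.frame(group = g, band = band),
            pearsonCorr(df[[paste0(band, "_TH")]],
                        df[[paste0(band, "_LF")]]))
    }))
  else data.frame(group = character(), band = character(),
                  estimate = numeric(), p_raw = numeric(), n = integer())
  # (5) demographic screens
  demo <- list()
  if ("age" %in% names(table))
    demo$age <- cbind(test = "biomarker_vs_age",
                      pearsonCorr(table$age, table$biomarker))
  if ("education" %in% names(table))
    demo$education <- cbind(test = "biomarker_vs_education",
                            pearsonCorr(table$education, table$biomarker))
  if ("sex" %in% names(table)) {
    sexes <- unique(table$sex)
    if (length(sexes) == 2L) {
      tt <- twoSampleT(table$biomarker[table$sex == sexes[1L]],
                       table$biomarker[table$sex == sexes[2L]])
      demo$sexT <- cbind(test = "biomarker_by_sex",
                         tt[, c("estimate", "p_raw")],
                         n = tt$n1 + tt$n2)
      cs <- chiSquare2x2(table(table$sex, table$group))
      demo$sexChi <- cbind(test = "sex_by_group",
                           cs[, c("estimate", "p_raw")],
                           n = nrow(table))
    }
  }
  demographics <- if (length(demo))
    do.call(rbind, lapply(demo, function(d) {
      rownames(d) <- NULL
      d[, c("test", "estimate", "p_raw", "n")]
    }))
  else data.frame(test = character(), estimate = numeric(),
                  p_raw = numeric(), n = integer())
  rownames(demographics) <- NULL
  rownames(whole) <- rownames(sub) <- rownames(thLf) <- NULL
  list(whole = whole, subgroup = sub, comparison = comparison,
       thLf = thLf, demographics = demographics,
       thresholds = list(whole = fw$threshold, subgroup = fs$threshold))
}
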