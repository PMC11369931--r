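# File-based pipeline: simulate -> connectivity -> mst -> stats.
# Plain-text interchange (TSV/CSV/JSON) for auditability; every stage
# writes the resolved configuration and a parameter log next to its output.

#' Pipeline configuration
#'
#' Bundles everything a pipeline run needs: output root, cohort spec,
#' bands, filter parameters, FDR level and seed. Serializable to JSON via
#' [writeConfig()] / [readConfig()]; every stage writes the resolved
#' configuration next to its outputs.
#'
#' @param outDir output root directory.
#' @param spec a [CohortSpec-class] (default [scaledCohortSpec()]).
#' @param bands list of [BandSpec-class] to analyse (defaults to the
#'   spec's bands).
#' @param filterOrder,padSamples band-pass filter parameters.
#' @param q FDR level.
#' @param seed overrides the spec's seed when given.
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(outDir, spec = scaledCohortSpec(), bands = NULL,
                           filterOrder = 450, padSamples = 2000, q = 0.1,
                           seed = NULL) {
  if (!is.null(seed)) spec@seed <- as.integer(seed)
  if (is.null(bands)) bands <- spec@bands
  structure(list(outDir = outDir, spec = spec, bands = bands,
                 filterOrder = filterOrder, padSamples = padSamples, q = q),
            class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param config a `PipelineConfig`.
#' @param path JSON file path.
#' @export
writeConfig <- function(config, path) {
  s <- config$spec
  lst <- list(
    outDir = config$outDir,
    filterOrder = config$filterOrder, padSamples = config$padSamples,
    q = config$q,
    bands = lapply(config$bands, function(b)
      list(name = b@name, low = b@low, high = b@high)),
    spec = list(nSubjects = s@nSubjects, nFHpos = s@nFHpos,
                nRegions = s@nRegions, nEpochs = s@nEpochs,
                epochSamples = s@epochSamples, fs = s@fs,
                bands = lapply(s@bands, function(b)
                  list(name = b@name, low = b@low, high = b@high)),
                couplingBase = s@couplingBase, couplingSd = s@couplingSd,
                effectSize = s@effectSize, noiseSd = s@noiseSd,
                intercept = s@intercept, seed = s@seed))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readConfig <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  mkBands <- function(bl) lapply(bl, function(b)
    bandSpec(b$name, b$low, b$high))
  s <- lst$spec
  spec <- cohortSpec(nSubjects = s$nSubjects, nFHpos = s$nFHpos,
                     nRegions = s$nRegions, nEpochs = s$nEpochs,
                     epochSamples = s$epochSamples, fs = s$fs,
                     bands = mkBands(s$bands),
                     couplingBase = s$couplingBase,
                     couplingSd = s$couplingSd, effectSize = s$effectSize,
                     noiseSd = s$noiseSd, intercept = s$intercept,
                     seed = s$seed)
  pipelineConfig(outDir = lst$outDir, spec = spec, bands = mkBands(lst$bands),
                 filterOrder = lst$filterOrder, padSamples = lst$padSamples,
                 q = lst$q)
}

.stageDir <- function(config, stage) {
  d <- file.path(config$outDir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

.logLine <- function(dir, ...) {
  cat(sprintf(...), "\n", sep = "",
      file = file.path(dir, "pipeline.log"), append = TRUE)
}

.provenance <- function(config, dir, stage) {
  writeConfig(config, file.path(dir, "config.json"))
  .logLine(dir, "stage=%s seed=%d filterOrder=%d padSamples=%d q=%g",
           stage, config$spec@seed, config$filterOrder, config$padSamples,
           config$q)
}

#' Write / read a tree as an edge-list TSV
#'
#' Three columns (`node_i`, `node_j`, `weight`) preceded by a comment
#' header line `# N=<n>` carrying the node count.
#'
#' @param tree a [SpanningTree-class].
#' @param path TSV file path.
#' @return `readTreeTSV` returns a [SpanningTree-class];
#'   `writeTreeTSV` returns the path invisibly.
#' @export
writeTreeTSV <- function(tree, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# N=%d\n", nNodes(tree)), file = con)
  df <- as.data.frame(edgeList(tree))
  names(df) <- c("node_i", "node_j", "weight")
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTreeTSV
#' @export
readTreeTSV <- function(path) {
  hdr <- readLines(path, n = 1L)
  n <- as.integer(sub("^# N=", "", hdr))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  spanningTree(as.matrix(df), nNodes = n)
}

#' Pipeline stages
#'
#' File-based pipeline verbs. `cmdSimulate` draws the synthetic cohort and
#' writes one time-series TSV per subject (long format: epoch, sample, one
#' column per region), the cohort CSV and a ground-truth sidecar.
#' `cmdConnectivity` computes per-epoch AEC-c matrices per subject and band
#' (long TSV: epoch, region_i, region_j, aec). `cmdMst` extracts the
#' per-epoch spanning trees (edge-list TSVs) and writes per-epoch and
#' epoch-averaged metric tables. `cmdStats` joins the averaged metrics with
#' the cohort table and runs [runAssociationBattery()]. `cmdRunAll` chains
#' all four and writes a summary report (rho and p per band x metric for
#' the whole sample and both groups).
#'
#' @param config a [pipelineConfig()].
#' @return Each stage invisibly returns its main output paths; `cmdStats`
#'   and `cmdRunAll` return the battery result list.
#' @export
cmdSimulate <- function(config) {
  dir <- .stageDir(config, "timeseries")
  .provenance(config, dir, "simulate")
  gen <- generateCohort(config$spec, timeseries = TRUE, storeTruth = FALSE)
  paths <- character(0)
  for (s in seq_along(gen$timeseries)) {
    ts <- gen$timeseries[[s]]
    d <- tsData(ts)
    long <- do.call(rbind, lapply(seq_len(nEpochs(ts)), function(e) {
      m <- t(d[, e, ])
      colnames(m) <- regionLabels(ts)
      data.frame(epoch = e, sample = seq_len(nrow(m)), m,
                 check.names = FALSE)
    }))
    p <- file.path(dir, sprintf("%s.tsv", gen$cohort$subject_id[s]))
    utils::write.table(format(long, digits = 8, trim = TRUE), p,
                       sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  utils::write.csv(gen$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  truth <- gen$cohort[, c("subject_id", "coupling_true")]
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  .logLine(dir, "subjects=%d files=%d", config$spec@nSubjects, length(paths))
  invisible(c(paths, file.path(dir, "cohort.csv")))
}

.readSubjectTS <- function(path, fs) {
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
  regions <- setdiff(names(long), c("epoch", "sample"))
  epochs <- sort(unique(long$epoch))
  n <- sum(long$epoch == epochs[1L])
  a <- array(NA_real_, dim = c(length(regions), length(epochs), n))
  for (e in seq_along(epochs)) {
    m <- as.matrix(long[long$epoch == epochs[e], regions, drop = FALSE])
    a[, e, ] <- t(m)
  }
  epochedTimeSeries(a, fs = fs, regionLabels = regions)
}

#' @rdname cmdSimulate
#' @export
cmdConnectivity <- function(config) {
  src <- file.path(config$outDir, "timeseries")
  cohortFile <- file.path(src, "cohort.csv")
  .stopIfNot(file.exists(cohortFile),
             "missing upstream artifact: %s (run cmdSimulate first)",
             cohortFile)
  dir <- .stageDir(config, "connectivity")
  .provenance(config, dir, "connectivity")
  cohort <- utils::read.csv(cohortFile)
  paths <- character(0)
  for (sid in cohort$subject_id) {
    f <- file.path(src, sprintf("%s.tsv", sid))
    .stopIfNot(file.exists(f), "missing upstream artifact: %s", f)
    ts <- .readSubjectTS(f, fs = config$spec@fs)
    for (band in config$bands) {
      stack <- connectivityStack(ts, band, order = config$filterOrder,
                                 padSamples = config$padSamples)
      idx <- which(upper.tri(matrix(0, nRegions(stack), nRegions(stack))),
                   arr.ind = TRUE)
      long <- do.call(rbind, lapply(seq_len(nEpochs(stack)), function(e) {
        m <- epochMatrix(stack, e)
        data.frame(epoch = e, region_i = idx[, 1L], region_j = idx[, 2L],
                   aec = m[idx])
      }))
      p <- file.path(dir, sprintf("conn_%s_%s.tsv", sid, band@name))
      utils::write.table(long, p, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

.connToMatrices <- function(path, nRegions) {
  long <- utils::read.table(path, header = TRUE, sep = "\t")
  lapply(sort(unique(long$epoch)), function(e) {
    sl <- long[long$epoch == e, ]
    m <- matrix(0, nRegions, nRegions)
    m[cbind(sl$region_i, sl$region_j)] <- sl$aec
    m + t(m)
  })
}

#' @rdname cmdSimulate
#' @export
cmdMst <- function(config) {
  src <- file.path(config$outDir, "connectivity")
  .stopIfNot(dir.exists(src),
             "missing upstream artifact: %s (run cmdConnectivity first)", src)
  dir <- .stageDir(config, "mst")
  .provenance(config, dir, "mst")
  files <- list.files(src, pattern = "^conn_.*\\.tsv$", full.names = TRUE)
  .stopIfNot(length(files) > 0L, "no connectivity files found in %s", src)
  perEpoch <- list()
  averaged <- list()
  for (f in files) {
    base <- sub("^conn_(.*)\\.tsv$", "\\1", basename(f))
    sid <- sub("_[^_]+$", "", base)
    band <- sub("^.*_", "", base)
    mats <- .connToMatrices(f, config$spec@nRegions)
    for (e in seq_along(mats)) {
      tr <- mstFromMatrix(mats[[e]])
      writeTreeTSV(tr, file.path(dir, sprintf("mst_%s_%s_e%02d.tsv",
                                              sid, band, e)))
    }
    sm <- subjectMetrics(mats)
    pe <- attr(sm, "perEpoch")
    perEpoch[[base]] <- cbind(subject_id = sid, band = band, pe)
    averaged[[base]] <- data.frame(subject_id = sid, band = band,
                                   LF = sm[["LF"]], D = sm[["D"]],
                                   TH = sm[["TH"]])
  }
  utils::write.csv(do.call(rbind, perEpoch),
                   file.path(dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, averaged),
                   file.path(dir, "metrics_mean.csv"), row.names = FALSE)
  invisible(file.path(dir, c("metrics.csv", "metrics_mean.csv")))
}

#' Assemble the cohort table from pipeline outputs
#'
#' Joins the epoch-averaged metrics (wide: one `<band>_<metric>` column per
#' band and metric) with the cohort CSV.
#'
#' @param config a [pipelineConfig()].
#' @return A cohort data.frame ready for [runAssociationBattery()].
#' @export
buildCohortTable <- function(config) {
  mm <- file.path(config$outDir, "mst", "metrics_mean.csv")
  cf <- file.path(config$outDir, "timeseries", "cohort.csv")
  .stopIfNot(file.exists(mm), "missing upstream artifact: %s", mm)
  .stopIfNot(file.exists(cf), "missing upstream artifact: %s", cf)
  metrics <- utils::read.csv(mm)
  cohort <- utils::read.csv(cf)
  .stopIfNot("biomarker" %in% names(cohort),
             "missing columns: biomarker (in %s)", cf)
  wide <- stats::reshape(metrics, direction = "wide", idvar = "subject_id",
                         timevar = "band")
  names(wide) <- sub("^(LF|D|TH)\\.(.*)$", "\\2_\\1", names(wide))
  merge(cohort, wide, by = "subject_id")
}

#' @rdname cmdSimulate
#' @export
cmdStats <- function(config) {
  dir <- .stageDir(config, "stats")
  .provenance(config, dir, "stats")
  tab <- buildCohortTable(config)
  bandNames <- vapply(config$bands, function(b) b@name, character(1))
  res <- runAssociationBattery(tab, q = config$q, bands = bandNames)
  utils::write.csv(res$whole, file.path(dir, "whole.csv"),
                   row.names = FALSE)
  utils::write.csv(res$subgroup, file.path(dir, "subgroup.csv"),
                   row.names = FALSE)
  utils::write.csv(res$comparison, file.path(dir, "comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(res$thLf, file.path(dir, "th_lf.csv"), row.names = FALSE)
  report <- .summaryReport(res)
  utils::write.csv(report, file.path(dir, "summary_report.csv"),
                   row.names = FALSE)
  .logLine(dir, "fdr thresholds: whole=%g subgroup=%g",
           res$thresholds$whole, res$thresholds$subgroup)
  invisible(res)
}

# rho and p per band x metric for the whole sample and both groups,
# mirroring the layout of a correlation results table.
.summaryReport <- function(res) {
  w <- res$whole[, c("band", "metric", "estimate", "p_raw", "q_adj")]
  names(w)[3:5] <- c("rho_whole", "p_whole", "q_whole")
  out <- w
  for (g in unique(res$subgroup$group)) {
    sg <- res$subgroup[res$subgroup$group == g,
                       c("band", "metric", "estimate", "p_raw", "q_adj")]
    tag <- if (g == "FH+") "fhpos" else if (g == "FH-") "fhneg" else g
    names(sg)[3:5] <- paste0(c("rho_", "p_", "q_"), tag)
    out <- merge(out, sg, by = c("band", "metric"), sort = FALSE)
  }
  cmp <- res$comparison[, c("band", "metric", "p_raw")]
  names(cmp)[3L] <- "p_group_difference"
  merge(out, cmp, by = c("band", "metric"), sort = FALSE)
}

#' @rdname cmdSimulate
#' @export
cmdRunAll <- function(config) {
  cmdSimulate(config)
  cmdConnectivity(config)
  cmdMst(config)
  cmdStats(config)
}
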