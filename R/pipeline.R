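#' Run the full discovery-to-validation pipeline on synthetic data
#'
#' Orchestrates the stages simulate, differential expression, positional
#' association, gene-set enrichment, candidate selection, qPCR
#' quantification and ROC evaluation as one reproducible run. Stages
#' communicate only via plain-text files under \code{outDir}, so each is
#' independently inspectable and resumable, and a manifest records the
#' parameters, the seed, per-stage record counts (the discovery funnel)
#' and the MD5 checksum of every output; rerunning with the same
#' configuration reproduces the checksums.
#'
#' The qPCR stage derives per-sample relative expression of the shortlist
#' (selected candidates, padded with top-A differential lncRNAs up to
#' \code{nPanel} markers when selection is stricter than the data) from
#' the raw intensities, simulates replicate Cp measurements from it with
#' a stable reference gene, and quantifies them back with the
#' 2^-ddCp method; ROC evaluation fits the logistic panel on the training
#' cohort and, when \code{nValidationPairs > 0}, freezes it for an
#' independently simulated validation cohort.
#'
#' @param outDir output directory (created if needed).
#' @param sim a [SimConfig-class]; defaults describe a small paired
#'   study.
#' @param seed optional integer overriding \code{sim@seed}; also offsets
#'   the qPCR and validation-cohort seeds.
#' @param fcThreshold,fdrThreshold volcano thresholds (strict;
#'   \code{fdrThreshold >= 1} disables the FDR filter).
#' @param test t-test mode for the differential stage.
#' @param gateLow,gateHigh,ratio candidate-filter parameters.
#' @param neighborWindow association neighbor window (bases).
#' @param nGeneSets random gene sets drawn for the enrichment stage.
#' @param referenceGene reference gene id for the qPCR stage.
#' @param calibrator ddCp calibration scheme (group-mean-of-normals by
#'   default so normal samples retain variation for ROC analysis).
#' @param nPanel maximum panel size.
#' @param nValidationPairs pairs in the independently simulated
#'   validation cohort (0 = none).
#' @param cpNoiseSd replicate noise of the simulated Cp measurements.
#' @return invisibly, the manifest list (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(outDir, sim = SimConfig(), seed = NULL,
                        fcThreshold = 2.0, fdrThreshold = 0.05,
                        test = c("two_sample", "paired"),
                        gateLow = 100, gateHigh = 20000, ratio = 10,
                        neighborWindow = 300000L, nGeneSets = 10L,
                        referenceGene = "ACTB",
                        calibrator = "group_mean_normal",
                        nPanel = 5L, nValidationPairs = 0L,
                        cpNoiseSd = 0.1) {
  test <- match.arg(test)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) sim@seed <- as.integer(seed)
  funnel <- list()
  outputs <- character()
  emit <- function(name, writer, obj) {
    p <- file.path(outDir, name)
    writer(obj, p)
    outputs <<- c(outputs, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## 1 -- simulate
  sim1 <- stage("simulate", {
    s <- simulateExpression(sim)
    ann <- simulateAnnotation(sim, s$truth)
    emit("expression.tsv", writeExpression, s$expr)
    emit("annotation.tsv", writeAnnotation, ann)
    emit("ground_truth.tsv", function(o, p)
      utils::write.table(as.data.frame(o), p, sep = "\t", quote = FALSE,
                         row.names = FALSE), s$truth)
    c(s, list(ann = ann))
  })
  funnel$probes <- nrow(sim1$expr)
  message("simulate: ", funnel$probes, " probes, ",
          sim@nPairs, " pairs")

  ## 2 -- normalize + differential expression
  de <- stage("de", runDifferentialExpression(
    sim1$expr, test = test, fcThreshold = fcThreshold,
    fdrThreshold = fdrThreshold))
  deLnc <- de[de$class == "lncRNA", ]
  deMrna <- de[de$class == "mRNA", ]
  stage("de", {
    emit("de_lncrna.tsv", writeDEResult, deLnc)
    emit("de_mrna.tsv", writeDEResult, deMrna)
  })
  funnel$deLnc <- sum(deLnc$passesFilter)
  funnel$deMrna <- sum(deMrna$passesFilter)
  message("de: ", funnel$deLnc, " DE lncRNAs, ",
          funnel$deMrna, " DE mRNAs")

  ## 3 -- positional association + co-expression
  assoc <- stage("associate", {
    rec <- associationRecords(sim1$ann, neighborWindow = neighborWindow)
    emit("associations.tsv", function(o, p)
      utils::write.table(o, p, sep = "\t", quote = FALSE,
                         row.names = FALSE), rec)
    summ <- coexpressionTable(deLnc, deMrna, rec)
    emit("coexpression_summary.tsv", function(o, p)
      utils::write.table(o, p, sep = "\t", quote = FALSE,
                         row.names = FALSE), summ)
    list(records = rec, summary = summ)
  })
  funnel$coDE <- sum(assoc$summary$nBothDE)

  ## 4 -- enrichment against random gene sets over the mRNA universe
  stage("enrich", {
    universe <- deMrna$probeId
    set.seed(sim@seed + 1L)
    sets <- split(sample(universe),
                  rep_len(seq_len(nGeneSets), length(universe)))
    names(sets) <- sprintf("SET%02d", seq_along(sets))
    emit("gene_sets.gmt", function(o, p) writeGMT(o, p), sets)
    enr <- enrichGeneSets(universe[deMrna$passesFilter], sets, universe)
    emit("enrichment.tsv", function(o, p)
      utils::write.table(o, p, sep = "\t", quote = FALSE,
                         row.names = FALSE), enr)
  })

  ## 5 -- candidate selection on raw intensities of DE lncRNAs
  cand <- stage("select", selectCandidates(
    sim1$expr, deLnc$probeId[deLnc$passesFilter],
    gateLow = gateLow, gateHigh = gateHigh, ratio = ratio))
  stage("select", emit("candidates.tsv", function(o, p)
    utils::write.table(as.data.frame(o), p, sep = "\t", quote = FALSE,
                       row.names = FALSE), cand$stats))
  selected <- c(cand$up, cand$down)
  funnel$candidates <- length(selected)
  message("select: ", length(cand$up), " up + ", length(cand$down),
          " down candidates")

  ## panel shortlist: selected candidates, padded by descending A
  shortlist <- selected
  if (length(shortlist) < min(nPanel, 2L)) {
    st <- as.data.frame(cand$stats)
    shortlist <- unique(c(shortlist, st$probeId))
  }
  shortlist <- utils::head(shortlist, nPanel)
  if (length(shortlist) == 0L)
    stop("pipeline stage 'qpcr' failed: no differential lncRNA to carry ",
         "forward", call. = FALSE)

  ## 6 -- qPCR: simulate Cp for the shortlist, quantify by 2^-ddCp
  rel <- stage("qpcr", {
    b <- pairedBlocks(sim1$expr)
    relTruth <- cbind(b$tumor[shortlist, , drop = FALSE],
                      b$normal[shortlist, , drop = FALSE])
    colnames(relTruth) <- c(paste0(b$pairs, "_T"), paste0(b$pairs, "_N"))
    relTruth <- relTruth / rowMeans(b$normal[shortlist, , drop = FALSE])
    grp <- rep(c("tumor", "normal"), each = length(b$pairs))
    cp <- simulateCpTable(relTruth, grp, cpNoiseSd = cpNoiseSd,
                          referenceGene = referenceGene,
                          seed = sim@seed + 2L)
    cp$pair <- sub("_[TN]$", "", cp$sample)
    emit("cp_table.csv", writeCpTable, cp)
    r <- relativeExpression(collapseReplicates(cp), referenceGene,
                            calibrator = calibrator)
    emit("relative_expression.tsv", function(o, p)
      utils::write.table(as.data.frame(o), p, sep = "\t", quote = FALSE,
                         row.names = FALSE), r)
    r
  })

  ## 7 -- ROC: single markers + logistic panel, optional validation cohort
  roc <- stage("roc", {
    train <- markerMatrix(rel)
    validation <- NULL
    if (nValidationPairs > 0L) {
      ## same population truth as the training cohort, new samples
      simV <- sim
      simV@nPairs <- as.integer(nValidationPairs)
      sv <- simulateExpression(simV, truth = sim1$truth,
                               sampleSeed = sim@seed + 3L)
      bv <- pairedBlocks(sv$expr)
      relTruthV <- cbind(bv$tumor[shortlist, , drop = FALSE],
                         bv$normal[shortlist, , drop = FALSE])
      colnames(relTruthV) <- c(paste0(bv$pairs, "_TV"),
                               paste0(bv$pairs, "_NV"))
      relTruthV <- relTruthV / rowMeans(bv$normal[shortlist, ,
                                                  drop = FALSE])
      grpV <- rep(c("tumor", "normal"), each = length(bv$pairs))
      cpV <- simulateCpTable(relTruthV, grpV, cpNoiseSd = cpNoiseSd,
                             referenceGene = referenceGene,
                             seed = sim@seed + 4L)
      cpV$pair <- sub("_[TN]V$", "", cpV$sample)
      relV <- relativeExpression(collapseReplicates(cpV), referenceGene,
                                 calibrator = calibrator)
      validation <- markerMatrix(relV)
    }
    ev <- evaluateCohorts(train, validation = validation,
                          panel = shortlist)
    emit("roc_table.tsv", function(o, p)
      utils::write.table(o, p, sep = "\t", quote = FALSE,
                         row.names = FALSE), ev$table)
    ev
  })
  panelRow <- roc$table[roc$table$marker == "panel" &
                          roc$table$cohort == "training", ]
  message("roc: training panel AUC ", round(panelRow$auc, 3))

  manifest <- list(
    package = as.character(utils::packageVersion("lncScreen")),
    seed = sim@seed,
    parameters = list(
      nPairs = sim@nPairs, nLnc = sim@nLnc, nMrna = sim@nMrna,
      fracDE = sim@fracDE, log2fcRange = sim@log2fcRange,
      pairSd = sim@pairSd, noiseSd = sim@noiseSd,
      fcThreshold = fcThreshold, fdrThreshold = fdrThreshold,
      test = test, gateLow = gateLow, gateHigh = gateHigh,
      ratio = ratio, neighborWindow = neighborWindow,
      referenceGene = referenceGene, calibrator = calibrator,
      nPanel = nPanel, nValidationPairs = nValidationPairs),
    funnel = funnel,
    panel = panelMarkers(roc$model),
    checksums = as.list(tools::md5sum(outputs)))
  names(manifest$checksums) <- basename(outputs)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
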