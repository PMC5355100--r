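#' Create a simulation configuration
#'
#' Defaults emulate a small paired microarray study: three tumor/normal
#' pairs, log-normal intensities centred near 1,000 (most probes falling in
#' the 100--20,000 working range of the candidate filter), a planted
#' fraction of differential probes with |log2 fold change| in [1, 3], a
#' per-pair (subject) random effect shared by the tumor and normal sample
#' of a pair, and residual log2 noise.
#'
#' @param nPairs number of tumor/normal sample pairs.
#' @param nLnc,nMrna number of lncRNA and mRNA probes.
#' @param fracDE fraction of probes planted differential; the planted count
#'   is the deterministic \code{round(fracDE * (nLnc + nMrna))}.
#' @param log2fcRange interval the planted |log2 fold change| is drawn from.
#' @param baselineLog2Mean,baselineLog2Sd probe baseline (log2 intensity).
#' @param pairSd SD of the per-probe, per-pair random effect (log2).
#' @param noiseSd residual SD per measurement (log2).
#' @param seed integer seed; same config implies bit-identical output.
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- SimConfig(nPairs = 3, nLnc = 50, nMrna = 50, seed = 7)
#' sim <- simulateExpression(cfg)
#' sum(sim$truth$isDE)
#' @export
SimConfig <- function(nPairs = 3L, nLnc = 500L, nMrna = 500L,
                      fracDE = 0.1, log2fcRange = c(1, 3),
                      baselineLog2Mean = 10, baselineLog2Sd = 1.5,
                      pairSd = 0.25, noiseSd = 0.3, seed = 1L) {
  if (any(c(nPairs, nLnc, nMrna) %% 1 != 0))
    stop("counts must be whole numbers")
  new("SimConfig",
      nPairs = as.integer(nPairs), nLnc = as.integer(nLnc),
      nMrna = as.integer(nMrna), fracDE = as.numeric(fracDE),
      log2fcRange = as.numeric(log2fcRange),
      baselineLog2Mean = as.numeric(baselineLog2Mean),
      baselineLog2Sd = as.numeric(baselineLog2Sd),
      pairSd = as.numeric(pairSd), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nPairs, "pairs,",
      object@nLnc, "lncRNA +", object@nMrna, "mRNA probes,",
      "fracDE =", object@fracDE, "\n")
  cat("  |log2FC| in [", paste(object@log2fcRange, collapse = ", "),
      "], pairSd =", object@pairSd, ", noiseSd =", object@noiseSd,
      ", seed =", object@seed, "\n")
})

probeIdsFor <- function(config) {
  c(sprintf("LNC%05d", seq_len(config@nLnc)),
    sprintf("MRN%05d", seq_len(config@nMrna)))
}

#' Simulate a paired tumor/normal expression matrix with ground truth
#'
#' Generates intensities as
#' \code{pmax(2^(baseline + pairEffect + isTumor * log2fc + noise), 1)}.
#' Differential probes are a deterministic count
#' (\code{round(fracDE * nProbes)}) chosen at random, with planted fold
#' changes balanced between up and down. Each lncRNA probe is linked
#' (while mRNA partners last) to a distinct mRNA probe with a planted
#' genomic relationship and distance, which [simulateAnnotation()] later
#' realises in coordinates. Linked partners planted as co-differential
#' share the lncRNA's direction, so positional co-expression summaries
#' have known truth.
#'
#' @param config a [SimConfig-class].
#' @param truth optional: the \code{truth} of an earlier run with the
#'   same probe layout, to draw a new cohort (e.g. an independent
#'   validation set) from the \emph{same} population — same planted
#'   effects, baselines and links — with fresh sample-level randomness.
#' @param sampleSeed optional seed for the sample-level draws (pair
#'   effects and noise) only; defaults to \code{config@seed}. Population
#'   quantities always derive from \code{config@seed}, so two runs that
#'   differ only in \code{sampleSeed} share their ground truth.
#' @return list with components \code{expr}
#'   (a [PairedExpressionSet-class]; columns named \code{<pair>_T} /
#'   \code{<pair>_N}) and \code{truth} (a \code{DataFrame} with
#'   \code{probeId}, \code{class}, \code{isDE}, \code{log2fc},
#'   \code{baselineLog2}, \code{partnerId}, \code{relation},
#'   \code{plantedDistance}).
#' @export
simulateExpression <- function(config, truth = NULL, sampleSeed = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  nProbes <- config@nLnc + config@nMrna
  if (is.null(truth)) {
    set.seed(config@seed)
    ids <- probeIdsFor(config)
    cls <- rep(c("lncRNA", "mRNA"), c(config@nLnc, config@nMrna))

    ## plant a deterministic number of DE probes, signs balanced up/down
    nDE <- round(config@fracDE * nProbes)
    log2fc <- numeric(nProbes)
    deIdx <- if (nDE > 0) sort(sample.int(nProbes, nDE)) else integer()
    if (nDE > 0) {
      mag <- stats::runif(nDE, config@log2fcRange[1],
                          config@log2fcRange[2])
      sgn <- sample(rep(c(1, -1), length.out = nDE))
      log2fc[deIdx] <- sgn * mag
    }

    ## positional links: lncRNA i <-> mRNA i while partners last
    relLevels <- c("sense_overlap", "antisense_overlap", "intronic_sense",
                   "enhancer_like_neighbor", "intergenic_neighbor")
    nLink <- min(config@nLnc, config@nMrna)
    partnerId <- rep(NA_character_, nProbes)
    relation <- rep(NA_character_, nProbes)
    plantedDistance <- rep(NA_integer_, nProbes)
    if (nLink > 0) {
      lncIdx <- seq_len(nLink)
      mrnaIdx <- config@nLnc + seq_len(nLink)
      rel <- sample(relLevels, nLink, replace = TRUE)
      dist <- ifelse(rel %in% c("enhancer_like_neighbor",
                                "intergenic_neighbor"),
                     sample(10000:290000, nLink, replace = TRUE), 0L)
      partnerId[lncIdx] <- ids[mrnaIdx]
      partnerId[mrnaIdx] <- ids[lncIdx]
      relation[lncIdx] <- rel
      relation[mrnaIdx] <- rel
      plantedDistance[lncIdx] <- as.integer(dist)
      plantedDistance[mrnaIdx] <- as.integer(dist)
      ## concordance truth: a DE mRNA partnered with a DE lncRNA inherits
      ## the lncRNA's direction
      both <- lncIdx[log2fc[lncIdx] != 0 & log2fc[mrnaIdx] != 0]
      if (length(both)) {
        m <- config@nLnc + both
        log2fc[m] <- sign(log2fc[both]) * abs(log2fc[m])
      }
    }
    baseline <- stats::rnorm(nProbes, config@baselineLog2Mean,
                             config@baselineLog2Sd)
    truth <- DataFrame(
      probeId = ids, class = cls, isDE = log2fc != 0, log2fc = log2fc,
      baselineLog2 = baseline, partnerId = partnerId,
      relation = relation, plantedDistance = plantedDistance,
      row.names = ids)
  } else {
    if (nrow(truth) != nProbes)
      stop("supplied truth has ", nrow(truth), " probes; config expects ",
           nProbes)
    ids <- truth$probeId
    cls <- truth$class
    log2fc <- truth$log2fc
    baseline <- truth$baselineLog2
  }

  set.seed(if (is.null(sampleSeed)) config@seed else
    as.integer(sampleSeed))
  pairs <- sprintf("P%02d", seq_len(config@nPairs))
  pairEffect <- matrix(stats::rnorm(nProbes * config@nPairs, 0,
                                    config@pairSd),
                       nProbes, config@nPairs)
  noise <- function() matrix(stats::rnorm(nProbes * config@nPairs, 0,
                                          config@noiseSd),
                             nProbes, config@nPairs)
  tumorLog2 <- baseline + pairEffect + log2fc + noise()
  normalLog2 <- baseline + pairEffect + noise()
  tumor <- pmax(2^tumorLog2, 1)
  normal <- pmax(2^normalLog2, 1)

  m <- matrix(0, nProbes, 2L * config@nPairs)
  m[, seq(1, ncol(m), by = 2)] <- tumor
  m[, seq(2, ncol(m), by = 2)] <- normal
  colnames(m) <- as.vector(rbind(paste0(pairs, "_T"), paste0(pairs, "_N")))
  rownames(m) <- ids

  expr <- PairedExpressionSet(
    m,
    pairId = rep(pairs, each = 2),
    group = rep(c("tumor", "normal"), config@nPairs),
    probeClass = cls)
  list(expr = expr, truth = truth)
}

#' Realise planted lncRNA-gene relationships as genomic coordinates
#'
#' Places every linked lncRNA/mRNA pair on its own pseudo-chromosome (so no
#' accidental overlaps arise) with intervals constructed so that the
#' planted relationship holds: overlap classes overlap on the appropriate
#' strand (the intronic class strictly inside the gene, same strand) and
#' neighbor classes are disjoint with a gap of exactly the planted
#' distance. Unlinked probes get their own chromosome.
#'
#' @param config the [SimConfig-class] used for the expression draw.
#' @param truth the \code{truth} component returned by
#'   [simulateExpression()].
#' @return a [GenomicRanges::GRanges] with metadata columns
#'   \code{probeId}, \code{probeClass}, \code{lncClass}
#'   (\code{genic}/\code{enhancer_like}/\code{intergenic}),
#'   \code{relation}, \code{partnerId}.
#' @export
simulateAnnotation <- function(config, truth) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed + 104729L)  # decoupled from the expression stream
  ids <- truth$probeId
  n <- length(ids)
  isLnc <- truth$class == "lncRNA"
  chrom <- character(n); start <- integer(n); end <- integer(n)
  strand <- rep("+", n)
  lncClass <- rep(NA_character_, n)

  geneStart <- 1000000L; geneWidth <- 20000L; lncWidth <- 2000L
  linked <- which(isLnc & !is.na(truth$partnerId))
  cluster <- 0L
  for (i in linked) {
    cluster <- cluster + 1L
    j <- match(truth$partnerId[i], ids)
    chr <- sprintf("chrS%05d", cluster)
    chrom[c(i, j)] <- chr
    geneStrand <- sample(c("+", "-"), 1L)
    start[j] <- geneStart; end[j] <- geneStart + geneWidth
    strand[j] <- geneStrand
    rel <- truth$relation[i]
    flip <- function(s) if (s == "+") "-" else "+"
    if (rel == "sense_overlap") {
      ## straddles the gene start: overlap without containment
      start[i] <- geneStart - 1000L; end[i] <- start[i] + lncWidth
      strand[i] <- geneStrand
      lncClass[i] <- "genic"
    } else if (rel == "antisense_overlap") {
      start[i] <- geneStart + 3000L; end[i] <- start[i] + lncWidth
      strand[i] <- flip(geneStrand)
      lncClass[i] <- "genic"
    } else if (rel == "intronic_sense") {
      start[i] <- geneStart + 5000L; end[i] <- start[i] + lncWidth
      strand[i] <- geneStrand
      lncClass[i] <- "genic"
    } else {
      gap <- truth$plantedDistance[i]
      start[i] <- end[j] + gap; end[i] <- start[i] + lncWidth
      strand[i] <- sample(c("+", "-"), 1L)
      lncClass[i] <- if (rel == "enhancer_like_neighbor")
        "enhancer_like" else "intergenic"
    }
  }
  solo <- which(chrom == "")
  for (i in solo) {
    cluster <- cluster + 1L
    chrom[i] <- sprintf("chrS%05d", cluster)
    start[i] <- geneStart
    end[i] <- geneStart + if (isLnc[i]) lncWidth else geneWidth
    strand[i] <- sample(c("+", "-"), 1L)
    if (isLnc[i]) lncClass[i] <- "intergenic"
  }

  ## 0-based half-open internally -> 1-based closed GRanges
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand)
  S4Vectors::mcols(gr) <- DataFrame(
    probeId = ids, probeClass = truth$class, lncClass = lncClass,
    relation = truth$relation, partnerId = truth$partnerId)
  names(gr) <- ids
  gr
}

#' Simulate a qPCR crossing-point (Cp) table from known expression
#'
#' Cp values follow the exponential-amplification identity
#' \code{Cp = c0 - log2(expression) + noise}: doubling the template lowers
#' the crossing point by one cycle. A reference gene with planted constant
#' expression across samples is appended, and each (sample, gene) is
#' measured in \code{nReplicates} replicate wells.
#'
#' @param expression positive numeric matrix, genes x samples (dimnames
#'   required), on the relative-expression scale.
#' @param group character vector per sample, \code{"tumor"} /
#'   \code{"normal"}.
#' @param c0 cycles at unit expression.
#' @param cpNoiseSd replicate noise SD in cycles.
#' @param nReplicates replicate wells per (sample, gene).
#' @param referenceGene id of the appended stable reference gene.
#' @param referenceExpression its constant expression level.
#' @param seed integer seed.
#' @return \code{data.frame} with columns \code{sample}, \code{group},
#'   \code{gene}, \code{replicate}, \code{cp}.
#' @export
simulateCpTable <- function(expression, group, c0 = 30, cpNoiseSd = 0.1,
                            nReplicates = 3L, referenceGene = "ACTB",
                            referenceExpression = 1, seed = 1L) {
  expression <- as.matrix(expression)
  if (any(!is.finite(expression)) || any(expression <= 0))
    stop("expression values must be positive and finite")
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("expression needs gene rownames and sample colnames")
  if (length(group) != ncol(expression))
    stop("one group label per sample is required")
  if (nReplicates < 1L) stop("nReplicates must be >= 1")
  set.seed(seed)
  expression <- rbind(expression,
                      matrix(referenceExpression, 1, ncol(expression),
                             dimnames = list(referenceGene, NULL)))
  grid <- expand.grid(replicate = seq_len(nReplicates),
                      gene = rownames(expression),
                      sample = colnames(expression),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- cbind(match(grid$gene, rownames(expression)),
               match(grid$sample, colnames(expression)))
  cp <- c0 - log2(expression[idx]) +
    stats::rnorm(nrow(grid), 0, cpNoiseSd)
  data.frame(sample = grid$sample,
             group = group[idx[, 2]],
             gene = grid$gene,
             replicate = grid$replicate,
             cp = cp,
             stringsAsFactors = FALSE)
}
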