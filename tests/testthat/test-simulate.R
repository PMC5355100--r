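test_that("simulation is bit-identical under the same config and seed", {
  cfg <- SimConfig(nPairs = 4, nLnc = 40, nMrna = 40, seed = 42)
  a <- simulateExpression(cfg)
  b <- simulateExpression(cfg)
  expect_identical(intensities(a$expr), intensities(b$expr))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  annA <- simulateAnnotation(cfg, a$truth)
  annB <- simulateAnnotation(cfg, b$truth)
  expect_identical(as.data.frame(annA), as.data.frame(annB))
})

test_that("planted differential probes follow the deterministic count rule", {
  cfg0 <- SimConfig(nPairs = 3, nLnc = 30, nMrna = 30, fracDE = 0, seed = 1)
  s0 <- simulateExpression(cfg0)
  expect_true(all(s0$truth$log2fc == 0))
  expect_false(any(s0$truth$isDE))

  cfg <- SimConfig(nPairs = 3, nLnc = 500, nMrna = 500, fracDE = 0.2,
                   seed = 2)
  s <- simulateExpression(cfg)
  expect_identical(sum(s$truth$isDE), 200L)  # round(0.2 * 1000)
  # signs balanced up/down, up to the same-direction forcing applied to
  # mRNA partners of co-differential positional links
  expect_lte(abs(sum(s$truth$log2fc > 0) - sum(s$truth$log2fc < 0)),
             0.1 * sum(s$truth$isDE))
  # non-DE probes carry zero planted effect
  expect_true(all(s$truth$log2fc[!s$truth$isDE] == 0))
})

test_that("a reused truth yields a new cohort from the same population", {
  cfg <- SimConfig(nPairs = 4, nLnc = 40, nMrna = 40, fracDE = 0.2,
                   seed = 77)
  a <- simulateExpression(cfg)
  cfgV <- cfg; cfgV@nPairs <- 6L
  b <- simulateExpression(cfgV, truth = a$truth, sampleSeed = 909)
  # same planted effects and baselines, different measurements
  expect_identical(as.data.frame(b$truth), as.data.frame(a$truth))
  expect_identical(nrow(SummarizedExperiment::colData(b$expr)), 12L)
  common <- intersect(colnames(a$expr), colnames(b$expr))
  expect_false(any(intensities(a$expr)[, common] ==
                     intensities(b$expr)[, common]))
  # probe-count mismatch is rejected
  cfgBad <- cfg; cfgBad@nLnc <- 10L
  expect_error(simulateExpression(cfgBad, truth = a$truth), "probes")
})

test_that("noise-free generation recovers planted log2 fold changes", {
  cfg <- SimConfig(nPairs = 5, nLnc = 50, nMrna = 50, fracDE = 0.3,
                   pairSd = 0, noiseSd = 0, seed = 3)
  s <- simulateExpression(cfg)
  b <- pairedBlocks(s$expr)
  obs <- log2(rowMeans(b$tumor) / rowMeans(b$normal))
  expect_lt(max(abs(obs - s$truth$log2fc)), 1e-9)
})

test_that("intensities are clipped at one and config is validated", {
  cfg <- SimConfig(nPairs = 2, nLnc = 100, nMrna = 0,
                   baselineLog2Mean = -10, seed = 4)
  s <- simulateExpression(cfg)
  expect_true(all(intensities(s$expr) >= 1))
  expect_error(SimConfig(nPairs = 0), "nPairs")
  expect_error(SimConfig(fracDE = 1.5), "fracDE")
  expect_error(SimConfig(noiseSd = -1), "SD")
})

test_that("annotation realises planted relationships by construction", {
  cfg <- SimConfig(nPairs = 2, nLnc = 80, nMrna = 80, seed = 7)
  s <- simulateExpression(cfg)
  ann <- simulateAnnotation(cfg, s$truth)
  mc <- S4Vectors::mcols(ann)
  # neighbor gaps equal the planted distances exactly
  lnc <- which(mc$probeClass == "lncRNA" &
                 mc$relation %in% c("enhancer_like_neighbor",
                                    "intergenic_neighbor"))
  expect_gt(length(lnc), 0)
  partner <- match(mc$partnerId[lnc], mc$probeId)
  gap <- GenomicRanges::distance(ann[lnc], ann[partner],
                                 ignore.strand = TRUE)
  expect_identical(as.integer(gap),
                   s$truth$plantedDistance[lnc])
  # intronic lncRNAs sit strictly inside their gene, same strand
  intr <- which(mc$relation == "intronic_sense" &
                  mc$probeClass == "lncRNA")
  pj <- match(mc$partnerId[intr], mc$probeId)
  expect_true(all(GenomicRanges::start(ann[intr]) >
                    GenomicRanges::start(ann[pj])))
  expect_true(all(GenomicRanges::end(ann[intr]) <
                    GenomicRanges::end(ann[pj])))
  expect_true(all(as.character(GenomicRanges::strand(ann[intr])) ==
                    as.character(GenomicRanges::strand(ann[pj]))))
})

test_that("Cp tables obey the log2 amplification identity", {
  expr <- matrix(c(1, 2, 4, 8), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cp <- simulateCpTable(expr, group = c("tumor", "normal"),
                        c0 = 30, cpNoiseSd = 0, nReplicates = 3,
                        seed = 9)
  # doubling expression lowers Cp by exactly one cycle
  g1 <- cp[cp$gene == "g1" & cp$replicate == 1, ]
  expect_equal(g1$cp[g1$sample == "s1"] - g1$cp[g1$sample == "s2"], 2)
  # reference gene: identical Cp in every sample at zero noise
  ref <- cp[cp$gene == "ACTB", ]
  expect_equal(length(unique(ref$cp)), 1L)
  # measured in triplicate: exactly 3 rows per (sample, gene)
  expect_true(all(table(cp$sample, cp$gene) == 3L))
  expect_true(all(is.finite(cp$cp)))
  expect_error(simulateCpTable(matrix(-1, 1, 1,
                                      dimnames = list("g", "s")), "tumor"),
               "positive")
})
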