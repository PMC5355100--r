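#' Quantile normalization
#'
#' Forces every sample (column) to share the same intensity distribution:
#' each column's sorted values are replaced by the row-wise mean of all
#' sorted columns, preserving within-column ranks (ties receive the mean
#' of the tied positions). Delegates to [limma::normalizeQuantiles()].
#' The operation is idempotent.
#'
#' @param x a numeric matrix (probes x samples) or a
#'   [PairedExpressionSet-class].
#' @return object of the same class as \code{x} with normalized
#'   intensities.
#' @examples
#' quantileNormalize(cbind(a = c(1, 3), b = c(2, 4)))  # both (1.5, 3.5)
#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "matrix", function(x) {
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty matrix")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "PairedExpressionSet", function(x) {
  SummarizedExperiment::assay(x, "intensity") <-
    quantileNormalize(intensities(x))
  x
})

#' Paired log2 fold change
#'
#' Mean over pairs of the per-pair log2 ratio,
#' \code{mean(log2((T_i + pseudocount) / (N_i + pseudocount)))}
#' (mean-of-ratios, which respects the paired design), tumor over normal.
#'
#' @param x a [PairedExpressionSet-class] of raw or normalized intensities.
#' @param pseudocount added to both numerator and denominator; default 1
#'   keeps ratios defined at zero intensity.
#' @return named numeric vector of per-probe log2 fold changes.
#' @export
pairedLog2FC <- function(x, pseudocount = 1) {
  b <- pairedBlocks(x)
  lfc <- rowMeans(log2((b$tumor + pseudocount) / (b$normal + pseudocount)))
  names(lfc) <- rownames(x)
  lfc
}

#' Per-probe Student t-test on log2 intensities
#'
#' Two-tailed Student t-test per probe on \code{log2(intensity + 1)},
#' either pooled equal-variance two-sample (default) or paired. Probes
#' with zero variance (degenerate inputs where the statistic is undefined)
#' are assigned p = 1 and counted in a single warning, keeping the
#' pipeline total.
#'
#' @param x a [PairedExpressionSet-class].
#' @param mode \code{"two_sample"} (pooled, equal variance) or
#'   \code{"paired"}.
#' @return named numeric vector of raw two-sided p-values in (0, 1].
#' @export
probeTTest <- function(x, mode = c("two_sample", "paired")) {
  mode <- match.arg(mode)
  b <- pairedBlocks(x)
  if (ncol(b$tumor) < 2L)
    stop("need at least 2 pairs for a t-test")
  lt <- log2(b$tumor + 1)
  ln <- log2(b$normal + 1)
  nDegenerate <- 0L
  p <- vapply(seq_len(nrow(lt)), function(i) {
    res <- tryCatch({
      if (mode == "paired")
        stats::t.test(lt[i, ], ln[i, ], paired = TRUE)$p.value
      else
        stats::t.test(lt[i, ], ln[i, ], var.equal = TRUE)$p.value
    }, error = function(e) NA_real_)
    if (is.na(res)) { nDegenerate <<- nDegenerate + 1L; 1 } else res
  }, numeric(1))
  if (nDegenerate > 0L)
    warning(nDegenerate, " probe(s) had zero variance; p set to 1")
  names(p) <- rownames(x)
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate,
#' \code{fdr_(i) = min_(j >= i) m * p_(j) / j} clipped at 1. Wraps
#' [stats::p.adjust()] with input validation; order-preserving, ties share
#' a value.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and names.
#' @export
benjaminiHochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Volcano filtering of differential-expression results
#'
#' Applies the strict double threshold: fold change \emph{greater than}
#' \code{fcThreshold} (i.e. |log2fc| > log2(fcThreshold)) \emph{and} FDR
#' \emph{less than} \code{fdrThreshold}. A probe at exactly the fold-change
#' line is excluded.
#'
#' @param de a [DEResult-class] (or data.frame with \code{log2fc} and
#'   \code{fdr}); rownames are probe ids.
#' @param fcThreshold fold-change threshold on the linear scale.
#' @param fdrThreshold FDR threshold.
#' @return list with \code{up} and \code{down} (character probe ids,
#'   partitioned by the sign of log2fc) and \code{counts}.
#' @export
volcanoFilter <- function(de, fcThreshold = 2.0, fdrThreshold = 0.05) {
  lfcCut <- log2(fcThreshold)
  ## a threshold >= 1 disables the FDR filter entirely
  pass <- abs(de$log2fc) > lfcCut &
    (fdrThreshold >= 1 | de$fdr < fdrThreshold)
  ids <- rownames(de)
  up <- ids[pass & de$log2fc > 0]
  down <- ids[pass & de$log2fc < 0]
  list(up = up, down = down,
       counts = c(up = length(up), down = length(down),
                  total = length(up) + length(down)))
}

#' Paired differential-expression analysis
#'
#' The full probe-level workflow: optional quantile normalization, paired
#' log2 fold change, per-probe Student t-test, Benjamini-Hochberg
#' adjustment (by default within each probe class separately, since lncRNA
#' and mRNA results are reported as separate lists), and strict volcano
#' filtering at fold change > \code{fcThreshold}, FDR <
#' \code{fdrThreshold}.
#'
#' @param x a [PairedExpressionSet-class].
#' @param normalize quantile-normalize first?
#' @param test t-test mode, \code{"two_sample"} or \code{"paired"}.
#' @param pseudocount for the fold-change ratios.
#' @param fcThreshold,fdrThreshold volcano thresholds (strict).
#' @param adjustByClass apply BH within each \code{rowData()$class}
#'   separately (TRUE, default when classes are annotated) or jointly.
#' @return a [DEResult-class] with columns \code{probeId}, \code{class},
#'   \code{log2fc}, \code{pRaw}, \code{fdr}, \code{direction},
#'   \code{passesFilter}; thresholds in \code{metadata()}.
#' @export
runDifferentialExpression <- function(x, normalize = TRUE,
                                      test = c("two_sample", "paired"),
                                      pseudocount = 1,
                                      fcThreshold = 2.0,
                                      fdrThreshold = 0.05,
                                      adjustByClass = TRUE) {
  test <- match.arg(test)
  stopifnot(is(x, "PairedExpressionSet"))
  if (normalize) x <- quantileNormalize(x)
  lfc <- pairedLog2FC(x, pseudocount = pseudocount)
  p <- probeTTest(x, mode = test)
  cls <- rowData(x)$class
  if (is.null(cls)) cls <- rep(NA_character_, nrow(x))
  fdr <- if (adjustByClass && !anyNA(cls)) {
    out <- numeric(length(p))
    for (cl in unique(cls)) {
      i <- cls == cl
      out[i] <- benjaminiHochberg(p[i])
    }
    out
  } else benjaminiHochberg(p)
  pass <- abs(lfc) > log2(fcThreshold) &
    (fdrThreshold >= 1 | fdr < fdrThreshold)
  direction <- ifelse(pass, ifelse(lfc > 0, "up", "down"), "none")
  res <- new("DEResult", DataFrame(
    probeId = rownames(x), class = cls, log2fc = unname(lfc),
    pRaw = unname(p), fdr = unname(fdr), direction = unname(direction),
    passesFilter = unname(pass), row.names = rownames(x)))
  metadata(res) <- list(fcThreshold = fcThreshold,
                        fdrThreshold = fdrThreshold,
                        test = test, normalized = normalize,
                        adjustByClass = adjustByClass)
  res
}
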