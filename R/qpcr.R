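#' Collapse replicate qPCR crossing points
#'
#' Averages the replicate Cp values of each (sample, gene) on the Cp
#' (cycle) scale, the convention of the relative-quantification
#' literature, and reports the replicate SD for QC. Every sample must
#' carry every gene; gaps are an error because downstream normalization
#' needs the complete crossing.
#'
#' @param cpTable \code{data.frame} with columns \code{sample},
#'   \code{group}, \code{gene}, \code{replicate}, \code{cp} (optionally
#'   \code{pair}); e.g. from [simulateCpTable()] or [readCpTable()].
#' @return \code{data.frame} with one row per (sample, gene):
#'   \code{sample}, \code{group}, optional \code{pair}, \code{gene},
#'   \code{meanCp}, \code{sdCp}, \code{nReplicates}.
#' @export
collapseReplicates <- function(cpTable) {
  required <- c("sample", "group", "gene", "cp")
  if (!all(required %in% names(cpTable)))
    stop("cpTable needs columns: ", paste(required, collapse = ", "))
  if (any(!is.finite(cpTable$cp)) || any(cpTable$cp <= 0))
    stop("Cp values must be positive and finite")
  key <- paste(cpTable$sample, cpTable$gene, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(
    sample = cpTable$sample[first],
    group = cpTable$group[first],
    gene = cpTable$gene[first],
    meanCp = as.numeric(tapply(cpTable$cp, key, mean)[key[first]]),
    sdCp = as.numeric(tapply(cpTable$cp, key, stats::sd)[key[first]]),
    nReplicates = as.integer(tapply(cpTable$cp, key, length)[key[first]]),
    stringsAsFactors = FALSE)
  out$sdCp[is.na(out$sdCp)] <- 0  # single replicate
  if ("pair" %in% names(cpTable)) out$pair <- cpTable$pair[first]
  ## the sample x gene crossing must be complete
  samples <- unique(out$sample); genes <- unique(out$gene)
  have <- paste(out$sample, out$gene)
  want <- as.vector(outer(samples, genes, paste))
  gaps <- setdiff(want, have)
  if (length(gaps))
    stop("missing (sample, gene) combination(s): ",
         paste(gaps, collapse = "; "))
  out
}

#' Relative expression by the 2^-ddCp method
#'
#' Reference-gene normalization followed by calibration:
#' \eqn{\Delta Cp = Cp_{target} - Cp_{reference}} within each sample,
#' \eqn{\Delta\Delta Cp = \Delta Cp_{sample} - \Delta Cp_{calibrator}},
#' and relative expression \eqn{2^{-\Delta\Delta Cp}} (amplification
#' efficiency fixed at 2). The calibrator is either the sample's paired
#' normal (\code{"paired_normal"}, default, matching a paired design) or
#' the mean \eqn{\Delta Cp} of all normal samples
#' (\code{"group_mean_normal"}, which leaves variation among normals and
#' suits group-level summaries and ROC analysis).
#'
#' @param meanCp output of [collapseReplicates()].
#' @param referenceGene the stable reference gene id (e.g. beta-actin);
#'   must be measured in every sample.
#' @param calibrator calibration scheme, see above.
#' @param pair optional named vector mapping sample id to pair id;
#'   defaults to a \code{pair} column of \code{meanCp} and is required
#'   for \code{"paired_normal"}.
#' @return a \code{DataFrame} of class RelativeExpression content:
#'   \code{sample}, \code{group}, \code{gene}, \code{deltaCp},
#'   \code{ddCp}, \code{relExpr}.
#' @examples
#' cp <- data.frame(sample = rep(c("s1", "s2"), each = 2),
#'                  group = rep(c("tumor", "normal"), each = 2),
#'                  gene = rep(c("tgt", "ref"), 2),
#'                  replicate = 1, cp = c(25, 20, 28, 20),
#'                  pair = "p1")
#' relativeExpression(collapseReplicates(cp), "ref")  # tgt tumor: 8
#' @export
relativeExpression <- function(meanCp, referenceGene,
                               calibrator = c("paired_normal",
                                              "group_mean_normal"),
                               pair = NULL) {
  calibrator <- match.arg(calibrator)
  samples <- unique(meanCp$sample)
  ref <- meanCp[meanCp$gene == referenceGene, , drop = FALSE]
  noRef <- setdiff(samples, ref$sample)
  if (length(noRef))
    stop("reference gene '", referenceGene, "' missing for sample(s): ",
         paste(noRef, collapse = ", "))
  tgt <- meanCp[meanCp$gene != referenceGene, , drop = FALSE]
  tgt$deltaCp <- tgt$meanCp - ref$meanCp[match(tgt$sample, ref$sample)]

  if (calibrator == "paired_normal") {
    if (is.null(pair)) {
      if (!"pair" %in% names(meanCp))
        stop("paired_normal calibration needs pair information ",
             "(a 'pair' column or the pair= argument)")
      pair <- stats::setNames(meanCp$pair, meanCp$sample)
      pair <- pair[!duplicated(names(pair))]
    }
    tgt$pair <- unname(pair[tgt$sample])
    normals <- tgt[tgt$group == "normal", , drop = FALSE]
    key <- paste(normals$pair, normals$gene)
    calib <- stats::setNames(normals$deltaCp, key)
    tgt$ddCp <- tgt$deltaCp - unname(calib[paste(tgt$pair, tgt$gene)])
    if (anyNA(tgt$ddCp))
      stop("no paired normal sample for: ",
           paste(unique(tgt$sample[is.na(tgt$ddCp)]), collapse = ", "))
  } else {
    normals <- tgt[tgt$group == "normal", , drop = FALSE]
    if (nrow(normals) == 0L) stop("no normal samples to calibrate against")
    calib <- tapply(normals$deltaCp, normals$gene, mean)
    tgt$ddCp <- tgt$deltaCp - as.numeric(calib[tgt$gene])
  }
  tgt$relExpr <- 2^(-tgt$ddCp)
  keep <- c("sample", "group", intersect("pair", names(tgt)), "gene",
            "deltaCp", "ddCp", "relExpr")
  DataFrame(tgt[, keep, drop = FALSE])
}

#' Pivot relative expression to a sample-by-gene marker matrix
#'
#' Convenience for ROC/panel analysis: rows are samples, columns genes,
#' values \code{relExpr}, with the per-sample \code{group} as an
#' attribute-free companion vector.
#'
#' @param relExpr output of [relativeExpression()].
#' @return list with \code{markers} (matrix samples x genes) and
#'   \code{group} (character vector aligned to rows).
#' @export
markerMatrix <- function(relExpr) {
  relExpr <- as.data.frame(relExpr)
  samples <- unique(relExpr$sample)
  genes <- unique(relExpr$gene)
  m <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(match(relExpr$sample, samples),
          match(relExpr$gene, genes))] <- relExpr$relExpr
  grp <- relExpr$group[match(samples, relExpr$sample)]
  list(markers = m, group = as.character(grp))
}
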