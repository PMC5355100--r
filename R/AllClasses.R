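#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData
NULL

#' Simulation configuration for paired tumor/normal expression studies
#'
#' A \code{SimConfig} bundles every parameter of the synthetic-data
#' generator: cohort size, probe counts, the fraction and magnitude of
#' planted differential expression, and the variance components of the
#' log2-scale signal model (probe baseline, per-pair random effect,
#' residual noise).
#'
#' Intensities are generated as
#' \code{2^(baseline + pair + is_tumor * log2fc + noise)} and clipped at 1
#' so log transforms are always defined. Differential probes are planted as
#' a deterministic count, \code{round(fracDE * nProbes)}, so count
#' assertions on ground truth are exact.
#'
#' @slot nPairs integer, number of tumor/normal sample pairs.
#' @slot nLnc,nMrna integer, number of lncRNA and mRNA probes.
#' @slot fracDE fraction of probes planted as differentially expressed.
#' @slot log2fcRange length-2 numeric, range of planted |log2 fold change|.
#' @slot baselineLog2Mean,baselineLog2Sd probe baseline distribution (log2).
#' @slot pairSd SD of the per-pair random effect (log2 scale).
#' @slot noiseSd residual SD (log2 scale).
#' @slot seed integer seed; identical config implies identical output.
#'
#' @seealso [simulateExpression()], [simulateAnnotation()],
#'   [simulateCpTable()]
#' @export
setClass("SimConfig",
  representation(
    nPairs = "integer",
    nLnc = "integer",
    nMrna = "integer",
    fracDE = "numeric",
    log2fcRange = "numeric",
    baselineLog2Mean = "numeric",
    baselineLog2Sd = "numeric",
    pairSd = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@nPairs) != 1L || is.na(object@nPairs) ||
      object@nPairs < 1L)
    msg <- c(msg, "nPairs must be a single integer >= 1")
  if (object@nLnc < 0L || object@nMrna < 0L)
    msg <- c(msg, "probe counts must be non-negative")
  if (object@nLnc + object@nMrna < 1L)
    msg <- c(msg, "at least one probe is required")
  if (length(object@fracDE) != 1L || is.na(object@fracDE) ||
      object@fracDE < 0 || object@fracDE > 1)
    msg <- c(msg, "fracDE must lie in [0, 1]")
  if (length(object@log2fcRange) != 2L ||
      any(object@log2fcRange < 0) || diff(object@log2fcRange) < 0)
    msg <- c(msg, "log2fcRange must be an increasing non-negative interval")
  sds <- c(object@baselineLog2Sd, object@pairSd, object@noiseSd)
  if (any(is.na(sds)) || any(sds < 0))
    msg <- c(msg, "all SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Paired tumor/normal expression matrix
#'
#' Thin [SummarizedExperiment::SummarizedExperiment] subclass that enforces
#' a complete paired design: the column metadata must carry a \code{pairId}
#' and a \code{group} (\code{"tumor"} or \code{"normal"}), every pair id
#' must occur exactly once per group, intensities must be non-negative and
#' probe (row) names unique. Row metadata typically carries the probe
#' \code{class} (\code{"lncRNA"} or \code{"mRNA"}).
#'
#' @seealso [PairedExpressionSet()] for the constructor, [pairId()],
#'   [sampleGroup()]
#' @export
setClass("PairedExpressionSet", contains = "SummarizedExperiment")

setValidity("PairedExpressionSet", function(object) {
  msg <- character()
  cd <- colData(object)
  if (!all(c("pairId", "group") %in% colnames(cd)))
    return("colData must contain 'pairId' and 'group'")
  grp <- as.character(cd$group)
  if (!all(grp %in% c("tumor", "normal")))
    msg <- c(msg, "group must be 'tumor' or 'normal'")
  tab <- table(as.character(cd$pairId), grp)
  if (nrow(tab) && !all(tab == 1L))
    msg <- c(msg, "every pairId must appear exactly once per group")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids (rownames) must be present and unique")
  if (length(assays(object)) >= 1L) {
    x <- assay(object)
    if (any(is.finite(x) & x < 0))
      msg <- c(msg, "intensities must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Per-probe differential-expression results
#'
#' A [S4Vectors::DFrame] subclass with one row per probe and columns
#' \code{log2fc}, \code{pRaw}, \code{fdr}, \code{direction}
#' (\code{up}/\code{down}/\code{none}) and \code{passesFilter}. The filter
#' is the strict volcano rule: fold change \eqn{>} threshold and
#' FDR \eqn{<} threshold. Thresholds and the test used are stored in
#' \code{metadata()}.
#'
#' @export
setClass("DEResult", contains = "DFrame")

#' Candidate-biomarker selection statistics
#'
#' A [S4Vectors::DFrame] subclass with one row per evaluated probe and the
#' components of the raw-intensity selection rule: group means \code{tBar}
#' and \code{nBar}, their absolute difference \code{a}, within-group ranges
#' \code{tRange} and \code{nRange}, the intensity-gate flag \code{inGate},
#' the \code{selected} flag and the \code{direction} of change. Gate bounds
#' and the range ratio live in \code{metadata()}.
#'
#' @export
setClass("CandidateStats", contains = "DFrame")

#' ROC summary for a marker or panel score
#'
#' Holds the Mann-Whitney AUC, its Hanley-McNeil standard error, the
#' Youden-optimal threshold and the sensitivity/specificity achieved there,
#' together with the class sizes.
#'
#' @slot auc area under the ROC curve, in [0, 1].
#' @slot se standard error of the AUC (Hanley-McNeil).
#' @slot threshold Youden-optimal cut; scores >= threshold call positive.
#' @slot sensitivity,specificity fractions in [0, 1] at the threshold.
#' @slot nPos,nNeg class sizes.
#'
#' @seealso [rocSummary()]
#' @export
setClass("RocSummary",
  representation(
    auc = "numeric",
    se = "numeric",
    threshold = "numeric",
    sensitivity = "numeric",
    specificity = "numeric",
    nPos = "integer",
    nNeg = "integer"
  )
)

setValidity("RocSummary", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must be in [0,1]")
  if (object@se < 0) msg <- c(msg, "se must be >= 0")
  if (object@sensitivity < 0 || object@sensitivity > 1 ||
      object@specificity < 0 || object@specificity > 1)
    msg <- c(msg, "sensitivity and specificity must be in [0,1]")
  if (object@nPos < 1L || object@nNeg < 1L)
    msg <- c(msg, "both classes must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Logistic multi-marker panel model
#'
#' The combination rule for a marker panel: a binary logistic regression of
#' class on the marker values, fit by iteratively reweighted least squares
#' with a small ridge penalty for separable data. The panel score of a
#' sample is the linear predictor; ROC analysis of the score is invariant
#' to the monotone logistic link.
#'
#' @slot markers character, marker ids in model order.
#' @slot coefficients named numeric: "(Intercept)" then one weight per
#'   marker.
#' @slot ridge ridge penalty applied to the slopes.
#' @slot iterations IRLS iterations used.
#' @slot converged logical.
#'
#' @seealso [fitPanel()], [panelScore()]
#' @export
setClass("PanelModel",
  representation(
    markers = "character",
    coefficients = "numeric",
    ridge = "numeric",
    iterations = "integer",
    converged = "logical"
  )
)

setValidity("PanelModel", function(object) {
  if (length(object@coefficients) != length(object@markers) + 1L)
    return("need one coefficient per marker plus an intercept")
  TRUE
})
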