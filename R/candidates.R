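#' Candidate-biomarker selection statistics for one probe
#'
#' The raw-intensity selection rule for screening differential probes into
#' a qPCR-validatable shortlist. For a probe with raw tumor intensities T
#' and paired normal intensities N: the group means \eqn{\bar T} and
#' \eqn{\bar N}, their absolute difference \eqn{A = |\bar T - \bar N|},
#' and the within-group ranges \eqn{T_{max} - T_{min}},
#' \eqn{N_{max} - N_{min}}. The probe is selected when every raw intensity
#' lies inside the gate (inclusive \code{[gateLow, gateHigh]}, disable
#' with infinite bounds) and at least one group's range is strictly
#' smaller than \eqn{A / ratio} — i.e. one group is tightly clustered far
#' from the other group's mean.
#'
#' @param tumor,normal numeric vectors of raw (pre-normalization,
#'   pre-log) intensities, pair-aligned.
#' @param gateLow,gateHigh inclusive intensity gate applied to every
#'   sample; defaults 100 and 20,000.
#' @param ratio the range must be smaller than A divided by this.
#' @param mode \code{"or"} (default: one stable group suffices) or
#'   \code{"and"} (both ranges must pass).
#' @return one-row \code{data.frame}: \code{tBar}, \code{nBar}, \code{a},
#'   \code{tRange}, \code{nRange}, \code{inGate}, \code{selected},
#'   \code{direction}; or NULL (probe unevaluable) when values are
#'   missing.
#' @examples
#' candidateStats(c(800, 805, 810), c(200, 210, 205))  # A = 600, selected
#' @export
candidateStats <- function(tumor, normal, gateLow = 100,
                           gateHigh = 20000, ratio = 10,
                           mode = c("or", "and")) {
  mode <- match.arg(mode)
  if (length(tumor) < 1L || length(normal) < 1L)
    stop("need at least one pair")
  if (anyNA(tumor) || anyNA(normal)) return(NULL)
  tBar <- mean(tumor); nBar <- mean(normal)
  a <- abs(tBar - nBar)
  tRange <- max(tumor) - min(tumor)
  nRange <- max(normal) - min(normal)
  all_ <- c(tumor, normal)
  inGate <- all(all_ >= gateLow & all_ <= gateHigh)
  stable <- c(nRange < a / ratio, tRange < a / ratio)
  selected <- inGate && if (mode == "or") any(stable) else all(stable)
  data.frame(tBar = tBar, nBar = nBar, a = a,
             tRange = tRange, nRange = nRange, inGate = inGate,
             selected = selected,
             direction = if (tBar >= nBar) "up" else "down",
             stringsAsFactors = FALSE)
}

#' Select candidate biomarkers from raw intensities of differential probes
#'
#' Applies [candidateStats()] to every probe on the differential list
#' using the \emph{raw} intensity matrix (the selection statistic is
#' defined on un-normalized intensities even though the differential list
#' itself comes from normalized data) and partitions the selected probes
#' by direction. Probes with missing values are flagged unevaluable and
#' excluded from selection.
#'
#' @param x a [PairedExpressionSet-class] of raw intensities containing
#'   every probe in \code{deList}.
#' @param deList character vector of differential probe ids.
#' @inheritParams candidateStats
#' @return list with \code{up} and \code{down} (selected probe ids,
#'   ordered by descending A) and \code{stats} (a
#'   [CandidateStats-class] table over all evaluable probes, descending
#'   A; gate parameters in \code{metadata()}).
#' @export
selectCandidates <- function(x, deList, gateLow = 100, gateHigh = 20000,
                             ratio = 10, mode = c("or", "and")) {
  mode <- match.arg(mode)
  stopifnot(is(x, "PairedExpressionSet"))
  missing <- setdiff(deList, rownames(x))
  if (length(missing))
    stop("differential probe(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  b <- pairedBlocks(x)
  rows <- lapply(deList, function(id) {
    st <- candidateStats(b$tumor[id, ], b$normal[id, ],
                         gateLow = gateLow, gateHigh = gateHigh,
                         ratio = ratio, mode = mode)
    if (is.null(st)) return(NULL)
    cbind(probeId = id, st, stringsAsFactors = FALSE)
  })
  evaluable <- !vapply(rows, is.null, logical(1))
  if (length(deList) && !all(evaluable))
    warning(sum(!evaluable), " probe(s) unevaluable (missing values)")
  df <- do.call(rbind, rows[evaluable])
  if (is.null(df))
    df <- data.frame(probeId = character(), tBar = numeric(),
                     nBar = numeric(), a = numeric(), tRange = numeric(),
                     nRange = numeric(), inGate = logical(),
                     selected = logical(), direction = character())
  df <- df[order(-df$a), , drop = FALSE]
  stats <- new("CandidateStats",
               DataFrame(df, row.names = df$probeId))
  metadata(stats) <- list(gateLow = gateLow, gateHigh = gateHigh,
                          ratio = ratio, mode = mode)
  sel <- df[df$selected, , drop = FALSE]
  list(up = sel$probeId[sel$direction == "up"],
       down = sel$probeId[sel$direction == "down"],
       stats = stats)
}
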