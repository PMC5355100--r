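#' Construct a PairedExpressionSet
#'
#' Wraps a probe-by-sample intensity matrix and its paired-design metadata
#' into a validated [PairedExpressionSet-class] object.
#'
#' @param intensities numeric matrix, probes in rows (rownames = probe
#'   ids), samples in columns; non-negative.
#' @param pairId vector of pair identifiers, one per column.
#' @param group character vector, \code{"tumor"} or \code{"normal"} per
#'   column.
#' @param probeClass optional per-probe class (\code{"lncRNA"} /
#'   \code{"mRNA"}), stored in \code{rowData()$class}.
#'
#' @return a \code{PairedExpressionSet}.
#' @examples
#' m <- matrix(c(100, 200, 400, 150), 1,
#'             dimnames = list("p1", c("a_T", "a_N", "b_T", "b_N")))
#' pes <- PairedExpressionSet(m, pairId = c("a", "a", "b", "b"),
#'                            group = c("tumor", "normal", "tumor", "normal"))
#' pairId(pes)
#' @export
PairedExpressionSet <- function(intensities, pairId, group,
                                probeClass = NULL) {
  intensities <- as.matrix(intensities)
  if (length(pairId) != ncol(intensities) ||
      length(group) != ncol(intensities))
    stop("pairId and group must have one entry per sample column")
  cd <- DataFrame(pairId = as.character(pairId),
                  group = as.character(group),
                  row.names = colnames(intensities))
  rd <- if (is.null(probeClass)) {
    DataFrame(row.names = rownames(intensities))
  } else {
    DataFrame(class = as.character(probeClass),
              row.names = rownames(intensities))
  }
  se <- SummarizedExperiment(assays = SimpleList(intensity = intensities),
                             colData = cd, rowData = rd)
  new("PairedExpressionSet", se)
}

#' @rdname PairedExpressionSet-class
#' @export
setMethod("pairId", "PairedExpressionSet",
          function(x) as.character(colData(x)$pairId))

#' @rdname PairedExpressionSet-class
#' @export
setMethod("sampleGroup", "PairedExpressionSet",
          function(x) as.character(colData(x)$group))

#' @describeIn PairedExpressionSet-class intensity matrix accessor.
#' @param x a \code{PairedExpressionSet}.
#' @export
intensities <- function(x) assay(x, "intensity")

#' Reorder the columns of a paired set as pair-aligned tumor/normal blocks
#'
#' Utility used by the paired operations: returns the intensity matrix
#' split into a tumor and a normal matrix whose columns are aligned by
#' pair id (same pair order in both).
#'
#' @param x a \code{PairedExpressionSet}.
#' @return list with elements \code{tumor}, \code{normal} (matrices) and
#'   \code{pairs} (the aligned pair ids).
#' @export
pairedBlocks <- function(x) {
  stopifnot(is(x, "PairedExpressionSet"))
  grp <- sampleGroup(x)
  pid <- pairId(x)
  pairs <- unique(pid)
  tcols <- which(grp == "tumor")[match(pairs, pid[grp == "tumor"])]
  ncols <- which(grp == "normal")[match(pairs, pid[grp == "normal"])]
  if (anyNA(tcols) || anyNA(ncols)) {
    bad <- pairs[is.na(tcols) | is.na(ncols)]
    stop("unpaired pair id(s): ", paste(bad, collapse = ", "))
  }
  m <- intensities(x)
  list(tumor = m[, tcols, drop = FALSE],
       normal = m[, ncols, drop = FALSE],
       pairs = pairs)
}

setMethod("show", "PairedExpressionSet", function(object) {
  cat("PairedExpressionSet:", nrow(object), "probes,",
      length(unique(pairId(object))), "tumor/normal pairs\n")
  cls <- rowData(object)$class
  if (!is.null(cls)) {
    tab <- table(cls)
    cat("  probe classes:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  callNextMethod()
})
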