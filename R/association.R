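#' Classify the genomic relationship between a lncRNA and a coding gene
#'
#' Overlap is tested on the interval coordinates regardless of strand;
#' strand then splits overlaps into sense and antisense, with the sense
#' case refined to \code{intronic_sense} when the lncRNA lies strictly
#' inside the gene. Disjoint intervals on the same chromosome closer than
#' \code{neighborWindow} (strictly) are neighbors, with the
#' enhancer-like/intergenic distinction taken from the lncRNA's annotation
#' class (it cannot be derived from coordinates). Different chromosomes
#' give \code{none} with \code{NA} distance.
#'
#' @param lnc,gene parallel [GenomicRanges::GRanges] (equal length; each
#'   lncRNA classified against the gene at the same position).
#' @param lncClass per-lncRNA annotation class (\code{"genic"},
#'   \code{"enhancer_like"}, \code{"intergenic"}); used only to resolve
#'   the neighbor subclass.
#' @param neighborWindow maximum neighbor gap in bases (strict \code{<};
#'   default 300 kb).
#' @return \code{data.frame} with columns \code{relation} and
#'   \code{distance} (0 when overlapping, gap in bases otherwise, NA
#'   across chromosomes).
#' @examples
#' library(GenomicRanges)
#' lnc  <- GRanges("chr1", IRanges(101, 200), "+")
#' gene <- GRanges("chr1", IRanges(1, 1000), "+")
#' classifyRelation(lnc, gene)  # intronic_sense, distance 0
#' @export
classifyRelation <- function(lnc, gene, lncClass = NA_character_,
                             neighborWindow = 300000L) {
  stopifnot(length(lnc) == length(gene))
  n <- length(lnc)
  lncClass <- rep_len(as.character(lncClass), n)
  sameChr <- as.character(GenomicRanges::seqnames(lnc)) ==
    as.character(GenomicRanges::seqnames(gene))
  ## strand-blind overlap; poverlaps compares position i with position i
  ov <- sameChr &
    (GenomicRanges::start(lnc) <= GenomicRanges::end(gene)) &
    (GenomicRanges::start(gene) <= GenomicRanges::end(lnc))
  sameStrand <- as.character(GenomicRanges::strand(lnc)) ==
    as.character(GenomicRanges::strand(gene))
  inside <- GenomicRanges::start(lnc) >= GenomicRanges::start(gene) &
    GenomicRanges::end(lnc) <= GenomicRanges::end(gene) &
    !(GenomicRanges::start(lnc) == GenomicRanges::start(gene) &
        GenomicRanges::end(lnc) == GenomicRanges::end(gene))
  gap <- rep(NA_integer_, n)
  if (any(sameChr)) {
    gp <- GenomicRanges::distance(lnc[sameChr], gene[sameChr],
                                  ignore.strand = TRUE)
    gap[sameChr] <- as.integer(gp)
  }
  relation <- rep("none", n)
  relation[ov & sameStrand] <- "sense_overlap"
  relation[ov & sameStrand & inside] <- "intronic_sense"
  relation[ov & !sameStrand] <- "antisense_overlap"
  neigh <- sameChr & !ov & !is.na(gap) & gap < neighborWindow
  relation[neigh] <- ifelse(!is.na(lncClass[neigh]) &
                              lncClass[neigh] == "enhancer_like",
                            "enhancer_like_neighbor",
                            "intergenic_neighbor")
  distance <- ifelse(relation == "none" & !sameChr, NA_integer_, gap)
  distance[ov] <- 0L
  data.frame(relation = relation, distance = distance)
}

#' Derive lncRNA-gene association records from a probe annotation
#'
#' For every lncRNA probe annotated with a partner gene probe, classifies
#' the relationship from the coordinates via [classifyRelation()].
#'
#' @param annotation a [GenomicRanges::GRanges] as produced by
#'   [simulateAnnotation()] (or read with [readAnnotation()]): metadata
#'   columns \code{probeId}, \code{probeClass}, \code{lncClass},
#'   \code{partnerId}.
#' @param neighborWindow passed to [classifyRelation()].
#' @return \code{data.frame} with \code{lncrnaId}, \code{geneId},
#'   \code{relation}, \code{distance}.
#' @export
associationRecords <- function(annotation, neighborWindow = 300000L) {
  mc <- S4Vectors::mcols(annotation)
  i <- which(mc$probeClass == "lncRNA" & !is.na(mc$partnerId))
  if (!length(i))
    return(data.frame(lncrnaId = character(), geneId = character(),
                      relation = character(), distance = integer()))
  j <- match(mc$partnerId[i], mc$probeId)
  if (anyNA(j))
    stop("partner id(s) absent from annotation: ",
         paste(mc$partnerId[i][is.na(j)], collapse = ", "))
  cls <- classifyRelation(annotation[i], annotation[j],
                          lncClass = mc$lncClass[i],
                          neighborWindow = neighborWindow)
  data.frame(lncrnaId = mc$probeId[i], geneId = mc$probeId[j],
             relation = cls$relation, distance = cls$distance)
}

#' Co-aberrant expression summary of associated lncRNA-gene pairs
#'
#' For each relationship class, counts the association links whose lncRNA
#' and gene are both differentially expressed and reports the fraction
#' changing in the same direction (both up or both down).
#'
#' @param deLnc,deMrna [DEResult-class] tables for lncRNA and mRNA probes.
#' @param associations \code{data.frame} from [associationRecords()].
#' @return \code{data.frame} per relation class: \code{nLinks} (links with
#'   a DE lncRNA), \code{nBothDE}, \code{concordant},
#'   \code{concordantFraction}.
#' @export
coexpressionTable <- function(deLnc, deMrna, associations) {
  if (nrow(associations) == 0L)
    return(data.frame(relation = character(), nLinks = integer(),
                      nBothDE = integer(), concordant = integer(),
                      concordantFraction = numeric()))
  li <- match(associations$lncrnaId, rownames(deLnc))
  gi <- match(associations$geneId, rownames(deMrna))
  if (anyNA(li) || anyNA(gi)) {
    bad <- c(associations$lncrnaId[is.na(li)], associations$geneId[is.na(gi)])
    stop("association references unknown probe id(s): ",
         paste(unique(bad), collapse = ", "))
  }
  lncDE <- deLnc$passesFilter[li]
  geneDE <- deMrna$passesFilter[gi]
  both <- lncDE & geneDE
  conc <- both & (deLnc$direction[li] == deMrna$direction[gi])
  out <- lapply(split(seq_len(nrow(associations)), associations$relation),
                function(k) {
    data.frame(nLinks = sum(lncDE[k]), nBothDE = sum(both[k]),
               concordant = sum(conc[k]),
               concordantFraction =
                 if (sum(both[k]) > 0) sum(conc[k]) / sum(both[k])
                 else NA_real_)
  })
  res <- do.call(rbind, out)
  data.frame(relation = names(out), res, row.names = NULL)
}
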