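#' Read and write the pipeline's plain-text interchange formats
#'
#' Expression matrices travel as TSV with the probe id in the first
#' column and one column per sample named \code{<pairId>_T} /
#' \code{<pairId>_N}; probe annotations as an 8-column BED-like TSV
#' (0-based half-open coordinates); Cp tables as CSV.
#'
#' @param x object to write.
#' @param path file path.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
writeExpression <- function(x, path) {
  stopifnot(is(x, "PairedExpressionSet"))
  df <- data.frame(probe_id = rownames(x), intensities(x),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @param probeClass optional probe classes to attach on read.
#' @export
readExpression <- function(path, probeClass = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  cn <- colnames(m)
  ok <- grepl("_[TN]$", cn)
  if (!all(ok))
    stop("sample column(s) not named <pairId>_T/<pairId>_N: ",
         paste(cn[!ok], collapse = ", "))
  PairedExpressionSet(
    m,
    pairId = sub("_[TN]$", "", cn),
    group = ifelse(grepl("_T$", cn), "tumor", "normal"),
    probeClass = probeClass)
}

#' @rdname pipeline-io
#' @param gr annotation \code{GRanges} (see [simulateAnnotation()]).
#' @export
writeAnnotation <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  ## class column: lncRNA annotation class, or "mRNA" for coding probes
  cls <- ifelse(mc$probeClass == "mRNA", "mRNA",
                ifelse(is.na(mc$lncClass), "intergenic", mc$lncClass))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # 0-based half-open on disk
    end = GenomicRanges::end(gr),
    probe_id = mc$probeId,
    class = cls,
    strand = as.character(GenomicRanges::strand(gr)),
    relation = ifelse(is.na(mc$relation), ".", mc$relation),
    partner_id = ifelse(is.na(mc$partnerId), ".", mc$partnerId))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readAnnotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr) <- DataFrame(
    probeId = df$probe_id,
    probeClass = ifelse(df$class == "mRNA", "mRNA", "lncRNA"),
    lncClass = ifelse(df$class == "mRNA", NA_character_, df$class),
    relation = ifelse(df$relation == ".", NA_character_, df$relation),
    partnerId = ifelse(df$partner_id == ".", NA_character_,
                       df$partner_id))
  names(gr) <- df$probe_id
  gr
}

#' @rdname pipeline-io
#' @param de a [DEResult-class].
#' @export
writeDEResult <- function(de, path) {
  df <- data.frame(probe_id = rownames(de), log2fc = de$log2fc,
                   p_raw = de$pRaw, fdr = de$fdr,
                   direction = de$direction,
                   passes_filter = de$passesFilter)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readDEResult <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  new("DEResult", DataFrame(
    probeId = df$probe_id, class = NA_character_, log2fc = df$log2fc,
    pRaw = df$p_raw, fdr = df$fdr, direction = df$direction,
    passesFilter = df$passes_filter, row.names = df$probe_id))
}

#' @rdname pipeline-io
#' @param cpTable Cp \code{data.frame} (sample, group, gene, replicate,
#'   cp, optional pair).
#' @export
writeCpTable <- function(cpTable, path) {
  utils::write.csv(cpTable, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
readCpTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
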