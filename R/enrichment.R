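#' Upper-tail hypergeometric p-value for gene-set overlap
#'
#' Exact over-representation p-value \eqn{P[X \ge x]} for drawing
#' \code{overlapX} or more members of a set of size \code{setK} when
#' \code{drawN} genes are drawn without replacement from a universe of
#' \code{universeN}. The observed overlap is included in the tail, the
#' standard over-representation convention. Computed through
#' [stats::phyper()] (log-space-stable binomial coefficients).
#'
#' @param universeN universe size N.
#' @param setK set size K.
#' @param drawN number of drawn (differential) genes n.
#' @param overlapX observed overlap x.
#' @return p-value in (0, 1]; \code{overlapX = 0} gives exactly 1.
#' @examples
#' hypergeomPValue(10, 5, 4, 4)  # choose(5,4)/choose(10,4) = 5/210
#' @export
hypergeomPValue <- function(universeN, setK, drawN, overlapX) {
  if (any(c(universeN, setK, drawN, overlapX) %% 1 != 0))
    stop("all counts must be whole numbers")
  if (overlapX < 0 || setK > universeN || drawN > universeN ||
      overlapX > min(setK, drawN))
    stop("inconsistent counts: need 0 <= x <= min(K, n) <= N")
  stats::phyper(overlapX - 1, setK, universeN - setK, drawN,
                lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' Tests each gene set for over-representation of a differential gene list
#' against a finite universe using the upper-tail hypergeometric test.
#' Sets are restricted to the universe; differential genes outside the
#' universe are dropped with a warning. No multiple-testing correction is
#' applied by default (sets are called enriched at raw p < \code{cutoff},
#' strictly); BH adjustment is available.
#'
#' @param deGenes character vector of differential gene ids.
#' @param sets named list of character vectors (e.g. from [readGMT()]).
#' @param universe character vector of all assayed gene ids.
#' @param cutoff significance cutoff (strict \code{<}).
#' @param adjust \code{"none"} (default) or \code{"BH"}; when BH, the
#'   enriched flag uses the adjusted values.
#' @return \code{data.frame} sorted by ascending p (ties by set name):
#'   \code{set}, \code{setSize}, \code{drawSize}, \code{overlap},
#'   \code{p}, optional \code{fdr}, \code{enriched}.
#' @export
enrichGeneSets <- function(deGenes, sets, universe, cutoff = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be uniquely named")
  deGenes <- unique(as.character(deGenes))
  outside <- setdiff(deGenes, universe)
  if (length(outside)) {
    warning(length(outside), " differential gene(s) not in universe dropped")
    deGenes <- intersect(deGenes, universe)
  }
  setsU <- lapply(sets, intersect, universe)
  N <- length(universe)
  n <- length(deGenes)
  K <- lengths(setsU)
  x <- vapply(setsU, function(s) length(intersect(s, deGenes)), integer(1))
  p <- mapply(hypergeomPValue, universeN = N, setK = K, drawN = n,
              overlapX = x)
  res <- data.frame(set = names(sets), setSize = unname(K),
                    drawSize = n, overlap = unname(x), p = unname(p),
                    stringsAsFactors = FALSE)
  if (adjust == "BH") {
    res$fdr <- benjaminiHochberg(res$p)
    res$enriched <- res$fdr < cutoff
  } else {
    res$enriched <- res$p < cutoff
  }
  res[order(res$p, res$set), , drop = FALSE]
}

#' Read and write GMT gene-set files
#'
#' GMT is the tab-separated gene-set interchange format: one set per line
#' as \code{name<TAB>description<TAB>member1<TAB>member2...}.
#'
#' @param path file path.
#' @return \code{readGMT}: named list of member character vectors with a
#'   \code{"description"} attribute.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2L)
  sets
}

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @param description optional per-set description strings.
#' @export
writeGMT <- function(sets, path, description = NULL) {
  if (is.null(description))
    description <- attr(sets, "description")
  if (is.null(description)) description <- rep("na", length(sets))
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}
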