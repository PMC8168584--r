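#' Extend peak summits into fixed-width regions
#'
#' Each summit is extended by \code{flank} bp on both sides (slopBed
#' semantics), giving regions of \code{2 * flank + 1} bp, clipped at
#' chromosome ends. The default 250-bp flank yields 501-bp regions.
#'
#' @param summits \code{GRanges} of width-1 summit positions (e.g. imported
#'   from a MACS2 summit BED via \code{rtracklayer::import}), with a
#'   \code{score} mcol.
#' @param flank Non-negative flank size in bp.
#' @param chromSizes Named integer vector of chromosome lengths.
#' @return \code{GRanges} of extended peaks; mcols keep \code{score} and add
#'   \code{summit} (1-based summit position).
#' @importFrom GenomicRanges start end width seqnames
#' @export
extendSummits <- function(summits, flank = 250L, chromSizes) {
  stopifnot(flank >= 0)
  if (any(GenomicRanges::width(summits) != 1L))
    stop("summits must be width-1 ranges")
  ch <- as.character(GenomicRanges::seqnames(summits))
  if (any(!ch %in% names(chromSizes)))
    stop("summit chromosome missing from chromSizes")
  s <- GenomicRanges::start(summits)
  sz <- chromSizes[ch]
  if (any(s < 1 | s > sz)) stop("summit outside chromosome bounds")
  out <- GenomicRanges::GRanges(ch,
    IRanges::IRanges(start = pmax(1L, s - flank),
                     end = pmin(as.integer(sz), s + flank)))
  S4Vectors::mcols(out)$score <-
    S4Vectors::mcols(summits)$score %||% rep(0, length(summits))
  S4Vectors::mcols(out)$summit <- s
  names(out) <- names(summits)
  out
}

#' Consolidate peak sets by iterative score-ranked selection
#'
#' Pools peaks from the reference-mapped and both haplotype-mapped calls
#' (haplotype peaks already lifted to reference coordinates) and repeatedly
#' keeps the highest-scoring peak while removing every peak overlapping it.
#' The result is non-overlapping and every retained peak is one of the
#' inputs verbatim.
#'
#' @param ... One or more \code{GRanges} with a numeric \code{score} mcol.
#' @return Non-overlapping \code{GRanges}, sorted by position.
#' @export
consolidatePeaks <- function(...) {
  pooled <- suppressWarnings(do.call(c, unname(list(...))))
  if (length(pooled) == 0) return(pooled)
  sc <- S4Vectors::mcols(pooled)$score
  if (is.null(sc)) stop("peaks need a score mcol")
  ord <- order(sc, decreasing = TRUE)
  pooled <- pooled[ord]
  keep <- logical(length(pooled))
  kept <- GenomicRanges::GRanges()
  for (i in seq_along(pooled)) {
    if (!any(IRanges::overlapsAny(pooled[i], kept))) {
      keep[i] <- TRUE
      kept <- c(kept, pooled[i])
    }
  }
  out <- pooled[keep]
  GenomicRanges::sort(out)
}
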