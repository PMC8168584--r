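#' Count haplotype-supporting reads at phased heterozygous SNVs inside peaks
#'
#' For every heterozygous SNV overlapping a peak, counts the
#' haplotype-1-exclusive reads that base-level cover the site and carry the
#' haplotype-1 allele (analogously for haplotype 2). Reads covering the site
#' with a third base (sequencing error) contribute to neither count. Reads
#' in the common sets are not allele-informative and are not counted here.
#' Indel variants are excluded from base-level counting (reason
#' \code{"indel"}), as are variants outside every peak.
#'
#' @param dg \code{\link{DiploidGenome}} (supplies variants, alleles and
#'   coordinate maps).
#' @param reads1,reads2 data.frames of haplotype-exclusive reads, columns
#'   \code{chrom}, \code{start0} (0-based start in that haplotype's
#'   coordinates), \code{seq} (read bases).
#' @param peaks \code{GRanges} of consolidated peaks (reference
#'   coordinates); peak ids taken from names or \code{peak_id} mcol.
#' @param assay One of \code{"ATAC"}, \code{"RNA"}, \code{"CHIP_H3K27AC"},
#'   \code{"CHIP_TF"}.
#' @param wgs Optional data.frame \code{chrom}, \code{pos} (1-based),
#'   \code{wgs_a}, \code{wgs_b} of WGS allele counts, merged by site.
#' @return data.frame with one row per counted variant: \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{gt}, \code{assay},
#'   \code{hap1_count}, \code{hap2_count}, \code{wgs_a}, \code{wgs_b},
#'   \code{peak_id}. Attribute \code{"excluded"} lists dropped variants
#'   with reasons.
#' @export
countAlleles <- function(dg, reads1, reads2, peaks,
                         assay = c("ATAC", "RNA", "CHIP_H3K27AC", "CHIP_TF"),
                         wgs = NULL) {
  assay <- match.arg(assay)
  v <- dg@variants
  mc <- S4Vectors::mcols(v)
  het <- mc$het
  isSnv <- variantType(mc$ref, mc$alt) == "snv"
  pid <- names(peaks) %||% S4Vectors::mcols(peaks)$peak_id
  if (is.null(pid)) pid <- paste0("peak_", seq_along(peaks))
  hits <- GenomicRanges::findOverlaps(v, peaks, select = "first")
  use <- het & isSnv & !is.na(hits)
  excluded <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(v))[!use],
    pos = GenomicRanges::start(v)[!use],
    reason = ifelse(!het[!use], "homozygous",
             ifelse(!isSnv[!use], "indel", "outside-peaks")))
  idx <- which(use)
  countOne <- function(reads, posH, allele) {
    if (is.null(reads) || nrow(reads) == 0 || is.na(posH)) return(0L)
    cov <- reads$start0 <= posH & posH < reads$start0 + nchar(reads$seq)
    if (!any(cov)) return(0L)
    b <- substr(reads$seq[cov], posH - reads$start0[cov] + 1L,
                posH - reads$start0[cov] + 1L)
    sum(b == allele)
  }
  rows <- lapply(idx, function(i) {
    ch <- as.character(GenomicRanges::seqnames(v))[i]
    pos0 <- GenomicRanges::start(v)[i] - 1L
    a1 <- if (mc$gt1[i] == 1L) mc$alt[i] else mc$ref[i]
    a2 <- if (mc$gt2[i] == 1L) mc$alt[i] else mc$ref[i]
    p1 <- liftPosition(dg@hap1@map, ch, pos0, "ref2hap")
    p2 <- liftPosition(dg@hap2@map, ch, pos0, "ref2hap")
    r1 <- if (is.null(reads1)) NULL else reads1[reads1$chrom == ch, , drop = FALSE]
    r2 <- if (is.null(reads2)) NULL else reads2[reads2$chrom == ch, , drop = FALSE]
    data.frame(chrom = ch, pos = GenomicRanges::start(v)[i],
               ref = mc$ref[i], alt = mc$alt[i],
               gt = paste0(mc$gt1[i], "|", mc$gt2[i]), assay = assay,
               hap1_count = countOne(r1, p1, a1),
               hap2_count = countOne(r2, p2, a2),
               peak_id = pid[hits[i]], stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), gt = character(0), assay = character(0),
               hap1_count = integer(0), hap2_count = integer(0),
               peak_id = character(0))
  if (!is.null(wgs)) {
    out <- merge(out, wgs[, c("chrom", "pos", "wgs_a", "wgs_b")],
                 by = c("chrom", "pos"), all.x = TRUE, sort = FALSE)
  } else {
    out$wgs_a <- rep(NA_integer_, nrow(out))
    out$wgs_b <- rep(NA_integer_, nrow(out))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Apply assay-specific minimum-coverage filters
#'
#' ATAC and ChIP records need at least 6 allele-informative reads; RNA
#' records at least 10. Thresholds are configurable.
#'
#' @param records Allele-count data.frame (see \code{\link{countAlleles}})
#'   with \code{assay}, \code{hap1_count}, \code{hap2_count}.
#' @param minAtac,minRna Minimum total depth for ATAC/ChIP and RNA.
#' @return The filtered data.frame.
#' @examples
#' r <- data.frame(assay = c("ATAC", "ATAC", "RNA"),
#'                 hap1_count = c(3, 4, 5), hap2_count = c(2, 2, 4))
#' nrow(filterMinCoverage(r)) # 1: depth-5 ATAC and depth-9 RNA removed
#' @export
filterMinCoverage <- function(records, minAtac = 6L, minRna = 10L) {
  if (nrow(records) == 0) return(records)
  depth <- records$hap1_count + records$hap2_count
  minDepth <- ifelse(records$assay == "RNA", minRna, minAtac)
  records[depth >= minDepth, , drop = FALSE]
}

#' Flag peaks whose variants disagree on allelic direction
#'
#' Peaks containing several heterozygous variants are only interpretable
#' for motif analysis when all variants favor the same haplotype; peaks
#' with inconsistent bias are flagged for removal.
#'
#' @param records Allele-count data.frame with \code{peak_id},
#'   \code{hap1_count}, \code{hap2_count}.
#' @return Character vector of inconsistent peak ids.
#' @export
flagInconsistentPeaks <- function(records) {
  if (nrow(records) == 0) return(character(0))
  dir <- sign(records$hap1_count - records$hap2_count)
  informative <- dir != 0
  tab <- tapply(dir[informative], records$peak_id[informative],
                function(d) length(unique(d)))
  names(tab)[tab > 1]
}
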