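#' Mutation copy number
#'
#' Number of chromosome copies carrying a variant, estimated from the total
#' tumor copy number, the variant allele frequency and sample purity as
#' \code{round(nTot * vaf / purity)}, with half rounded away from zero (the
#' discretization feeding early/late timing), floored at 0 and, when the
#' major copy number is supplied, capped at it.
#'
#' @param nTot Total copy number of the segment (major + minor).
#' @param vaf Variant allele frequency in [0, 1].
#' @param purity Sample purity in (0, 1]; 1 for pure cell lines.
#' @param nMajor Optional major copy number used as a cap.
#' @return Integer mutation copy number; vectorized.
#' @examples
#' mutationCopyNumber(2, 0.5, 1)  # 1
#' mutationCopyNumber(4, 0.5, 1)  # 2
#' @export
mutationCopyNumber <- function(nTot, vaf, purity = 1, nMajor = NULL) {
  if (any(purity <= 0)) stop("purity must be in (0, 1]")
  stopifnot(all(nTot >= 1), all(vaf >= 0 & vaf <= 1))
  mcn <- pmax(0, roundHalfUp(nTot * vaf / purity))
  if (!is.null(nMajor)) mcn <- pmin(mcn, nMajor)
  as.integer(mcn)
}

#' Time a variant relative to copy-number gains
#'
#' A variant present on \code{mcn >= 2} copies arose before the duplication
#' of its chromosome ("early"); a variant on a single copy arose after
#' ("late"). The two scenarios are only distinguishable in segments with
#' loss of heterozygosity plus gain (\code{nMinor == 0 && nMajor >= 2}) or
#' gains on both alleles (\code{nMinor >= 2}); every other copy-number
#' context is untimeable ("na"). An \code{mcn} exceeding the major copy
#' number is inconsistent and yields "na".
#'
#' @param mcn Mutation copy number (\code{\link{mutationCopyNumber}}).
#' @param nMajor,nMinor Allele-specific copy numbers of the segment.
#' @return Character vector over \code{"early"}, \code{"late"}, \code{"na"}.
#' @examples
#' timeVariant(2, 2, 0) # "early"
#' timeVariant(1, 2, 0) # "late"
#' timeVariant(2, 1, 1) # "na" (untimeable context)
#' @export
timeVariant <- function(mcn, nMajor, nMinor) {
  stopifnot(all(nMajor >= nMinor), all(nMinor >= 0))
  n <- max(length(mcn), length(nMajor))
  mcn <- rep_len(mcn, n); nMajor <- rep_len(nMajor, n)
  nMinor <- rep_len(nMinor, n)
  timeable <- (nMinor == 0 & nMajor >= 2) | nMinor >= 2
  out <- rep("na", n)
  consistent <- mcn <= nMajor
  out[timeable & consistent & mcn >= 2] <- "early"
  out[timeable & consistent & mcn == 1] <- "late"
  out
}

#' Classify a sample as whole-genome doubled
#'
#' Applies a linear decision boundary in the (LOH fraction, ploidy) plane:
#' WGD iff \code{ploidy > c0 - c1 * lohFraction}. The default constants
#' (2.9, 2.0) are this package's substitute for the published criterion and
#' are fully configurable.
#'
#' @param ploidy Genome-average total copy number.
#' @param lohFraction Fraction of the genome with minor copy number 0.
#' @param c0,c1 Boundary intercept and slope.
#' @return Logical; strict inequality, so a sample exactly on the boundary
#'   is not WGD.
#' @examples
#' classifyWgd(3.8, 0.2)  # TRUE
#' classifyWgd(2.0, 0.05) # FALSE
#' @export
classifyWgd <- function(ploidy, lohFraction, c0 = 2.9, c1 = 2.0) {
  stopifnot(all(ploidy > 0), all(lohFraction >= 0 & lohFraction <= 1))
  ploidy > c0 - c1 * lohFraction
}

#' Read an ASCAT-style allele-specific copy-number segment table
#'
#' Tab-separated with header \code{chrom start end nMajor nMinor}.
#'
#' @param file Path.
#' @return data.frame with an added \code{nTot} column.
#' @export
readCnSegments <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "nMajor", "nMinor")
  if (!all(need %in% names(df)))
    stop("segment file must have columns ", paste(need, collapse = " "))
  df$nTot <- df$nMajor + df$nMinor
  df
}

#' Time all variants in a VAF table against copy-number segments
#'
#' Joins variants to their covering segment and applies
#' \code{\link{mutationCopyNumber}} and \code{\link{timeVariant}}.
#'
#' @param variants data.frame \code{chrom}, \code{pos} (1-based),
#'   \code{vaf}.
#' @param segments Segment data.frame (\code{\link{readCnSegments}};
#'   \code{start}/\code{end} 0-based half-open).
#' @param purity Sample purity.
#' @return Input data.frame plus \code{nMajor}, \code{nMinor}, \code{mcn},
#'   \code{timing_class} (\code{"na"} outside any segment).
#' @export
timeVariants <- function(variants, segments, purity = 1) {
  n <- nrow(variants)
  out <- cbind(variants,
    data.frame(nMajor = NA_integer_, nMinor = NA_integer_,
               mcn = NA_integer_, timing_class = rep("na", n)))
  for (i in seq_len(n)) {
    seg <- segments[segments$chrom == variants$chrom[i] &
                    segments$start < variants$pos[i] &
                    variants$pos[i] <= segments$end, , drop = FALSE]
    if (nrow(seg) == 0) next
    seg <- seg[1, ]
    if (seg$nTot < 1) next
    mcn <- mutationCopyNumber(seg$nTot, variants$vaf[i], purity,
                              nMajor = NULL)
    out$nMajor[i] <- seg$nMajor; out$nMinor[i] <- seg$nMinor
    out$mcn[i] <- mcn
    out$timing_class[i] <- timeVariant(mcn, seg$nMajor, seg$nMinor)
  }
  out
}
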