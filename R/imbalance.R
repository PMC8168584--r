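#' Copy-number/bias-corrected allelic ratio
#'
#' Removes the genomic (copy-number) component and any residual
#' reference-mapping bias from an observed allelic fraction in odds space:
#' \code{odds(corrected) = odds(observed) / odds(genomic) * odds(0.5) /
#' odds(refBias)}. With a balanced genome and no mapping bias the observed
#' ratio is returned unchanged; an observed ratio fully explained by the
#' genomic ratio corrects to 0.5.
#'
#' @param observed Observed assay allele fraction in (0, 1).
#' @param genomic Genomic (WGS) allele fraction in (0, 1).
#' @param refBias Residual reference-mapping bias; 0.5 (none) for
#'   personalized-genome alignments.
#' @param eps Ratios of exactly 0 or 1 are clamped into
#'   \code{[eps, 1 - eps]}.
#' @return Corrected ratio in [0, 1]; vectorized.
#' @examples
#' correctedAllelicRatio(0.75, 0.5)   # 0.75
#' correctedAllelicRatio(0.75, 0.75)  # 0.5
#' correctedAllelicRatio(0.9, 0.75)   # 0.75
#' @export
correctedAllelicRatio <- function(observed, genomic, refBias = 0.5,
                                  eps = 1e-6) {
  cl <- function(x) pmin(pmax(x, eps), 1 - eps)
  odds <- function(x) x / (1 - x)
  co <- odds(cl(observed)) / odds(cl(genomic)) / odds(cl(refBias))
  co / (1 + co)
}

assayEventType <- c(ATAC = "ASCAV", RNA = "ASEV",
                    CHIP_H3K27AC = "ASHV", CHIP_TF = "ASB")

#' Call allele-specific events from filtered allele-count records
#'
#' Runs the WGS-informed two-tailed beta-binomial test
#' (\code{\link{aseTest}}) on every record, BH-adjusts across records, and
#' applies the event decision rule. Expression events (RNA) are significant
#' at \code{q < fdrThreshold}; accessibility/binding events (ATAC, ChIP)
#' additionally require the copy-number-corrected allelic ratio to fall
#' outside the balance band, so imbalance fully explained by copy number is
#' not called. Non-significant records form the control-variant set.
#'
#' @param records Allele-count data.frame (post
#'   \code{\link{filterMinCoverage}}) with \code{assay},
#'   \code{hap1_count}, \code{hap2_count}, \code{wgs_a}, \code{wgs_b}.
#' @param fdrThreshold FDR cutoff, default 0.05.
#' @param balanceBand Two-sided corrected-ratio band treated as balanced,
#'   default \code{c(0.4, 0.6)}.
#' @param refBias Passed to \code{\link{correctedAllelicRatio}}.
#' @return List with \code{calls} (records plus \code{p}, \code{q},
#'   \code{observed_raf}, \code{genomic_raf}, \code{corrected_raf},
#'   \code{significant}, \code{event_type}) and \code{controls} (the
#'   non-significant subset).
#' @export
callEvents <- function(records, fdrThreshold = 0.05,
                       balanceBand = c(0.4, 0.6), refBias = 0.5) {
  if (nrow(records) == 0)
    return(list(calls = records, controls = records))
  p <- vapply(seq_len(nrow(records)), function(i)
    aseTest(records$hap1_count[i], records$hap2_count[i],
            records$wgs_a[i], records$wgs_b[i]), 0)
  q <- bhFdr(p)
  depth <- records$hap1_count + records$hap2_count
  obs <- records$hap1_count / depth
  gen <- records$wgs_a / (records$wgs_a + records$wgs_b)
  corr <- correctedAllelicRatio(obs, gen, refBias)
  needsBand <- records$assay != "RNA"
  sig <- q < fdrThreshold &
    (!needsBand | corr < balanceBand[1] | corr > balanceBand[2])
  calls <- cbind(records,
    data.frame(p = p, q = q, observed_raf = obs, genomic_raf = gen,
               corrected_raf = corr, significant = sig,
               event_type = unname(assayEventType[records$assay])))
  list(calls = calls, controls = calls[!sig, , drop = FALSE])
}

#' Cross-sample concordance of allele-specific calls
#'
#' For variants called significant in at least two samples, reports whether
#' the favored allele (haplotype with the higher corrected ratio) agrees
#' across samples; discordant variants are flagged.
#'
#' @param callsList Named list of \code{calls} data.frames from
#'   \code{\link{callEvents}}, one per sample.
#' @return data.frame with \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{n_samples}, \code{favored} (comma-separated per sample) and
#'   \code{concordant}; variants significant in fewer than two samples are
#'   excluded.
#' @export
crossSampleConcordance <- function(callsList) {
  stopifnot(length(names(callsList)) == length(callsList))
  sig <- lapply(names(callsList), function(s) {
    d <- callsList[[s]]
    d <- d[d$significant, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    data.frame(sample = s, chrom = d$chrom, pos = d$pos, ref = d$ref,
               alt = d$alt,
               favored = ifelse(d$corrected_raf > 0.5, "hap1", "hap2"))
  })
  sig <- do.call(rbind, sig)
  if (is.null(sig) || nrow(sig) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      n_samples = integer(0), favored = character(0),
                      concordant = logical(0)))
  key <- paste(sig$chrom, sig$pos, sig$ref, sig$alt, sep = ":")
  shared <- names(which(table(key) >= 2))
  rows <- lapply(shared, function(k) {
    d <- sig[key == k, , drop = FALSE]
    data.frame(chrom = d$chrom[1], pos = d$pos[1], ref = d$ref[1],
               alt = d$alt[1], n_samples = nrow(d),
               favored = paste(d$favored, collapse = ","),
               concordant = length(unique(d$favored)) == 1L)
  })
  do.call(rbind, rows)
}
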