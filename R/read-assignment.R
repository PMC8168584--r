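#' Classify the haplotype of origin of one read from its two alignments
#'
#' Compares the alignment of a read against haplotype 1 with its alignment
#' against haplotype 2, tier by tier: higher mapping quality wins, then more
#' aligned (CIGAR M) bases, then fewer mismatches. If all three tiers are
#' equal the read maps commonly to both haplotypes.
#'
#' @param mapq1,mapq2 Mapping qualities on haplotype 1 / 2.
#' @param matched1,matched2 Summed CIGAR M-operation lengths.
#' @param mismatches1,mismatches2 Mismatch counts (XM-style tag).
#' @return Character vector over \code{"HAP1_EXCLUSIVE"},
#'   \code{"HAP2_EXCLUSIVE"}, \code{"COMMON"}; vectorized over reads.
#' @examples
#' classifyRead(42, 42, 100, 100, 0, 1) # hap1 wins on mismatches
#' @export
classifyRead <- function(mapq1, mapq2, matched1, matched2,
                         mismatches1, mismatches2) {
  n <- length(mapq1)
  out <- rep("COMMON", n)
  # tier 1: mapq (higher better); tier 2: matched bases (higher);
  # tier 3: mismatches (lower)
  d <- sign(mapq1 - mapq2)
  t2 <- sign(matched1 - matched2)
  t3 <- sign(mismatches2 - mismatches1)
  d[d == 0] <- t2[d == 0]
  d[d == 0] <- t3[d == 0]
  out[d > 0] <- "HAP1_EXCLUSIVE"
  out[d < 0] <- "HAP2_EXCLUSIVE"
  out
}

#' Ambiguity filter for commonly mapping reads
#'
#' A read whose two alignments are metrically identical should still be
#' discarded when the two placements do not correspond to the same reference
#' locus. Both loci are lifted to reference coordinates through the
#' haplotypes' coordinate maps; reads whose lifted positions disagree beyond
#' \code{slack} (default 0 bp), or that sit in haplotype-only sequence and
#' cannot be lifted, are discarded.
#'
#' @param chrom1,pos1 Locus of the haplotype-1 alignment (0-based).
#' @param chrom2,pos2 Locus of the haplotype-2 alignment.
#' @param map1,map2 \code{\link{CoordinateMap}}s for haplotype 1 and 2.
#' @param slack Maximum allowed distance between lifted starts.
#' @return Character vector: \code{"keep"}, \code{"discordant"} or
#'   \code{"unmappable"}.
#' @export
ambiguityFilter <- function(chrom1, pos1, chrom2, pos2, map1, map2,
                            slack = 0L) {
  n <- length(pos1)
  out <- rep("keep", n)
  r1 <- rep(NA_integer_, n); r2 <- rep(NA_integer_, n)
  for (ch in unique(chrom1)) {
    i <- chrom1 == ch
    r1[i] <- liftPosition(map1, ch, pos1[i], "hap2ref")
  }
  for (ch in unique(chrom2)) {
    i <- chrom2 == ch
    r2[i] <- liftPosition(map2, ch, pos2[i], "hap2ref")
  }
  out[is.na(r1) | is.na(r2)] <- "unmappable"
  disc <- !is.na(r1) & !is.na(r2) &
    (chrom1 != chrom2 | abs(r1 - r2) > slack)
  out[disc] <- "discordant"
  out
}

#' Read the tabular alignment-metrics dialect
#'
#' One row per read per haplotype:
#' \code{read_id mapq matched_bases mismatches chrom pos is_dup}
#' (tab-separated, header required, \code{pos} 0-based).
#'
#' @param file Path to a metrics TSV.
#' @return data.frame.
#' @export
readAlignmentMetrics <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("read_id", "mapq", "matched_bases", "mismatches", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("metrics file must have columns ", paste(need, collapse = " "))
  if (is.null(df$is_dup)) df$is_dup <- FALSE
  df
}

#' Partition reads into haplotype-exclusive, common and discarded sets
#'
#' Full read-assignment pass: joins the two per-haplotype metric tables by
#' read id, removes duplicates, classifies every read
#' (\code{\link{classifyRead}}), and applies the ambiguity filter to
#' commonly mapping reads when coordinate maps are supplied. Reads aligned
#' to only one haplotype are exclusive to it (reason \code{single-mapping}).
#'
#' Duplicate handling: reads flagged \code{is_dup} in either table are
#' removed; in addition, among reads sharing the same placement on both
#' haplotypes the first seen is kept when \code{dedupeByLocus = TRUE}.
#'
#' @param hap1,hap2 data.frames in the alignment-metrics dialect
#'   (\code{\link{readAlignmentMetrics}}).
#' @param map1,map2 Optional \code{\link{CoordinateMap}}s enabling the
#'   ambiguity filter.
#' @param slack Passed to \code{\link{ambiguityFilter}}.
#' @param dedupeByLocus Remove locus-level duplicates (Picard-like,
#'   first seen kept).
#' @return List with \code{assignments} (data.frame \code{read_id},
#'   \code{label}, \code{reason}) over unique non-duplicate reads, and
#'   \code{summary} (named counts of the four labels).
#' @export
assignReads <- function(hap1, hap2, map1 = NULL, map2 = NULL, slack = 0L,
                        dedupeByLocus = TRUE) {
  if (anyDuplicated(hap1$read_id) || anyDuplicated(hap2$read_id))
    stop("metrics tables must have one row per read ",
         "(exclude secondary/supplementary alignments)")
  m <- merge(hap1, hap2, by = "read_id", all = TRUE,
             suffixes = c(".1", ".2"), sort = FALSE)
  dup <- (!is.na(m$is_dup.1) & m$is_dup.1) |
         (!is.na(m$is_dup.2) & m$is_dup.2)
  if (dedupeByLocus) {
    key <- paste(m$chrom.1, m$pos.1, m$chrom.2, m$pos.2)
    dup <- dup | duplicated(key)
  }
  m <- m[!dup, , drop = FALSE]
  n <- nrow(m)
  label <- character(n); reason <- character(n)
  only1 <- is.na(m$mapq.2); only2 <- is.na(m$mapq.1)
  label[only1] <- "HAP1_EXCLUSIVE"; reason[only1] <- "single-mapping"
  label[only2] <- "HAP2_EXCLUSIVE"; reason[only2] <- "single-mapping"
  both <- !only1 & !only2
  label[both] <- classifyRead(m$mapq.1[both], m$mapq.2[both],
                              m$matched_bases.1[both], m$matched_bases.2[both],
                              m$mismatches.1[both], m$mismatches.2[both])
  reason[both & label != "COMMON"] <- "better-alignment"
  com <- which(label == "COMMON")
  reason[com] <- "equal-alignment"
  if (length(com) && !is.null(map1) && !is.null(map2)) {
    verdict <- ambiguityFilter(m$chrom.1[com], m$pos.1[com],
                               m$chrom.2[com], m$pos.2[com],
                               map1, map2, slack)
    label[com][verdict != "keep"] <- "DISCARDED"
    reason[com][verdict != "keep"] <- verdict[verdict != "keep"]
  }
  assignments <- data.frame(read_id = m$read_id, label = label,
                            reason = reason, stringsAsFactors = FALSE)
  lv <- c("HAP1_EXCLUSIVE", "HAP2_EXCLUSIVE", "COMMON", "DISCARDED")
  summary <- table(factor(label, levels = lv))
  stopifnot(sum(summary) == n)
  list(assignments = assignments, summary = summary)
}
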