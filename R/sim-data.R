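#' Configuration for the synthetic diploid dataset generator
#'
#' Defaults describe the miniature study system: a 2 x 500 kb diploid
#' genome, ~2,000 phased heterozygous SNVs, 200 accessible peaks of 501 bp,
#' allele-specific copy-number segments with pure-sample WGS counts, and
#' assay counts drawn from a beta-binomial around the truth ratio (10% of
#' peak variants planted imbalanced at 0.85).
#'
#' @param seed Integer RNG seed; identical config + seed gives identical
#'   output.
#' @param nChroms,chromLength Genome shape.
#' @param hetSnvRate Background heterozygous SNV rate per bp (outside
#'   peaks; every peak additionally gets one variant).
#' @param indelRate Background heterozygous simple-indel rate per bp.
#' @param cnSegments data.frame \code{nMajor}, \code{nMinor}, \code{frac}
#'   describing the allele-specific copy-number segmentation applied to
#'   every chromosome (fractions sum to 1).
#' @param purity Sample purity in (0, 1].
#' @param nPeaks,peakWidth Accessible peak count and width.
#' @param plantedAscavFraction Fraction of peak variants planted with true
#'   allelic imbalance.
#' @param trueImbalanceRatio Assay fraction of the preferred allele at
#'   planted sites.
#' @param wgsDepth,atacDepth,rnaDepth Fixed per-site depths.
#' @param overdispersion Beta-binomial intra-class correlation of assay
#'   counts (0 = pure binomial).
#' @param plantedMotif Optional \code{\link{PWMotif}}: planted-imbalance
#'   sites become motif gains on the preferred allele.
#' @return A validated config list of class \code{"ascavSimConfig"}.
#' @export
simConfig <- function(seed = 1L, nChroms = 2L, chromLength = 500000L,
                      hetSnvRate = 0.002, indelRate = 0,
                      cnSegments = data.frame(
                        nMajor = c(1L, 2L, 2L),
                        nMinor = c(1L, 0L, 2L),
                        frac = c(0.6, 0.2, 0.2)),
                      purity = 1, nPeaks = 200L, peakWidth = 501L,
                      plantedAscavFraction = 0.1,
                      trueImbalanceRatio = 0.85,
                      wgsDepth = 40L, atacDepth = 30L, rnaDepth = 30L,
                      overdispersion = 0.02, plantedMotif = NULL) {
  cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
              chromLength = as.integer(chromLength),
              hetSnvRate = hetSnvRate, indelRate = indelRate,
              cnSegments = cnSegments, purity = purity,
              nPeaks = as.integer(nPeaks), peakWidth = as.integer(peakWidth),
              plantedAscavFraction = plantedAscavFraction,
              trueImbalanceRatio = trueImbalanceRatio,
              wgsDepth = as.integer(wgsDepth),
              atacDepth = as.integer(atacDepth),
              rnaDepth = as.integer(rnaDepth),
              overdispersion = overdispersion,
              plantedMotif = plantedMotif)
  with(cfg, {
    stopifnot(hetSnvRate >= 0, hetSnvRate <= 1, indelRate >= 0,
              plantedAscavFraction >= 0, plantedAscavFraction <= 1,
              trueImbalanceRatio > 0, trueImbalanceRatio < 1,
              purity > 0, purity <= 1,
              wgsDepth >= 1, atacDepth >= 1, rnaDepth >= 1,
              overdispersion >= 0, overdispersion < 1,
              abs(sum(cnSegments$frac) - 1) < 1e-9,
              all(cnSegments$nMajor >= cnSegments$nMinor),
              all(cnSegments$nMinor >= 0))
  })
  if (cfg$nPeaks * (cfg$peakWidth + 20L) > cfg$nChroms * cfg$chromLength)
    stop("infeasible config: peaks exceed the genome")
  class(cfg) <- "ascavSimConfig"
  cfg
}

# beta-binomial sampler parameterized by mean and intra-class correlation
rBetaBinomMu <- function(n, size, mu, rho) {
  mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
  if (rho <= 0) return(stats::rbinom(n, size, mu))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

#' Counts-level generator for allele-specific sites
#'
#' Emits allele-count records in the package's count-table format with
#' known ground truth: WGS counts binomial at the genomic allele fraction,
#' assay counts beta-binomial at the truth ratio (the genomic fraction for
#' null sites, a planted imbalance for the rest).
#'
#' @param nSites Number of sites.
#' @param wgsDepth,assayDepth Fixed depths.
#' @param genomicRatio Per-site genomic (copy-number) allele-1 fraction;
#'   recycled.
#' @param plantedFraction Fraction of sites with planted assay imbalance.
#' @param plantedRatio Preferred-allele assay fraction at planted sites
#'   (preferred haplotype randomized).
#' @param overdispersion Beta-binomial intra-class correlation.
#' @param assay Assay label for the records.
#' @param seed Integer seed.
#' @return List: \code{records} (count data.frame) and \code{truth}
#'   (\code{site}, \code{planted}, \code{true_ratio}).
#' @export
simulateAlleleCounts <- function(nSites, wgsDepth = 40L, assayDepth = 30L,
                                 genomicRatio = 0.5, plantedFraction = 0,
                                 plantedRatio = 0.85, overdispersion = 0.02,
                                 assay = "ATAC", seed = 1L) {
  withr::local_seed(seed)
  gen <- rep_len(genomicRatio, nSites)
  planted <- seq_len(nSites) %in%
    sample.int(nSites, round(plantedFraction * nSites))
  prefHap1 <- stats::runif(nSites) < 0.5
  trueRatio <- ifelse(planted,
                      ifelse(prefHap1, plantedRatio, 1 - plantedRatio),
                      gen)
  wgsA <- stats::rbinom(nSites, wgsDepth, gen)
  h1 <- rBetaBinomMu(nSites, assayDepth, trueRatio, overdispersion)
  records <- data.frame(
    chrom = "chrS", pos = seq_len(nSites) * 10L,
    ref = "A", alt = "C", gt = "1|0", assay = assay,
    hap1_count = h1, hap2_count = assayDepth - h1,
    wgs_a = wgsA, wgs_b = wgsDepth - wgsA,
    peak_id = paste0("peak_", seq_len(nSites)))
  truth <- data.frame(site = seq_len(nSites), planted = planted,
                      true_ratio = trueRatio)
  list(records = records, truth = truth)
}

#' Plant a motif gain across the two alleles of a peak sequence
#'
#' Writes the motif consensus into one haplotype's copy of the peak and a
#' single-base disruption into the other; the differing base is the planted
#' phased heterozygous variant.
#'
#' @param peakSeq Backbone peak sequence.
#' @param pwm \code{\link{PWMotif}} to plant.
#' @param motifStart 1-based start of the motif inside the peak.
#' @param disruptPos 1-based position within the motif to disrupt.
#' @param gainHap Haplotype (1 or 2) that carries the intact consensus.
#' @return List: \code{hap1_seq}, \code{hap2_seq}, \code{variant}
#'   (data.frame \code{pos} in-peak 1-based, \code{gain_base},
#'   \code{disrupt_base}, \code{gain_hap}).
#' @export
plantMotifGain <- function(peakSeq, pwm, motifStart = NULL,
                           disruptPos = NULL, gainHap = 1L) {
  m <- pwm@matrix
  L <- nrow(m)
  if (nchar(peakSeq) < L) stop("motif does not fit inside the peak")
  if (is.null(motifStart))
    motifStart <- (nchar(peakSeq) - L) %/% 2L + 1L
  if (is.null(disruptPos)) disruptPos <- (L + 1L) %/% 2L
  consensus <- BASES[apply(m, 1, which.max)]
  worst <- BASES[apply(m, 1, which.min)]
  gainBase <- consensus[disruptPos]
  disruptBase <- worst[disruptPos]
  withGain <- peakSeq
  substr(withGain, motifStart, motifStart + L - 1L) <-
    paste(consensus, collapse = "")
  withLoss <- withGain
  p <- motifStart + disruptPos - 1L
  substr(withLoss, p, p) <- disruptBase
  variant <- data.frame(pos = p, gain_base = gainBase,
                        disrupt_base = disruptBase, gain_hap = gainHap)
  if (gainHap == 1L)
    list(hap1_seq = withGain, hap2_seq = withLoss, variant = variant)
  else
    list(hap1_seq = withLoss, hap2_seq = withGain, variant = variant)
}

#' Simulate a miniature diploid dataset with full ground truth
#'
#' Generates a random reference genome, allele-specific copy-number
#' segments, non-overlapping accessible peaks, phased heterozygous SNVs
#' (one per peak plus background sites), WGS counts consistent with the
#' copy-number state, and ATAC/RNA allele counts at the truth ratio.
#' When \code{outDir} is given, the bundle is written as plain-text
#' FASTA/VCF/BED/TSV files; either way everything is returned in memory.
#'
#' @param config A \code{\link{simConfig}}.
#' @param outDir Optional output directory.
#' @return List: \code{reference} (DNAStringSet), \code{variants}
#'   (phased-variant GRanges), \code{peaks} (GRanges), \code{segments}
#'   (data.frame), \code{atacCounts}, \code{rnaCounts} (count
#'   data.frames), \code{truth} (per-variant ground truth), \code{config}.
#' @export
simulateDataset <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "ascavSimConfig"))
  withr::local_seed(config$seed)
  chroms <- paste0("chr", seq_len(config$nChroms))
  L <- config$chromLength

  refChars <- lapply(chroms, function(ch)
    sample(BASES, L, replace = TRUE))
  names(refChars) <- chroms

  # copy-number segmentation, identical layout on every chromosome
  segs <- do.call(rbind, lapply(chroms, function(ch) {
    bounds <- round(cumsum(c(0, config$cnSegments$frac)) * L)
    data.frame(chrom = ch, start = bounds[-length(bounds)],
               end = bounds[-1], nMajor = config$cnSegments$nMajor,
               nMinor = config$cnSegments$nMinor)
  }))
  segs$nTot <- segs$nMajor + segs$nMinor

  # non-overlapping peaks on a grid, then jittered
  perChrom <- diff(round(seq(0, config$nPeaks, length.out =
                             config$nChroms + 1)))
  pw <- config$peakWidth
  peakRows <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    k <- perChrom[ci]
    if (k == 0) return(NULL)
    slot <- floor((L - 2 * pw) / k)
    if (slot < pw + 10) stop("infeasible config: peaks exceed the genome")
    start0 <- pw + (seq_len(k) - 1L) * slot +
      sample.int(slot - pw, k, replace = TRUE)
    data.frame(chrom = chroms[ci], start0 = start0)
  }))
  peaks <- GenomicRanges::GRanges(peakRows$chrom,
    IRanges::IRanges(start = peakRows$start0 + 1L, width = pw))
  S4Vectors::mcols(peaks)$score <- round(stats::runif(length(peaks),
                                                      10, 100), 2)
  names(peaks) <- paste0("peak_", seq_along(peaks))

  # one het SNV per peak (at a random in-peak offset), planted subset;
  # imbalance is only planted where both alleles are retained (a lost
  # allele cannot carry assay signal)
  nP <- length(peaks)
  inPeakOff <- sample.int(pw - 60L, nP, replace = TRUE) + 30L
  vPos <- GenomicRanges::start(peaks) + inPeakOff  # 1-based
  vChrom <- as.character(GenomicRanges::seqnames(peaks))
  segOf <- function(ch, pos) which(segs$chrom == ch & segs$start < pos &
                                   pos <= segs$end)[1]
  peakSeg <- mapply(segOf, vChrom, vPos)
  eligible <- which(segs$nMinor[peakSeg] >= 1L)
  nPlant <- min(length(eligible),
                round(config$plantedAscavFraction * nP))
  planted <- seq_len(nP) %in% sample(eligible, nPlant)
  prefHap1 <- stats::runif(nP) < 0.5

  # background het SNVs outside peaks
  nBg <- max(0L, round(config$hetSnvRate * config$nChroms * L) - nP)
  bg <- NULL
  if (nBg > 0) {
    bgChrom <- sample(chroms, nBg, replace = TRUE)
    bgPos <- sample.int(L - 10L, nBg, replace = TRUE) + 5L
    gr <- GenomicRanges::GRanges(bgChrom, IRanges::IRanges(bgPos, width = 1))
    keep <- !IRanges::overlapsAny(gr, peaks) &
      !duplicated(paste(bgChrom, bgPos))
    bg <- data.frame(chrom = bgChrom, pos = bgPos)[keep, ]
  }

  # plant motif gains: rewrite the reference so the alt allele completes
  # the consensus on the preferred haplotype
  refAllele <- character(nP); altAllele <- character(nP)
  if (!is.null(config$plantedMotif)) {
    pwmM <- config$plantedMotif@matrix
    mlen <- nrow(pwmM)
    consensus <- BASES[apply(pwmM, 1, which.max)]
    worst <- BASES[apply(pwmM, 1, which.min)]
    dPos <- (mlen + 1L) %/% 2L
  }
  for (i in seq_len(nP)) {
    ch <- vChrom[i]
    if (planted[i] && !is.null(config$plantedMotif)) {
      mStart <- vPos[i] - dPos + 1L   # variant sits at motif pos dPos
      site <- consensus
      site[dPos] <- worst[dPos]
      refChars[[ch]][mStart:(mStart + mlen - 1L)] <- site
      refAllele[i] <- worst[dPos]
      altAllele[i] <- consensus[dPos]
    } else {
      refAllele[i] <- refChars[[ch]][vPos[i]]
      altAllele[i] <- sample(setdiff(BASES, refAllele[i]), 1)
    }
  }
  # planted sites: alt on the preferred haplotype; others random phase
  altOnHap1 <- ifelse(planted, prefHap1, stats::runif(nP) < 0.5)
  gtPeak <- ifelse(altOnHap1, "1|0", "0|1")

  reference <- Biostrings::DNAStringSet(
    vapply(refChars, paste, "", collapse = ""))
  names(reference) <- chroms

  vdf <- data.frame(chrom = vChrom, pos = vPos, ref = refAllele,
                    alt = altAllele, gt = gtPeak,
                    peak_id = names(peaks), planted = planted,
                    pref_hap1 = prefHap1, stringsAsFactors = FALSE)
  if (!is.null(bg) && nrow(bg)) {
    bgRef <- vapply(seq_len(nrow(bg)), function(i)
      refChars[[bg$chrom[i]]][bg$pos[i]], "")
    bgAlt <- vapply(bgRef, function(r) sample(setdiff(BASES, r), 1), "")
    vdf <- rbind(vdf, data.frame(chrom = bg$chrom, pos = bg$pos,
      ref = bgRef, alt = bgAlt,
      gt = ifelse(stats::runif(nrow(bg)) < 0.5, "1|0", "0|1"),
      peak_id = NA, planted = FALSE, pref_hap1 = NA))
  }
  vdf <- vdf[order(vdf$chrom, vdf$pos), ]
  rownames(vdf) <- NULL
  variants <- phasedVariants(vdf$chrom, vdf$pos, vdf$ref, vdf$alt, vdf$gt)

  # per-site copy-number context: hap1-allele copy number is the major or
  # minor count at random; genomic allele-1 fraction follows purity
  nV <- nrow(vdf)
  segIdx <- vapply(seq_len(nV), function(i)
    which(segs$chrom == vdf$chrom[i] & segs$start < vdf$pos[i] &
          vdf$pos[i] <= segs$end)[1], 0L)
  nMaj <- segs$nMajor[segIdx]; nMin <- segs$nMinor[segIdx]
  hap1Major <- stats::runif(nV) < 0.5
  cn1 <- ifelse(hap1Major, nMaj, nMin)
  nTot <- nMaj + nMin
  rho <- config$purity
  baf1 <- (rho * cn1 + (1 - rho)) / (rho * nTot + 2 * (1 - rho))
  wgsA <- stats::rbinom(nV, config$wgsDepth, baf1)

  inPeak <- !is.na(vdf$peak_id)
  trueRatio <- ifelse(vdf$planted,
                      ifelse(vdf$pref_hap1, config$trueImbalanceRatio,
                             1 - config$trueImbalanceRatio),
                      baf1)
  mkCounts <- function(depth, assay) {
    idx <- which(inPeak)
    h1 <- rBetaBinomMu(length(idx), depth, trueRatio[idx],
                       config$overdispersion)
    data.frame(chrom = vdf$chrom[idx], pos = vdf$pos[idx],
               ref = vdf$ref[idx], alt = vdf$alt[idx], gt = vdf$gt[idx],
               assay = assay, hap1_count = h1, hap2_count = depth - h1,
               wgs_a = wgsA[idx],
               wgs_b = config$wgsDepth - wgsA[idx],
               peak_id = vdf$peak_id[idx])
  }
  atacCounts <- mkCounts(config$atacDepth, "ATAC")
  rnaCounts <- mkCounts(config$rnaDepth, "RNA")

  vafTrue <- rho * cn1 / (rho * nTot + 2 * (1 - rho))
  timeable <- (nMin == 0 & nMaj >= 2) | nMin >= 2
  truth <- data.frame(chrom = vdf$chrom, pos = vdf$pos,
    peak_id = vdf$peak_id, planted = vdf$planted,
    pref_hap1 = vdf$pref_hap1, true_ratio = trueRatio,
    cn_hap1 = cn1, nMajor = nMaj, nMinor = nMin,
    vaf_hap1 = vafTrue, mcn_true = cn1,
    timing_true = ifelse(!timeable, "na",
                  ifelse(cn1 >= 2, "early", ifelse(cn1 == 1, "late", "na"))))
  out <- list(reference = reference, variants = variants, peaks = peaks,
              segments = segs, atacCounts = atacCounts,
              rnaCounts = rnaCounts, truth = truth, config = config)
  if (!is.null(outDir)) writeSimBundle(out, outDir)
  out
}

# write the bundle as plain-text files
writeSimBundle <- function(sim, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$reference,
                              file.path(outDir, "reference.fa"))
  writePhasedVcf(sim$variants, file.path(outDir, "phased.vcf"),
                 contigLengths = stats::setNames(
                   Biostrings::width(sim$reference), names(sim$reference)))
  rtracklayer::export(sim$peaks, file.path(outDir, "peaks.bed"))
  utils::write.table(sim$segments, file.path(outDir, "cn_segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$atacCounts, file.path(outDir, "atac_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$rnaCounts, file.path(outDir, "rna_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(outDir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outDir)
}

#' Write a phased-variant GRanges as a minimal VCF 4.2 file
#'
#' @param variants Phased-variant \code{GRanges}.
#' @param file Output path.
#' @param sampleName Sample column name.
#' @param contigLengths Optional named lengths for contig header lines.
#' @return Invisibly, \code{file}.
#' @export
writePhasedVcf <- function(variants, file, sampleName = "SIM",
                           contigLengths = NULL) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(contigLengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(contigLengths), contigLengths), con)
  writeLines(paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">"), con)
  writeLines(paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\t",
                    "FORMAT\t", sampleName), con)
  mc <- S4Vectors::mcols(variants)
  if (length(variants))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%d|%d",
      as.character(GenomicRanges::seqnames(variants)),
      GenomicRanges::start(variants), mc$ref, mc$alt, mc$gt1, mc$gt2), con)
  invisible(file)
}

#' Simulate haplotype-resolved reads with exact alignment metrics
#'
#' Samples reads around each peak from haplotype 1 or 2 at the
#' truth-specified ratio, applies sequencing errors, and computes the
#' alignment-metrics pair for both haplotypes by exact comparison: the
#' mismatch count against each haplotype is the true Hamming distance of
#' the read to that haplotype's sequence at the lifted position. No
#' alignment is performed, so read-level fixtures use SNV-only genomes.
#'
#' @param dg A \code{\link{DiploidGenome}}.
#' @param peaks \code{GRanges} of peaks (reference coordinates).
#' @param peakRatio Per-peak probability that a read originates from
#'   haplotype 1; recycled.
#' @param readsPerPeak Reads sampled per peak.
#' @param readLength Read length.
#' @param errorRate Per-base sequencing error probability.
#' @param seed Integer seed.
#' @return List: \code{hap1}, \code{hap2} (alignment-metrics data.frames),
#'   \code{reads} (\code{read_id}, \code{chrom}, \code{start0},
#'   \code{seq}), \code{truth} (\code{read_id}, \code{true_hap}).
#' @export
simulateReads <- function(dg, peaks, peakRatio = 0.5, readsPerPeak = 60L,
                          readLength = 50L, errorRate = 0, seed = 1L) {
  withr::local_seed(seed)
  ratio <- rep_len(peakRatio, length(peaks))
  rows <- list(); k <- 0L
  for (i in seq_along(peaks)) {
    ch <- as.character(GenomicRanges::seqnames(peaks))[i]
    lo <- GenomicRanges::start(peaks)[i] - 1L          # 0-based peak start
    hi <- GenomicRanges::end(peaks)[i]
    starts <- sample(max(0L, lo - readLength + 1L):(hi - 1L),
                     readsPerPeak, replace = TRUE)
    hap <- ifelse(stats::runif(readsPerPeak) < ratio[i], 1L, 2L)
    for (j in seq_len(readsPerPeak)) {
      k <- k + 1L
      hg <- if (hap[j] == 1L) dg@hap1 else dg@hap2
      other <- if (hap[j] == 1L) dg@hap2 else dg@hap1
      s0 <- liftPosition(hg@map, ch, starts[j], "ref2hap")
      if (is.na(s0) || s0 + readLength > hg@map@hapLengths[[ch]]) next
      own <- as.character(Biostrings::subseq(hg@sequences[[ch]],
                                             start = s0 + 1L,
                                             width = readLength))
      if (errorRate > 0) {
        nerr <- stats::rbinom(1, readLength, errorRate)
        if (nerr > 0) {
          at <- sample.int(readLength, nerr)
          for (a in at) {
            substr(own, a, a) <- sample(setdiff(BASES,
              substr(own, a, a)), 1)
          }
        }
      }
      mmOwn <- sum(strsplit(own, "")[[1]] !=
        strsplit(as.character(Biostrings::subseq(hg@sequences[[ch]],
          start = s0 + 1L, width = readLength)), "")[[1]])
      oS0 <- liftPosition(other@map, ch, starts[j], "ref2hap")
      mmOther <- NA_integer_
      if (!is.na(oS0) && oS0 + readLength <= other@map@hapLengths[[ch]]) {
        oSeq <- as.character(Biostrings::subseq(other@sequences[[ch]],
                                                start = oS0 + 1L,
                                                width = readLength))
        mmOther <- sum(strsplit(own, "")[[1]] != strsplit(oSeq, "")[[1]])
      }
      rows[[k]] <- data.frame(read_id = paste0("r", k), true_hap = hap[j],
        chrom = ch, start0 = s0, other_start0 = oS0, seq = own,
        mm_own = mmOwn, mm_other = mmOther)
    }
  }
  rr <- do.call(rbind, rows)
  mk <- function(isHap1) {
    own <- rr$true_hap == ifelse(isHap1, 1L, 2L)
    pos <- ifelse(own, rr$start0, rr$other_start0)
    mm <- ifelse(own, rr$mm_own, rr$mm_other)
    df <- data.frame(read_id = rr$read_id, mapq = 42L,
                     matched_bases = readLength, mismatches = mm,
                     chrom = rr$chrom, pos = pos, is_dup = FALSE)
    df[!is.na(df$pos) & !is.na(df$mismatches), ]
  }
  list(hap1 = mk(TRUE), hap2 = mk(FALSE),
       reads = data.frame(read_id = rr$read_id, chrom = rr$chrom,
                          start0 = rr$start0, seq = rr$seq,
                          true_hap = rr$true_hap),
       truth = data.frame(read_id = rr$read_id, true_hap = rr$true_hap))
}
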