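# a small config that keeps the full bundle fast to generate
smallConfig <- function(seed = 1L, ...) {
  simConfig(seed = seed, nChroms = 2L, chromLength = 60000L,
            hetSnvRate = 0.001, nPeaks = 40L, ...)
}

test_that("identical config and seed give byte-identical file bundles", {
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  unlink(c(d1, d2), recursive = TRUE)
  simulateDataset(smallConfig(7L), d1)
  simulateDataset(smallConfig(7L), d2)
  f1 <- list.files(d1, full.names = TRUE)
  expect_gte(length(f1), 6L)
  h1 <- tools::md5sum(f1)
  h2 <- tools::md5sum(list.files(d2, full.names = TRUE))
  expect_identical(unname(h1), unname(h2))
  # a different seed changes the bundle
  d3 <- file.path(tempdir(), "simC")
  simulateDataset(smallConfig(8L), d3)
  h3 <- tools::md5sum(list.files(d3, full.names = TRUE))
  expect_false(all(unname(h1) == unname(h3)))
})

test_that("emitted structures satisfy the generator's own contracts", {
  sim <- simulateDataset(smallConfig(3L))
  # every planted (ground-truth imbalanced) site lies inside a peak
  planted <- sim$truth[sim$truth$planted, ]
  expect_gt(nrow(planted), 0)
  expect_true(all(!is.na(planted$peak_id)))
  gr <- GenomicRanges::GRanges(planted$chrom,
                               IRanges::IRanges(planted$pos, width = 1))
  expect_true(all(IRanges::overlapsAny(gr, sim$peaks)))
  # peaks are non-overlapping and of the configured width
  expect_equal(sum(IRanges::countOverlaps(sim$peaks, sim$peaks)),
               length(sim$peaks))
  expect_true(all(GenomicRanges::width(sim$peaks) == 501L))
  # counts and depths
  expect_true(all(sim$atacCounts$hap1_count + sim$atacCounts$hap2_count ==
                  sim$config$atacDepth))
  # the variants pass ref-allele validation against the emitted reference
  dg <- buildHaplotypes(sim$reference, sim$variants)
  expect_s4_class(dg, "DiploidGenome")
  # segment annotation in the truth table is internally consistent
  expect_true(all(sim$truth$nMajor >= sim$truth$nMinor))
  expect_true(all(sim$truth$cn_hap1 %in%
    c(sim$truth$nMajor, sim$truth$nMinor)))
})

test_that("WGS counts track the copy-number-determined allele fraction", {
  cfg <- simConfig(seed = 11L, nChroms = 2L, chromLength = 100000L,
                   hetSnvRate = 0.004, nPeaks = 60L, wgsDepth = 40L)
  sim <- simulateDataset(cfg)
  tr <- sim$truth
  idx <- match(paste(sim$atacCounts$chrom, sim$atacCounts$pos),
               paste(tr$chrom, tr$pos))
  # aggregate BAF error per copy-number state at >= 200 aggregate depth
  key <- paste(tr$nMajor[idx], tr$nMinor[idx], tr$cn_hap1[idx])
  for (k in unique(key)) {
    i <- which(key == k)
    depth <- 40L * length(i)
    if (depth < 200) next
    expBaf <- tr$cn_hap1[idx][i][1] /
      (tr$nMajor[idx][i][1] + tr$nMinor[idx][i][1])
    obsBaf <- sum(sim$atacCounts$wgs_a[i]) / depth
    expect_lt(abs(obsBaf - expBaf), 0.05)
  }
})

test_that("planted motif gains reproduce the expected delta arithmetic", {
  lom <- toyLogOdds("ACGTAC")
  pwm <- toyPwm("ACGTAC", "toy", match = 0.9)
  peakSeq <- paste(rep("T", 30), collapse = "")
  res <- plantMotifGain(peakSeq, pwm, motifStart = 10L, disruptPos = 3L,
                        gainHap = 1L)
  expect_equal(substr(res$hap1_seq, 10, 15), "ACGTAC")
  expect_equal(substr(res$hap2_seq, 10, 15),
               paste0("AC", res$variant$disrupt_base, "TAC"))
  # with the +-1 toy matrix the planted variant scores 6 vs 4: delta 2
  d <- deltaMotifScore(res$hap1_seq, res$hap2_seq, lom)
  expect_equal(d$delta, 2)
  # planting on hap2 flips the preferred allele
  res2 <- plantMotifGain(peakSeq, pwm, motifStart = 10L, disruptPos = 3L,
                         gainHap = 2L)
  expect_equal(res2$hap2_seq, res$hap1_seq)
  # a disruption clear of the motif leaves the delta at 0
  untouched <- res$hap1_seq
  other <- untouched; substr(other, 25, 25) <- "A"
  expect_equal(deltaMotifScore(untouched, other, lom)$delta, 0)
  expect_error(plantMotifGain("ACG", pwm), "fit")
})

test_that("simulated reads carry exact per-haplotype mismatch metrics", {
  ref <- randomReference(c(chr1 = 2000L), seed = 17)
  p <- 1000L
  refA <- substr(as.character(ref[[1]]), p, p)
  altA <- setdiff(c("A", "C", "G", "T"), refA)[1]
  dg <- buildHaplotypes(ref, phasedVariants("chr1", p, refA, altA, "1|0"))
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(p - 100L, p + 100L))
  S4Vectors::mcols(peaks)$score <- 1
  sim <- simulateReads(dg, peaks, peakRatio = 0.5, readsPerPeak = 200L,
                       readLength = 40L, errorRate = 0, seed = 2)
  m <- merge(sim$hap1, sim$hap2, by = "read_id", suffixes = c(".1", ".2"))
  m <- merge(m, sim$truth, by = "read_id")
  spans <- m$pos.1 <= (p - 1) & (p - 1) < m$pos.1 + 40
  # error-free: mismatches are (0,1) or (1,0) by true origin at the SNV
  expect_true(all(m$mismatches.1[spans & m$true_hap == 1] == 0))
  expect_true(all(m$mismatches.2[spans & m$true_hap == 1] == 1))
  expect_true(all(m$mismatches.1[spans & m$true_hap == 2] == 1))
  # reads clear of the variant are metric-identical on both haplotypes
  expect_true(all(m$mismatches.1[!spans] == m$mismatches.2[!spans]))
})

test_that("exclusive-read ratios recover the planted sampling ratio", {
  ref <- randomReference(c(chr1 = 2000L), seed = 19)
  p <- 1000L
  refA <- substr(as.character(ref[[1]]), p, p)
  altA <- setdiff(c("A", "C", "G", "T"), refA)[1]
  dg <- buildHaplotypes(ref, phasedVariants("chr1", p, refA, altA, "1|0"))
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(p - 30L, p + 30L))
  S4Vectors::mcols(peaks)$score <- 1
  sim <- simulateReads(dg, peaks, peakRatio = 0.8, readsPerPeak = 3000L,
                       readLength = 40L, errorRate = 0, seed = 4)
  asg <- assignReads(sim$hap1, sim$hap2, dedupeByLocus = FALSE)
  n1 <- sum(asg$assignments$label == "HAP1_EXCLUSIVE")
  n2 <- sum(asg$assignments$label == "HAP2_EXCLUSIVE")
  n <- n1 + n2
  expect_gt(n, 200)
  lo <- qbinom(0.005, n, 0.8); hi <- qbinom(0.995, n, 0.8)
  expect_gte(n1, lo); expect_lte(n1, hi)
})

test_that("counts-level generator is deterministic and respects its knobs", {
  a <- simulateAlleleCounts(200, seed = 5)
  b <- simulateAlleleCounts(200, seed = 5)
  expect_identical(a, b)
  c2 <- simulateAlleleCounts(200, plantedFraction = 0.3, seed = 5)
  expect_equal(sum(c2$truth$planted), 60L)
  expect_true(all(c2$records$hap1_count + c2$records$hap2_count == 30L))
  # planted sites are imbalanced in expectation
  pr <- c2$records$hap1_count / 30
  expect_gt(mean(abs(pr[c2$truth$planted] - 0.5)),
            mean(abs(pr[!c2$truth$planted] - 0.5)))
})
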