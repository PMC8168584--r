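test_that("single substitutions, indel bookkeeping and the identity case", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))

  dg <- buildHaplotypes(ref, phasedVariants("chr1", 3, "G", "T", "1|0"))
  expect_equal(unname(as.character(hapSequences(dg, 1))), "ACTTACGT")
  expect_equal(unname(as.character(hapSequences(dg, 2))), "ACGTACGT")

  dg2 <- buildHaplotypes(ref, phasedVariants("chr1", 4, "T", "TAA", "0|1"))
  expect_equal(unname(Biostrings::width(hapSequences(dg2, 1))), 8L)
  expect_equal(unname(Biostrings::width(hapSequences(dg2, 2))), 10L)
  expect_equal(unname(as.character(hapSequences(dg2, 2))), "ACGTAAACGT")

  dg3 <- buildHaplotypes(ref, phasedVariants(character(0), integer(0),
                                             character(0), character(0),
                                             character(0)))
  expect_equal(as.character(hapSequences(dg3, 1)), as.character(ref))
  expect_equal(liftPosition(coordinateMap(dg3, 1), "chr1", 0:7, "ref2hap"),
               0:7)
})

test_that("invalid variants are rejected with the offending site named", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
  expect_error(buildHaplotypes(ref, phasedVariants("chr1", 3, "A", "T",
                                                   "1|0")),
               "mismatch.*chr1:3")
  expect_error(buildHaplotypes(ref, phasedVariants("chr1", 3, "GT", "CA",
                                                   "1|0")),
               "multi-nucleotide")
  v <- phasedVariants(c("chr1", "chr1"), c(3, 4), c("GTA", "T"),
                      c("G", "A"), c("1|0", "1|0"))
  expect_error(buildHaplotypes(ref, v), "overlapping")
  expect_error(buildHaplotypes(ref, phasedVariants("chr2", 1, "A", "C",
                                                   "1|0")),
               "absent")
  expect_error(phasedVariants("chr1", 3, "G", "T", "1/0"), "phased")
})

test_that("liftPosition handles identity, insertion offsets and unmapped bases", {
  ref <- randomReference(c(chr1 = 40L), seed = 11)
  idm <- coordinateMap(buildHaplotypes(ref,
    phasedVariants(character(0), integer(0), character(0), character(0),
                   character(0))), 1)
  expect_equal(liftPosition(idm, "chr1", 17L, "ref2hap"), 17L)
  expect_error(liftPosition(idm, "chrX", 1L, "ref2hap"), "unknown")

  # 2-bp insertion anchored at ref offset 4 (1-based pos 5)
  rb <- substr(as.character(ref[[1]]), 5, 5)
  dg <- buildHaplotypes(ref, phasedVariants("chr1", 5, rb,
                                            paste0(rb, "AA"), "0|1"))
  m2 <- coordinateMap(dg, 2)
  expect_equal(liftPosition(m2, "chr1", 10L, "ref2hap"), 12L)
  # haplotype positions 5 and 6 are the inserted bases
  expect_true(is.na(liftPosition(m2, "chr1", 5L, "hap2ref")))
  expect_equal(liftPosition(m2, "chr1", 7L, "hap2ref"), 5L)
})

test_that("round-trip liftover and allele re-extraction over random genomes", {
  ref <- randomReference(c(chr1 = 5000L, chr2 = 3000L), seed = 42)
  withr::local_seed(7)
  mkVars <- function(ch, L) {
    pos <- sort(sample(seq(10, L - 10, by = 25), 60))
    refA <- vapply(pos, function(p) substr(as.character(ref[[ch]]), p, p),
                   "")
    type <- sample(c("snv", "ins", "del"), length(pos), replace = TRUE,
                   prob = c(0.7, 0.15, 0.15))
    alt <- refA
    for (i in seq_along(pos)) {
      if (type[i] == "snv")
        alt[i] <- sample(setdiff(c("A", "C", "G", "T"), refA[i]), 1)
      if (type[i] == "ins")
        alt[i] <- paste0(refA[i],
          paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                       replace = TRUE), collapse = ""))
      if (type[i] == "del") {
        w <- sample(1:3, 1)
        refA[i] <- substr(as.character(ref[[ch]]), pos[i], pos[i] + w)
        alt[i] <- substr(refA[i], 1, 1)
      }
    }
    data.frame(chrom = ch, pos = pos, ref = refA, alt = alt,
               gt = sample(c("1|0", "0|1", "1|1"), length(pos),
                           replace = TRUE))
  }
  vd <- rbind(mkVars("chr1", 5000L), mkVars("chr2", 3000L))
  v <- phasedVariants(vd$chrom, vd$pos, vd$ref, vd$alt, vd$gt)
  dg <- buildHaplotypes(ref, v)

  # length conservation per haplotype/chromosome (vd rows parallel v)
  for (h in 1:2) {
    m <- coordinateMap(dg, h)
    applied_h <- S4Vectors::mcols(v)[[paste0("gt", h)]] == 1L
    for (ch in c("chr1", "chr2")) {
      applied <- vd[vd$chrom == ch & applied_h, ]
      expLen <- Biostrings::width(ref)[match(ch, names(ref))] +
        sum(nchar(applied$alt) - nchar(applied$ref))
      expect_equal(unname(m@hapLengths[[ch]]), expLen)
    }
  }

  # round trip ref -> hap -> ref for 1000 random positions outside
  # deletion footprints
  for (h in 1:2) {
    m <- coordinateMap(dg, h)
    for (ch in c("chr1", "chr2")) {
      L <- Biostrings::width(ref)[match(ch, names(ref))]
      pos <- sample(0:(L - 1), 500, replace = TRUE)
      hp <- liftPosition(m, ch, pos, "ref2hap")
      ok <- !is.na(hp)
      back <- liftPosition(m, ch, hp[ok], "hap2ref")
      expect_equal(back, pos[ok])
    }
  }

  # re-extracting alleles at lifted positions reproduces the genotype
  mc <- S4Vectors::mcols(v)
  for (i in seq_along(v)) {
    ch <- as.character(GenomicRanges::seqnames(v))[i]
    p0 <- GenomicRanges::start(v)[i] - 1L
    for (h in 1:2) {
      hg <- if (h == 1) dg@hap1 else dg@hap2
      hp <- liftPosition(hg@map, ch, p0, "ref2hap")
      allele <- if (S4Vectors::mcols(v)[[paste0("gt", h)]][i] == 1L)
        mc$alt[i] else mc$ref[i]
      got <- as.character(Biostrings::subseq(hg@sequences[[ch]],
                                             start = hp + 1L,
                                             width = nchar(allele)))
      expect_equal(got, allele)
    }
  }
})

test_that("chain and block-table serialization round-trips block content", {
  ref <- randomReference(c(chr1 = 200L), seed = 3)
  rb <- substr(as.character(ref[[1]]), 50, 50)
  dg <- buildHaplotypes(ref, phasedVariants("chr1", 50, rb,
                                            paste0(rb, "TT"), "1|0"))
  m <- coordinateMap(dg, 1)
  tf <- tempfile(fileext = ".tsv")
  writeBlockTable(m, tf)
  back <- read.table(tf, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  expect_equal(back$ref_start, m@blocks$ref_start)
  expect_equal(back$hap_start, m@blocks$hap_start)
  expect_equal(back$length, m@blocks$length)

  cf <- tempfile(fileext = ".chain")
  writeChain(m, cf)
  lines <- readLines(cf)
  expect_match(lines[1], "^chain ")
  # chain alignment lines: first block length 50, gap dt=0 dq=2
  expect_equal(lines[2], "50 0 2")
  expect_equal(lines[3], "150")
})

test_that("VCF round trip through readPhasedVcf preserves phased sites", {
  v <- phasedVariants(c("chr1", "chr1", "chr2"), c(5, 20, 7),
                      c("A", "C", "G"), c("T", "CAT", "A"),
                      c("1|0", "0|1", "1|1"))
  tf <- tempfile(fileext = ".vcf")
  writePhasedVcf(v, tf, contigLengths = c(chr1 = 100L, chr2 = 50L))
  back <- readPhasedVcf(tf)
  expect_equal(length(back), 3L)
  expect_equal(S4Vectors::mcols(back)$ref, S4Vectors::mcols(v)$ref)
  expect_equal(S4Vectors::mcols(back)$alt, S4Vectors::mcols(v)$alt)
  expect_equal(S4Vectors::mcols(back)$gt1, S4Vectors::mcols(v)$gt1)
  expect_equal(S4Vectors::mcols(back)$het, c(TRUE, TRUE, FALSE))
})
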