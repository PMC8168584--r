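mkWindow <- function(L, seed = 1) {
  withr::local_seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

test_that("the scan covers exactly 3L mutants and reconstructs each mutant", {
  L <- 40L
  scorer <- functionScorer(function(s) matrix(0.5, length(s), 2), 2,
                           window = L)
  seq <- mkWindow(L, 3)
  res <- saturationMutagenesis(seq, scorer, "w1")
  long <- satMutToLong(res)
  expect_equal(nrow(long), 3L * L * 2L)
  expect_equal(nrow(unique(long[, c("pos", "base")])), 3L * L)
  # applying any recorded (pos, base) to the reference reproduces a valid
  # mutant differing from the reference at exactly that position
  for (i in sample(nrow(long), 20)) {
    mut <- seq
    substr(mut, long$pos[i], long$pos[i]) <- long$base[i]
    expect_equal(sum(strsplit(mut, "")[[1]] != strsplit(seq, "")[[1]]), 1L)
  }
  # constant scorer: all deltas are zero
  expect_true(all(long$delta == 0))
  # reference-base entries of the array are zero by construction
  refIdx <- cbind(seq_len(L),
                  match(strsplit(seq, "")[[1]], c("A", "C", "G", "T")), 1L)
  expect_true(all(res@delta[refIdx] == 0))
  expect_error(saturationMutagenesis(mkWindow(30), scorer), "length")
})

test_that("a consensus-completing mutation carries the maximal positive delta", {
  L <- 60L
  pwm <- toyPwm("ACGTACG", "planted", match = 0.9)
  scorer <- pwmReferenceScorer(list(pwm), slope = 1, offset = -2,
                               window = L)
  seq <- mkWindow(L, 8)
  # plant a one-mismatch version of the consensus at position 20
  site <- "ACGAACG"   # position 4 broken (T -> A)
  substr(seq, 20, 26) <- site
  res <- saturationMutagenesis(seq, scorer)
  long <- satMutToLong(res)
  best <- long[which.max(long$delta), ]
  expect_equal(best$pos, 23L)
  expect_equal(best$base, "T")
  expect_gt(best$delta, 0)
})

test_that("batch and one-by-one scoring paths are identical", {
  L <- 30L
  pwm <- toyPwm("GATTACA", "m")
  scorer <- pwmReferenceScorer(list(pwm, toyPwm("CCCGGG", "m2")),
                               window = L)
  seqs <- vapply(1:5, function(i) mkWindow(L, i), "")
  batch <- scoreSequences(scorer, seqs)
  single <- t(vapply(seqs, function(s) drop(scoreSequences(scorer, s)),
                     numeric(2)))
  expect_equal(unname(batch), unname(single), tolerance = 1e-14)
})

test_that("variant deltas are antisymmetric and match logistic arithmetic", {
  L <- 50L
  pwm <- toyPwm("ACGTAC", "m", match = 0.9)
  scorer <- pwmReferenceScorer(list(pwm), slope = 1, offset = -2,
                               window = L)
  seq <- mkWindow(L, 12)
  substr(seq, 10, 15) <- "ACGAAC"  # broken consensus, fixed by pos 13 T
  dAB <- variantDelta(seq, 13L, "T", "A", scorer)
  dBA <- variantDelta(seq, 13L, "A", "T", scorer)
  expect_equal(unname(dAB), -unname(dBA))
  expect_equal(unname(variantDelta(seq, 13L, "A", "A", scorer)), 0)
  # exact logistic arithmetic from best-site scores
  sA <- seq; substr(sA, 13, 13) <- "T"
  sB <- seq; substr(sB, 13, 13) <- "A"
  want <- plogis(bestSiteScore(sA, pwm) - 2) -
          plogis(bestSiteScore(sB, pwm) - 2)
  expect_equal(unname(dAB), want, tolerance = 1e-12)
  expect_error(variantDelta(seq, 51L, "A", "C", scorer), "outside")
})

test_that("the PWM reference scorer is a calibrated logistic of the best site", {
  lomPwm <- toyPwm("ACGT", "m")
  sc <- pwmReferenceScorer(list(lomPwm), slope = 1, offset = -2,
                           window = 12L)
  s <- "AAAAACGTAAAA"
  best <- bestSiteScore(s, lomPwm)
  expect_equal(unname(drop(scoreSequences(sc, s))), plogis(best - 2),
               tolerance = 1e-12)
  # logistic(2) ~ 0.8808 when the best site scores 4
  expect_equal(plogis(4 * 1 - 2), 0.880797, tolerance = 1e-6)
  # monotonicity: improving the best site never decreases the class score
  weaker <- "AAAAACGAAAAA"
  expect_lt(drop(scoreSequences(sc, weaker)), drop(scoreSequences(sc, s)))
})

test_that("haplotype windows are re-extracted around the lifted summit", {
  ref <- randomReference(c(chr1 = 800L), seed = 31)
  rb <- substr(as.character(ref[[1]]), 300, 300)
  dg <- buildHaplotypes(ref, phasedVariants("chr1", 300, rb,
    paste0(rb, "TTTT"), "1|0"))
  w <- extractAlleleWindows(dg, "chr1", 400L, window = 100L)
  expect_equal(nchar(w[["hap1"]]), 100L)
  expect_equal(nchar(w[["hap2"]]), 100L)
  # hap2 window equals the reference window (no variant applied)
  expect_equal(w[["hap2"]],
    substr(as.character(ref[[1]]), 400 - 50 + 1, 400 + 50))
  # windows off the chromosome end are NA
  expect_true(is.na(extractAlleleWindows(dg, "chr1", 790L,
                                         window = 100L)[["hap2"]]))
})

test_that("explainedByModel flags detections and respects class subsets", {
  ev <- cbind(c(0, 0.4, 0.6), c(0, 0.01, 0.02))
  ct <- matrix(abs(rnorm(600, 0, 0.01)), ncol = 2)
  res <- explainedByModel(ev, ct, fpr = 0.05, detectionThreshold = 0.05)
  expect_equal(res$explained, c(FALSE, TRUE, TRUE))
  expect_equal(res$detected, c(FALSE, TRUE, TRUE))
  expect_equal(res$fraction, 2 / 3)
  # all-zero event deltas: nothing explained
  res0 <- explainedByModel(matrix(0, 3, 2), ct)
  expect_equal(res0$fraction, 0)
  # max-over-classes never explains less than a single separating class
  r1 <- explainedByModel(ev, ct, classSubset = 1)
  expect_gte(res$fraction, r1$fraction)
  expect_error(explainedByModel(ev, ct, classSubset = integer(0)),
               "nonempty")
})

test_that("an external command scorer honors the file contract", {
  script <- tempfile(fileext = ".R")
  writeLines(c(
    'a <- commandArgs(TRUE)',
    'x <- read.table(a[1], header = TRUE, sep = "\t",',
    '                stringsAsFactors = FALSE)',
    'gc <- vapply(strsplit(x$seq, ""), function(b)',
    '  mean(b %in% c("G", "C")), 0)',
    'write.table(data.frame(seq_id = x$seq_id, class_0 = gc),',
    '            a[2], sep = "\t", quote = FALSE, row.names = FALSE)'),
    script)
  sc <- commandScorer(paste(shQuote(file.path(R.home("bin"), "Rscript")),
                            shQuote(script)), 1, window = 20L)
  seqs <- c("GGGGGGGGGGCCCCCCCCCC", "ATATATATATATATATATAT")
  got <- scoreSequences(sc, seqs)
  expect_equal(unname(got[, 1]), c(1, 0))
})
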