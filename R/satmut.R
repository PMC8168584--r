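#' @rdname nClasses
setMethod("nClasses", "PwmScorer", function(scorer) length(scorer@pwms))

#' @rdname nClasses
setMethod("nClasses", "FunctionScorer", function(scorer) scorer@numClasses)

#' @rdname classNames
setMethod("classNames", "PwmScorer", function(scorer)
  vapply(scorer@pwms, motifId, ""))

#' @rdname classNames
setMethod("classNames", "FunctionScorer", function(scorer)
  scorer@classNames)

#' @rdname scoreSequences
setMethod("scoreSequences", "PwmScorer", function(scorer, seqs) {
  bad <- nchar(seqs) != scorer@windowLength
  if (any(bad))
    stop("sequences must have the scorer's window length (",
         scorer@windowLength, ")")
  out <- vapply(seqs, function(s)
    vapply(scorer@pwms, function(p)
      logistic(scorer@slope * bestSiteScore(s, p) + scorer@offset), 0),
    numeric(length(scorer@pwms)))
  out <- matrix(out, ncol = length(scorer@pwms), byrow = TRUE)
  colnames(out) <- classNames(scorer)
  out
})

#' @rdname scoreSequences
setMethod("scoreSequences", "FunctionScorer", function(scorer, seqs) {
  if (any(nchar(seqs) != scorer@windowLength))
    stop("sequences must have the scorer's window length (",
         scorer@windowLength, ")")
  out <- scorer@fun(seqs)
  out <- matrix(out, nrow = length(seqs))
  colnames(out) <- scorer@classNames
  out
})

setMethod("show", "PwmScorer", function(object) {
  cat("PwmScorer:", length(object@pwms), "class(es), window",
      object@windowLength, "bp, logistic(", object@slope, "* score +",
      object@offset, ")\n")
})

#' PWM-based reference sequence scorer
#'
#' A deterministic multi-class scorer standing in the role of a trained
#' enhancer model: class c scores
#' \code{logistic(slope * bestSiteScore(seq, pwm_c) + offset)}, one class
#' per motif.
#'
#' @param pwms List of \code{\link{PWMotif}}, one per class.
#' @param slope,offset Logistic calibration.
#' @param window Required sequence length, default 500.
#' @return A \code{\link{PwmScorer}}.
#' @export
pwmReferenceScorer <- function(pwms, slope = 1, offset = 0, window = 500L) {
  methods::new("PwmScorer", pwms = pwms, slope = slope, offset = offset,
               windowLength = as.integer(window))
}

#' Wrap a plain function as a SequenceScorer
#'
#' @param fun function(character vector) -> numeric matrix (sequences x
#'   classes) with values in [0, 1].
#' @param numClasses Number of classes returned.
#' @param window Required sequence length.
#' @param classNames Optional class labels.
#' @return A \code{\link{FunctionScorer}}.
#' @export
functionScorer <- function(fun, numClasses, window = 500L,
                           classNames = paste0("class_", seq_len(numClasses) - 1L)) {
  methods::new("FunctionScorer", fun = fun,
               numClasses = as.integer(numClasses),
               classNames = classNames, windowLength = as.integer(window))
}

#' Wrap an external scoring executable as a SequenceScorer
#'
#' File contract: the command is invoked as \code{cmd input.tsv output.tsv};
#' the input TSV has header \code{seq_id seq}; the output TSV must have
#' header \code{seq_id class_0 ... class_k} with one row per input sequence
#' in any order. This lets a trained model running in its own environment
#' plug into the saturation-mutagenesis engine without any framework
#' dependency here.
#'
#' @param cmd Command string (the two file paths are appended).
#' @param numClasses Number of classes the command emits.
#' @param window Required sequence length.
#' @return A \code{\link{FunctionScorer}}.
#' @export
commandScorer <- function(cmd, numClasses, window = 500L) {
  fun <- function(seqs) {
    fin <- tempfile(fileext = ".tsv"); fout <- tempfile(fileext = ".tsv")
    on.exit(unlink(c(fin, fout)))
    ids <- paste0("s", seq_along(seqs))
    utils::write.table(data.frame(seq_id = ids, seq = seqs), fin,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    status <- system(paste(cmd, shQuote(fin), shQuote(fout)))
    if (status != 0) stop("scorer command failed with status ", status)
    out <- utils::read.table(fout, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    m <- as.matrix(out[match(ids, out$seq_id), -1, drop = FALSE])
    if (ncol(m) != numClasses) stop("scorer emitted wrong class count")
    m
  }
  functionScorer(fun, numClasses, window)
}

#' In silico saturation mutagenesis of one sequence
#'
#' Scores the unperturbed window and every one of its 3L single-nucleotide
#' substitutions, recording per-class score differences against the
#' reference. For the standard 500-bp window this is exactly 1,500 mutant
#' sequences.
#'
#' @param seq DNA string of the scorer's window length.
#' @param scorer A \code{\link{SequenceScorer}}.
#' @param seqId Identifier stored in the result.
#' @return A \code{\link{SatMutResult}}; the delta array is positions x 4
#'   bases x classes with zeros at each position's reference base.
#' @export
saturationMutagenesis <- function(seq, scorer, seqId = "seq") {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L != scorer@windowLength)
    stop("sequence length ", L, " != scorer window ", scorer@windowLength)
  refBase <- strsplit(seq, "")[[1]]
  pos <- rep(seq_len(L), each = 3L)
  alt <- unlist(lapply(refBase, function(b) setdiff(BASES, b)))
  mutants <- vapply(seq_along(pos), function(i) {
    s <- seq
    substr(s, pos[i], pos[i]) <- alt[i]
    s
  }, "")
  stopifnot(length(mutants) == 3L * L)
  refScores <- drop(scoreSequences(scorer, seq))
  mutScores <- scoreSequences(scorer, mutants)
  C <- length(refScores)
  delta <- array(0, dim = c(L, 4L, C),
                 dimnames = list(NULL, BASES, names(refScores)))
  for (cidx in seq_len(C)) {
    dmat <- mutScores[, cidx] - refScores[cidx]
    delta[cbind(pos, match(alt, BASES), cidx)] <- dmat
  }
  methods::new("SatMutResult", seqId = seqId, sequence = seq,
               refScores = refScores, delta = delta)
}

#' Long-format export of a saturation-mutagenesis scan
#'
#' @param res A \code{\link{SatMutResult}}.
#' @return data.frame \code{seq_id}, \code{pos} (1-based), \code{base},
#'   \code{class}, \code{delta}; 3L x classes rows (reference-base entries
#'   omitted).
#' @export
satMutToLong <- function(res) {
  L <- dim(res@delta)[1]; C <- dim(res@delta)[3]
  refBase <- strsplit(res@sequence, "")[[1]]
  rows <- expand.grid(pos = seq_len(L), base = BASES,
                      class = seq_len(C), stringsAsFactors = FALSE)
  rows <- rows[rows$base != refBase[rows$pos], ]
  rows$delta <- res@delta[cbind(rows$pos, match(rows$base, BASES),
                                rows$class)]
  cn <- dimnames(res@delta)[[3]] %||% paste0("class_", seq_len(C) - 1L)
  data.frame(seq_id = res@seqId, pos = rows$pos, base = rows$base,
             class = cn[rows$class], delta = rows$delta)
}

setMethod("show", "SatMutResult", function(object) {
  d <- dim(object@delta)
  cat("SatMutResult", object@seqId, "-", d[1], "bp,", 3 * d[1],
      "mutants,", d[3], "class(es)\n")
})

#' Per-class allele delta of one variant inside a scored window
#'
#' Builds the two single-base allele versions of the window and returns the
#' per-class score difference (allele A minus allele B); antisymmetric
#' under allele swap.
#'
#' @param windowSeq DNA string of the scorer's window length (either
#'   allele's backbone; the variant base is overwritten for both alleles).
#' @param posInWindow 1-based variant position within the window.
#' @param alleleA,alleleB Single bases.
#' @param scorer A \code{\link{SequenceScorer}}.
#' @return Named numeric vector of per-class deltas.
#' @export
variantDelta <- function(windowSeq, posInWindow, alleleA, alleleB, scorer) {
  L <- nchar(windowSeq)
  if (posInWindow < 1 || posInWindow > L)
    stop("variant position outside the window")
  stopifnot(nchar(alleleA) == 1, nchar(alleleB) == 1)
  sA <- windowSeq; substr(sA, posInWindow, posInWindow) <- alleleA
  sB <- windowSeq; substr(sB, posInWindow, posInWindow) <- alleleB
  sc <- scoreSequences(scorer, c(sA, sB))
  drop(sc[1, ] - sc[2, ])
}

#' Extract per-haplotype windows around a reference summit
#'
#' Each haplotype's window is re-extracted around the lifted summit so that
#' indels shifting coordinates still yield centered, equal-length windows.
#'
#' @param dg A \code{\link{DiploidGenome}}.
#' @param chrom Chromosome.
#' @param summitRefPos0 0-based reference summit position.
#' @param window Window length, default 500.
#' @return Named character vector \code{c(hap1 = ..., hap2 = ...)}, or
#'   \code{NA} entries where the summit does not lift or the window runs
#'   off the chromosome.
#' @export
extractAlleleWindows <- function(dg, chrom, summitRefPos0, window = 500L) {
  half <- window %/% 2L
  getWin <- function(hg) {
    p <- liftPosition(hg@map, chrom, summitRefPos0, "ref2hap")
    if (is.na(p)) return(NA_character_)
    s0 <- p - half
    if (s0 < 0 || s0 + window > hg@map@hapLengths[[chrom]])
      return(NA_character_)
    as.character(Biostrings::subseq(hg@sequences[[chrom]],
                                    start = s0 + 1L, width = window))
  }
  c(hap1 = getWin(dg@hap1), hap2 = getWin(dg@hap2))
}

#' Explained fraction of events under a model's allele deltas
#'
#' Per-variant score = max over the selected classes of the absolute
#' per-class allele delta; the explained fraction at the target FPR is then
#' computed against the control variants, and variants whose score exceeds
#' the absolute detection threshold are flagged.
#'
#' @param eventDeltas,controlDeltas Numeric matrices, variants x classes
#'   (per-class allele deltas from \code{\link{variantDelta}}).
#' @param classSubset Columns to use (indices or names); default all.
#' @param fpr Target false-positive rate.
#' @param detectionThreshold Absolute delta flag threshold, default 0.05.
#' @return List: \code{threshold}, \code{fraction}, \code{explained}
#'   (logical per event), \code{detected} (logical per event).
#' @export
explainedByModel <- function(eventDeltas, controlDeltas, classSubset = NULL,
                             fpr = 0.05, detectionThreshold = 0.05) {
  eventDeltas <- as.matrix(eventDeltas)
  controlDeltas <- as.matrix(controlDeltas)
  if (!is.null(classSubset) && length(classSubset) == 0)
    stop("class subset must be nonempty")
  if (!is.null(classSubset)) {
    eventDeltas <- eventDeltas[, classSubset, drop = FALSE]
    controlDeltas <- controlDeltas[, classSubset, drop = FALSE]
  }
  ev <- apply(abs(eventDeltas), 1, max)
  ct <- apply(abs(controlDeltas), 1, max)
  ef <- explainedFractionAtFpr(ev, ct, fpr)
  list(threshold = ef$threshold, fraction = ef$fraction,
       explained = ev > ef$threshold, detected = ev > detectionThreshold)
}
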