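#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
NULL

#' CoordinateMap: exact reference <-> haplotype position mapping
#'
#' A set of collinear blocks per chromosome linking reference coordinates to
#' the coordinates of one personalized haplotype sequence. Blocks are 0-based
#' half-open and strictly increasing on both axes; positions between blocks
#' correspond to bases present on only one side (deletion or insertion
#' footprints) and do not lift.
#'
#' @slot blocks data.frame with columns \code{chrom}, \code{ref_start},
#'   \code{hap_start}, \code{length} (0-based half-open block starts).
#' @slot refLengths named integer vector of reference chromosome lengths.
#' @slot hapLengths named integer vector of haplotype chromosome lengths.
#' @export
setClass("CoordinateMap",
  representation(
    blocks = "data.frame",
    refLengths = "integer",
    hapLengths = "integer"
  )
)

setValidity("CoordinateMap", function(object) {
  b <- object@blocks
  need <- c("chrom", "ref_start", "hap_start", "length")
  if (!all(need %in% names(b)))
    return(paste("blocks must have columns", paste(need, collapse = ", ")))
  for (ch in unique(b$chrom)) {
    bb <- b[b$chrom == ch, , drop = FALSE]
    if (is.unsorted(bb$ref_start, strictly = TRUE))
      return(sprintf("blocks on %s not sorted by ref_start", ch))
    if (any(bb$length < 0)) return("negative block length")
    re <- bb$ref_start + bb$length
    he <- bb$hap_start + bb$length
    if (nrow(bb) > 1 &&
        (any(bb$ref_start[-1] < re[-nrow(bb)]) ||
         any(bb$hap_start[-1] < he[-nrow(bb)])))
      return(sprintf("overlapping blocks on %s", ch))
  }
  if (!setequal(names(object@refLengths), names(object@hapLengths)))
    return("refLengths and hapLengths name different chromosomes")
  TRUE
})

#' HaplotypeGenome: one personalized haplotype
#'
#' @slot haplotypeId integer, 1 or 2.
#' @slot sequences \code{DNAStringSet}, one entry per chromosome.
#' @slot map \code{CoordinateMap} linking reference and this haplotype.
#' @slot appliedVariants \code{GRanges} of the variants substituted into this
#'   haplotype (reference coordinates, mcols \code{ref}, \code{alt}).
#' @export
setClass("HaplotypeGenome",
  representation(
    haplotypeId = "integer",
    sequences = "ANY",
    map = "CoordinateMap",
    appliedVariants = "ANY"
  )
)

setValidity("HaplotypeGenome", function(object) {
  if (!object@haplotypeId %in% 1:2) return("haplotypeId must be 1 or 2")
  if (!methods::is(object@sequences, "DNAStringSet"))
    return("sequences must be a DNAStringSet")
  TRUE
})

#' DiploidGenome: a pair of personalized haplotypes plus their source
#'
#' Returned by \code{\link{buildHaplotypes}}. Holds the reference, both
#' haplotype genomes (each with its coordinate map), and the phased variant
#' set that was applied.
#'
#' @slot reference \code{DNAStringSet}.
#' @slot hap1,hap2 \code{HaplotypeGenome}.
#' @slot variants \code{GRanges} with mcols \code{ref}, \code{alt},
#'   \code{gt1}, \code{gt2}, \code{het} (the phased variant table).
#' @export
setClass("DiploidGenome",
  representation(
    reference = "ANY",
    hap1 = "HaplotypeGenome",
    hap2 = "HaplotypeGenome",
    variants = "ANY"
  )
)

#' PWMotif: a position weight matrix over A/C/G/T
#'
#' Probabilities per position; a pseudocount is applied at scoring time, not
#' here, so count matrices normalized on read-in keep their sharpness.
#'
#' @slot motifId character scalar.
#' @slot matrix numeric matrix, positions x 4, columns A,C,G,T, rows sum to 1.
#' @slot background numeric 4-vector of base frequencies, sums to 1.
#' @export
setClass("PWMotif",
  representation(
    motifId = "character",
    matrix = "matrix",
    background = "numeric"
  )
)

setValidity("PWMotif", function(object) {
  m <- object@matrix
  if (ncol(m) != 4 || !identical(colnames(m), c("A", "C", "G", "T")))
    return("matrix must have 4 columns named A,C,G,T")
  if (nrow(m) < 1) return("motif length must be >= 1")
  if (any(m < 0)) return("negative probabilities")
  if (any(abs(rowSums(m) - 1) > 1e-6)) return("rows must sum to 1")
  if (length(object@background) != 4 ||
      abs(sum(object@background) - 1) > 1e-6)
    return("background must be a 4-vector summing to 1")
  TRUE
})

#' SequenceScorer: interface for fixed-window multi-class sequence scorers
#'
#' A scorer maps a DNA sequence of the configured window length to a vector
#' of per-class scores in [0, 1]. The saturation-mutagenesis engine and the
#' allele-delta machinery are written against this interface so a trained
#' model (run out-of-process) and the built-in PWM reference scorer are
#' interchangeable.
#'
#' @slot windowLength integer, required input sequence length.
#' @export
setClass("SequenceScorer",
  representation("VIRTUAL", windowLength = "integer")
)

#' PwmScorer: logistic-calibrated best-motif-site reference scorer
#'
#' Class c score = logistic(slope * bestSiteScore(seq, pwm_c) + offset).
#' Deterministic and closed-form, so engine behaviour is exactly checkable.
#'
#' @slot pwms list of \code{PWMotif}, one per class.
#' @slot slope,offset numeric calibration of the logistic link.
#' @export
setClass("PwmScorer",
  contains = "SequenceScorer",
  representation(pwms = "list", slope = "numeric", offset = "numeric")
)

setValidity("PwmScorer", function(object) {
  if (length(object@pwms) < 1) return("need at least one PWM")
  if (!all(vapply(object@pwms, methods::is, TRUE, "PWMotif")))
    return("pwms must all be PWMotif objects")
  TRUE
})

#' FunctionScorer: wrap an arbitrary scoring function as a SequenceScorer
#'
#' @slot fun function(character vector of sequences) -> numeric matrix
#'   (sequences x classes) with values in [0, 1].
#' @slot numClasses integer.
#' @slot classNames character.
#' @export
setClass("FunctionScorer",
  contains = "SequenceScorer",
  representation(fun = "function", numClasses = "integer",
                 classNames = "character")
)

#' SatMutResult: full single-nucleotide perturbation scan of one sequence
#'
#' @slot seqId character scalar.
#' @slot sequence character scalar, the unperturbed window.
#' @slot refScores numeric per-class scores of the unperturbed window.
#' @slot delta numeric array (position x base x class); entries at the
#'   reference base are 0 by construction, so exactly 3L mutants carry
#'   information for a length-L window.
#' @export
setClass("SatMutResult",
  representation(
    seqId = "character",
    sequence = "character",
    refScores = "numeric",
    delta = "array"
  )
)

setValidity("SatMutResult", function(object) {
  d <- object@delta
  if (length(dim(d)) != 3) return("delta must be a 3-d array")
  if (dim(d)[1] != nchar(object@sequence))
    return("delta position dimension must equal sequence length")
  if (dim(d)[2] != 4) return("delta base dimension must be 4 (A,C,G,T)")
  if (dim(d)[3] != length(object@refScores))
    return("delta class dimension must match refScores")
  TRUE
})
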