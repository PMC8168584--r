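#' Lift a position between reference and haplotype coordinates
#'
#' @param map A \code{\link{CoordinateMap}}.
#' @param chrom Chromosome name.
#' @param pos Integer vector of 0-based positions.
#' @param direction \code{"ref2hap"} or \code{"hap2ref"}.
#' @return Integer vector of mapped 0-based positions; \code{NA} where the
#'   position falls in bases absent from the target sequence (a deletion when
#'   lifting ref to haplotype, an insertion the other way).
#' @export
setGeneric("liftPosition", function(map, chrom, pos,
                                    direction = c("ref2hap", "hap2ref"))
  standardGeneric("liftPosition"))

#' Score sequences with a SequenceScorer
#'
#' @param scorer A \code{\link{SequenceScorer}}.
#' @param seqs Character vector of DNA sequences, each of the scorer's
#'   window length.
#' @return Numeric matrix, sequences x classes, values in [0, 1].
#' @export
setGeneric("scoreSequences", function(scorer, seqs)
  standardGeneric("scoreSequences"))

#' Number of output classes of a scorer
#' @param scorer A \code{\link{SequenceScorer}}.
#' @return Integer.
#' @export
setGeneric("nClasses", function(scorer) standardGeneric("nClasses"))

#' Class names of a scorer
#' @param scorer A \code{\link{SequenceScorer}}.
#' @return Character vector of length \code{nClasses(scorer)}.
#' @export
setGeneric("classNames", function(scorer) standardGeneric("classNames"))

#' Per-chromosome sequences of a haplotype genome
#' @param x A \code{\link{HaplotypeGenome}} or \code{\link{DiploidGenome}}.
#' @param ... Passed to methods (\code{haplotype = 1} or \code{2} for
#'   \code{DiploidGenome}).
#' @return A \code{DNAStringSet}.
#' @export
setGeneric("hapSequences", function(x, ...) standardGeneric("hapSequences"))

#' Coordinate map of a haplotype genome
#' @param x A \code{\link{HaplotypeGenome}} or \code{\link{DiploidGenome}}.
#' @param ... Passed to methods.
#' @return A \code{\link{CoordinateMap}}.
#' @export
setGeneric("coordinateMap", function(x, ...) standardGeneric("coordinateMap"))

#' Motif matrix accessor
#' @param x A \code{\link{PWMotif}}.
#' @return Numeric matrix, positions x 4.
#' @export
setGeneric("motifMatrix", function(x) standardGeneric("motifMatrix"))

#' Motif identifier accessor
#' @param x A \code{\link{PWMotif}}.
#' @return Character scalar.
#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))
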