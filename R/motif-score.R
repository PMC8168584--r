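#' Construct a PWMotif
#'
#' @param motifId Identifier.
#' @param m Numeric matrix of base probabilities or counts, either
#'   positions x 4 or 4 x positions with rows/columns in A,C,G,T order;
#'   counts are normalized per position.
#' @param background Base frequencies, default uniform.
#' @return A \code{\link{PWMotif}}.
#' @export
pwMotif <- function(motifId, m, background = rep(0.25, 4)) {
  if (nrow(m) == 4 && ncol(m) != 4) m <- t(m)
  colnames(m) <- BASES
  m <- m / rowSums(m)
  methods::new("PWMotif", motifId = motifId, matrix = m,
               background = background / sum(background))
}

#' @rdname motifMatrix
setMethod("motifMatrix", "PWMotif", function(x) x@matrix)

#' @rdname motifId
setMethod("motifId", "PWMotif", function(x) x@motifId)

setMethod("show", "PWMotif", function(object) {
  cat("PWMotif", object@motifId, "- length", nrow(object@matrix), "\n")
})

#' Read motif collections from JASPAR or Cluster-Buster text files
#'
#' \code{readJasparMotifs} parses the JASPAR flat format (\code{>ID name}
#' followed by four \code{A [ ... ]}-style rows); \code{readClusterBusterMotifs}
#' parses \code{.cb} files (\code{>ID} followed by one line of four counts
#' per motif position).
#'
#' @param file Path to the motif file.
#' @param background Base frequencies assigned to every motif.
#' @return Named list of \code{\link{PWMotif}}.
#' @export
readJasparMotifs <- function(file, background = rep(0.25, 4)) {
  lines <- readLines(file)
  starts <- grep("^>", lines)
  out <- list()
  for (i in seq_along(starts)) {
    id <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(id, "[ \t]+")[[1]][1]
    rows <- lines[(starts[i] + 1):(starts[i] + 4)]
    counts <- t(vapply(rows, function(l) {
      nums <- regmatches(l, gregexpr("[0-9.eE+-]+", l))[[1]]
      # drop a leading base letter if it was captured as nothing; rows are
      # "A [ 1 2 3 ]" so all matches are numeric
      as.numeric(nums)
    }, numeric(length(regmatches(rows[1],
      gregexpr("[0-9.eE+-]+", rows[1]))[[1]]))))
    out[[id]] <- pwMotif(id, t(counts), background)  # 4 x L -> L x 4
  }
  out
}

#' @rdname readJasparMotifs
#' @export
readClusterBusterMotifs <- function(file, background = rep(0.25, 4)) {
  lines <- trimws(readLines(file))
  lines <- lines[lines != ""]
  starts <- grep("^>", lines)
  bounds <- c(starts, length(lines) + 1L)
  out <- list()
  for (i in seq_along(starts)) {
    id <- sub("^>\\s*", "", lines[starts[i]])
    body <- lines[(starts[i] + 1):(bounds[i + 1] - 1)]
    m <- do.call(rbind, lapply(body, function(l)
      as.numeric(strsplit(l, "[ \t]+")[[1]])))
    if (ncol(m) != 4) stop("malformed .cb matrix for motif ", id)
    out[[id]] <- pwMotif(id, m, background)  # L x 4
  }
  out
}

#' Log-odds matrix of a PWM
#'
#' Adds the pseudocount per cell, renormalizes each position, and returns
#' \code{log2(p / background)}.
#'
#' @param pwm A \code{\link{PWMotif}}.
#' @param pseudocount Per-cell pseudocount, default 0.001.
#' @return Numeric matrix positions x 4.
#' @export
pwmLogOdds <- function(pwm, pseudocount = 1e-3) {
  m <- (pwm@matrix + pseudocount)
  m <- m / rowSums(m)
  log2(sweep(m, 2, pwm@background, "/"))
}

# scan a log-odds matrix over one strand of integer-coded sequence;
# windows containing N (NA codes) score -Inf
scanLogOdds <- function(codes, lom) {
  L <- nrow(lom); n <- length(codes)
  W <- n - L + 1L
  if (W < 1L) stop("sequence shorter than motif")
  idx <- outer(seq_len(W) - 1L, seq_len(L), "+")  # W x L positions
  vals <- matrix(lom[cbind(rep(seq_len(L), each = W),
                           codes[as.vector(idx)])], nrow = W)
  sc <- rowSums(vals)
  sc[is.na(sc)] <- -Inf
  sc
}

#' Best motif-site log-odds score of a sequence
#'
#' Maximum over all windows on both strands of the summed per-position
#' log2(p/background). Windows containing N score \code{-Inf}; a sequence
#' with no valid window returns \code{-Inf}.
#'
#' @param seq DNA string over A/C/G/T/N, at least as long as the motif.
#' @param pwm A \code{\link{PWMotif}}, or a plain numeric positions-x-4
#'   log-odds matrix (columns A,C,G,T) used as-is.
#' @param pseudocount Passed to \code{\link{pwmLogOdds}} when \code{pwm} is
#'   a \code{PWMotif}.
#' @return Numeric scalar.
#' @export
bestSiteScore <- function(seq, pwm, pseudocount = 1e-3) {
  lom <- if (methods::is(pwm, "PWMotif")) pwmLogOdds(pwm, pseudocount)
         else pwm
  fwd <- scanLogOdds(dnaCodes(seq), lom)
  rev <- scanLogOdds(dnaCodes(revcompChar(seq)), lom)
  max(c(fwd, rev))
}

#' Delta motif score between the two allele sequences of a peak
#'
#' The difference in best-site log-odds between the preferred allele
#' (higher assay signal) and the other allele: positive deltas are motif
#' gains on the preferred allele, negative deltas losses. Antisymmetric
#' under allele swap and exactly 0 for identical sequences.
#'
#' @param seqPreferred,seqOther The two allele versions of the peak window.
#' @param pwm A \code{\link{PWMotif}} or log-odds matrix.
#' @param peakId,motifIdOverride Optional identifiers carried through.
#' @param pseudocount Passed to \code{\link{bestSiteScore}}.
#' @return data.frame \code{peak_id}, \code{motif_id},
#'   \code{score_preferred}, \code{score_other}, \code{delta}.
#' @export
deltaMotifScore <- function(seqPreferred, seqOther, pwm, peakId = NA,
                            motifIdOverride = NULL, pseudocount = 1e-3) {
  sp <- bestSiteScore(seqPreferred, pwm, pseudocount)
  so <- bestSiteScore(seqOther, pwm, pseudocount)
  mid <- motifIdOverride %||%
    (if (methods::is(pwm, "PWMotif")) pwm@motifId else NA_character_)
  data.frame(peak_id = peakId, motif_id = mid,
             score_preferred = sp, score_other = so, delta = sp - so)
}
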