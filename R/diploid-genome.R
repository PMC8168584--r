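#' Construct a phased variant table
#'
#' Builds the \code{GRanges} representation of phased variants used
#' throughout the package: one row per site with reference and alternative
#' alleles and the ordered phased genotype. Positions are 1-based (VCF
#' convention); ranges span the reference allele.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based reference positions.
#' @param ref,alt Character vectors of upper-case alleles (A/C/G/T only).
#' @param gt Character vector of phased genotypes, e.g. \code{"1|0"};
#'   the first field is haplotype 1.
#' @return \code{GRanges} with mcols \code{ref}, \code{alt}, \code{gt1},
#'   \code{gt2}, \code{het}.
#' @examples
#' phasedVariants("chr1", 4, "C", "T", "1|0")
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @export
phasedVariants <- function(chrom, pos, ref, alt, gt) {
  stopifnot(length(chrom) == length(pos), length(ref) == length(pos),
            length(alt) == length(pos), length(gt) == length(pos))
  if (length(pos) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      ref = character(0), alt = character(0),
      gt1 = integer(0), gt2 = integer(0), het = logical(0))
    return(gr)
  }
  bad <- grepl("[^ACGT]", ref) | grepl("[^ACGT]", alt)
  if (any(bad))
    stop("alleles must contain only A/C/G/T at: ",
         paste(chrom[bad], pos[bad], sep = ":", collapse = ", "))
  parts <- strsplit(gt, "|", fixed = TRUE)
  if (any(lengths(parts) != 2 | !grepl("^[01]\\|[01]$", gt)))
    stop("genotypes must be phased '0|1'-style pairs")
  gt1 <- as.integer(vapply(parts, `[`, "", 1L))
  gt2 <- as.integer(vapply(parts, `[`, "", 2L))
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start = pos, width = nchar(ref)))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    ref = ref, alt = alt, gt1 = gt1, gt2 = gt2, het = gt1 != gt2)
  gr
}

#' Read phased heterozygous variants from a VCF file
#'
#' Thin wrapper around \code{VariantAnnotation::readVcf} that keeps
#' biallelic SNVs and simple indels with a phased genotype and returns the
#' package's phased-variant \code{GRanges}. Unphased genotypes (with
#' \code{/}) are dropped with a message.
#'
#' @param file Path to a VCF (plain text or bgzipped).
#' @param sample Sample column to use; default the first.
#' @return See \code{\link{phasedVariants}}.
#' @export
readPhasedVcf <- function(file, sample = 1L) {
  vcf <- VariantAnnotation::readVcf(file)
  gts <- VariantAnnotation::geno(vcf)$GT[, sample]
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  keep <- lengths(altl) == 1L & grepl("^[01]\\|[01]$", gts)
  if (any(!keep)) message(sum(!keep), " multi-allelic or unphased records dropped")
  alt <- vapply(as.list(altl[keep]), function(a) as.character(a[[1]]), "")
  phasedVariants(as.character(GenomicRanges::seqnames(rr))[keep],
                 GenomicRanges::start(rr)[keep], ref[keep], alt, gts[keep])
}

# classify a variant: "snv", "ins", "del", or NA for unsupported shapes
variantType <- function(ref, alt) {
  rl <- nchar(ref); al <- nchar(alt)
  ifelse(rl == 1 & al == 1, "snv",
    ifelse(rl == 1 & al > 1, "ins",
      ifelse(rl > 1 & al == 1, "del", NA_character_)))
}

# collinear blocks for one chromosome given applied indels (0-based starts)
# indels: data.frame(start0, ref_len, alt_len) sorted by start0
makeBlocks <- function(refLen, indels) {
  refCur <- 0L; hapCur <- 0L
  rs <- integer(0); hs <- integer(0); ln <- integer(0)
  if (nrow(indels)) {
    for (i in seq_len(nrow(indels))) {
      s <- indels$start0[i]
      bl <- s + 1L - refCur  # collinear through the shared anchor base
      rs <- c(rs, refCur); hs <- c(hs, hapCur); ln <- c(ln, bl)
      refCur <- s + indels$ref_len[i]
      hapCur <- hapCur + bl + (indels$alt_len[i] - 1L)
    }
  }
  if (refLen - refCur > 0L) {
    rs <- c(rs, refCur); hs <- c(hs, hapCur); ln <- c(ln, refLen - refCur)
  }
  data.frame(ref_start = rs, hap_start = hs, length = ln)
}

#' Build personalized haplotype genomes from phased variants
#'
#' Substitutes each haplotype's alleles into the reference and constructs an
#' exact coordinate map per haplotype. Only SNVs and simple indels (one
#' allele of length 1) are accepted; multi-nucleotide substitutions are
#' rejected rather than skipped. Homozygous-alt variants are applied to both
#' haplotypes. Soft-masked reference bases are uppercased on load so allele
#' checks are deterministic.
#'
#' @param reference A \code{DNAStringSet} (or named character vector) of
#'   reference chromosome sequences.
#' @param variants Phased variant \code{GRanges} from
#'   \code{\link{phasedVariants}} / \code{\link{readPhasedVcf}}, sorted by
#'   position within chromosome.
#' @return A \code{\link{DiploidGenome}}.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
#' v <- phasedVariants("chr1", 3, "G", "T", "1|0")
#' dg <- buildHaplotypes(ref, v)
#' as.character(hapSequences(dg, 1)) # "ACTTACGT"
#' @export
buildHaplotypes <- function(reference, variants) {
  if (!methods::is(reference, "DNAStringSet"))
    reference <- Biostrings::DNAStringSet(reference)
  reference <- Biostrings::DNAStringSet(toupper(reference))
  if (is.null(names(reference)))
    stop("reference sequences must be named by chromosome")
  v <- variants
  chrom <- as.character(GenomicRanges::seqnames(v))
  if (length(v) && any(!chrom %in% names(reference)))
    stop("variants on chromosomes absent from the reference: ",
         paste(unique(setdiff(chrom, names(reference))), collapse = ", "))
  ref <- S4Vectors::mcols(v)$ref
  alt <- S4Vectors::mcols(v)$alt
  vt <- variantType(ref, alt)
  if (any(is.na(vt)))
    stop("unsupported (multi-nucleotide/structural) variants at: ",
         paste(chrom[is.na(vt)], GenomicRanges::start(v)[is.na(vt)],
               sep = ":", collapse = ", "))
  # reference-allele consistency
  if (length(v)) {
    obs <- vapply(seq_along(v), function(i) {
      as.character(Biostrings::subseq(reference[[chrom[i]]],
        start = GenomicRanges::start(v)[i], width = nchar(ref[i])))
    }, "")
    bad <- obs != ref
    if (any(bad))
      stop("ref allele mismatch at: ",
           paste0(chrom[bad], ":", GenomicRanges::start(v)[bad],
                  " (vcf ", ref[bad], ", fasta ", obs[bad], ")",
                  collapse = ", "))
  }
  refLens <- stats::setNames(Biostrings::width(reference), names(reference))

  buildOne <- function(hapIdx) {
    gtcol <- if (hapIdx == 1L) "gt1" else "gt2"
    apply_ <- S4Vectors::mcols(v)[[gtcol]] == 1L
    av <- v[apply_]
    avChrom <- chrom[apply_]; avRef <- ref[apply_]; avAlt <- alt[apply_]
    seqs <- reference
    blocks <- NULL
    hapLens <- refLens
    for (ch in names(reference)) {
      sel <- avChrom == ch
      st <- GenomicRanges::start(av)[sel]
      if (any(sel)) {
        o <- order(st)
        st <- st[o]; rA <- avRef[sel][o]; aA <- avAlt[sel][o]
        ends <- st + nchar(rA) - 1L
        if (any(st[-1] <= ends[-length(ends)]))
          stop("overlapping variants on haplotype ", hapIdx, " chrom ", ch,
               " near position ",
               st[which(st[-1] <= ends[-length(ends)])[1] + 1L])
        seqs[[ch]] <- Biostrings::replaceAt(reference[[ch]],
          IRanges::IRanges(start = st, width = nchar(rA)),
          Biostrings::DNAStringSet(aA))
        ind <- nchar(rA) != nchar(aA)
        bl <- makeBlocks(refLens[[ch]],
          data.frame(start0 = st[ind] - 1L,
                     ref_len = nchar(rA)[ind], alt_len = nchar(aA)[ind]))
      } else {
        bl <- makeBlocks(refLens[[ch]],
          data.frame(start0 = integer(0), ref_len = integer(0),
                     alt_len = integer(0)))
      }
      hapLens[[ch]] <- Biostrings::width(seqs)[match(ch, names(seqs))]
      blocks <- rbind(blocks, cbind(chrom = ch, bl))
    }
    map <- methods::new("CoordinateMap", blocks = blocks,
                        refLengths = refLens, hapLengths = hapLens)
    methods::new("HaplotypeGenome", haplotypeId = hapIdx, sequences = seqs,
                 map = map, appliedVariants = av)
  }
  h1 <- buildOne(1L); h2 <- buildOne(2L)
  # length conservation law
  for (hg in list(h1, h2)) {
    av <- hg@appliedVariants
    dl <- tapply(nchar(S4Vectors::mcols(av)$alt) -
                 nchar(S4Vectors::mcols(av)$ref),
                 as.character(GenomicRanges::seqnames(av)), sum)
    for (ch in names(reference)) {
      expLen <- refLens[[ch]] + (if (ch %in% names(dl)) dl[[ch]] else 0L)
      stopifnot(hg@map@hapLengths[[ch]] == expLen)
    }
  }
  methods::new("DiploidGenome", reference = reference,
               hap1 = h1, hap2 = h2, variants = v)
}

#' @rdname liftPosition
setMethod("liftPosition", "CoordinateMap",
  function(map, chrom, pos, direction = c("ref2hap", "hap2ref")) {
    direction <- match.arg(direction)
    if (!chrom %in% names(map@refLengths))
      stop("unknown chromosome: ", chrom)
    b <- map@blocks[map@blocks$chrom == chrom, , drop = FALSE]
    if (direction == "ref2hap") {
      src <- b$ref_start; dst <- b$hap_start
    } else {
      src <- b$hap_start; dst <- b$ref_start
    }
    out <- rep(NA_integer_, length(pos))
    if (nrow(b) == 0) return(out)
    idx <- findInterval(pos, src)
    ok <- idx >= 1 & !is.na(pos)
    okIdx <- which(ok)
    inBlock <- pos[okIdx] < src[idx[okIdx]] + b$length[idx[okIdx]]
    okIdx <- okIdx[inBlock]
    out[okIdx] <- dst[idx[okIdx]] + (pos[okIdx] - src[idx[okIdx]])
    out
  })

#' Write haplotype FASTA files
#'
#' @param dg A \code{\link{DiploidGenome}}.
#' @param prefix Output path prefix; files \code{<prefix>.hap1.fa} and
#'   \code{<prefix>.hap2.fa} are written.
#' @return Invisibly, the two file paths.
#' @export
writeHaplotypeFasta <- function(dg, prefix) {
  p1 <- paste0(prefix, ".hap1.fa"); p2 <- paste0(prefix, ".hap2.fa")
  Biostrings::writeXStringSet(dg@hap1@sequences, p1)
  Biostrings::writeXStringSet(dg@hap2@sequences, p2)
  invisible(c(p1, p2))
}

#' Serialize a CoordinateMap
#'
#' \code{writeChain} emits UCSC chain format (reference as target, haplotype
#' as query); \code{writeBlockTable} emits the simpler TSV block table
#' (\code{chrom ref_start hap_start length}).
#'
#' @param map A \code{\link{CoordinateMap}}.
#' @param file Output path.
#' @return Invisibly, \code{file}.
#' @export
writeChain <- function(map, file) {
  con <- file(file, "w"); on.exit(close(con))
  id <- 0L
  for (ch in names(map@refLengths)) {
    b <- map@blocks[map@blocks$chrom == ch, , drop = FALSE]
    if (nrow(b) == 0) next
    id <- id + 1L
    tStart <- b$ref_start[1]; tEnd <- b$ref_start[nrow(b)] + b$length[nrow(b)]
    qStart <- b$hap_start[1]; qEnd <- b$hap_start[nrow(b)] + b$length[nrow(b)]
    writeLines(sprintf("chain %d %s %d + %d %d %s_hap %d + %d %d %d",
      1000L, ch, map@refLengths[[ch]], tStart, tEnd,
      ch, map@hapLengths[[ch]], qStart, qEnd, id), con)
    if (nrow(b) > 1) {
      dt <- b$ref_start[-1] - (b$ref_start[-nrow(b)] + b$length[-nrow(b)])
      dq <- b$hap_start[-1] - (b$hap_start[-nrow(b)] + b$length[-nrow(b)])
      writeLines(paste(b$length[-nrow(b)], dt, dq), con)
    }
    writeLines(as.character(b$length[nrow(b)]), con)
    writeLines("", con)
  }
  invisible(file)
}

#' @rdname writeChain
#' @export
writeBlockTable <- function(map, file) {
  utils::write.table(map@blocks, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname hapSequences
setMethod("hapSequences", "HaplotypeGenome", function(x, ...) x@sequences)

#' @rdname hapSequences
#' @param haplotype 1 or 2.
setMethod("hapSequences", "DiploidGenome", function(x, haplotype = 1, ...) {
  if (haplotype == 1) x@hap1@sequences else x@hap2@sequences
})

#' @rdname coordinateMap
setMethod("coordinateMap", "HaplotypeGenome", function(x, ...) x@map)

#' @rdname coordinateMap
#' @param haplotype 1 or 2.
setMethod("coordinateMap", "DiploidGenome", function(x, haplotype = 1, ...) {
  if (haplotype == 1) x@hap1@map else x@hap2@map
})

setMethod("show", "DiploidGenome", function(object) {
  cat("DiploidGenome:", length(object@reference), "chromosome(s),",
      length(object@variants), "phased variant(s)\n")
  cat("  het sites:", sum(S4Vectors::mcols(object@variants)$het), "\n")
})

setMethod("show", "CoordinateMap", function(object) {
  cat("CoordinateMap:", length(object@refLengths), "chromosome(s),",
      nrow(object@blocks), "block(s)\n")
})
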