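BASES <- c("A", "C", "G", "T")

# round half away from zero (base round() is banker's rounding)
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

logistic <- function(x) 1 / (1 + exp(-x))

# DNA string -> integer codes 1..4 (A,C,G,T), NA for anything else (N etc.)
dnaCodes <- function(seq) {
  m <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], BASES)
  m
}

revcompChar <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
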