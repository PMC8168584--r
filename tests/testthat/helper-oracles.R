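# Independent oracles and small fixture builders shared across tests.
# These deliberately use different code paths (explicit loops, direct
# formulas) than the package implementations they check.

# +1/-1 toy log-odds matrix for a consensus word: consensus base scores +1,
# every other base -1, at each position
toyLogOdds <- function(consensus) {
  b <- strsplit(consensus, "")[[1]]
  m <- matrix(-1, nrow = length(b), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(b), match(b, c("A", "C", "G", "T")))] <- 1
  m
}

# sharp probability PWM for a consensus word
toyPwm <- function(consensus, id = "toy", match = 0.85) {
  b <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - match) / 3, nrow = length(b), ncol = 4)
  m[cbind(seq_along(b), match(b, c("A", "C", "G", "T")))] <- match
  colnames(m) <- c("A", "C", "G", "T")
  pwMotif(id, m)
}

# brute-force best-site scan: explicit loops over windows and strands
bruteBestSite <- function(seq, lom) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(toupper(seq), "")[[1]]
  rcChars <- rev(unname(comp[chars]))
  L <- nrow(lom)
  best <- -Inf
  for (strandChars in list(chars, rcChars)) {
    n <- length(strandChars)
    if (n < L) stop("sequence shorter than motif")
    for (i in seq_len(n - L + 1)) {
      s <- 0
      for (j in seq_len(L)) {
        k <- match(strandChars[i + j - 1], c("A", "C", "G", "T"))
        if (is.na(k)) { s <- -Inf; break }
        s <- s + unname(lom[j, k])
      }
      if (s > best) best <- s
    }
  }
  best
}

# beta-binomial pmf via direct product formula (no lchoose/lbeta):
# C(n,k) * prod_{i=0}^{k-1}(a+i) * prod_{i=0}^{n-k-1}(b+i) / prod_{i=0}^{n-1}(a+b+i)
bruteBetaBinomPmf <- function(k, n, a, b) {
  num1 <- if (k > 0) prod(a + 0:(k - 1)) else 1
  num2 <- if (n - k > 0) prod(b + 0:(n - k - 1)) else 1
  den <- prod(a + b + 0:(n - 1))
  choose(n, k) * num1 * num2 / den
}

# full-enumeration two-sided minimum-likelihood p-value oracle
bruteTwoSidedP <- function(obsA, n, a, b) {
  pmf <- vapply(0:n, bruteBetaBinomPmf, 0, n = n, a = a, b = b)
  pObs <- pmf[obsA + 1]
  min(1, sum(pmf[pmf <= pObs * (1 + 1e-9)]))
}

# brute-force three-key lexicographic read comparator
bruteClassify <- function(q1, q2, m1, m2, x1, x2) {
  if (q1 != q2) return(if (q1 > q2) "HAP1_EXCLUSIVE" else "HAP2_EXCLUSIVE")
  if (m1 != m2) return(if (m1 > m2) "HAP1_EXCLUSIVE" else "HAP2_EXCLUSIVE")
  if (x1 != x2) return(if (x1 < x2) "HAP1_EXCLUSIVE" else "HAP2_EXCLUSIVE")
  "COMMON"
}

# random reference sequence as a named DNAStringSet
randomReference <- function(lens, seed = 1) {
  withr::local_seed(seed)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    "")
  Biostrings::DNAStringSet(setNames(seqs, names(lens)))
}

# random probability PWM (for decoy sets)
randomPwm <- function(id, len = 8, seed = 1) {
  withr::local_seed(seed)
  m <- matrix(stats::rgamma(len * 4, 0.8), nrow = len)
  colnames(m) <- c("A", "C", "G", "T")
  pwMotif(id, m)
}
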