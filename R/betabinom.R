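#' Beta-binomial probability mass
#'
#' P(K = k) for K ~ BetaBinomial(n, alpha, beta):
#' C(n,k) B(k + alpha, n - k + beta) / B(alpha, beta), computed on the log
#' scale for stability.
#'
#' @param k Integer vector of successes, 0 <= k <= n.
#' @param n Number of trials.
#' @param alpha,beta Positive shape parameters.
#' @return Numeric vector of probabilities.
#' @examples
#' dBetaBinom(0, 1, 1, 1) # 0.5
#' sum(dBetaBinom(0:20, 20, 31, 11)) # 1
#' @export
dBetaBinom <- function(k, n, alpha, beta) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (any(k < 0 | k > n)) stop("k must be in 0..n")
  exp(lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta))
}

#' Two-tailed beta-binomial test of allelic counts against a WGS prior
#'
#' The genomic allele fraction at a site is estimated from WGS counts
#' (#A, #B) as the conjugate posterior Beta(1 + #A, 1 + #B) under a uniform
#' prior; the assay counts are then tested against the implied
#' BetaBinomial(n, 1 + #A, 1 + #B) null. The two-sided p-value is the
#' minimum-likelihood mass: the sum over all outcomes whose probability does
#' not exceed that of the observation (relative tie tolerance 1e-9), which
#' is exact, never exceeds 1, and is symmetric for symmetric priors.
#'
#' @param assayA,assayB Assay read counts for the two alleles (allele A is
#'   the one counted by \code{#A} in the WGS prior).
#' @param wgsA,wgsB WGS read counts for the two alleles.
#' @return p-value in (0, 1].
#' @examples
#' aseTest(5, 5, 10, 10)   # 1: observation at the mode
#' aseTest(20, 0, 30, 10)  # strong imbalance beyond the genomic ratio
#' @export
aseTest <- function(assayA, assayB, wgsA, wgsB) {
  n <- assayA + assayB
  if (n < 1) stop("assay depth must be >= 1")
  pmf <- dBetaBinom(0:n, n, 1 + wgsA, 1 + wgsB)
  pObs <- pmf[assayA + 1L]
  min(1, sum(pmf[pmf <= pObs * (1 + 1e-9)]))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values (wrapper over \code{stats::p.adjust}).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Numeric vector of q-values.
#' @export
bhFdr <- function(p) stats::p.adjust(p, method = "BH")
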