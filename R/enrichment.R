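#' Motif-delta enrichment in allele-specific vs control peaks
#'
#' Builds the 2x2 table of absolute delta scores exceeding the cutoff in
#' event peaks vs control peaks and tests it one-sided (hypergeometric /
#' Fisher). \code{direction = "greater"} tests over-representation of large
#' deltas among events (motif gains/losses associated with the allelic
#' signal); \code{"less"} tests under-representation (negative
#' association). The odds ratio is the cross-product ad/bc with a Haldane
#' 0.5 correction when any cell is zero.
#'
#' @param eventDeltas,controlDeltas Numeric vectors of per-peak deltas for
#'   one motif.
#' @param motifId Identifier carried through.
#' @param threshold Absolute-delta cutoff (log-odds units).
#' @param direction \code{"greater"} or \code{"less"}.
#' @return data.frame \code{motif_id}, \code{threshold},
#'   \code{event_above}, \code{event_below}, \code{control_above},
#'   \code{control_below}, \code{odds_ratio}, \code{p_value}.
#' @export
enrichmentTest <- function(eventDeltas, controlDeltas, motifId = NA,
                           threshold = 3.0,
                           direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(length(eventDeltas) > 0, length(controlDeltas) > 0)
  a <- sum(abs(eventDeltas) > threshold)
  b <- length(eventDeltas) - a
  cc <- sum(abs(controlDeltas) > threshold)
  d <- length(controlDeltas) - cc
  tab <- matrix(c(a, b, cc, d), nrow = 2)
  p <- stats::fisher.test(tab, alternative = direction)$p.value
  h <- if (any(tab == 0)) 0.5 else 0
  or <- ((a + h) * (d + h)) / ((b + h) * (cc + h))
  data.frame(motif_id = motifId, threshold = threshold,
             event_above = a, event_below = b,
             control_above = cc, control_below = d,
             odds_ratio = or, p_value = p)
}

#' Per-motif enrichment table with BH correction
#'
#' Runs \code{\link{enrichmentTest}} for every motif column and BH-adjusts
#' the p-values across motifs.
#'
#' @param eventDeltaMat,controlDeltaMat Numeric matrices, peaks x motifs,
#'   with matching motif columns.
#' @param threshold,direction Passed to \code{\link{enrichmentTest}}.
#' @return data.frame, one row per motif, with a \code{q_value} column.
#' @export
enrichmentTable <- function(eventDeltaMat, controlDeltaMat, threshold = 3.0,
                            direction = "greater") {
  stopifnot(identical(colnames(eventDeltaMat), colnames(controlDeltaMat)))
  rows <- lapply(colnames(eventDeltaMat), function(m)
    enrichmentTest(eventDeltaMat[, m], controlDeltaMat[, m], m,
                   threshold, direction))
  out <- do.call(rbind, rows)
  out$q_value <- bhFdr(out$p_value)
  out
}

#' Fraction of allele-specific events explained at a false-positive rate
#'
#' Finds the smallest score threshold t at which at most \code{fpr} of
#' control scores lie strictly above t (the empirical (1 - fpr)-quantile
#' under the higher-interpolation convention), then reports the share of
#' event scores strictly above t.
#'
#' @param eventScores,controlScores Per-variant scores (typically max
#'   absolute delta across motifs or model classes).
#' @param fpr Target false-positive rate in (0, 1).
#' @return List with \code{threshold} and \code{fraction}.
#' @examples
#' explainedFractionAtFpr(c(10, 96, 99), 1:100, 0.05) # threshold 95, 2/3
#' @export
explainedFractionAtFpr <- function(eventScores, controlScores, fpr = 0.05) {
  if (fpr <= 0 || fpr >= 1) stop("fpr must be in (0, 1)")
  stopifnot(length(eventScores) > 0, length(controlScores) > 0)
  cand <- sort(unique(controlScores))
  frac <- vapply(cand, function(t) mean(controlScores > t), 0)
  t <- cand[which(frac <= fpr)[1]]
  list(threshold = t, fraction = mean(eventScores > t))
}

#' Label-shuffle baseline for the explained fraction
#'
#' Repeatedly permutes the event/control labels over the pooled scores and
#' recomputes \code{\link{explainedFractionAtFpr}}; under exchangeability
#' the mean baseline fraction is close to \code{fpr}.
#'
#' @param eventScores,controlScores As in
#'   \code{\link{explainedFractionAtFpr}}.
#' @param fpr Target false-positive rate.
#' @param nPerm Number of permutations.
#' @param seed RNG seed for reproducibility.
#' @return Numeric vector of \code{nPerm} baseline fractions.
#' @export
labelShuffleBaseline <- function(eventScores, controlScores, fpr = 0.05,
                                 nPerm = 100, seed = 1L) {
  stopifnot(nPerm >= 1)
  pool <- c(eventScores, controlScores)
  nE <- length(eventScores)
  withr::local_seed(seed)
  vapply(seq_len(nPerm), function(i) {
    lab <- sample.int(length(pool), nE)
    explainedFractionAtFpr(pool[lab], pool[-lab], fpr)$fraction
  }, 0)
}
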