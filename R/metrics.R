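#' Balanced Matthews correlation coefficient
#'
#' MCC computed after rescaling the inactive-class counts to the
#' active-class size: with \eqn{s = n_A / n_I}, the rescaled counts
#' \eqn{FP' = s\,FP} and \eqn{TN' = s\,TN} replace FP and TN in the
#' standard MCC formula
#' \deqn{MCC = \frac{TP\,TN' - FP'\,FN}{\sqrt{(TP+FP')(TP+FN)(TN'+FP')(TN'+FN)}}.}
#' This removes the class-imbalance bias of screening datasets where
#' presumed inactives outnumber actives 10- to 25-fold; it equals the
#' standard MCC on a dataset in which every active row is replicated
#' \eqn{n_I} times and every inactive row \eqn{n_A} times.  A zero factor
#' in the denominator yields 0 by convention.
#'
#' @param counts a [ConfusionCounts-class] (or an object coercible via
#'   \code{tp/fp/tn/fn} arguments of [ConfusionCounts()]).
#' @return A number in \eqn{[-1, 1]}.
#' @examples
#' balancedMCC(ConfusionCounts(tp = 285, fp = 124, tn = 9876, fn = 110))
#' @export
balancedMCC <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; fp <- counts@fp; tn <- counts@tn; fn <- counts@fn
  nA <- tp + fn; nI <- fp + tn
  if (nA <= 0 || nI <= 0)
    stop("balanced MCC requires both classes present (nActives and nInactives > 0)")
  s <- nA / nI
  fp2 <- s * fp; tn2 <- s * tn
  den2 <- (tp + fp2) * (tp + fn) * (tn2 + fp2) * (tn2 + fn)
  if (den2 <= 0) return(0)
  (tp * tn2 - fp2 * fn) / sqrt(den2)
}

#' Standard (unbalanced) Matthews correlation coefficient
#'
#' The textbook MCC on raw counts, zero-denominator convention 0.  Used
#' mainly as the reference in the replication identity that defines
#' [balancedMCC()].
#'
#' @param counts a [ConfusionCounts-class].
#' @return A number in \eqn{[-1, 1]}.
#' @export
standardMCC <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; fp <- counts@fp; tn <- counts@tn; fn <- counts@fn
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 <= 0) return(0)
  (tp * tn - fp * fn) / sqrt(den2)
}

#' @describeIn balancedMCC true-positive rate \eqn{TP/(TP+FN)}.
#' @export
truePositiveRate <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  nA <- counts@tp + counts@fn
  if (nA <= 0) return(NA_real_)
  counts@tp / nA
}

#' @describeIn balancedMCC false-positive rate \eqn{FP/(FP+TN)}.
#' @export
falsePositiveRate <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  nI <- counts@fp + counts@tn
  if (nI <= 0) return(NA_real_)
  counts@fp / nI
}

#' Enrichment factor at a score threshold
#'
#' \eqn{EF = (TP/n_A) / (FP/n_I)}: how many-fold the active rate above
#' the threshold exceeds the active rate of the whole library.  When
#' \code{FP = 0} the factor is undefined and \code{Inf} is returned (a
#' report prints it as \code{"-"}).
#'
#' @param counts a [ConfusionCounts-class] with both classes present.
#' @return A positive number, or \code{Inf} when FP = 0, or \code{NaN}
#'   when TP = FP = 0.
#' @examples
#' enrichmentFactor(ConfusionCounts(tp = 314, fp = 318, tn = 9682, fn = 81))
#' @export
enrichmentFactor <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  nA <- counts@tp + counts@fn
  nI <- counts@fp + counts@tn
  if (nA <= 0 || nI <= 0)
    stop("enrichment factor requires both classes present")
  if (counts@fp == 0 && counts@tp == 0) return(NaN)
  if (counts@fp == 0) return(Inf)
  (counts@tp / nA) / (counts@fp / nI)
}

#' Enrichment factor from a prospective hit rate
#'
#' The screening-campaign form of the enrichment factor: the observed hit
#' rate among tested molecules over an assumed background hit rate,
#' \eqn{(hits/tested) / baseRate}.
#'
#' @param hits number of confirmed actives among the tested molecules.
#' @param tested number of molecules tested.
#' @param baseRate assumed background hit rate of the library (e.g.
#'   0.001 for the conventional 1-in-1000 HTS discovery rate).
#' @return A non-negative number.
#' @examples
#' hitRateEF(27, 306, 1560 / 1560000)  # ~88
#' @export
hitRateEF <- function(hits, tested, baseRate) {
  stopifnot(tested > 0, baseRate > 0, hits >= 0)
  (hits / tested) / baseRate
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%g FP=%g TN=%g FN=%g (nA=%g, nI=%g)\n",
              object@tp, object@fp, object@tn, object@fn,
              object@tp + object@fn, object@fp + object@tn))
  if (object@tp + object@fn > 0 && object@fp + object@tn > 0) {
    ef <- enrichmentFactor(object)
    cat(sprintf("  balanced MCC = %.3f, EF = %s\n", balancedMCC(object),
                ifelse(is.finite(ef), sprintf("%.1f", ef), "-")))
  }
})
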