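#' Molecular bioactivity index (MBI) scores
#'
#' Scores molecules against an [ISEModel-class]: every filter a molecule
#' passes adds that filter's weight to the score, every filter it fails
#' subtracts the same weight, so
#' \deqn{MBI = \sum_{i \in passed} w_i - \sum_{i \in failed} w_i.}
#' With the default \code{"rate"} weighting, \eqn{w_i = TPR_i / FPR_i}
#' (the FPR floored at \eqn{1/(2 n_I)} when a filter has no false
#' positives); \code{"count"} weighting uses raw \eqn{TP_i / FP_i}.  When
#' \code{config$mbiNormalize} is TRUE, scores are divided by the filter
#' count.
#'
#' @param model an [ISEModel-class].
#' @param values a [DescriptorTable-class], a molecule-by-descriptor
#'   matrix, or a single named descriptor vector.  Must cover every
#'   descriptor the model uses.
#' @return A data.frame with columns \code{id} and \code{mbi}, plus the
#'   per-filter logical pass matrix as attribute \code{"pass"}.
#' @seealso [thresholdReport()], [rocAndEnrichment()]
#' @export
mbiScore <- function(model, values) {
  stopifnot(is(model, "ISEModel"))
  if (is(values, "DescriptorTable")) values <- descriptorMatrix(values)
  if (is.null(dim(values)))
    values <- matrix(values, 1L, dimnames = list("M000001", names(values)))
  used <- unique(unlist(lapply(model@filters, function(f) f@descriptors)))
  miss <- setdiff(used, colnames(values))
  if (length(miss))
    stop("descriptor(s) required by the model are missing: ",
         paste(miss, collapse = ", "))
  pass <- vapply(model@filters, filterPasses, logical(nrow(values)),
                 values = values)
  if (nrow(values) == 1L) pass <- matrix(pass, nrow = 1L)
  w <- model@weights
  # passed filters contribute +w, failed ones -w
  mbi <- as.numeric(pass %*% w - (!pass) %*% w)
  if (isTRUE(model@config$mbiNormalize)) mbi <- mbi / length(w)
  ids <- rownames(values)
  if (is.null(ids)) ids <- sprintf("M%06d", seq_len(nrow(values)))
  out <- data.frame(id = ids, mbi = mbi, stringsAsFactors = FALSE)
  rownames(pass) <- ids
  attr(out, "pass") <- pass
  out
}

#' Confusion tables and metrics across MBI borders
#'
#' For each border \code{b}, molecules with \code{score >= b} are called
#' positive; the report row gives TN, FN, TP, FP, the enrichment factor
#' and the balanced MCC at that border.  TP and FP are non-increasing in
#' the border, and TP+FN / FP+TN are constant (the class sizes).
#'
#' @param scores numeric MBI scores (or the data.frame from [mbiScore()]).
#' @param labels parallel activity labels (\code{"active"}/\code{"inactive"});
#'   other labels are dropped with a warning.
#' @param borders numeric vector of MBI borders.
#' @return A data.frame, one row per border, with columns \code{border},
#'   \code{tn}, \code{fn}, \code{tp}, \code{fp}, \code{enrichment},
#'   \code{mcc}.  An undefined enrichment (FP = 0) is \code{Inf} and
#'   prints as \code{"-"} via [formatThresholdReport()].
#' @export
thresholdReport <- function(scores, labels,
                            borders = c(-3, 3, 6, 9, 10, 13)) {
  if (is.data.frame(scores)) scores <- scores$mbi
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  keep <- labels %in% c("active", "inactive")
  if (!all(keep)) {
    warning(sum(!keep), " molecule(s) with 'unknown' label dropped from the report")
    scores <- scores[keep]; labels <- labels[keep]
  }
  isA <- labels == "active"
  if (!any(isA) || all(isA))
    stop("threshold report requires both classes present")
  rows <- lapply(borders, function(b) {
    pos <- scores >= b
    cc <- ConfusionCounts(tp = sum(pos & isA), fp = sum(pos & !isA),
                          tn = sum(!pos & !isA), fn = sum(!pos & isA))
    data.frame(border = b, tn = cc@tn, fn = cc@fn, tp = cc@tp, fp = cc@fp,
               enrichment = enrichmentFactor(cc), mcc = balancedMCC(cc))
  })
  do.call(rbind, rows)
}

#' @describeIn thresholdReport print-ready version of a report: counts as
#'   integers, enrichment rounded as in screening write-ups (one decimal
#'   below 10, whole numbers above, \code{"-"} when undefined), MCC to 3
#'   decimals.
#' @param report a data.frame from [thresholdReport()].
#' @export
formatThresholdReport <- function(report) {
  ef <- vapply(report$enrichment, function(e) {
    if (!is.finite(e)) "-"
    else if (e < 10) sprintf("%.1f", round(e, 1))
    else sprintf("%d", round(e))
  }, character(1))
  data.frame(border = report$border, tn = as.integer(report$tn),
             fn = as.integer(report$fn), tp = as.integer(report$tp),
             fp = as.integer(report$fp), enrichment = ef,
             mcc = sprintf("%.3f", round(report$mcc, 3)),
             stringsAsFactors = FALSE)
}

#' ROC AUC and active-capture curve
#'
#' Rank-based AUC (Mann-Whitney statistic with ties averaged) plus the
#' cumulative capture curve: the fraction of actives found within the
#' top x\% of scores.
#'
#' @param scores numeric scores, higher = more active-like.
#' @param labels parallel labels (\code{"active"}/\code{"inactive"}).
#' @param topFractions fractions of the ranked library at which capture
#'   is evaluated (default 0.5\%..100\%).
#' @return List with \code{auc} and a data.frame \code{capture}
#'   (\code{topFraction}, \code{activesCaptured}).
#' @examples
#' rocAndEnrichment(c(4, 3, 2, 1), c("active", "inactive", "active",
#'                                   "inactive"))$auc  # 0.75
#' @export
rocAndEnrichment <- function(scores, labels,
                             topFractions = c(0.005, 0.01, 0.02, 0.05,
                                              0.1, 0.25, 0.5, 1)) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  isA <- labels == "active"
  nA <- sum(isA); nI <- sum(labels == "inactive")
  if (nA == 0 || nI == 0) stop("both classes required")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[isA]) - nA * (nA + 1) / 2) / (nA * nI)
  ord <- order(scores, decreasing = TRUE)
  cum <- cumsum(isA[ord]) / nA
  n <- length(scores)
  capture <- data.frame(
    topFraction = topFractions,
    activesCaptured = vapply(topFractions,
                             function(f) cum[max(1L, floor(f * n))],
                             numeric(1))
  )
  list(auc = auc, capture = capture)
}

# ---- model serialization ---------------------------------------------------

.MODEL_FORMAT <- "iseScreen-model"
.MODEL_VERSION <- 1L

#' Save / load an ISE model
#'
#' Models are stored as versioned JSON holding descriptor names, clause
#' bounds as decimals and confusion counts as integers; MCC values and
#' MBI weights are re-derived on load, so \code{loadModel(saveModel(m))}
#' reproduces the model exactly without float drift.
#'
#' @param model an [ISEModel-class].
#' @param path file path for the JSON model.
#' @return \code{saveModel}: \code{path}, invisibly.  \code{loadModel}:
#'   an [ISEModel-class]; truncated files, wrong formats or missing
#'   class sizes are fatal.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "ISEModel"))
  validObject(model)
  filters <- lapply(model@filters, function(f) {
    list(descriptors = f@descriptors, low = f@low, high = f@high,
         tp = as.integer(f@counts@tp), fp = as.integer(f@counts@fp),
         tn = as.integer(f@counts@tn), fn = as.integer(f@counts@fn))
  })
  obj <- list(format = .MODEL_FORMAT, version = .MODEL_VERSION,
              nActives = model@nActives, nInactives = model@nInactives,
              config = model@config, filters = filters)
  # 17 significant digits guarantee bit-exact double roundtrip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("cannot parse model file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, .MODEL_FORMAT))
    stop("not an ISE model file (format tag missing or wrong): ", path)
  if (is.null(obj$version) || obj$version > .MODEL_VERSION)
    stop("unsupported model file version: ", obj$version %||% "<missing>")
  if (is.null(obj$nActives) || is.null(obj$nInactives))
    stop("model file is missing the training class sizes")
  if (!length(obj$filters)) stop("model file contains no filters")
  cfg <- obj$config
  cfg$quantileProbs <- as.numeric(unlist(cfg$quantileProbs))
  config <- do.call(iseConfig, cfg)
  filters <- lapply(obj$filters, function(f) {
    need <- c("descriptors", "low", "high", "tp", "fp", "tn", "fn")
    if (!all(need %in% names(f)))
      stop("model filter entry is missing fields: ",
           paste(setdiff(need, names(f)), collapse = ", "))
    cc <- ConfusionCounts(tp = f$tp, fp = f$fp, tn = f$tn, fn = f$fn)
    RangeFilter(unlist(f$descriptors), unlist(f$low), unlist(f$high),
                counts = cc, mcc = balancedMCC(cc))
  })
  model <- .newISEModel(filters, obj$nActives, obj$nInactives, config)
  validObject(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
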