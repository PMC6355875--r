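#' Configuration for iterative stochastic elimination
#'
#' Bundles the tunable parameters of [buildModel()].  Defaults are the
#' package's working settings for descriptor pools of a few dozen
#' descriptors; all fractions must lie in (0, 1).
#'
#' @param k clauses (descriptors) per filter; the method uses small
#'   conjunctions of 4-5 ranges, default 4.
#' @param filtersPerIteration random filters sampled and scored per
#'   elimination iteration (default 500).
#' @param elimFraction fraction of the surviving descriptor pool removed
#'   per iteration (default 0.2); at least one descriptor is always
#'   removed, so the pool strictly shrinks.
#' @param exhaustiveMax iterations stop once the number of remaining
#'   k-descriptor combinations \eqn{C(|pool|, k)} is at or below this
#'   threshold, after which all combinations are enumerated.  The
#'   default, \code{choose(k + 2, k)}, lets elimination -- the method's
#'   informative step -- run until only \code{k + 2} descriptors
#'   survive; raise it to trade elimination for blind enumeration (and
#'   larger, less selective models).
#' @param bandFraction the final model keeps every deduplicated filter
#'   whose balanced MCC is at least \code{(1 - bandFraction)} times the
#'   best MCC (default 0.20, i.e. "up to about 20\% less than the top").
#' @param dedupOverlap two filters whose per-molecule pass/fail vectors
#'   agree on more than this fraction of molecules are considered
#'   duplicates; the lower-MCC one is dropped (default 0.99).
#' @param quantileProbs probability grid whose empirical quantiles of the
#'   actives' values supply candidate clause bounds (default deciles).
#' @param seed integer seed driving all stochastic steps.
#' @param weightMode \code{"rate"} (default): MBI filter weight =
#'   TPR/FPR; \code{"count"}: raw TP/FP.
#' @param mbiNormalize divide MBI scores by the filter count (default
#'   FALSE).
#' @return A validated list of class \code{"ISEConfig"}.
#' @seealso [buildModel()]
#' @export
iseConfig <- function(k = 4L,
                      filtersPerIteration = 500L,
                      elimFraction = 0.2,
                      exhaustiveMax = NULL,
                      bandFraction = 0.20,
                      dedupOverlap = 0.99,
                      quantileProbs = seq(0, 1, by = 0.1),
                      seed = 1L,
                      weightMode = c("rate", "count"),
                      mbiNormalize = FALSE) {
  weightMode <- match.arg(weightMode)
  if (is.null(exhaustiveMax)) exhaustiveMax <- choose(as.integer(k) + 2L, as.integer(k))
  cfg <- list(k = as.integer(k),
              filtersPerIteration = as.integer(filtersPerIteration),
              elimFraction = elimFraction,
              exhaustiveMax = as.integer(exhaustiveMax),
              bandFraction = bandFraction,
              dedupOverlap = dedupOverlap,
              quantileProbs = as.numeric(quantileProbs),
              seed = as.integer(seed),
              weightMode = weightMode,
              mbiNormalize = isTRUE(mbiNormalize))
  if (cfg$k < 1L) stop("k must be >= 1")
  if (cfg$filtersPerIteration < 1L) stop("filtersPerIteration must be >= 1")
  for (f in c("elimFraction", "bandFraction")) {
    if (!(cfg[[f]] > 0 && cfg[[f]] < 1)) stop(f, " must lie in (0, 1)")
  }
  if (!(cfg$dedupOverlap > 0 && cfg$dedupOverlap <= 1))
    stop("dedupOverlap must lie in (0, 1]")
  if (cfg$exhaustiveMax < 1L) stop("exhaustiveMax must be positive")
  if (length(cfg$quantileProbs) < 2L || is.unsorted(cfg$quantileProbs) ||
      any(cfg$quantileProbs < 0 | cfg$quantileProbs > 1))
    stop("quantileProbs must be an increasing grid in [0, 1]")
  class(cfg) <- "ISEConfig"
  cfg
}

#' Does a molecule pass a range filter?
#'
#' TRUE iff every clause is satisfied, i.e. \code{low <= value <= high}
#' for every descriptor named by the filter (closed intervals: boundary
#' values pass).
#'
#' @param filter a [RangeFilter-class].
#' @param values named numeric vector of descriptor values, or a
#'   molecule-by-descriptor matrix / [DescriptorTable-class] for a
#'   vectorized answer.
#' @return Logical, one element per molecule.
#' @export
filterPasses <- function(filter, values) {
  stopifnot(is(filter, "RangeFilter"))
  if (is(values, "DescriptorTable")) values <- descriptorMatrix(values)
  if (is.null(dim(values))) values <- matrix(values, 1L,
                                             dimnames = list(NULL, names(values)))
  miss <- setdiff(filter@descriptors, colnames(values))
  if (length(miss))
    stop("descriptor(s) required by the filter are missing from the data: ",
         paste(miss, collapse = ", "))
  v <- values[, filter@descriptors, drop = FALSE]
  pass <- rep(TRUE, nrow(v))
  for (j in seq_along(filter@descriptors)) {
    pass <- pass & v[, j] >= filter@low[j] & v[, j] <= filter@high[j]
  }
  unname(pass)
}

# ---- internal training machinery ------------------------------------------
#
# The training loop works on a plain "ise dataset" list:
#   X        molecules x descriptors matrix
#   isActive logical per molecule
#   idxA/idxI row indices of the two classes
# plus a per-descriptor cache of candidate clause ranges (empirical
# quantiles of the ACTIVES) and the pass mask of every candidate range,
# so that scoring a filter reduces to ANDing k logical vectors.

.iseDataset <- function(table) {
  stopifnot(is(table, "DescriptorTable"))
  X <- descriptorMatrix(table)
  lab <- moleculeLabels(table)
  keep <- lab %in% c("active", "inactive")
  X <- X[keep, , drop = FALSE]
  lab <- lab[keep]
  isActive <- lab == "active"
  if (!any(isActive) || all(isActive))
    stop("training requires both actives and inactives")
  list(X = X, isActive = isActive,
       idxA = which(isActive), idxI = which(!isActive),
       nA = sum(isActive), nI = sum(!isActive),
       descriptors = colnames(X))
}

# Candidate clause bounds per descriptor: all ordered pairs (low <= high)
# of the actives' empirical quantiles on the configured grid.  Constant
# descriptors collapse to the single value (a zero-width clause).
.rangeGrid <- function(ds, cfg) {
  nq <- length(cfg$quantileProbs)
  pairs <- which(upper.tri(matrix(0, nq, nq), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  grid <- lapply(ds$descriptors, function(d) {
    q <- unname(quantile(ds$X[ds$idxA, d], probs = cfg$quantileProbs,
                         type = 7, names = FALSE))
    low <- q[pairs[, "row"]]
    high <- q[pairs[, "col"]]
    x <- ds$X[, d]
    mask <- matrix(FALSE, length(x), length(low))
    for (r in seq_along(low)) mask[, r] <- x >= low[r] & x <= high[r]
    # wide ranges (>= 80% of the grid span) are the sampling pool of the
    # stochastic phase: they keep per-clause sensitivity near 1, so a
    # filter's MCC grows with every informative clause it contains and
    # the per-descriptor attribution driving elimination stays sharp;
    # narrow ranges collapse the sensitivity of k-clause conjunctions
    # and invert that signal.  The exhaustive phase searches all pairs.
    span <- pairs[, "col"] - pairs[, "row"]
    wide <- which(span >= 0.8 * (nq - 1))
    if (!length(wide)) wide <- seq_along(low)
    list(low = low, high = high, mask = mask, wide = wide,
         full = which(low == min(q) & high == max(q))[1])
  })
  names(grid) <- ds$descriptors
  grid
}

.countsFromPass <- function(pass, ds) {
  tp <- sum(pass[ds$idxA]); fp <- sum(pass[ds$idxI])
  ConfusionCounts(tp = tp, fp = fp, tn = ds$nI - fp, fn = ds$nA - tp)
}

# Score a filter given grid range indices; returns a scored RangeFilter.
.scoreRanges <- function(desc, ridx, ds, grid) {
  pass <- rep(TRUE, nrow(ds$X))
  for (j in seq_along(desc)) pass <- pass & grid[[desc[j]]]$mask[, ridx[j]]
  cc <- .countsFromPass(pass, ds)
  RangeFilter(desc,
              low = vapply(seq_along(desc),
                           function(j) grid[[desc[j]]]$low[ridx[j]], numeric(1)),
              high = vapply(seq_along(desc),
                            function(j) grid[[desc[j]]]$high[ridx[j]], numeric(1)),
              counts = cc, mcc = balancedMCC(cc))
}

#' Sample and score one random range filter
#'
#' Draws \code{k} distinct descriptors uniformly from the pool and, for
#' each, a clause \code{[low, high]} as an ordered pair of distinct
#' empirical quantiles of the actives' values (decile grid by default),
#' then scores the filter on the dataset.  Consumes the current R random
#' stream; seed it (or use the seeded [buildModel()] loop) for
#' reproducibility.
#'
#' @param pool character vector of candidate descriptor names.
#' @param table a [DescriptorTable-class] with active/inactive labels.
#' @param config an [iseConfig()].
#' @return A scored [RangeFilter-class].
#' @export
sampleFilter <- function(pool, table, config = iseConfig()) {
  ds <- .iseDataset(table)
  grid <- .rangeGrid(ds, config)
  .sampleFilterFast(pool, ds, grid, config)
}

.sampleFilterFast <- function(pool, ds, grid, cfg) {
  if (length(pool) < cfg$k)
    stop("descriptor pool smaller than k")
  desc <- if (length(pool) == cfg$k) pool else sample(pool, cfg$k)
  ridx <- vapply(desc, function(d) {
    w <- grid[[d]]$wide
    if (length(w) == 1L) w else w[sample.int(length(w), 1L)]
  }, integer(1))
  .scoreRanges(desc, ridx, ds, grid)
}

#' Eliminate the consistently worst-scoring descriptors
#'
#' Each pool descriptor is scored by the mean balanced MCC of the sampled
#' filters that contain it; the lowest \code{elimFraction} of descriptors
#' (at least one) is removed.  Ties are broken by descriptor-name order.
#' If removal would leave fewer than \code{k} descriptors, the pool is
#' returned unchanged (the caller proceeds to the exhaustive phase).
#'
#' @param filters list of scored [RangeFilter-class] from the current
#'   iteration; every pool descriptor must occur in at least one.
#' @param pool character vector of surviving descriptor names.
#' @param config an [iseConfig()].
#' @return Character vector: the reduced pool.
#' @export
eliminateDescriptors <- function(filters, pool, config = iseConfig()) {
  mccs <- vapply(filters, function(f) f@mcc, numeric(1))
  descs <- lapply(filters, function(f) f@descriptors)
  idx <- rep(seq_along(filters), lengths(descs))
  byDesc <- split(mccs[idx], unlist(descs))
  uncovered <- setdiff(pool, names(byDesc))
  if (length(uncovered))
    stop("descriptor(s) without any scored filter this iteration: ",
         paste(uncovered, collapse = ", "))
  meanMCC <- vapply(byDesc[pool], mean, numeric(1))
  nDrop <- max(1L, floor(config$elimFraction * length(pool)))
  if (length(pool) - nDrop < config$k) return(pool)
  ord <- order(meanMCC, pool)           # ties broken by name order
  sort(setdiff(pool, pool[ord[seq_len(nDrop)]]))
}

# Best range assignment for one descriptor subset by coordinate ascent
# over the quantile grid: clauses start at the actives' full span, then
# each clause in turn is moved to the grid pair maximizing the filter's
# balanced MCC with the other clauses fixed, until a sweep changes
# nothing (at most maxSweeps).
.bestFilterForSubset <- function(desc, ds, grid, maxSweeps = 3L) {
  k <- length(desc)
  ridx <- vapply(desc, function(d) grid[[d]]$full, integer(1))
  masks <- lapply(seq_len(k), function(j) grid[[desc[j]]]$mask[, ridx[j]])
  s <- ds$nA / ds$nI
  bestOf <- function(j) {
    other <- rep(TRUE, nrow(ds$X))
    for (l in seq_len(k)[-j]) other <- other & masks[[l]]
    M <- grid[[desc[j]]]$mask
    wA <- ds$idxA[other[ds$idxA]]
    wI <- ds$idxI[other[ds$idxI]]
    tp <- colSums(M[wA, , drop = FALSE])
    fp <- colSums(M[wI, , drop = FALSE])
    fn <- ds$nA - tp; tn <- ds$nI - fp
    fp2 <- s * fp; tn2 <- s * tn
    den2 <- (tp + fp2) * (tp + fn) * (tn2 + fp2) * (tn2 + fn)
    mcc <- ifelse(den2 > 0, (tp * tn2 - fp2 * fn) / sqrt(pmax(den2, 0)), 0)
    which.max(mcc)
  }
  for (sweep in seq_len(maxSweeps)) {
    changed <- FALSE
    for (j in seq_len(k)) {
      r <- bestOf(j)
      if (r != ridx[j]) {
        ridx[j] <- r
        masks[[j]] <- grid[[desc[j]]]$mask[, r]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  .scoreRanges(desc, ridx, ds, grid)
}

#' Exhaustively instantiate all k-subsets of a descriptor pool
#'
#' For every k-descriptor combination of the pool, the best-scoring range
#' assignment over the quantile grid is found by coordinate ascent and
#' the resulting filter scored.  Refuses pools whose combination count
#' exceeds \code{exhaustiveMax}.
#'
#' @param pool character vector of descriptor names.
#' @param table a [DescriptorTable-class] with active/inactive labels.
#' @param config an [iseConfig()].
#' @return List of scored [RangeFilter-class], one per subset.
#' @export
exhaustivePhase <- function(pool, table, config = iseConfig()) {
  ds <- .iseDataset(table)
  grid <- .rangeGrid(ds, config)
  .exhaustivePhaseFast(pool, ds, grid, config)
}

.exhaustivePhaseFast <- function(pool, ds, grid, cfg) {
  nComb <- choose(length(pool), cfg$k)
  if (nComb > cfg$exhaustiveMax)
    stop(sprintf("combination count %d exceeds the exhaustive threshold %d",
                 nComb, cfg$exhaustiveMax))
  if (length(pool) < cfg$k) stop("pool smaller than k")
  subsets <- combn(sort(pool), cfg$k, simplify = FALSE)
  lapply(subsets, .bestFilterForSubset, ds = ds, grid = grid)
}

#' Drop near-duplicate filters
#'
#' Two filters are duplicates when their per-molecule pass/fail vectors
#' on the training set agree on more than \code{overlap} of the
#' molecules; the lower-MCC member of each such pair is discarded.  The
#' survivors are returned sorted by decreasing MCC.
#'
#' @param filters list of scored [RangeFilter-class].
#' @param table the [DescriptorTable-class] they were scored on.
#' @param overlap agreement fraction above which filters are duplicates
#'   (default 0.99).
#' @return List of surviving filters, MCC-descending.
#' @export
dedupFilters <- function(filters, table, overlap = 0.99) {
  if (!length(filters)) return(filters)
  ds <- .iseDataset(table)
  pass <- vapply(filters, filterPasses, logical(nrow(ds$X)), values = ds$X)
  ord <- order(vapply(filters, function(f) f@mcc, numeric(1)),
               decreasing = TRUE)
  keep <- integer(0)
  n <- nrow(pass)
  for (i in ord) {
    dup <- FALSE
    for (j in keep) {
      if (sum(pass[, i] == pass[, j]) / n > overlap) { dup <- TRUE; break }
    }
    if (!dup) keep <- c(keep, i)
  }
  filters[keep]
}

# Weight of each filter under the configured MBI weighting rule.
.filterWeight <- function(f, nI, weightMode) {
  cc <- f@counts
  if (weightMode == "count") {
    fp <- if (cc@fp == 0) 0.5 else cc@fp
    return(cc@tp / fp)
  }
  tpr <- truePositiveRate(cc)
  fpr <- falsePositiveRate(cc)
  if (fpr == 0) fpr <- 1 / (2 * nI)    # floor when FP = 0
  tpr / fpr
}

# Assemble an ISEModel from scored filters (sorts, derives weights).
.newISEModel <- function(filters, nA, nI, config) {
  ord <- order(vapply(filters, function(f) f@mcc, numeric(1)),
               decreasing = TRUE)
  filters <- filters[ord]
  weights <- vapply(filters, .filterWeight, numeric(1),
                    nI = nI, weightMode = config$weightMode)
  new("ISEModel", filters = filters, nActives = nA, nInactives = nI,
      weights = weights, config = unclass(config))
}

#' Train an ISE filter model
#'
#' Runs the full iterative-stochastic-elimination loop on a labeled
#' descriptor table: (1) sample and score \code{filtersPerIteration}
#' random k-descriptor range filters; (2) score each descriptor by the
#' mean balanced MCC of the filters containing it and eliminate the worst
#' \code{elimFraction}; (3) repeat until at most \code{exhaustiveMax}
#' k-combinations remain, then enumerate them all with per-subset range
#' optimization; (4) drop near-duplicate filters and keep every filter
#' whose MCC is within \code{bandFraction} of the best.  Fully
#' reproducible under \code{config$seed}.
#'
#' @param table a [DescriptorTable-class] with both classes labeled.
#' @param config an [iseConfig()].
#' @param verbose log pool size and best MCC per iteration (default FALSE).
#' @return An [ISEModel-class].
#' @examples
#' \donttest{
#' dt <- genDescriptorDataset(syntheticSpec(nActives = 60, nInactives = 300,
#'                                          nInformative = 3, nNoise = 7,
#'                                          shift = 3, seed = 7))
#' m <- buildModel(dt, iseConfig(filtersPerIteration = 150, seed = 7))
#' m
#' }
#' @export
buildModel <- function(table, config = iseConfig(), verbose = FALSE) {
  stopifnot(inherits(config, "ISEConfig"))
  ds <- .iseDataset(table)
  grid <- .rangeGrid(ds, config)
  pool <- sort(ds$descriptors)
  if (length(pool) < config$k)
    stop("fewer descriptors than clauses per filter (k)")
  withr::local_seed(config$seed)

  iter <- 0L
  while (choose(length(pool), config$k) > config$exhaustiveMax) {
    iter <- iter + 1L
    filters <- replicate(config$filtersPerIteration,
                         .sampleFilterFast(pool, ds, grid, config),
                         simplify = FALSE)
    # guarantee every pool descriptor appears in at least one filter
    seen <- unique(unlist(lapply(filters, function(f) f@descriptors)))
    for (d in setdiff(pool, seen)) {
      extra <- .sampleFilterFast(c(d, sample(setdiff(pool, d), config$k - 1L)),
                                 ds, grid, config)
      filters <- c(filters, list(extra))
    }
    newPool <- eliminateDescriptors(filters, pool, config)
    if (verbose)
      message(sprintf("iteration %d: pool %d -> %d, best sampled MCC %.3f",
                      iter, length(pool), length(newPool),
                      max(vapply(filters, function(f) f@mcc, numeric(1)))))
    if (length(newPool) == length(pool)) break  # cannot shrink below k
    pool <- newPool
  }

  scored <- .exhaustivePhaseFast(pool, ds, grid, config)
  mccs <- vapply(scored, function(f) f@mcc, numeric(1))
  best <- max(mccs)
  if (best <= 0)
    stop("no discriminating filter: best balanced MCC is ", signif(best, 3),
         "; the classes may be identically distributed")
  floorMCC <- (1 - config$bandFraction) * best
  band <- scored[mccs >= floorMCC]
  band <- dedupFilters(band, table, overlap = config$dedupOverlap)
  if (verbose)
    message(sprintf("exhaustive phase: %d subsets, best MCC %.3f, %d filters kept",
                    length(scored), best, length(band)))
  .newISEModel(band, ds$nA, ds$nI, config)
}

setMethod("show", "ISEModel", function(object) {
  mccs <- vapply(object@filters, function(f) f@mcc, numeric(1))
  cat(sprintf("ISEModel: %d filters (balanced MCC %.3f .. %.3f)\n",
              length(object@filters), max(mccs), min(mccs)))
  cat(sprintf("  trained on %g actives / %g inactives; k = %s, seed = %s\n",
              object@nActives, object@nInactives,
              object@config$k, object@config$seed))
  cat(sprintf("  MBI weights (%s): %.2f .. %.2f\n", object@config$weightMode,
              max(object@weights), min(object@weights)))
})

setMethod("show", "RangeFilter", function(object) {
  cat("RangeFilter:",
      paste(sprintf("%s in [%.4g, %.4g]", object@descriptors, object@low,
                    object@high), collapse = " & "), "\n")
  if (!is.na(object@mcc))
    cat(sprintf("  balanced MCC = %.3f (TP=%g FP=%g TN=%g FN=%g)\n",
                object@mcc, object@counts@tp, object@counts@fp,
                object@counts@tn, object@counts@fn))
})

#' @describeIn buildModel number of filters in a model.
#' @param x an [ISEModel-class].
#' @export
setMethod("length", "ISEModel", function(x) length(x@filters))

#' Accessors for ISE models
#'
#' @param model an [ISEModel-class].
#' @return \code{modelFilters}: list of [RangeFilter-class];
#'   \code{modelWeights}: numeric MBI weight per filter.
#' @export
modelFilters <- function(model) {
  stopifnot(is(model, "ISEModel"))
  model@filters
}

#' @rdname modelFilters
#' @export
modelWeights <- function(model) {
  stopifnot(is(model, "ISEModel"))
  model@weights
}
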