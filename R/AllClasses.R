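#' @import methods
#' @importFrom stats quantile sd rnorm runif
#' @importFrom utils combn head read.table write.table
NULL

#' Confusion counts for a binary screening classifier
#'
#' Holds the four cells of a confusion table (actives are the positive
#' class).  Row totals are fixed by the dataset: \code{TP + FN} is the
#' number of actives and \code{FP + TN} the number of inactives.
#' Derived quantities (true/false positive rates, balanced Matthews
#' correlation, enrichment factor) are computed by accessors rather than
#' stored, so a \code{ConfusionCounts} can never go stale.
#'
#' @slot tp,fp,tn,fn non-negative integer counts.
#' @seealso [balancedMCC()], [enrichmentFactor()], [truePositiveRate()]
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric", tn = "numeric", fn = "numeric"),
  prototype(tp = 0, fp = 0, tn = 0, fn = 0)
)

setValidity("ConfusionCounts", function(object) {
  v <- c(tp = object@tp, fp = object@fp, tn = object@tn, fn = object@fn)
  if (any(lengths(list(object@tp, object@fp, object@tn, object@fn)) != 1L))
    return("tp, fp, tn, fn must each have length 1")
  if (any(!is.finite(v)) || any(v < 0))
    return("confusion counts must be finite and non-negative")
  if (any(v != round(v)))
    return("confusion counts must be whole numbers")
  TRUE
})

#' Construct confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts (actives are positives).
#' @return A [ConfusionCounts-class] object.
#' @examples
#' cc <- ConfusionCounts(tp = 285, fp = 124, tn = 9876, fn = 110)
#' balancedMCC(cc)
#' @export
ConfusionCounts <- function(tp, fp, tn, fn) {
  new("ConfusionCounts", tp = as.numeric(tp), fp = as.numeric(fp),
      tn = as.numeric(tn), fn = as.numeric(fn))
}

#' A conjunction of closed descriptor ranges
#'
#' A range filter is a conjunction of \code{k} clauses, each a closed
#' interval \code{[low, high]} over one named molecular descriptor.  A
#' molecule passes the filter iff every one of its descriptor values lies
#' inside the corresponding interval (boundary values pass).  A scored
#' filter also carries the confusion counts and balanced MCC it obtained
#' on the dataset it was trained on.
#'
#' @slot descriptors character vector of distinct descriptor names.
#' @slot low,high numeric clause bounds, \code{low <= high} elementwise.
#' @slot counts a [ConfusionCounts-class]; zero counts if unscored.
#' @slot mcc balanced Matthews correlation of the filter on its dataset.
#' @export
setClass("RangeFilter",
  representation(descriptors = "character", low = "numeric", high = "numeric",
                 counts = "ConfusionCounts", mcc = "numeric"),
  prototype(counts = new("ConfusionCounts"), mcc = NA_real_)
)

setValidity("RangeFilter", function(object) {
  n <- length(object@descriptors)
  if (n < 1L) return("filter needs at least one clause")
  if (length(object@low) != n || length(object@high) != n)
    return("low/high must match the number of descriptors")
  if (anyDuplicated(object@descriptors))
    return("descriptor names must be distinct within a filter")
  if (any(!is.finite(object@low)) || any(!is.finite(object@high)))
    return("clause bounds must be finite")
  if (any(object@low > object@high))
    return("each clause must satisfy low <= high")
  TRUE
})

#' Construct a range filter
#'
#' @param descriptors character vector of distinct descriptor names.
#' @param low,high numeric clause bounds (closed intervals).
#' @param counts optional [ConfusionCounts-class] from scoring.
#' @param mcc optional balanced MCC from scoring.
#' @return A [RangeFilter-class].
#' @examples
#' f <- RangeFilter(c("MW", "cLogP"), low = c(300, 2), high = c(600, 8))
#' filterPasses(f, c(MW = 450, cLogP = 5))
#' @export
RangeFilter <- function(descriptors, low, high,
                        counts = ConfusionCounts(0, 0, 0, 0), mcc = NA_real_) {
  new("RangeFilter", descriptors = as.character(descriptors),
      low = as.numeric(low), high = as.numeric(high),
      counts = counts, mcc = as.numeric(mcc))
}

#' An ISE screening model
#'
#' The final product of iterative stochastic elimination: a deduplicated,
#' MCC-sorted list of [RangeFilter-class] objects together with the class
#' sizes of the training set and one MBI weight per filter.  The weight of
#' filter \emph{i} is its true-positive rate over its false-positive rate
#' (with the FPR floored at \code{1/(2 nInactives)} when \code{FP = 0});
#' a screened molecule gains \code{w_i} for every filter it passes and
#' loses \code{w_i} for every filter it fails.
#'
#' @slot filters list of scored [RangeFilter-class], sorted by decreasing MCC.
#' @slot nActives,nInactives training-set class sizes.
#' @slot weights numeric, one MBI weight per filter.
#' @slot config list snapshot of the [iseConfig()] used for training.
#' @seealso [buildModel()], [mbiScore()], [saveModel()]
#' @export
setClass("ISEModel",
  representation(filters = "list", nActives = "numeric", nInactives = "numeric",
                 weights = "numeric", config = "list")
)

setValidity("ISEModel", function(object) {
  if (length(object@filters) < 1L) return("model must contain at least one filter")
  if (!all(vapply(object@filters, is, logical(1), "RangeFilter")))
    return("filters must all be RangeFilter objects")
  if (length(object@weights) != length(object@filters))
    return("one weight per filter required")
  if (object@nActives < 1 || object@nInactives < 1)
    return("both class sizes must be positive")
  mccs <- vapply(object@filters, function(f) f@mcc, numeric(1))
  if (is.unsorted(rev(mccs))) return("filters must be sorted by decreasing MCC")
  ok <- vapply(object@filters, function(f) {
    cc <- f@counts
    isTRUE(all.equal(cc@tp + cc@fn, object@nActives)) &&
      isTRUE(all.equal(cc@fp + cc@tn, object@nInactives))
  }, logical(1))
  if (!all(ok)) return("filter counts must total the model class sizes")
  TRUE
})

#' Geometric acceptance criteria for docking poses
#'
#' Residue identities are strings \code{"chain:resName:resSeq"} (e.g.
#' \code{"A:HIS:323"}).  A pose is accepted when it approaches at least
#' \code{minCrucial} crucial-to-H-bond residues closer than
#' \code{dCrucial} and at least \code{minImportant} important residues
#' closer than \code{dImportant} (strict inequalities).  The contact
#' thresholds \code{hbondMax} / \code{vdwMax} are the maximum
#' donor-acceptor and heavy-atom distances used when profiling reference
#' complexes.
#'
#' @slot crucial,important character vectors of residue ids; crucial
#'   residues are normally a subset of the important ones.
#' @slot dCrucial,dImportant distance cutoffs in Angstrom (default 3.5 / 5.0).
#' @slot minCrucial,minImportant minimum residue counts (default 2 / 7).
#' @slot hbondMax,vdwMax contact typing cutoffs in Angstrom (default 3.3 / 3.9).
#' @seealso [posePasses()], [deriveConsensusResidues()]
#' @export
setClass("GeometryCriteria",
  representation(crucial = "character", important = "character",
                 dCrucial = "numeric", dImportant = "numeric",
                 minCrucial = "numeric", minImportant = "numeric",
                 hbondMax = "numeric", vdwMax = "numeric"),
  prototype(dCrucial = 3.5, dImportant = 5.0, minCrucial = 2, minImportant = 7,
            hbondMax = 3.3, vdwMax = 3.9)
)

setValidity("GeometryCriteria", function(object) {
  thr <- c(object@dCrucial, object@dImportant, object@hbondMax, object@vdwMax)
  if (any(thr <= 0)) return("distance thresholds must be positive")
  if (object@minImportant > length(object@important))
    return("minImportant exceeds the number of important residues")
  if (anyDuplicated(object@crucial) || anyDuplicated(object@important))
    return("residue sets must not contain duplicates")
  TRUE
})

#' Construct geometry criteria
#'
#' @param crucial,important character vectors of \code{"chain:resName:resSeq"} ids.
#' @param dCrucial,dImportant pose distance cutoffs in Angstrom.
#' @param minCrucial,minImportant minimum counts of satisfied residues.
#' @param hbondMax,vdwMax contact typing cutoffs in Angstrom.
#' @return A [GeometryCriteria-class].
#' @export
GeometryCriteria <- function(crucial, important, dCrucial = 3.5, dImportant = 5.0,
                             minCrucial = 2, minImportant = 7,
                             hbondMax = 3.3, vdwMax = 3.9) {
  new("GeometryCriteria", crucial = as.character(crucial),
      important = as.character(important),
      dCrucial = dCrucial, dImportant = dImportant,
      minCrucial = minCrucial, minImportant = minImportant,
      hbondMax = hbondMax, vdwMax = vdwMax)
}

#' A set of docked ligand poses for one molecule
#'
#' Heavy-atom coordinates, element symbols and an energy score per pose
#' (lower is better), as produced by an external docking program and read
#' from an SDF file with [readPoses()].
#'
#' @slot coords list of numeric matrices (nAtoms x 3), one per pose.
#' @slot elements list of character vectors of element symbols, parallel
#'   to \code{coords}.
#' @slot energy numeric energy score per pose.
#' @slot poseIds character pose identifiers.
#' @export
setClass("PoseSet",
  representation(coords = "list", elements = "list", energy = "numeric",
                 poseIds = "character")
)

setValidity("PoseSet", function(object) {
  n <- length(object@coords)
  if (n < 1L) return("pose set must contain at least one pose")
  if (length(object@elements) != n || length(object@energy) != n ||
      length(object@poseIds) != n)
    return("coords, elements, energy and poseIds must have equal length")
  for (i in seq_len(n)) {
    xyz <- object@coords[[i]]
    if (!is.matrix(xyz) || ncol(xyz) != 3L || nrow(xyz) < 1L)
      return("each pose needs an nAtoms x 3 coordinate matrix with >= 1 atom")
    if (any(!is.finite(xyz))) return("pose coordinates must be finite")
    if (length(object@elements[[i]]) != nrow(xyz))
      return("one element symbol per atom required")
  }
  if (any(!is.finite(object@energy))) return("energy scores must be finite")
  TRUE
})

#' Construct a pose set
#'
#' @param coords list of nAtoms x 3 coordinate matrices (Angstrom).
#' @param elements list of element-symbol vectors parallel to \code{coords}.
#' @param energy numeric energy score per pose (lower = better).
#' @param poseIds optional pose identifiers.
#' @return A [PoseSet-class].
#' @export
PoseSet <- function(coords, elements, energy, poseIds = NULL) {
  if (is.null(poseIds)) poseIds <- sprintf("pose%03d", seq_along(coords))
  new("PoseSet", coords = coords, elements = elements,
      energy = as.numeric(energy), poseIds = as.character(poseIds))
}
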