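#' @importFrom ChemmineR fingerprintOB as.matrix
#' @importFrom graphics hist
NULL

.RO5_DESCRIPTORS <- c("lip_acc", "lip_don", "cLogP", "MW")

#' Hashed path fingerprints (FP2)
#'
#' Open Babel FP2 fingerprints: linear paths of 1-7 bonds hashed and
#' folded to 1024 bits.  Identical structures yield identical bitsets
#' regardless of input atom order; a molecule with no bonds yields an
#' empty bitset (flagged with a warning).
#'
#' @param molecules a [MoleculeSet-class].
#' @return A \code{ChemmineR::FPset} of 1024-bit fingerprints, one per
#'   molecule, named by molecule id.
#' @seealso [tanimoto()], [diversityPrune()]
#' @export
moleculeFingerprints <- function(molecules) {
  stopifnot(is(molecules, "MoleculeSet"))
  fp <- fingerprintOB(molecules@sdf, "FP2")
  ChemmineR::cid(fp) <- molecules@ids
  m <- as.matrix(fp)
  empty <- rowSums(m) == 0
  if (any(empty))
    warning("empty fingerprint (no bonded path) for molecule(s): ",
            paste(molecules@ids[empty], collapse = ", "), call. = FALSE)
  fp
}

.fpBits <- function(x) {
  if (is(x, "FPset") || is(x, "FP")) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (nrow(x) != 1L) stop("expected a single fingerprint")
    x <- x[1L, ]
  }
  as.logical(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' \eqn{|a \wedge b| / |a \vee b|}, defined as 0 when both bitsets are
#' empty.  Fingerprints of different lengths are a fatal error.
#'
#' @param a,b fingerprints: logical/0-1 vectors or single-molecule
#'   \code{FPset}/\code{FP} objects.
#' @return Similarity in \eqn{[0, 1]}.
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' @export
tanimoto <- function(a, b) {
  a <- .fpBits(a); b <- .fpBits(b)
  if (length(a) != length(b))
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  un <- sum(a | b)
  if (un == 0) return(0)
  sum(a & b) / un
}

# All-pairs Tanimoto matrix between two FPsets (rows = x, cols = y).
.tanimotoMatrix <- function(fpx, fpy) {
  X <- as.matrix(fpx) * 1; Y <- as.matrix(fpy) * 1
  if (ncol(X) != ncol(Y)) stop("fingerprint length mismatch")
  inter <- X %*% t(Y)
  cx <- rowSums(X); cy <- rowSums(Y)
  un <- outer(cx, cy, `+`) - inter
  out <- ifelse(un > 0, inter / un, 0)
  dimnames(out) <- list(rownames(X), rownames(Y))
  out
}

#' Greedy Tanimoto diversity pruning
#'
#' Walks the molecules in input order and keeps each one unless its
#' Tanimoto similarity to an already-retained molecule is at or above
#' \code{threshold}.  The retained set therefore contains no pair with
#' similarity \eqn{\ge} the threshold, and the rule is deterministic:
#' of a similar pair, the earlier molecule survives.
#'
#' @param molecules a [MoleculeSet-class].
#' @param threshold Tanimoto cutoff in (0, 1]; 0.8 is the conventional
#'   balance between diversity and set size.
#' @return The retained [MoleculeSet-class]; the ids of the dropped
#'   molecules are attached as attribute \code{"excluded"}.
#' @export
diversityPrune <- function(molecules, threshold = 0.8) {
  stopifnot(is(molecules, "MoleculeSet"))
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must lie in (0, 1]")
  fp <- suppressWarnings(moleculeFingerprints(molecules))
  sim <- .tanimotoMatrix(fp, fp)
  n <- length(molecules)
  keep <- logical(n)
  for (i in seq_len(n)) {
    keep[i] <- !any(sim[i, which(keep)] >= threshold)
  }
  out <- molecules[which(keep)]
  attr(out, "excluded") <- molecules@ids[!keep]
  out
}

#' Pairwise similarity summary of two molecule sets
#'
#' Computes the full |X| x |Y| Tanimoto matrix and reduces it to the
#' summaries used when judging the novelty of screening hits: the
#' maximum, counts of pairs above standard cutoffs, and a binned
#' histogram.
#'
#' @param x,y [MoleculeSet-class] objects (non-empty).
#' @param cutoffs similarities above which pairs are counted
#'   (default 0.4 and 0.7).
#' @param breaks histogram bin breaks on [0, 1].
#' @return List with \code{max}, \code{countsAbove} (named by cutoff),
#'   \code{histogram} (data.frame of bin and count), \code{nPairs}, and
#'   the full \code{matrix}.
#' @export
similarityReport <- function(x, y, cutoffs = c(0.4, 0.7),
                             breaks = seq(0, 1, by = 0.1)) {
  stopifnot(is(x, "MoleculeSet"), is(y, "MoleculeSet"))
  fx <- suppressWarnings(moleculeFingerprints(x))
  fy <- suppressWarnings(moleculeFingerprints(y))
  sim <- .tanimotoMatrix(fx, fy)
  h <- hist(as.numeric(sim), breaks = breaks, plot = FALSE)
  list(
    max = max(sim),
    countsAbove = stats::setNames(
      vapply(cutoffs, function(ct) sum(sim > ct), numeric(1)),
      paste0(">", cutoffs)),
    histogram = data.frame(bin = paste0("(", head(breaks, -1), ",",
                                        breaks[-1], "]"),
                           count = h$counts),
    nPairs = length(sim),
    matrix = sim
  )
}

#' Applicability-domain box of a set of actives
#'
#' For each of the four Rule-of-Five descriptors (\code{lip_acc},
#' \code{lip_don}, \code{cLogP}, \code{MW}) computes the actives' mean
#' and sample standard deviation (n-1 denominator) and the acceptance
#' range \eqn{[\mu - 2\sigma, \mu + 2\sigma]}.  Presumed inactives for
#' training are drawn only from inside this box, so that the two classes
#' occupy the same gross region of chemical space and the model learns
#' finer distinctions than "looks like a drug".
#'
#' @param actives a [DescriptorTable-class]; only rows labeled
#'   \code{"active"} are used (all rows if none is labeled).
#' @param descriptors descriptor names defining the box (default the
#'   four RO5 names).
#' @param sigma half-width of the box in standard deviations (default 2).
#' @return data.frame with columns \code{descriptor}, \code{mean},
#'   \code{sd}, \code{low}, \code{high}.
#' @export
domainBox <- function(actives, descriptors = .RO5_DESCRIPTORS, sigma = 2) {
  stopifnot(is(actives, "DescriptorTable"))
  X <- descriptorMatrix(actives)
  lab <- moleculeLabels(actives)
  if (any(lab == "active")) X <- X[lab == "active", , drop = FALSE]
  miss <- setdiff(descriptors, colnames(X))
  if (length(miss))
    stop("applicability-domain descriptor(s) missing from the table: ",
         paste(miss, collapse = ", "))
  mu <- colMeans(X[, descriptors, drop = FALSE])
  sdv <- apply(X[, descriptors, drop = FALSE], 2, sd)
  data.frame(descriptor = descriptors, mean = unname(mu), sd = unname(sdv),
             low = unname(mu - sigma * sdv), high = unname(mu + sigma * sdv),
             stringsAsFactors = FALSE)
}

#' Sample presumed inactives inside the applicability domain
#'
#' Restricts \code{candidates} to those lying inside the actives'
#' \eqn{\pm 2\sigma} box on all four RO5 descriptors, then draws
#' \code{n} of them uniformly at random (all eligible ones, with a
#' warning, if fewer than \code{n} qualify).  Reproducible under
#' \code{seed}.
#'
#' @param actives a [DescriptorTable-class] of labeled actives carrying
#'   the four RO5 descriptors.
#' @param candidates a [DescriptorTable-class] of candidate molecules.
#' @param n number of inactives to draw.
#' @param seed integer seed.
#' @param sigma box half-width in standard deviations (default 2).
#' @return A [DescriptorTable-class] subset of \code{candidates} with
#'   labels set to \code{"inactive"}; the domain box is attached as
#'   attribute \code{"domainBox"}.
#' @export
sampleInactives <- function(actives, candidates, n, seed = 1L, sigma = 2) {
  stopifnot(is(candidates, "DescriptorTable"), n >= 1)
  box <- domainBox(actives, sigma = sigma)
  X <- descriptorMatrix(candidates)
  miss <- setdiff(box$descriptor, colnames(X))
  if (length(miss))
    stop("candidate table lacks descriptor(s): ", paste(miss, collapse = ", "))
  inside <- rep(TRUE, nrow(X))
  perDesc <- integer(nrow(box))
  for (i in seq_len(nrow(box))) {
    okD <- X[, box$descriptor[i]] >= box$low[i] &
           X[, box$descriptor[i]] <= box$high[i]
    perDesc[i] <- sum(okD)
    inside <- inside & okD
  }
  eligible <- which(inside)
  if (!length(eligible)) {
    worst <- box$descriptor[which.min(perDesc)]
    stop("no candidate lies inside the applicability domain; ",
         "most limiting descriptor: ", worst)
  }
  if (length(eligible) < n) {
    warning(sprintf("only %d of the requested %d candidates are eligible; returning all",
                    length(eligible), n), call. = FALSE)
    pick <- eligible
  } else {
    pick <- withr::with_seed(as.integer(seed), sort(sample(eligible, n)))
  }
  out <- candidates[, pick]
  SummarizedExperiment::colData(out)$label <- "inactive"
  out <- new("DescriptorTable", out)
  attr(out, "domainBox") <- box
  out
}
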