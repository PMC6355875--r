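#' Specification of a synthetic descriptor dataset
#'
#' Describes a two-class dataset with known ground truth, emulating an
#' ISE training set of confirmed actives against presumed inactives:
#' informative descriptors are class-shifted unit-variance normals
#' (actives centered at \code{shift}, inactives at 0), noise descriptors
#' are standard normal in both classes.  The default sizes mirror a
#' desk-scale screening exercise: 200 actives against a 10-fold excess
#' of 2000 inactives, 5 informative among 50 descriptors, and a
#' standardized separation of 3.
#'
#' @param nActives,nInactives class sizes (positive).
#' @param nInformative,nNoise descriptor counts.
#' @param shift standardized mean separation on informative descriptors
#'   (\eqn{\ge 0}).
#' @param seed integer seed; the same spec always generates the same
#'   table.
#' @return A validated list of class \code{"SyntheticSpec"}.
#' @seealso [genDescriptorDataset()]
#' @export
syntheticSpec <- function(nActives = 200L, nInactives = 2000L,
                          nInformative = 5L, nNoise = 45L,
                          shift = 3, seed = 11L) {
  spec <- list(nActives = as.integer(nActives),
               nInactives = as.integer(nInactives),
               nInformative = as.integer(nInformative),
               nNoise = as.integer(nNoise),
               shift = as.numeric(shift), seed = as.integer(seed))
  with(spec, {
    if (nActives < 1L || nInactives < 1L) stop("class sizes must be positive")
    if (nInformative < 0L || nNoise < 0L || nInformative + nNoise < 1L)
      stop("need at least one descriptor")
    if (shift < 0) stop("shift must be >= 0")
  })
  class(spec) <- "SyntheticSpec"
  spec
}

#' Generate a labeled synthetic descriptor table
#'
#' Draws the dataset described by a [syntheticSpec()].  Informative
#' descriptors separate the classes by \code{shift} standard deviations;
#' noise descriptors are identically distributed in both classes.  The
#' ground-truth role of every descriptor is recorded in
#' \code{rowData(x)$informative}.  When at least four informative
#' descriptors exist, the first four take the Rule-of-Five names
#' (\code{lip_acc}, \code{lip_don}, \code{cLogP}, \code{MW}) so that
#' curation operations run unchanged on synthetic data; values stay on
#' the standardized scale.
#'
#' @param spec a [syntheticSpec()].
#' @return A [DescriptorTable-class]; byte-identical across runs for a
#'   given spec.
#' @examples
#' dt <- genDescriptorDataset(syntheticSpec(nActives = 20, nInactives = 50,
#'                                          nInformative = 4, nNoise = 6,
#'                                          seed = 3))
#' dt
#' @export
genDescriptorDataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  nMol <- spec$nActives + spec$nInactives
  p <- spec$nInformative + spec$nNoise
  withr::local_seed(spec$seed)
  X <- matrix(rnorm(nMol * p), nMol, p)
  if (spec$nInformative > 0) {
    X[seq_len(spec$nActives), seq_len(spec$nInformative)] <-
      X[seq_len(spec$nActives), seq_len(spec$nInformative)] + spec$shift
  }
  infNames <- if (spec$nInformative >= 4L) {
    c(.RO5_DESCRIPTORS, sprintf("inf%02d", seq_len(max(0, spec$nInformative - 4L)) + 4L))
  } else if (spec$nInformative > 0) {
    sprintf("inf%02d", seq_len(spec$nInformative))
  } else character(0)
  colnames(X) <- c(infNames, sprintf("noise%02d", seq_len(spec$nNoise)))
  rownames(X) <- c(sprintf("A%05d", seq_len(spec$nActives)),
                   sprintf("I%05d", seq_len(spec$nInactives)))
  DescriptorTable(X,
                  labels = rep(c("active", "inactive"),
                               c(spec$nActives, spec$nInactives)),
                  informative = rep(c(TRUE, FALSE),
                                    c(spec$nInformative, spec$nNoise)))
}

# ---- toy receptor/pose fixtures -------------------------------------------

.POSE_SPACING <- 100   # A between pose anchor points
.MAX_PLAN_DIST <- 25   # keeps each pose's nearest residue atom unambiguous

#' Plan a toy receptor-ligand complex
#'
#' A plan fixes, for every pose and every binding-site residue, the
#' intended minimum heavy-atom distance.  [genToyComplex()] then emits
#' coordinates realizing those distances exactly (to file-format
#' precision), so pose-filter verdicts have an analytic ground truth.
#'
#' @param distances nPoses x nResidues numeric matrix of intended
#'   minimum distances in Angstrom; all must lie in (0, 25) -- the
#'   construction separates poses by 100 A, and larger values would make
#'   a residue's nearest atom ambiguous (infeasible plans are fatal).
#' @param roles character per residue: \code{"crucial"} or
#'   \code{"important"} (crucial residues are important too).
#' @param energies optional energy score per pose (lower = better);
#'   defaults to \code{-10, -9.5, ...}.
#' @return A list of class \code{"ToyComplexPlan"}.
#' @export
toyComplexPlan <- function(distances, roles, energies = NULL) {
  distances <- as.matrix(distances)
  if (length(roles) != ncol(distances))
    stop("one role per residue (column) required")
  if (!all(roles %in% c("crucial", "important")))
    stop("roles must be 'crucial' or 'important'")
  if (any(!is.finite(distances)) || any(distances <= 0) ||
      any(distances >= .MAX_PLAN_DIST))
    stop("infeasible plan: all distances must lie in (0, ", .MAX_PLAN_DIST,
         ") Angstrom")
  if (is.null(energies)) energies <- -10 + 0.5 * (seq_len(nrow(distances)) - 1)
  if (length(energies) != nrow(distances))
    stop("one energy per pose required")
  structure(list(distances = distances, roles = roles,
                 energies = as.numeric(energies)),
            class = "ToyComplexPlan")
}

# Analytic verdicts implied by a plan under given criteria thresholds.
.planTruth <- function(plan, dCrucial = 3.5, dImportant = 5.0,
                       minCrucial = 2, minImportant = 7) {
  cru <- plan$roles == "crucial"
  nCru <- rowSums(plan$distances[, cru, drop = FALSE] < dCrucial)
  nImp <- rowSums(plan$distances < dImportant)  # crucial residues count as important
  posePass <- nCru >= minCrucial & nImp >= minImportant
  sel <- NA_integer_
  if (any(posePass)) {
    cand <- which(posePass)
    sel <- cand[order(plan$energies[cand], cand)][1L]
  }
  list(posePass = posePass, accepted = any(posePass), selectedPose = sel)
}

#' Generate a toy receptor / pose fixture with known verdicts
#'
#' Builds a synthetic single-chain receptor (glycine-like one-residue
#' placeholders with explicit O and N atoms) and a multi-record pose SDF
#' realizing a [toyComplexPlan()]'s distances to within 0.01 A, plus the
#' matching [GeometryCriteria-class] and the analytically derived
#' ground-truth verdicts.  Each pose is a single heavy atom (an oxygen)
#' anchored 100 A from its neighbours; every residue contributes one
#' contact atom per pose at exactly the planned distance, which makes
#' arbitrary per-pose distance plans geometrically consistent.  These
#' fixtures exercise file parsing, contact typing and the pose filter --
#' they are not chemistry.
#'
#' @param plan a [toyComplexPlan()].
#' @param dir directory for \code{receptor.pdb} / \code{poses.sdf}; NULL
#'   (default) keeps everything in memory.
#' @param seed integer seed for the residue direction vectors.
#' @return List: \code{protein} (receptor table), \code{poses}
#'   ([PoseSet-class]), \code{criteria}, \code{truth} (from the plan),
#'   and file paths when \code{dir} was given.
#' @export
genToyComplex <- function(plan, dir = NULL, seed = 1L) {
  stopifnot(inherits(plan, "ToyComplexPlan"))
  nPose <- nrow(plan$distances); nRes <- ncol(plan$distances)
  withr::local_seed(as.integer(seed))

  anchors <- cbind((seq_len(nPose) - 1) * .POSE_SPACING, 0, 0)
  rows <- list()
  for (r in seq_len(nRes)) {
    resid <- if (plan$roles[r] == "crucial") "HIS" else "LEU"
    # one contact atom per pose at the planned distance, O for crucial
    # (H-bond capable), C otherwise; plus a backbone-like N further out
    for (p in seq_len(nPose)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      at <- anchors[p, ] + plan$distances[p, r] * u
      rows[[length(rows) + 1L]] <- data.frame(
        key = .resKey("A", resid, r), chain = "A", resid = resid, resno = r,
        elety = if (plan$roles[r] == "crucial") "OD1" else "CD1",
        element = if (plan$roles[r] == "crucial") "O" else "C",
        x = at[1], y = at[2], z = at[3], het = FALSE,
        stringsAsFactors = FALSE)
      far <- anchors[p, ] + (plan$distances[p, r] + 1.5) * u
      rows[[length(rows) + 1L]] <- data.frame(
        key = .resKey("A", resid, r), chain = "A", resid = resid, resno = r,
        elety = "N", element = "N",
        x = far[1], y = far[2], z = far[3], het = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  protein <- do.call(rbind, rows)
  # round to PDB precision so in-memory and re-read geometry agree
  protein[, c("x", "y", "z")] <- round(protein[, c("x", "y", "z")], 3)

  # two coincident ligand atoms: minimum distances equal the plan exactly,
  # and the SDF record keeps a bond (single-atom records parse poorly)
  poses <- PoseSet(
    coords = lapply(seq_len(nPose),
                    function(p) rbind(anchors[p, ], anchors[p, ])),
    elements = rep(list(c("O", "O")), nPose),
    energy = plan$energies)

  keys <- unique(protein$key)
  roleOf <- plan$roles[match(as.integer(sub(".*:", "", keys)), seq_len(nRes))]
  criteria <- GeometryCriteria(
    crucial = keys[roleOf == "crucial"], important = keys,
    minImportant = min(7, length(keys)))

  out <- list(protein = protein, poses = poses, criteria = criteria,
              truth = .planTruth(plan,
                                 dCrucial = criteria@dCrucial,
                                 dImportant = criteria@dImportant,
                                 minCrucial = criteria@minCrucial,
                                 minImportant = criteria@minImportant),
              plan = plan)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$receptorFile <- file.path(dir, "receptor.pdb")
    out$poseFile <- file.path(dir, "poses.sdf")
    out$criteriaFile <- file.path(dir, "criteria.cfg")
    bio3d::write.pdb(file = out$receptorFile,
                     xyz = as.numeric(t(as.matrix(protein[, c("x", "y", "z")]))),
                     resno = protein$resno, resid = protein$resid,
                     elety = protein$elety, chain = protein$chain,
                     elesy = protein$element)
    .writePoseSDF(poses, out$poseFile)
    writeGeometryCriteria(criteria, out$criteriaFile)
  }
  out
}

#' Draw a random feasible toy-complex plan
#'
#' Distances are drawn uniformly between 2 and 8 Angstrom, avoiding a
#' +-0.05 A guard band around the 3.5 / 5.0 A decision thresholds so
#' that file-format rounding (0.001 A in PDB) can never flip a verdict.
#'
#' @param nCrucial,nImportant residue counts (important excludes the
#'   crucial ones here; both roles are emitted).
#' @param nPoses number of poses.
#' @return A [toyComplexPlan()].  Consumes the current random stream.
#' @export
randomToyPlan <- function(nCrucial = 3L, nImportant = 8L, nPoses = 5L) {
  nRes <- nCrucial + nImportant
  draw <- function(n) {
    d <- runif(n, 2, 8)
    bad <- (abs(d - 3.5) < 0.05) | (abs(d - 5.0) < 0.05)
    while (any(bad)) {
      d[bad] <- runif(sum(bad), 2, 8)
      bad <- (abs(d - 3.5) < 0.05) | (abs(d - 5.0) < 0.05)
    }
    d
  }
  toyComplexPlan(matrix(draw(nPoses * nRes), nPoses, nRes),
                 roles = rep(c("crucial", "important"), c(nCrucial, nImportant)),
                 energies = round(runif(nPoses, -12, -4), 2))
}

# Minimal V2000 SDF writer for pose fixtures (chain-bonded atoms,
# energy tag); always re-read through ChemmineR's parser.
.writePoseSDF <- function(poses, path, energyTag = "ENERGY") {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(poses@energy)) {
    xyz <- poses@coords[[i]]
    n <- nrow(xyz)
    nb <- max(0L, n - 1L)
    writeLines(c(
      poses@poseIds[i], "  iseScreen toy pose", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              xyz[, 1], xyz[, 2], xyz[, 3], poses@elements[[i]]),
      if (nb > 0) sprintf("%3d%3d  1  0  0  0  0", seq_len(nb), seq_len(nb) + 1L),
      "M  END",
      sprintf(">  <%s>", energyTag),
      sprintf("%.4f", poses@energy[i]),
      "", "$$$$"), con)
  }
  invisible(path)
}
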