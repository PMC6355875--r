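#' @importFrom bio3d read.pdb write.pdb
NULL

# Residue identity string used throughout the geometry module.
.resKey <- function(chain, resid, resno) paste(chain, resid, resno, sep = ":")

#' Read a receptor structure from PDB
#'
#' Loads ATOM/HETATM records, drops hydrogens and waters, and returns a
#' heavy-atom table addressed by \code{"chain:resName:resSeq"} keys.
#' Ligand atoms (HETATM with residue name \code{ligandResid}) can be
#' extracted with [receptorLigand()].
#'
#' @param path PDB file.
#' @return data.frame with columns \code{key}, \code{chain},
#'   \code{resid}, \code{resno}, \code{elety}, \code{element}, \code{x},
#'   \code{y}, \code{z} and a logical \code{het} flag.
#' @export
readReceptor <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  noEl <- is.na(elem) | !nzchar(trimws(elem))
  elem[noEl] <- substr(trimws(at$elety[noEl]), 1L, 1L)
  elem <- toupper(trimws(elem))
  keep <- elem != "H" & at$resid != "HOH"
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (!nrow(at)) stop("no heavy atoms in ", path)
  data.frame(key = .resKey(at$chain, at$resid, at$resno),
             chain = at$chain, resid = at$resid, resno = at$resno,
             elety = trimws(at$elety), element = elem,
             x = at$x, y = at$y, z = at$z,
             het = at$type == "HETATM",
             stringsAsFactors = FALSE)
}

#' @describeIn readReceptor split a receptor table into protein residues
#'   and the bound ligand's heavy atoms (by HETATM residue name).
#' @param receptor a receptor table from \code{readReceptor}.
#' @param ligandResid HETATM residue name of the ligand.
#' @return \code{receptorLigand}: list with \code{protein} (table) and
#'   \code{ligand} (list of \code{coords} matrix and \code{elements}).
#' @export
receptorLigand <- function(receptor, ligandResid) {
  lig <- receptor[receptor$het & receptor$resid == ligandResid, , drop = FALSE]
  if (!nrow(lig))
    stop("no HETATM atoms with residue name '", ligandResid, "'")
  list(protein = receptor[!receptor$het, , drop = FALSE],
       ligand = list(coords = as.matrix(lig[, c("x", "y", "z")]),
                     elements = lig$element))
}

#' Read docked poses from SDF
#'
#' One conformer per SDF record; the energy score is taken from the
#' named data field (lower = better).  Hydrogens are dropped.
#'
#' @param path SDF file of poses.
#' @param energyTag name of the SDF data field holding the energy score.
#' @return A [PoseSet-class].
#' @export
readPoses <- function(path, energyTag = "ENERGY") {
  sdf <- read.SDFset(path)
  if (!length(sdf)) stop("no poses in ", path)
  coords <- list(); elements <- list(); energy <- numeric(length(sdf))
  for (i in seq_along(sdf)) {
    ab <- atomblock(sdf[[i]])
    el <- toupper(sub("_.*$", "", rownames(ab)))
    heavy <- el != "H"
    coords[[i]] <- unname(as.matrix(ab[heavy, 1:3, drop = FALSE]))
    elements[[i]] <- el[heavy]
    db <- datablock(sdf[[i]])
    if (!energyTag %in% names(db))
      stop("pose record ", i, " in ", path, " lacks the energy field '",
           energyTag, "'")
    energy[i] <- as.numeric(db[[energyTag]])
  }
  PoseSet(coords, elements, energy, poseIds = sdfid(sdf))
}

# Minimum Euclidean distance between two coordinate sets.
.minDist <- function(A, B) {
  A <- matrix(as.numeric(A), ncol = 3); B <- matrix(as.numeric(B), ncol = 3)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Minimum residue-ligand heavy-atom distance
#'
#' The distance from a residue to a ligand pose is the minimum Euclidean
#' distance over all residue-heavy-atom x ligand-heavy-atom pairs
#' (side chain and backbone alike).
#'
#' @param residueCoords nAtoms x 3 matrix of the residue's heavy atoms.
#' @param ligandCoords nAtoms x 3 matrix of the pose's heavy atoms.
#' @return Distance in Angstrom.
#' @examples
#' residueLigandDistance(rbind(c(0, 0, 0), c(10, 0, 0)), rbind(c(4, 0, 0)))
#' @export
residueLigandDistance <- function(residueCoords, ligandCoords) {
  .minDist(residueCoords, ligandCoords)
}

#' Contact profile of one receptor-ligand complex
#'
#' Classifies every protein residue's contact with the ligand:
#' \code{vdw} when any heavy-atom pair is within \code{vdwMax} (3.9 A by
#' default) and \code{hbond} when any N/O-N/O donor-acceptor pair is
#' within \code{hbondMax} (3.3 A).  An H-bond contact implies a van der
#' Waals contact in the output.
#'
#' @param protein receptor table ([readReceptor()]) restricted to
#'   protein atoms.
#' @param ligand list with \code{coords} (matrix) and \code{elements},
#'   as returned by [receptorLigand()], or a bare coordinate matrix of
#'   unknown elements (then no H-bond typing is possible).
#' @param hbondMax,vdwMax contact cutoffs in Angstrom.
#' @return data.frame with columns \code{key}, \code{minDist},
#'   \code{hbond}, \code{vdw}, one row per residue.
#' @export
contactProfile <- function(protein, ligand, hbondMax = 3.3, vdwMax = 3.9) {
  if (is.matrix(ligand)) ligand <- list(coords = ligand,
                                        elements = rep("C", nrow(ligand)))
  ligNO <- ligand$elements %in% c("N", "O")
  keys <- unique(protein$key)
  rows <- lapply(keys, function(k) {
    res <- protein[protein$key == k, , drop = FALSE]
    rc <- as.matrix(res[, c("x", "y", "z")])
    dmin <- .minDist(rc, ligand$coords)
    hb <- FALSE
    resNO <- res$element %in% c("N", "O")
    if (any(resNO) && any(ligNO))
      hb <- .minDist(rc[resNO, , drop = FALSE],
                     ligand$coords[ligNO, , drop = FALSE]) <= hbondMax
    vdw <- dmin <= vdwMax || hb
    data.frame(key = k, minDist = dmin, hbond = hb, vdw = vdw,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Derive consensus important / crucial residues
#'
#' Aggregates contact profiles of several reference complexes of the
#' same target.  Under the default rule, a residue is \emph{important}
#' when it contacts more than \code{minLigands} of the ligands or forms
#' an H-bond with at least one; under the \code{"fraction"} rule it is
#' important when it contacts at least \code{fraction} of the ligands.
#' Residues that H-bond \emph{every} ligand are \emph{crucial to
#' H-bonds} (and important).  An empty crucial set degrades the pose
#' filter and triggers a warning.
#'
#' @param profiles list of data.frames from [contactProfile()], one per
#'   complex.
#' @param rule \code{"contacts"} (default) or \code{"fraction"}.
#' @param minLigands contact-count threshold of the default rule (3).
#' @param fraction ligand fraction of the alternative rule (0.7).
#' @param ... further arguments passed to [GeometryCriteria()].
#' @return A [GeometryCriteria-class] (with \code{minImportant} capped
#'   at the important-set size).
#' @export
deriveConsensusResidues <- function(profiles, rule = c("contacts", "fraction"),
                                    minLigands = 3, fraction = 0.7, ...) {
  rule <- match.arg(rule)
  stopifnot(length(profiles) >= 1)
  m <- length(profiles)
  all <- do.call(rbind, profiles)
  agg <- do.call(rbind, lapply(split(all, all$key), function(d) {
    data.frame(key = d$key[1], nContact = sum(d$vdw), nHbond = sum(d$hbond))
  }))
  important <- if (rule == "contacts") {
    agg$key[agg$nContact > minLigands | agg$nHbond >= 1]
  } else {
    agg$key[agg$nContact >= fraction * m]
  }
  crucial <- agg$key[agg$nHbond == m]
  important <- union(important, crucial)
  if (!length(crucial))
    warning("no residue H-bonds every reference ligand; the crucial set is empty ",
            "and the pose filter degenerates", call. = FALSE)
  dots <- list(...)
  minImp <- dots$minImportant %||% 7
  dots$minImportant <- min(minImp, length(important))
  do.call(GeometryCriteria,
          c(list(crucial = crucial, important = important), dots))
}

#' Does one docking pose satisfy the geometric criteria?
#'
#' TRUE iff the pose lies closer than \code{dCrucial} (strict) to at
#' least \code{minCrucial} crucial-to-H-bond residues \emph{and} closer
#' than \code{dImportant} (strict) to at least \code{minImportant}
#' important residues, distances being whole-residue heavy-atom minima.
#'
#' @param poseCoords nAtoms x 3 heavy-atom matrix of the pose.
#' @param protein receptor table ([readReceptor()]), protein atoms.
#' @param criteria a [GeometryCriteria-class].
#' @return Logical scalar; counts attached as attributes
#'   \code{"nCrucial"} and \code{"nImportant"}.
#' @export
posePasses <- function(poseCoords, protein, criteria) {
  stopifnot(is(criteria, "GeometryCriteria"))
  distTo <- function(keys) {
    vapply(keys, function(k) {
      res <- protein[protein$key == k, c("x", "y", "z"), drop = FALSE]
      if (!nrow(res)) stop("criteria residue not present in receptor: ", k)
      .minDist(as.matrix(res), poseCoords)
    }, numeric(1))
  }
  nCru <- sum(distTo(criteria@crucial) < criteria@dCrucial)
  nImp <- sum(distTo(criteria@important) < criteria@dImportant)
  out <- nCru >= criteria@minCrucial && nImp >= criteria@minImportant
  attr(out, "nCrucial") <- nCru
  attr(out, "nImportant") <- nImp
  out
}

#' Accept or reject a molecule from its docked poses
#'
#' A molecule is accepted when at least one of its (at most 30) poses
#' satisfies the geometric criteria; the selected pose is then the
#' lowest-energy passing pose (ties broken by pose index).  More than 30
#' poses are truncated to the 30 best energies with a warning.
#'
#' @param poses a [PoseSet-class].
#' @param protein receptor table ([readReceptor()]), protein atoms.
#' @param criteria a [GeometryCriteria-class].
#' @param maxPoses pose budget per molecule (default 30).
#' @return List: \code{accepted} (logical), \code{pose} (selected pose
#'   id or NA), \code{energy} (its score or NA), \code{nPassing}.
#' @export
moleculeDockVerdict <- function(poses, protein, criteria, maxPoses = 30L) {
  stopifnot(is(poses, "PoseSet"))
  n <- length(poses@energy)
  idx <- seq_len(n)
  if (n > maxPoses) {
    warning(sprintf("%d poses supplied; truncating to the %d best energies",
                    n, maxPoses), call. = FALSE)
    idx <- order(poses@energy)[seq_len(maxPoses)]
    idx <- sort(idx)                     # keep original pose order
  }
  pass <- vapply(idx, function(i)
    as.logical(posePasses(poses@coords[[i]], protein, criteria)), logical(1))
  if (!any(pass))
    return(list(accepted = FALSE, pose = NA_character_, energy = NA_real_,
                nPassing = 0L))
  cand <- idx[pass]
  sel <- cand[order(poses@energy[cand], cand)][1L]
  list(accepted = TRUE, pose = poses@poseIds[sel], energy = poses@energy[sel],
       nPassing = sum(pass))
}

#' Consensus vote across receptor structures
#'
#' A molecule survives when it was accepted against at least
#' \code{required} of the reference structures (default: all of them).
#'
#' @param verdicts logical matrix, molecules x structures (TRUE =
#'   accepted), or a list of per-structure logical vectors.
#' @param required minimum number of accepting structures.
#' @return data.frame with \code{id}, \code{votes}, \code{accepted};
#'   the 3/2/1-structure tally is attached as attribute \code{"tally"}.
#' @export
consensusVote <- function(verdicts, required = NULL) {
  if (is.list(verdicts) && !is.data.frame(verdicts))
    verdicts <- do.call(cbind, verdicts)
  verdicts <- as.matrix(verdicts)
  if (is.null(required)) required <- ncol(verdicts)
  stopifnot(required >= 1, required <= ncol(verdicts))
  votes <- rowSums(verdicts)
  ids <- rownames(verdicts)
  if (is.null(ids)) ids <- sprintf("M%06d", seq_len(nrow(verdicts)))
  out <- data.frame(id = ids, votes = as.integer(votes),
                    accepted = votes >= required, stringsAsFactors = FALSE)
  tal <- table(factor(votes, levels = ncol(verdicts):0))
  attr(out, "tally") <- tal
  out
}

#' Read / write geometry criteria as a text config
#'
#' Plain-text format: one entry per line, \code{crucial} or
#' \code{important} followed by a \code{chain:resName:resSeq} id, plus
#' optional \code{set <param> <value>} lines for the thresholds
#' (\code{dCrucial}, \code{dImportant}, \code{minCrucial},
#' \code{minImportant}, \code{hbondMax}, \code{vdwMax});
#' \code{#} starts a comment.
#'
#' @param path config file path.
#' @return \code{readGeometryCriteria}: a [GeometryCriteria-class].
#' @export
readGeometryCriteria <- function(path) {
  if (!file.exists(path)) stop("criteria file not found: ", path)
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  args <- list(crucial = character(0), important = character(0))
  for (l in ln) {
    tok <- strsplit(l, "[ \t]+")[[1]]
    if (tok[1] %in% c("crucial", "important")) {
      args[[tok[1]]] <- c(args[[tok[1]]], tok[2])
    } else if (tok[1] == "set" && length(tok) == 3L) {
      args[[tok[2]]] <- as.numeric(tok[3])
    } else stop("cannot parse criteria line: ", l)
  }
  args$important <- union(args$important, args$crucial)
  do.call(GeometryCriteria, args)
}

#' @rdname readGeometryCriteria
#' @param criteria a [GeometryCriteria-class] to write.
#' @export
writeGeometryCriteria <- function(criteria, path) {
  stopifnot(is(criteria, "GeometryCriteria"))
  ln <- c("# iseScreen geometry criteria",
          paste("crucial", criteria@crucial),
          paste("important", setdiff(criteria@important, criteria@crucial)),
          sprintf("set dCrucial %g", criteria@dCrucial),
          sprintf("set dImportant %g", criteria@dImportant),
          sprintf("set minCrucial %g", criteria@minCrucial),
          sprintf("set minImportant %g", criteria@minImportant),
          sprintf("set hbondMax %g", criteria@hbondMax),
          sprintf("set vdwMax %g", criteria@vdwMax))
  writeLines(ln, path)
  invisible(path)
}

setMethod("show", "GeometryCriteria", function(object) {
  cat("GeometryCriteria:\n")
  cat(sprintf("  crucial (%d, < %.1f A to >= %g): %s\n",
              length(object@crucial), object@dCrucial, object@minCrucial,
              paste(object@crucial, collapse = ", ")))
  cat(sprintf("  important (%d, < %.1f A to >= %g): %s\n",
              length(object@important), object@dImportant, object@minImportant,
              paste(object@important, collapse = ", ")))
  cat(sprintf("  contact typing: hbond <= %.1f A, vdw <= %.1f A\n",
              object@hbondMax, object@vdwMax))
})

setMethod("show", "PoseSet", function(object) {
  cat(sprintf("PoseSet of %d poses (energy %.2f .. %.2f)\n",
              length(object@energy), min(object@energy), max(object@energy)))
})
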