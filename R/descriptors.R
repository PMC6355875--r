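#' @importFrom ChemmineR propOB atomcountMA rings groups atomblock bondblock
NULL

# SMARTS patterns behind the counted descriptors.  lip_acc / lip_don
# follow the Rule-of-Five semantics: all N+O atoms, and all N/O atoms
# bearing at least one hydrogen (OH + NH).
.SMARTS_DESCRIPTORS <- c(
  lip_acc          = "[#7,#8]",
  lip_don          = "[#7!H0,#8!H0]",
  rotatable_bonds  = "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]",
  sp3_carbons      = "[CX4]",
  aromatic_atoms   = "[a]",
  heteroaromatic_atoms = "[a;!#6]",
  halogen_atoms    = "[F,Cl,Br,I]",
  carbonyl_groups  = "[CX3]=[OX1]",
  amide_groups     = "[NX3][CX3]=[OX1]",
  positive_atoms   = "[+,++,+++]",
  negative_atoms   = "[-,--,---]",
  ring_atoms       = "[R]"
)

.ELEMENT_DESCRIPTORS <- c(n_carbon = "C", n_nitrogen = "N", n_oxygen = "O",
                          n_sulfur = "S", n_fluorine = "F", n_chlorine = "Cl",
                          n_bromine = "Br", n_phosphorus = "P")

.GROUP_DESCRIPTORS <- c("RNH2", "R2NH", "R3N", "ROPO3", "ROH", "RCHO", "RCOR",
                        "RCOOH", "RCOOR", "ROR", "RCCH", "RCN")

#' Names of the default 2D descriptor set
#'
#' Forty-plus 2D physico-chemical descriptors computed by
#' [computeDescriptors()]: Open Babel property estimates (\code{MW},
#' \code{cLogP}, \code{TPSA}, molar refractivity, H-bond donor/acceptor
#' counts), SMARTS-counted features (rotatable bonds, aromatic and
#' charged atoms, functional groups), element counts and simple graph
#' statistics.  The four applicability-domain descriptors keep their
#' Rule-of-Five semantics under the pinned names \code{lip_acc} (all
#' N+O), \code{lip_don} (all OH+NH), \code{cLogP} and \code{MW}.
#'
#' @return Character vector of descriptor names.
#' @export
defaultDescriptorSet <- function() {
  c("MW", "cLogP", "TPSA", "molar_refractivity", "HBA1", "HBA2", "HBD",
    names(.SMARTS_DESCRIPTORS), names(.ELEMENT_DESCRIPTORS),
    .GROUP_DESCRIPTORS,
    "heavy_atoms", "bond_count", "double_bonds", "triple_bonds",
    "ring_count", "aromatic_fraction", "heteroatom_fraction")
}

#' Compute 2D physico-chemical descriptors
#'
#' Produces a labeled [DescriptorTable-class] with one value per molecule
#' and descriptor.  All descriptors are 2D (connectivity-based), hence
#' deterministic for a given structure and invariant under atom-order
#' permutation.  Count descriptors are non-negative integers.  Molecules
#' for which a descriptor is undefined get \code{NaN} and are reported in
#' a warning; drop them before training.
#'
#' @param molecules a [MoleculeSet-class].
#' @param descriptors character vector of descriptor names to keep, a
#'   subset of [defaultDescriptorSet()] (default: all of it).
#' @return A [DescriptorTable-class] with the molecules' labels.
#' @examples
#' \donttest{
#' tf <- tempfile(fileext = ".smi")
#' writeLines(c("CCO ethanol", "c1ccccc1 benzene"), tf)
#' dt <- computeDescriptors(readMolecules(tf))
#' descriptorMatrix(dt)[, c("MW", "lip_acc", "lip_don")]
#' }
#' @export
computeDescriptors <- function(molecules, descriptors = defaultDescriptorSet()) {
  stopifnot(is(molecules, "MoleculeSet"))
  unknown <- setdiff(descriptors, defaultDescriptorSet())
  if (length(unknown))
    stop("unknown descriptor name(s): ", paste(unknown, collapse = ", "))
  if (!length(descriptors)) stop("descriptor specification must be non-empty")
  sdf <- molecules@sdf
  n <- length(sdf)

  prop <- propOB(sdf)
  out <- matrix(NA_real_, n, length(defaultDescriptorSet()),
                dimnames = list(molecules@ids, defaultDescriptorSet()))
  out[, "MW"] <- prop$MW
  out[, "cLogP"] <- prop$logP
  out[, "TPSA"] <- prop$TPSA
  out[, "molar_refractivity"] <- prop$MR
  out[, "HBA1"] <- prop$HBA1
  out[, "HBA2"] <- prop$HBA2
  out[, "HBD"] <- prop$HBD

  for (nm in names(.SMARTS_DESCRIPTORS))
    out[, nm] <- .smartsCount(sdf, .SMARTS_DESCRIPTORS[[nm]])

  ac <- atomcountMA(sdf, addH = FALSE)
  if (is.null(dim(ac))) ac <- matrix(ac, nrow = n, dimnames = list(NULL, names(ac)))
  for (nm in names(.ELEMENT_DESCRIPTORS)) {
    el <- .ELEMENT_DESCRIPTORS[[nm]]
    out[, nm] <- if (el %in% colnames(ac)) ac[, el] else 0
  }
  heavy <- rowSums(ac)
  out[, "heavy_atoms"] <- heavy

  grp <- groups(sdf, groups = "fctgroup")
  for (nm in .GROUP_DESCRIPTORS) out[, nm] <- grp[, nm]

  bonds <- lapply(seq_len(n), function(i) bondblock(sdf[[i]]))
  out[, "bond_count"] <- vapply(bonds, nrow, numeric(1))
  out[, "double_bonds"] <- vapply(bonds, function(b) sum(b[, 3] == 2), numeric(1))
  out[, "triple_bonds"] <- vapply(bonds, function(b) sum(b[, 3] == 3), numeric(1))
  out[, "ring_count"] <- unlist(rings(sdf, type = "count"), use.names = FALSE)
  out[, "aromatic_fraction"] <- ifelse(heavy > 0, out[, "aromatic_atoms"] / heavy, NaN)
  out[, "heteroatom_fraction"] <- ifelse(heavy > 0, (heavy - out[, "n_carbon"]) / heavy, NaN)

  out <- out[, descriptors, drop = FALSE]
  ok <- rowSums(!is.finite(out)) == 0
  if (any(!ok)) {
    warning(sprintf("descriptors undefined for %d molecule(s), excluded: %s",
                    sum(!ok), paste(head(rownames(out)[!ok], 5L), collapse = ", ")),
            call. = FALSE)
    out <- out[ok, , drop = FALSE]
    if (!nrow(out)) stop("no molecule with a complete descriptor vector")
  }
  DescriptorTable(out, labels = molecules@label[ok])
}
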