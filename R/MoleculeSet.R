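#' @importFrom ChemmineR read.SDFset write.SDF smiles2sdf sdfid validSDF
#'   datablock atomblock bondblock cid 'cid<-' fpSim
#' @importFrom ChemmineOB convertFormat forEachMol smartsSearch_OB
NULL

#' A set of small molecules with ids, canonical SMILES and labels
#'
#' Thin wrapper around a ChemmineR \code{SDFset} that pins the three
#' things every downstream step relies on: a unique id per molecule, a
#' canonical SMILES (recomputed by Open Babel on ingest, so two input
#' spellings of the same structure compare equal), and an activity label.
#'
#' @slot sdf a \code{ChemmineR::SDFset} with one record per molecule.
#' @slot ids unique molecule identifiers.
#' @slot smiles canonical SMILES, parallel to \code{ids}.
#' @slot label activity labels (\code{"active"}, \code{"inactive"},
#'   \code{"unknown"}).
#' @seealso [readMolecules()], [computeDescriptors()], [moleculeFingerprints()]
#' @export
setClass("MoleculeSet",
  representation(sdf = "ANY", ids = "character", smiles = "character",
                 label = "character")
)

setValidity("MoleculeSet", function(object) {
  n <- length(object@ids)
  if (n < 1L) return("molecule set must not be empty")
  if (anyDuplicated(object@ids)) return("molecule ids must be unique")
  if (length(object@smiles) != n || length(object@label) != n)
    return("ids, smiles and label must have equal length")
  if (!all(object@label %in% .LABEL_LEVELS))
    return("labels must be 'active', 'inactive' or 'unknown'")
  if (!is(object@sdf, "SDFset") || length(object@sdf) != n)
    return("sdf must be an SDFset with one record per molecule")
  TRUE
})

setMethod("show", "MoleculeSet", function(object) {
  lab <- table(factor(object@label, levels = .LABEL_LEVELS))
  cat("MoleculeSet of", length(object@ids), "molecules",
      sprintf("(%d active / %d inactive / %d unknown)\n",
              lab[["active"]], lab[["inactive"]], lab[["unknown"]]))
  k <- min(3L, length(object@ids))
  for (i in seq_len(k))
    cat(sprintf("  %s  %s\n", object@ids[i], object@smiles[i]))
  if (length(object@ids) > k) cat("  ...\n")
})

#' @describeIn MoleculeSet-class canonical SMILES strings.
#' @param x a \code{MoleculeSet}.
#' @export
canonicalSmiles <- function(x) {
  stopifnot(is(x, "MoleculeSet"))
  x@smiles
}

#' Canonicalize SMILES strings
#'
#' Round-trips each SMILES through Open Babel's canonical writer;
#' idempotent, so alternative spellings of one structure map to one
#' string.  Unparsable inputs yield \code{NA}.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES (NA where invalid).
#' @examples
#' canonicalizeSmiles(c("OCC", "CCO"))  # both "CCO"
#' @export
canonicalizeSmiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    out <- tryCatch(
      suppressWarnings(convertFormat("SMI", "CAN", paste0(s, "\n"))),
      error = function(e) ""
    )
    out <- sub("[ \t].*$", "", trimws(strsplit(out, "\n")[[1]][1]))
    if (is.na(out) || !nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Parse one SMILES into a single-record SDFset, NULL when invalid.
.smilesToSdf <- function(smiles, id) {
  sdf <- tryCatch(
    suppressWarnings(smiles2sdf(stats::setNames(smiles, id))),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) != 1L || !all(validSDF(sdf))) return(NULL)
  sdf
}

# Assemble a MoleculeSet from parallel vectors of raw SMILES.
.moleculeSetFromSmiles <- function(smiles, ids, labels, source = "input") {
  stopifnot(length(smiles) == length(ids))
  if (length(labels) == 1L) labels <- rep(labels, length(smiles))
  parsed <- mapply(.smilesToSdf, smiles, ids, SIMPLIFY = FALSE)
  bad <- vapply(parsed, is.null, logical(1))
  if (any(bad)) {
    warning(sprintf("%d of %d structures in %s could not be parsed: %s",
                    sum(bad), length(smiles), source,
                    paste(head(ids[bad], 5L), collapse = ", ")),
            call. = FALSE)
  }
  if (all(bad)) return(NULL)
  sdf <- new("SDFset", SDF = lapply(parsed[!bad], function(s) s[[1]]),
             ID = ids[!bad])
  new("MoleculeSet", sdf = sdf, ids = ids[!bad],
      smiles = canonicalizeSmiles(smiles[!bad]), label = labels[!bad])
}

#' Read molecules from SMILES, SDF or CSV
#'
#' Structures are canonicalized on ingest.  Records that fail to parse
#' are reported in one summary warning and dropped, never silently.
#'
#' Formats: \code{"smiles"} is one molecule per line with an optional id
#' after whitespace (missing ids become \code{"M000001"}-style);
#' \code{"sdf"} is V2000 SDF, with an optional \code{label} data field;
#' \code{"csv"} needs columns \code{id} and \code{smiles} plus an
#' optional \code{label}.
#'
#' @param path input file.
#' @param format one of \code{"smiles"}, \code{"sdf"}, \code{"csv"}
#'   (default guessed from the file extension).
#' @param label default activity label for formats that carry none.
#' @return A [MoleculeSet-class]; error if no record parses.
#' @export
readMolecules <- function(path, format = c("auto", "smiles", "sdf", "csv"),
                          label = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("molecule file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", mol = "sdf", csv = "csv",
                     smi = "smiles", smiles = "smiles", txt = "smiles",
                     stop("cannot guess molecule format from extension '",
                          ext, "'; pass format= explicitly"))
  }
  ms <- switch(format,
    smiles = {
      ln <- trimws(readLines(path, warn = FALSE))
      ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
      if (!length(ln)) stop("no molecule lines in ", path)
      tok <- strsplit(ln, "[ \t]+")
      smi <- vapply(tok, `[[`, character(1), 1L)
      ids <- vapply(tok, function(t) if (length(t) > 1L) t[[2]] else NA_character_,
                    character(1))
      ids[is.na(ids)] <- sprintf("M%06d", which(is.na(ids)))
      .moleculeSetFromSmiles(smi, ids, label, source = path)
    },
    csv = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      need <- c("id", "smiles")
      if (!all(need %in% names(df)))
        stop("CSV molecule file needs columns: ", paste(need, collapse = ", "))
      lab <- if ("label" %in% names(df)) as.character(df$label) else label
      .moleculeSetFromSmiles(as.character(df$smiles), as.character(df$id),
                             lab, source = path)
    },
    sdf = {
      sdf <- read.SDFset(path)
      ok <- validSDF(sdf)
      if (any(!ok))
        warning(sprintf("%d of %d SDF records in %s are invalid and were dropped",
                        sum(!ok), length(ok), path), call. = FALSE)
      sdf <- sdf[ok]
      if (!length(sdf)) stop("no valid SDF records in ", path)
      ids <- sdfid(sdf)
      ids[is.na(ids) | !nzchar(ids)] <-
        sprintf("M%06d", which(is.na(ids) | !nzchar(ids)))
      if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
      cid(sdf) <- ids
      labs <- rep(label, length(sdf))
      db <- datablock(sdf)
      got <- vapply(db, function(d) "label" %in% names(d), logical(1))
      labs[got] <- vapply(db[got], function(d) d[["label"]], character(1))
      smi <- canonicalizeSmiles(.sdfToSmiles(sdf))
      new("MoleculeSet", sdf = sdf, ids = ids, smiles = smi, label = labs)
    }
  )
  if (is.null(ms)) stop("no parsable molecule in ", path)
  ms
}

# SDFset -> raw SMILES via Open Babel.
.sdfToSmiles <- function(sdf) {
  txt <- .sdfsetText(sdf)
  out <- convertFormat("SDF", "SMI", txt)
  ln <- strsplit(out, "\n")[[1]]
  vapply(ln[nzchar(ln)], function(l) sub("[ \t].*$", "", l), character(1),
         USE.NAMES = FALSE)
}

# Full SDF text of an SDFset, newline-terminated (as Open Babel expects).
.sdfsetText <- function(sdf) {
  lines <- unlist(lapply(as(sdf, "SDFstr")@a, identity), use.names = FALSE)
  paste(c(lines, ""), collapse = "\n")
}

# Count of SMARTS matches per molecule of an SDFset.
.smartsCount <- function(sdf, pattern) {
  res <- forEachMol("SDF", .sdfsetText(sdf),
                    function(m) smartsSearch_OB(list(m), pattern,
                                                uniqueMatches = TRUE))
  n <- vapply(res, function(x) as.numeric(x[[1]]), numeric(1))
  if (length(n) != length(sdf))
    stop("SMARTS matching returned ", length(n), " results for ",
         length(sdf), " molecules")
  n
}

#' Write molecules to SMILES or SDF
#'
#' @param x a [MoleculeSet-class].
#' @param path output file.
#' @param format \code{"smiles"} (canonical SMILES + id per line) or
#'   \code{"sdf"}.
#' @return \code{path}, invisibly.
#' @export
writeMolecules <- function(x, path, format = c("smiles", "sdf")) {
  stopifnot(is(x, "MoleculeSet"))
  format <- match.arg(format)
  if (format == "smiles") {
    writeLines(paste(x@smiles, x@ids), path)
  } else {
    write.SDF(x@sdf, path, cid = TRUE)
  }
  invisible(path)
}

#' Subset a molecule set
#'
#' @param x a [MoleculeSet-class].
#' @param i index vector (logical, integer, or molecule ids).
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("MoleculeSet", sdf = x@sdf[i], ids = x@ids[i],
      smiles = x@smiles[i], label = x@label[i])
})

#' @describeIn MoleculeSet-class number of molecules.
#' @export
setMethod("length", "MoleculeSet", function(x) length(x@ids))
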