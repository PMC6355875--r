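#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.LABEL_LEVELS <- c("active", "inactive", "unknown")

#' Labeled molecule-by-descriptor table
#'
#' The central container for ISE training and screening: a numeric matrix
#' of named physico-chemical descriptors (rows) by molecules (columns)
#' with an activity label per molecule, stored as a
#' \linkS4class{SummarizedExperiment} so the usual Bioconductor accessors
#' (\code{assay}, \code{colData}, \code{rowData}, subsetting) all work.
#' Labels live in \code{colData(x)$label} and take values
#' \code{"active"}, \code{"inactive"} or \code{"unknown"}.
#'
#' @seealso [DescriptorTable()], [descriptorMatrix()], [moleculeLabels()]
#' @export
setClass("DescriptorTable", contains = "SummarizedExperiment")

setValidity("DescriptorTable", function(object) {
  if (!"descriptors" %in% SummarizedExperiment::assayNames(object))
    return("assay 'descriptors' is required")
  m <- assay(object, "descriptors")
  if (!is.numeric(m)) return("descriptor matrix must be numeric")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("descriptor names must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    return("molecule ids must be present and unique")
  if (!"label" %in% colnames(colData(object)))
    return("colData must contain a 'label' column")
  lab <- as.character(colData(object)$label)
  if (!all(lab %in% .LABEL_LEVELS))
    return(sprintf("labels must be one of: %s", paste(.LABEL_LEVELS, collapse = ", ")))
  TRUE
})

#' Construct a descriptor table
#'
#' @param values numeric matrix of descriptor values, molecules in rows
#'   and descriptors in columns (the natural orientation of a CSV
#'   descriptor table; it is transposed into assay orientation
#'   internally).  Row names are molecule ids, column names descriptor
#'   names; missing molecule ids are generated as \code{"M000001"}-style.
#' @param labels activity labels, one per molecule, from
#'   \code{c("active", "inactive", "unknown")}; recycled if length 1.
#' @param informative optional logical vector flagging ground-truth
#'   informative descriptors (used by the synthetic generator); stored in
#'   \code{rowData}.
#' @return A [DescriptorTable-class].
#' @examples
#' m <- matrix(rnorm(20), 5, 4,
#'             dimnames = list(NULL, c("MW", "cLogP", "lip_acc", "lip_don")))
#' dt <- DescriptorTable(m, labels = c("active", "active", "inactive",
#'                                     "inactive", "unknown"))
#' dim(descriptorMatrix(dt))
#' @export
DescriptorTable <- function(values, labels = "unknown", informative = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("descriptor values must be numeric")
  if (is.null(colnames(values))) stop("descriptor names (column names) are required")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("M%06d", seq_len(nrow(values)))
  if (anyNA(values))
    stop("descriptor table contains NA values; validate or impute before use")
  labels <- as.character(labels)
  if (length(labels) == 1L) labels <- rep(labels, nrow(values))
  if (length(labels) != nrow(values))
    stop("need one label per molecule")
  rd <- DataFrame(row.names = colnames(values))
  if (!is.null(informative)) {
    stopifnot(length(informative) == ncol(values))
    rd$informative <- as.logical(informative)
  }
  se <- SummarizedExperiment(
    assays = list(descriptors = t(values)),
    rowData = rd,
    colData = DataFrame(label = labels, row.names = rownames(values))
  )
  new("DescriptorTable", se)
}

#' @describeIn DescriptorTable-class molecule-by-descriptor numeric matrix
#'   (molecules in rows).
#' @param x a \code{DescriptorTable}.
#' @export
descriptorMatrix <- function(x) {
  stopifnot(is(x, "DescriptorTable"))
  t(assay(x, "descriptors"))
}

#' @describeIn DescriptorTable-class molecule identifiers.
#' @export
moleculeIds <- function(x) {
  if (is(x, "DescriptorTable")) return(colnames(x))
  if (is(x, "MoleculeSet")) return(x@ids)
  stop("no molecule ids for objects of class ", class(x)[1])
}

#' @describeIn DescriptorTable-class descriptor names.
#' @export
descriptorNames <- function(x) {
  stopifnot(is(x, "DescriptorTable"))
  rownames(x)
}

#' @describeIn DescriptorTable-class activity labels
#'   (\code{"active"}/\code{"inactive"}/\code{"unknown"}).
#' @export
moleculeLabels <- function(x) {
  if (is(x, "DescriptorTable")) return(as.character(colData(x)$label))
  if (is(x, "MoleculeSet")) return(x@label)
  stop("no labels for objects of class ", class(x)[1])
}

setMethod("show", "DescriptorTable", function(object) {
  lab <- table(factor(moleculeLabels(object), levels = .LABEL_LEVELS))
  cat("DescriptorTable:", ncol(object), "molecules x", nrow(object),
      "descriptors\n")
  cat(sprintf("  labels: %d active / %d inactive / %d unknown\n",
              lab[["active"]], lab[["inactive"]], lab[["unknown"]]))
  if ("informative" %in% colnames(rowData(object)))
    cat("  ground truth:", sum(rowData(object)$informative),
        "informative descriptors\n")
})

#' Read a CSV descriptor table
#'
#' Expects a header row of descriptor names, molecule ids in the first
#' column and an optional \code{label} column; all remaining columns must
#' be numeric.
#'
#' @param path CSV file path.
#' @return A [DescriptorTable-class].
#' @seealso [writeDescriptorTable()]
#' @export
readDescriptorTable <- function(path) {
  if (!file.exists(path)) stop("descriptor table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("descriptor table needs an id column plus descriptors")
  ids <- as.character(df[[1]])
  df <- df[-1]
  labels <- "unknown"
  if ("label" %in% names(df)) {
    labels <- as.character(df[["label"]])
    df <- df[names(df) != "label"]
  }
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  DescriptorTable(m, labels = labels)
}

#' Write a descriptor table to CSV
#'
#' Inverse of [readDescriptorTable()]: molecule ids in column \code{id},
#' one column per descriptor, labels in a trailing \code{label} column.
#'
#' @param x a [DescriptorTable-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeDescriptorTable <- function(x, path) {
  stopifnot(is(x, "DescriptorTable"))
  df <- data.frame(id = moleculeIds(x), descriptorMatrix(x),
                   label = moleculeLabels(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
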