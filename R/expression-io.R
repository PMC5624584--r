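#' Construct a two-phenotype expression profile
#'
#' Container for a gene x sample matrix of normalized expression values plus
#' a two-class phenotype labelling of the samples.  Class 1 is the "case"
#' phenotype and class 2 the "control"; all downstream t-statistics are
#' signed case minus control.
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (colnames).
#' @param labels integer vector of 1/2, named by sample, covering every
#'   column of `values`.
#' @return an object of class `expression_profile`: a list with elements
#'   `values` and `labels`.
#' @export
expression_profile <- function(values, labels) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("gene identifiers (rownames) must be present and unique")
  if (is.null(colnames(values))) stop("sample identifiers (colnames) required")
  labels <- labels[colnames(values)]
  if (anyNA(labels)) stop("every sample must have exactly one phenotype label")
  if (!all(labels %in% c(1L, 2L))) stop("phenotype labels must be 1 or 2")
  for (cl in 1:2)
    if (sum(labels == cl) < 3L)
      stop("phenotype class ", cl, " has fewer than 3 samples; ",
           "at least 3 per class are required for the per-class variance")
  structure(list(values = values, labels = as.integer(labels)),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("Expression profile: ", nrow(x$values), " genes x ",
      ncol(x$values), " samples (", sum(x$labels == 1L), " case / ",
      sum(x$labels == 2L), " control)\n", sep = "")
  invisible(x)
}

#' Read an expression matrix and phenotype labels from TSV files
#'
#' The matrix file has a header row of sample identifiers and gene
#' identifiers in the first column.  The labels file has two columns,
#' sample identifier and label; an optional `sample<TAB>label` header is
#' skipped.  Samples present in the matrix but absent from the labels file
#' are dropped with a warning; a label other than the declared case/control
#' values is an error.
#'
#' @param matrix_path path to the expression matrix TSV.
#' @param labels_path path to the sample-label TSV.
#' @param case,control label values mapped to phenotype classes 1 and 2.
#' @return an [expression_profile()].
#' @export
read_expression <- function(matrix_path, labels_path,
                            case = "1", control = "2") {
  if (!file.exists(matrix_path)) stop("expression matrix not found: ", matrix_path)
  if (!file.exists(labels_path)) stop("labels file not found: ", labels_path)

  tab <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "")
  genes <- tab[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene rows in expression matrix: ",
         paste(unique(dup), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(genes, colnames(vals))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric expression value at gene '", genes[bad[1]],
         "', sample '", colnames(num)[bad[2]], "'")
  }

  lab <- utils::read.table(labels_path, header = FALSE, sep = "\t",
                           colClasses = "character", comment.char = "#",
                           quote = "")
  if (ncol(lab) < 2L) stop("labels file must have two columns: sample, label")
  if (nrow(lab) > 0L && tolower(lab[1, 1]) == "sample") lab <- lab[-1, , drop = FALSE]
  if (anyDuplicated(lab[[1]])) stop("duplicate sample in labels file")
  lmap <- ifelse(lab[[2]] == case, 1L, ifelse(lab[[2]] == control, 2L, NA_integer_))
  if (anyNA(lmap))
    stop("unknown phenotype label(s): ",
         paste(unique(lab[[2]][is.na(lmap)]), collapse = ", "),
         " (expected '", case, "' or '", control, "')")
  names(lmap) <- lab[[1]]

  unlabeled <- setdiff(colnames(num), names(lmap))
  if (length(unlabeled)) {
    warning("dropping ", length(unlabeled), " unlabeled sample(s): ",
            paste(unlabeled, collapse = ", "))
    num <- num[, setdiff(colnames(num), unlabeled), drop = FALSE]
  }
  extra <- setdiff(names(lmap), colnames(num))
  if (length(extra))
    warning(length(extra), " labeled sample(s) absent from the matrix ignored")
  expression_profile(num, lmap[colnames(num)])
}

#' Write an expression profile to TSV files
#'
#' @param profile an [expression_profile()].
#' @param matrix_path,labels_path output paths.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(profile, matrix_path, labels_path) {
  vals <- profile$values
  header <- paste(c("gene", colnames(vals)), collapse = "\t")
  body <- vapply(seq_len(nrow(vals)), function(i)
    paste(c(rownames(vals)[i],
            format(vals[i, ], digits = 17, trim = TRUE)), collapse = "\t"),
    character(1))
  writeLines(c(header, body), matrix_path)
  writeLines(paste(colnames(vals), profile$labels, sep = "\t"), labels_path)
  invisible(c(matrix_path, labels_path))
}
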