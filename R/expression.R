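#' Construct an expression set
#'
#' Bundles a gene x sample FPKM matrix with its sample annotation. FPKM
#' (fragments per kilobase of exon model per million mapped reads) values
#' must be finite and non-negative; gene and sample identifiers must be
#' unique; every sample must carry exactly one tissue annotation.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param annotation data.frame with columns `sample_id`, `tissue` and
#'   optionally `replicate` (positive integer index within tissue; assigned
#'   by column order when absent).
#' @return an object of class `expression_set`: a list with elements
#'   `values` and `annotation` (annotation ordered as the matrix columns).
#' @seealso [read_expression_set()], [average_replicates()]
#' @export
expression_set <- function(values, annotation) {
  if (!is.matrix(values) || !is.numeric(values))
    fail("'values' must be a numeric matrix")
  if ((is.null(rownames(values)) && nrow(values) > 0) ||
      is.null(colnames(values)))
    fail("'values' must have gene rownames and sample colnames")
  if (is.null(rownames(values)))
    rownames(values) <- character()
  if (anyDuplicated(rownames(values)))
    fail("duplicated gene id: %s",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    fail("duplicated sample id: %s",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    fail("negative, missing or non-finite FPKM at gene '%s', sample '%s'",
         rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]])
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tissue") %in% names(annotation)))
    fail("annotation must have columns 'sample_id' and 'tissue'")
  annotation$sample_id <- as.character(annotation$sample_id)
  annotation$tissue <- as.character(annotation$tissue)
  if (anyDuplicated(annotation$sample_id))
    fail("annotation has duplicated sample_id")
  missing_ann <- setdiff(colnames(values), annotation$sample_id)
  if (length(missing_ann) > 0)
    fail("samples without tissue annotation: %s",
         paste(missing_ann, collapse = ", "))
  extra <- setdiff(annotation$sample_id, colnames(values))
  if (length(extra) > 0)
    warning("annotated samples absent from matrix: ",
            paste(extra, collapse = ", "), call. = FALSE)
  annotation <- annotation[match(colnames(values), annotation$sample_id), ,
                           drop = FALSE]
  rownames(annotation) <- NULL
  if (!"replicate" %in% names(annotation)) {
    annotation$replicate <- stats::ave(seq_len(nrow(annotation)),
                                       annotation$tissue, FUN = seq_along)
  }
  annotation$replicate <- as.integer(annotation$replicate)
  if (any(annotation$replicate < 1))
    fail("replicate indices must be positive integers")
  structure(list(values = values, annotation = annotation),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes x %d samples over %d tissues\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$annotation$tissue))))
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' Read an FPKM matrix and sample annotation from TSV files
#'
#' The matrix file is tab-separated with a header row; the first column
#' (named `gene`) holds gene identifiers, the remaining columns one sample
#' each. The annotation file is tab-separated with columns `sample_id`,
#' `tissue` and optionally `replicate`. Duplicated gene ids, negative or
#' non-numeric values, explicit NA tokens and unannotated samples are hard
#' errors; annotated samples absent from the matrix are reported with a
#' warning.
#'
#' @param path path to the matrix TSV.
#' @param annotation_path path to the annotation TSV.
#' @return an [expression_set()].
#' @export
read_expression_set <- function(path, annotation_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = NULL)
  if (ncol(tab) < 2) fail("matrix file needs a gene column plus >= 1 sample")
  genes <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (is.character(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num))
      if (length(bad) > 0)
        fail("non-numeric FPKM '%s' at gene '%s', sample '%s'",
             col[bad[1]], genes[bad[1]], names(vals)[j])
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  expression_set(m, ann)
}

#' Write an expression set to TSV files
#'
#' Inverse of [read_expression_set()]: writes the FPKM matrix with a
#' leading `gene` column and the sample annotation table. Reading the files
#' back yields an object equal to the original.
#'
#' @param x an [expression_set()].
#' @param path matrix TSV output path.
#' @param annotation_path annotation TSV output path.
#' @return invisibly, `x`.
#' @export
write_expression_set <- function(x, path, annotation_path) {
  stopifnot(inherits(x, "expression_set"))
  tab <- data.frame(gene = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$annotation, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Average replicates into a tissue-level profile
#'
#' Collapses the gene x sample matrix to a gene x tissue matrix by taking
#' the arithmetic mean FPKM over the replicates of each tissue, on the
#' linear scale. Tissue columns are ordered lexicographically so the result
#' is independent of sample column order.
#'
#' @param x an [expression_set()].
#' @return numeric matrix, genes x tissues, of mean FPKM.
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "expression_set"))
  tissues <- sort(unique(x$annotation$tissue))
  prof <- vapply(tissues, function(t) {
    cols <- x$annotation$sample_id[x$annotation$tissue == t]
    rowMeans(x$values[, cols, drop = FALSE])
  }, numeric(nrow(x$values)))
  prof <- matrix(prof, nrow = nrow(x$values),
                 dimnames = list(rownames(x$values), tissues))
  prof
}

#' Detection mask at an FPKM cutoff
#'
#' A gene counts as detected in a tissue when its mean FPKM is greater than
#' or equal to the cutoff (so a value exactly at the limit of detection is
#' detected). The default cutoff of 1 FPKM is the conventional limit of
#' detection for bulk RNA-seq abundance.
#'
#' @param profile gene x tissue matrix from [average_replicates()].
#' @param cutoff positive detection limit in FPKM units (default 1).
#' @return logical matrix of the same dimensions as `profile`.
#' @export
detection_mask <- function(profile, cutoff = 1) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0)
    fail("'cutoff' must be a single positive number")
  profile >= cutoff
}

#' Write a gene x tissue profile (or 0/1 detection mask) to TSV
#' @param m numeric or logical matrix with gene rownames.
#' @param path output path.
#' @return invisibly, `m`.
#' @export
write_profile <- function(m, path) {
  tab <- data.frame(gene = rownames(m), m + 0, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}
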