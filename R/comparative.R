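#' Spearman rank correlation
#'
#' Rank correlation with average (mid) ranks for ties, the appropriate
#' statistic for heavily zero-inflated FPKM vectors. A constant vector has
#' no defined rank correlation and yields `NA`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the correlation coefficient, or `NA` for constant input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    fail("'x' and 'y' must have equal length >= 3")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Pairwise Spearman correlation matrix
#'
#' At `level = "sample"` correlates the raw FPKM columns of the expression
#' set; at `level = "tissue"` correlates replicate-averaged tissue
#' profiles. Constant columns propagate `NA` into their off-diagonal
#' entries; the diagonal is always 1.
#'
#' @param x an [expression_set()] or a numeric matrix whose columns are
#'   profiles.
#' @param level `"sample"` or `"tissue"` (ignored when `x` is a matrix).
#' @return symmetric correlation matrix.
#' @export
correlation_matrix <- function(x, level = c("sample", "tissue")) {
  level <- match.arg(level)
  m <- if (inherits(x, "expression_set")) {
    if (level == "tissue") average_replicates(x) else x$values
  } else x
  if (ncol(m) < 2) fail("need >= 2 columns")
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  constant <- apply(m, 2, function(col) length(unique(col)) == 1)
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- 1
  rho
}

#' Hierarchically cluster samples by expression profile
#'
#' Agglomerative clustering of the samples with distance
#' `1 - Spearman rho` computed on `log2(FPKM + 1)` columns (the +1
#' pseudo-count keeps zeros finite on the log scale) and average linkage.
#' Replicates of the same tissue are expected to merge before tissues do
#' when biological signal dominates noise.
#'
#' @param x an [expression_set()] or numeric matrix with >= 2 columns.
#' @return an object of class [stats::hclust]; leaves are sample ids and
#'   merge heights are the average-linkage distances.
#' @seealso [as_newick()] to export the dendrogram.
#' @export
cluster_samples <- function(x) {
  m <- if (inherits(x, "expression_set")) x$values else x
  if (ncol(m) < 2) fail("need >= 2 samples")
  rho <- correlation_matrix(log2(m + 1), level = "sample")
  if (anyNA(rho)) {
    bad <- colnames(rho)[apply(is.na(rho), 2, any)]
    fail("undefined correlation for sample(s): %s",
         paste(bad, collapse = ", "))
  }
  stats::hclust(stats::as.dist(1 - rho), method = "average")
}

#' Export a dendrogram as a Newick string
#'
#' @param hc an [stats::hclust] object (e.g. from [cluster_samples()]).
#' @param path optional file path; when given the tree is also written.
#' @return the Newick string, invisibly when `path` is given.
#' @export
as_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Genes detected in one tissue but not another
#'
#' Returns the genes whose mean FPKM is at or above the cutoff in tissue
#' `a` and below it in tissue `b` — the asymmetric differential-detection
#' set (so the `a`-vs-`b` and `b`-vs-`a` sets are disjoint).
#'
#' @param profile gene x tissue matrix from [average_replicates()].
#' @param a,b distinct tissue names present in `profile`.
#' @param cutoff detection cutoff in FPKM (default 1).
#' @return a list of class `differential_set` with elements `tissue_a`,
#'   `tissue_b`, `cutoff` and `genes`.
#' @export
differential_detection <- function(profile, a, b, cutoff = 1) {
  if (identical(a, b)) fail("'a' and 'b' must differ")
  missing_t <- setdiff(c(a, b), colnames(profile))
  if (length(missing_t) > 0)
    fail("unknown tissue: %s", paste(missing_t, collapse = ", "))
  sel <- profile[, a] >= cutoff & profile[, b] < cutoff
  structure(list(tissue_a = a, tissue_b = b, cutoff = cutoff,
                 genes = rownames(profile)[sel]),
            class = "differential_set")
}

#' @export
print.differential_set <- function(x, ...) {
  cat(sprintf("%d genes detected in %s but not in %s (cutoff %g FPKM)\n",
              length(x$genes), x$tissue_a, x$tissue_b, x$cutoff))
  invisible(x)
}

#' Write a differential-detection gene set
#'
#' One gene id per line, preceded by `#tissue_a`, `#tissue_b` and
#' `#cutoff` metadata header lines.
#'
#' @param x a `differential_set`.
#' @param path output path.
#' @return invisibly, `x`.
#' @export
write_differential_set <- function(x, path) {
  stopifnot(inherits(x, "differential_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#tissue_a\t", x$tissue_a),
               paste0("#tissue_b\t", x$tissue_b),
               paste0("#cutoff\t", format(x$cutoff)),
               "gene", x$genes), con)
  invisible(x)
}

#' Cross-reference a differential set against other tissues
#'
#' Splits the genes of a differential-detection set by whether they are
#' also detected (mean FPKM >= cutoff) in at least one of the reference
#' tissues — e.g. asking how many appendix-specific genes are shared with
#' gastrointestinal tissues. The shared fraction is reported as a whole
#' percent, rounded half-up.
#'
#' @param ds a `differential_set` from [differential_detection()].
#' @param profile gene x tissue matrix containing the reference tissues.
#' @param reference_tissues character vector of tissue names.
#' @param cutoff detection cutoff in FPKM (default 1).
#' @return list with `shared` and `private` gene vectors and
#'   `shared_fraction` (percent, `NA` for an empty set).
#' @export
cross_reference <- function(ds, profile, reference_tissues, cutoff = 1) {
  stopifnot(inherits(ds, "differential_set"))
  missing_t <- setdiff(reference_tissues, colnames(profile))
  if (length(missing_t) > 0)
    fail("unknown reference tissue: %s", paste(missing_t, collapse = ", "))
  genes <- ds$genes
  if (length(genes) == 0)
    return(list(shared = character(), private = character(),
                shared_fraction = NA_real_))
  ref <- profile[genes, reference_tissues, drop = FALSE]
  is_shared <- apply(ref >= cutoff, 1, any)
  list(shared = genes[is_shared], private = genes[!is_shared],
       shared_fraction = round_half_up(100 * mean(is_shared), 0))
}
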