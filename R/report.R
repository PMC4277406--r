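#' Summarise a classification: counts, percentages, elevated tallies
#'
#' Computes per-category gene counts and percentages of the total (rounded
#' half-up, integer at or above 10%, one decimal below), per-tissue
#' tallies (tissue-enriched genes, genes whose enriched group involves the
#' tissue, enhanced genes) and the elevated totals. *Elevated* is the
#' union of the tissue-enriched, group-enriched and enhanced categories;
#' since every gene carries exactly one category the three totals are
#' disjoint and sum to the elevated total.
#'
#' @param classification a `gene_classification` from [classify_profile()].
#' @param total_genes denominator for percentages (default: number of
#'   classified genes).
#' @return a list of class `category_summary` with elements `counts`,
#'   `percent`, `per_tissue` (data.frame), `elevated` (named vector) and
#'   `total_genes`.
#' @export
summarize_classification <- function(classification,
                                     total_genes = nrow(classification)) {
  stopifnot(inherits(classification, "gene_classification"))
  cls <- as.data.frame(classification)
  counts <- table(cls$category)
  counts <- stats::setNames(as.integer(counts), names(counts))
  pct <- percent_of(counts, total_genes)
  names(pct) <- names(counts)

  tissues <- attr(classification, "tissues")
  per_tissue <- data.frame(
    tissue = tissues,
    tissue_enriched = vapply(tissues, function(t)
      sum(cls$enriched_tissue == t, na.rm = TRUE), integer(1)),
    group_enriched_involving = vapply(tissues, function(t) {
      g <- cls$enriched_group[!is.na(cls$enriched_group)]
      sum(vapply(strsplit(g, ";", fixed = TRUE),
                 function(m) t %in% m, logical(1)))
    }, integer(1)),
    enhanced = vapply(tissues, function(t) {
      e <- cls$enhanced_in[!is.na(cls$enhanced_in)]
      sum(vapply(strsplit(e, ";", fixed = TRUE),
                 function(m) t %in% m, logical(1)))
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  tissue_enriched_total <- counts[["highly_tissue_enriched"]] +
    counts[["moderately_tissue_enriched"]]
  elevated <- c(tissue_enriched_total = tissue_enriched_total,
                group_enriched_total = counts[["group_enriched"]],
                enhanced_total = counts[["enhanced"]],
                elevated_total = tissue_enriched_total +
                  counts[["group_enriched"]] + counts[["enhanced"]])
  structure(list(counts = counts, percent = pct, per_tissue = per_tissue,
                 elevated = elevated, total_genes = total_genes),
            class = "category_summary")
}

#' @export
print.category_summary <- function(x, ...) {
  cat(sprintf("classification of %d genes (%d total):\n",
              sum(x$counts), x$total_genes))
  for (k in names(x$counts))
    cat(sprintf("  %-28s %6d  (%s%%)\n", k, x$counts[[k]],
                format(x$percent[[k]])))
  cat(sprintf("  elevated (enriched or enhanced): %d (%s%%)\n",
              x$elevated[["elevated_total"]],
              format(percent_of(x$elevated[["elevated_total"]],
                                x$total_genes))))
  invisible(x)
}

#' Fraction of a tissue's transcripts contributed by each category
#'
#' For one tissue, sums the mean FPKM of the genes in each category and
#' divides by the tissue's total FPKM — the transcript-abundance analogue
#' of the gene-count breakdown. A handful of very highly expressed
#' enriched genes can dominate this measure even when the enriched gene
#' count is small.
#'
#' @param classification a `gene_classification`.
#' @param profile the gene x tissue matrix that was classified.
#' @param tissue tissue name.
#' @return named numeric vector over the seven categories summing to 1
#'   (all `NA` when the tissue's total FPKM is zero).
#' @export
transcript_fractions <- function(classification, profile, tissue) {
  stopifnot(inherits(classification, "gene_classification"))
  if (!tissue %in% colnames(profile)) fail("unknown tissue: %s", tissue)
  v <- profile[match(classification$gene, rownames(profile)), tissue]
  tot <- sum(v)
  cats <- expression_categories()
  if (tot == 0)
    return(stats::setNames(rep(NA_real_, length(cats)), cats))
  by_cat <- tapply(v, classification$category, sum, default = 0)
  stats::setNames(as.numeric(by_cat[cats]) / tot, cats)
}

#' Per-tissue summary statistics
#'
#' For each tissue: number of replicates, percent of genes detected
#' (mean FPKM >= cutoff), the top FPKM value of the tissue profile, and
#' the range of pairwise Spearman correlations between its replicates
#' (`NA` for single-replicate tissues).
#'
#' @param x an [expression_set()].
#' @param cutoff detection cutoff in FPKM (default 1).
#' @return data.frame with columns `tissue`, `n_replicates`,
#'   `pct_detected`, `top_fpkm`, `rho_min`, `rho_max`.
#' @export
tissue_stats <- function(x, cutoff = 1) {
  stopifnot(inherits(x, "expression_set"))
  profile <- average_replicates(x)
  tissues <- colnames(profile)
  out <- data.frame(tissue = tissues, stringsAsFactors = FALSE)
  out$n_replicates <- vapply(tissues, function(t)
    sum(x$annotation$tissue == t), integer(1))
  out$pct_detected <- percent_of(colSums(profile >= cutoff), nrow(profile))
  out$top_fpkm <- apply(profile, 2, max)
  rng <- t(vapply(tissues, function(t) {
    cols <- x$annotation$sample_id[x$annotation$tissue == t]
    if (length(cols) < 2) return(c(NA_real_, NA_real_))
    rho <- correlation_matrix(x$values[, cols, drop = FALSE])
    off <- rho[lower.tri(rho)]
    c(min(off), max(off))
  }, numeric(2)))
  out$rho_min <- rng[, 1]
  out$rho_max <- rng[, 2]
  rownames(out) <- NULL
  out
}

#' @rdname summarize_classification
#' @param object a `gene_classification`.
#' @param ... passed on.
#' @export
summary.gene_classification <- function(object, ...) {
  summarize_classification(object, ...)
}

#' @export
print.gene_classification <- function(x, n = 6, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("gene_classification: %d genes over %d tissues (mode: %s)\n",
              nrow(x), length(attr(x, "tissues")), cfg$mode))
  print(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat(sprintf("  ... %d more genes\n", nrow(x) - n))
  invisible(x)
}

#' Barplot of category counts
#'
#' @param x a `gene_classification`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the category counts.
#' @export
plot.gene_classification <- function(x, ...) {
  counts <- table(x$category)
  graphics::barplot(counts, las = 2, ylab = "genes",
                    main = "expression categories", ...)
  invisible(counts)
}
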