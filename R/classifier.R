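#' Classifier configuration
#'
#' One authoritative home for every threshold of the seven-category
#' tissue-specificity scheme. A gene is *highly tissue enriched* when its
#' FPKM in one tissue is at least `high_enrich_fold` (50x) the second
#' highest of all other tissues, *moderately tissue enriched* at
#' `moderate_enrich_fold` (5x), *group enriched* when the mean FPKM of a
#' group of `group_size_min`..`group_size_max` tissues is at least
#' `group_fold` (5x) the highest value outside the group, and *enhanced*
#' when one tissue is at least `enhanced_fold` (5x) the mean of all other
#' tissues together. Detection is mean FPKM >= `detection_cutoff`.
#'
#' In `mode = "focus"` two rules change, following the focus-set variant of
#' the scheme: a gene is *not detected* when it is below the cutoff in
#' every focus tissue (rather than every tissue), and a qualifying group
#' must contain at least one focus tissue. All fold arithmetic always uses
#' all tissues.
#'
#' @param detection_cutoff limit of detection in FPKM (default 1).
#' @param high_enrich_fold fold threshold for high tissue enrichment (50).
#' @param moderate_enrich_fold fold threshold for moderate enrichment (5).
#' @param group_fold fold threshold for group enrichment (5).
#' @param enhanced_fold fold threshold for enhanced expression (5).
#' @param group_size_min,group_size_max allowed group sizes (2 and 7).
#' @param focus_tissues character vector of focus tissues (may be empty in
#'   global mode; required in focus mode).
#' @param mode `"global"` or `"focus"`.
#' @param outside_rank 1 (default) compares the group mean to the maximum
#'   FPKM outside the group; 2 compares to the second-highest outside
#'   value, an alternative reading of the group criterion.
#' @return a list of class `classifier_config`.
#' @export
classifier_config <- function(detection_cutoff = 1,
                              high_enrich_fold = 50,
                              moderate_enrich_fold = 5,
                              group_fold = 5,
                              enhanced_fold = 5,
                              group_size_min = 2,
                              group_size_max = 7,
                              focus_tissues = character(),
                              mode = c("global", "focus"),
                              outside_rank = 1) {
  mode <- match.arg(mode)
  if (detection_cutoff <= 0) fail("'detection_cutoff' must be positive")
  if (!(high_enrich_fold > moderate_enrich_fold && moderate_enrich_fold >= 1))
    fail("need high_enrich_fold > moderate_enrich_fold >= 1")
  if (group_size_min < 2) fail("'group_size_min' must be >= 2")
  if (group_size_max < group_size_min)
    fail("'group_size_max' must be >= group_size_min")
  if (!outside_rank %in% c(1, 2)) fail("'outside_rank' must be 1 or 2")
  if (mode == "focus" && length(focus_tissues) == 0)
    fail("focus mode requires a non-empty 'focus_tissues'")
  structure(list(detection_cutoff = detection_cutoff,
                 high_enrich_fold = high_enrich_fold,
                 moderate_enrich_fold = moderate_enrich_fold,
                 group_fold = group_fold,
                 enhanced_fold = enhanced_fold,
                 group_size_min = as.integer(group_size_min),
                 group_size_max = as.integer(group_size_max),
                 focus_tissues = as.character(focus_tissues),
                 mode = mode,
                 outside_rank = as.integer(outside_rank)),
            class = "classifier_config")
}

#' @export
print.classifier_config <- function(x, ...) {
  cat("tissue-specificity classifier configuration\n")
  cat(sprintf("  detection cutoff: %g FPKM; folds: %gx/%gx enriched, %gx group, %gx enhanced\n",
              x$detection_cutoff, x$high_enrich_fold, x$moderate_enrich_fold,
              x$group_fold, x$enhanced_fold))
  cat(sprintf("  group sizes %d-%d (outside rank %d); mode: %s%s\n",
              x$group_size_min, x$group_size_max, x$outside_rank, x$mode,
              if (length(x$focus_tissues))
                paste0("; focus: ", paste(x$focus_tissues, collapse = ", "))
              else ""))
  invisible(x)
}

#' The seven expression categories, in precedence order
#' @export
expression_categories <- function() {
  c("not_detected", "highly_tissue_enriched", "moderately_tissue_enriched",
    "group_enriched", "enhanced", "expressed_in_all", "mixed")
}

# order tissues by decreasing value, ties broken by tissue name (ascending):
# deterministic across platforms
order_desc <- function(v) order(-v, names(v), method = "radix")

#' Single-tissue enrichment test
#'
#' Finds the top tissue (ties broken by lexicographic tissue name) and
#' compares its FPKM with the second-highest value, i.e. the maximum over
#' all other tissues. Qualifies when the top value is at least `cutoff` and
#' at least `fold` times the runner-up. When every other tissue is exactly
#' zero the ratio is `Inf` and the gene qualifies provided the top tissue
#' is detected.
#'
#' @param v named numeric vector of per-tissue mean FPKM (>= 2 tissues).
#' @param fold fold-change threshold.
#' @param cutoff detection cutoff.
#' @return `NULL` if the criterion fails, else
#'   `list(tissue = <name>, fold_change = <ratio>)`.
#' @export
tissue_enrichment <- function(v, fold, cutoff = 1) {
  if (length(v) < 2) fail("tissue_enrichment needs >= 2 tissues")
  if (is.null(names(v))) names(v) <- paste0("t", seq_along(v))
  ord <- order_desc(v)
  top <- ord[1]
  second <- max(v[-top])
  if (v[top] < cutoff) return(NULL)
  ratio <- if (second == 0) {
    if (v[top] > 0) Inf else NaN
  } else v[top] / second
  if (is.nan(ratio) || ratio < fold) return(NULL)
  list(tissue = names(v)[top], fold_change = unname(ratio))
}

#' Group enrichment by top-k prefix search
#'
#' Sorts tissues by decreasing FPKM (ties by name) and tests, for k from
#' `group_size_min` up to `group_size_max`, whether the mean FPKM of the
#' top-k tissues is at least `group_fold` times the highest value outside
#' those k (or the second-highest outside value if `outside_rank = 2`) and
#' at least the detection cutoff. The smallest qualifying k wins. Because
#' the top-k prefix simultaneously maximises the group mean and minimises
#' every outside order statistic, the prefix search finds a qualifying
#' group exactly when some subset of allowed size qualifies.
#'
#' In focus mode the group must contain at least one focus tissue.
#'
#' @param v named numeric vector of per-tissue mean FPKM.
#' @param config a [classifier_config()].
#' @return `NULL`, or `list(tissues = <sorted names>, fold_change = <ratio>)`.
#' @export
group_enrichment <- function(v, config = classifier_config()) {
  n <- length(v)
  if (n <= config$group_size_max)
    fail("group_enrichment needs more tissues than 'group_size_max'")
  if (is.null(names(v))) names(v) <- paste0("t", seq_along(v))
  ord <- order_desc(v)
  sv <- v[ord]
  for (k in config$group_size_min:config$group_size_max) {
    gm <- mean(sv[seq_len(k)])
    if (gm < config$detection_cutoff) next
    outside <- sv[(k + 1):n]
    ref <- if (config$outside_rank == 1) outside[1]
           else if (length(outside) >= 2) outside[2] else outside[1]
    ratio <- if (ref == 0) { if (gm > 0) Inf else NaN } else gm / ref
    if (is.nan(ratio) || ratio < config$group_fold) next
    members <- names(sv)[seq_len(k)]
    if (config$mode == "focus" &&
        !any(members %in% config$focus_tissues)) next
    return(list(tissues = sort(members), fold_change = unname(ratio)))
  }
  NULL
}

#' Enhanced-expression tissues
#'
#' Returns every tissue whose FPKM is at least the detection cutoff and at
#' least `enhanced_fold` times the mean FPKM of all other tissues together.
#' Several tissues of one gene may qualify simultaneously.
#'
#' @param v named numeric vector of per-tissue mean FPKM (>= 2 tissues).
#' @param config a [classifier_config()].
#' @return character vector of qualifying tissue names (possibly empty),
#'   with the achieved ratios as the `fold_change` attribute.
#' @export
enhanced_tissues <- function(v, config = classifier_config()) {
  if (length(v) < 2) fail("enhanced_tissues needs >= 2 tissues")
  if (is.null(names(v))) names(v) <- paste0("t", seq_along(v))
  other_mean <- (sum(v) - v) / (length(v) - 1)
  ratio <- ifelse(other_mean == 0, ifelse(v > 0, Inf, NaN), v / other_mean)
  ok <- !is.nan(ratio) & v >= config$detection_cutoff &
    ratio >= config$enhanced_fold
  out <- sort(names(v)[ok])
  attr(out, "fold_change") <- unname(ratio[match(out, names(v))])
  out
}

# classify one gene's tissue profile; returns a list record
classify_gene <- function(v, config) {
  cutoff <- config$detection_cutoff
  detected <- v >= cutoff
  n_det <- sum(detected)
  rec <- list(category = "mixed", enriched_tissue = NA_character_,
              enriched_group = NA_character_, enhanced_in = NA_character_,
              fold_change = NA_real_, n_tissues_detected = n_det)

  nd_scope <- if (config$mode == "focus") {
    v[names(v) %in% config$focus_tissues]
  } else v
  if (all(nd_scope < cutoff)) {
    rec$category <- "not_detected"
    rec$n_tissues_detected <- n_det
    return(rec)
  }

  te <- tissue_enrichment(v, config$high_enrich_fold, cutoff)
  if (!is.null(te)) {
    rec$category <- "highly_tissue_enriched"
    rec$enriched_tissue <- te$tissue
    rec$fold_change <- te$fold_change
    return(rec)
  }
  te <- tissue_enrichment(v, config$moderate_enrich_fold, cutoff)
  if (!is.null(te)) {
    rec$category <- "moderately_tissue_enriched"
    rec$enriched_tissue <- te$tissue
    rec$fold_change <- te$fold_change
    return(rec)
  }
  ge <- NULL
  if (length(v) > config$group_size_min) {
    # on small panels cap the group size at n - 1 so at least one tissue
    # remains outside the candidate group
    cfg_g <- config
    cfg_g$group_size_max <- min(config$group_size_max, length(v) - 1L)
    ge <- group_enrichment(v, cfg_g)
  }
  if (!is.null(ge)) {
    rec$category <- "group_enriched"
    rec$enriched_group <- paste(ge$tissues, collapse = ";")
    rec$fold_change <- ge$fold_change
    return(rec)
  }
  eh <- enhanced_tissues(v, config)
  if (length(eh) > 0) {
    rec$category <- "enhanced"
    rec$enhanced_in <- paste(eh, collapse = ";")
    rec$fold_change <- max(attr(eh, "fold_change"))
    return(rec)
  }
  if (all(detected)) {
    rec$category <- "expressed_in_all"
    return(rec)
  }
  rec
}

#' Classify all genes of a tissue profile
#'
#' Applies the seven-category scheme to every row of a replicate-averaged
#' gene x tissue FPKM matrix. Categories are assigned top-down with first
#' match winning: not detected, highly tissue enriched, moderately tissue
#' enriched, group enriched, enhanced, expressed in all, mixed; the
#' ordering makes the categories a partition of the gene set (the *mixed*
#' class is defined by exclusion).
#'
#' @param profile numeric gene x tissue matrix (see [average_replicates()]).
#' @param config a [classifier_config()].
#' @return a data.frame of class `gene_classification` with columns `gene`,
#'   `category` (factor over the seven levels in precedence order),
#'   `enriched_tissue`, `enriched_group` and `enhanced_in`
#'   (semicolon-joined), `fold_change` (the ratio that satisfied the
#'   winning criterion; `NA` when no fold criterion applies) and
#'   `n_tissues_detected`. The configuration is attached as attribute
#'   `config`, the tissue names as `tissues`.
#' @examples
#' p <- rbind(gA = c(liver = 100, lung = 1, skin = 1, testis = 1, brain = 1,
#'                   heart = 1, colon = 1, kidney = 1))
#' classify_profile(p)
#' @export
classify_profile <- function(profile, config = classifier_config()) {
  stopifnot(is.matrix(profile), is.numeric(profile))
  if (is.null(rownames(profile)))
    rownames(profile) <- paste0("gene", seq_len(nrow(profile)))
  if (is.null(colnames(profile)))
    colnames(profile) <- paste0("tissue", seq_len(ncol(profile)))
  if (config$mode == "focus" &&
      !all(config$focus_tissues %in% colnames(profile)))
    fail("focus tissues absent from profile: %s",
         paste(setdiff(config$focus_tissues, colnames(profile)),
               collapse = ", "))
  n <- nrow(profile)
  cats <- character(n); et <- character(n); eg <- character(n)
  ei <- character(n); fc <- numeric(n); nd <- integer(n)
  for (i in seq_len(n)) {
    rec <- classify_gene(profile[i, ], config)
    cats[i] <- rec$category
    et[i] <- rec$enriched_tissue
    eg[i] <- rec$enriched_group
    ei[i] <- rec$enhanced_in
    fc[i] <- rec$fold_change
    nd[i] <- rec$n_tissues_detected
  }
  out <- data.frame(gene = rownames(profile),
                    category = factor(cats, levels = expression_categories()),
                    enriched_tissue = et, enriched_group = eg,
                    enhanced_in = ei, fold_change = fc,
                    n_tissues_detected = nd,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "config") <- config
  attr(out, "tissues") <- colnames(profile)
  class(out) <- c("gene_classification", "data.frame")
  out
}

#' Write a gene classification table to TSV
#' @param x a `gene_classification` from [classify_profile()].
#' @param path output path.
#' @return invisibly, `x`.
#' @export
write_classification <- function(x, path) {
  stopifnot(inherits(x, "gene_classification"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
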