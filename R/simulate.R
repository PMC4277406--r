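#' The 27-tissue panel used by the default simulation
#' @return character vector of 27 tissue names.
#' @export
default_tissues <- function() {
  c("adipose_tissue", "adrenal_gland", "appendix", "bone_marrow",
    "cerebral_cortex", "colon", "duodenum", "endometrium", "esophagus",
    "gallbladder", "heart_muscle", "kidney", "liver", "lung", "lymph_node",
    "ovary", "pancreas", "placenta", "prostate", "salivary_gland",
    "skeletal_muscle", "skin", "small_intestine", "spleen", "stomach",
    "testis", "thyroid")
}

#' The four lymphohematopoietic focus tissues
#' @return character vector: appendix, bone marrow, lymph node, spleen.
#' @export
lymphohematopoietic_tissues <- function() {
  c("appendix", "bone_marrow", "lymph_node", "spleen")
}

#' Simulation configuration
#'
#' Defines the synthetic study: a 27-tissue bulk RNA-seq FPKM matrix with
#' planted category structure. Defaults emulate the design of a 27-tissue,
#' ~20,050-gene profiling study: the four lymphohematopoietic tissues get
#' their published replicate counts (bone marrow 4, lymph node 5, spleen 4,
#' appendix 3) and the remaining tissues draw 1-5 replicates; category
#' counts echo the published global proportions (about 17% tissue- or
#' group-enriched, ~9,200 expressed-in-all housekeeping genes). Background
#' expression is log-normal on the log2 scale (mu 1.5, sd 1), replicate
#' values are tissue means times multiplicative log-normal noise with the
#' given coefficient of variation, and a small fraction of signal leaks
#' between co-multiplexed samples (barcode leakage, default 0.1%).
#'
#' Planted genes satisfy their category criterion with at least a 2x
#' margin over the classification threshold (highly enriched genes are
#' drawn at 100-200x the outside maximum against the 50x threshold, group
#' and moderately enriched genes at 10-25x against 5x), so that moderate
#' replicate noise does not flip calls.
#'
#' @param n_tissues number of tissues (default 27; truncates/recycles
#'   [default_tissues()]).
#' @param category_counts named integer vector over the seven categories.
#' @param replicates named integer vector of replicates per tissue, or
#'   `NULL` for the default design; unnamed length-2 vector = range to
#'   draw from uniformly.
#' @param baseline_log2_mean,baseline_log2_sd log2-scale parameters of the
#'   background FPKM distribution.
#' @param noise_cv coefficient of variation of the multiplicative
#'   replicate noise (default 0.1; 0 disables noise).
#' @param leakage_rate barcode leakage rate in `[0, 0.5)` (default 0.001).
#' @param pool_size number of co-multiplexed samples per leakage pool
#'   (default 8).
#' @param seed integer RNG seed.
#' @param config [classifier_config()] whose thresholds the planted
#'   structure must satisfy.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_tissues = 27,
                              category_counts = c(
                                not_detected = 2000,
                                highly_tissue_enriched = 350,
                                moderately_tissue_enriched = 1650,
                                group_enriched = 1500,
                                enhanced = 2000,
                                expressed_in_all = 9222,
                                mixed = 3328),
                              replicates = NULL,
                              baseline_log2_mean = 1.5,
                              baseline_log2_sd = 1,
                              noise_cv = 0.1,
                              leakage_rate = 0.001,
                              pool_size = 8,
                              seed = 1,
                              config = classifier_config()) {
  if (any(category_counts < 0)) fail("category counts must be >= 0")
  miss <- setdiff(names(category_counts), expression_categories())
  if (length(miss) > 0)
    fail("unknown category: %s", paste(miss, collapse = ", "))
  full <- stats::setNames(integer(7), expression_categories())
  full[names(category_counts)] <- as.integer(category_counts)
  if (leakage_rate < 0 || leakage_rate >= 0.5)
    fail("'leakage_rate' must be in [0, 0.5)")
  if (noise_cv < 0) fail("'noise_cv' must be >= 0")
  if (n_tissues < 3) fail("need >= 3 tissues")
  if (config$group_size_max >= n_tissues)
    fail("group size limit must be below the number of tissues")
  structure(list(n_tissues = as.integer(n_tissues),
                 category_counts = full,
                 replicates = replicates,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 noise_cv = noise_cv,
                 leakage_rate = leakage_rate,
                 pool_size = as.integer(pool_size),
                 seed = as.integer(seed),
                 config = config),
            class = "simulation_config")
}

# draw background FPKM values: log-normal on the log2 scale, floored so a
# sensible outside maximum exists for planted fold arithmetic
rbackground <- function(n, cfg, floor_at = 0.2) {
  pmax(2^stats::rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd),
       floor_at)
}

#' Simulate an FPKM matrix with planted category structure
#'
#' Builds tissue-level mean profiles per planted gene (each satisfying its
#' category's criterion with margin, see [simulation_config()]), expands
#' them to replicate columns with multiplicative log-normal noise of the
#' configured CV, and applies barcode leakage across multiplexing pools.
#' Mixed genes are generated by rejection sampling: detected in a random
#' subset of tissues at background levels, redrawn until the classifier
#' calls them mixed, since the mixed class is defined only by exclusion.
#'
#' @param cfg a [simulation_config()].
#' @return a list of class `fpkm_simulation`: `expression` (an
#'   [expression_set()]), `truth` (data.frame `gene`, `category`,
#'   `tissues` — semicolon-joined planted tissue/group — and `fold`), and
#'   `config`.
#' @examples
#' sim <- simulate_fpkm(simulation_config(
#'   category_counts = c(highly_tissue_enriched = 5, expressed_in_all = 20),
#'   noise_cv = 0, leakage_rate = 0, seed = 42))
#' table(classify_profile(average_replicates(sim$expression))$category)
#' @export
simulate_fpkm <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  tissues <- default_tissues()
  if (cfg$n_tissues <= length(tissues)) {
    tissues <- sort(tissues[seq_len(cfg$n_tissues)])
  } else {
    tissues <- sort(c(tissues, sprintf("tissue%02d",
                                       seq_len(cfg$n_tissues - length(tissues)))))
  }
  nt <- cfg$n_tissues
  counts <- cfg$category_counts
  n_genes <- sum(counts)
  ccfg <- cfg$config

  M <- matrix(0, nrow = n_genes, ncol = nt,
              dimnames = list(NULL, tissues))
  truth_cat <- character(n_genes)
  truth_tis <- rep(NA_character_, n_genes)
  truth_fold <- rep(NA_real_, n_genes)
  row <- 0L

  add_gene <- function(v, category, planted, fold) {
    row <<- row + 1L
    M[row, ] <<- v
    truth_cat[row] <<- category
    truth_tis[row] <<- planted
    truth_fold[row] <<- fold
  }

  for (i in seq_len(counts[["not_detected"]])) {
    add_gene(stats::runif(nt, 0, 0.3), "not_detected", NA_character_,
             NA_real_)
  }

  for (i in seq_len(counts[["highly_tissue_enriched"]])) {
    v <- rbackground(nt, cfg)
    t <- sample.int(nt, 1)
    fold <- stats::runif(1, 2 * ccfg$high_enrich_fold,
                         4 * ccfg$high_enrich_fold)
    v[t] <- fold * max(v[-t])
    add_gene(v, "highly_tissue_enriched", tissues[t], fold)
  }

  for (i in seq_len(counts[["moderately_tissue_enriched"]])) {
    v <- rbackground(nt, cfg)
    t <- sample.int(nt, 1)
    # at least 2x above the 5x threshold, at most half the 50x threshold
    fold <- stats::runif(1, 2 * ccfg$moderate_enrich_fold,
                         ccfg$high_enrich_fold / 2)
    v[t] <- fold * max(v[-t])
    add_gene(v, "moderately_tissue_enriched", tissues[t], fold)
  }

  for (i in seq_len(counts[["group_enriched"]])) {
    k <- sample(ccfg$group_size_min:ccfg$group_size_max, 1)
    members <- sample.int(nt, k)
    v <- rbackground(nt, cfg)
    fold <- stats::runif(1, 2 * ccfg$group_fold, 5 * ccfg$group_fold)
    level <- fold * max(v[-members])
    v[members] <- level * stats::runif(k, 0.9, 1.1)
    add_gene(v, "group_enriched",
             paste(sort(tissues[members]), collapse = ";"),
             mean(v[members]) / max(v[-members]))
  }

  for (i in seq_len(counts[["enhanced"]])) {
    # one clearly elevated tissue, one runner-up high enough to block the
    # 5x tissue-enrichment call, flat background low enough to pass the
    # enhanced (vs mean of others) criterion but fail the group one; the
    # elevated value is drawn between those two bounds
    for (try in seq_len(100)) {
      s <- 2^stats::runif(1, -1, 2)
      pair <- sample.int(nt, 2)
      v <- rep(4, nt) * stats::runif(nt, 0.95, 1.05)
      v[pair[2]] <- 10
      rest_max <- max(v[-pair])
      other_mean <- (sum(v) - v[pair[1]]) / (nt - 1)
      lo <- 1.1 * ccfg$enhanced_fold * other_mean
      hi <- min(0.95 * (2 * ccfg$group_fold * rest_max - 10),
                0.95 * ccfg$moderate_enrich_fold * 10)
      if (lo >= hi) next
      v[pair[1]] <- stats::runif(1, lo, hi)
      v <- v * s
      if (classify_gene(stats::setNames(v, tissues), ccfg)$category ==
          "enhanced") break
      if (try == 100) fail("enhanced-gene construction failed; panel too small")
    }
    fold <- v[pair[1]] / ((sum(v) - v[pair[1]]) / (nt - 1))
    add_gene(v, "enhanced", tissues[pair[1]], fold)
  }

  for (i in seq_len(counts[["expressed_in_all"]])) {
    g <- pmax(2^stats::rnorm(1, cfg$baseline_log2_mean,
                             cfg$baseline_log2_sd), 2)
    add_gene(g * stats::runif(nt, 0.8, 1.25), "expressed_in_all",
             NA_character_, NA_real_)
  }

  for (i in seq_len(counts[["mixed"]])) {
    for (try in seq_len(500)) {
      k <- sample.int(nt - 1, 1)
      det <- sample.int(nt, k)
      v <- stats::runif(nt, 0.2, 0.95)
      g <- 2^stats::runif(1, 0.8, 3)
      v[det] <- g * stats::runif(k, 0.9, 1.1)
      if (classify_gene(stats::setNames(v, tissues), ccfg)$category ==
          "mixed") break
      if (try == 500) fail("mixed-gene rejection sampling did not converge")
    }
    add_gene(v, "mixed", NA_character_, NA_real_)
  }

  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  rownames(M) <- gene_ids

  # replicate design
  reps <- cfg$replicates
  if (is.null(reps)) {
    reps <- stats::setNames(sample(1:5, nt, replace = TRUE), tissues)
    fixed <- c(appendix = 3L, bone_marrow = 4L, lymph_node = 5L, spleen = 4L)
    common <- intersect(names(fixed), tissues)
    reps[common] <- fixed[common]
  } else if (is.null(names(reps)) && length(reps) == 2) {
    reps <- stats::setNames(sample(reps[1]:reps[2], nt, replace = TRUE),
                            tissues)
  } else if (is.null(names(reps)) && length(reps) == 1) {
    reps <- stats::setNames(rep(as.integer(reps), nt), tissues)
  } else {
    if (!all(tissues %in% names(reps)))
      fail("'replicates' must name every tissue")
    reps <- reps[tissues]
  }

  ann <- data.frame(
    sample_id = unlist(lapply(tissues, function(t)
      sprintf("%s_rep%d", t, seq_len(reps[[t]]))), use.names = FALSE),
    tissue = rep(tissues, times = reps),
    replicate = unlist(lapply(reps, seq_len), use.names = FALSE),
    stringsAsFactors = FALSE)

  vals <- M[, ann$tissue, drop = FALSE]
  colnames(vals) <- ann$sample_id
  if (cfg$noise_cv > 0 && n_genes > 0) {
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    noise <- matrix(stats::rlnorm(length(vals), meanlog = -sdlog^2 / 2,
                                  sdlog = sdlog),
                    nrow = n_genes)
    vals <- vals * noise
  }

  x <- expression_set(vals, ann)
  if (cfg$leakage_rate > 0 && n_genes > 0)
    x <- apply_leakage(x, cfg$leakage_rate, pool_size = cfg$pool_size)

  truth <- data.frame(gene = gene_ids, category = truth_cat,
                      tissues = truth_tis, fold = truth_fold,
                      stringsAsFactors = FALSE)
  structure(list(expression = x, truth = truth, config = cfg),
            class = "fpkm_simulation")
}

#' @export
print.fpkm_simulation <- function(x, ...) {
  cat(sprintf("fpkm_simulation: %d genes x %d samples (%d tissues), CV %g, leakage %g\n",
              nrow(x$expression$values), ncol(x$expression$values),
              x$config$n_tissues, x$config$noise_cv,
              x$config$leakage_rate))
  print(table(x$truth$category))
  invisible(x)
}

#' Mix signal between co-multiplexed samples (barcode leakage)
#'
#' Emulates index hopping on multiplexed sequencing runs: sample columns
#' are grouped into pools of `pool_size` consecutive columns and each
#' column becomes `(1 - rate) * own + rate * mean(other columns in pool)`.
#' The total signal of each gene across the samples of a pool is conserved
#' exactly, as read misassignment moves reads rather than creating them.
#'
#' @param x an [expression_set()] or numeric matrix.
#' @param rate leakage rate in `[0, 0.5)`.
#' @param pool_size samples per multiplexing pool (default 8).
#' @return object of the same type as `x` with mixed columns.
#' @export
apply_leakage <- function(x, rate, pool_size = 8) {
  if (rate < 0 || rate >= 0.5) fail("'rate' must be in [0, 0.5)")
  m <- if (inherits(x, "expression_set")) x$values else x
  if (rate > 0 && ncol(m) > 1) {
    pools <- split(seq_len(ncol(m)),
                   (seq_len(ncol(m)) - 1) %/% pool_size)
    for (p in pools) {
      if (length(p) < 2) next
      sub <- m[, p, drop = FALSE]
      others_mean <- (rowSums(sub) - sub) / (length(p) - 1)
      m[, p] <- (1 - rate) * sub + rate * others_mean
    }
  }
  if (inherits(x, "expression_set")) {
    x$values <- m
    x
  } else m
}
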