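cfg <- classifier_config()

test_that("single-tissue enrichment follows the fold rule", {
  v <- c(t1 = 100, t2 = 1, t3 = 1, t4 = 1)
  expect_equal(tissue_enrichment(v, 50), list(tissue = "t1", fold_change = 100))

  v2 <- c(t1 = 100, t2 = 3, t3 = 1, t4 = 1)
  expect_null(tissue_enrichment(v2, 50))             # 100 < 50 * 3
  hit <- tissue_enrichment(v2, 5)
  expect_equal(hit$tissue, "t1")
  expect_equal(hit$fold_change, 100 / 3)

  # all-zero runners-up: ratio is infinite but the cutoff still guards
  expect_equal(tissue_enrichment(c(a = 2, b = 0, c = 0), 50)$fold_change, Inf)
  expect_null(tissue_enrichment(c(a = 0.3, b = 0, c = 0), 50))

  # ties for the top tissue break lexicographically
  expect_null(tissue_enrichment(c(b = 5, a = 5, c = 0.1), 5))
  expect_equal(tissue_enrichment(c(b = 5, a = 5, c = 0.1), 1)$tissue, "a")

  expect_error(tissue_enrichment(c(a = 1), 5), ">= 2")
})

test_that("group enrichment finds the smallest qualifying top-k prefix", {
  v <- c(50, 50, rep(1, 25))
  names(v) <- sprintf("t%02d", 1:27)
  hit <- group_enrichment(v, cfg)
  expect_equal(hit$tissues, c("t01", "t02"))
  expect_equal(hit$fold_change, 50)

  expect_null(group_enrichment(setNames(rep(3, 27), sprintf("t%02d", 1:27)),
                               cfg))
  expect_error(group_enrichment(c(a = 1, b = 2, c = 3), cfg), "group_size_max")
})

test_that("prefix search agrees with exhaustive subset enumeration", {
  set.seed(7)
  for (i in 1:300) {
    v <- rand_profile(8)
    hit <- group_enrichment(v, cfg)
    expect_equal(!is.null(hit), oracle_group_exists(v),
                 info = paste(round(v, 2), collapse = ","))
    if (!is.null(hit)) {
      # the reported group really does qualify
      gm <- mean(v[hit$tissues])
      om <- max(v[setdiff(names(v), hit$tissues)])
      expect_gte(gm, 1)
      expect_true(gm >= 5 * om)
    }
  }
})

test_that("enhanced tissues compare against the mean of all others", {
  e <- enhanced_tissues(c(t1 = 10, t2 = 1, t3 = 1, t4 = 1, t5 = 1), cfg)
  expect_equal(as.character(e), "t1")

  v <- setNames(c(10, 10, rep(0, 10)), paste0("t", sprintf("%02d", 1:12)))
  e2 <- enhanced_tissues(v, cfg)
  expect_equal(as.character(e2), c("t01", "t02"))
  expect_equal(attr(e2, "fold_change"), rep(10 / (10 / 11), 2))

  expect_length(enhanced_tissues(setNames(rep(2, 8), paste0("t", 1:8)), cfg), 0)
})

test_that("engineered genes recover all seven categories", {
  nt <- 27
  tis <- sprintf("t%02d", 1:nt)
  p <- rbind(
    nd  = rep(0, nt),
    hi  = c(500, rep(0.5, nt - 1)),
    mod = c(20, rep(0.5, nt - 1)),
    grp = c(30, 30, 30, rep(0.5, nt - 3)),
    enh = c(25, 10, rep(4, nt - 2)),
    all = rep(1.5, nt),
    mix = c(rep(2, 12), rep(0.5, nt - 12)))
  colnames(p) <- tis
  cls <- classify_profile(p, cfg)
  expect_equal(as.character(cls$category),
               c("not_detected", "highly_tissue_enriched",
                 "moderately_tissue_enriched", "group_enriched", "enhanced",
                 "expressed_in_all", "mixed"))
  expect_equal(cls$enriched_tissue[2], "t01")
  expect_equal(cls$enriched_group[4], "t01;t02;t03")
  expect_equal(cls$fold_change[2], 1000)   # 500 / 0.5
  expect_true(is.na(cls$fold_change[1]))
  expect_equal(cls$n_tissues_detected, c(0L, 1L, 1L, 3L, nt, nt, 12L))
})

test_that("classification matches an independent transcription of the rules", {
  set.seed(11)
  n <- 2000
  p <- t(replicate(n, rand_profile(8)))
  rownames(p) <- paste0("g", seq_len(n))
  cls <- classify_profile(p, cfg)
  expected <- apply(p, 1, oracle_classify)
  expect_equal(as.character(cls$category), unname(expected))
})

test_that("focus mode restricts not-detected and group membership", {
  fcfg <- classifier_config(mode = "focus", focus_tissues = c("t01", "t02"))
  tis <- sprintf("t%02d", 1:10)

  # expressed only outside the focus set: not detected in focus mode
  v <- setNames(c(0.2, 0.2, rep(3, 8)), tis)
  p <- rbind(g1 = v)
  expect_equal(as.character(classify_profile(p, fcfg)$category),
               "not_detected")
  expect_equal(as.character(classify_profile(p, cfg)$category), "mixed")

  # a qualifying non-focus group is rejected, and no larger prefix that
  # would pull in a focus tissue qualifies (the mean drops too far)
  w <- setNames(c(9, 9, 50, 50, rep(9, 6)), tis)
  expect_equal(as.character(classify_profile(rbind(g = w), fcfg)$category),
               "expressed_in_all")
  expect_equal(as.character(classify_profile(rbind(g = w), cfg)$category),
               "group_enriched")
  w2 <- setNames(c(50, 1, 50, 1, rep(0.1, 6)), tis)
  expect_equal(as.character(classify_profile(rbind(g = w2), fcfg)$category),
               "group_enriched")

  # focus-mode categories match the oracle on random profiles
  set.seed(13)
  for (i in 1:200) {
    v <- rand_profile(8)
    got <- classify_profile(rbind(g = v), fcfg)
    expect_equal(as.character(got$category),
                 oracle_classify(v, focus = c("t01", "t02")))
  }
})

test_that("the seven categories partition any gene set", {
  set.seed(17)
  for (nt in c(8, 12, 27)) {
    p <- t(replicate(300, rand_profile(nt)))
    rownames(p) <- paste0("g", 1:300)
    cls <- classify_profile(p, cfg)
    expect_false(anyNA(cls$category))
    expect_equal(sum(table(cls$category)), nrow(p))
    # evidence invariants
    hi <- cls$category == "highly_tissue_enriched"
    expect_true(all(cls$fold_change[hi] >= 50))
    expect_true(all(!is.na(cls$enriched_tissue[hi])))
    mod <- cls$category == "moderately_tissue_enriched"
    expect_true(all(cls$fold_change[mod] >= 5))
    grp <- cls$category == "group_enriched"
    sizes <- lengths(strsplit(cls$enriched_group[grp], ";"))
    expect_true(all(sizes >= 2 & sizes <= 7))
    expect_true(all(is.na(cls$fold_change[cls$category == "not_detected"])))
  }
})

test_that("verdicts are scale-free and monotone in the enriched tissue", {
  set.seed(19)
  for (i in 1:100) {
    v <- rand_profile(8) + 1.5   # everywhere above cutoff
    base <- classify_profile(rbind(g = v), cfg)
    for (s in c(2, 10)) {
      scaled <- classify_profile(rbind(g = s * v), cfg)
      expect_equal(as.character(scaled$category),
                   as.character(base$category))
    }
  }

  # boosting the enriched tissue of a moderately enriched gene never
  # demotes it below moderate enrichment
  set.seed(23)
  for (i in 1:200) {
    v <- rand_profile(8)
    cls <- classify_profile(rbind(g = v), cfg)
    if (cls$category != "moderately_tissue_enriched") next
    v[cls$enriched_tissue] <- v[cls$enriched_tissue] * 10
    up <- classify_profile(rbind(g = v), cfg)
    expect_true(as.character(up$category) %in%
                c("highly_tissue_enriched", "moderately_tissue_enriched"))
  }
})

test_that("50-fold enrichment implies 5-fold enrichment", {
  relaxed <- classifier_config(high_enrich_fold = 1e9)
  set.seed(29)
  found <- 0
  for (i in 1:500) {
    v <- rand_profile(8)
    cls <- classify_profile(rbind(g = v), cfg)
    if (cls$category != "highly_tissue_enriched") next
    found <- found + 1
    demoted <- classify_profile(rbind(g = v), relaxed)
    expect_equal(as.character(demoted$category),
                 "moderately_tissue_enriched")
    expect_equal(demoted$enriched_tissue, cls$enriched_tissue)
  }
  expect_gt(found, 5)
})

test_that("gene order equivariance holds", {
  set.seed(31)
  p <- t(replicate(50, rand_profile(8)))
  rownames(p) <- paste0("g", 1:50)
  cls <- classify_profile(p, cfg)
  perm <- sample(nrow(p))
  clsp <- classify_profile(p[perm, ], cfg)
  reord <- as.data.frame(cls)[perm, ]
  rownames(reord) <- NULL
  expect_equal(as.data.frame(clsp), reord)
})

test_that("configuration invariants are enforced", {
  expect_error(classifier_config(high_enrich_fold = 5,
                                 moderate_enrich_fold = 5), "fold")
  expect_error(classifier_config(group_size_min = 1), "group_size_min")
  expect_error(classifier_config(mode = "focus"), "focus")
  expect_error(classifier_config(detection_cutoff = 0), "positive")
  expect_error(classifier_config(outside_rank = 3), "outside_rank")
})
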