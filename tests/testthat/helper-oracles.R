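# Independent oracles used across test files. These re-derive the category
# rules in deliberately literal, brute-force style (full sorts, exhaustive
# subset enumeration) and must stay independent of the package internals.

# literal re-evaluation of the seven-category scheme for one profile row
oracle_classify <- function(v, cutoff = 1, focus = NULL) {
  nms <- names(v)
  scope <- if (is.null(focus)) v else v[focus]
  if (all(scope < cutoff)) return("not_detected")
  n <- length(v)
  srt <- sort(v, decreasing = TRUE)
  top <- srt[1]
  second <- srt[2]
  ratio <- if (second == 0) Inf else top / second
  if (top >= cutoff && ratio >= 50) return("highly_tissue_enriched")
  if (top >= cutoff && ratio >= 5) return("moderately_tissue_enriched")
  if (is.null(focus)) {
    # global mode: exhaustive subset enumeration (provably equivalent to
    # the prefix search when no focus constraint applies)
    for (k in 2:min(7, n - 1)) {
      for (s in utils::combn(n, k, simplify = FALSE)) {
        gm <- mean(v[s])
        om <- max(v[-s])
        r <- if (om == 0) Inf else gm / om
        if (gm >= cutoff && r >= 5) return("group_enriched")
      }
    }
  } else {
    # focus mode: candidate groups are the descending top-k prefixes (the
    # focus constraint breaks the prefix/exhaustive equivalence, so the
    # rule is defined on prefixes), smallest k first, ties by name
    ord <- order(-v, nms)
    for (k in 2:min(7, n - 1)) {
      s <- ord[1:k]
      gm <- mean(v[s])
      om <- max(v[-s])
      r <- if (om == 0) Inf else gm / om
      if (gm >= cutoff && r >= 5 && any(nms[s] %in% focus))
        return("group_enriched")
    }
  }
  for (t in seq_len(n)) {
    om <- mean(v[-t])
    r <- if (om == 0) (if (v[t] > 0) Inf else NaN) else v[t] / om
    if (!is.nan(r) && v[t] >= cutoff && r >= 5) return("enhanced")
  }
  if (all(v >= cutoff)) return("expressed_in_all")
  "mixed"
}

# does any group of 2..7 tissues qualify for group enrichment? exhaustive
oracle_group_exists <- function(v, cutoff = 1, fold = 5) {
  n <- length(v)
  for (k in 2:min(7, n - 1)) {
    for (s in utils::combn(n, k, simplify = FALSE)) {
      gm <- mean(v[s])
      om <- max(v[-s])
      r <- if (om == 0) Inf else gm / om
      if (gm >= cutoff && r >= 5) return(TRUE)
    }
  }
  FALSE
}

# random FPKM-like profile: zero-inflated log-normal with occasional spikes
rand_profile <- function(n_tissues = 8) {
  v <- 2^rnorm(n_tissues, 1.5, 1.5)
  v[runif(n_tissues) < 0.3] <- 0
  if (runif(1) < 0.3)
    v[sample.int(n_tissues, 1)] <- 2^runif(1, 3, 9)
  if (runif(1) < 0.1) v[] <- round(v, 1)  # exercise ties
  names(v) <- paste0("t", sprintf("%02d", seq_len(n_tissues)))
  v
}

# small canned expression set: 2 tissues x 2 replicates, 3 genes
tiny_expression_set <- function() {
  m <- matrix(c(2, 4, 10, 10,
                0.5, 0.5, 8, 6,
                0, 0, 0, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("s1", "s2", "s3", "s4")))
  ann <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                    tissue = c("liver", "liver", "lung", "lung"),
                    replicate = c(1L, 2L, 1L, 2L))
  expression_set(m, ann)
}
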