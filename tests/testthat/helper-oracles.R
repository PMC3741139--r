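# Independent oracles and fixture builders used across test files.

# Expression tibble from a plain matrix with default ids.
toy_expr <- function(values, genes = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) {
    genes <- rownames(values)
    if (is.null(genes) || anyDuplicated(genes)) {
      genes <- paste0("g", seq_len(nrow(values)))
    }
  }
  if (is.null(samples)) {
    samples <- colnames(values)
    if (is.null(samples) || anyDuplicated(samples)) {
      samples <- paste0("s", seq_len(ncol(values)))
    }
  }
  dimnames(values) <- NULL
  expr_tbl(values, genes, samples)
}

toy_annotation <- function(sample_ids, subtype, batch = "b1") {
  tibble::tibble(sample_id = sample_ids, subtype = subtype, batch = batch)
}

# Exhaustive hypergeometric enumeration for the two-sided Fisher p-value,
# built from choose() only (independent of stats::fisher.test / dhyper).
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(ks, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- prob[ks == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Brute-force UPGMA: member lists, mean inter-cluster distance recomputed
# from the original matrix at every step (O(n^3) re-scan), lexicographic
# member-label tie-break. Returns merge heights and the cophenetic matrix.
upgma_bruteforce <- function(D, labels = rownames(D)) {
  n <- nrow(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        h <- mean(D[clusters[[i]], clusters[[j]]])
        lo <- min(labels[clusters[[i]]]); hi <- min(labels[clusters[[j]]])
        pair_tags <- sort(c(lo, hi))
        if (is.null(best) || h < best$h ||
            (h == best$h && (pair_tags[1] < best$tags[1] ||
                             (pair_tags[1] == best$tags[1] &&
                              pair_tags[2] < best$tags[2])))) {
          best <- list(h = h, i = i, j = j, tags = pair_tags)
        }
      }
    }
    heights[step] <- best$h
    mi <- clusters[[best$i]]; mj <- clusters[[best$j]]
    coph[mi, mj] <- best$h
    coph[mj, mi] <- best$h
    clusters[[best$i]] <- c(mi, mj)
    clusters[[best$j]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}

# Exhaustive SAM permutation oracle for tiny two-group designs: enumerates
# every distinct group-2 subset with combn and averages sorted d statistics.
dbar_exhaustive_oracle <- function(m, n2, s0) {
  n <- ncol(m)
  subsets <- utils::combn(n, n2)
  perm <- apply(subsets, 2, function(idx) {
    g2 <- seq_len(n) %in% idx
    m2 <- rowMeans(m[, g2, drop = FALSE])
    m1 <- rowMeans(m[, !g2, drop = FALSE])
    ss2 <- rowSums((m[, g2, drop = FALSE] - m2)^2)
    ss1 <- rowSums((m[, !g2, drop = FALSE] - m1)^2)
    s <- sqrt(((1 / sum(!g2) + 1 / n2) / (n - 2)) * (ss1 + ss2))
    sort((m2 - m1) / (s + s0))
  })
  rowMeans(perm)
}
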