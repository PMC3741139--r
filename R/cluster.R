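#' Pearson correlation distance between samples
#'
#' Distance `1 - r(i, j)` with `r` the Pearson correlation of two samples'
#' expression vectors across genes (the similarity metric used for the
#' unsupervised clustering of tumors). The uncentered variant divides the raw
#' cross product by the root raw sums of squares instead of centering.
#'
#' @param x log2-scale expression tibble with >= 2 genes.
#' @param uncentered use the uncentered correlation.
#' @return a [stats::dist] object over samples (zero diagonal dropped,
#'   symmetric by construction).
#' @export
pearson_distance <- function(x, uncentered = FALSE) {
  m <- expr_values(x)
  if (nrow(m) < 2) stop("need >= 2 genes to correlate samples", call. = FALSE)
  if (!uncentered) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant expression vector for sample ",
           colnames(m)[which(sds == 0)[1]], "; correlation undefined",
           call. = FALSE)
    }
    r <- stats::cor(m)
  } else {
    norms <- sqrt(colSums(m^2))
    if (any(norms == 0)) {
      stop("all-zero expression vector for sample ",
           colnames(m)[which(norms == 0)[1]], call. = FALSE)
    }
    r <- crossprod(m) / tcrossprod(norms)
  }
  stats::as.dist(1 - r)
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Unweighted average linkage: the pair of clusters with minimal mean
#' inter-cluster distance is merged at that mean, iterated to a single tree.
#' Distance ties are broken deterministically by the lexicographically
#' smallest pair of cluster member labels, so the topology is reproducible
#' across platforms. The result is a standard `hclust`-compatible object
#' (subclass `upgma`), so [stats::cutree()], [stats::cophenetic()] and
#' `plot()` all apply.
#'
#' @param d symmetric distance matrix or [stats::dist] object.
#' @return object of class `c("upgma", "hclust")`.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) {
    labels <- attr(d, "Labels")
    D <- as.matrix(d)
  } else {
    D <- as.matrix(d)
    if (!isSymmetric(unname(D), tol = 0)) {
      stop("distance matrix must be symmetric", call. = FALSE)
    }
    labels <- rownames(D)
  }
  n <- nrow(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 2) stop("need >= 2 leaves", call. = FALSE)
  diag(D) <- Inf

  node <- -seq_len(n)            # hclust coding: negative = leaf
  size <- rep(1L, n)
  tag <- labels                  # lexicographically smallest member label
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    mn <- min(D)
    cand <- which(D == mn, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    t1 <- pmin(tag[cand[, 1]], tag[cand[, 2]])
    t2 <- pmax(tag[cand[, 1]], tag[cand[, 2]])
    pick <- cand[order(t1, t2)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    first <- if (tag[i] <= tag[j]) i else j
    second <- if (first == i) j else i
    merge[step, ] <- c(node[first], node[second])
    height[step] <- mn
    # Lance-Williams update for unweighted average linkage
    newd <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    D[i, ] <- newd; D[, i] <- newd; D[i, i] <- Inf
    node[i] <- step
    size[i] <- size[i] + size[j]
    tag[i] <- min(tag[i], tag[j])
    keep <- setdiff(seq_len(nrow(D)), j)
    D <- D[keep, keep, drop = FALSE]
    node <- node[keep]; size <- size[keep]; tag <- tag[keep]
  }
  leaf_order <- function(k) {
    if (k < 0) return(-k)
    c(leaf_order(merge[k, 1]), leaf_order(merge[k, 2]))
  }
  structure(list(merge = merge, height = height,
                 order = leaf_order(n - 1), labels = labels,
                 method = "average", dist.method = "pearson",
                 call = match.call()),
            class = c("upgma", "hclust"))
}

#' Cut a dendrogram into its two major clusters
#'
#' Removes the final (highest) merge; the two remaining subtrees define the
#' groups.
#'
#' @param tree an `upgma` / `hclust` object.
#' @return tibble with `sample_id` (leaf labels in input order) and `cluster`
#'   (1 or 2; cluster 1 is the left child of the root).
#' @export
cut_two <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  leaves <- function(k) {
    if (k < 0) return(-k)
    c(leaves(tree$merge[k, 1]), leaves(tree$merge[k, 2]))
  }
  left <- leaves(tree$merge[n - 1, 1])
  cl <- rep(2L, n)
  cl[left] <- 1L
  tibble::tibble(sample_id = tree$labels, cluster = cl)
}

#' Agreement between a two-group clustering and a reference labeling
#'
#' Accuracy maximized over the two possible matchings of cluster to reference
#' labels, so complementing the cluster labels leaves the score unchanged.
#'
#' @param pred tibble from [cut_two()] (columns `sample_id`, `cluster`) or a
#'   named vector of cluster labels.
#' @param truth reference two-group labels: a tibble with `sample_id` plus a
#'   label column, or a named vector (e.g. MMR status per sample).
#' @return agreement fraction in \[0, 1\].
#' @export
cluster_agreement <- function(pred, truth) {
  p <- as_two_groups(pred)
  t <- as_two_groups(truth)
  if (!setequal(names(p), names(t))) {
    stop("pred and truth must label the same samples", call. = FALSE)
  }
  t <- t[names(p)]
  acc <- mean(p == t)
  max(acc, 1 - acc)
}

as_two_groups <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("sample_id" %in% names(x), ncol(x) >= 2)
    val_col <- setdiff(names(x), "sample_id")[1]
    v <- x[[val_col]]
    names(v) <- x$sample_id
    x <- v
  }
  if (is.null(names(x))) stop("labels must be named by sample id", call. = FALSE)
  lv <- unique(as.character(x))
  if (length(lv) > 2) stop("more than two groups in labeling", call. = FALSE)
  out <- as.integer(factor(as.character(x), levels = lv))
  names(out) <- names(x)
  out
}
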