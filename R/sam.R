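#' Configure a SAM analysis
#'
#' Parameters of the two-class unpaired Significance Analysis of Microarrays
#' (SAM) procedure: permutation count and seed, the target false discovery
#' rate, how the fudge factor `s0` is chosen, the resolution of the delta
#' threshold search, and how the null proportion `pi0` is estimated.
#'
#' @param n_permutations number of label permutations; when the number of
#'   distinct two-group assignments is at most this, permutations are
#'   enumerated exhaustively and the seed becomes irrelevant.
#' @param seed integer RNG seed for sampled permutations.
#' @param target_fdr target false discovery rate in (0, 1); the default 0.05
#'   is the 5% threshold used to call the differential-expression signatures.
#' @param s0_method `"cv_minimization"` (window-dispersion method),
#'   `"fixed_percentile"` of the per-gene standard errors, or `"zero"` (plain
#'   pooled t ranking).
#' @param s0_percentile percentile in \[0, 1\] used by `"fixed_percentile"`.
#' @param delta_grid number of evenly spaced candidate thresholds between 0
#'   and the largest |observed - expected| score gap.
#' @param pi0_method `"quartile"` (permuted scores inside the observed
#'   interquartile band) or `"one"` (conservative, no null-proportion
#'   correction).
#' @param false_call_method how the false-call count at a candidate threshold
#'   is summarized across permutations: `"mean"` (the average number of
#'   permuted scores beyond the cuts, as in the original SAM procedure) or
#'   `"median"`. The median is robust but collapses to zero in the extreme
#'   tail, which lets a handful of null genes through; the mean keeps the
#'   false discovery rate controlled there.
#' @return a `sam_config` list.
#' @export
sam_config <- function(n_permutations = 1000, seed = 1L, target_fdr = 0.05,
                       s0_method = c("cv_minimization", "fixed_percentile", "zero"),
                       s0_percentile = 0.05, delta_grid = 200,
                       pi0_method = c("quartile", "one"),
                       false_call_method = c("mean", "median")) {
  s0_method <- match.arg(s0_method)
  pi0_method <- match.arg(pi0_method)
  false_call_method <- match.arg(false_call_method)
  stopifnot(n_permutations >= 1, target_fdr > 0, target_fdr < 1,
            s0_percentile >= 0, s0_percentile <= 1, delta_grid >= 2)
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), target_fdr = target_fdr,
                 s0_method = s0_method, s0_percentile = s0_percentile,
                 delta_grid = as.integer(delta_grid), pi0_method = pi0_method,
                 false_call_method = false_call_method),
            class = "sam_config")
}

#' Relative-difference statistic on a values matrix
#'
#' Core SAM statistic: per gene, `s = sqrt(((1/n1 + 1/n2) / (n1 + n2 - 2)) *
#' (SS1 + SS2))` with `SSi` the within-group sum of squared deviations, and
#' `d = (mean2 - mean1) / (s + s0)`. With `s0 = 0`, `d` is exactly the
#' pooled-variance two-sample t statistic.
#' @noRd
d_stat <- function(m, in_group2, s0 = 0, check = TRUE) {
  n2 <- sum(in_group2)
  n1 <- ncol(m) - n2
  m2 <- rowMeans(m[, in_group2, drop = FALSE])
  m1 <- rowMeans(m[, !in_group2, drop = FALSE])
  ss2 <- rowSums((m[, in_group2, drop = FALSE] - m2)^2)
  ss1 <- rowSums((m[, !in_group2, drop = FALSE] - m1)^2)
  s <- sqrt(((1 / n1 + 1 / n2) / (n1 + n2 - 2)) * (ss1 + ss2))
  denom <- s + s0
  if (check && any(denom == 0)) {
    stop("constant gene with zero standard error and s0 = 0: ",
         rownames(m)[which(denom == 0)[1]], call. = FALSE)
  }
  list(r = m2 - m1, s = s, d = (m2 - m1) / denom)
}

as_group2 <- function(groups, contrast) {
  groups <- as.character(groups)
  if (!all(groups %in% contrast)) {
    stop("every sample must belong to one of the two contrast groups",
         call. = FALSE)
  }
  g2 <- groups == contrast[2]
  if (sum(g2) < 2 || sum(!g2) < 2) {
    stop("both groups need >= 2 samples (", contrast[1], ": ", sum(!g2),
         ", ", contrast[2], ": ", sum(g2), ")", call. = FALSE)
  }
  g2
}

#' Per-gene SAM scores for a two-group comparison
#'
#' @param x log2-scale expression tibble.
#' @param groups character/factor vector aligned with the samples of `x`,
#'   taking exactly the two values of `contrast`.
#' @param contrast length-2 character vector `c(group1, group2)`; positive
#'   `d` means higher expression in `group2`.
#' @param s0 non-negative fudge factor added to the per-gene standard error.
#' @return tibble with `gene_id`, `d` (relative difference score) and `s`
#'   (pooled two-group standard error).
#' @export
sam_d_scores <- function(x, groups, contrast = sort(unique(as.character(groups))),
                         s0 = 0) {
  m <- expr_values(x)
  stopifnot(length(groups) == ncol(m), s0 >= 0)
  st <- d_stat(m, as_group2(groups, contrast), s0)
  tibble::tibble(gene_id = rownames(m), d = unname(st$d), s = unname(st$s))
}

#' Estimate the SAM fudge factor
#'
#' The fudge factor stabilizes scores of low-variance genes. For
#' `"cv_minimization"`, candidate values are the 0, 5, ..., 100 percentiles of
#' `s`; for each, genes are binned into 100 `s`-quantile windows and the
#' candidate minimizing the coefficient of variation of the window-wise median
#' absolute deviations of `d` is chosen. `"fixed_percentile"` returns that
#' percentile of `s`; `"zero"` returns 0.
#'
#' @param r per-gene mean differences (numerator of `d`).
#' @param s per-gene pooled standard errors.
#' @param config a [sam_config()].
#' @return the selected non-negative `s0`.
#' @export
sam_estimate_s0 <- function(r, s, config = sam_config()) {
  stopifnot(length(r) == length(s))
  if (length(s) < 100) {
    warning("s0 estimation with < 100 genes is unstable", call. = FALSE)
  }
  if (config$s0_method == "zero") return(0)
  if (config$s0_method == "fixed_percentile") {
    return(unname(stats::quantile(s, config$s0_percentile, type = 7)))
  }
  if (max(s) == min(s)) {
    warning("degenerate standard-error profile (all equal); s0 = 0", call. = FALSE)
    return(0)
  }
  candidates <- unname(stats::quantile(s, seq(0, 1, by = 0.05), type = 7))
  breaks <- unique(stats::quantile(s, seq(0, 1, length.out = 101), type = 7))
  win <- cut(s, breaks, include.lowest = TRUE)
  cv <- vapply(candidates, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, win, stats::mad)
    v <- v[!is.na(v)]
    if (mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  candidates[which.min(cv)]
}

#' Permutation null for SAM scores
#'
#' Recomputes the d statistic under label permutations and returns the
#' expected order statistics (`dbar`, the per-rank mean of the sorted permuted
#' scores) together with the full matrix of sorted permuted scores. When the
#' number of distinct two-group assignments `choose(n, n2)` is at most
#' `n_permutations`, all assignments are enumerated and the result is
#' seed-independent; otherwise `n_permutations` uniform label shuffles are
#' drawn under the config seed.
#'
#' @inheritParams sam_d_scores
#' @param config a [sam_config()].
#' @return list with `dbar` (length n-genes, ascending rank order),
#'   `perm_d` (genes x permutations matrix of sorted scores), and
#'   `exhaustive` flag.
#' @export
sam_permutation_null <- function(x, groups, contrast = sort(unique(as.character(groups))),
                                 s0 = 0, config = sam_config()) {
  m <- expr_values(x)
  g2 <- as_group2(groups, contrast)
  permutation_null_m(m, g2, s0, config)
}

permutation_null_m <- function(m, g2, s0, config) {
  n <- ncol(m)
  n2 <- sum(g2)
  total <- choose(n, n2)
  exhaustive <- total <= config$n_permutations
  idx_list <- if (exhaustive) {
    asplit(utils::combn(n, n2), 2)
  } else {
    with_seed(config$seed,
              replicate(config$n_permutations, sample.int(n, n2),
                        simplify = FALSE))
  }
  perm_d <- vapply(idx_list, function(idx) {
    g <- logical(n); g[idx] <- TRUE
    unname(sort(d_stat(m, g, s0, check = FALSE)$d))
  }, numeric(nrow(m)))
  dimnames(perm_d) <- NULL
  list(dbar = rowMeans(perm_d), perm_d = perm_d, exhaustive = exhaustive)
}

#' Select the SAM significance threshold at a target FDR
#'
#' Scans a grid of `delta` thresholds. At each delta, the sorted observed
#' scores are compared with the permutation expected order statistics:
#' moving outward from the origin of the quantile plot, the first rank whose
#' observed score exceeds its expected value by more than delta sets the
#' upper cut, and symmetrically for the lower cut; every gene beyond a cut is
#' called, with its direction given by the sign of its score. The false-call
#' count is the mean (or median, per `false_call_method`) over permutations
#' of permuted scores beyond the cuts, and `FDR = pi0 * false_calls /
#' called`. The smallest delta whose
#' estimated FDR meets the target is returned (an empty call set reports
#' FDR 0). `pi0` (quartile method) is the fraction of permuted scores inside
#' the observed interquartile band divided by 0.5.
#'
#' @param d observed per-gene scores (any order).
#' @param dbar expected order statistics from [sam_permutation_null()].
#' @param perm_d sorted permuted score matrix from [sam_permutation_null()].
#' @param config a [sam_config()].
#' @return list with `delta`, `fdr`, `pi0`, `cut_up`, `cut_low`, logical
#'   `called` vector aligned with `d`, and the full `fdr_curve` tibble
#'   (delta, n_called, median_false_calls, fdr).
#' @export
sam_select_delta <- function(d, dbar, perm_d, config = sam_config()) {
  n <- length(d)
  stopifnot(length(dbar) == n, nrow(perm_d) == n)
  ord <- order(d)
  ds <- unname(d[ord])
  gap <- ds - unname(dbar)
  deltas <- seq(0, max(abs(gap)), length.out = config$delta_grid)
  pi0 <- if (config$pi0_method == "one") 1 else {
    q <- stats::quantile(d, c(0.25, 0.75), type = 7)
    p <- sum(perm_d >= q[1] & perm_d <= q[2]) / (0.5 * ncol(perm_d) * n)
    min(1, max(p, 1 / (ncol(perm_d) * n)))
  }
  # scan starts at the origin of the d vs dbar plot and moves outward
  i_up_start <- which(dbar >= 0)[1]
  i_low_start <- rev(which(dbar <= 0))[1]
  eval_delta <- function(delta) {
    cut_up <- Inf
    if (!is.na(i_up_start)) {
      up_ranks <- i_up_start:n
      first_up <- up_ranks[gap[up_ranks] > delta][1]
      if (!is.na(first_up)) cut_up <- ds[first_up]
    }
    cut_low <- -Inf
    if (!is.na(i_low_start)) {
      low_ranks <- i_low_start:1
      first_low <- low_ranks[gap[low_ranks] < -delta][1]
      if (!is.na(first_low)) cut_low <- ds[first_low]
    }
    called <- sum(ds >= cut_up) + sum(ds <= cut_low)
    beyond <- colSums(perm_d >= cut_up) + colSums(perm_d <= cut_low)
    false_calls <- if (config$false_call_method == "mean") {
      mean(beyond)
    } else {
      stats::median(beyond)
    }
    fdr <- if (called == 0) 0 else min(1, pi0 * false_calls / called)
    c(called = called, false_calls = false_calls, fdr = fdr,
      cut_up = cut_up, cut_low = cut_low)
  }
  curve <- t(vapply(deltas, eval_delta, numeric(5)))
  hit <- which(curve[, "fdr"] <= config$target_fdr)[1]
  chosen <- curve[hit, ]
  called <- d >= chosen[["cut_up"]] | d <= chosen[["cut_low"]]
  list(delta = deltas[hit], fdr = chosen[["fdr"]], pi0 = pi0,
       cut_up = chosen[["cut_up"]], cut_low = chosen[["cut_low"]],
       called = called,
       fdr_curve = tibble::tibble(delta = deltas,
                                  n_called = curve[, "called"],
                                  false_calls = curve[, "false_calls"],
                                  fdr = curve[, "fdr"]))
}

#' Two-class SAM differential expression
#'
#' Full SAM orchestration for a named two-group contrast: fudge-factor
#' estimation, observed scores, permutation null, and delta selection at the
#' target FDR. The result carries every intermediate needed to re-derive the
#' call set.
#'
#' @param x log2-scale expression tibble (all samples; the contrast selects
#'   its subset).
#' @param annotation annotation tibble.
#' @param contrast length-2 character vector naming the two groups,
#'   `c(group1, group2)`; positive scores / `"up"` direction mean higher
#'   expression in `group2`. E.g. `c("FCCTX", "LYNCH")` for the hereditary
#'   signature, or `c("proficient", "deficient")` with
#'   `group_var = "mmr_status"` for the MMR signature.
#' @param group_var annotation column defining the groups (default
#'   `"subtype"`).
#' @param config a [sam_config()].
#' @return a `sam_fit` object; see [tidy.sam_fit()], [glance.sam_fit()],
#'   [significant_genes()] and [autoplot.sam_fit()].
#' @export
sam_two_class <- function(x, annotation, contrast, group_var = "subtype",
                          config = sam_config()) {
  stopifnot(length(contrast) == 2)
  ann <- align_annotation(x, annotation)
  if (!group_var %in% names(ann)) {
    stop("annotation has no column '", group_var, "'", call. = FALSE)
  }
  in_contrast <- ann[[group_var]] %in% contrast
  xs <- x[, c(TRUE, in_contrast), drop = FALSE]
  groups <- ann[[group_var]][in_contrast]
  m <- expr_values(xs)
  g2 <- as_group2(groups, contrast)

  base <- d_stat(m, g2, 0, check = FALSE)
  s0 <- sam_estimate_s0(base$r, base$s, config)
  st <- d_stat(m, g2, s0)
  null <- permutation_null_m(m, g2, s0, config)
  sel <- sam_select_delta(st$d, null$dbar, null$perm_d, config)

  gene_table <- tibble::tibble(
    gene_id = rownames(m), d = unname(st$d), s = unname(st$s),
    rank = rank(st$d, ties.method = "first"),
    called = sel$called,
    direction = dplyr::case_when(!sel$called ~ NA_character_,
                                 st$d > 0 ~ "up", TRUE ~ "down")
  )
  structure(list(
    gene_table = gene_table, s0 = s0, dbar = null$dbar,
    perm_d = null$perm_d, delta = sel$delta, fdr_estimate = sel$fdr,
    pi0 = sel$pi0, cut_up = sel$cut_up, cut_low = sel$cut_low,
    fdr_curve = sel$fdr_curve, contrast = contrast, group_var = group_var,
    n1 = sum(!g2), n2 = sum(g2),
    n_permutations = ncol(null$perm_d), exhaustive = null$exhaustive,
    seed = config$seed, target_fdr = config$target_fdr
  ), class = "sam_fit")
}

#' Extract the significant-gene signature from a SAM fit
#'
#' @param fit a `sam_fit`.
#' @return gene-list tibble (`gene_id`, `direction`) of called genes, ordered
#'   by |d| descending.
#' @export
significant_genes <- function(fit) {
  stopifnot(inherits(fit, "sam_fit"))
  fit$gene_table |>
    dplyr::filter(.data$called) |>
    dplyr::arrange(dplyr::desc(abs(.data$d))) |>
    dplyr::select("gene_id", "direction")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat("Two-class SAM fit: ", x$contrast[1], " vs ", x$contrast[2],
      " (", x$n1, " + ", x$n2, " samples)\n", sep = "")
  cat(sprintf("  s0 = %.4g, delta = %.4g, pi0 = %.3f\n", x$s0, x$delta, x$pi0))
  cat(sprintf("  %d genes called at estimated FDR %.3g (target %.3g), %d permutations%s\n",
              sum(x$gene_table$called), x$fdr_estimate, x$target_fdr,
              x$n_permutations, if (x$exhaustive) " (exhaustive)" else ""))
  invisible(x)
}
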