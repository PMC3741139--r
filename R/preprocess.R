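#' Preprocessing parameters
#'
#' Bundles the tunable parameters of the in-study and external preprocessing
#' paths. Defaults follow the analysis recipe: features detected at
#' p <= 0.01 in at least 80% of samples are kept; the external RPKM path adds
#' an offset of 32, caps at 65,000 and removes the 50% least-varying genes.
#'
#' @param detection_p_threshold detection p-value call threshold, in (0, 1).
#' @param detection_sample_fraction minimum fraction of samples in which a
#'   gene must be detected, in (0, 1].
#' @param qspline_anchors number of quantile anchor points for
#'   [normalize_qspline()].
#' @param offset intensity offset added before capping (external path).
#' @param cap intensity ceiling applied after the offset.
#' @param variance_keep_fraction fraction of most-varying genes retained by
#'   [filter_variance()], in (0, 1].
#' @return a `preprocess_params` list.
#' @export
preprocess_params <- function(detection_p_threshold = 0.01,
                              detection_sample_fraction = 0.80,
                              qspline_anchors = 20,
                              offset = 32, cap = 65000,
                              variance_keep_fraction = 0.50) {
  stopifnot(detection_p_threshold > 0, detection_p_threshold < 1,
            detection_sample_fraction > 0, detection_sample_fraction <= 1,
            qspline_anchors >= 2, offset >= 0, cap > offset,
            variance_keep_fraction > 0, variance_keep_fraction <= 1)
  structure(list(detection_p_threshold = detection_p_threshold,
                 detection_sample_fraction = detection_sample_fraction,
                 qspline_anchors = as.integer(qspline_anchors),
                 offset = offset, cap = cap,
                 variance_keep_fraction = variance_keep_fraction),
            class = "preprocess_params")
}

#' Filter features on detection p-values
#'
#' Retains exactly the genes whose fraction of samples with detection p-value
#' at or below the threshold is at least `detection_sample_fraction` (the
#' boundary is inclusive: a gene detected in exactly 80% of samples at the
#' default is kept). Gene order is preserved.
#'
#' @param x linear-scale expression tibble.
#' @param detection detection-p tibble matching `x`; defaults to the table
#'   attached by [read_expression()] / [simulate_cohort()].
#' @param params a [preprocess_params()].
#' @return the filtered expression tibble (detection attribute filtered
#'   alongside).
#' @export
filter_detection <- function(x, detection = detection_p(x),
                             params = preprocess_params()) {
  if (is.null(detection)) {
    stop("no detection p-values available; attach a detection table or skip ",
         "the detection-filter stage explicitly", call. = FALSE)
  }
  validate_expr(x, detection = detection)
  dm <- as.matrix(detection[, -1, drop = FALSE])
  frac <- rowMeans(dm <= params$detection_p_threshold)
  keep <- frac >= params$detection_sample_fraction
  out <- x[keep, , drop = FALSE]
  attr(out, "detection_p") <- detection[keep, , drop = FALSE]
  out
}

#' Cubic-spline normalization against a mean-quantile reference
#'
#' Maps every sample through a monotone piecewise-cubic function fitted
#' between its own quantile anchors and the reference array's, where the
#' reference is the per-rank mean of the sorted sample values. Anchors are
#' `qspline_anchors` equally spaced quantiles including both extremes, so the
#' fitted map covers each sample's full range and positive input maps to
#' positive output; ranks within a sample are preserved and the output stays
#' on the linear scale.
#'
#' @inheritParams filter_detection
#' @return normalized expression tibble.
#' @export
normalize_qspline <- function(x, params = preprocess_params()) {
  validate_expr(x, positive = TRUE)
  modify_expr(x, function(m) {
    ref <- rowMeans(apply(m, 2, sort))
    probs <- seq(0, 1, length.out = params$qspline_anchors)
    qr <- stats::quantile(ref, probs, names = FALSE, type = 7)
    out <- m
    for (j in seq_len(ncol(m))) {
      qx <- stats::quantile(m[, j], probs, names = FALSE, type = 7)
      keep <- !duplicated(qx)
      if (sum(keep) < length(qx)) {
        warning("fewer distinct values than anchor points in sample ",
                colnames(m)[j], "; anchors reduced to ", sum(keep), call. = FALSE)
      }
      kx <- qx[keep]
      ky <- vapply(split(qr, cumsum(keep)), mean, numeric(1))
      if (length(kx) < 2) {
        out[, j] <- m[, j] - mean(kx) + mean(ky)
        next
      }
      ky <- cummax(ky)  # guard: reference quantiles are non-decreasing
      f <- stats::splinefun(kx, ky, method = "hyman")
      v <- m[, j]
      lo <- kx[1]; hi <- kx[length(kx)]
      y <- f(v)
      below <- v < lo; above <- v > hi
      if (any(below)) y[below] <- f(lo) + f(lo, deriv = 1) * (v[below] - lo)
      if (any(above)) y[above] <- f(hi) + f(hi, deriv = 1) * (v[above] - hi)
      out[, j] <- y
    }
    out
  })
}

#' Scale each plate to the global mean intensity
#'
#' Multiplies every sample on a plate by one scalar chosen so that all plate
#' mean intensities equal the global mean intensity; within-plate value ratios
#' are preserved exactly.
#'
#' @param x linear-scale expression tibble.
#' @param annotation annotation tibble carrying the `batch` (plate) labels.
#' @return scaled expression tibble.
#' @export
scale_plates <- function(x, annotation) {
  ann <- align_annotation(x, annotation)
  modify_expr(x, function(m) {
    global_mean <- mean(m)
    for (p in unique(ann$batch)) {
      cols <- which(ann$batch == p)
      pm <- mean(m[, cols, drop = FALSE])
      if (pm == 0) stop("plate ", p, " has zero mean intensity", call. = FALSE)
      m[, cols] <- m[, cols, drop = FALSE] * (global_mean / pm)
    }
    m
  })
}

#' Log2 transform and median-center genes across assays
#'
#' Replaces values by `log2(value)` and subtracts each gene's median across
#' samples, so every gene row has median zero afterwards.
#'
#' @param x strictly positive linear-scale expression tibble.
#' @return log2-scale, gene-median-centered expression tibble.
#' @export
log2_median_center <- function(x) {
  validate_expr(x, positive = TRUE)
  modify_expr(x, function(m) {
    lm2 <- log2(m)
    lm2 - apply(lm2, 1, stats::median)
  })
}

#' Quantile normalization
#'
#' Forces every sample's empirical distribution onto the per-rank mean
#' distribution; ties within a sample receive the mean of the target values at
#' their tied ranks (delegated to [limma::normalizeQuantiles()]).
#'
#' @param x expression tibble.
#' @return quantile-normalized expression tibble.
#' @export
normalize_quantiles <- function(x) {
  validate_expr(x)
  modify_expr(x, function(m) limma::normalizeQuantiles(m, ties = TRUE))
}

#' Add an intensity offset and cap
#'
#' Elementwise `min(value + offset, cap)`, in that order; monotone by
#' construction. Defaults map 0 to 32 and 70,000 to 65,000.
#'
#' @inheritParams filter_detection
#' @return offset-and-capped expression tibble.
#' @export
offset_and_cap <- function(x, params = preprocess_params()) {
  validate_expr(x)
  modify_expr(x, function(m) pmin(m + params$offset, params$cap))
}

#' Center each gene across samples
#'
#' @param x log2-scale expression tibble.
#' @param statistic `"median"` (the default, matching median-centering across
#'   assays) or `"mean"`.
#' @return centered expression tibble (the chosen statistic of every gene row
#'   is zero; idempotent).
#' @export
center_genes <- function(x, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  validate_expr(x)
  stat_fun <- if (statistic == "median") stats::median else mean
  modify_expr(x, function(m) m - apply(m, 1, stat_fun))
}

#' Adjust gene expression for a batch variable
#'
#' Per gene and batch, subtracts the batch mean and restores the gene's grand
#' mean, so each gene's batch means are exactly equal afterwards. A batch with
#' a single sample is rejected (the adjustment would zero that sample's
#' deviation entirely).
#'
#' @param x log2-scale expression tibble.
#' @param annotation annotation tibble carrying `batch` labels.
#' @return batch-mean-adjusted expression tibble.
#' @export
adjust_batch_means <- function(x, annotation) {
  ann <- align_annotation(x, annotation)
  sizes <- table(ann$batch)
  if (any(sizes < 2)) {
    stop("batch(es) with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  modify_expr(x, function(m) {
    grand <- rowMeans(m)
    for (b in unique(ann$batch)) {
      cols <- which(ann$batch == b)
      m[, cols] <- m[, cols, drop = FALSE] -
        rowMeans(m[, cols, drop = FALSE]) + grand
    }
    m
  })
}

#' Remove the least-varying genes
#'
#' Ranks genes by across-sample variance and retains the top
#' `ceil(variance_keep_fraction * n)`; ties are broken by input order (earlier
#' genes kept first) and the retained genes keep their input order.
#'
#' @inheritParams filter_detection
#' @return filtered expression tibble.
#' @export
filter_variance <- function(x, params = preprocess_params()) {
  validate_expr(x)
  m <- expr_values(x)
  if (ncol(m) < 2) stop("variance filtering needs >= 2 samples", call. = FALSE)
  v <- apply(m, 1, stats::var)
  k <- ceiling(params$variance_keep_fraction * nrow(m))
  ord <- order(v, decreasing = TRUE)  # stable: earlier genes win ties
  keep <- sort(ord[seq_len(k)])
  x[keep, , drop = FALSE]
}

#' In-study preprocessing path
#'
#' The composition applied to the profiled cohort: detection filtering, then
#' cubic-spline normalization, plate scaling, and log2 transform with
#' per-gene median centering.
#'
#' @param x linear-scale expression tibble with detection p-values.
#' @param annotation annotation tibble with plate (`batch`) labels.
#' @param detection detection-p tibble; defaults to the attached table.
#' @param params a [preprocess_params()].
#' @return log2-scale, median-centered expression tibble of detected genes.
#' @export
preprocess_cohort <- function(x, annotation, detection = detection_p(x),
                              params = preprocess_params()) {
  x |>
    filter_detection(detection, params) |>
    normalize_qspline(params) |>
    scale_plates(annotation) |>
    log2_median_center()
}

#' Harmonize an external RPKM-scale cohort
#'
#' The transfer recipe that makes RNA-seq abundance data comparable with the
#' array-derived signature: quantile normalization, an intensity offset of 32
#' capped at 65,000, log2 transform, per-gene median centering, batch-mean
#' adjustment, and removal of the 50% least-varying genes — applied in exactly
#' that order.
#'
#' @param x linear-scale (RPKM-like) expression tibble.
#' @param annotation annotation tibble with `batch` labels.
#' @param params a [preprocess_params()].
#' @param verbose print each stage as it runs.
#' @return log2-scale harmonized expression tibble.
#' @export
harmonize_external <- function(x, annotation, params = preprocess_params(),
                               verbose = FALSE) {
  stage <- function(label, val) {
    if (verbose) message("harmonize_external: ", label)
    val
  }
  x <- stage("quantile normalization", normalize_quantiles(x))
  x <- stage("offset and cap", offset_and_cap(x, params))
  x <- stage("log2 + gene median centering",
             modify_expr(x, function(m) {
               lm2 <- log2(m)
               lm2 - apply(lm2, 1, stats::median)
             }))
  x <- stage("batch-mean adjustment", adjust_batch_means(x, annotation))
  stage("variance filter", filter_variance(x, params))
}
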