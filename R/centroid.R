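#' Build per-class expression centroids over a signature
#'
#' Constructs the transferable signature classifier: for each class (by
#' default the two hereditary subsets, Lynch syndrome and FCCTX) and each
#' signature gene, the arithmetic mean expression across that class's
#' samples.
#'
#' @param x log2-scale expression tibble of the training cohort.
#' @param annotation annotation tibble.
#' @param signature gene list (tibble with `gene_id`, or character vector);
#'   every signature gene must be present in `x`.
#' @param classes length-2 character vector of class labels to average.
#' @param group_var annotation column holding the class labels.
#' @return a `centroid_model`: tibble of per-gene class means plus metadata.
#' @export
build_centroids <- function(x, annotation, signature,
                            classes = c("LYNCH", "FCCTX"),
                            group_var = "subtype") {
  stopifnot(length(classes) == 2)
  ann <- align_annotation(x, annotation)
  sig <- as_gene_list(signature)$gene_id
  missing_genes <- setdiff(sig, expr_gene_ids(x))
  if (length(missing_genes) > 0) {
    stop("signature gene(s) absent from training matrix: ",
         paste(utils::head(missing_genes, 10), collapse = ", "),
         if (length(missing_genes) > 10) ", ...", call. = FALSE)
  }
  m <- expr_values(x)[sig, , drop = FALSE]
  centroid <- vapply(classes, function(cl) {
    cols <- which(ann[[group_var]] == cl)
    if (length(cols) == 0) {
      stop("no training samples for class ", cl, call. = FALSE)
    }
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(length(sig)))
  out <- tibble::tibble(gene_id = sig)
  out[[classes[1]]] <- unname(centroid[, 1])
  out[[classes[2]]] <- unname(centroid[, 2])
  structure(list(centroids = out, classes = classes, group_var = group_var,
                 signature_size = length(sig),
                 n_train = table(ann[[group_var]])[classes]),
            class = "centroid_model")
}

#' @export
print.centroid_model <- function(x, ...) {
  cat("Nearest-centroid model: classes", paste(x$classes, collapse = " / "),
      "over", x$signature_size, "signature genes\n")
  invisible(x)
}

#' Nearest-centroid classification by maximum Pearson correlation
#'
#' Assigns each sample to the class whose centroid its expression correlates
#' with most strongly over the signature genes. Gene matching is exact-id
#' intersection; samples covering less than `min_overlap` of the signature
#' are rejected. Pearson correlation makes the call invariant to per-sample
#' positive affine transforms. Exact correlation ties are flagged and
#' reported unassigned.
#'
#' @param x log2-scale expression tibble to classify (e.g. a harmonized
#'   external cohort).
#' @param model a [build_centroids()] model.
#' @param min_overlap minimum fraction of signature genes that must be
#'   present in `x`, in (0, 1].
#' @return tibble with one row per sample: `sample_id`, one correlation
#'   column per class (`r_<class>`), `class` (NA when tied), `tie`, and the
#'   `gene_overlap` fraction used.
#' @export
classify_samples <- function(x, model, min_overlap = 0.5) {
  stopifnot(inherits(model, "centroid_model"))
  common <- intersect(model$centroids$gene_id, expr_gene_ids(x))
  overlap <- length(common) / model$signature_size
  if (overlap < min_overlap) {
    stop(sprintf(paste0("only %.1f%% of the %d signature genes are present ",
                        "(minimum %.1f%%)"),
                 100 * overlap, model$signature_size, 100 * min_overlap),
         call. = FALSE)
  }
  m <- expr_values(x)[common, , drop = FALSE]
  cen <- model$centroids[match(common, model$centroids$gene_id), ]
  c1 <- cen[[model$classes[1]]]
  c2 <- cen[[model$classes[2]]]
  const <- apply(m, 2, stats::sd) == 0
  if (any(const)) {
    stop("constant signature vector for sample ", colnames(m)[which(const)[1]],
         "; correlation undefined", call. = FALSE)
  }
  r1 <- as.numeric(stats::cor(m, c1))
  r2 <- as.numeric(stats::cor(m, c2))
  tie <- r1 == r2
  cls <- ifelse(tie, NA_character_,
                ifelse(r1 > r2, model$classes[1], model$classes[2]))
  out <- tibble::tibble(sample_id = colnames(m))
  out[[paste0("r_", model$classes[1])]] <- r1
  out[[paste0("r_", model$classes[2])]] <- r2
  out$class <- cls
  out$tie <- tie
  out$gene_overlap <- overlap
  out
}

#' Summarize classification accuracy by MMR status
#'
#' The study's external-validation readout: the fraction of MMR-proficient
#' samples assigned to the FCCTX centroid and of MMR-deficient samples
#' assigned to the Lynch-syndrome centroid. Ties count as incorrect. Groups
#' with no samples are omitted from the summary.
#'
#' @param assignments tibble from [classify_samples()].
#' @param annotation annotation tibble with `mmr_status` for every classified
#'   sample.
#' @param deficient_class,proficient_class which model class counts as the
#'   correct call for each MMR group.
#' @return a `classification_report`: list with `per_sample` (assignments
#'   joined with MMR status and correctness) and `summary` (per-MMR-group
#'   counts and accuracy fractions).
#' @export
evaluate_by_mmr <- function(assignments, annotation,
                            deficient_class = "LYNCH",
                            proficient_class = "FCCTX") {
  ann <- validate_annotation(annotation)
  missing_samples <- setdiff(assignments$sample_id, ann$sample_id)
  if (length(missing_samples) > 0) {
    stop("classified sample(s) lack annotation: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  per_sample <- assignments |>
    dplyr::left_join(dplyr::select(ann, "sample_id", "mmr_status"),
                     by = "sample_id") |>
    dplyr::mutate(
      expected = ifelse(.data$mmr_status == "deficient",
                        deficient_class, proficient_class),
      correct = !is.na(.data$class) & .data$class == .data$expected
    )
  summary <- per_sample |>
    dplyr::group_by(.data$mmr_status) |>
    dplyr::summarise(n = dplyr::n(),
                     n_correct = sum(.data$correct),
                     accuracy = mean(.data$correct),
                     .groups = "drop") |>
    dplyr::mutate(assigned_class = ifelse(.data$mmr_status == "deficient",
                                          deficient_class, proficient_class))
  structure(list(per_sample = per_sample, summary = summary,
                 gene_overlap = assignments$gene_overlap[1]),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Nearest-centroid classification by MMR status\n")
  for (i in seq_len(nrow(x$summary))) {
    row <- x$summary[i, ]
    cat(sprintf("  MMR %-10s -> %s: %d/%d (%.0f%%)\n", row$mmr_status,
                row$assigned_class, row$n_correct, row$n, 100 * row$accuracy))
  }
  cat(sprintf("  signature overlap used: %.0f%%\n", 100 * x$gene_overlap))
  invisible(x)
}
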