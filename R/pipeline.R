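#' Configure an end-to-end pipeline run
#'
#' Bundles every stage parameter for [run_pipeline()]. One global seed
#' deterministically derives the per-stage seeds (simulation, SAM contrasts),
#' so individual stages can be re-run reproducibly; any seed set inside the
#' stage configs is overridden by this derivation.
#'
#' @param output_dir directory for run artifacts (created if needed).
#' @param seed global integer seed.
#' @param synthetic a [synthetic_config()] (simulate mode).
#' @param preprocess a [preprocess_params()].
#' @param sam a [sam_config()].
#' @param min_overlap classifier gene-overlap guard, see [classify_samples()].
#' @param inputs `NULL` for simulate mode, or a named list of TSV paths
#'   (`expression`, `detection`, `annotation`, optionally
#'   `external_expression` + `external_annotation`) for ingest mode.
#' @param external run the external harmonization + classification stages
#'   (always skipped when ingest mode supplies no external cohort).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, seed = 1L,
                            synthetic = synthetic_config(),
                            preprocess = preprocess_params(),
                            sam = sam_config(),
                            min_overlap = 0.5,
                            inputs = NULL,
                            external = TRUE) {
  seed <- as.integer(seed)
  synthetic$seed <- derive_seed(seed, 1)
  sam$seed <- derive_seed(seed, 2)
  if (!is.null(inputs)) {
    need <- c("expression", "annotation")
    miss <- setdiff(need, names(inputs))
    if (length(miss) > 0) {
      stop("ingest mode needs input path(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    missing_files <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(missing_files) > 0) {
      stop("input file(s) not found: ", paste(missing_files, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(output_dir = output_dir, seed = seed, synthetic = synthetic,
                 preprocess = preprocess, sam = sam,
                 min_overlap = min_overlap, inputs = inputs,
                 external = external),
            class = "pipeline_config")
}

#' Run the full signature pipeline
#'
#' Executes, in order: cohort simulation (or TSV ingestion), the in-study
#' preprocessing path (detection filter, cubic-spline normalization, plate
#' scaling, log2 + median centering), SAM for the hereditary
#' (FCCTX vs Lynch) and the MMR-status contrasts at the target FDR,
#' average-linkage clustering of the cohort with the two-cluster/MMR
#' agreement, centroid training on the hereditary subset, and — when an
#' external cohort is available — RPKM harmonization plus nearest-centroid
#' classification summarized by MMR group. Every artifact is written as TSV
#' or JSON under `output_dir`; a fixed config and seed reproduce all numeric
#' artifacts byte for byte. In simulate mode the run summary also reports
#' signature recovery (sensitivity and realized FDR) against the planted
#' truth.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return invisibly, a list with the in-memory stage results (`cohort`,
#'   `preprocessed`, `sam_subtype`, `sam_mmr`, `tree`, `clusters`, `centroids`,
#'   `external`, `report`, `summary`); the `summary` is also written as
#'   `run_summary.json`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  simulate_mode <- is.null(config$inputs)

  stage_wrap <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("cohort")
  cohort <- stage_wrap("cohort", {
    if (simulate_mode) {
      simulate_cohort(config$synthetic)
    } else {
      expr <- read_expression(config$inputs$expression,
                              config$inputs$detection)
      list(expression = expr, detection = detection_p(expr),
           annotation = read_annotation(config$inputs$annotation),
           truth = NULL)
    }
  })
  write_expression(cohort$expression, out("expression.tsv"))
  if (!is.null(cohort$detection)) {
    write_expression(cohort$detection, out("detection.tsv"))
  }
  write_annotation(cohort$annotation, out("annotation.tsv"))
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(list(
      seed = cohort$truth$seed,
      mmr_genes = cohort$truth$mmr_genes,
      subtype_genes = cohort$truth$subtype_genes,
      plate = cohort$truth$plate
    ), out("truth.json"), digits = NA)
  }

  say("preprocess")
  pre <- stage_wrap("preprocess", {
    if (is.null(cohort$detection)) {
      cohort$expression |>
        normalize_qspline(config$preprocess) |>
        scale_plates(cohort$annotation) |>
        log2_median_center()
    } else {
      preprocess_cohort(cohort$expression, cohort$annotation,
                        cohort$detection, config$preprocess)
    }
  })
  write_expression(pre, out("preprocessed.tsv"))

  say("SAM: hereditary contrast (FCCTX vs LYNCH)")
  sam_subtype <- stage_wrap("sam_subtype",
    sam_two_class(pre, cohort$annotation, c("FCCTX", "LYNCH"),
                  group_var = "subtype", config = config$sam))
  readr::write_tsv(tidy(sam_subtype), out("sam_subtype.tsv"))
  signature <- significant_genes(sam_subtype)
  write_gene_list(signature, out("signature.tsv"))

  say("SAM: MMR-status contrast")
  sam_mmr <- stage_wrap("sam_mmr",
    sam_two_class(pre, cohort$annotation, c("proficient", "deficient"),
                  group_var = "mmr_status", config = config$sam))
  readr::write_tsv(tidy(sam_mmr), out("sam_mmr.tsv"))
  write_gene_list(significant_genes(sam_mmr), out("mmr_signature.tsv"))

  say("clustering")
  tree <- stage_wrap("clustering", upgma(pearson_distance(pre)))
  clusters <- cut_two(tree)
  mmr_truth <- cohort$annotation$mmr_status
  names(mmr_truth) <- cohort$annotation$sample_id
  agreement <- cluster_agreement(clusters, mmr_truth)
  readr::write_tsv(tibble::tibble(step = seq_along(tree$height),
                                  left = tree$merge[, 1],
                                  right = tree$merge[, 2],
                                  height = tree$height),
                   out("cluster_merges.tsv"))
  readr::write_tsv(clusters, out("cluster_groups.tsv"))

  say("centroid training")
  centroids <- stage_wrap("centroids", {
    if (nrow(signature) >= 2) {
      build_centroids(pre, cohort$annotation, signature)
    } else NULL
  })
  if (!is.null(centroids)) {
    readr::write_tsv(centroids$centroids, out("centroids.tsv"))
  }

  external <- NULL
  report <- NULL
  run_external <- !is.null(centroids) &&
    ((simulate_mode && config$external) ||
       (!simulate_mode && !is.null(config$inputs$external_expression)))
  if (run_external) {
    say("external harmonization + classification")
    external <- stage_wrap("external", {
      ext <- if (simulate_mode) {
        simulate_external_cohort(config$synthetic, signature)
      } else {
        list(expression = read_expression(config$inputs$external_expression),
             annotation = read_annotation(config$inputs$external_annotation))
      }
      ext$harmonized <- harmonize_external(ext$expression, ext$annotation,
                                           config$preprocess)
      ext
    })
    write_expression(external$harmonized, out("harmonized_external.tsv"))
    write_annotation(external$annotation, out("external_annotation.tsv"))
    report <- stage_wrap("classification", {
      assignments <- classify_samples(external$harmonized, centroids,
                                      config$min_overlap)
      evaluate_by_mmr(assignments, external$annotation)
    })
    readr::write_tsv(tidy(report), out("classification.tsv"))
  }

  recovery <- if (!is.null(cohort$truth)) {
    analyzed <- expr_gene_ids(pre)
    truth_subtype <- union(cohort$truth$subtype_genes$gene_id,
                           cohort$truth$mmr_genes$gene_id)
    truth_mmr <- cohort$truth$mmr_genes$gene_id
    list(
      subtype = recovery_metrics(signature$gene_id,
                                 intersect(truth_subtype, analyzed)),
      mmr = recovery_metrics(significant_genes(sam_mmr)$gene_id,
                             intersect(truth_mmr, analyzed))
    )
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("mmrsig")),
    seed = config$seed,
    stage_seeds = list(simulation = config$synthetic$seed,
                       sam = config$sam$seed),
    mode = if (simulate_mode) "simulate" else "ingest",
    n_genes_input = nrow(cohort$expression),
    n_genes_detected = nrow(pre),
    n_samples = length(expr_sample_ids(cohort$expression)),
    sam_subtype = as.list(glance(sam_subtype)),
    sam_mmr = as.list(glance(sam_mmr)),
    cluster_mmr_agreement = agreement,
    recovery = recovery,
    classification = if (!is.null(report)) as.list(glance(report)),
    parameters = list(preprocess = unclass(config$preprocess),
                      sam = unclass(config$sam),
                      synthetic = if (simulate_mode) {
                        lapply(unclass(config$synthetic), unname)
                      },
                      min_overlap = config$min_overlap),
    artifacts = artifact_hashes(config$output_dir)
  )
  jsonlite::write_json(summary, out("run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, preprocessed = pre,
                 sam_subtype = sam_subtype, sam_mmr = sam_mmr,
                 tree = tree, clusters = clusters, agreement = agreement,
                 centroids = centroids, external = external, report = report,
                 summary = summary))
}

recovery_metrics <- function(called, truth) {
  tp <- length(intersect(called, truth))
  list(n_called = length(called), n_true = length(truth),
       sensitivity = if (length(truth)) tp / length(truth) else NA,
       realized_fdr = if (length(called)) {
         (length(called) - tp) / length(called)
       } else 0)
}

artifact_hashes <- function(dir) {
  files <- sort(setdiff(list.files(dir), "run_summary.json"))
  hashes <- tools::md5sum(file.path(dir, files))
  as.list(stats::setNames(unname(hashes), files))
}
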