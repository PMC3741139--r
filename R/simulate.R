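#' Configure the synthetic cohort generator
#'
#' Builds the configuration for a simulated colorectal-cancer expression
#' cohort with the structure the analysis assumes: a dominant mismatch-repair
#' (MMR) status effect, a weaker hereditary-subtype (Lynch vs FCCTX) effect
#' restricted to the hereditary tumors, gene-specific plate effects, and
#' detection p-values that fall with signal intensity. Default group sizes are
#' the study cohort: 39 Lynch, 37 FCCTX, 26 sporadic MMR-deficient and 21
#' sporadic MMR-proficient tumors.
#'
#' Planted effects are additive on the log2 scale with signs drawn +/-1 with
#' equal probability and magnitudes uniform in `[effect_low, effect_high]`.
#' The MMR-effect and subtype-effect gene sets are disjoint. Detection
#' p-values follow `p = 1 - pnorm((signal - detection_tau) / detection_slope)`,
#' so brighter features are detected more reliably.
#'
#' @param n_genes number of genes in the simulated universe.
#' @param group_sizes named integer vector of samples per subtype, in the order
#'   `LYNCH`, `FCCTX`, `SPORADIC_MMR_DEFICIENT`, `SPORADIC_MMR_PROFICIENT`.
#' @param n_mmr_genes genes carrying an MMR-status effect.
#' @param n_subtype_genes genes carrying a Lynch-vs-FCCTX effect (hereditary
#'   samples only; sporadic tumors receive only the MMR effect).
#' @param effect_low,effect_high bounds of planted |log2 fold change|.
#' @param baseline_mean,baseline_sd per-gene baseline log2-intensity location.
#' @param noise_sd_low,noise_sd_high bounds of per-gene residual log2 sd.
#' @param n_plates,plate_sd number of plates and sd of the gene-specific
#'   additive log2 plate offsets; samples are assigned to plates round-robin so
#'   plates stay balanced across subtypes.
#' @param detection_tau,detection_slope location/scale linking log2 signal to
#'   the detection p-value.
#' @param n_external named sizes (`deficient`, `proficient`) of the external
#'   RPKM-scale validation cohort.
#' @param n_batches,library_size_sd batch count and per-sample log2
#'   library-size sd of the external cohort.
#' @param seed integer seed; fixed seed gives bit-reproducible output.
#' @return a `synthetic_config` list.
#' @seealso [simulate_cohort()], [simulate_external_cohort()]
#' @export
synthetic_config <- function(n_genes = 2000,
                             group_sizes = c(LYNCH = 39, FCCTX = 37,
                                             SPORADIC_MMR_DEFICIENT = 26,
                                             SPORADIC_MMR_PROFICIENT = 21),
                             n_mmr_genes = 400,
                             n_subtype_genes = 200,
                             effect_low = 0.75, effect_high = 1.5,
                             baseline_mean = 8, baseline_sd = 2,
                             noise_sd_low = 0.3, noise_sd_high = 0.6,
                             n_plates = 3, plate_sd = 0.25,
                             detection_tau = 5, detection_slope = 1,
                             n_external = c(deficient = 30, proficient = 30),
                             n_batches = 4, library_size_sd = 0.25,
                             seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), group_sizes = group_sizes,
    n_mmr_genes = as.integer(n_mmr_genes),
    n_subtype_genes = as.integer(n_subtype_genes),
    effect_low = effect_low, effect_high = effect_high,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    noise_sd_low = noise_sd_low, noise_sd_high = noise_sd_high,
    n_plates = as.integer(n_plates), plate_sd = plate_sd,
    detection_tau = detection_tau, detection_slope = detection_slope,
    n_external = n_external, n_batches = as.integer(n_batches),
    library_size_sd = library_size_sd, seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1 || any(group_sizes < 1) || n_plates < 1 || n_batches < 1) {
      stop("all counts in a synthetic_config must be positive", call. = FALSE)
    }
    if (!identical(sort(names(group_sizes)), sort(names(.subtype_mmr)))) {
      stop("group_sizes must name the four subtypes", call. = FALSE)
    }
    if (n_mmr_genes < 0 || n_subtype_genes < 0 ||
        n_mmr_genes + n_subtype_genes > n_genes) {
      stop("planted gene sets must be disjoint and fit in n_genes", call. = FALSE)
    }
    if (effect_low > effect_high || noise_sd_low > noise_sd_high) {
      stop("effect / noise-sd bounds must be ordered (low <= high)", call. = FALSE)
    }
    if (plate_sd < 0 || library_size_sd < 0 || detection_slope <= 0) {
      stop("plate_sd / library_size_sd must be >= 0 and detection_slope > 0",
           call. = FALSE)
    }
    if (any(n_external < 1) ||
        !all(c("deficient", "proficient") %in% names(n_external))) {
      stop("n_external must give positive 'deficient' and 'proficient' sizes",
           call. = FALSE)
    }
  })
  cfg
}

#' Evaluate code under a temporary RNG seed
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483629)
}

#' Gene-level parameters are a pure function of the config seed, so the study
#' cohort and the external cohort share the same planted truth.
#' @noRd
gene_params <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 0), {
    n <- cfg$n_genes
    width <- nchar(as.character(n))
    gene_ids <- sprintf(paste0("g%0", width, "d"), seq_len(n))
    baseline <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
    noise_sd <- stats::runif(n, cfg$noise_sd_low, cfg$noise_sd_high)
    planted <- sample.int(n, cfg$n_mmr_genes + cfg$n_subtype_genes)
    mmr_idx <- planted[seq_len(cfg$n_mmr_genes)]
    sub_idx <- planted[cfg$n_mmr_genes + seq_len(cfg$n_subtype_genes)]
    draw_effect <- function(k) {
      sample(c(-1, 1), k, replace = TRUE) * stats::runif(k, cfg$effect_low, cfg$effect_high)
    }
    mmr_effect <- numeric(n); mmr_effect[mmr_idx] <- draw_effect(cfg$n_mmr_genes)
    sub_effect <- numeric(n); sub_effect[sub_idx] <- draw_effect(cfg$n_subtype_genes)
    plate_off <- matrix(stats::rnorm(n * cfg$n_plates, 0, cfg$plate_sd),
                        n, cfg$n_plates)
    batch_off <- matrix(stats::rnorm(n * cfg$n_batches, 0, cfg$plate_sd),
                        n, cfg$n_batches)
    list(gene_ids = gene_ids, baseline = baseline, noise_sd = noise_sd,
         mmr_idx = mmr_idx, sub_idx = sub_idx,
         mmr_effect = mmr_effect, sub_effect = sub_effect,
         plate_off = plate_off, batch_off = batch_off)
  })
}

#' Simulate the four-subtype study cohort
#'
#' Generates a linear-scale expression table (values are `2^signal` with the
#' log2 signal built as baseline + MMR effect + subtype effect + plate effect
#' + Gaussian noise), a matching detection-p table, per-sample annotations
#' with round-robin plate assignment, and the planted ground truth.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `expression` (linear-scale tibble, detection
#'   table also attached as attribute `"detection_p"`), `detection`,
#'   `annotation`, and `truth` (class `synthetic_truth`: tibbles of planted
#'   MMR-effect and subtype-effect genes with signed log2 effects, plate
#'   assignments, seed).
#' @examples
#' cohort <- simulate_cohort(synthetic_config(n_genes = 50, seed = 7))
#' nrow(cohort$annotation)  # 39 + 37 + 26 + 21 = 123 samples
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_synthetic_config(config)
  gp <- gene_params(cfg)
  sizes <- cfg$group_sizes[c("LYNCH", "FCCTX", "SPORADIC_MMR_DEFICIENT",
                             "SPORADIC_MMR_PROFICIENT")]
  subtype <- rep(names(sizes), times = sizes)
  n_s <- length(subtype)
  prefix <- c(LYNCH = "L", FCCTX = "F", SPORADIC_MMR_DEFICIENT = "SD",
              SPORADIC_MMR_PROFICIENT = "SP")
  sample_id <- unlist(lapply(names(sizes), function(g) {
    sprintf("%s%02d", prefix[[g]], seq_len(sizes[[g]]))
  }), use.names = FALSE)
  plate <- sprintf("plate%d", ((seq_len(n_s) - 1L) %% cfg$n_plates) + 1L)
  deficient <- mmr_status_of(subtype) == "deficient"
  is_lynch <- subtype == "LYNCH"

  signal <- with_seed(derive_seed(cfg$seed, 1), {
    mu <- outer(gp$baseline, rep(1, n_s)) +
      outer(gp$mmr_effect, as.numeric(deficient)) +
      outer(gp$sub_effect, as.numeric(is_lynch)) +
      gp$plate_off[, as.integer(sub("plate", "", plate)), drop = FALSE]
    mu + matrix(stats::rnorm(cfg$n_genes * n_s, 0, gp$noise_sd),
                cfg$n_genes, n_s)
  })
  detect <- 1 - stats::pnorm((signal - cfg$detection_tau) / cfg$detection_slope)

  expression <- expr_tbl(2^signal, gp$gene_ids, sample_id)
  detection <- expr_tbl(detect, gp$gene_ids, sample_id)
  attr(expression, "detection_p") <- detection
  annotation <- validate_annotation(tibble::tibble(
    sample_id = sample_id, subtype = subtype, batch = plate
  ))
  truth <- structure(list(
    mmr_genes = tibble::tibble(gene_id = gp$gene_ids[gp$mmr_idx],
                               effect = gp$mmr_effect[gp$mmr_idx]),
    subtype_genes = tibble::tibble(gene_id = gp$gene_ids[gp$sub_idx],
                                   effect = gp$sub_effect[gp$sub_idx]),
    plate = tibble::tibble(sample_id = sample_id, plate = plate),
    seed = cfg$seed
  ), class = "synthetic_truth")
  list(expression = expression, detection = detection,
       annotation = annotation, truth = truth)
}

#' Simulate an external RPKM-scale validation cohort
#'
#' Emulates an RNA-seq validation set: a two-class (MMR deficient vs
#' proficient) cohort on a positive RPKM-like scale, sharing the planted
#' MMR-effect genes of the study cohort generated from the same config, with
#' gene-specific batch offsets and per-sample library-size factors. Values are
#' `2^(baseline + mmr_effect + batch_offset + library_size + noise)`.
#'
#' @param config a [synthetic_config()].
#' @param centroid_genes optional gene list (or character vector); an error is
#'   raised if it does not overlap the generator's gene universe.
#' @return list with `expression` (linear-scale tibble) and `annotation`
#'   (subtypes `SPORADIC_MMR_DEFICIENT` / `SPORADIC_MMR_PROFICIENT`, batch
#'   labels).
#' @export
simulate_external_cohort <- function(config, centroid_genes = NULL) {
  cfg <- validate_synthetic_config(config)
  gp <- gene_params(cfg)
  if (!is.null(centroid_genes)) {
    ids <- as_gene_list(centroid_genes)$gene_id
    if (length(intersect(ids, gp$gene_ids)) == 0) {
      stop("centroid gene list does not overlap the simulated gene universe",
           call. = FALSE)
    }
  }
  n_def <- cfg$n_external[["deficient"]]
  n_pro <- cfg$n_external[["proficient"]]
  n_s <- n_def + n_pro
  subtype <- rep(c("SPORADIC_MMR_DEFICIENT", "SPORADIC_MMR_PROFICIENT"),
                 c(n_def, n_pro))
  sample_id <- sprintf("EXT%03d", seq_len(n_s))
  batch <- sprintf("batch%d", ((seq_len(n_s) - 1L) %% cfg$n_batches) + 1L)
  deficient <- subtype == "SPORADIC_MMR_DEFICIENT"

  signal <- with_seed(derive_seed(cfg$seed, 2), {
    libsize <- stats::rnorm(n_s, 0, cfg$library_size_sd)
    mu <- outer(gp$baseline, rep(1, n_s)) +
      outer(gp$mmr_effect, as.numeric(deficient)) +
      gp$batch_off[, as.integer(sub("batch", "", batch)), drop = FALSE] +
      outer(rep(1, cfg$n_genes), libsize)
    mu + matrix(stats::rnorm(cfg$n_genes * n_s, 0, gp$noise_sd),
                cfg$n_genes, n_s)
  })
  expression <- expr_tbl(2^signal, gp$gene_ids, sample_id)
  annotation <- validate_annotation(tibble::tibble(
    sample_id = sample_id, subtype = subtype, batch = batch
  ))
  list(expression = expression, annotation = annotation)
}

#' Default clinical proportions per subtype
#'
#' Per-subtype percentages of proximal tumor location, high/moderate
#' differentiation and stage I/II/III distribution used by
#' [simulate_clinical()], as reported for the study cohort. Stage rows are
#' renormalized to sum to one before sampling (one printed row sums to 92%).
#'
#' @return tibble with one row per subtype.
#' @export
clinical_proportions <- function() {
  tibble::tibble(
    subtype = c("LYNCH", "FCCTX", "SPORADIC_MMR_DEFICIENT",
                "SPORADIC_MMR_PROFICIENT"),
    proximal = c(0.77, 0.05, 0.81, 0.52),
    high_moderate = c(0.67, 0.92, 0.46, 0.86),
    stage_I = c(13, 8, 4, 0),
    stage_II = c(51, 43, 73, 43),
    stage_III = c(36, 49, 15, 57)
  )
}

#' Attach simulated clinical covariates to an annotation table
#'
#' Samples tumor location, differentiation grade and stage independently per
#' sample from the subtype's proportions.
#'
#' @param annotation annotation tibble (from [simulate_cohort()] or
#'   [read_annotation()]).
#' @param proportions per-subtype probability table, see
#'   [clinical_proportions()]; probabilities outside \[0, 1\] are rejected.
#' @param seed integer seed.
#' @return the annotation tibble with `location`, `differentiation` and
#'   `stage` columns added.
#' @export
simulate_clinical <- function(annotation, proportions = clinical_proportions(),
                              seed = 1L) {
  ann <- validate_annotation(annotation)
  pr <- tibble::as_tibble(proportions)
  if (any(pr$proximal < 0 | pr$proximal > 1) ||
      any(pr$high_moderate < 0 | pr$high_moderate > 1) ||
      any(pr$stage_I < 0) || any(pr$stage_II < 0) || any(pr$stage_III < 0)) {
    stop("clinical proportions must be probabilities in [0, 1] (stages >= 0)",
         call. = FALSE)
  }
  missing_sub <- setdiff(unique(ann$subtype), pr$subtype)
  if (length(missing_sub) > 0) {
    stop("no clinical proportions for subtype(s): ",
         paste(missing_sub, collapse = ", "), call. = FALSE)
  }
  row <- pr[match(ann$subtype, pr$subtype), , drop = FALSE]
  with_seed(seed, {
    n <- nrow(ann)
    ann$location <- ifelse(stats::runif(n) < row$proximal, "proximal", "distal")
    ann$differentiation <- ifelse(stats::runif(n) < row$high_moderate,
                                  "high_moderate", "low")
    stage_p <- as.matrix(row[, c("stage_I", "stage_II", "stage_III")])
    stage_p <- stage_p / rowSums(stage_p)
    u <- stats::runif(n)
    cum1 <- stage_p[, 1]; cum2 <- stage_p[, 1] + stage_p[, 2]
    ann$stage <- ifelse(u < cum1, "I", ifelse(u < cum2, "II", "III"))
  })
  ann
}
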