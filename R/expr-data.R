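#' Expression tables
#'
#' Throughout the package an expression cohort is an ordinary tibble whose
#' first column, `gene_id`, holds unique gene identifiers and whose remaining
#' columns are numeric per-sample expression values (genes in rows, samples in
#' columns). Detection p-values travel in a second tibble of identical layout.
#' These helpers build, validate and convert such tables.
#'
#' @param values numeric matrix, genes in rows and samples in columns.
#' @param gene_ids character vector of unique gene identifiers; defaults to the
#'   matrix row names.
#' @param sample_ids character vector of unique sample identifiers; defaults to
#'   the matrix column names.
#' @return `expr_tbl()` returns a tibble with a `gene_id` column followed by
#'   one numeric column per sample; `expr_values()` the reverse conversion, a
#'   numeric matrix with gene ids as row names.
#' @examples
#' m <- matrix(1:6, 2, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' x <- expr_tbl(m)
#' identical(expr_values(x), m * 1.0)
#' @export
expr_tbl <- function(values, gene_ids = rownames(values),
                     sample_ids = colnames(values)) {
  stopifnot(is.matrix(values), !is.null(gene_ids), !is.null(sample_ids))
  values <- matrix(as.numeric(values), nrow(values), ncol(values))
  colnames(values) <- sample_ids
  out <- tibble::as_tibble(values, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(gene_id = as.character(gene_ids)), out)
  validate_expr(out)
}

#' @rdname expr_tbl
#' @param x an expression tibble (`gene_id` column plus numeric sample columns).
#' @export
expr_values <- function(x) {
  x <- validate_expr(x)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$gene_id
  storage.mode(m) <- "double"
  m
}

#' @rdname expr_tbl
#' @export
expr_gene_ids <- function(x) validate_expr(x)$gene_id

#' @rdname expr_tbl
#' @export
expr_sample_ids <- function(x) setdiff(names(validate_expr(x)), "gene_id")

#' Validate an expression tibble
#'
#' Checks the structural invariants every pipeline stage relies on: a leading
#' `gene_id` column with unique non-missing ids, all-numeric sample columns
#' with unique names, and finite values. Optionally enforces the linear-scale
#' contract (non-negative or strictly positive values) and that a companion
#' detection-p table matches the expression table gene-for-gene and
#' sample-for-sample with entries in \[0, 1\].
#'
#' @param x expression tibble.
#' @param positive require all values strictly positive (e.g. ahead of log2).
#' @param nonnegative require all values >= 0 (linear-scale contract).
#' @param detection optional detection-p tibble to check against `x`.
#' @return `x`, invisibly unchanged, for chaining; errors describe the first
#'   offending gene or sample.
#' @export
validate_expr <- function(x, positive = FALSE, nonnegative = FALSE,
                          detection = NULL) {
  if (!is.data.frame(x) || ncol(x) < 2 || names(x)[1] != "gene_id") {
    stop("expression table must have a leading 'gene_id' column plus >=1 sample column",
         call. = FALSE)
  }
  ids <- x$gene_id
  if (anyNA(ids)) stop("missing gene_id", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicated gene_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop("duplicated sample id: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  }
  vals <- x[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric sample column(s): ", paste(names(vals)[bad], collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(vals)
  if (any(!is.finite(m))) {
    g <- ids[which(rowSums(!is.finite(m)) > 0)[1]]
    stop("non-finite expression value (gene ", g, ")", call. = FALSE)
  }
  if (positive && any(m <= 0)) {
    idx <- which(m <= 0, arr.ind = TRUE)[1, ]
    stop("non-positive value at gene ", ids[idx[1]], ", sample ",
         colnames(m)[idx[2]], " (strictly positive values required)", call. = FALSE)
  }
  if (nonnegative && any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative value at gene ", ids[idx[1]], ", sample ", colnames(m)[idx[2]],
         " (linear-scale values must be >= 0)", call. = FALSE)
  }
  if (!is.null(detection)) {
    d <- validate_expr(detection)
    if (!identical(d$gene_id, ids) || !identical(names(d), names(x))) {
      stop("detection-p table does not match the expression table's genes/samples",
           call. = FALSE)
    }
    dm <- as.matrix(d[, -1, drop = FALSE])
    if (any(dm < 0 | dm > 1)) {
      stop("detection p-values must lie in [0, 1]", call. = FALSE)
    }
  }
  invisible(x)
  x
}

#' Rebuild an expression tibble around transformed values
#'
#' Internal helper: applies `f` to the numeric matrix of `x` and re-wraps the
#' result, preserving gene and sample order.
#' @noRd
modify_expr <- function(x, f, ...) {
  m <- expr_values(x)
  out <- f(m, ...)
  expr_tbl(out, rownames(out) %||% rownames(m),
           colnames(out) %||% colnames(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive mismatch-repair status from tumor subtype
#'
#' The four in-study subtypes determine MMR status: Lynch-syndrome and sporadic
#' MMR-deficient tumors are `"deficient"`; FCCTX (familial colorectal cancer
#' type X) and sporadic MMR-proficient tumors are `"proficient"`.
#'
#' @param subtype character vector of subtype tokens (`LYNCH`, `FCCTX`,
#'   `SPORADIC_MMR_DEFICIENT`, `SPORADIC_MMR_PROFICIENT`).
#' @return character vector of `"deficient"` / `"proficient"`.
#' @export
mmr_status_of <- function(subtype) {
  ok <- subtype %in% names(.subtype_mmr)
  if (!all(ok)) {
    stop("unknown subtype token(s): ", paste(unique(subtype[!ok]), collapse = ", "),
         call. = FALSE)
  }
  unname(.subtype_mmr[subtype])
}

.subtype_mmr <- c(
  LYNCH = "deficient",
  SPORADIC_MMR_DEFICIENT = "deficient",
  FCCTX = "proficient",
  SPORADIC_MMR_PROFICIENT = "proficient"
)

#' Validate a sample annotation tibble
#'
#' An annotation table needs `sample_id`, `subtype` and `batch` columns; the
#' `mmr_status` column is (re)derived from subtype so the two can never
#' disagree. Optional clinical columns (`location`, `differentiation`, `stage`,
#' `age`, `sex`) pass through untouched.
#'
#' @param ann data frame of per-sample annotations.
#' @param expr optional expression tibble; if given, every annotated sample
#'   must be a column of it.
#' @return annotation tibble with `mmr_status` populated.
#' @export
validate_annotation <- function(ann, expr = NULL) {
  need <- c("sample_id", "subtype", "batch")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0) {
    stop("annotation is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ann <- tibble::as_tibble(ann)
  ann$sample_id <- as.character(ann$sample_id)
  ann$batch <- as.character(ann$batch)
  if (anyDuplicated(ann$sample_id)) {
    stop("duplicated sample_id in annotation", call. = FALSE)
  }
  ann$mmr_status <- mmr_status_of(ann$subtype)
  if (!is.null(expr)) {
    missing_samples <- setdiff(ann$sample_id, expr_sample_ids(expr))
    if (length(missing_samples) > 0) {
      stop("annotated sample(s) absent from expression table: ",
           paste(missing_samples, collapse = ", "), call. = FALSE)
    }
  }
  ann
}

#' Align an annotation table to an expression table's sample order
#' @noRd
align_annotation <- function(expr, ann) {
  ann <- validate_annotation(ann, expr)
  ids <- expr_sample_ids(expr)
  missing_ann <- setdiff(ids, ann$sample_id)
  if (length(missing_ann) > 0) {
    stop("sample(s) lack annotation: ", paste(missing_ann, collapse = ", "),
         call. = FALSE)
  }
  ann[match(ids, ann$sample_id), , drop = FALSE]
}
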