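#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of sample ids, a first column of gene ids, and one
#' numeric cell per gene/sample. Duplicate gene ids, NA tokens, ragged rows and
#' non-numeric cells are rejected with an error naming the offender — analysis
#' inputs are never imputed or silently reordered.
#'
#' @param path path to the expression TSV.
#' @param detection_path optional path to a detection-p TSV of identical
#'   layout (same genes, same samples, same order).
#' @return an expression tibble; when `detection_path` is given, the detection
#'   table is attached as attribute `"detection_p"` (see [detection_p()]).
#' @seealso [write_expression()], [filter_detection()]
#' @export
read_expression <- function(path, detection_path = NULL) {
  x <- read_expr_tsv(path)
  if (!is.null(detection_path)) {
    d <- read_expr_tsv(detection_path)
    validate_expr(x, detection = d)
    attr(x, "detection_p") <- d
  }
  x
}

#' @rdname read_expression
#' @param x an expression tibble returned by [read_expression()] or
#'   [simulate_cohort()].
#' @export
detection_p <- function(x) attr(x, "detection_p", exact = TRUE)

read_expr_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != nfield[1])) {
    stop("ragged row at line ", which(nfield != nfield[1])[1], " of ", path,
         call. = FALSE)
  }
  header <- fields[[1]]
  if (length(header) < 2) stop("no sample columns in ", path, call. = FALSE)
  body <- fields[-1]
  ids <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicated gene id '", ids[duplicated(ids)][1], "' in ", path,
         call. = FALSE)
  }
  vals <- vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    v
  }, numeric(length(header) - 1))
  vals <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = length(header) - 1)
  if (anyNA(vals)) {
    bad_row <- which(rowSums(is.na(vals)) > 0)[1]
    stop("non-numeric or missing value at line ", bad_row + 1, " (gene ",
         ids[bad_row], ") of ", path, call. = FALSE)
  }
  expr_tbl(vals, gene_ids = ids, sample_ids = header[-1])
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression()]: first column `gene_id`, one column per
#' sample, full numeric precision, no quoting.
#'
#' @param x expression tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  x <- validate_expr(x)
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], format_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_num <- function(v) formatC(v, digits = 15, format = "g")

#' Read a sample annotation table
#'
#' Tab-separated with required columns `sample_id`, `subtype` and `batch`;
#' optional clinical columns pass through. `mmr_status` is derived from the
#' subtype (Lynch and sporadic MMR-deficient tumors are deficient) and any
#' `mmr_status` column in the file is ignored in favour of the derivation.
#'
#' @param path path to the annotation TSV.
#' @return annotation tibble with `mmr_status` populated.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  validate_annotation(df)
}

#' @rdname read_annotation
#' @param ann annotation tibble.
#' @export
write_annotation <- function(ann, path) {
  ann <- validate_annotation(ann)
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write signed gene lists
#'
#' A gene list is a tibble with a `gene_id` column and, for signed signatures,
#' a `direction` column of `"up"` / `"down"` calls relative to a named
#' contrast. Files are one gene per line with a header; order is preserved and
#' the round trip is lossless.
#'
#' @param genes gene-list tibble (or character vector of ids for an unsigned
#'   list).
#' @param path file path.
#' @return `read_gene_list()` returns the gene-list tibble;
#'   `write_gene_list()` returns `path` invisibly.
#' @export
write_gene_list <- function(genes, path) {
  genes <- as_gene_list(genes)
  utils::write.table(as.data.frame(genes), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0) df <- data.frame(gene_id = character(), df[0, -1, drop = FALSE])
  as_gene_list(df)
}

#' @rdname write_gene_list
#' @export
as_gene_list <- function(genes) {
  if (is.character(genes)) genes <- tibble::tibble(gene_id = genes)
  genes <- tibble::as_tibble(genes)
  if (!"gene_id" %in% names(genes)) {
    stop("gene list needs a gene_id column", call. = FALSE)
  }
  genes$gene_id <- as.character(genes$gene_id)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicated gene id in gene list: ",
         genes$gene_id[duplicated(genes$gene_id)][1], call. = FALSE)
  }
  if ("direction" %in% names(genes)) {
    if (!all(genes$direction %in% c("up", "down"))) {
      stop("direction must be 'up' or 'down' for every gene", call. = FALSE)
    }
  }
  genes
}
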