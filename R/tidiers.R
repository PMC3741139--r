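#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a SAM fit into a per-gene tibble
#'
#' @param x a `sam_fit` from [sam_two_class()].
#' @param ... unused.
#' @return tibble with one row per gene: `gene_id`, `d` (relative-difference
#'   score), `s` (pooled standard error), `rank` (by ascending `d`),
#'   `expected_d` (the permutation expected order statistic at that rank),
#'   `called`, `direction`.
#' @export
tidy.sam_fit <- function(x, ...) {
  x$gene_table |>
    dplyr::mutate(expected_d = x$dbar[.data$rank])
}

#' One-row summary of a SAM fit
#'
#' @param x a `sam_fit`.
#' @param ... unused.
#' @return tibble with `s0`, `delta`, `pi0`, `fdr_estimate`, `target_fdr`,
#'   `n_called`, `n_up`, `n_down`, group sizes, `n_permutations` and the
#'   `exhaustive` flag.
#' @export
glance.sam_fit <- function(x, ...) {
  tab <- x$gene_table
  tibble::tibble(
    s0 = x$s0, delta = x$delta, pi0 = x$pi0,
    fdr_estimate = x$fdr_estimate, target_fdr = x$target_fdr,
    n_called = sum(tab$called),
    n_up = sum(tab$called & tab$direction == "up", na.rm = TRUE),
    n_down = sum(tab$called & tab$direction == "down", na.rm = TRUE),
    n_group1 = x$n1, n_group2 = x$n2,
    n_permutations = x$n_permutations, exhaustive = x$exhaustive
  )
}

#' Tidy a centroid model
#'
#' @param x a `centroid_model` from [build_centroids()].
#' @param ... unused.
#' @return long tibble with `gene_id`, `class`, `centroid` mean expression.
#' @export
tidy.centroid_model <- function(x, ...) {
  x$centroids |>
    tidyr::pivot_longer(-"gene_id", names_to = "class", values_to = "centroid")
}

#' Tidy / summarize a classification report
#'
#' `tidy()` returns the per-sample assignments with correctness flags;
#' `glance()` the per-MMR-group accuracy in one row.
#'
#' @param x a `classification_report` from [evaluate_by_mmr()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.classification_report <- function(x, ...) x$per_sample

#' @rdname tidy.classification_report
#' @export
glance.classification_report <- function(x, ...) {
  s <- x$summary
  def <- s[s$mmr_status == "deficient", ]
  pro <- s[s$mmr_status == "proficient", ]
  tibble::tibble(
    deficient_n = if (nrow(def)) def$n else NA_integer_,
    deficient_accuracy = if (nrow(def)) def$accuracy else NA_real_,
    proficient_n = if (nrow(pro)) pro$n else NA_integer_,
    proficient_accuracy = if (nrow(pro)) pro$accuracy else NA_real_,
    gene_overlap = x$gene_overlap
  )
}
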