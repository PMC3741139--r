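test_that("detection filtering applies the inclusive >=80% rule exactly", {
  # 5 genes detected in {10, 8, 7, 0, 9} of 10 samples
  counts <- c(10, 8, 7, 0, 9)
  det <- t(sapply(counts, function(k) c(rep(0.005, k), rep(0.5, 10 - k))))
  x <- toy_expr(matrix(100, 5, 10))
  d <- toy_expr(det)
  kept <- filter_detection(x, d)
  expect_identical(expr_gene_ids(kept), c("g1", "g2", "g5"))

  # saturated detection keeps everything
  all_in <- filter_detection(x, toy_expr(matrix(0, 5, 10)))
  expect_identical(expr_gene_ids(all_in), expr_gene_ids(x))

  expect_error(filter_detection(x, NULL), "skip")
})

test_that("qspline normalization is an identity on the reference and removes shifts", {
  set.seed(21)
  base <- sort(rlnorm(200, 5, 1))
  x_id <- toy_expr(cbind(base, base, base))
  out_id <- expr_values(normalize_qspline(x_id))
  expect_equal(out_id, expr_values(x_id), tolerance = 1e-9)

  # a constant shift between samples is exactly removable by a monotone map
  x_shift <- toy_expr(cbind(base, base + 50))
  out <- expr_values(normalize_qspline(x_shift))
  ref <- rowMeans(apply(expr_values(x_shift), 2, sort))
  for (j in 1:2) {
    expect_equal(unname(sort(out[, j]) / ref), rep(1, length(ref)),
                 tolerance = 1e-6)
  }

  # monotone: within-sample rank order is untouched
  set.seed(22)
  x_rand <- toy_expr(matrix(rlnorm(300, 6, 1.5), 100, 3))
  out_rand <- expr_values(normalize_qspline(x_rand))
  for (j in 1:3) {
    expect_equal(cor(out_rand[, j], expr_values(x_rand)[, j], method = "spearman"), 1)
  }
  expect_true(all(out_rand > 0))
})

test_that("plate scaling equalizes plate means and preserves ratios", {
  x <- toy_expr(matrix(c(50, 150, 100, 300), 2))  # plate means 100 and 200
  ann <- toy_annotation(c("s1", "s2"), c("LYNCH", "FCCTX"), batch = c("A", "B"))
  out <- expr_values(scale_plates(x, ann))
  expect_equal(mean(out[, 1]), 150)
  expect_equal(mean(out[, 2]), 150)
  expect_equal(unname(out[, 1]), c(50, 150) * 1.5)
  expect_equal(out[2, 2] / out[1, 2], 3)  # within-plate ratios exact

  one_plate <- scale_plates(x, toy_annotation(c("s1", "s2"), c("LYNCH", "FCCTX")))
  expect_equal(expr_values(one_plate), expr_values(x))
})

test_that("log2 median centering matches hand computation", {
  x <- toy_expr(matrix(c(2, 8, 32), 1))
  expect_equal(unname(expr_values(log2_median_center(x))[1, ]), c(-2, 0, 2))

  const <- toy_expr(matrix(5, 1, 4))
  expect_equal(unname(expr_values(log2_median_center(const))[1, ]), rep(0, 4))

  set.seed(30)
  x_rand <- toy_expr(matrix(rlnorm(60, 4, 1), 12, 5))
  meds <- apply(expr_values(log2_median_center(x_rand)), 1, median)
  expect_true(all(abs(meds) < 1e-12))

  bad <- toy_expr(matrix(c(1, 0, 2, 3), 2))
  expect_error(log2_median_center(bad), "g2.*s1|s1.*g2")
})

test_that("quantile normalization equalizes sample distributions", {
  x <- toy_expr(cbind(c(1, 3, 5), c(2, 4, 6)))
  out <- expr_values(normalize_quantiles(x))
  expect_equal(unname(out), cbind(c(1.5, 3.5, 5.5), c(1.5, 3.5, 5.5)))

  same <- toy_expr(cbind(c(1, 5, 2), c(1, 5, 2)))
  expect_equal(expr_values(normalize_quantiles(same)), expr_values(same))

  set.seed(31)
  big <- toy_expr(matrix(rlnorm(400), 100, 4))
  nb <- expr_values(normalize_quantiles(big))
  sorted <- apply(nb, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # idempotent
  expect_equal(expr_values(normalize_quantiles(normalize_quantiles(big))), nb)
})

test_that("offset/cap maps the documented boundary values and is monotone", {
  x <- toy_expr(matrix(c(0, 70000, 10, 64990), 4, 1))
  out <- expr_values(offset_and_cap(x))
  expect_equal(unname(out[, 1]), c(32, 65000, 42, 65000))
  v <- sort(runif(50, 0, 1e5))
  fx <- expr_values(offset_and_cap(toy_expr(matrix(v, ncol = 1))))[, 1]
  expect_true(all(diff(fx) >= 0))
})

test_that("gene centering hits zero statistic and is idempotent", {
  expect_equal(unname(expr_values(center_genes(toy_expr(matrix(1:3, 1)), "mean"))[1, ]),
               c(-1, 0, 1))
  expect_equal(unname(expr_values(center_genes(toy_expr(matrix(c(1, 2, 6), 1)), "median"))[1, ]),
               c(-1, 0, 4))
  set.seed(32)
  x <- toy_expr(matrix(rnorm(50), 10, 5))
  once <- center_genes(x, "median")
  expect_equal(expr_values(center_genes(once, "median")), expr_values(once))
})

test_that("batch adjustment equalizes per-gene batch means around the grand mean", {
  x <- toy_expr(matrix(c(1, 3, 5, 7), 1))
  ann <- toy_annotation(paste0("s", 1:4), rep("LYNCH", 4),
                        batch = c("A", "A", "B", "B"))
  out <- expr_values(adjust_batch_means(x, ann))
  expect_equal(unname(out[1, ]), c(3, 5, 3, 5))

  single <- toy_annotation(paste0("s", 1:4), rep("LYNCH", 4), batch = "A")
  expect_equal(expr_values(adjust_batch_means(x, single)), expr_values(x))

  set.seed(33)
  xr <- toy_expr(matrix(rnorm(80), 10, 8))
  annr <- toy_annotation(paste0("s", 1:8), rep("FCCTX", 8),
                         batch = rep(c("A", "B"), 4))
  outr <- expr_values(adjust_batch_means(xr, annr))
  spread <- apply(outr, 1, function(v) {
    bm <- tapply(v, annr$batch, mean); max(bm) - min(bm)
  })
  expect_true(all(spread < 1e-12))

  lonely <- toy_annotation(paste0("s", 1:4), rep("LYNCH", 4),
                           batch = c("A", "A", "A", "B"))
  expect_error(adjust_batch_means(x, lonely), "single sample")
})

test_that("variance filtering keeps the top ceil fraction with stable ties", {
  x <- toy_expr(rbind(rep(1, 4), c(0, 1, 0, 1), c(0, 2, 0, 2), c(0, 3, 0, 3)))
  kept <- filter_variance(x, preprocess_params(variance_keep_fraction = 0.5))
  expect_identical(expr_gene_ids(kept), c("g3", "g4"))

  expect_identical(expr_gene_ids(filter_variance(x, preprocess_params(variance_keep_fraction = 1))),
                   expr_gene_ids(x))

  # constant gene never survives while any gene varies
  kept3 <- filter_variance(x, preprocess_params(variance_keep_fraction = 0.75))
  expect_false("g1" %in% expr_gene_ids(kept3))

  # stable tie-break: duplicated variance keeps the earlier gene
  tie <- toy_expr(rbind(c(0, 1), c(0, 1), c(5, 5)))
  kept_tie <- filter_variance(tie, preprocess_params(variance_keep_fraction = 1 / 3))
  expect_identical(expr_gene_ids(kept_tie), "g1")
})

test_that("the external harmonization recipe composes its stages in order", {
  set.seed(34)
  m <- matrix(rlnorm(400, 3, 1), 50, 8)
  x <- toy_expr(m)
  ann <- toy_annotation(paste0("s", 1:8), rep("SPORADIC_MMR_PROFICIENT", 8),
                        batch = rep(c("A", "B"), each = 4))

  out <- harmonize_external(x, ann)
  expect_equal(nrow(out), ceiling(0.5 * 50))

  # single batch + keep-all: neutral stages drop out of the composition
  ann1 <- toy_annotation(paste0("s", 1:8), rep("SPORADIC_MMR_PROFICIENT", 8))
  manual <- x |>
    normalize_quantiles() |>
    offset_and_cap()
  manual <- center_genes(toy_expr(log2(expr_values(manual)),
                                  expr_gene_ids(manual), expr_sample_ids(manual)),
                         "median")
  full <- harmonize_external(x, ann1, preprocess_params(variance_keep_fraction = 1))
  expect_equal(expr_values(full), expr_values(manual), tolerance = 1e-12)

  # per-gene batch means are equalized before the variance filter
  no_filter <- harmonize_external(x, ann, preprocess_params(variance_keep_fraction = 1))
  spread <- apply(expr_values(no_filter), 1, function(v) {
    bm <- tapply(v, ann$batch, mean); max(bm) - min(bm)
  })
  expect_true(all(spread < 1e-12))
})

test_that("harmonization reduces batch-explained variance on a confounded cohort", {
  cfg <- synthetic_config(n_genes = 300, n_mmr_genes = 60, n_subtype_genes = 30,
                          plate_sd = 0.5, seed = 9)
  ext <- simulate_external_cohort(cfg)
  b <- ext$annotation$batch
  frac_batch <- function(m) {
    apply(m, 1, function(v) {
      bm <- tapply(v, b, mean)[b]
      sum((bm - mean(v))^2) / sum((v - mean(v))^2)
    })
  }
  before <- frac_batch(log2(expr_values(ext$expression)))
  h <- harmonize_external(ext$expression, ext$annotation,
                          preprocess_params(variance_keep_fraction = 1))
  after <- frac_batch(expr_values(h))
  expect_gte(mean(after < before), 0.95)
})

test_that("preprocessing stages never change the sample count", {
  co <- simulate_cohort(synthetic_config(n_genes = 80, n_mmr_genes = 10,
                                         n_subtype_genes = 5, seed = 10))
  n_s <- length(expr_sample_ids(co$expression))
  pre <- preprocess_cohort(co$expression, co$annotation)
  expect_equal(length(expr_sample_ids(pre)), n_s)
  expect_lte(nrow(pre), nrow(co$expression))
})
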