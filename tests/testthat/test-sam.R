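test_that("the relative-difference statistic matches its closed form", {
  x <- toy_expr(matrix(c(1, 2, 3, 3, 4, 5), 1))
  sc <- sam_d_scores(x, rep(c("a", "b"), each = 3), c("a", "b"), s0 = 0)
  expect_equal(sc$s, sqrt(2 / 3), tolerance = 1e-5)
  expect_equal(sc$d, 2 / sqrt(2 / 3), tolerance = 1e-5)

  # identical group means give d = 0 for any s0
  x0 <- toy_expr(matrix(c(1, 2, 3, 3, 2, 1), 1))
  expect_equal(sam_d_scores(x0, rep(c("a", "b"), each = 3), c("a", "b"), s0 = 0.7)$d, 0)
})

test_that("with s0 = 0 the statistic is exactly the pooled-variance t", {
  set.seed(41)
  x <- toy_expr(matrix(rnorm(100 * 20), 100))
  groups <- rep(c("a", "b"), each = 10)
  sc <- sam_d_scores(x, groups, c("a", "b"), s0 = 0)
  m <- expr_values(x)
  t_oracle <- apply(m, 1, function(v) {
    unname(stats::t.test(v[11:20], v[1:10], var.equal = TRUE)$statistic)
  })
  expect_equal(sc$d, unname(t_oracle), tolerance = 1e-10)
})

test_that("scores are antisymmetric under label swap and invariant to gene shifts", {
  set.seed(42)
  x <- toy_expr(matrix(rnorm(200), 20, 10))
  groups <- rep(c("a", "b"), each = 5)
  d_ab <- sam_d_scores(x, groups, c("a", "b"), s0 = 0.2)$d
  d_ba <- sam_d_scores(x, groups, c("b", "a"), s0 = 0.2)$d
  expect_equal(d_ab, -d_ba)

  shifted <- toy_expr(expr_values(x) + seq_len(20))  # per-gene constants
  expect_equal(sam_d_scores(shifted, groups, c("a", "b"), s0 = 0.2)$d, d_ab)
})

test_that("fudge-factor estimation behaves across its methods", {
  set.seed(43)
  r <- rnorm(500); s <- rep(0.5, 500)
  expect_warning(out <- sam_estimate_s0(r, s, sam_config()), "degenerate")
  expect_equal(out, 0)
  expect_equal(sam_estimate_s0(r, s + runif(500), sam_config(s0_method = "zero")), 0)
  sfix <- runif(500, 0.1, 1)
  expect_equal(sam_estimate_s0(r, sfix,
                               sam_config(s0_method = "fixed_percentile",
                                          s0_percentile = 0.5)),
               unname(quantile(sfix, 0.5)))

  # variance-dependent score inflation at small s drives the window method
  # to a positive fudge factor in nearly all replicates
  picks <- vapply(1:50, function(seed) {
    set.seed(seed)
    sd_g <- runif(1000, 0.1, 1)
    r_g <- rnorm(1000, 0, sd_g + 0.3)
    sam_estimate_s0(r_g, sd_g, sam_config()) > 0
  }, logical(1))
  expect_gte(mean(picks), 0.9)
})

test_that("the permutation null is reproducible and exact for tiny designs", {
  set.seed(44)
  x <- toy_expr(matrix(rnorm(60), 10, 6))
  groups <- rep(c("a", "b"), each = 3)
  cfg <- sam_config(n_permutations = 25, seed = 5)

  n1 <- sam_permutation_null(x, groups, c("a", "b"), s0 = 0.1, config = cfg)
  n2 <- sam_permutation_null(x, groups, c("a", "b"), s0 = 0.1, config = cfg)
  expect_identical(n1$dbar, n2$dbar)

  # C(6,3) = 20 <= B: exhaustive enumeration, independent of the seed,
  # identical to the combn oracle
  expect_true(n1$exhaustive)
  n_other_seed <- sam_permutation_null(x, groups, c("a", "b"), s0 = 0.1,
                                       config = sam_config(n_permutations = 25, seed = 99))
  expect_identical(n1$dbar, n_other_seed$dbar)
  expect_equal(n1$dbar, unname(dbar_exhaustive_oracle(expr_values(x), 3, 0.1)),
               tolerance = 1e-12)

  # symmetric null data: dbar is centred near zero
  set.seed(45)
  big <- toy_expr(matrix(rnorm(200 * 12), 200, 12))
  nb <- sam_permutation_null(big, rep(c("a", "b"), each = 6), c("a", "b"),
                             s0 = 0.1, config = sam_config(n_permutations = 200, seed = 1))
  se <- sd(nb$dbar) / sqrt(length(nb$dbar))
  expect_lt(abs(mean(nb$dbar)), 3 * max(se, 0.01))
})

test_that("sampled and exhaustive permutation modes agree in distribution", {
  set.seed(46)
  m <- matrix(rnorm(50 * 6), 50, 6)
  x <- toy_expr(m)
  groups <- rep(c("a", "b"), each = 3)
  exact <- sam_permutation_null(x, groups, c("a", "b"), s0 = 0.1,
                                config = sam_config(n_permutations = 25, seed = 1))
  sampled <- lapply(1:30, function(s) {
    sam_permutation_null(x, groups, c("a", "b"), s0 = 0.1,
                         config = sam_config(n_permutations = 19, seed = s))$dbar
  })
  expect_false(any(vapply(sampled, function(v) identical(v, exact$dbar), logical(1))))
  avg_sampled <- rowMeans(do.call(cbind, sampled))
  ks <- suppressWarnings(stats::ks.test(avg_sampled, exact$dbar))
  expect_gt(ks$p.value, 0.01)
})

test_that("delta selection reports an empty call set gracefully", {
  set.seed(47)
  x <- toy_expr(matrix(rnorm(100 * 10), 100, 10))
  groups <- rep(c("a", "b"), each = 5)
  nl <- sam_permutation_null(x, groups, c("a", "b"), s0 = 0.1,
                             config = sam_config(n_permutations = 50, seed = 2))
  d <- sam_d_scores(x, groups, c("a", "b"), s0 = 0.1)$d
  sel <- sam_select_delta(d, nl$dbar, nl$perm_d, sam_config(n_permutations = 50, seed = 2))
  last <- sel$fdr_curve[nrow(sel$fdr_curve), ]
  expect_equal(last$n_called, 0)
  expect_equal(last$fdr, 0)
  # called counts never increase along the delta grid
  expect_true(all(diff(sel$fdr_curve$n_called) <= 0))
  expect_true(sel$pi0 > 0 && sel$pi0 <= 1)
})

test_that("the full two-class fit is antisymmetric and recovers planted signal", {
  cfg <- synthetic_config(n_genes = 300, n_mmr_genes = 0, n_subtype_genes = 40,
                          effect_low = 1.5, effect_high = 1.5, seed = 11)
  co <- simulate_cohort(cfg)
  x <- log2_median_center(co$expression)
  sam_cfg <- sam_config(n_permutations = 60, seed = 3)
  fit <- sam_two_class(x, co$annotation, c("FCCTX", "LYNCH"), config = sam_cfg)
  swapped <- sam_two_class(x, co$annotation, c("LYNCH", "FCCTX"), config = sam_cfg)

  expect_equal(fit$gene_table$d, -swapped$gene_table$d)
  expect_identical(fit$gene_table$called, swapped$gene_table$called)
  both <- dplyr::inner_join(significant_genes(fit), significant_genes(swapped),
                            by = "gene_id")
  expect_true(all(both$direction.x != both$direction.y))

  # ranking with s0 = 0 equals the pooled-t ranking
  fit0 <- sam_two_class(x, co$annotation, c("FCCTX", "LYNCH"),
                        config = sam_config(n_permutations = 10, seed = 3,
                                            s0_method = "zero"))
  m <- expr_values(x)
  lynch <- co$annotation$sample_id[co$annotation$subtype == "LYNCH"]
  fcctx <- co$annotation$sample_id[co$annotation$subtype == "FCCTX"]
  t_stat <- apply(m, 1, function(v) {
    unname(stats::t.test(v[lynch], v[fcctx], var.equal = TRUE)$statistic)
  })
  expect_identical(order(fit0$gene_table$d), order(t_stat))

  # strong planted subtype signal is recovered with few false calls
  sig <- significant_genes(fit)$gene_id
  truth <- co$truth$subtype_genes$gene_id
  expect_gte(length(intersect(sig, truth)) / length(truth), 0.8)
  expect_lte(length(setdiff(sig, truth)) / max(1, length(sig)), 0.15)

  expect_error(sam_two_class(x, co$annotation, c("FCCTX", "LYNCH"),
                             group_var = "nope"), "nope")
  expect_output(print(fit), "SAM fit")
})

test_that("null cohorts yield empty signatures in most replicates", {
  called <- vapply(1:6, function(s) {
    cfg <- synthetic_config(n_genes = 400, n_mmr_genes = 0, n_subtype_genes = 0,
                            seed = s)
    co <- simulate_cohort(cfg)
    x <- log2_median_center(co$expression)
    fit <- sam_two_class(x, co$annotation, c("FCCTX", "LYNCH"),
                         config = sam_config(n_permutations = 60, seed = s))
    sum(fit$gene_table$called)
  }, numeric(1))
  expect_equal(median(called), 0)
})

test_that("tidy and glance expose the fit consistently", {
  cfg <- synthetic_config(n_genes = 150, n_mmr_genes = 30, n_subtype_genes = 15,
                          seed = 12)
  co <- simulate_cohort(cfg)
  fit <- sam_two_class(log2_median_center(co$expression), co$annotation,
                       c("proficient", "deficient"), group_var = "mmr_status",
                       config = sam_config(n_permutations = 40, seed = 1))
  td <- tidy(fit)
  expect_equal(nrow(td), 150)
  expect_true(all(c("gene_id", "d", "s", "expected_d", "called", "direction") %in%
                    names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_called, sum(td$called))
  expect_equal(gl$n_called, gl$n_up + gl$n_down)
  expect_lte(gl$fdr_estimate, gl$target_fdr)
  expect_s3_class(autoplot(fit), "ggplot")
})
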