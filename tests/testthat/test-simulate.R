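small_cfg <- function(...) {
  synthetic_config(n_genes = 60, n_mmr_genes = 12, n_subtype_genes = 6, ...)
}

test_that("default group sizes reproduce the four-subtype cohort", {
  co <- simulate_cohort(small_cfg(seed = 1))
  expect_equal(nrow(co$annotation), 123)
  expect_equal(as.vector(table(co$annotation$subtype)[
    c("LYNCH", "FCCTX", "SPORADIC_MMR_DEFICIENT", "SPORADIC_MMR_PROFICIENT")]),
    c(39, 37, 26, 21))
  expect_true(all(expr_values(co$expression) >= 0))
  expect_equal(dim(expr_values(co$detection)), c(60, 123))
})

test_that("fixed seed is bit-reproducible; seeds change noise but not truth", {
  a <- simulate_cohort(small_cfg(seed = 7))
  b <- simulate_cohort(small_cfg(seed = 7))
  expect_identical(a, b)
  c <- simulate_cohort(small_cfg(seed = 8))
  expect_false(identical(expr_values(a$expression), expr_values(c$expression)))
  expect_equal(nrow(c$truth$mmr_genes), nrow(a$truth$mmr_genes))
  expect_equal(nrow(c$truth$subtype_genes), nrow(a$truth$subtype_genes))
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_genes = 10, n_mmr_genes = 8, n_subtype_genes = 5),
               "disjoint")
  expect_error(synthetic_config(effect_low = 2, effect_high = 1), "ordered")
  expect_error(synthetic_config(n_plates = 0), "positive")
})

test_that("null configuration plants no group differences", {
  cfg <- synthetic_config(n_genes = 40, n_mmr_genes = 0, n_subtype_genes = 0,
                          plate_sd = 0, seed = 3)
  co <- simulate_cohort(cfg)
  lm2 <- log2(expr_values(co$expression))
  def <- co$annotation$mmr_status == "deficient"
  diffs <- rowMeans(lm2[, def]) - rowMeans(lm2[, !def])
  se <- sqrt(apply(lm2[, def], 1, var) / sum(def) +
               apply(lm2[, !def], 1, var) / sum(!def))
  expect_true(all(abs(diffs) < 4 * se))
})

test_that("planted effects are recovered at the stated magnitude", {
  # effect 1.0, 60 vs 60 samples, noise sd 1: empirical group difference
  # within +/- 2 SE (0.37) of the planted effect in >= 95% of 100 seeds
  ok <- vapply(1:100, function(s) {
    cfg <- synthetic_config(
      n_genes = 20,
      group_sizes = c(LYNCH = 30, FCCTX = 30, SPORADIC_MMR_DEFICIENT = 30,
                      SPORADIC_MMR_PROFICIENT = 30),
      n_mmr_genes = 1, n_subtype_genes = 0,
      effect_low = 1, effect_high = 1,
      noise_sd_low = 1, noise_sd_high = 1, plate_sd = 0, seed = s)
    co <- simulate_cohort(cfg)
    g <- co$truth$mmr_genes$gene_id
    eff <- co$truth$mmr_genes$effect
    lm2 <- log2(expr_values(co$expression))
    def <- co$annotation$mmr_status == "deficient"
    abs((mean(lm2[g, def]) - mean(lm2[g, !def])) - eff) <= 0.37
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("detection p decreases monotonically with signal", {
  co <- simulate_cohort(small_cfg(seed = 2))
  sig <- log2(expr_values(co$expression))
  det <- expr_values(co$detection)
  o <- order(as.vector(sig))
  expect_true(all(diff(as.vector(det)[o]) <= 1e-12))
  expect_true(all(det >= 0 & det <= 1))
})

test_that("the external cohort is positive, truth-sharing and batch-structured", {
  cfg <- synthetic_config(n_genes = 400, n_mmr_genes = 80, n_subtype_genes = 40,
                          plate_sd = 0.5, seed = 5)
  ext <- simulate_external_cohort(cfg)
  m <- expr_values(ext$expression)
  expect_true(all(is.finite(m)) && all(m >= 0))
  expect_equal(nrow(ext$annotation), 60)
  expect_equal(sort(unique(ext$annotation$batch)), paste0("batch", 1:4))

  # per-gene batch means separate clearly relative to within-batch SE
  lm2 <- log2(m)
  b <- ext$annotation$batch
  spread_vs_se <- apply(lm2, 1, function(v) {
    bm <- tapply(v, b, mean)
    bse <- tapply(v, b, function(z) sd(z) / sqrt(length(z)))
    (max(bm) - min(bm)) / mean(bse)
  })
  expect_gt(median(spread_vs_se), 2)

  # noiseless limit: any planted gene separates the two MMR groups
  cfg0 <- synthetic_config(n_genes = 30, n_mmr_genes = 10, n_subtype_genes = 0,
                           noise_sd_low = 0, noise_sd_high = 0, plate_sd = 0,
                           library_size_sd = 0, effect_low = 2, effect_high = 2,
                           seed = 6)
  ext0 <- simulate_external_cohort(cfg0)
  co0 <- simulate_cohort(cfg0)
  m0 <- log2(expr_values(ext0$expression))
  def <- ext0$annotation$mmr_status == "deficient"
  for (g in co0$truth$mmr_genes$gene_id) {
    expect_true(min(m0[g, def]) > max(m0[g, !def]) ||
                  max(m0[g, def]) < min(m0[g, !def]))
  }

  expect_error(simulate_external_cohort(cfg, c("not_a_gene")), "overlap")
})

test_that("clinical covariates follow the per-subtype proportions", {
  co <- simulate_cohort(small_cfg(seed = 4))
  pr <- clinical_proportions()
  pr$proximal <- 1
  ann <- simulate_clinical(co$annotation, pr, seed = 1)
  expect_true(all(ann$location == "proximal"))
  expect_true(all(ann$stage %in% c("I", "II", "III")))

  # Lynch default proportions: proximal 77%, high/moderate 67%
  defaults <- clinical_proportions()
  expect_equal(defaults$proximal[defaults$subtype == "LYNCH"], 0.77)
  expect_equal(defaults$high_moderate[defaults$subtype == "FCCTX"], 0.92)

  bad <- clinical_proportions(); bad$proximal[1] <- 1.5
  expect_error(simulate_clinical(co$annotation, bad, seed = 1), "probabilities")
})
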