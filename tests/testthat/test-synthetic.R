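# Synthetic data generator: determinism, generative limits, noise calibration.

test_that("configs are validated", {
  expect_error(simConfig(class_fractions = c(proportional = 0.6,
                                             compensated_flat = 0.3)),
               "sum to 1")
  expect_error(simConfig(replicate_sd = 0), "replicate_sd")
  expect_error(simConfig(sub_slope = 1.2), "sub_slope")
  expect_error(simConfig(copy_ratio_linear = -1), "copy ratios")
})

test_that("the same seed reproduces the pair dataset exactly", {
  cfg <- simConfig(n_genes = 300, seed = 7)
  s1 <- simulatePair(cfg)
  s2 <- simulatePair(cfg)
  expect_identical(countMatrix(s1$counts), countMatrix(s2$counts))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$categories, s2$categories)
  # a different seed changes the data
  s3 <- simulatePair(simConfig(n_genes = 300, seed = 8))
  expect_false(identical(countMatrix(s1$counts), countMatrix(s3$counts)))
})

test_that("ground truth respects the configured class structure", {
  cfg <- simConfig(n_genes = 1000, seed = 3)
  sim <- simulatePair(cfg)
  tr <- sim$truth
  expect_true(all(tr$class[tr$amplified] %in% names(cfg$class_fractions)))
  expect_true(all(tr$class[!tr$amplified] == "unamplified"))
  # telomeric genes of the amplified chromosome stay unamplified
  expect_true(all(!tr$amplified[tr$telomeric]))
  expect_true(all(tr$chromosome[tr$telomeric] == "chr1"))
})

test_that("in the low-noise limit a proportional gene's mRNA ratio equals log2 copy ratio", {
  # tiny biological and counting noise; center-correct against unamplified
  # genes to remove the global RPKM shift of the amplified totals
  cfg <- simConfig(n_genes = 800, replicate_sd = 0.01, nb_dispersion = 0,
                   dna_dispersion = 0, copy_jitter_sd = 0,
                   mean_expression = 1e5, dna_mean_depth = 1e5,
                   class_fractions = c(proportional = 1),
                   trans_modules = list(), telomere_unamplified_fraction = 0,
                   seed = 5)
  an <- pairAnalysis(cfg)
  amp <- an$sim$truth$gene_id[an$sim$truth$amplified]
  unamp <- setdiff(an$sim$truth$gene_id, amp)
  center <- distributionCenter(an$rt, genes = unamp, molecule = "RNA",
                               comparisons = "aneuploid1_vs_euploid1")
  mAmp <- distributionCenter(an$rt, genes = amp, molecule = "RNA",
                             comparisons = "aneuploid1_vs_euploid1")
  expect_equal(mAmp - center, 1.0, tolerance = 0.02)
})

test_that("amplified-gene mRNA ratios average log2(copy ratio) under proportional dosage", {
  cfg <- simConfig(n_genes = 2000, class_fractions = c(proportional = 1),
                   trans_modules = list(), telomere_unamplified_fraction = 0,
                   seed = 11)
  an <- pairAnalysis(cfg)
  tr <- an$sim$truth
  amp <- tr$gene_id[tr$amplified]
  unamp <- setdiff(tr$gene_id, amp)
  rna <- an$rt[an$rt$molecule == "RNA", ]
  center <- mean(rna$log2_ratio[rna$gene_id %in% unamp])
  vals <- rna$log2_ratio[rna$gene_id %in% amp] - center
  sem <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - log2(cfg$copy_ratio_linear)), 3 * sem + 1e-3)

  # DNA ratios on the amplified chromosome center at log2(copy ratio) too
  dna <- an$rt[an$rt$molecule == "DNA", ]
  centerD <- mean(dna$log2_ratio[dna$gene_id %in% unamp])
  valsD <- dna$log2_ratio[dna$gene_id %in% amp] - centerD
  semD <- sd(valsD) / sqrt(length(valsD))
  expect_lt(abs(mean(valsD) - 1), 3 * semD + 1e-3)
})

test_that("replicate log2 mRNA ratio SD matches replicate_sd", {
  # >= 3 replicates; the sample-SD small-n bias (c4) is corrected for
  cfg <- simConfig(n_genes = 2000, n_rna_reps = 4, seed = 13,
                   trans_modules = list())
  an <- pairAnalysis(cfg)
  rna <- an$rt[an$rt$molecule == "RNA" &
                 an$rt$comparison_id == "aneuploid1_vs_euploid1", ]
  sds <- tapply(rna$log2_ratio, rna$gene_id, sd)
  c4 <- sqrt(2 / 3) * gamma(2) / gamma(1.5)   # E[sd]/sigma at n = 4
  expect_lt(abs(mean(sds) / c4 - cfg$replicate_sd) / cfg$replicate_sd, 0.15)
})

test_that("null data are centered: synthetic centers lie within 3 SEM of 0", {
  # euploid self-panel: copy state 1 only, so every ratio is a resampled null
  cfg <- simConfig(n_genes = 600, panel_copy_states = 1, seed = 17,
                   trans_modules = list())
  sim <- simulatePanel(cfg)
  si <- sampleInfo(sim$counts)
  abund <- rpkmNormalize(sim$counts)
  pairs <- data.frame(test = c("panel_2n_RNA_1", "panel_2n_RNA_2"),
                      ref = c("panel_2n_RNA_2", "panel_2n_RNA_3"),
                      comparison_id = "self")
  rt <- log2Ratios(abund, pairs, si)
  ctr <- distributionCenter(rt, molecule = "RNA")
  sem <- sd(rt$log2_ratio) / sqrt(nrow(rt))
  expect_lt(abs(ctr), 3 * sem + 1e-3)
})

test_that("panel: flat genes stay near 0 and unamplified DNA ratios center at 0", {
  cfg <- simConfig(n_genes = 2000, seed = 19, trans_modules = list(),
                   telomere_unamplified_fraction = 0)
  sim <- simulatePanel(cfg)
  si <- sampleInfo(sim$counts)
  # exclude the amplified chromosome from totals so centers are interpretable
  abund <- rpkmNormalize(sim$counts, excludeChromosomes = "chr1")
  pairs <- rbind(comparisonPairs(si, "panel_3n", "panel_2n"),
                 comparisonPairs(si, "panel_4n", "panel_2n"))
  rt <- log2Ratios(abund, pairs, si)
  tr <- sim$truth
  flat <- tr$gene_id[tr$class == "compensated_flat"]
  unamp <- tr$gene_id[!tr$amplified]
  for (cmp in unique(attr(rt, "comparisons")$comparison_id)) {
    rna <- rt[rt$molecule == "RNA" & rt$comparison_id == cmp, ]
    vals <- rna$log2_ratio[rna$gene_id %in% flat]
    expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)) + 0.02)
    dna <- rt[rt$molecule == "DNA" & rt$comparison_id == cmp, ]
    valsD <- dna$log2_ratio[dna$gene_id %in% unamp]
    expect_lt(abs(mean(valsD)), 3 * sd(valsD) / sqrt(length(valsD)) + 0.02)
  }
})

test_that("population CNV: binomial rates, determinism, degenerate rate 0", {
  classes <- setNames(rep(c("proportional", "compensated_flat"), each = 1000),
                      sprintf("g%04d", 1:2000))
  cnv <- simulatePopulationCNV(classes, seed = 23)
  cnv2 <- simulatePopulationCNV(classes, seed = 23)
  expect_identical(cnv, cnv2)
  expect_equal(attr(cnv, "n_strains"), 103)

  # rate 0.05 over 103 strains: mean count ~ 5.15 within 3 SEM on 1000 genes
  comp <- cnv$n_strains_amplified[cnv$class == "compensated_flat"]
  sem <- sd(comp) / sqrt(length(comp))
  expect_lt(abs(mean(comp) - 103 * 0.05), 3 * sem)

  # rate 0 -> all zero -> CNV fraction 0
  cnv0 <- simulatePopulationCNV(classes, rateMap = c(proportional = 0,
                                                     compensated_flat = 0,
                                                     unamplified = 0),
                                seed = 2)
  expect_true(all(cnv0$n_strains_amplified == 0))
  expect_equal(cnvFraction(cnv0, minStrains = 3), 0)
})

test_that("simulations write a complete plain-text directory", {
  d <- withr::local_tempdir()
  cfg <- simConfig(n_genes = 200, seed = 29)
  sim <- simulatePair(cfg)
  cnv <- simulatePopulationCNV(setNames(sim$truth$class, sim$truth$gene_id),
                               seed = 30)
  writeSimulation(sim, d, cnv = cnv)
  expect_true(all(file.exists(file.path(d,
    c("counts.tsv", "samples.tsv", "annotation.tsv", "truth.tsv",
      "categories.gmt", "cnv.tsv")))))
  back <- readCounts(file.path(d, "counts.tsv"), file.path(d, "samples.tsv"),
                     file.path(d, "annotation.tsv"))
  expect_identical(countMatrix(back), countMatrix(sim$counts))
})
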