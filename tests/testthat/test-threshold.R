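# Gene-specific thresholds, the all-replicates call rule, permutation FDR.

# two-comparison fixture with hand-set DNA ratios and mRNA replicates
twoPairFixture <- function(mrna1, mrna2, dna = 1.0, sdGenes = c(1.0, 1.2, 0.8)) {
  cmp <- data.frame(comparison_id = c("c1", "c2"),
                    test_strain = c("A1", "A2"), ref_strain = c("E1", "E2"))
  rows <- list()
  for (cc in c("c1", "c2")) {
    # three amplified genes define the chromosome SD (sd = 0.2 by hand)
    for (i in seq_along(sdGenes))
      rows[[length(rows) + 1]] <- list(gene = paste0("sd", i), cmp = cc,
                                       rep = 1, mol = "DNA", val = sdGenes[i])
    rows[[length(rows) + 1]] <- list(gene = "target", cmp = cc, rep = 1,
                                     mol = "DNA", val = dna)
    m <- if (cc == "c1") mrna1 else mrna2
    for (r in seq_along(m))
      rows[[length(rows) + 1]] <- list(gene = "target", cmp = cc, rep = r,
                                       mol = "RNA", val = m[r])
    for (i in seq_along(sdGenes)) for (r in seq_along(m))
      rows[[length(rows) + 1]] <- list(gene = paste0("sd", i), cmp = cc,
                                       rep = r, mol = "RNA", val = sdGenes[i])
  }
  rt <- makeRatioTable(rows, cmp)
  gi <- makeGeneData(c(paste0("sd", 1:3), "target"),
                     amplifiedIn = "A1,A2")
  list(rt = rt, gi = gi)
}

test_that("chromosome SD is the sample SD of amplified DNA ratios", {
  f <- twoPairFixture(c(0.7, 0.75), c(0.7, 0.75))
  # genes {1.0, 1.2, 0.8, 1.0} -> sd computed over all amplified genes
  expect_equal(chromosomeSD(f$rt, f$gi, "c1"),
               sd(c(1.0, 1.2, 0.8, 1.0)))
  # the three-gene fixture {1.0, 1.2, 0.8} alone gives exactly 0.2
  gi3 <- makeGeneData(paste0("sd", 1:3), amplifiedIn = "A1,A2")
  rt3 <- f$rt[f$rt$gene_id != "target", ]
  attr(rt3, "comparisons") <- attr(f$rt, "comparisons")
  expect_equal(chromosomeSD(rt3, gi3, "c1"), 0.2)

  # constant DNA ratios -> zero SD is surfaced as an error
  rtc <- makeRatioTable(list(
    list(gene = "a", cmp = "c1", rep = 1, mol = "DNA", val = 1),
    list(gene = "b", cmp = "c1", rep = 1, mol = "DNA", val = 1)),
    data.frame(comparison_id = "c1", test_strain = "A1", ref_strain = "E1"))
  gic <- makeGeneData(c("a", "b"), amplifiedIn = "A1")
  expect_error(chromosomeSD(rtc, gic, "c1"), "zero")
  # fewer than 2 genes
  expect_error(chromosomeSD(rtc[1, , drop = FALSE], gic[1, ], "c1"), ">=2")
})

test_that("gene thresholds subtract k SDs from the measured DNA ratio", {
  f <- twoPairFixture(c(0.7, 0.75), c(0.7, 0.75))
  thr1 <- geneThresholds(f$rt, f$gi, "c1", kSd = 1, sdChr = 0.197)
  expect_equal(thr1$threshold[thr1$gene_id == "target"], 1.0 - 0.197)
  thr3 <- geneThresholds(f$rt, f$gi, "c1", kSd = 3, sdChr = 0.2)
  expect_equal(thr3$threshold[thr3$gene_id == "target"], 0.4)
  thr0 <- geneThresholds(f$rt, f$gi, "c1", kSd = 0, sdChr = 0.2)
  expect_equal(thr0$threshold, thr0$dna_ratio)  # k = 0 identity
  # a gene without a DNA ratio is dropped with a warning
  rtNoDna <- f$rt[!(f$rt$gene_id == "target" & f$rt$molecule == "DNA"), ]
  attr(rtNoDna, "comparisons") <- attr(f$rt, "comparisons")
  expect_warning(thrD <- geneThresholds(rtNoDna, f$gi, "c1", sdChr = 0.2),
                 "without a DNA ratio")
  expect_false("target" %in% thrD$gene_id)
})

test_that("a gene is called only when below threshold in every replicate of every comparison", {
  # chromosome SD of the fixture is sd(c(1, 1.2, 0.8, 1)) ~= 0.163;
  # target threshold ~= 1 - 0.163 = 0.837
  called <- twoPairFixture(c(0.70, 0.75), c(0.70, 0.75))
  cs <- callLowerExpressed(called$rt, called$gi)
  expect_true("target" %in% calledGenes(cs))

  notCalled <- twoPairFixture(c(0.70, 0.85), c(0.70, 0.75))
  cs2 <- callLowerExpressed(notCalled$rt, notCalled$gi)
  expect_false("target" %in% calledGenes(cs2))
  expect_equal(thresholdCalls(cs2)$n_replicates_below[
    thresholdCalls(cs2)$gene_id == "target"], 3L)

  # a ratio exactly at threshold is not "below" (strict inequality)
  sdc <- sd(c(1.0, 1.2, 0.8, 1.0))
  tie <- twoPairFixture(c(1 - sdc, 0.5), c(0.5, 0.5))
  cs3 <- callLowerExpressed(tie$rt, tie$gi)
  expect_false("target" %in% calledGenes(cs3))

  # effect size = mean mRNA ratio - DNA ratio, averaged over comparisons
  eff <- thresholdCalls(cs)$effect_size[thresholdCalls(cs)$gene_id == "target"]
  expect_equal(eff, mean(c(mean(c(0.70, 0.75)) - 1, mean(c(0.70, 0.75)) - 1)))
})

test_that("raising k never increases calls and k=3 calls nest within k=1", {
  an <- pairAnalysis(simConfig(n_genes = 800, seed = 31))
  k1 <- callLowerExpressed(an$rt, an$gi, kSd = 1)
  k2 <- callLowerExpressed(an$rt, an$gi, kSd = 2)
  k3 <- callLowerExpressed(an$rt, an$gi, kSd = 3)
  expect_gte(length(calledGenes(k1)), length(calledGenes(k2)))
  expect_gte(length(calledGenes(k2)), length(calledGenes(k3)))
  expect_true(all(calledGenes(k3) %in% calledGenes(k1)))
})

test_that("permutation FDR: determinism, saturation, undefined at zero calls", {
  set.seed(1)
  d <- matrix(rnorm(400), 100, 4)
  p1 <- permutationFDR(d, nIter = 500, seed = 9)
  p2 <- permutationFDR(d, nIter = 500, seed = 9)
  expect_identical(p1, p2)
  p3 <- permutationFDR(d, nIter = 500, seed = 10)
  expect_false(identical(p1$nullCounts, p3$nullCounts))

  # all-negative d: every permutation calls every gene -> FDR = 1
  f <- twoPairFixture(c(0.1, 0.2), c(0.1, 0.2))
  cs <- callLowerExpressed(f$rt, f$gi)   # every gene far below threshold?
  dAll <- matrix(-abs(rnorm(200)), 50, 4)
  csAll <- new("ThresholdCallSet",
               calls = data.frame(gene_id = sprintf("g%02d", 1:50),
                                  called = rep(TRUE, 50),
                                  n_replicates_below = 4L,
                                  effect_size = -1),
               thresholds = matrix(0, 50, 1), diffs = dAll, kSd = 1,
               sdChr = c(c1 = 0.2), comparisons = "c1",
               notAssessed = character(0), fdrEstimate = NA_real_,
               nullCounts = numeric(0))
  out <- permutationFDR(csAll, nIter = 200, seed = 2)
  expect_equal(fdrEstimate(out), 1)

  # zero observed calls -> FDR undefined, flagged
  dPos <- matrix(abs(rnorm(200)), 50, 4)
  csNone <- new("ThresholdCallSet",
                calls = data.frame(gene_id = sprintf("g%02d", 1:50),
                                   called = rep(FALSE, 50),
                                   n_replicates_below = 0L,
                                   effect_size = 1),
                thresholds = matrix(0, 50, 1), diffs = dPos, kSd = 1,
                sdChr = c(c1 = 0.2), comparisons = "c1",
                notAssessed = character(0), fdrEstimate = NA_real_,
                nullCounts = numeric(0))
  expect_warning(outNone <- permutationFDR(csNone, nIter = 100, seed = 3),
                 "undefined")
  expect_true(is.na(fdrEstimate(outNone)))
})

test_that("permuted null counts match the analytic expectation given column margins", {
  set.seed(5)
  d <- matrix(rnorm(200 * 4), 200, 4)
  perm <- permutationFDR(d, nIter = 2000, seed = 6)
  margins <- colMeans(d < 0)
  analytic <- 200 * prod(margins)  # independent permutations factorize
  se <- sd(perm$nullCounts) / sqrt(2000)
  expect_lt(abs(perm$meanNull - analytic), 5 * se + 0.05)
})

test_that("matched unamplified calls use the amplified chromosome's SD", {
  cmp <- data.frame(comparison_id = "c1", test_strain = "A1", ref_strain = "E1")
  rows <- list(
    list(gene = "a1", cmp = "c1", rep = 1, mol = "DNA", val = 1.0),
    list(gene = "a2", cmp = "c1", rep = 1, mol = "DNA", val = 1.2),
    list(gene = "a3", cmp = "c1", rep = 1, mol = "DNA", val = 0.8),
    list(gene = "u1", cmp = "c1", rep = 1, mol = "DNA", val = 0.0),
    list(gene = "u1", cmp = "c1", rep = 1, mol = "RNA", val = -0.7),
    list(gene = "u1", cmp = "c1", rep = 2, mol = "RNA", val = -0.8))
  for (g in c("a1", "a2", "a3")) for (r in 1:2)
    rows[[length(rows) + 1]] <- list(gene = g, cmp = "c1", rep = r,
                                     mol = "RNA", val = 1.0)
  rt <- makeRatioTable(rows, cmp)
  gi <- makeGeneData(c("a1", "a2", "a3", "u1"),
                     chromosome = c("chr1", "chr1", "chr1", "chr2"),
                     amplifiedIn = c("A1", "A1", "A1", ""))
  cs <- matchedUnamplifiedCalls(rt, gi, kSd = 3)
  # amplified chromosome SD = 0.2; threshold = 0.0 - 3 * 0.2 = -0.6
  expect_equal(unname(cs@thresholds["u1", "c1"]), -0.6)
  expect_true("u1" %in% calledGenes(cs))  # -0.7, -0.8 both below -0.6
  expect_false(any(c("a1", "a2", "a3") %in% thresholdCalls(cs)$gene_id))
})

test_that("unamplified null call rate matches the closed-form normal tail", {
  # construct mRNA replicates centered on each gene's own DNA ratio so the
  # per-replicate below-threshold probability is exactly pnorm(-k*sd/sigma)
  set.seed(41)
  G <- 3000; sigma <- 0.2; k <- 1
  cmp <- data.frame(comparison_id = "c1", test_strain = "A1", ref_strain = "E1")
  ampDna <- rnorm(60, 1, 0.2)
  uDna <- rnorm(G, 0, 0.15)
  ids <- sprintf("u%04d", 1:G)
  rt <- rbind(
    data.frame(gene_id = sprintf("a%02d", 1:60), comparison_id = "c1",
               replicate = 1, molecule = "DNA", log2_ratio = ampDna),
    data.frame(gene_id = ids, comparison_id = "c1", replicate = 1,
               molecule = "DNA", log2_ratio = uDna),
    data.frame(gene_id = rep(ids, 2), comparison_id = "c1",
               replicate = rep(1:2, each = G), molecule = "RNA",
               log2_ratio = rep(uDna, 2) + rnorm(2 * G, 0, sigma)),
    data.frame(gene_id = rep(sprintf("a%02d", 1:60), 2), comparison_id = "c1",
               replicate = rep(1:2, each = 60), molecule = "RNA",
               log2_ratio = rep(ampDna, 2)))
  attr(rt, "comparisons") <- cmp
  gi <- makeGeneData(c(sprintf("a%02d", 1:60), ids),
                     chromosome = c(rep("chr1", 60), rep("chr2", G)),
                     amplifiedIn = c(rep("A1", 60), rep("", G)))
  cs <- matchedUnamplifiedCalls(rt, gi, kSd = k)
  sdChr <- unname(cs@sdChr["c1"])
  expected <- pnorm(-k * sdChr / sigma)^2
  rate <- mean(thresholdCalls(cs)$called)
  se <- sqrt(expected * (1 - expected) / G)
  expect_lt(abs(rate - expected), 4 * se + 0.002)
})

test_that("trans-repressed unamplified genes are called at k = 1", {
  cfg <- simConfig(n_genes = 1000, seed = 43)
  an <- pairAnalysis(cfg)
  cs <- matchedUnamplifiedCalls(an$rt, an$gi, kSd = 1)
  tr <- an$sim$truth
  strong <- tr$gene_id[!tr$amplified & tr$trans_effect_log2 <= -1]
  strong <- intersect(strong, thresholdCalls(cs)$gene_id)
  expect_gt(mean(strong %in% calledGenes(cs)), 0.9)
})
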