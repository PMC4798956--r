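# Unamplified-gene DE stand-in, hypergeometric enrichment, the
# indirect-response filter, and effect-size tertiles.

test_that("identical counts give zero fold-change and no selection", {
  cmp <- data.frame(comparison_id = "c1", test_strain = "A1", ref_strain = "E1")
  rows <- list()
  for (g in paste0("u", 1:5)) for (r in 1:3)
    rows[[length(rows) + 1]] <- list(gene = g, cmp = "c1", rep = r,
                                     mol = "RNA", val = 0)
  rt <- makeRatioTable(rows, cmp)
  gi <- makeGeneData(paste0("u", 1:5))
  de <- suppressWarnings(callDEUnamplified(rt, gi, "c1"))
  expect_true(all(de$log2fc == 0))
  expect_length(lowerExpressedSet(de), 0)
})

test_that("trans-module genes are detected with high power at 3 replicates", {
  cfg <- simConfig(n_genes = 1500, n_rna_reps = 3, n_pairs = 1, seed = 53)
  an <- pairAnalysis(cfg)
  de <- callDEUnamplified(an$rt, an$gi, "aneuploid1_vs_euploid1")
  lower <- lowerExpressedSet(de, fdrCut = 0.01)
  tr <- an$sim$truth
  module <- tr$gene_id[!tr$amplified & tr$trans_effect_log2 <= -1]
  module <- intersect(module, de$gene_id)
  expect_gt(mean(module %in% lower), 0.9)
  # BH adjustment equals a brute-force step-up oracle on the same p-vector
  p <- de$pvalue
  n <- length(p)
  o <- order(p)
  bh <- numeric(n)
  bh[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
  expect_equal(de$fdr, pmin(bh, 1))
})

test_that("the plain ratio t-test variant runs and the import hook reads tables", {
  cfg <- simConfig(n_genes = 300, n_rna_reps = 3, n_pairs = 1, seed = 59)
  an <- pairAnalysis(cfg)
  de <- callDEUnamplified(an$rt, an$gi, "aneuploid1_vs_euploid1",
                          method = "ratio_t")
  expect_true(all(de$pvalue >= 0 & de$pvalue <= 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  de2 <- callDEUnamplified(an$rt, an$gi, "aneuploid1_vs_euploid1",
                           method = "import", importPath = path)
  expect_equal(de2, de)
})

test_that("hypergeometric enrichment equals the combinatorial oracle", {
  universe <- sprintf("g%03d", 1:100)
  categories <- list(setA = universe[1:10])
  query <- universe[1:5]
  res <- enrichCategories(query, categories, universe)
  # P(all 5 of a size-5 draw land in the 10-gene category)
  oracle <- choose(10, 5) / choose(100, 5)
  expect_equal(res$p, oracle)
  expect_equal(res$overlap, 5)

  # overlap 0: the upper tail includes 0, so p = 1
  res0 <- enrichCategories(universe[11:15], categories, universe)
  expect_equal(res0$p, 1)

  # full brute-force tail sum for a partial overlap
  query2 <- c(universe[1:3], universe[51:55])
  res2 <- enrichCategories(query2, categories, universe)
  tailSum <- sum(vapply(3:8, function(k)
    choose(10, k) * choose(90, 8 - k) / choose(100, 8), numeric(1)))
  expect_equal(res2$p, tailSum)

  # invariance under relabeling genes
  relabel <- setNames(sprintf("x%03d", 1:100), universe)
  res3 <- enrichCategories(unname(relabel[query2]),
                           list(setA = unname(relabel[categories$setA])),
                           unname(relabel[universe]))
  expect_equal(res3$p, res2$p)

  # empty query -> empty result; query outside universe errors
  expect_equal(nrow(enrichCategories(character(0), categories, universe)), 0)
  expect_error(enrichCategories("nope", categories, universe), "subset")
})

test_that("localization-flagged categories are skipped when requested", {
  universe <- sprintf("g%03d", 1:50)
  categories <- list(real = universe[1:10], loc = universe[1:10])
  attr(categories, "localization") <- c(real = FALSE, loc = TRUE)
  res <- enrichCategories(universe[1:5], categories, universe,
                          excludeLocalization = TRUE)
  expect_equal(res$category, "real")
  resAll <- enrichCategories(universe[1:5], categories, universe,
                             excludeLocalization = FALSE)
  expect_setequal(resAll$category, c("real", "loc"))
})

test_that("filter removes calls in strain-specific enriched categories, idempotently", {
  categories <- list(module = c("a1", "a2", "u1", "u2"),
                     other = c("a3", "u3"))
  calls <- data.frame(gene_id = c("a1", "a2", "a3", "a4"),
                      strain = "S1", stringsAsFactors = FALSE)
  enrNone <- list(S1 = data.frame(category = "module", p = 0.5))
  # no category passes the threshold -> revised set = original set
  f0 <- filterAmplifiedCalls(calls, enrNone, categories)
  expect_equal(f0$kept, calls)
  expect_equal(f0$removal_fraction, 0)

  enrHit <- list(S1 = data.frame(category = "module", p = 1e-6))
  f1 <- filterAmplifiedCalls(calls, enrHit, categories)
  expect_setequal(f1$removed$gene_id, c("a1", "a2"))
  expect_setequal(f1$kept$gene_id, c("a3", "a4"))  # a4 has no category: kept
  expect_equal(f1$removal_fraction, 0.5)

  # idempotence
  f2 <- filterAmplifiedCalls(f1$kept, enrHit, categories)
  expect_equal(f2$kept, f1$kept)
  expect_equal(nrow(f2$removed), 0)

  # anti-monotone in the p threshold: loosening it never grows the kept set
  fLoose <- filterAmplifiedCalls(calls, list(S1 = data.frame(
    category = c("module", "other"), p = c(1e-6, 1e-4))), categories,
    pThreshold = 1e-3)
  expect_true(all(fLoose$kept$gene_id %in% f1$kept$gene_id))
})

test_that("amplified members of simulated trans modules are removed, others kept", {
  cfg <- simConfig(n_genes = 1500, n_rna_reps = 3, n_pairs = 1, seed = 61)
  an <- pairAnalysis(cfg)
  tr <- an$sim$truth
  cs <- callLowerExpressed(an$rt, an$gi)
  de <- callDEUnamplified(an$rt, an$gi, "aneuploid1_vs_euploid1")
  lower <- lowerExpressedSet(de)
  enr <- list(aneuploid1 = enrichCategories(lower, an$sim$categories,
                                            universe = de$gene_id))
  # the strong trans module must come out enriched
  expect_true("mito_translation" %in%
                enr$aneuploid1$category[enr$aneuploid1$p < 4e-4])
  calls <- data.frame(gene_id = calledGenes(cs), strain = "aneuploid1",
                      stringsAsFactors = FALSE)
  f <- filterAmplifiedCalls(calls, enr, an$sim$categories)
  enriched <- enr$aneuploid1$category[enr$aneuploid1$p < 4e-4]
  inModule <- vapply(calls$gene_id, function(g)
    any(vapply(enriched, function(m) g %in% an$sim$categories[[m]],
               logical(1))), logical(1))
  expect_setequal(f$removed$gene_id, calls$gene_id[inModule])
  expect_setequal(f$kept$gene_id, calls$gene_id[!inModule])
})

test_that("effect-size tertiles are deterministic and as equal as possible", {
  eff9 <- setNames(seq(-0.9, -0.1, by = 0.1), paste0("g", 1:9))
  t9 <- partitionByEffect(eff9)
  expect_equal(unname(table(t9)[c("top", "middle", "bottom")]),
               c(3L, 3L, 3L), ignore_attr = TRUE)
  # most negative effects land in the top third
  expect_equal(sort(names(t9)[t9 == "top"]), paste0("g", 1:3))

  eff10 <- setNames(-(10:1) / 10, paste0("g", 1:10))
  t10 <- partitionByEffect(eff10)
  expect_equal(sum(t10 == "top"), 4L)      # the extra gene goes to the top
  expect_equal(sum(t10 == "middle"), 3L)
  expect_equal(sum(t10 == "bottom"), 3L)

  eff3 <- setNames(c(-1.0, -0.5, -0.1), c("gA", "gB", "gC"))
  t3 <- partitionByEffect(eff3)
  expect_equal(names(t3)[t3 == "top"], "gA")

  # ties broken by gene id
  effTie <- setNames(c(-0.5, -0.5, -0.5), c("b", "a", "c"))
  tTie <- partitionByEffect(effTie)
  expect_equal(unname(tTie[c("a", "b", "c")]), c("top", "middle", "bottom"))

  # fewer calls than bins: one bin per gene, with a warning
  expect_warning(t2 <- partitionByEffect(eff3[1:2]), "fewer")
  expect_length(unique(t2), 2)

  # the union of tertiles is exactly the input set
  expect_setequal(names(t10), paste0("g", 1:10))
})
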