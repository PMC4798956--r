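# Shared in-code fixtures for the test suite. Everything is built
# programmatically; no files are read from disk except through tempfiles.

# minimal 3-gene / 2-sample count set
tinyCountSet <- function() {
  cts <- matrix(c(10L, 0L, 7L, 20L, 5L, 7L), nrow = 3,
                dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  sm <- data.frame(strain = c("A", "A"), molecule = c("RNA", "DNA"),
                   replicate = c(1, 1), row.names = c("s1", "s2"))
  gn <- data.frame(chromosome = c("chr1", "chr1", "chr2"),
                   length_bp = c(1000, 2000, 1500),
                   row.names = paste0("g", 1:3))
  AneuploidyCountSet(cts, sm, gn)
}

# hand-built ratio table: one value row per (gene, comparison, replicate,
# molecule); `comparisons` maps ids to test/ref strains
makeRatioTable <- function(rows, comparisons) {
  rt <- do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r$gene, comparison_id = r$cmp, replicate = r$rep,
               molecule = r$mol, log2_ratio = r$val, stringsAsFactors = FALSE)))
  attr(rt, "comparisons") <- comparisons
  rt
}

# annotation data.frame for hand-built fixtures
makeGeneData <- function(ids, chromosome = "chr1", amplifiedIn = "",
                         categories = "") {
  data.frame(gene_id = ids, chromosome = chromosome, length_bp = 1000,
             amplified_in = amplifiedIn, categories = categories,
             stringsAsFactors = FALSE)
}

# small paired simulation plus its ratio table, reused across tests
pairAnalysis <- function(cfg) {
  sim <- simulatePair(cfg)
  abund <- rpkmNormalize(sim$counts)
  si <- sampleInfo(sim$counts)
  pairs <- do.call(rbind, lapply(seq_len(cfg$n_pairs), function(p)
    comparisonPairs(si, sprintf("aneuploid%d", p), sprintf("euploid%d", p))))
  rt <- log2Ratios(abund, pairs, si)
  list(sim = sim, rt = rt, gi = geneInfo(sim$counts))
}

panelAnalysis <- function(cfg) {
  sim <- simulatePanel(cfg)
  abund <- rpkmNormalize(sim$counts)
  si <- sampleInfo(sim$counts)
  states <- sort(setdiff(cfg$panel_copy_states, 1))
  pairs <- do.call(rbind, lapply(states, function(s)
    comparisonPairs(si, sprintf("panel_%gn", 2 * s), "panel_2n")))
  rt <- log2Ratios(abund, pairs, si)
  list(sim = sim, rt = rt, gi = geneInfo(sim$counts))
}

# truth-derived gene groups
classGenes <- function(sim, cls) sim$truth$gene_id[sim$truth$class %in% cls]

# map truth class labels to mixture component labels
classToComponent <- c(proportional = "class1_proportional",
                      compensated_flat = "class2_flat",
                      sub_proportional = "class3a_sub",
                      super_proportional = "class3b_super")

# genes whose expression is genuinely lower than copy-proportional:
# compensated/flat classes plus trans-repressed amplified genes
trulyLowerExpressed <- function(sim) {
  tr <- sim$truth
  tr$gene_id[tr$class == "compensated_flat" |
               (tr$amplified & tr$trans_effect_log2 < 0)]
}
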