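#' Configuration for the synthetic aneuploidy data generator
#'
#' Defines the study conditions that [simulatePair()], [simulatePanel()] and
#' [simulatePopulationCNV()] emulate: chromosome-scale DNA copy ratios (1.5x /
#' 2x), replicate log2 mRNA-ratio noise with per-gene SD around
#' `replicate_sd`, a minority of amplified genes with sub-proportional or flat
#' mRNA response, trans-acting indirect-response modules on functionally
#' related genes, unamplified telomere-proximal genes on the amplified
#' chromosome, and spike-in reads proportional to counted cells.
#'
#' `replicate_sd` parameterizes the observed SD of replicate log2 mRNA ratios;
#' the per-sample log-normal biological jitter scale is derived from it per
#' gene by subtracting the expected count-sampling variance (negative binomial
#' with dispersion `nb_dispersion` at the gene's expected depth), floored at
#' zero, so that the generated replicate ratio SD matches `replicate_sd`.
#'
#' @param n_genes total number of genes.
#' @param n_chromosomes chromosomes, filled with equal contiguous gene blocks.
#' @param amplified_chromosome index of the amplified chromosome.
#' @param copy_ratio_linear linear DNA copy ratio of the amplified chromosome
#'   in the pair design (e.g. 2 for a 4n vs 2n comparison).
#' @param panel_copy_states linear copy ratios of the panel strains relative to
#'   the euploid (state 1 is the euploid itself).
#' @param class_fractions named proportions over the dosage-response classes
#'   `proportional` (slope 1), `sub_proportional` (slope `sub_slope`),
#'   `compensated_flat` (slope 0) and `super_proportional` (slope
#'   `super_slope`); must sum to 1.
#' @param sub_slope true dosage slope of sub-proportional genes, in (0, 1).
#' @param super_slope true dosage slope of super-proportional genes, > 1.
#' @param replicate_sd target SD of replicate log2 mRNA ratios (log2 units).
#' @param n_rna_reps,n_dna_reps RNA/DNA replicates per strain; `NULL` uses the
#'   design default (pair: 2 RNA + 1 DNA; panel: 3 RNA + 2 DNA).
#' @param n_pairs number of strain pairs sharing the same ground truth in the
#'   pair design (default 2: an isogenic and a non-isogenic-relative pair, so
#'   the four-biological-replicate calling rule is exercised).
#' @param trans_modules list of `list(category=, effect_log2=, n_genes=)`
#'   indirect-response modules: functionally related genes whose expression
#'   shifts by `effect_log2` in every aneuploid strain regardless of their own
#'   copy number.
#' @param telomere_unamplified_fraction fraction of the amplified chromosome's
#'   genes (at the block ends) that stay at copy 1.
#' @param copy_jitter_sd log2 SD of the per-gene realized copy ratio around the
#'   chromosome's nominal ratio in each aneuploid culture (segmental variation,
#'   sub-population heterogeneity, gene-level amplification biases). This
#'   variation is biologically real: DNA read depth and mRNA output both track
#'   the realized copy number, which is why gene-specific DNA-derived
#'   thresholds carry information about the mRNA expectation.
#' @param nb_dispersion negative-binomial dispersion of RNA read-count
#'   sampling (`var = mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param dna_dispersion negative-binomial dispersion of DNA read-count
#'   sampling; genomic DNA libraries are technically much tighter than RNA,
#'   so the amplified chromosome's DNA-ratio spread is dominated by the
#'   realized-copy jitter rather than by count noise.
#' @param mean_expression mean RNA reads per gene per sample.
#' @param dna_mean_depth mean DNA reads per gene per sample (euploid).
#' @param expression_sdlog log-scale SD of the per-gene baseline expression.
#' @param n_decoy_categories number of random (no-effect) functional categories
#'   added to the category map, one of them localization-flagged.
#' @param seed integer master seed; all stream splitting derives from it.
#' @return A validated `SimConfig` (list).
#' @export
simConfig <- function(n_genes = 2000,
                      n_chromosomes = 16,
                      amplified_chromosome = 1,
                      copy_ratio_linear = 2,
                      panel_copy_states = c(1, 1.5, 2),
                      class_fractions = c(proportional = 0.75,
                                          sub_proportional = 0.10,
                                          compensated_flat = 0.10,
                                          super_proportional = 0.05),
                      sub_slope = 0.4,
                      super_slope = 1.5,
                      replicate_sd = 0.2,
                      n_rna_reps = NULL,
                      n_dna_reps = NULL,
                      n_pairs = 2,
                      trans_modules = list(
                        list(category = "mito_translation", effect_log2 = -1.0, n_genes = 60),
                        list(category = "ribosome_biogenesis", effect_log2 = -0.6, n_genes = 40)),
                      telomere_unamplified_fraction = 0.05,
                      copy_jitter_sd = 0.17,
                      nb_dispersion = 0.002,
                      dna_dispersion = 5e-4,
                      mean_expression = 2000,
                      dna_mean_depth = 2000,
                      expression_sdlog = 0.7,
                      n_decoy_categories = 8,
                      seed = 1) {
  cfg <- list(n_genes = n_genes, n_chromosomes = n_chromosomes,
              amplified_chromosome = amplified_chromosome,
              copy_ratio_linear = copy_ratio_linear,
              panel_copy_states = panel_copy_states,
              class_fractions = class_fractions, sub_slope = sub_slope,
              super_slope = super_slope, replicate_sd = replicate_sd,
              n_rna_reps = n_rna_reps, n_dna_reps = n_dna_reps,
              n_pairs = n_pairs, trans_modules = trans_modules,
              telomere_unamplified_fraction = telomere_unamplified_fraction,
              copy_jitter_sd = copy_jitter_sd,
              nb_dispersion = nb_dispersion, dna_dispersion = dna_dispersion,
              mean_expression = mean_expression,
              dna_mean_depth = dna_mean_depth,
              expression_sdlog = expression_sdlog,
              n_decoy_categories = n_decoy_categories, seed = seed)
  known <- c("proportional", "sub_proportional", "compensated_flat", "super_proportional")
  stopIfNot(all(names(class_fractions) %in% known),
            "class_fractions names must be among: ", paste(known, collapse = ", "))
  stopIfNot(abs(sum(class_fractions) - 1) < 1e-8, "class_fractions must sum to 1")
  stopIfNot(all(class_fractions >= 0), "class_fractions must be non-negative")
  stopIfNot(replicate_sd > 0, "replicate_sd must be > 0")
  stopIfNot(copy_ratio_linear > 0 && all(panel_copy_states > 0),
            "copy ratios must be > 0")
  stopIfNot(sub_slope > 0 && sub_slope < 1, "sub_slope must lie in (0, 1)")
  stopIfNot(super_slope > 1, "super_slope must be > 1")
  stopIfNot(nb_dispersion >= 0 && dna_dispersion >= 0,
            "dispersions must be >= 0")
  stopIfNot(telomere_unamplified_fraction >= 0 && telomere_unamplified_fraction < 1,
            "telomere_unamplified_fraction must lie in [0, 1)")
  stopIfNot(copy_jitter_sd >= 0, "copy_jitter_sd must be >= 0")
  structure(cfg, class = "SimConfig")
}

# --- internal gene-level ground work -------------------------------------

.simClassSlopes <- function(cfg) {
  c(proportional = 1, sub_proportional = cfg$sub_slope,
    compensated_flat = 0, super_proportional = cfg$super_slope)
}

# gene table: ids, chromosomes, lengths, baseline depths, classes, modules
.simGenes <- function(cfg) {
  n <- cfg$n_genes
  ids <- sprintf("g%05d", seq_len(n))
  chrom <- paste0("chr", rep(seq_len(cfg$n_chromosomes),
                             each = ceiling(n / cfg$n_chromosomes))[seq_len(n)])
  len <- pmin(pmax(round(rlnorm(n, log(1250), 0.4)), 200L), 15000L)
  w <- rlnorm(n, 0, cfg$expression_sdlog)
  muRNA <- cfg$mean_expression * (w * len) / mean(w * len)
  muDNA <- cfg$dna_mean_depth * len / mean(len)

  ampChr <- paste0("chr", cfg$amplified_chromosome)
  onAmp <- which(chrom == ampChr)
  nTel <- floor(length(onAmp) * cfg$telomere_unamplified_fraction)
  telomeric <- logical(n)
  if (nTel > 0) {
    left <- onAmp[seq_len(ceiling(nTel / 2))]
    right <- onAmp[length(onAmp) - seq_len(floor(nTel / 2)) + 1L]
    telomeric[unique(c(left, right))] <- TRUE
  }
  amplified <- chrom == ampChr & !telomeric

  cls <- rep("unamplified", n)
  nAmp <- sum(amplified)
  if (nAmp > 0) {
    fr <- cfg$class_fractions[cfg$class_fractions > 0]
    cls[amplified] <- sample(names(fr), nAmp, replace = TRUE, prob = fr)
  }
  slopes <- .simClassSlopes(cfg)
  b <- ifelse(amplified, slopes[cls], 1)

  transEffect <- numeric(n)
  moduleOf <- rep("", n)
  categories <- list()
  avail <- seq_len(n)
  for (m in cfg$trans_modules) {
    pick <- sample(avail, min(m$n_genes, length(avail)))
    avail <- setdiff(avail, pick)
    transEffect[pick] <- transEffect[pick] + m$effect_log2
    moduleOf[pick] <- ifelse(moduleOf[pick] == "", m$category,
                             paste(moduleOf[pick], m$category, sep = ","))
    categories[[m$category]] <- ids[pick]
  }
  loc <- setNames(logical(length(categories)), names(categories))
  if (cfg$n_decoy_categories > 0) {
    for (k in seq_len(cfg$n_decoy_categories)) {
      nm <- if (k == 1) "membrane_localization" else sprintf("category_%02d", k)
      pick <- sample(n, round(runif(1, 20, 50)))
      categories[[nm]] <- ids[pick]
      loc[nm] <- (k == 1)
    }
  }
  attr(categories, "localization") <- loc
  attr(categories, "description") <-
    setNames(ifelse(loc, "synthetic category #localization", "synthetic category"),
             names(categories))

  list(ids = ids, chrom = chrom, len = len, muRNA = muRNA, muDNA = muDNA,
       amplified = amplified, telomeric = telomeric, class = cls, b = b,
       transEffect = transEffect, moduleOf = moduleOf, categories = categories,
       ampChr = ampChr)
}

# per-sample jitter SD so that replicate log2 ratio SD ~= replicate_sd
.jitterSD <- function(cfg, muRNA) {
  v <- (cfg$nb_dispersion + 1 / pmax(muRNA, 1)) / log(2)^2
  sqrt(pmax(0, cfg$replicate_sd^2 - 2 * v) / 2)
}

.rcounts <- function(mu, dispersion) {
  mu <- pmax(mu, 1e-8)
  if (dispersion <= 0) rpois(length(mu), mu)
  else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

# realized per-gene copy ratio of one aneuploid culture: nominal chromosome
# ratio with per-gene log-normal jitter on the amplified genes
.realizedCopy <- function(cfg, g, nominal) {
  jit <- ifelse(g$amplified & nominal != 1,
                2^rnorm(length(nominal), 0, cfg$copy_jitter_sd), 1)
  nominal * jit
}

.rnaSample <- function(cfg, g, copy, aneuploid) {
  jit <- 2^rnorm(length(g$muRNA), 0, .jitterSD(cfg, g$muRNA))
  trans <- if (aneuploid) 2^g$transEffect else 1
  mu <- g$muRNA * copy^g$b * trans * jit
  .rcounts(mu, cfg$nb_dispersion)
}

.dnaSample <- function(cfg, g, copy) {
  .rcounts(g$muDNA * copy, cfg$dna_dispersion)
}

.spikeCols <- function(nSamples) {
  cells <- round(runif(nSamples, 1.5e7, 2.5e7))
  spike <- round(cells * 0.025 * 2^rnorm(nSamples, 0, 0.03))
  list(cells = cells, spike = spike)
}

.assembleSim <- function(cfg, g, cols, samples, design) {
  counts <- do.call(cbind, cols)
  rownames(counts) <- g$ids
  sampleData <- do.call(rbind, samples)
  rownames(sampleData) <- colnames(counts)
  sp <- .spikeCols(nrow(sampleData))
  sampleData$cells_counted <- sp$cells
  sampleData$spike_total <- sp$spike
  aneuStrains <- unique(sampleData$strain[sampleData$aneuploid])
  sampleData$aneuploid <- NULL
  geneData <- data.frame(
    chromosome = g$chrom, length_bp = g$len,
    amplified_in = ifelse(g$amplified, paste(aneuStrains, collapse = ","), ""),
    categories = vapply(g$ids, function(id) {
      paste(names(g$categories)[vapply(g$categories, function(v) id %in% v, logical(1))],
            collapse = ",")
    }, character(1)),
    row.names = g$ids, stringsAsFactors = FALSE)
  truth <- data.frame(
    gene_id = g$ids, chromosome = g$chrom, amplified = g$amplified,
    telomeric = g$telomeric, class = g$class, true_slope = g$b,
    trans_effect_log2 = g$transEffect, modules = g$moduleOf,
    stringsAsFactors = FALSE)
  structure(list(counts = AneuploidyCountSet(counts, sampleData, geneData),
                 truth = truth, categories = g$categories, config = cfg,
                 design = design),
            class = "AneuploidySim")
}

#' Simulate an aneuploid / euploid strain-pair experiment
#'
#' Generates `n_pairs` strain pairs (aneuploid vs euploid) that share one
#' ground truth: DNA counts are negative binomial with mean proportional to
#' copy number times gene length; RNA counts are negative binomial with mean
#' proportional to `copy_ratio^b` times baseline expression times trans-module
#' effects, with per-sample log-normal biological jitter calibrated so
#' replicate log2 mRNA ratios have SD `replicate_sd`. Telomere-proximal genes
#' of the amplified chromosome stay at copy 1. The default design gives each
#' strain 2 RNA replicates and 1 DNA sample, so calling across both pairs uses
#' four biological mRNA measurements per gene.
#'
#' @param cfg a [simConfig()].
#' @return List of class `AneuploidySim`: `counts` ([AneuploidyCountSet]),
#'   `truth` (per-gene class labels, true slopes, module membership),
#'   `categories` (GMT-style list), `config`, `design`.
#' @export
simulatePair <- function(cfg = simConfig()) {
  withSeed(cfg$seed, function() {
    nr <- if (is.null(cfg$n_rna_reps)) 2L else cfg$n_rna_reps
    nd <- if (is.null(cfg$n_dna_reps)) 1L else cfg$n_dna_reps
    g <- .simGenes(cfg)
    copyAneu <- ifelse(g$amplified, cfg$copy_ratio_linear, 1)
    cols <- list(); samples <- list()
    for (p in seq_len(cfg$n_pairs)) {
      for (st in c("aneuploid", "euploid")) {
        strain <- sprintf("%s%d", st, p)
        aneu <- st == "aneuploid"
        copy <- if (aneu) .realizedCopy(cfg, g, copyAneu) else rep(1, cfg$n_genes)
        lab <- if (aneu) sprintf("%s-%gn", g$ampChr, 2 * cfg$copy_ratio_linear) else "2n"
        for (r in seq_len(nr)) {
          nm <- sprintf("%s_RNA_%d", strain, r)
          cols[[nm]] <- .rnaSample(cfg, g, copy, aneu)
          samples[[nm]] <- data.frame(strain = strain, molecule = "RNA",
                                      replicate = r, ploidy_label = lab,
                                      aneuploid = aneu, stringsAsFactors = FALSE)
        }
        for (r in seq_len(nd)) {
          nm <- sprintf("%s_DNA_%d", strain, r)
          cols[[nm]] <- .dnaSample(cfg, g, copy)
          samples[[nm]] <- data.frame(strain = strain, molecule = "DNA",
                                      replicate = r, ploidy_label = lab,
                                      aneuploid = aneu, stringsAsFactors = FALSE)
        }
      }
    }
    .assembleSim(cfg, g, cols, samples, design = "pair")
  })
}

#' Simulate an isogenic copy-number panel experiment
#'
#' One euploid reference strain plus one strain per copy state in
#' `panel_copy_states` greater than 1 (e.g. states 1.5 and 2 emulate diploids
#' carrying three and four copies of the amplified chromosome). Default design:
#' 3 RNA replicates and 2 DNA samples per strain. The generative model is that
#' of [simulatePair()], with each gene's mRNA response following its class
#' slope across all copy states.
#'
#' @param cfg a [simConfig()].
#' @return An `AneuploidySim` list, as for [simulatePair()].
#' @export
simulatePanel <- function(cfg = simConfig()) {
  withSeed(cfg$seed, function() {
    nr <- if (is.null(cfg$n_rna_reps)) 3L else cfg$n_rna_reps
    nd <- if (is.null(cfg$n_dna_reps)) 2L else cfg$n_dna_reps
    g <- .simGenes(cfg)
    states <- sort(unique(cfg$panel_copy_states))
    stopIfNot(1 %in% states, "panel_copy_states must include the euploid state 1")
    cols <- list(); samples <- list()
    for (s in states) {
      strain <- sprintf("panel_%gn", 2 * s)
      aneu <- s > 1
      copy <- .realizedCopy(cfg, g, ifelse(g$amplified, s, 1))
      lab <- sprintf("%s-%gn", g$ampChr, 2 * s)
      for (r in seq_len(nr)) {
        nm <- sprintf("%s_RNA_%d", strain, r)
        cols[[nm]] <- .rnaSample(cfg, g, copy, aneu)
        samples[[nm]] <- data.frame(strain = strain, molecule = "RNA",
                                    replicate = r, ploidy_label = lab,
                                    aneuploid = aneu, stringsAsFactors = FALSE)
      }
      for (r in seq_len(nd)) {
        nm <- sprintf("%s_DNA_%d", strain, r)
        cols[[nm]] <- .dnaSample(cfg, g, copy)
        samples[[nm]] <- data.frame(strain = strain, molecule = "DNA",
                                    replicate = r, ploidy_label = lab,
                                    aneuploid = aneu, stringsAsFactors = FALSE)
      }
    }
    .assembleSim(cfg, g, cols, samples, design = "panel")
  })
}

#' Simulate a population CNV survey with expression-constraint values
#'
#' Per-gene counts of strains (out of `nStrains`, 103 by default) carrying a
#' duplication are binomial with a class-dependent duplication rate;
#' expression-constraint values Vg/Vm are log-normal around a class-dependent
#' median. Defaults encode the scenario that genes subject to dosage
#' compensation show elevated CNV rates despite stronger expression constraint
#' (lower Vg/Vm), while unamplified-reduced genes behave like the background.
#'
#' @param classes named character vector of per-gene class labels (names are
#'   gene ids), e.g. from an `AneuploidySim` truth table.
#' @param nStrains population size.
#' @param rateMap named per-class duplication rates in `[0, 1]`; unnamed
#'   classes fall back to `rateMap["unamplified"]`.
#' @param vgvmMap named per-class median Vg/Vm (> 0).
#' @param vgvmSdlog log-scale SD of the Vg/Vm draw.
#' @param seed integer seed.
#' @return data.frame with `gene_id`, `class`, `n_strains_amplified`, `vg_vm`;
#'   attribute `"n_strains"` records the population size.
#' @export
simulatePopulationCNV <- function(classes, nStrains = 103,
                                  rateMap = c(proportional = 0.01,
                                              sub_proportional = 0.03,
                                              compensated_flat = 0.05,
                                              super_proportional = 0.01,
                                              unamplified = 0.01),
                                  vgvmMap = c(proportional = 1.0,
                                              sub_proportional = 0.6,
                                              compensated_flat = 0.4,
                                              super_proportional = 1.2,
                                              unamplified = 1.0),
                                  vgvmSdlog = 0.5, seed = NULL) {
  stopIfNot(all(rateMap >= 0 & rateMap <= 1), "rates must lie in [0, 1]")
  stopIfNot(all(vgvmMap > 0), "Vg/Vm medians must be > 0")
  cls <- as.character(classes)
  ids <- names(classes)
  stopIfNot(!is.null(ids), "classes must be a named vector (names = gene ids)")
  rate <- unname(rateMap[cls])
  rate[is.na(rate)] <- rateMap[["unamplified"]]
  med <- unname(vgvmMap[cls])
  med[is.na(med)] <- vgvmMap[["unamplified"]]
  withSeed(seed, function() {
    out <- data.frame(
      gene_id = ids, class = cls,
      n_strains_amplified = rbinom(length(cls), nStrains, rate),
      vg_vm = rlnorm(length(cls), log(med), vgvmSdlog),
      stringsAsFactors = FALSE)
    attr(out, "n_strains") <- nStrains
    out
  })
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' Writes `counts.tsv`, `samples.tsv`, `annotation.tsv`, `truth.tsv`,
#' `categories.gmt`, and (when `cnv` is supplied) `cnv.tsv`.
#'
#' @param sim an `AneuploidySim` from [simulatePair()] or [simulatePanel()].
#' @param dir output directory (created if needed).
#' @param cnv optional CNV table from [simulatePopulationCNV()].
#' @return Invisibly, the directory.
#' @export
writeSimulation <- function(sim, dir, cnv = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCounts(sim$counts, file.path(dir, "counts.tsv"),
              file.path(dir, "samples.tsv"), file.path(dir, "annotation.tsv"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeGMT(sim$categories, file.path(dir, "categories.gmt"))
  if (!is.null(cnv))
    write.table(cnv, file.path(dir, "cnv.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(dir)
}
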