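# End-to-end orchestration: data -> normalization -> ratios -> threshold calls
# -> MLR + LRT (panel) -> indirect-response filter -> evolution scores.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Assemble and validate a pipeline configuration
#'
#' Exactly one input mode is allowed: `simulate` (a design plus [simConfig()]
#' overrides) or `paths` (count/sample/annotation TSVs, a GMT category map,
#' optionally a `cnv.tsv` and a `comparisons` table). Every analysis knob
#' carries its standard default: `normalization` `"rpkm"` (alternatives
#' `"rpkm_excl_amplified"`, `"spike_in"`), `k_sd` 1, `n_perm` 10000, `de_fdr`
#' 0.01, `enrich_p` 4e-4, `min_strains` 3. The master `seed` is propagated to
#' every stochastic stage through deterministic child seeds.
#'
#' @param config named list, or path to a YAML file holding one.
#' @return Validated config list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopIfNot(is.list(config), "config must be a list or a YAML file path")
  hasSim <- !is.null(config$simulate)
  hasPaths <- !is.null(config$paths)
  stopIfNot(xor(hasSim, hasPaths),
            "config needs exactly one input mode: 'simulate' or 'paths'")
  defaults <- list(normalization = "rpkm", k_sd = 1, n_perm = 10000,
                   de_fdr = 0.01, enrich_p = 4e-4, min_strains = 3,
                   de_method = "moderated_t", seed = 1, out_dir = NULL)
  config <- modifyList(defaults, config)
  stopIfNot(config$normalization %in% c("rpkm", "rpkm_excl_amplified", "spike_in"),
            "unknown normalization: ", config$normalization)
  if (hasSim)
    stopIfNot(!is.null(config$simulate$design) &&
                config$simulate$design %in% c("pair", "panel"),
              "simulate$design must be 'pair' or 'panel'")
  structure(config, class = "PipelineConfig")
}

.pipelineData <- function(config) {
  if (!is.null(config$simulate)) {
    opts <- config$simulate
    design <- opts$design
    opts$design <- NULL
    if (is.null(opts$seed)) opts$seed <- childSeed(config$seed, 11L)
    cfg <- do.call(simConfig, opts)
    sim <- if (design == "pair") simulatePair(cfg) else simulatePanel(cfg)
    list(acs = sim$counts, categories = sim$categories, sim = sim,
         design = design, cnv = NULL)
  } else {
    p <- config$paths
    acs <- readCounts(p$counts, p$samples, p$annotation)
    categories <- if (!is.null(p$categories)) readGMT(p$categories) else list()
    cnv <- if (!is.null(p$cnv)) read.delim(p$cnv, stringsAsFactors = FALSE) else NULL
    list(acs = acs, categories = categories, sim = NULL,
         design = config$design %||% "pair", cnv = cnv)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive the test-vs-reference strain comparisons
.pipelineComparisons <- function(config, data) {
  if (!is.null(config$comparisons)) {
    cmp <- as.data.frame(do.call(rbind, lapply(config$comparisons, as.data.frame)))
    return(cmp)
  }
  si <- sampleInfo(data$acs)
  strains <- unique(si$strain)
  if (data$design == "panel") {
    ref <- grep("_2n$", strains, value = TRUE)
    stopIfNot(length(ref) == 1, "cannot infer the panel reference strain")
    tests <- setdiff(strains, ref)
    data.frame(test = tests, ref = ref, stringsAsFactors = FALSE)
  } else {
    aneu <- grep("^aneuploid", strains, value = TRUE)
    stopIfNot(length(aneu) >= 1, "cannot infer aneuploid strains; give config$comparisons")
    data.frame(test = aneu, ref = sub("^aneuploid", "euploid", aneu),
               stringsAsFactors = FALSE)
  }
}

#' Run the full dosage-compensation analysis
#'
#' Executes every stage on one dataset: input (simulated or read from files),
#' normalization, log2 ratio tables, gene-specific threshold calls with
#' permutation FDR, the MLR dosage-response model plus the likelihood-ratio
#' cross-check (panel designs), the strain-specific indirect-response filter
#' with effect-size tertiles, and population CNV / buffering-score
#' comparisons. All stage outputs are returned as a bundle and, when
#' `out_dir` is set, written as TSV/JSON files together with a run manifest
#' (package version, config, config hash, per-stage gene counts). Reruns with
#' an identical config are bit-identical.
#'
#' @param config a [pipelineConfig()], a plain list, or a YAML path.
#' @return A `PipelineBundle` list; see [summarizeBundle()].
#' @export
runPipeline <- function(config) {
  config <- pipelineConfig(config)
  bundle <- list(config = config)

  data <- .stage("input", .pipelineData(config))
  acs <- data$acs
  gi <- geneInfo(acs)
  si <- sampleInfo(acs)
  bundle$design <- data$design
  bundle$truth <- data$sim$truth

  abund <- .stage("normalize", {
    switch(config$normalization,
      rpkm = rpkmNormalize(acs),
      rpkm_excl_amplified = {
        ampChrom <- unique(gi$chromosome[vapply(splitCommaField(gi$amplified_in),
                                                length, integer(1)) > 0])
        rpkmNormalize(acs, excludeChromosomes = ampChrom)
      },
      spike_in = spikeInNormalize(acs))
  })

  rt <- .stage("ratios", {
    cmp <- .pipelineComparisons(config, data)
    pairs <- do.call(rbind, lapply(seq_len(nrow(cmp)), function(i)
      comparisonPairs(si, cmp$test[i], cmp$ref[i])))
    log2Ratios(abund, pairs, si)
  })
  bundle$ratios <- rt

  bundle$calls <- .stage("threshold", {
    cs <- callLowerExpressed(rt, gi, kSd = config$k_sd)
    permutationFDR(cs, nIter = config$n_perm, seed = childSeed(config$seed, 23L))
  })

  if (data$design == "panel") {
    bundle$mlr <- .stage("mlr", {
      dp <- dosagePoints(rt, gi)
      fit <- fitMLR(dp, seed = childSeed(config$seed, 31L))
      lrt <- lrtProportionality(dp)
      list(points = dp, fit = fit, lrt = lrt,
           agreement = compareNullProportions(fit, lrt))
    })
  }

  bundle$filter <- .stage("filter", {
    comparisons <- attr(rt, "comparisons")
    de <- list(); lower <- list(); enr <- list()
    for (i in seq_len(nrow(comparisons))) {
      cmpId <- comparisons$comparison_id[i]
      strain <- comparisons$test_strain[i]
      tab <- callDEUnamplified(rt, gi, cmpId, method = config$de_method)
      de[[strain]] <- tab
      lower[[strain]] <- lowerExpressedSet(tab, fdrCut = config$de_fdr)
      enr[[strain]] <- enrichCategories(lower[[strain]], data$categories,
                                        universe = tab$gene_id)
    }
    called <- calledGenes(bundle$calls)
    mlrCalled <- if (!is.null(bundle$mlr))
      names(classLabels(bundle$mlr$fit))[classLabels(bundle$mlr$fit) == "class3a_sub"]
    else character(0)
    allCalled <- union(called, mlrCalled)
    strains <- comparisons$test_strain
    callsDF <- do.call(rbind, lapply(unique(strains), function(s)
      data.frame(gene_id = allCalled, strain = s, stringsAsFactors = FALSE)))
    flt <- filterAmplifiedCalls(callsDF, enr, data$categories,
                                pThreshold = config$enrich_p)
    keptGenes <- setdiff(allCalled, unique(flt$removed$gene_id))
    eff <- thresholdCalls(bundle$calls)
    effSize <- setNames(eff$effect_size, eff$gene_id)[keptGenes]
    effSize <- effSize[!is.na(effSize)]
    tertiles <- if (length(effSize)) partitionByEffect(effSize) else character(0)
    list(de = de, lower_expressed = lower, enrichment = enr,
         removed = unique(flt$removed$gene_id), kept = keptGenes,
         removal_fraction = if (length(allCalled))
           length(unique(flt$removed$gene_id)) / length(allCalled) else 0,
         tertiles = tertiles)
  })

  bundle$evolution <- .stage("evolution", {
    cnv <- data$cnv
    if (is.null(cnv) && !is.null(bundle$truth)) {
      cls <- setNames(bundle$truth$class, bundle$truth$gene_id)
      cnv <- simulatePopulationCNV(cls, seed = childSeed(config$seed, 47L))
    }
    if (is.null(cnv)) {
      NULL
    } else {
      eff <- thresholdCalls(bundle$calls)
      assessed <- eff$gene_id
      kept <- bundle$filter$kept
      groups <- list(
        top = names(bundle$filter$tertiles)[bundle$filter$tertiles == "top"],
        middle = names(bundle$filter$tertiles)[bundle$filter$tertiles == "middle"],
        bottom = names(bundle$filter$tertiles)[bundle$filter$tertiles == "bottom"],
        proportionate = setdiff(assessed, union(kept, bundle$filter$removed)),
        unamplified_reduced = unique(unlist(bundle$filter$lower_expressed)),
        all_genes = gi$gene_id)
      frac <- vapply(groups, function(g) {
        if (length(intersect(g, cnv$gene_id)) == 0) NA_real_
        else cnvFraction(cnv, g, minStrains = config$min_strains)
      }, numeric(1))
      ref <- bufferingScores(cnv, groups$proportionate)
      comparisonsOut <- lapply(groups[c("top", "middle", "bottom",
                                        "unamplified_reduced")], function(g) {
        sc <- bufferingScores(cnv, g)
        if (length(sc) < 2 || length(ref) < 2)
          list(p = NA_real_, direction = NA_real_, test = "rank_sum",
               n_a = length(sc), n_b = length(ref))
        else compareGroups(sc, ref)
      })
      list(cnv = cnv, groups = groups, cnv_fraction = frac,
           buffering_vs_proportionate = comparisonsOut)
    }
  })

  class(bundle) <- "PipelineBundle"
  if (!is.null(config$out_dir))
    .writeBundle(bundle, config$out_dir)
  bundle
}

.writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeRatioTable(bundle$ratios, file.path(dir, "ratios.tsv"))
  write.table(thresholdCalls(bundle$calls), file.path(dir, "calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$mlr)) {
    write.table(bundle$mlr$fit@components, file.path(dir, "mlr_components.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    post <- data.frame(gene_id = rownames(posteriors(bundle$mlr$fit)),
                       posteriors(bundle$mlr$fit), check.names = FALSE)
    write.table(post, file.path(dir, "mlr_posteriors.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cl <- classLabels(bundle$mlr$fit)
    write.table(data.frame(gene_id = names(cl), class = unname(cl)),
                file.path(dir, "mlr_classes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(lrtResults(bundle$mlr$lrt), file.path(dir, "lrt.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(sprintf("%.6f", pi0Estimate(bundle$mlr$lrt)),
               file.path(dir, "pi0.txt"))
  }
  write.table(data.frame(gene_id = bundle$filter$kept),
              file.path(dir, "revised_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$evolution)) {
    write.table(bundle$evolution$cnv, file.path(dir, "cnv.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    evoRows <- data.frame(
      group = names(bundle$evolution$cnv_fraction),
      cnv_fraction = unname(bundle$evolution$cnv_fraction))
    write.table(evoRows, file.path(dir, "evo_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  cfg <- unclass(bundle$config)
  cfg$out_dir <- NULL   # path-independent, so reruns hash identically
  cfgJSON <- jsonlite::toJSON(cfg, auto_unbox = TRUE,
                              digits = NA, null = "null")
  cfgPath <- file.path(dir, "config.json")
  writeLines(cfgJSON, cfgPath)
  manifest <- list(
    package = "aneudose",
    version = as.character(utils::packageVersion("aneudose")),
    seed = bundle$config$seed,
    config_md5 = unname(md5sum(cfgPath)),
    design = bundle$design,
    n_genes_assessed = nrow(thresholdCalls(bundle$calls)),
    n_not_assessed = length(bundle$calls@notAssessed),
    n_called = length(calledGenes(bundle$calls)),
    n_kept_after_filter = length(bundle$filter$kept))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
  writeLines(summarizeBundle(bundle), file.path(dir, "summary.txt"))
  invisible(dir)
}

#' Summarize a pipeline bundle
#'
#' Per-analysis assessed-gene denominators, call counts and percentages, the
#' permutation FDR, mixture-class proportions, conditional FDR, pi0, and the
#' indirect-response removal fraction, as text lines.
#'
#' @param bundle result of [runPipeline()].
#' @return Character vector of summary lines.
#' @export
summarizeBundle <- function(bundle) {
  lines <- character(0)
  calls <- thresholdCalls(bundle$calls)
  n <- nrow(calls); k <- sum(calls$called)
  lines <- c(lines, sprintf("design: %s", bundle$design))
  lines <- c(lines, sprintf("threshold (k = %g): %s genes called; %d not assessed",
                            bundle$calls@kSd,
                            if (n > 0) fmtCount(k, n) else "0/0",
                            length(bundle$calls@notAssessed)))
  fdr <- fdrEstimate(bundle$calls)
  lines <- c(lines, if (k == 0 || is.na(fdr)) "permutation FDR: undefined (0 calls)"
             else sprintf("permutation FDR: %.1f%%", 100 * fdr))
  if (!is.null(bundle$mlr)) {
    pi <- mixingProportions(bundle$mlr$fit)
    lines <- c(lines, paste0("MLR mixing proportions: ",
                             paste(sprintf("%s=%.3f", names(pi), pi), collapse = ", ")))
    cls <- classLabels(bundle$mlr$fit)
    n3a <- sum(cls == "class3a_sub")
    if (n3a > 0)
      lines <- c(lines, sprintf(
        "MLR class3a (sub-proportional): %s of fitted genes; conditional FDR %.1f%%",
        fmtCount(n3a, length(cls)),
        100 * conditionalFDR(bundle$mlr$fit, "class3a_sub")))
    agr <- bundle$mlr$agreement
    lines <- c(lines, sprintf(
      "LRT pi0 = %.3f; MLR non-proportional = %.3f vs 1 - pi0 = %.3f (|diff| = %.3f)",
      pi0Estimate(bundle$mlr$lrt), agr$mlr_nonproportional,
      agr$lrt_nonnull, agr$difference))
  }
  lines <- c(lines, sprintf(
    "indirect-response filter: removed %.1f%% of calls; %d genes kept",
    100 * bundle$filter$removal_fraction, length(bundle$filter$kept)))
  if (!is.null(bundle$evolution)) {
    fr <- bundle$evolution$cnv_fraction
    lines <- c(lines, paste0("recurrent-CNV fraction: ",
                             paste(sprintf("%s=%.3f", names(fr), fr), collapse = ", ")))
  }
  lines
}
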