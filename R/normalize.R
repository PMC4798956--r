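#' RPKM normalization
#'
#' Reads per kilobase of gene length per million mapped reads:
#' `RPKM(g, s) = count(g, s) / (length_bp(g)/1000) / (total(s)/1e6)`.
#' Optionally, whole chromosomes (typically the amplified ones) can be removed
#' from the per-sample totals while their genes keep their values — the
#' "RPKM excluding the amplified chromosomes" variant.
#'
#' @param x an [AneuploidyCountSet].
#' @param excludeChromosomes character vector of chromosome names to drop from
#'   the library totals (default none).
#' @return Numeric matrix of RPKM values, genes x samples.
#' @export
rpkmNormalize <- function(x, excludeChromosomes = NULL) {
  cts <- countMatrix(x)
  gi <- geneInfo(x)
  keep <- !(gi$chromosome %in% excludeChromosomes)
  totals <- colSums(cts[keep, , drop = FALSE])
  stopIfNot(all(totals > 0), "zero library total after exclusions")
  kb <- gi$length_bp / 1000
  sweep(cts / kb, 2, totals / 1e6, "/")
}

#' Cell-count (spike-in) normalization
#'
#' Scales counts to per-cell abundances using reads from a foreign species
#' doped in proportion to the number of counted cells:
#' `abundance(g, s) = count(g, s) * f(ref) / f(s)` with
#' `f(s) = spike_total(s) / cells_counted(s)` and `ref` the first sample. The
#' result is invariant (up to one global constant) to which sample is taken as
#' reference, so between-sample ratios do not depend on it.
#'
#' @param x an [AneuploidyCountSet] whose every sample carries `spike_total`
#'   and `cells_counted`.
#' @return Numeric matrix of per-cell abundances, genes x samples.
#' @export
spikeInNormalize <- function(x) {
  cd <- as.data.frame(colData(x))
  for (col in c("spike_total", "cells_counted")) {
    bad <- !col %in% colnames(cd) | is.na(cd[[col]]) | cd[[col]] <= 0
    if (any(bad))
      stop("spike-in normalization needs positive ", col, " for sample(s): ",
           paste(colnames(x)[bad], collapse = ", "), call. = FALSE)
  }
  f <- cd$spike_total / cd$cells_counted
  sweep(countMatrix(x), 2, f / f[1], "/")
}

#' Log2 ratio tables for strain comparisons
#'
#' For each `(test_sample, ref_sample, comparison_id)` pair, computes per-gene
#' `log2(test / ref)` of normalized abundances. Genes with zero abundance in
#' either sample of a pair are excluded from that pair (no pseudocount) and
#' listed in the drop report. RNA and DNA ratios are carried as separate
#' molecule-tagged rows keyed to the same comparison id, with the replicate
#' number taken from the test sample's metadata.
#'
#' @param abund numeric matrix of normalized abundances (genes x samples), from
#'   [rpkmNormalize()] or [spikeInNormalize()].
#' @param pairs data.frame with columns `test`, `ref`, `comparison_id` naming
#'   abundance columns.
#' @param sampleData data.frame of sample metadata (rownames = sample names),
#'   e.g. `sampleInfo(x)` with rownames set; used for `molecule`, `replicate`
#'   and strains.
#' @return data.frame with columns `gene_id`, `comparison_id`, `replicate`,
#'   `molecule`, `log2_ratio`; attribute `"dropped"` is the drop report
#'   (gene/pair), attribute `"comparisons"` maps comparison ids to test and
#'   reference strains.
#' @export
log2Ratios <- function(abund, pairs, sampleData) {
  stopIfNot(all(c("test", "ref", "comparison_id") %in% colnames(pairs)),
            "pairs needs columns test, ref, comparison_id")
  if ("sample" %in% colnames(sampleData) &&
      !identical(rownames(sampleData), sampleData$sample))
    rownames(sampleData) <- sampleData$sample
  miss <- setdiff(unique(c(pairs$test, pairs$ref)), colnames(abund))
  stopIfNot(length(miss) == 0, "samples missing from abundance matrix: ",
            paste(miss, collapse = ", "))
  rows <- vector("list", nrow(pairs))
  drops <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    tst <- pairs$test[i]; ref <- pairs$ref[i]
    a <- abund[, tst]; b <- abund[, ref]
    ok <- a > 0 & b > 0
    md <- sampleData[tst, ]
    rows[[i]] <- data.frame(
      gene_id = rownames(abund)[ok],
      comparison_id = pairs$comparison_id[i],
      replicate = md$replicate,
      molecule = md$molecule,
      log2_ratio = log2(a[ok] / b[ok]),
      stringsAsFactors = FALSE)
    if (any(!ok))
      drops[[i]] <- data.frame(gene_id = rownames(abund)[!ok],
                               comparison_id = pairs$comparison_id[i],
                               test = tst, ref = ref, molecule = md$molecule,
                               stringsAsFactors = FALSE)
  }
  rt <- do.call(rbind, rows)
  rownames(rt) <- NULL
  dropped <- do.call(rbind, drops[!vapply(drops, is.null, logical(1))])
  attr(rt, "dropped") <- dropped
  cmp <- unique(data.frame(
    comparison_id = pairs$comparison_id,
    test_strain = sampleData[pairs$test, "strain"],
    ref_strain = sampleData[pairs$ref, "strain"],
    stringsAsFactors = FALSE))
  rownames(cmp) <- NULL
  attr(rt, "comparisons") <- cmp
  rt
}

#' Center (mean) of a log2 ratio distribution
#'
#' Normalization diagnostic: the arithmetic mean of log2 ratios over a gene
#' subset (typically all unamplified genes of a comparison). A well-normalized
#' comparison has a center near 0; the value is reported, not used as a
#' correction.
#'
#' @param rt ratio table from [log2Ratios()].
#' @param genes gene ids to average over (default: all genes in `rt`).
#' @param molecule `"RNA"` or `"DNA"`.
#' @param comparisons comparison ids to include (default all).
#' @param replicate optionally restrict to one replicate.
#' @return Mean log2 ratio (a single number).
#' @export
distributionCenter <- function(rt, genes = NULL, molecule = "RNA",
                               comparisons = NULL, replicate = NULL) {
  sel <- rt$molecule == molecule
  if (!is.null(genes)) sel <- sel & rt$gene_id %in% genes
  if (!is.null(comparisons)) sel <- sel & rt$comparison_id %in% comparisons
  if (!is.null(replicate)) sel <- sel & rt$replicate %in% replicate
  stopIfNot(any(sel), "empty gene subset for distribution center")
  mean(rt$log2_ratio[sel])
}

#' Build the replicate-matched comparison pairs for a strain comparison
#'
#' Pairs RNA replicate i of the test strain with RNA replicate i of the
#' reference strain (likewise for DNA), the design used throughout: each
#' replicate ratio compares one test culture with one reference culture.
#'
#' @param sampleData sample metadata (`sampleInfo(x)`).
#' @param testStrain,refStrain strain names.
#' @param comparisonId id to assign (default `"<test>_vs_<ref>"`).
#' @return data.frame of `test`, `ref`, `comparison_id` rows for [log2Ratios()].
#' @export
comparisonPairs <- function(sampleData, testStrain, refStrain,
                            comparisonId = paste0(testStrain, "_vs_", refStrain)) {
  if (!"sample" %in% colnames(sampleData))
    sampleData$sample <- rownames(sampleData)
  out <- list()
  for (mol in c("RNA", "DNA")) {
    t <- sampleData[sampleData$strain == testStrain & sampleData$molecule == mol, ]
    r <- sampleData[sampleData$strain == refStrain & sampleData$molecule == mol, ]
    reps <- intersect(t$replicate, r$replicate)
    if (length(reps) == 0) next
    out[[mol]] <- data.frame(
      test = t$sample[match(reps, t$replicate)],
      ref = r$sample[match(reps, r$replicate)],
      comparison_id = comparisonId, stringsAsFactors = FALSE)
  }
  stopIfNot(length(out) > 0, "no replicate-matched samples between ",
            testStrain, " and ", refStrain)
  do.call(rbind, out)
}
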