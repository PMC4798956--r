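# Gene-specific threshold calling of lower-than-expected expression.

# mean DNA log2 ratio per gene for one comparison (averaging DNA replicates)
.dnaRatioPerGene <- function(rt, comparison, genes = NULL) {
  sel <- rt$molecule == "DNA" & rt$comparison_id == comparison
  if (!is.null(genes)) sel <- sel & rt$gene_id %in% genes
  if (!any(sel)) return(setNames(numeric(0), character(0)))
  agg <- tapply(rt$log2_ratio[sel], rt$gene_id[sel], mean)
  setNames(as.numeric(agg), names(agg))
}

.testStrainOf <- function(rt, comparison) {
  cmp <- attr(rt, "comparisons")
  stopIfNot(!is.null(cmp), "ratio table lacks the 'comparisons' attribute")
  hit <- cmp$test_strain[cmp$comparison_id == comparison]
  stopIfNot(length(hit) == 1L, "unknown comparison: ", comparison)
  hit
}

#' SD of DNA log2 ratios on the affected chromosome
#'
#' Sample standard deviation (n-1 denominator) of the log2 DNA ratios of the
#' amplified genes of a chromosome in one strain comparison. This chromosome
#' SD defines the margin of the gene-specific thresholds. Telomere-proximal
#' unamplified genes are excluded through the annotation's `amplified_in`
#' field.
#'
#' @param rt ratio table from [log2Ratios()].
#' @param geneData gene annotation (`geneInfo(x)`).
#' @param comparison comparison id.
#' @param chromosome chromosome name; default: the chromosome carrying the
#'   test strain's amplified genes (must be unique).
#' @return A single positive number; fewer than 2 usable genes, or a zero SD,
#'   is an error.
#' @export
chromosomeSD <- function(rt, geneData, comparison, chromosome = NULL) {
  strain <- .testStrainOf(rt, comparison)
  amp <- amplifiedGenes(geneData, strain)
  if (is.null(chromosome)) {
    chromosome <- unique(geneData$chromosome[geneData$gene_id %in% amp])
    stopIfNot(length(chromosome) == 1L,
              "amplified genes span several chromosomes; give `chromosome`")
  }
  genes <- intersect(amp, geneData$gene_id[geneData$chromosome == chromosome])
  dna <- .dnaRatioPerGene(rt, comparison, genes)
  stopIfNot(length(dna) >= 2,
            "need >=2 amplified genes with DNA ratios on ", chromosome)
  out <- sd(dna)
  stopIfNot(out > 0, "chromosome SD is zero (constant DNA ratios)")
  out
}

#' Gene-specific thresholds for lower-than-expected expression
#'
#' `threshold(g) = log2 DNA ratio(g) - kSd * sdChr`: each gene's measured
#' relative DNA abundance minus `kSd` standard deviations of the affected
#' chromosome's DNA-ratio spread (kSd = 1 default; 3 for the stringent
#' variant). Genes without a DNA ratio in the comparison are dropped with a
#' warning.
#'
#' @param rt ratio table.
#' @param geneData gene annotation.
#' @param comparison comparison id.
#' @param kSd SD multiplier.
#' @param sdChr chromosome SD; computed by [chromosomeSD()] when `NULL`.
#' @param genes genes to threshold (default: the test strain's amplified
#'   genes).
#' @return data.frame `gene_id`, `dna_ratio`, `threshold`, with attribute
#'   `"sdChr"`.
#' @export
geneThresholds <- function(rt, geneData, comparison, kSd = 1,
                           sdChr = NULL, genes = NULL) {
  stopIfNot(kSd >= 0, "kSd must be non-negative")
  if (is.null(sdChr)) sdChr <- chromosomeSD(rt, geneData, comparison)
  stopIfNot(sdChr > 0, "sdChr must be > 0")
  if (is.null(genes)) genes <- amplifiedGenes(geneData, .testStrainOf(rt, comparison))
  dna <- .dnaRatioPerGene(rt, comparison, genes)
  missing <- setdiff(genes, names(dna))
  if (length(missing))
    warning(length(missing), " gene(s) without a DNA ratio dropped in ",
            comparison, call. = FALSE)
  out <- data.frame(gene_id = names(dna), dna_ratio = unname(dna),
                    threshold = unname(dna) - kSd * sdChr,
                    stringsAsFactors = FALSE)
  attr(out, "sdChr") <- sdChr
  out
}

# shared engine for amplified and matched-unamplified calls
.thresholdCalls <- function(rt, geneData, comparisons, kSd, geneSets) {
  stopIfNot(length(comparisons) >= 1, "need at least one comparison")
  thr <- list(); sdChr <- numeric(0)
  for (cmp in comparisons) {
    s <- chromosomeSD(rt, geneData, cmp)
    thr[[cmp]] <- geneThresholds(rt, geneData, cmp, kSd = kSd, sdChr = s,
                                 genes = geneSets[[cmp]])
    sdChr[cmp] <- s
  }
  # callable = genes thresholded and with >=1 mRNA replicate in every comparison
  callable <- Reduce(intersect, lapply(comparisons, function(cmp) {
    rna <- unique(rt$gene_id[rt$molecule == "RNA" & rt$comparison_id == cmp])
    intersect(thr[[cmp]]$gene_id, rna)
  }))
  universe <- Reduce(union, geneSets)
  notAssessed <- setdiff(universe, callable)
  callable <- sort(callable)
  if (length(notAssessed))
    message(length(notAssessed), " gene(s) not assessed (missing from >=1 comparison)")

  diffCols <- list(); effParts <- list()
  thrMat <- matrix(NA_real_, length(callable), length(comparisons),
                   dimnames = list(callable, comparisons))
  for (cmp in comparisons) {
    t <- thr[[cmp]]
    thrMat[, cmp] <- t$threshold[match(callable, t$gene_id)]
    rna <- rt[rt$molecule == "RNA" & rt$comparison_id == cmp &
                rt$gene_id %in% callable, ]
    mrnaMeans <- tapply(rna$log2_ratio, rna$gene_id, mean)
    effParts[[cmp]] <- as.numeric(mrnaMeans[callable]) -
      t$dna_ratio[match(callable, t$gene_id)]
    for (r in sort(unique(rna$replicate))) {
      sub <- rna[rna$replicate == r, ]
      v <- setNames(sub$log2_ratio, sub$gene_id)[callable] - thrMat[, cmp]
      diffCols[[paste(cmp, "rep", r, sep = "_")]] <- v
    }
  }
  diffs <- do.call(cbind, diffCols)
  rownames(diffs) <- callable
  if (anyNA(diffs)) {
    # a gene missing one replicate ratio cannot be assessed either
    drop <- rownames(diffs)[!complete.cases(diffs)]
    notAssessed <- union(notAssessed, drop)
    keep <- setdiff(callable, drop)
    diffs <- diffs[keep, , drop = FALSE]
    thrMat <- thrMat[keep, , drop = FALSE]
    effParts <- lapply(effParts, function(v) v[match(keep, callable)])
    callable <- keep
  }
  effect <- Reduce(`+`, effParts) / length(effParts)
  nBelow <- rowSums(diffs < 0)           # ties (== threshold) are not "below"
  calls <- data.frame(gene_id = callable,
                      called = nBelow == ncol(diffs),
                      n_replicates_below = as.integer(nBelow),
                      effect_size = as.numeric(effect),
                      stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  new("ThresholdCallSet", calls = calls, thresholds = thrMat, diffs = diffs,
      kSd = kSd, sdChr = sdChr, comparisons = comparisons,
      notAssessed = sort(notAssessed), fdrEstimate = NA_real_,
      nullCounts = numeric(0))
}

#' Call amplified genes with lower-than-expected expression
#'
#' A gene is called when its log2 mRNA ratio lies strictly below its
#' gene-specific threshold in every replicate of every listed comparison — with
#' the default two strain pairs of two mRNA replicates each, below threshold in
#' four biological measurements. Genes missing from any comparison are not
#' assessed (reported in `notAssessed` for denominator bookkeeping). The
#' effect size is the mean log2 mRNA ratio minus the log2 DNA ratio, averaged
#' over comparisons.
#'
#' @param rt ratio table from [log2Ratios()].
#' @param geneData gene annotation.
#' @param comparisons comparison ids to intersect over (default: all
#'   comparisons present in `rt`).
#' @param kSd SD multiplier (1 default, 3 stringent).
#' @return A [ThresholdCallSet].
#' @export
callLowerExpressed <- function(rt, geneData, comparisons = NULL, kSd = 1) {
  if (is.null(comparisons))
    comparisons <- attr(rt, "comparisons")$comparison_id
  geneSets <- lapply(comparisons, function(cmp)
    amplifiedGenes(geneData, .testStrainOf(rt, cmp)))
  names(geneSets) <- comparisons
  .thresholdCalls(rt, geneData, comparisons, kSd, geneSets)
}

#' Matched control calls on unamplified genes
#'
#' Applies the identical thresholding rule to the genes that are unamplified
#' in every test strain, using each gene's own measured DNA ratio (near 0) and
#' the same chromosome SD as used for the amplified genes.
#'
#' @inheritParams callLowerExpressed
#' @return A [ThresholdCallSet] over unamplified genes.
#' @export
matchedUnamplifiedCalls <- function(rt, geneData, comparisons = NULL, kSd = 1) {
  if (is.null(comparisons))
    comparisons <- attr(rt, "comparisons")$comparison_id
  geneSets <- lapply(comparisons, function(cmp) {
    amp <- amplifiedGenes(geneData, .testStrainOf(rt, cmp))
    setdiff(geneData$gene_id, amp)
  })
  names(geneSets) <- comparisons
  .thresholdCalls(rt, geneData, comparisons, kSd, geneSets)
}

#' @rdname permutationFDR
#' @export
setMethod("permutationFDR", "matrix", function(x, nIter = 10000, seed = NULL, ...) {
  stopIfNot(nrow(x) > 0 && ncol(x) > 0, "empty difference matrix")
  neg <- x < 0
  G <- nrow(neg)
  withSeed(seed, function() {
    nullCounts <- integer(nIter)
    for (i in seq_len(nIter)) {
      allBelow <- neg[sample.int(G), 1L]
      for (j in seq_len(ncol(neg))[-1L])
        allBelow <- allBelow & neg[sample.int(G), j]
      nullCounts[i] <- sum(allBelow)
    }
    list(nullCounts = nullCounts, meanNull = mean(nullCounts))
  })
})

#' @rdname permutationFDR
#' @export
setMethod("permutationFDR", "ThresholdCallSet",
          function(x, nIter = 10000, seed = NULL, ...) {
  observed <- sum(x@calls$called)
  perm <- permutationFDR(x@diffs, nIter = nIter, seed = seed)
  x@nullCounts <- as.numeric(perm$nullCounts)
  if (observed == 0) {
    warning("no observed calls: permutation FDR undefined", call. = FALSE)
    x@fdrEstimate <- NA_real_
  } else {
    x@fdrEstimate <- perm$meanNull / observed
  }
  x
})

#' @rdname ThresholdCallSet-accessors
#' @param ... unused.
#' @export
setMethod("calledGenes", "ThresholdCallSet", function(object, ...) {
  object@calls$gene_id[object@calls$called]
})

#' @rdname ThresholdCallSet-accessors
#' @export
setMethod("fdrEstimate", "ThresholdCallSet", function(object) object@fdrEstimate)

#' @rdname ThresholdCallSet-accessors
#' @export
thresholdCalls <- function(object) object@calls

setMethod("show", "ThresholdCallSet", function(object) {
  n <- nrow(object@calls)
  k <- sum(object@calls$called)
  cat("ThresholdCallSet (kSd =", object@kSd, ")\n")
  cat("  comparisons:", paste(object@comparisons, collapse = ", "), "\n")
  cat("  assessed:", n, "genes | not assessed:", length(object@notAssessed), "\n")
  if (n > 0) cat("  called:", fmtCount(k, n), "\n")
  if (!is.na(object@fdrEstimate))
    cat("  permutation FDR:", sprintf("%.1f%%", 100 * object@fdrEstimate),
        sprintf("(%d iterations)", length(object@nullCounts)), "\n")
  invisible(NULL)
})
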