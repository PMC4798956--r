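#' Container for paired RNA/DNA read counts of aneuploid and euploid strains
#'
#' `AneuploidyCountSet` extends
#' [SummarizedExperiment::SummarizedExperiment] with a `"counts"` assay of
#' non-negative integer read counts (genes x samples), sample metadata
#' (`strain`, `molecule`, `replicate`, `ploidy_label`, and optional
#' `spike_total` / `cells_counted` for cell-count normalization), and gene
#' annotation (`chromosome`, `length_bp`, the set of strains in which the gene
#' is amplified, and functional categories).
#'
#' @slot .Data inherits everything from `SummarizedExperiment`.
#' @seealso [AneuploidyCountSet()] for construction, [readCounts()] for file
#'   input, [rpkmNormalize()] and [spikeInNormalize()] for normalization.
#' @export
setClass("AneuploidyCountSet", contains = "SummarizedExperiment")

setValidity("AneuploidyCountSet", function(object) {
  msg <- character(0)
  if (!"counts" %in% names(assays(object)))
    return("assay 'counts' is required")
  cts <- assay(object, "counts")
  if (any(is.na(cts)) || any(cts < 0))
    msg <- c(msg, "counts must be non-negative and non-missing")
  if (any(abs(cts - round(cts)) > 1e-8))
    msg <- c(msg, "counts must be integers")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  cd <- colData(object)
  need <- c("strain", "molecule", "replicate")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, sprintf("colData must contain columns: %s",
                          paste(need, collapse = ", ")))
  } else {
    if (!all(cd$molecule %in% c("RNA", "DNA")))
      msg <- c(msg, "molecule must be 'RNA' or 'DNA'")
    key <- paste(cd$strain, cd$molecule, cd$replicate)
    if (anyDuplicated(key))
      msg <- c(msg, "every sample needs a distinct (strain, molecule, replicate) triple")
    if (any(cd$replicate < 1))
      msg <- c(msg, "replicate must be a positive integer")
  }
  rd <- rowData(object)
  needG <- c("chromosome", "length_bp")
  if (!all(needG %in% colnames(rd))) {
    msg <- c(msg, sprintf("rowData must contain columns: %s",
                          paste(needG, collapse = ", ")))
  } else if (any(is.na(rd$length_bp)) || any(rd$length_bp < 1)) {
    msg <- c(msg, "length_bp must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Gene-specific threshold calls for lower-than-expected expression
#'
#' Holds, for a set of assessed genes, the per-comparison gene-specific
#' thresholds (measured log2 DNA ratio minus `kSd` chromosome SDs), the
#' per-replicate differences `d = log2 mRNA ratio - threshold`, the final calls
#' (below threshold in every replicate of every comparison), effect sizes, and
#' the label-permutation FDR estimate once [permutationFDR()] has run.
#'
#' @slot calls data.frame with columns `gene_id`, `called`,
#'   `n_replicates_below`, `effect_size` (mean log2 mRNA ratio minus mean log2
#'   DNA ratio across comparisons).
#' @slot thresholds numeric matrix, genes x comparisons.
#' @slot diffs numeric matrix, genes x replicate columns (one column per RNA
#'   replicate per comparison).
#' @slot kSd numeric, SD multiplier used (1 default, 3 stringent).
#' @slot sdChr named numeric, per-comparison SD of DNA log2 ratios on the
#'   affected chromosome.
#' @slot comparisons character, comparison ids used.
#' @slot notAssessed character, genes dropped because they were missing from
#'   at least one comparison (kept for denominator bookkeeping).
#' @slot fdrEstimate numeric, permutation FDR (NA until estimated).
#' @slot nullCounts numeric, per-iteration null call counts.
#' @export
setClass("ThresholdCallSet",
  representation(calls = "data.frame", thresholds = "matrix",
                 diffs = "matrix", kSd = "numeric", sdChr = "numeric",
                 comparisons = "character", notAssessed = "character",
                 fdrEstimate = "numeric", nullCounts = "numeric"))

setValidity("ThresholdCallSet", function(object) {
  msg <- character(0)
  cls <- object@calls
  need <- c("gene_id", "called", "n_replicates_below", "effect_size")
  if (!all(need %in% colnames(cls)))
    msg <- c(msg, "calls must have gene_id, called, n_replicates_below, effect_size")
  if (nrow(cls) && any(!is.finite(cls$effect_size)))
    msg <- c(msg, "effect_size must be finite")
  if (nrow(cls) && nrow(object@diffs) != nrow(cls))
    msg <- c(msg, "diffs rows must match calls rows")
  if (nrow(cls)) {
    recomputed <- rowSums(object@diffs < 0) == ncol(object@diffs)
    if (!identical(unname(recomputed), unname(cls$called)))
      msg <- c(msg, "called must equal AND over all replicate below-threshold flags")
  }
  if (length(object@kSd) != 1L || object@kSd < 0)
    msg <- c(msg, "kSd must be a single non-negative number")
  if (any(object@sdChr <= 0))
    msg <- c(msg, "per-comparison chromosome SD must be > 0")
  if (length(msg)) msg else TRUE
})

#' Fitted mixture-of-linear-regressions dosage-response model
#'
#' @slot components data.frame describing each mixture component: `label`,
#'   `intercept`, `slope` (fitted or fixed), `fixed_intercept`, `fixed_slope`,
#'   `slope_lower`, `slope_upper`, `var_inflation`.
#' @slot pi numeric mixing proportions (sum 1).
#' @slot sigma numeric shared residual SD (log2 units).
#' @slot posteriors genes x components matrix of posterior membership
#'   probabilities (rows sum to 1).
#' @slot classes named character, per-gene maximum-posterior class label.
#' @slot loglik numeric log-likelihood trace of the best EM start.
#' @slot converged logical.
#' @slot nTies integer, number of exact posterior ties broken toward the
#'   lower-index component.
#' @export
setClass("MLRFit",
  representation(components = "data.frame", pi = "numeric", sigma = "numeric",
                 posteriors = "matrix", classes = "character",
                 loglik = "numeric", converged = "logical", nTies = "integer"))

setValidity("MLRFit", function(object) {
  msg <- character(0)
  if (abs(sum(object@pi) - 1) > 1e-6)
    msg <- c(msg, "mixing proportions must sum to 1")
  if (nrow(object@posteriors)) {
    rs <- rowSums(object@posteriors)
    if (any(abs(rs - 1) > 1e-6))
      msg <- c(msg, "posterior rows must sum to 1")
  }
  if (length(object@loglik) > 1L &&
      any(diff(object@loglik) < -1e-6 * (abs(object@loglik[-1]) + 1)))
    msg <- c(msg, "EM log-likelihood must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Per-gene likelihood-ratio test of proportional dosage response
#'
#' Results of testing, gene by gene, the null hypothesis that log2 mRNA ratio
#' equals log2 DNA ratio (intercept 0, slope 1) against an unrestricted linear
#' model, with the statistic referred to a chi-squared distribution on 2
#' degrees of freedom, plus the Storey-style null-proportion estimate and
#' q-values.
#'
#' @slot results data.frame with `gene_id`, `n` (points used), `lambda`
#'   (statistic), `p`, `q`.
#' @slot pi0 numeric in `[0, 1]`, estimated proportion of null
#'   (proportional-dosage) genes.
#' @slot pi0Method character, `"plugin"` or `"smoother"`.
#' @slot skipped character, genes skipped (too few points or degenerate x).
#' @export
setClass("LRTResult",
  representation(results = "data.frame", pi0 = "numeric",
                 pi0Method = "character", skipped = "character"))

setValidity("LRTResult", function(object) {
  msg <- character(0)
  r <- object@results
  if (nrow(r) && (any(r$p < 0) || any(r$p > 1)))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (object@pi0 < 0 || object@pi0 > 1)
    msg <- c(msg, "pi0 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
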