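# Indirect-response (trans-effect) filter and effect-size partition.

#' Differential expression of unamplified genes in one strain comparison
#'
#' Stand-in for a count-based DE analysis of aneuploid versus isogenic euploid
#' expression, restricted to unamplified genes. The default `"moderated_t"`
#' method runs a limma moderated one-sample t-test on the replicate log2 mRNA
#' ratios against 0 (empirical-Bayes variance moderation is what gives usable
#' power at 2-3 replicates); `"ratio_t"` is a plain per-gene one-sample
#' t-test; `"import"` reads an externally produced table unchanged (see
#' [importDETable()]). P-values are BH-adjusted. Downstream selection always
#' takes FDR < `fdrCut` and negative mean log2 fold-change.
#'
#' @param rt ratio table from [log2Ratios()].
#' @param geneData gene annotation.
#' @param comparison comparison id (one aneuploid strain vs its euploid).
#' @param method `"moderated_t"`, `"ratio_t"` or `"import"`.
#' @param importPath TSV path for `method = "import"`.
#' @return data.frame with `gene_id`, `log2fc`, `pvalue`, `fdr`.
#' @export
callDEUnamplified <- function(rt, geneData, comparison,
                              method = c("moderated_t", "ratio_t", "import"),
                              importPath = NULL) {
  method <- match.arg(method)
  if (method == "import") {
    stopIfNot(!is.null(importPath), "method='import' needs importPath")
    return(importDETable(importPath))
  }
  strain <- .testStrainOf(rt, comparison)
  unamp <- setdiff(geneData$gene_id, amplifiedGenes(geneData, strain))
  rna <- rt[rt$molecule == "RNA" & rt$comparison_id == comparison &
              rt$gene_id %in% unamp, ]
  stopIfNot(nrow(rna) > 0, "no unamplified mRNA ratios in ", comparison)
  mat <- tapply(rna$log2_ratio, list(rna$gene_id, rna$replicate), mean)
  mat <- mat[complete.cases(mat), , drop = FALSE]
  nrep <- ncol(mat)
  stopIfNot(nrep >= 2,
            "need >=2 mRNA replicates for method='", method,
            "'; use method='import' for external DE results")
  if (method == "moderated_t") {
    fit <- limma::eBayes(limma::lmFit(mat, design = matrix(1, nrep, 1)))
    p <- fit$p.value[, 1]
    fc <- fit$coefficients[, 1]
  } else {
    fc <- rowMeans(mat)
    se <- apply(mat, 1, sd) / sqrt(nrep)
    tstat <- fc / se
    p <- 2 * pt(-abs(tstat), df = nrep - 1)
    p[se == 0 & fc == 0] <- 1
  }
  data.frame(gene_id = rownames(mat), log2fc = unname(fc),
             pvalue = unname(p), fdr = p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the lower-expressed unamplified genes from a DE table
#' @param de DE table from [callDEUnamplified()].
#' @param fdrCut FDR cutoff (default 0.01).
#' @return Character vector of gene ids with `fdr < fdrCut` and negative mean
#'   log2 fold-change.
#' @export
lowerExpressedSet <- function(de, fdrCut = 0.01) {
  de$gene_id[de$fdr < fdrCut & de$log2fc < 0]
}

#' Hypergeometric functional-category enrichment
#'
#' Upper-tail hypergeometric test of each category's overlap with a query gene
#' set within a universe (the assessed unamplified genes of a strain, by
#' default convention). Categories flagged as localization-based are skipped
#' when `excludeLocalization` is set, mirroring the practice of ignoring
#' cellular-localization annotations when defining indirect-response groups.
#'
#' @param query character vector of gene ids (must lie within `universe`).
#' @param categories named list of gene-id vectors (see [readGMT()]); an
#'   optional `localization` attribute (named logical) marks
#'   localization-based categories.
#' @param universe character vector of gene ids.
#' @param excludeLocalization skip localization-flagged categories.
#' @return data.frame with `category`, `overlap`, `category_size`,
#'   `query_size`, `universe_size`, `p` (upper tail, includes the observed
#'   overlap). Empty query gives an empty result.
#' @export
enrichCategories <- function(query, categories, universe,
                             excludeLocalization = TRUE) {
  stopIfNot(all(query %in% universe), "query must be a subset of the universe")
  empty <- data.frame(category = character(0), overlap = integer(0),
                      category_size = integer(0), query_size = integer(0),
                      universe_size = integer(0), p = numeric(0))
  if (length(query) == 0) return(empty)
  loc <- attr(categories, "localization")
  keep <- names(categories)
  if (excludeLocalization && !is.null(loc))
    keep <- keep[!vapply(keep, function(nm) isTRUE(loc[[nm]]), logical(1))]
  if (length(keep) == 0) return(empty)
  N <- length(unique(universe))
  n <- length(unique(query))
  rows <- lapply(keep, function(nm) {
    K <- length(intersect(categories[[nm]], universe))
    k <- length(intersect(categories[[nm]], query))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = nm, overlap = k, category_size = K,
               query_size = n, universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Remove amplified calls that belong to strain-specific indirect-response
#' categories
#'
#' A called amplified gene is removed when it belongs to at least one
#' functional category enriched (p < `pThreshold`) among the down-regulated
#' unamplified genes of its own strain — the signature of a trans-acting
#' response to the aneuploid state rather than to the gene's own copy number.
#' Genes without category annotation cannot match and are retained. The
#' operation is idempotent.
#'
#' @param calls data.frame with columns `gene_id` and `strain` (strain of
#'   origin of each call), e.g. assembled from one or more
#'   [ThresholdCallSet]s and/or the MLR sub-proportional class.
#' @param enrichments named list (by strain) of enrichment tables from
#'   [enrichCategories()].
#' @param categories named list of gene-id vectors.
#' @param pThreshold enrichment significance cutoff (default 4e-4).
#' @return List with `kept` and `removed` (both subsets of `calls`),
#'   `removal_fraction`, and `enriched_categories` (per strain).
#' @export
filterAmplifiedCalls <- function(calls, enrichments, categories,
                                 pThreshold = 4e-4) {
  stopIfNot(all(c("gene_id", "strain") %in% colnames(calls)),
            "calls needs columns gene_id and strain")
  enrichedBy <- lapply(enrichments, function(e) {
    if (is.null(e) || nrow(e) == 0) character(0)
    else e$category[e$p < pThreshold]
  })
  remove <- vapply(seq_len(nrow(calls)), function(i) {
    cats <- enrichedBy[[calls$strain[i]]]
    if (is.null(cats) || length(cats) == 0) return(FALSE)
    any(vapply(cats, function(nm) calls$gene_id[i] %in% categories[[nm]],
               logical(1)))
  }, logical(1))
  list(kept = calls[!remove, , drop = FALSE],
       removed = calls[remove, , drop = FALSE],
       removal_fraction = if (nrow(calls)) mean(remove) else 0,
       enriched_categories = enrichedBy)
}

#' Partition calls into effect-size thirds
#'
#' Ranks calls by effect size (most negative = strongest reduction = "top")
#' and splits them into `nBins` groups as equal as possible, extra genes going
#' to the stronger bins; ties are broken by gene id for determinism. With
#' fewer calls than bins, each gene becomes its own bin with a warning.
#'
#' @param effects named numeric vector: effect size per called gene (mean log2
#'   mRNA ratio minus log2 DNA ratio).
#' @param nBins number of bins (default 3).
#' @return Named character vector of bin labels (`"top"`, `"middle"`,
#'   `"bottom"` for 3 bins; `"bin1"`, ... otherwise) in the input order.
#' @export
partitionByEffect <- function(effects, nBins = 3) {
  stopIfNot(!is.null(names(effects)), "effects must be named by gene id")
  n <- length(effects)
  if (n < nBins) {
    warning("fewer calls than bins: each gene is its own bin", call. = FALSE)
    nBins <- max(n, 1L)
  }
  sizes <- rep(n %/% nBins, nBins)
  extra <- n %% nBins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- if (nBins == 3) c("top", "middle", "bottom")
            else sprintf("bin%d", seq_len(nBins))
  o <- order(effects, names(effects))   # most negative first
  out <- rep(labels, sizes)
  res <- character(n)
  res[o] <- out
  setNames(res, names(effects))
}
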