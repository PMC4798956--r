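# Population CNV summaries, buffering scores, and group comparisons.

#' Fraction of genes with recurrent amplification in a population
#'
#' The fraction of a gene group for which at least `minStrains` of the
#' surveyed strains carry an amplification of the gene (default 3 of the
#' population; 2 is the common robustness variant).
#'
#' @param records data.frame with columns `gene_id` and `n_strains_amplified`
#'   (e.g. from [simulatePopulationCNV()] or a `cnv.tsv`).
#' @param group gene ids of the group (default: all records).
#' @param minStrains minimum number of strains (default 3).
#' @return A single fraction in `[0, 1]`; empty groups are an error.
#' @export
cnvFraction <- function(records, group = NULL, minStrains = 3) {
  if (!is.null(group)) records <- records[records$gene_id %in% group, ]
  stopIfNot(nrow(records) > 0, "empty gene group")
  mean(records$n_strains_amplified >= minStrains)
}

#' CNV buffering scores
#'
#' For genes with CNV (amplified in at least one surveyed strain), the
#' buffering score is the number of strains carrying a duplication divided by
#' the gene's expression constraint Vg/Vm. High scores mean frequent copy
#' number variation despite strong constraint on expression — the signature
#' expected of genes whose expression is buffered against dosage. Genes with
#' non-positive Vg/Vm are excluded with a warning.
#'
#' @param records data.frame with `gene_id`, `n_strains_amplified`, `vg_vm`.
#' @param group optional gene ids to restrict to.
#' @return Named numeric vector of scores over genes with
#'   `n_strains_amplified >= 1` and `vg_vm > 0`.
#' @export
bufferingScores <- function(records, group = NULL) {
  if (!is.null(group)) records <- records[records$gene_id %in% group, ]
  records <- records[records$n_strains_amplified >= 1, ]
  bad <- records$vg_vm <= 0 | !is.finite(records$vg_vm)
  if (any(bad)) {
    warning(sum(bad), " gene(s) with non-positive Vg/Vm excluded", call. = FALSE)
    records <- records[!bad, ]
  }
  setNames(records$n_strains_amplified / records$vg_vm, records$gene_id)
}

#' Compare two gene groups statistically
#'
#' For score vectors (`test = "rank_sum"`): a two-sided Wilcoxon rank-sum
#' test, with the effect direction as the sign of the median difference
#' (group a minus group b). For binary indicators (`test = "fisher"`, e.g.
#' recurrent-CNV membership): a two-sided Fisher exact test on the 2x2 table.
#' The test used is declared in the output so downstream reports can state it.
#'
#' @param a,b numeric score vectors (rank_sum) or logical vectors (fisher).
#' @param test `"rank_sum"` or `"fisher"`.
#' @return List with `p`, `direction` (-1, 0 or 1), `test`, `n_a`, `n_b`.
#' @export
compareGroups <- function(a, b, test = c("rank_sum", "fisher")) {
  test <- match.arg(test)
  stopIfNot(length(a) >= 2 && length(b) >= 2, "both groups need >= 2 elements")
  if (test == "rank_sum") {
    p <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))$p.value
    dir <- sign(median(a) - median(b))
  } else {
    tab <- matrix(c(sum(a), sum(!a), sum(b), sum(!b)), 2)
    p <- fisher.test(tab)$p.value
    dir <- sign(mean(a) - mean(b))
  }
  list(p = p, direction = dir, test = test,
       n_a = length(a), n_b = length(b))
}

#' Hold-out robustness of a group comparison
#'
#' Reruns a buffering-score (or recurrent-CNV fraction) comparison between two
#' gene groups with each cell of a partition (chromosome or functional
#' category) removed in turn, reporting the effect direction and p-value per
#' hold-out. A hold-out that empties either group is flagged rather than
#' failed.
#'
#' @param records CNV records (`gene_id`, `n_strains_amplified`, `vg_vm`).
#' @param partition named character vector: partition cell per gene id.
#' @param groupA,groupB gene-id vectors of the two groups.
#' @param statistic `"buffering"` (rank-sum on scores) or `"cnv_fraction"`
#'   (Fisher on recurrent-CNV indicators).
#' @param minStrains recurrence cutoff for `"cnv_fraction"`.
#' @return data.frame with one row per partition cell: `holdout`, `n_a`,
#'   `n_b`, `direction`, `p`, `flagged`.
#' @export
holdoutRobustness <- function(records, partition, groupA, groupB,
                              statistic = c("buffering", "cnv_fraction"),
                              minStrains = 3) {
  statistic <- match.arg(statistic)
  stopIfNot(!is.null(names(partition)), "partition must be named by gene id")
  cells <- sort(unique(partition))
  rows <- lapply(cells, function(cell) {
    drop <- names(partition)[partition == cell]
    keep <- records[!records$gene_id %in% drop, ]
    gA <- setdiff(groupA, drop); gB <- setdiff(groupB, drop)
    if (statistic == "buffering") {
      a <- bufferingScores(keep, gA); b <- bufferingScores(keep, gB)
    } else {
      a <- keep$n_strains_amplified[keep$gene_id %in% gA] >= minStrains
      b <- keep$n_strains_amplified[keep$gene_id %in% gB] >= minStrains
    }
    if (length(a) < 2 || length(b) < 2) {
      return(data.frame(holdout = cell, n_a = length(a), n_b = length(b),
                        direction = NA_real_, p = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    cmp <- compareGroups(a, b,
                         test = if (statistic == "buffering") "rank_sum" else "fisher")
    data.frame(holdout = cell, n_a = cmp$n_a, n_b = cmp$n_b,
               direction = cmp$direction, p = cmp$p, flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
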