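#' Read count, sample-sheet and annotation TSVs into an AneuploidyCountSet
#'
#' The count file is a TSV with a header row, first column `gene_id`, remaining
#' columns one per sample. The sample sheet declares those samples (columns
#' `sample`, `strain`, `molecule`, `replicate`, optional `ploidy_label`,
#' `spike_total`, `cells_counted`). The annotation file has columns `gene_id`,
#' `chromosome`, `length_bp`, and optional comma-separated `amplified_in` and
#' `categories`. Genes missing from the annotation are rejected; negative,
#' non-integer or duplicated entries raise input errors.
#'
#' @param countsPath,samplesPath,annotationPath file paths.
#' @return An [AneuploidyCountSet].
#' @seealso [writeCounts()] for the inverse.
#' @export
readCounts <- function(countsPath, samplesPath, annotationPath) {
  raw <- read.delim(countsPath, check.names = FALSE, stringsAsFactors = FALSE)
  stopIfNot(ncol(raw) >= 2, "count table needs gene_id plus >=1 sample column")
  stopIfNot(colnames(raw)[1] == "gene_id", "first column must be 'gene_id'")
  ids <- as.character(raw[[1]])
  stopIfNot(!anyDuplicated(ids), "duplicate gene_id in count table")
  cts <- as.matrix(raw[, -1, drop = FALSE])
  stopIfNot(is.numeric(cts), "counts must be numeric")
  stopIfNot(!any(is.na(cts)) && all(cts >= 0), "counts must be non-negative")
  stopIfNot(all(abs(cts - round(cts)) < 1e-8), "counts must be integers")
  rownames(cts) <- ids

  samples <- read.delim(samplesPath, stringsAsFactors = FALSE)
  stopIfNot("sample" %in% colnames(samples), "sample sheet needs a 'sample' column")
  rownames(samples) <- samples$sample
  samples$sample <- NULL
  stopIfNot(all(colnames(cts) %in% rownames(samples)),
            "count columns missing from sample sheet")

  ann <- read.delim(annotationPath, stringsAsFactors = FALSE)
  stopIfNot(all(c("gene_id", "chromosome", "length_bp") %in% colnames(ann)),
            "annotation needs gene_id, chromosome, length_bp")
  rownames(ann) <- ann$gene_id
  AneuploidyCountSet(cts, samples[colnames(cts), , drop = FALSE], ann)
}

#' Write an AneuploidyCountSet back to counts/samples/annotation TSVs
#'
#' @param x an [AneuploidyCountSet].
#' @param countsPath,samplesPath,annotationPath output file paths.
#' @return Invisibly, the three paths.
#' @export
writeCounts <- function(x, countsPath, samplesPath, annotationPath) {
  cts <- data.frame(gene_id = rownames(x), countMatrix(x), check.names = FALSE)
  write.table(cts, countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sampleInfo(x), samplesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(geneInfo(x), annotationPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(countsPath, samplesPath, annotationPath))
}

#' Read a gene-category map in GMT format
#'
#' One category per line: name, description, then member genes, tab-separated.
#' A description containing the token `#localization` marks the category as
#' localization-based (skipped by [enrichCategories()] when
#' `excludeLocalization = TRUE`).
#'
#' @param path GMT file path.
#' @return Named list of gene-id character vectors with attributes
#'   `description` and `localization` (named logical).
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, function(f) if (length(f) >= 2) f[[2]] else "", character(1))
  genes <- lapply(fields, function(f) if (length(f) > 2) f[-(1:2)] else character(0))
  names(genes) <- nms
  attr(genes, "description") <- setNames(desc, nms)
  attr(genes, "localization") <- setNames(grepl("#localization", desc, fixed = TRUE), nms)
  genes
}

#' Write a gene-category map in GMT format
#' @param categories named list of gene-id vectors; an optional `localization`
#'   attribute (named logical) is encoded as a `#localization` token in the
#'   description field.
#' @param path output path.
#' @export
writeGMT <- function(categories, path) {
  loc <- attr(categories, "localization")
  desc <- attr(categories, "description")
  lines <- vapply(names(categories), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else ""
    if (!is.null(loc) && isTRUE(loc[[nm]]) && !grepl("#localization", d, fixed = TRUE))
      d <- trimws(paste(d, "#localization"))
    paste(c(nm, d, categories[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a log2 ratio table as TSV
#'
#' Columns: `gene_id`, `comparison_id`, `replicate`, `molecule`, `log2_ratio`.
#' The comparison metadata (test/reference strain per comparison) is written to
#' a companion file `<path>.comparisons` and restored on read when present.
#'
#' @param rt ratio table as produced by [log2Ratios()].
#' @param path TSV path.
#' @return `writeRatioTable` the path, invisibly; `readRatioTable` the table.
#' @export
writeRatioTable <- function(rt, path) {
  write.table(rt[, c("gene_id", "comparison_id", "replicate", "molecule", "log2_ratio")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  cmp <- attr(rt, "comparisons")
  if (!is.null(cmp))
    write.table(cmp, paste0(path, ".comparisons"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRatioTable
#' @export
readRatioTable <- function(path) {
  rt <- read.delim(path, stringsAsFactors = FALSE)
  cmpPath <- paste0(path, ".comparisons")
  if (file.exists(cmpPath))
    attr(rt, "comparisons") <- read.delim(cmpPath, stringsAsFactors = FALSE)
  rt
}

#' Import an externally produced differential-expression table
#'
#' Accepts a TSV with columns `gene_id`, `log2fc`, `pvalue`, `fdr` (for example
#' exported from a count-based DE package), for use as the unamplified-gene DE
#' input of the indirect-response filter.
#'
#' @param path TSV path.
#' @return data.frame with the four columns above.
#' @export
importDETable <- function(path) {
  de <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "pvalue", "fdr")
  stopIfNot(all(need %in% colnames(de)),
            "DE table needs columns: ", paste(need, collapse = ", "))
  de[, need]
}
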