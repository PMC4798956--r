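#' Construct an AneuploidyCountSet
#'
#' @param counts integer matrix of read counts, genes x samples, with gene ids
#'   as rownames and sample names as colnames.
#' @param sampleData data.frame (or DataFrame) with one row per sample:
#'   columns `strain`, `molecule` ("RNA"/"DNA"), `replicate`, and optionally
#'   `ploidy_label`, `spike_total`, `cells_counted`.
#' @param geneData data.frame with one row per gene: columns `chromosome`,
#'   `length_bp`, and optionally `amplified_in` (comma-separated strain names)
#'   and `categories` (comma-separated category names). A `gene_id` column, if
#'   present, must match the count matrix rownames.
#' @return A validated [AneuploidyCountSet].
#' @examples
#' cts <- matrix(c(10L, 0L, 7L, 20L, 5L, 7L), nrow = 3,
#'               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' sm <- data.frame(strain = c("A", "A"), molecule = c("RNA", "DNA"),
#'                  replicate = c(1, 1), row.names = c("s1", "s2"))
#' gn <- data.frame(chromosome = "chr1", length_bp = c(1000, 2000, 1500),
#'                  row.names = paste0("g", 1:3))
#' acs <- AneuploidyCountSet(cts, sm, gn)
#' @export
AneuploidyCountSet <- function(counts, sampleData, geneData) {
  counts <- as.matrix(counts)
  stopIfNot(!is.null(rownames(counts)), "counts needs gene ids as rownames")
  stopIfNot(!is.null(colnames(counts)), "counts needs sample names as colnames")
  sampleData <- as.data.frame(sampleData)
  geneData <- as.data.frame(geneData)
  if ("sample" %in% colnames(sampleData) && is.null(rownames(sampleData)))
    rownames(sampleData) <- sampleData$sample
  if (!is.null(rownames(sampleData)) &&
      !identical(rownames(sampleData), colnames(counts))) {
    stopIfNot(all(colnames(counts) %in% rownames(sampleData)),
              "every count column needs a row in sampleData")
    sampleData <- sampleData[colnames(counts), , drop = FALSE]
  }
  if ("gene_id" %in% colnames(geneData) && is.null(rownames(geneData)))
    rownames(geneData) <- geneData$gene_id
  if (!is.null(rownames(geneData)) &&
      !identical(rownames(geneData), rownames(counts))) {
    missing <- setdiff(rownames(counts), rownames(geneData))
    stopIfNot(length(missing) == 0,
              "genes absent from annotation: ", paste(head(missing, 5), collapse = ", "))
    geneData <- geneData[rownames(counts), , drop = FALSE]
  }
  geneData$gene_id <- NULL
  if (!"ploidy_label" %in% colnames(sampleData)) sampleData$ploidy_label <- NA_character_
  if (!"amplified_in" %in% colnames(geneData)) geneData$amplified_in <- ""
  if (!"categories" %in% colnames(geneData)) geneData$categories <- ""
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = DataFrame(sampleData),
                             rowData = DataFrame(geneData))
  new("AneuploidyCountSet", se)
}

#' @rdname AneuploidyCountSet
#' @export
setMethod("sampleInfo", "AneuploidyCountSet", function(x) {
  df <- as.data.frame(colData(x))
  df$sample <- colnames(x)
  df[, c("sample", setdiff(colnames(df), "sample"))]
})

#' @rdname AneuploidyCountSet
#' @export
setMethod("geneInfo", "AneuploidyCountSet", function(x) {
  df <- as.data.frame(rowData(x))
  df$gene_id <- rownames(x)
  df[, c("gene_id", setdiff(colnames(df), "gene_id"))]
})

#' Extract the raw count matrix
#' @param x an `AneuploidyCountSet`.
#' @return integer matrix, genes x samples.
#' @export
countMatrix <- function(x) assay(x, "counts")

setMethod("show", "AneuploidyCountSet", function(object) {
  cd <- colData(object)
  cat("AneuploidyCountSet:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  strains:", paste(unique(cd$strain), collapse = ", "), "\n")
  cat("  RNA samples:", sum(cd$molecule == "RNA"),
      "| DNA samples:", sum(cd$molecule == "DNA"), "\n")
  nAmp <- sum(vapply(splitCommaField(rowData(object)$amplified_in),
                     length, integer(1)) > 0)
  cat("  genes amplified in >=1 strain:", nAmp, "\n")
  invisible(NULL)
})

# genes amplified in a given strain (by annotation)
amplifiedGenes <- function(geneData, strain) {
  amp <- splitCommaField(geneData$amplified_in)
  geneData$gene_id[vapply(amp, function(v) strain %in% v, logical(1))]
}
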