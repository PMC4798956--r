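#' @rdname AneuploidyCountSet
#' @param x,object an `AneuploidyCountSet` (or other class as documented).
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname AneuploidyCountSet
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))

#' Estimate the false discovery rate of threshold calls by label permutation
#'
#' Each iteration independently permutes every replicate column of the
#' difference matrix `d = log2 mRNA ratio - gene threshold` over genes and
#' counts genes whose permuted values are negative in all columns. The FDR
#' estimate is the mean null call count divided by the observed call count.
#'
#' @param x a [ThresholdCallSet] or a numeric genes x replicate-columns matrix
#'   of d values.
#' @param nIter number of permutation iterations (10000 default).
#' @param seed integer seed for reproducibility; `NULL` uses the current RNG.
#' @param ... passed to methods.
#' @return For a matrix: a list with `nullCounts`, `meanNull`. For a
#'   `ThresholdCallSet`: the object with `fdrEstimate` and `nullCounts` filled
#'   in (FDR is `NA` with a warning when no gene was called).
#' @export
setGeneric("permutationFDR",
           function(x, nIter = 10000, seed = NULL, ...)
             standardGeneric("permutationFDR"))

#' @rdname MLRFit-accessors
#' @export
setGeneric("classLabels", function(object, ...) standardGeneric("classLabels"))

#' @rdname MLRFit-accessors
#' @export
setGeneric("posteriors", function(object) standardGeneric("posteriors"))

#' @rdname MLRFit-accessors
#' @export
setGeneric("mixingProportions", function(object) standardGeneric("mixingProportions"))

#' @rdname MLRFit-accessors
#' @export
setGeneric("conditionalFDR",
           function(object, classLabel, ...) standardGeneric("conditionalFDR"))

#' @rdname ThresholdCallSet-accessors
#' @param object a `ThresholdCallSet`.
#' @export
setGeneric("calledGenes", function(object, ...) standardGeneric("calledGenes"))

#' @rdname ThresholdCallSet-accessors
#' @export
setGeneric("fdrEstimate", function(object) standardGeneric("fdrEstimate"))
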