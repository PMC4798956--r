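# Independent per-gene likelihood-ratio check of proportional dosage response.

#' Per-gene likelihood-ratio test of proportional expression
#'
#' For each gene, compares the null model `y = x` (intercept 0, slope 1: mRNA
#' rises proportionally with DNA) against an unrestricted per-gene ordinary
#' least-squares line. With `RSS0 = sum((y - x)^2)` and `RSS1` the OLS residual
#' sum of squares, the statistic is `lambda = (n - 2) * ln(RSS0 / RSS1)` and is
#' referred to the upper tail of a chi-squared distribution on 2 degrees of
#' freedom. The residual-df multiplier (rather than `n`) is a Bartlett-type
#' small-sample correction that keeps the chi-squared reference accurate for
#' the handful of points available per gene (see the methods vignette). A
#' variance floor is applied to both RSS terms; when both sit at the floor
#' (perfect proportional fit) the statistic is 0 and p = 1. Genes with fewer
#' than `minPoints` points or a single distinct x are skipped with a warning.
#'
#' @param dp dosage points from [dosagePoints()].
#' @param varFloor floor applied to both RSS terms (default 1e-12).
#' @param minPoints minimum points per gene (default 3).
#' @param pi0Lambda,pi0Method passed to [estimatePi0()] for the q-value and
#'   null-proportion computation.
#' @return An [LRTResult].
#' @export
lrtProportionality <- function(dp, varFloor = 1e-12, minPoints = 3,
                               pi0Lambda = 0.5, pi0Method = "plugin") {
  f <- factor(dp$gene_id)
  n <- as.numeric(tapply(dp$y, f, length))
  sx <- as.numeric(tapply(dp$x, f, sum))
  sy <- as.numeric(tapply(dp$y, f, sum))
  sxx <- as.numeric(tapply(dp$x^2, f, sum))
  syy <- as.numeric(tapply(dp$y^2, f, sum))
  sxy <- as.numeric(tapply(dp$x * dp$y, f, sum))
  genes <- levels(f)
  cxx <- sxx - sx^2 / n
  cxy <- sxy - sx * sy / n
  cyy <- syy - sy^2 / n
  usable <- n >= minPoints & cxx > 1e-10
  if (any(!usable))
    warning(sum(!usable), " gene(s) skipped: too few points or degenerate x",
            call. = FALSE)
  rss1 <- pmax(cyy - cxy^2 / pmax(cxx, 1e-300), varFloor)
  rss0 <- pmax(syy - 2 * sxy + sxx, varFloor)
  lambda <- ifelse(rss0 <= varFloor & rss1 <= varFloor, 0,
                   pmax(n - 2, 1) * log(rss0 / rss1))
  lambda <- pmax(lambda, 0)  # null is nested: RSS0 >= RSS1 up to rounding
  p <- pchisq(lambda, df = 2, lower.tail = FALSE)
  res <- data.frame(gene_id = genes, n = n, lambda = lambda, p = p,
                    stringsAsFactors = FALSE)[usable, ]
  rownames(res) <- NULL
  pi0est <- estimatePi0(res$p, lambda = pi0Lambda, method = pi0Method)
  res$q <- pi0est$qvalues
  new("LRTResult", results = res, pi0 = pi0est$pi0,
      pi0Method = pi0est$method, skipped = genes[!usable])
}

#' Storey-style null-proportion estimate and q-values
#'
#' `pi0(lambda) = #\{p > lambda\} / (G * (1 - lambda))`, clipped to `[0, 1]`.
#' The default is the plug-in estimate at `lambda = 0.5`; `method = "smoother"`
#' fits a cubic smoothing spline to `pi0(lambda)` over
#' `lambda = 0.05, ..., 0.95` and takes its value at the largest lambda.
#' q-values are the `pi0`-scaled step-up transform of the p-values:
#' `q_(i) = min_{j >= i} pi0 * G * p_(j) / j`, capped at 1.
#'
#' @param p p-values in `[0, 1]`.
#' @param lambda tuning parameter of the plug-in estimator.
#' @param method `"plugin"` or `"smoother"`.
#' @return List with `pi0`, `qvalues` (in the order of `p`), `method`.
#' @export
estimatePi0 <- function(p, lambda = 0.5, method = c("plugin", "smoother")) {
  method <- match.arg(method)
  stopIfNot(length(p) > 0, "empty p-value vector")
  stopIfNot(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  G <- length(p)
  if (method == "plugin") {
    pi0 <- sum(p > lambda) / (G * (1 - lambda))
  } else {
    grid <- seq(0.05, 0.95, by = 0.05)
    pi0grid <- vapply(grid, function(l) sum(p > l) / (G * (1 - l)), numeric(1))
    fit <- smooth.spline(grid, pi0grid, df = 3)
    pi0 <- predict(fit, x = max(grid))$y
  }
  pi0 <- min(max(pi0, 0), 1)
  o <- order(p)
  q <- pi0 * G * p[o] / seq_len(G)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  qvalues <- numeric(G)
  qvalues[o] <- q
  list(pi0 = pi0, qvalues = qvalues, method = method)
}

#' Compare the MLR and likelihood-ratio views of the null proportion
#'
#' Reports, on the same gene set and among genes showing a linear mRNA-vs-DNA
#' relationship (the mixture's outlier component, when present, is excluded
#' from both sides), (i) the proportion of genes the mixture model classifies
#' away from the proportional class and (ii) `1 - pi0` re-estimated from the
#' likelihood-ratio p-values of those linearly behaving genes, plus their
#' absolute difference. The two conventions answer the same question — what
#' fraction of genes deviates from proportional dosage response — from
#' independent machinery, so close agreement is a cross-method check.
#'
#' @param fit an [MLRFit].
#' @param lrt an [LRTResult] computed on the same genes.
#' @return List with `mlr_nonproportional`, `lrt_nonnull`, `difference`,
#'   `n_genes` (linear genes used).
#' @export
compareNullProportions <- function(fit, lrt) {
  mlrGenes <- sort(names(fit@classes))
  lrtGenes <- sort(lrt@results$gene_id)
  stopIfNot(identical(mlrGenes, lrtGenes),
            "MLR and LRT results cover different gene sets")
  cls <- fit@classes
  linear <- names(cls)[cls != "nonlinear_outlier"]
  mlrNonProp <- mean(cls[linear] != "class1_proportional")
  pLinear <- lrt@results$p[lrt@results$gene_id %in% linear]
  pi0 <- estimatePi0(pLinear, method = lrt@pi0Method)$pi0
  lrtNonNull <- 1 - pi0
  list(mlr_nonproportional = mlrNonProp,
       lrt_nonnull = lrtNonNull,
       difference = abs(mlrNonProp - lrtNonNull),
       n_genes = length(linear))
}

#' @rdname LRTResult-accessors
#' @param object an `LRTResult`.
#' @export
lrtResults <- function(object) object@results

#' Accessors for LRTResult objects
#' @param object an [LRTResult].
#' @return `lrtResults`: the per-gene statistics table; `pi0Estimate`: the
#'   estimated null proportion.
#' @name LRTResult-accessors
NULL

#' @rdname LRTResult-accessors
#' @export
pi0Estimate <- function(object) object@pi0

setMethod("show", "LRTResult", function(object) {
  r <- object@results
  cat("LRTResult:", nrow(r), "genes tested,",
      length(object@skipped), "skipped\n")
  cat("  pi0 (", object@pi0Method, "):", sprintf("%.3f", object@pi0), "\n")
  cat("  genes with q < 0.05:", sum(r$q < 0.05), "\n")
  invisible(NULL)
})
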