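# Mixture-of-linear-regressions dosage-response model, fit by EM.

#' Per-gene dosage-response points from a panel ratio table
#'
#' For every panel comparison, pairs each gene's x = mean log2 DNA ratio
#' (DNA replicates averaged per strain) with every replicate log2 mRNA ratio
#' y of that comparison, keeping the replicate structure. Genes with fewer
#' than two distinct x values are dropped with a warning (a single copy state
#' cannot constrain a slope).
#'
#' @param rt ratio table from [log2Ratios()] over a copy-number panel.
#' @param geneData gene annotation.
#' @param genes genes to include; default: genes amplified in every test
#'   strain of the panel.
#' @param minPoints minimum usable points per gene (default 3, the smallest
#'   number that also supports the per-gene likelihood-ratio test, so mixture
#'   and LRT results cover the same genes).
#' @return data.frame with `gene_id`, `comparison_id`, `x`, `y`.
#' @export
dosagePoints <- function(rt, geneData, genes = NULL, minPoints = 3) {
  comparisons <- attr(rt, "comparisons")$comparison_id
  stopIfNot(length(comparisons) >= 2,
            "dosage points need >=2 comparisons (copy states)")
  if (is.null(genes)) {
    genes <- Reduce(intersect, lapply(comparisons, function(cmp)
      amplifiedGenes(geneData, .testStrainOf(rt, cmp))))
  }
  pts <- list()
  for (cmp in comparisons) {
    dna <- .dnaRatioPerGene(rt, cmp, genes)
    rna <- rt[rt$molecule == "RNA" & rt$comparison_id == cmp &
                rt$gene_id %in% names(dna), ]
    pts[[cmp]] <- data.frame(gene_id = rna$gene_id, comparison_id = cmp,
                             x = unname(dna[rna$gene_id]), y = rna$log2_ratio,
                             stringsAsFactors = FALSE)
  }
  dp <- do.call(rbind, pts)
  rownames(dp) <- NULL
  # x must actually spread: the same tolerance the per-gene LRT applies
  cxx <- tapply(dp$x, dp$gene_id, function(v) sum((v - mean(v))^2))
  np <- tapply(dp$x, dp$gene_id, length)
  bad <- union(names(cxx)[cxx <= 1e-10], names(np)[np < minPoints])
  if (length(bad)) {
    warning(length(bad), " gene(s) dropped: degenerate x values ",
            "or fewer than ", minPoints, " points", call. = FALSE)
    dp <- dp[!dp$gene_id %in% bad, ]
  }
  stopIfNot(all(is.finite(dp$x)) && all(is.finite(dp$y)),
            "dosage points must be finite")
  dp
}

#' Default mixture components of the dosage-response model
#'
#' Four labeled regression lines through the origin — proportional (slope
#' fixed at 1), flat/compensated (slope 0), shared sub-proportional slope free
#' in (0, 1), shared super-proportional slope free above 1 — plus an optional
#' outlier component with free intercept and slope and inflated variance that
#' absorbs genes without a linear mRNA-vs-DNA relationship, so the labeled
#' classes are estimated among linearly behaving genes.
#'
#' @param outlier include the outlier component (default TRUE).
#' @param delta identifiability margin: free slopes are projected into
#'   `(delta, 1 - delta)` and `(1 + delta, Inf)`. The margin must be
#'   comparable to the per-gene slope resolution (roughly
#'   `sigma / sqrt(sum(x^2))`, about 0.1 at typical panel noise), otherwise a
#'   free slope can park at its boundary next to a fixed component and absorb
#'   proportional genes on pure-null data.
#' @param varInflation residual-variance multiplier of the outlier component.
#' @return data.frame consumed by [fitMLR()].
#' @export
mlrComponents <- function(outlier = TRUE, delta = 0.1, varInflation = 5) {
  comp <- data.frame(
    label = c("class1_proportional", "class2_flat", "class3a_sub", "class3b_super"),
    intercept = 0,
    slope = c(1, 0, 0.5, 1.5),
    fixed_intercept = TRUE,
    fixed_slope = c(TRUE, TRUE, FALSE, FALSE),
    slope_lower = c(NA, NA, delta, 1 + delta),
    slope_upper = c(NA, NA, 1 - delta, Inf),
    var_inflation = 1,
    stringsAsFactors = FALSE)
  if (outlier) {
    comp <- rbind(comp, data.frame(
      label = "nonlinear_outlier", intercept = 0, slope = 1,
      fixed_intercept = FALSE, fixed_slope = FALSE,
      slope_lower = NA, slope_upper = NA, var_inflation = varInflation))
  }
  comp
}

# one EM run from a given start; returns list(fit pieces, loglik trace)
.emRun <- function(gidx, x, y, G, comp, pi0, maxIter, tol) {
  K <- nrow(comp)
  a <- comp$intercept; b <- comp$slope
  pi <- pi0
  sigma2 <- max(stats::var(y - x), 1e-6)
  nPts <- length(y)
  trace <- numeric(0)
  post <- NULL
  converged <- FALSE
  eStep <- function() {
    genell <- matrix(0, G, K)
    for (k in seq_len(K)) {
      v <- sigma2 * comp$var_inflation[k]
      r <- y - a[k] - b[k] * x
      lp <- -0.5 * log(2 * pi_const) - 0.5 * log(v) - r^2 / (2 * v)
      genell[, k] <- rowsum(lp, gidx, reorder = TRUE)[, 1]
    }
    logpi <- ifelse(pi > 0, log(pi), -Inf)
    lp <- sweep(genell, 2, logpi, "+")
    lse <- logsumexp(lp)
    list(ll = sum(lse), post = exp(lp - lse))
  }
  for (iter in seq_len(maxIter)) {
    # E-step: per-gene posteriors and observed-data log-likelihood
    es <- eStep()
    ll <- es$ll
    post <- es$post
    trace <- c(trace, ll)
    if (iter > 1 && abs(ll - trace[iter - 1]) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }

    # M-step
    piNew <- colMeans(post)
    frozen <- piNew < 1e-8
    if (any(frozen & pi > 0) && any(!frozen))
      piNew[frozen] <- 0
    pi <- piNew / sum(piNew)
    w <- post[gidx, , drop = FALSE]
    for (k in seq_len(K)) {
      if (pi[k] == 0) next
      if (comp$fixed_intercept[k] && !comp$fixed_slope[k]) {
        bk <- sum(w[, k] * x * y) / max(sum(w[, k] * x^2), 1e-12)
        lo <- comp$slope_lower[k]; up <- comp$slope_upper[k]
        if (!is.na(lo)) bk <- max(bk, lo)
        if (!is.na(up)) bk <- min(bk, up)
        b[k] <- bk
      } else if (!comp$fixed_intercept[k]) {
        # weighted OLS with intercept (outlier component)
        sw <- sum(w[, k])
        if (sw > 1e-10) {
          mx <- sum(w[, k] * x) / sw; my <- sum(w[, k] * y) / sw
          sxx <- sum(w[, k] * (x - mx)^2); sxy <- sum(w[, k] * (x - mx) * (y - my))
          bk <- if (sxx > 1e-12) sxy / sxx else b[k]
          b[k] <- bk; a[k] <- my - bk * mx
        }
      }
    }
    num <- 0
    for (k in seq_len(K)) {
      r <- y - a[k] - b[k] * x
      num <- num + sum(w[, k] * r^2 / comp$var_inflation[k])
    }
    sigma2 <- max(num / nPts, 1e-8)
  }
  if (!converged) {
    # sync posteriors with the final parameter state
    es <- eStep()
    post <- es$post
    trace <- c(trace, es$ll)
  }
  comp$intercept <- a; comp$slope <- b
  list(comp = comp, pi = pi, sigma2 = sigma2, post = post,
       trace = trace, converged = converged)
}

pi_const <- base::pi  # the constant; `pi` names mixing proportions here

#' Fit the mixture-of-linear-regressions dosage-response model
#'
#' EM over all replicate measurements on all genes simultaneously. The E-step
#' computes gene-level posteriors from the product of normal densities of each
#' gene's (x, y) points under every component; the M-step updates the mixing
#' proportions (posterior means), the free shared slopes (posterior-weighted
#' least squares through the origin, projected into their identifiability
#' intervals), the outlier component's free line, and the shared residual SD.
#' Multiple jittered starts keep the best log-likelihood; a component whose
#' proportion collapses is frozen at zero with a warning.
#'
#' @param dp dosage points from [dosagePoints()].
#' @param components component definition, see [mlrComponents()].
#' @param maxIter maximum EM iterations per start.
#' @param tol relative log-likelihood convergence tolerance.
#' @param nStarts number of EM starts (first start uses the components'
#'   listed slopes; later starts jitter them).
#' @param seed integer seed for the start jitter.
#' @return An [MLRFit].
#' @export
fitMLR <- function(dp, components = mlrComponents(), maxIter = 500,
                   tol = 1e-6, nStarts = 5, seed = NULL) {
  stopIfNot(nrow(components) >= 2, "need at least two components")
  genes <- sort(unique(dp$gene_id))
  gidx <- match(dp$gene_id, genes)
  G <- length(genes)
  K <- nrow(components)
  withSeed(seed, function() {
    best <- NULL
    for (s in seq_len(nStarts)) {
      comp <- components
      pi0 <- rep(1 / K, K)
      if (s > 1) {
        free <- !comp$fixed_slope & comp$fixed_intercept
        for (k in which(free)) {
          lo <- comp$slope_lower[k]; up <- comp$slope_upper[k]
          comp$slope[k] <- runif(1, max(lo, 0.05),
                                 min(ifelse(is.finite(up), up, 2.5), 2.5))
        }
        pi0 <- runif(K, 0.5, 1.5); pi0 <- pi0 / sum(pi0)
      }
      run <- .emRun(gidx, dp$x, dp$y, G, comp, pi0, maxIter, tol)
      if (is.null(best) || max(run$trace) > max(best$trace)) best <- run
    }
    if (!best$converged)
      warning("EM did not converge in ", maxIter,
              " iterations; returning best fit", call. = FALSE)
    if (any(best$pi == 0))
      warning("component(s) frozen at zero mixing proportion: ",
              paste(best$comp$label[best$pi == 0], collapse = ", "),
              call. = FALSE)
    post <- best$post
    dimnames(post) <- list(genes, best$comp$label)
    amax <- max.col(post, ties.method = "first")
    # count exact ties (broken toward the lower-index component)
    ties <- sum(apply(post, 1L, function(p) sum(p == max(p)) > 1))
    classes <- setNames(best$comp$label[amax], genes)
    new("MLRFit", components = best$comp,
        pi = setNames(best$pi, best$comp$label),
        sigma = sqrt(best$sigma2), posteriors = post, classes = classes,
        loglik = best$trace, converged = best$converged, nTies = as.integer(ties))
  })
}

#' @describeIn MLRFit-accessors per-gene maximum-posterior class labels; exact
#'   ties go to the lower-index component (`nTies` counts them).
#' @export
setMethod("classLabels", "MLRFit", function(object, ...) object@classes)

#' Accessors for MLRFit objects
#'
#' @param object an [MLRFit].
#' @param classLabel a component label, e.g. `"class3a_sub"`.
#' @param ... unused.
#' @name MLRFit-accessors
NULL

#' @describeIn MLRFit-accessors genes x components posterior matrix.
#' @export
setMethod("posteriors", "MLRFit", function(object) object@posteriors)

#' @describeIn MLRFit-accessors named mixing proportions.
#' @export
setMethod("mixingProportions", "MLRFit", function(object) object@pi)

#' @describeIn MLRFit-accessors conditional FDR of a called class: the mean,
#'   over genes called to `classLabel`, of one minus the posterior probability
#'   of that class. `NA` with a warning when no gene is called to the class.
#' @export
setMethod("conditionalFDR", "MLRFit", function(object, classLabel, ...) {
  stopIfNot(classLabel %in% colnames(object@posteriors),
            "unknown class label: ", classLabel)
  called <- object@classes == classLabel
  if (!any(called)) {
    warning("no gene called to ", classLabel, ": conditional FDR undefined",
            call. = FALSE)
    return(NA_real_)
  }
  mean(1 - object@posteriors[called, classLabel])
})

setMethod("show", "MLRFit", function(object) {
  cat("MLRFit:", nrow(object@posteriors), "genes,",
      nrow(object@components), "components\n")
  tab <- data.frame(label = object@components$label,
                    slope = round(object@components$slope, 3),
                    intercept = round(object@components$intercept, 3),
                    pi = round(object@pi, 3),
                    n_called = as.integer(table(factor(object@classes,
                      levels = object@components$label))))
  print(tab, row.names = FALSE)
  cat("  sigma:", round(object@sigma, 4),
      "| log-likelihood:", round(max(object@loglik), 2),
      "| converged:", object@converged, "\n")
  invisible(NULL)
})
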