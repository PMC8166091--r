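## Per-gene differential-expression classification and cross-experiment
## intersection: a two-sided pooled-variance Student t-test of test vs
## control per gene, an inclusive significance threshold, and set
## intersection of same-direction calls between two experiments. With
## the design's 2 replicates per group the test has 2 degrees of
## freedom; no variance moderation and no multiple-testing correction is
## applied (classification is on raw p-values), though BH-adjusted
## values can be emitted for information.

.groupMatrices <- function(se) {
  stopifnot(is(se, "SummarizedExperiment"))
  grp <- SummarizedExperiment::colData(se)$group
  if (is.null(grp)) stop("colData(se)$group missing")
  m <- SummarizedExperiment::assay(se)
  list(test = m[, grp == "test", drop = FALSE],
       ctrl = m[, grp == "control", drop = FALSE])
}

#' Two-sample Student t-test for one gene
#'
#' Two-sided pooled-variance t-test of the gene's test values against its
#' control values; direction is the sign of `mean(test) - mean(control)`
#' (`"flat"` only when the means are exactly equal). Zero pooled
#' variance with equal means gives `t = 0, p = 1`; with unequal means,
#' `p = 0` and a degenerate flag.
#'
#' @param se a `SummarizedExperiment` from [readExpression()].
#' @param geneId gene to test.
#' @return a list with `gene_id`, `t`, `df`, `p`, `direction`,
#'   `degenerate`.
#' @export
geneTtest <- function(se, geneId) {
  gm <- .groupMatrices(se)
  if (!geneId %in% rownames(gm$test))
    stop("gene not in expression matrix: ", geneId)
  r <- .pooledTVec(gm$test[geneId, ], gm$ctrl[geneId, ])
  d <- r$mean1 - r$mean2
  list(gene_id = geneId, t = r$t, df = r$df, p = r$p,
       direction = if (d > 0) "up" else if (d < 0) "down" else "flat",
       degenerate = r$degenerate)
}

#' Classify genes as Up / Dn / Nu for one experiment
#'
#' Applies the per-gene t-test to every gene and calls a gene Up when
#' `p <= alpha` with test mean above control, Dn when `p <= alpha` with
#' test mean below control, and Nu otherwise (threshold inclusive). The
#' three calls partition the gene universe.
#'
#' @param se a `SummarizedExperiment` from [readExpression()].
#' @param alpha significance threshold, default 0.05.
#' @param experimentId label stored with the result.
#' @param adjust also compute Benjamini-Hochberg adjusted p-values in a
#'   `p_adj` column (informational only; calls always use raw p).
#' @return a [GeneClassification].
#' @export
classifyGenes <- function(se, alpha = 0.05, experimentId = "exp",
                          adjust = FALSE) {
  stopifnot(alpha > 0, alpha <= 1)
  gm <- .groupMatrices(se)
  r <- .pooledT(gm$test, gm$ctrl)
  delta <- r$mean1 - r$mean2
  direction <- ifelse(delta > 0, "up", ifelse(delta < 0, "down", "flat"))
  call <- ifelse(r$p <= alpha & direction == "up", "Up",
          ifelse(r$p <= alpha & direction == "down", "Dn", "Nu"))
  res <- data.frame(gene_id = rownames(gm$test), t = r$t,
                    df = rep(r$df, length(r$t)), p = r$p,
                    direction = direction, call = call,
                    stringsAsFactors = FALSE)
  if (any(r$degenerate))
    message(sum(r$degenerate),
            " gene(s) with zero pooled variance and unequal means (p = 0)")
  if (adjust) res$p_adj <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  new("GeneClassification", experimentId = experimentId,
      alpha = alpha, results = res)
}

#' Intersect same-direction calls between two experiments
#'
#' Returns the genes called `direction` in both classifications over the
#' shared gene universe; genes present in only one experiment are
#' dropped with a warning. Optionally attaches a hypergeometric
#' upper-tail p-value for the overlap size given the universe (an
#' extension beyond the original intersection procedure, which reports
#' no overlap statistic).
#'
#' @param cls1,cls2 [GeneClassification] objects.
#' @param direction `"Dn"` or `"Up"`.
#' @param overlapTest compute the hypergeometric overlap p-value.
#' @return an [IntersectionResult].
#' @export
intersectCalls <- function(cls1, cls2, direction = c("Dn", "Up"),
                           overlapTest = TRUE) {
  direction <- match.arg(direction)
  stopifnot(is(cls1, "GeneClassification"), is(cls2, "GeneClassification"))
  c1 <- classCalls(cls1); c2 <- classCalls(cls2)
  universe <- intersect(names(c1), names(c2))
  if (length(universe) == 0L)
    stop("empty shared gene universe between the two experiments")
  dropped <- length(c1) + length(c2) - 2L * length(universe)
  if (dropped > 0L)
    warning(dropped, " gene occurrence(s) outside the shared universe dropped")
  s1 <- names(c1)[c1 == direction & names(c1) %in% universe]
  s2 <- names(c2)[c2 == direction & names(c2) %in% universe]
  genes <- intersect(s1, s2)
  k <- length(genes); n1 <- length(s1); n2 <- length(s2)
  N <- length(universe)
  p <- if (overlapTest && n1 > 0L && n2 > 0L)
    stats::phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE) else NA_real_
  new("IntersectionResult", direction = direction, genes = genes,
      counts = c(n1 = n1, n2 = n2, overlap = k, universe = N),
      pValue = p)
}

#' Filter an intersection by per-experiment p-value
#'
#' Keeps the intersection genes whose classification p-values are
#' `<= pCut` in BOTH experiments (the rule behind "overlapping genes
#' filtered with a P-value <= cut").
#'
#' @param result an [IntersectionResult].
#' @param cls1,cls2 the classifications the intersection came from.
#' @param pCut p-value cut, must not exceed either classification alpha.
#' @return character vector of gene ids.
#' @export
filterByPvalue <- function(result, cls1, cls2, pCut) {
  stopifnot(is(result, "IntersectionResult"))
  if (pCut > alphaLevel(cls1) || pCut > alphaLevel(cls2))
    stop("pCut must be <= the classification alpha")
  g <- intersectGenes(result)
  if (length(g) == 0L) return(character(0))
  p1 <- setNames(testResults(cls1)$p, testResults(cls1)$gene_id)[g]
  p2 <- setNames(testResults(cls2)$p, testResults(cls2)$gene_id)[g]
  g[p1 <= pCut & p2 <= pCut]
}
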