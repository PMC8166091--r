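#' @import methods
#' @importFrom GenomicRanges GRanges seqnames strand start end width
#'   findOverlaps pintersect
#' @importFrom GenomeInfoDb seqlengths seqinfo Seqinfo seqlevels
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols queryHits subjectHits DataFrame
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   alphabetFrequency reverseComplement
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom stats pt rnorm rpois runif phyper setNames sd t.test
#'   p.adjust
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom tools md5sum
NULL

#' RepeatIndex: genome-wide set of perfect homopolymer runs
#'
#' Container for the maximal ("intact") single-base runs found on a genome,
#' after filtering to a length window, together with the scan parameters
#' that produced them. Runs are held as a [GenomicRanges::GRanges] with a
#' `base` metadata column, sorted by chromosome and start; `seqinfo`
#' carries chromosome lengths so downstream windowing can clip at
#' chromosome ends.
#'
#' @slot runs `GRanges` of runs; `mcols(runs)$base` is "A" or "T", run
#'   length is `width(runs)`.
#' @slot params named `list` with `minLen`, `maxLen`, `bases`.
#'
#' @seealso [scanGenome()], [repeatRuns()], [writeRepeatsBed()]
#' @exportClass RepeatIndex
setClass("RepeatIndex",
  representation(runs = "GRanges", params = "list"))

setValidity("RepeatIndex", function(object) {
  msg <- character()
  p <- object@params
  if (!all(c("minLen", "maxLen", "bases") %in% names(p)))
    msg <- c(msg, "params must contain minLen, maxLen, bases")
  if (length(object@runs)) {
    b <- S4Vectors::mcols(object@runs)$base
    if (is.null(b) || !all(b %in% c("A", "T", "C", "G")))
      msg <- c(msg, "runs must carry a 'base' metadata column in A/C/G/T")
    if (!.isGroupedSorted(as.character(GenomicRanges::seqnames(object@runs)),
                          GenomicRanges::start(object@runs)))
      msg <- c(msg, "runs must be grouped by chromosome and sorted by start")
    if (!is.null(p$minLen) &&
        any(GenomicRanges::width(object@runs) < p$minLen |
            GenomicRanges::width(object@runs) > p$maxLen))
      msg <- c(msg, "run lengths outside [minLen, maxLen]")
  }
  if (length(msg)) msg else TRUE
})

#' BinProfileSet: per-gene binned repeat base pairs around the TSS
#'
#' Holds, for a cohort of genes sharing one window geometry, the repeat
#' base pairs assigned to each TSS-anchored bin (`binBp`) and the genomic
#' base pairs each bin actually covers after chromosome-boundary clipping
#' (`coveredBp`). Bins are indexed 1..nBins in transcription direction;
#' with the defaults (10 kb upstream, 10 kb downstream, 100 bp bins) there
#' are 200 bins and bins 1-100 lie upstream of the TSS.
#'
#' @slot binBp numeric matrix, genes x bins, repeat bp per bin.
#' @slot coveredBp numeric matrix, genes x bins, covered bp per bin
#'   (`<= binWidth`).
#' @slot base requested base label ("A" or "T"); under `strandMode`
#'   "sense" this is the base on the gene's sense strand.
#' @slot strandMode "sense" or "reference".
#' @slot upstream,downstream,binWidth window geometry in bp.
#' @slot genes data.frame of the profiled genes (gene_id, chrom, strand,
#'   tss), rows aligned with the matrices.
#'
#' @seealso [binProfiles()], [geneWindowDensity()], [groupDensityProfile()]
#' @exportClass BinProfileSet
setClass("BinProfileSet",
  representation(binBp = "matrix", coveredBp = "matrix", base = "character",
    strandMode = "character", upstream = "numeric", downstream = "numeric",
    binWidth = "numeric", genes = "data.frame"))

setValidity("BinProfileSet", function(object) {
  msg <- character()
  if (!identical(dim(object@binBp), dim(object@coveredBp)))
    msg <- c(msg, "binBp and coveredBp dimensions differ")
  if (nrow(object@binBp) != nrow(object@genes))
    msg <- c(msg, "matrix rows must match gene table rows")
  if (any(object@binBp < 0) || any(object@coveredBp < 0))
    msg <- c(msg, "negative entries")
  if (any(object@binBp > object@coveredBp + 1e-9))
    msg <- c(msg, "binBp exceeds coveredBp")
  nb <- (object@upstream + object@downstream) / object@binWidth
  if (ncol(object@binBp) != nb)
    msg <- c(msg, "number of bins inconsistent with window geometry")
  if (length(msg)) msg else TRUE
})

#' DensityProfile: pooled per-bin repeat density for a gene group
#'
#' @slot label group label (e.g. "Dn", "Nu", "Up").
#' @slot base base label inherited from the profiles.
#' @slot nGenes number of genes pooled.
#' @slot density numeric vector of per-bin pooled densities in bp/Mbp:
#'   `1e6 * colSums(binBp) / colSums(coveredBp)`.
#' @slot meanWindowDensity mean over genes of the per-gene whole-window
#'   density (bp/Mbp).
#'
#' @exportClass DensityProfile
setClass("DensityProfile",
  representation(label = "character", base = "character",
    nGenes = "integer", density = "numeric", meanWindowDensity = "numeric"))

#' GeneClassification: Up/Dn/Nu calls for one experiment
#'
#' Result of per-gene two-sample Student t-tests (test vs control) with an
#' inclusive significance threshold: a gene is Up if `p <= alpha` and the
#' test-group mean exceeds the control mean, Dn if `p <= alpha` with the
#' opposite sign, Nu otherwise. Up, Dn and Nu partition the gene universe.
#'
#' @slot experimentId label for the experiment.
#' @slot alpha significance threshold (inclusive).
#' @slot results data.frame with columns gene_id, t, df, p, direction
#'   (up/down/flat), call (Up/Dn/Nu).
#'
#' @seealso [classifyGenes()], [intersectCalls()]
#' @exportClass GeneClassification
setClass("GeneClassification",
  representation(experimentId = "character", alpha = "numeric",
    results = "data.frame"))

setValidity("GeneClassification", function(object) {
  msg <- character()
  r <- object@results
  need <- c("gene_id", "t", "df", "p", "direction", "call")
  if (!all(need %in% names(r)))
    msg <- c(msg, paste("results must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(r$gene_id)) msg <- c(msg, "duplicate gene ids")
    if (any(r$p < 0 | r$p > 1, na.rm = TRUE)) msg <- c(msg, "p outside [0,1]")
    if (!all(r$call %in% c("Up", "Dn", "Nu"))) msg <- c(msg, "bad call value")
    bad <- (r$call == "Up" & !(r$p <= object@alpha & r$direction == "up")) |
           (r$call == "Dn" & !(r$p <= object@alpha & r$direction == "down"))
    if (any(bad)) msg <- c(msg, "call inconsistent with p/direction")
  }
  if (object@alpha <= 0 || object@alpha > 1) msg <- c(msg, "alpha outside (0,1]")
  if (length(msg)) msg else TRUE
})

#' IntersectionResult: genes called the same direction in two experiments
#'
#' @slot direction "Dn" or "Up".
#' @slot genes character vector of gene ids called `direction` in both
#'   experiments.
#' @slot counts named integer vector: n1, n2, overlap, universe.
#' @slot pValue hypergeometric upper-tail p-value for the overlap given
#'   the shared universe (`NA` when not requested).
#'
#' @seealso [intersectCalls()], [filterByPvalue()]
#' @exportClass IntersectionResult
setClass("IntersectionResult",
  representation(direction = "character", genes = "character",
    counts = "integer", pValue = "numeric"))

## ---- generics -------------------------------------------------------------

#' @describeIn RepeatIndex-accessors runs as a `GRanges`
#' @export
setGeneric("repeatRuns", function(x) standardGeneric("repeatRuns"))

#' @describeIn RepeatIndex-accessors scan parameters as a list
#' @export
setGeneric("scanParams", function(x) standardGeneric("scanParams"))

#' @describeIn BinProfileSet-accessors repeat bp matrix (genes x bins)
#' @export
setGeneric("binBp", function(x) standardGeneric("binBp"))

#' @describeIn BinProfileSet-accessors covered bp matrix (genes x bins)
#' @export
setGeneric("coveredBp", function(x) standardGeneric("coveredBp"))

#' @describeIn BinProfileSet-accessors number of bins
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @describeIn BinProfileSet-accessors gene identifiers
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @describeIn GeneClassification-accessors named vector of Up/Dn/Nu calls
#' @export
setGeneric("classCalls", function(x) standardGeneric("classCalls"))

#' @describeIn GeneClassification-accessors full per-gene test table
#' @export
setGeneric("testResults", function(x) standardGeneric("testResults"))

#' @describeIn GeneClassification-accessors the significance threshold
#' @export
setGeneric("alphaLevel", function(x) standardGeneric("alphaLevel"))

#' @describeIn IntersectionResult-accessors gene ids in the intersection
#' @export
setGeneric("intersectGenes", function(x) standardGeneric("intersectGenes"))

## ---- accessors ------------------------------------------------------------

#' Accessors for RepeatIndex
#' @name RepeatIndex-accessors
#' @param x a `RepeatIndex`
#' @return `repeatRuns`: `GRanges`; `scanParams`: list.
NULL

#' @export
setMethod("repeatRuns", "RepeatIndex", function(x) x@runs)
#' @export
setMethod("scanParams", "RepeatIndex", function(x) x@params)

#' Accessors for BinProfileSet
#' @name BinProfileSet-accessors
#' @param x a `BinProfileSet`
#' @return matrices, counts or ids as documented per accessor.
NULL

#' @export
setMethod("binBp", "BinProfileSet", function(x) x@binBp)
#' @export
setMethod("coveredBp", "BinProfileSet", function(x) x@coveredBp)
#' @export
setMethod("nBins", "BinProfileSet", function(x) ncol(x@binBp))
#' @export
setMethod("geneIds", "BinProfileSet", function(x) x@genes$gene_id)

#' Accessors for GeneClassification
#' @name GeneClassification-accessors
#' @param x a `GeneClassification`
#' @return `classCalls`: named character vector; `testResults`:
#'   data.frame; `alphaLevel`: numeric.
NULL

#' @export
setMethod("classCalls", "GeneClassification",
  function(x) setNames(x@results$call, x@results$gene_id))
#' @export
setMethod("testResults", "GeneClassification", function(x) x@results)
#' @export
setMethod("alphaLevel", "GeneClassification", function(x) x@alpha)

#' Accessors for IntersectionResult
#' @name IntersectionResult-accessors
#' @param x an `IntersectionResult`
#' @return `intersectGenes`: character vector of gene ids.
NULL

#' @export
setMethod("intersectGenes", "IntersectionResult", function(x) x@genes)

## ---- show -----------------------------------------------------------------

setMethod("show", "RepeatIndex", function(object) {
  p <- object@params
  cat("RepeatIndex with", length(object@runs), "runs\n")
  cat("  bases:", paste(p$bases, collapse = ","),
      " length window: [", p$minLen, ",", p$maxLen, "] bp\n")
  tab <- table(S4Vectors::mcols(object@runs)$base)
  if (length(tab))
    cat("  per base:", paste(names(tab), as.integer(tab),
                             sep = "=", collapse = "  "), "\n")
})

setMethod("show", "BinProfileSet", function(object) {
  cat("BinProfileSet:", nrow(object@binBp), "genes x",
      ncol(object@binBp), "bins\n")
  cat("  base:", object@base, "(", object@strandMode, "mode )",
      " bin width:", object@binWidth, "bp\n")
  cat("  window: ", object@upstream, "bp upstream /",
      object@downstream, "bp downstream of TSS\n")
})

setMethod("show", "DensityProfile", function(object) {
  cat("DensityProfile '", object@label, "' (base ", object@base, "): ",
      object@nGenes, " genes, mean window density ",
      signif(object@meanWindowDensity, 5), " bp/Mbp\n", sep = "")
})

setMethod("show", "GeneClassification", function(object) {
  tab <- table(factor(object@results$call, c("Dn", "Nu", "Up")))
  cat("GeneClassification '", object@experimentId, "' (alpha = ",
      object@alpha, ")\n", sep = "")
  cat(" ", paste(names(tab), as.integer(tab), sep = "=", collapse = "  "),
      "of", nrow(object@results), "genes\n")
})

setMethod("show", "IntersectionResult", function(object) {
  cat("IntersectionResult (", object@direction, "): ",
      object@counts["overlap"], " shared of ",
      object@counts["n1"], " and ", object@counts["n2"],
      " (universe ", object@counts["universe"], ")\n", sep = "")
  if (!is.na(object@pValue))
    cat("  hypergeometric overlap p =", signif(object@pValue, 4), "\n")
})
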