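## TSS-anchored window construction and binned repeat counting.
##
## Window geometry (defaults): 10,000 bp upstream + 10,000 bp downstream
## of the TSS, split into contiguous 100 bp bins indexed 1..200 in
## transcription direction; bins 1-100 are upstream (the TSS base is the
## first position of bin 101). For minus-strand genes "upstream" is to
## the right on the reference, so bin order runs right-to-left.

## numeric bin coordinates for one gene; 1-based closed intervals
.binCoords <- function(tss1, strandChar, upstream, downstream, binWidth) {
  nBins <- (upstream + downstream) / binWidth
  i <- seq_len(nBins)
  if (strandChar == "+") {
    s <- tss1 - upstream + (i - 1L) * binWidth
    e <- s + binWidth - 1L
  } else {
    e <- tss1 + upstream - (i - 1L) * binWidth
    s <- e - binWidth + 1L
  }
  list(start = s, end = e, n = nBins)
}

#' Build TSS-anchored bin windows for a set of genes
#'
#' For every gene, constructs the window of `(upstream + downstream) /
#' binWidth` contiguous bins anchored at the TSS, ordered in
#' transcription direction (bin 1 is always the farthest-upstream bin).
#' Bins are clipped at chromosome boundaries: the `covered` metadata
#' column records the genomic bp each bin retains (0 for bins entirely
#' off-chromosome, which are kept as placeholders so bin indices stay
#' aligned across genes).
#'
#' @param genes annotation `GRanges` from [readAnnotation()] (metadata
#'   columns `gene_id`, `tss`).
#' @param upstream,downstream window extents in bp, each divisible by
#'   `binWidth`; defaults 10000/10000.
#' @param binWidth bin width in bp, default 100.
#' @param chromLengths named vector of chromosome lengths for boundary
#'   clipping; `NULL` clips only at position 1.
#' @return a `GRanges` of bins with metadata columns `gene_id`, `bin`
#'   (1-based index in transcription direction) and `covered`.
#' @export
tssWindows <- function(genes, upstream = 10000L, downstream = 10000L,
                       binWidth = 100L, chromLengths = NULL) {
  stopifnot(is(genes, "GRanges"), length(genes) > 0L)
  if (binWidth < 1L) stop("bin_width must be positive")
  if (upstream %% binWidth != 0L || downstream %% binWidth != 0L)
    stop("upstream and downstream extents must be divisible by bin_width")
  tss <- S4Vectors::mcols(genes)$tss
  ids <- S4Vectors::mcols(genes)$gene_id
  if (is.null(tss) || is.null(ids))
    stop("genes must carry 'gene_id' and 'tss' metadata columns")
  str <- as.character(strand(genes))
  chrom <- as.character(seqnames(genes))
  nBins <- (upstream + downstream) %/% binWidth
  n <- length(genes)
  starts <- ends <- integer(n * nBins)
  for (k in seq_len(n)) {
    bc <- .binCoords(tss[k], str[k], upstream, downstream, binWidth)
    idx <- ((k - 1L) * nBins + 1L):(k * nBins)
    starts[idx] <- bc$start
    ends[idx] <- bc$end
  }
  chromAll <- rep(chrom, each = nBins)
  ## clip: [1, chromLength]
  cs <- pmax(starts, 1L)
  ce <- if (is.null(chromLengths)) ends else
    pmin(ends, unname(chromLengths[chromAll]))
  covered <- pmax(0L, ce - cs + 1L)
  ## degenerate placeholders for fully clipped bins (zero-width range)
  cs2 <- ifelse(covered > 0L, cs, 1L)
  ce2 <- ifelse(covered > 0L, ce, 0L)
  gr <- GenomicRanges::GRanges(chromAll, IRanges::IRanges(cs2, ce2),
                               strand = rep(str, each = nBins))
  S4Vectors::mcols(gr)$gene_id <- rep(ids, each = nBins)
  S4Vectors::mcols(gr)$bin <- rep(seq_len(nBins), n)
  S4Vectors::mcols(gr)$covered <- as.integer(covered)
  gr
}

#' Assign a repeat run's base pairs to window bins proportionally
#'
#' Each bin receives exactly the number of the run's base pairs whose
#' genomic positions fall inside that bin; a run straddling a bin
#' boundary contributes to each bin proportionately and base pairs
#' outside the window are dropped. No length filter is applied at this
#' stage. The sum of the contributions equals the run-window overlap.
#'
#' @param run a single-range `GRanges` (or `IRanges` if `window` carries
#'   a single chromosome).
#' @param window bin `GRanges` for one gene from [tssWindows()].
#' @return named numeric vector, names = bin indices, values = bp
#'   contributed (only bins with positive contribution; empty when the
#'   run misses the window).
#' @export
assignRunToBins <- function(run, window) {
  stopifnot(is(window, "GRanges"))
  if (is(run, "IRanges")) {
    ch <- unique(as.character(seqnames(window)))
    if (length(ch) != 1L)
      stop("chrom-less run with multi-chromosome window")
    run <- GenomicRanges::GRanges(ch, run)
  }
  stopifnot(is(run, "GRanges"), length(run) == 1L)
  hits <- GenomicRanges::findOverlaps(window, run, ignore.strand = TRUE)
  if (length(hits) == 0L) return(setNames(numeric(0), character(0)))
  i <- S4Vectors::queryHits(hits)
  ov <- pmin(end(window)[i], end(run)) - pmax(start(window)[i], start(run)) + 1L
  setNames(as.numeric(ov), S4Vectors::mcols(window)$bin[i])
}

#' Binned repeat profiles for a gene cohort
#'
#' Computes, for every gene, the repeat base pairs assigned to each
#' TSS-anchored bin for one base. Under `strandMode = "sense"` (default)
#' the base refers to the gene's sense strand: for minus-strand genes
#' the complementary base is looked up on the reference strand, so an
#' "A-repeat" profile always means poly(A) in the transcript's own
#' orientation. Under `"reference"` the base is taken literally on the
#' reference strand for all genes. Genes whose window loses more than
#' `dropTruncated` of its span to chromosome boundaries are dropped with
#' a warning.
#'
#' @param genes annotation `GRanges` ([readAnnotation()]).
#' @param index a [RepeatIndex] from [scanGenome()] (already
#'   length-filtered).
#' @param base `"A"` or `"T"` (sense-strand base under the default mode).
#' @param upstream,downstream,binWidth window geometry, defaults
#'   10000/10000/100.
#' @param strandMode `"sense"` or `"reference"`.
#' @param dropTruncated maximum tolerated truncated fraction of the
#'   window (default 0.5) before a gene is dropped.
#' @return a [BinProfileSet].
#' @export
binProfiles <- function(genes, index, base = c("A", "T"),
                        upstream = 10000L, downstream = 10000L,
                        binWidth = 100L,
                        strandMode = c("sense", "reference"),
                        dropTruncated = 0.5) {
  base <- match.arg(base)
  strandMode <- match.arg(strandMode)
  stopifnot(is(index, "RepeatIndex"), is(genes, "GRanges"))
  runs <- repeatRuns(index)
  chromLengths <- GenomeInfoDb::seqlengths(runs)
  gchrom <- unique(as.character(seqnames(genes)))
  known <- if (length(chromLengths)) names(chromLengths) else
    unique(as.character(seqnames(runs)))
  miss <- setdiff(gchrom, known)
  if (length(miss))
    stop("gene chromosome(s) absent from repeat index: ",
         paste(miss, collapse = ","))
  if (!all(is.na(chromLengths)) && length(chromLengths)) {
    cl <- chromLengths
  } else cl <- NULL
  bins <- tssWindows(genes, upstream, downstream, binWidth,
                     chromLengths = cl)
  nBins <- (upstream + downstream) %/% binWidth
  n <- length(genes)
  covered <- matrix(S4Vectors::mcols(bins)$covered, nrow = n,
                    ncol = nBins, byrow = TRUE)
  windowSpan <- upstream + downstream
  keep <- rowSums(covered) >= (1 - dropTruncated) * windowSpan
  if (!all(keep)) {
    warning(sum(!keep), " gene(s) dropped: window more than ",
            dropTruncated * 100, "% truncated by chromosome boundaries")
    genes <- genes[keep]
    n <- length(genes)
    if (n == 0L) stop("no genes left after truncation filtering")
    bins <- bins[rep(keep, each = nBins)]
    covered <- covered[keep, , drop = FALSE]
  }
  str <- as.character(strand(genes))
  runBase <- S4Vectors::mcols(runs)$base
  ## per-gene reference-strand base to query
  queryBase <- if (strandMode == "sense")
    ifelse(str == "+", base, .complementBase(base)) else rep(base, n)
  mat <- matrix(0, nrow = n, ncol = nBins)
  for (qb in unique(queryBase)) {
    sel <- which(queryBase == qb)
    gBins <- bins[rep(seq_len(length(genes)) %in% sel, each = nBins)]
    r <- runs[runBase == qb]
    if (length(r) == 0L || length(gBins) == 0L) next
    hits <- GenomicRanges::findOverlaps(gBins, r, ignore.strand = TRUE)
    if (length(hits) == 0L) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- pmin(end(gBins)[qi], end(r)[si]) -
          pmax(start(gBins)[qi], start(r)[si]) + 1L
    geneRow <- sel[ (qi - 1L) %/% nBins + 1L ]
    binIdx <- S4Vectors::mcols(gBins)$bin[qi]
    flat <- (geneRow - 1L) * nBins + binIdx
    agg <- rowsum(as.numeric(ov), group = flat)
    idx <- as.integer(rownames(agg))
    row <- (idx - 1L) %/% nBins + 1L
    col <- (idx - 1L) %% nBins + 1L
    mat[cbind(row, col)] <- mat[cbind(row, col)] + agg[, 1L]
  }
  gdf <- data.frame(gene_id = S4Vectors::mcols(genes)$gene_id,
                    chrom = as.character(seqnames(genes)),
                    strand = str,
                    tss = S4Vectors::mcols(genes)$tss,
                    stringsAsFactors = FALSE)
  rownames(mat) <- gdf$gene_id
  rownames(covered) <- gdf$gene_id
  new("BinProfileSet", binBp = mat, coveredBp = covered, base = base,
      strandMode = strandMode, upstream = as.numeric(upstream),
      downstream = as.numeric(downstream), binWidth = as.numeric(binWidth),
      genes = gdf)
}

#' Per-gene whole-window repeat density in bp/Mbp
#'
#' `1e6 * sum(binBp) / sum(coveredBp)` per gene: repeat base pairs per
#' million base pairs of surveyed sequence. The denominator is the
#' actually covered window span, so boundary-truncated windows are not
#' biased downward.
#'
#' @param profiles a [BinProfileSet].
#' @return named numeric vector (bp/Mbp), one entry per gene.
#' @export
geneWindowDensity <- function(profiles) {
  stopifnot(is(profiles, "BinProfileSet"))
  tot <- rowSums(coveredBp(profiles))
  if (any(tot <= 0))
    stop("gene(s) with zero covered bp: ",
         paste(geneIds(profiles)[tot <= 0][1:min(3, sum(tot <= 0))],
               collapse = ","))
  1e6 * rowSums(binBp(profiles)) / tot
}

#' Pooled per-bin density profile for a gene group
#'
#' Pools the genes' bin counts: `density[i] = 1e6 * sum_g binBp[g,i] /
#' sum_g coveredBp[g,i]`, and additionally reports the mean over genes of
#' the per-gene whole-window density. With a single gene the pooled
#' profile equals that gene's own per-bin density.
#'
#' @param profiles a [BinProfileSet].
#' @param genes optional character vector of gene ids to pool (default
#'   all genes in `profiles`).
#' @param label group label stored in the result (e.g. `"Dn"`).
#' @return a [DensityProfile].
#' @export
groupDensityProfile <- function(profiles, genes = NULL, label = "all") {
  stopifnot(is(profiles, "BinProfileSet"))
  ids <- geneIds(profiles)
  if (is.null(genes)) genes <- ids
  miss <- setdiff(genes, ids)
  if (length(miss))
    stop("gene(s) absent from profiles: ", paste(miss[1:min(3,
         length(miss))], collapse = ","))
  sel <- ids %in% genes
  bb <- binBp(profiles)[sel, , drop = FALSE]
  cb <- coveredBp(profiles)[sel, , drop = FALSE]
  denom <- colSums(cb)
  dens <- ifelse(denom > 0, 1e6 * colSums(bb) / denom, 0)
  sub <- profiles
  sub@binBp <- bb
  sub@coveredBp <- cb
  sub@genes <- profiles@genes[sel, , drop = FALSE]
  new("DensityProfile", label = label, base = profiles@base,
      nGenes = sum(sel), density = as.numeric(dens),
      meanWindowDensity = mean(geneWindowDensity(sub)))
}
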