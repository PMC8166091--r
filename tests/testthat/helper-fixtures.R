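# Shared fixture builders. All fixtures are generated in code; nothing
# is read from disk except files the tests themselves write.

# random sequence over ACGT(N)
randomSeq <- function(n, withN = FALSE) {
  ab <- c("A", "C", "G", "T")
  pr <- c(0.3, 0.2, 0.2, 0.3)
  if (withN) { ab <- c(ab, "N"); pr <- c(0.28, 0.19, 0.19, 0.28, 0.06) }
  paste(sample(ab, n, replace = TRUE, prob = pr), collapse = "")
}

# independent maximal-run oracle: regex over the character sequence
regexRuns <- function(seq, base) {
  m <- gregexpr(paste0(base, "+"), seq)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(0), width = integer(0)))
  data.frame(start = as.integer(m), width = attr(m, "match.length"))
}

# one-gene annotation GRanges
makeGene <- function(tss1, strand = "+", chrom = "chr1", id = "g1",
                     bodyLen = 10000L) {
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(min(tss1, tss1 + ifelse(strand == "+", bodyLen - 1L,
                                             -bodyLen + 1L)),
                     max(tss1, tss1 + ifelse(strand == "+", bodyLen - 1L,
                                             -bodyLen + 1L))),
    strand = strand)
  S4Vectors::mcols(gr)$gene_id <- id
  S4Vectors::mcols(gr)$tss <- as.integer(tss1)
  gr
}

# RepeatIndex from explicit runs on one or more chromosomes
makeIndex <- function(chrom, start, width, base, seqlen,
                      minLen = 1L, maxLen = 10000L) {
  si <- GenomeInfoDb::Seqinfo(seqnames = names(seqlen),
                              seqlengths = unname(seqlen))
  chrom <- rep(chrom, length.out = length(start))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = width),
                               seqinfo = si)
  S4Vectors::mcols(gr)$base <- base
  o <- if (length(gr)) order(match(chrom, names(seqlen)), start)
       else integer(0)
  new("RepeatIndex", runs = gr[o],
      params = list(minLen = as.integer(minLen),
                    maxLen = as.integer(maxLen), bases = unique(base)))
}

# expression SummarizedExperiment from a matrix with 2+2 samples
makeSe <- function(mat) {
  colnames(mat) <- c("t1", "t2", "c1", "c2")[seq_len(ncol(mat))]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat),
    colData = S4Vectors::DataFrame(
      group = factor(rep(c("test", "control"), each = ncol(mat) / 2),
                     levels = c("test", "control")),
      row.names = colnames(mat)))
}

# tiny but non-trivial simulation config used across tests
tinySimConfig <- function(seed, ...) {
  args <- list(seed = seed, nDn = 8L, nNu = 30L, nUp = 8L,
               upstream = 2000L, downstream = 2000L, binWidth = 100L,
               backgroundRunsPerWindow = 2)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simConfig, args)
}
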