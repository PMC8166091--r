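## Readers/writers for all external representations. BED is 0-based
## half-open on disk; everything in memory is GRanges (1-based closed).
## The annotation TSV dialect carries 0-based coordinates: `tss` is the
## 0-based position of the TSS base, `gene_end` the 0-based exclusive end
## of the gene body in transcription direction.

VALID_BASES <- c("A", "C", "G", "T", "N")

## chromosomes contiguous (first-appearance order), starts sorted within
.isGroupedSorted <- function(chrom, start) {
  if (length(chrom) < 2L) return(TRUE)
  grp <- match(chrom, unique(chrom))
  if (is.unsorted(grp)) return(FALSE)
  all(diff(start) > 0 | diff(grp) > 0)
}

#' Read a genome from FASTA
#'
#' Loads a FASTA file into a [Biostrings::DNAStringSet], uppercasing
#' sequences and enforcing the strict alphabet `{A,C,G,T,N}`. Record
#' names are the first whitespace-delimited token of each header and must
#' be unique and non-empty; ambiguity codes other than N are rejected
#' with the offending record and offset.
#'
#' @param path path to a FASTA file.
#' @return a `DNAStringSet`, one element per chromosome, record order
#'   preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' g <- readGenome(fa)
#' as.character(g$chr1)  # "ACGTACGT"
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  g <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(g) == 0L) stop("FASTA file contains no records: ", path)
  nm <- sub("\\s.*$", "", names(g))
  if (any(!nzchar(nm))) stop("FASTA record with empty name in ", path)
  if (anyDuplicated(nm))
    stop("duplicate FASTA record name: ", nm[duplicated(nm)][1L])
  names(g) <- nm
  if (any(width(g) == 0L))
    stop("empty FASTA record: ", nm[width(g) == 0L][1L])
  af <- Biostrings::alphabetFrequency(g, baseOnly = FALSE)
  extra <- af[, setdiff(colnames(af), VALID_BASES), drop = FALSE]
  bad <- which(rowSums(extra) > 0)
  if (length(bad)) {
    i <- bad[1L]
    chars <- charToRaw(as.character(g[[i]]))
    off <- which(!(chars %in% charToRaw(paste(VALID_BASES, collapse = ""))))[1L]
    stop("illegal character '", rawToChar(chars[off]), "' in record '",
         nm[i], "' at position ", off,
         " (alphabet is A,C,G,T,N)")
  }
  g
}

## Build the annotation GRanges from a validated data.frame with 0-based
## tss / gene_end columns (the TSV contract). Shared by readAnnotation()
## and the simulator so both produce identical objects.
.annotationFromDf <- function(df, genome = NULL) {
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in annotation: ",
         df$gene_id[duplicated(df$gene_id)][1L])
  if (!all(df$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ","),
         " (must be + or -)")
  plus <- df$strand == "+"
  bad <- (plus & df$gene_end <= df$tss) | (!plus & df$gene_end >= df$tss)
  if (any(bad))
    stop("gene_end not downstream of tss in transcription direction for: ",
         paste(df$gene_id[bad][seq_len(min(3, sum(bad)))], collapse = ","))
  start1 <- ifelse(plus, df$tss + 1L, df$gene_end + 2L)
  end1 <- ifelse(plus, df$gene_end, df$tss + 1L)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(start1, end1),
                               strand = df$strand)
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$tss <- as.integer(df$tss + 1L)  # 1-based TSS base
  if (!is.null(genome)) {
    lens <- setNames(width(genome), names(genome))
    miss <- setdiff(unique(df$chrom), names(lens))
    if (length(miss))
      stop("annotation chromosome(s) absent from genome: ",
           paste(miss, collapse = ","))
    out <- S4Vectors::mcols(gr)$tss > lens[as.character(seqnames(gr))] |
           S4Vectors::mcols(gr)$tss < 1L
    if (any(out))
      stop("TSS outside chromosome bounds for: ",
           paste(df$gene_id[out][seq_len(min(3, sum(out)))], collapse = ","))
  }
  gr
}

#' Read a gene annotation (one TSS per gene)
#'
#' Two dialects are accepted. `tsv`: a tab-separated table with columns
#' `gene_id, chrom, strand, tss, gene_end`, where `tss` is the 0-based
#' TSS position and `gene_end` the 0-based exclusive end of the gene body
#' in transcription direction. `bed`: standard 6-column BED where the
#' TSS is the strand-aware 5' end (`start` for `+`, `end - 1` for `-`,
#' in BED's 0-based coordinates) and `name` is the gene id.
#'
#' @param path annotation file.
#' @param dialect `"tsv"` or `"bed"`.
#' @param genome optional `DNAStringSet`; when supplied, chromosome names
#'   and TSS bounds are validated against it.
#' @return a `GRanges` of gene bodies with metadata columns `gene_id` and
#'   `tss` (the 1-based genomic position of the TSS base).
#' @export
readAnnotation <- function(path, dialect = c("tsv", "bed"), genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "tss", "gene_end")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("annotation TSV missing column(s): ", paste(miss, collapse = ","))
    if (!is.numeric(df$tss) || !is.numeric(df$gene_end))
      stop("tss and gene_end must be numeric (0-based)")
  } else {
    bed <- rtracklayer::import(path, format = "bed")
    if (length(bed) == 0L) stop("BED annotation is empty: ", path)
    str <- as.character(strand(bed))
    if (any(str == "*"))
      stop("unknown strand symbol in BED (must be + or -)")
    df <- data.frame(
      gene_id = S4Vectors::mcols(bed)$name,
      chrom = as.character(seqnames(bed)),
      strand = str,
      # back to 0-based: BED start0 = start-1; tss0 = start0 (+) / end0-1 (-)
      tss = ifelse(str == "+", start(bed) - 1L, end(bed) - 1L),
      gene_end = ifelse(str == "+", end(bed), start(bed) - 2L),
      stringsAsFactors = FALSE)
  }
  .annotationFromDf(df, genome = genome)
}

#' Read a log-intensity expression matrix with group labels
#'
#' Reads a tab-separated genes x samples matrix (first column `gene_id`,
#' remaining columns numeric log-scale intensities) and attaches a
#' test/control group factor. Intensities are assumed already normalised
#' on the log scale; they are never transformed. Each group needs at
#' least two replicate samples or the per-gene t-test is undefined.
#'
#' @param path TSV file.
#' @param groups named character vector or list mapping every sample
#'   column to `"test"` or `"control"`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs` and `colData(se)$group`.
#' @export
readExpression <- function(path, groups) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id")
    stop("first column of expression TSV must be 'gene_id'")
  ids <- df$gene_id
  if (anyDuplicated(ids))
    stop("duplicate gene_id in expression matrix: ",
         ids[duplicated(ids)][1L])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric cell in expression matrix")
  if (anyNA(mat)) stop("missing values in expression matrix")
  rownames(mat) <- ids
  groups <- unlist(groups)
  miss <- setdiff(colnames(mat), names(groups))
  if (length(miss))
    stop("sample(s) in file absent from group map: ",
         paste(miss, collapse = ","))
  extra <- setdiff(names(groups), colnames(mat))
  if (length(extra))
    stop("sample(s) in group map absent from file: ",
         paste(extra, collapse = ","))
  groups <- groups[colnames(mat)]
  if (!all(groups %in% c("test", "control")))
    stop("group labels must be 'test' or 'control'")
  tab <- table(groups)
  if (any(tab < 2L) || length(tab) < 2L)
    stop("at least 2 replicates required per group; the two-sample ",
         "t-test is undefined otherwise")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat),
    colData = S4Vectors::DataFrame(
      group = factor(groups, levels = c("test", "control")),
      row.names = colnames(mat)))
}

#' Write repeat runs as BED6
#'
#' Emits one line per run: `chrom, start (0-based), end (exclusive),
#' name` (base + length, e.g. `A15`), `score` (the run length), strand
#' `"."`. Input must already be sorted by (chromosome, start).
#'
#' @param runs a `RepeatIndex` or a `GRanges` with a `base` metadata
#'   column.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeRepeatsBed <- function(runs, path) {
  if (is(runs, "RepeatIndex")) runs <- repeatRuns(runs)
  if (!is(runs, "GRanges") || (length(runs) &&
      is.null(S4Vectors::mcols(runs)$base)))
    stop("runs must be a RepeatIndex or a GRanges with a 'base' column")
  if (length(runs)) {
    if (!.isGroupedSorted(as.character(seqnames(runs)), start(runs)))
      stop("runs must be sorted by (chromosome, start) before writing")
    lines <- paste(as.character(seqnames(runs)),
                   format(start(runs) - 1L, scientific = FALSE, trim = TRUE),
                   format(end(runs), scientific = FALSE, trim = TRUE),
                   paste0(S4Vectors::mcols(runs)$base, width(runs)),
                   width(runs), ".", sep = "\t")
  } else lines <- character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Read repeat runs back from BED6
#'
#' Inverse of [writeRepeatsBed()]; the base and length are recovered from
#' the name field and cross-checked against the interval width.
#'
#' @param path BED file written by [writeRepeatsBed()].
#' @param minLen,maxLen,bases parameters recorded in the returned index.
#' @return a `RepeatIndex`.
#' @export
readRepeatsBed <- function(path, minLen = 13L, maxLen = 27L,
                           bases = c("A", "T")) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$base <- character(0)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    nm <- S4Vectors::mcols(gr)$name
    base <- substr(nm, 1L, 1L)
    len <- as.integer(substring(nm, 2L))
    if (any(is.na(len)) || !all(base %in% c("A", "C", "G", "T")))
      stop("malformed run name field (expected e.g. 'A15')")
    if (!all(len == width(gr)))
      stop("run name length disagrees with interval width")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(base = base)
    ch <- as.character(seqnames(gr))
    gr <- gr[order(match(ch, unique(ch)), start(gr))]
  }
  new("RepeatIndex", runs = gr,
      params = list(minLen = as.integer(minLen),
                    maxLen = as.integer(maxLen), bases = bases))
}
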