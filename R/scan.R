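## Maximal ("intact"/perfect) homopolymer run detection. A run is maximal
## when the flanking characters (where they exist) differ from the run
## base; N terminates runs and never belongs to one. Detection works on
## the raw byte vector of a chromosome: single pass, no regex.

.rawAlphabet <- charToRaw("ACGTN")

.alphabetLookup <- local({
  ok <- logical(256L)
  ok[as.integer(charToRaw("ACGTN")) + 1L] <- TRUE
  ok
})

.checkAlphabet <- function(bytes) {
  bad <- which(!.alphabetLookup[as.integer(bytes) + 1L])
  if (length(bad)) {
    off <- bad[1L]
    stop("illegal character '", rawToChar(bytes[off]),
         "' at position ", off, " (alphabet is A,C,G,T,N)")
  }
  invisible(TRUE)
}

## all maximal runs of `base` in a raw vector: the sorted positions of
## the base are grouped into stretches of consecutive coordinates; each
## stretch is one maximal run (flanks differ from the base or are
## sequence ends by construction). Single pass, O(n).
.findRunsRaw <- function(bytes, base, validate = TRUE) {
  if (validate) .checkAlphabet(bytes)
  w <- which(bytes == charToRaw(base))
  nw <- length(w)
  if (!nw) return(list(start = integer(0), length = integer(0)))
  brk <- which(c(TRUE, w[-1L] != w[-nw] + 1L))
  list(start = w[brk], length = c(brk[-1L], nw + 1L) - brk)
}

#' Find all maximal single-base runs in a sequence
#'
#' Scans one nucleotide sequence for maximal runs of `base` of every
#' length (>= 1). Maximality means the characters immediately before and
#' after the run, when inside the sequence, differ from `base`; a 15-mer
#' inside a 30-mer is therefore never reported separately. `N` is a run
#' terminator, never a run member.
#'
#' @param seq a character string or `DNAString` over `{A,C,G,T,N}`.
#' @param base `"A"` or `"T"` (any of A/C/G/T accepted).
#' @return an [IRanges::IRanges] of runs (1-based start, width = run
#'   length), sorted by start.
#' @examples
#' findRuns(paste0("CC", strrep("A", 15), "GG"), "A")  # start 3, width 15
#' @export
findRuns <- function(seq, base = "A") {
  stopifnot(length(base) == 1L, base %in% c("A", "C", "G", "T"))
  if (is(seq, "DNAString") || is(seq, "DNAStringSet"))
    seq <- as.character(seq)
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(IRanges::IRanges())
  r <- .findRunsRaw(charToRaw(seq), base)
  IRanges::IRanges(start = r$start, width = r$length)
}

#' Filter runs to a length window
#'
#' Keeps runs whose length satisfies `minLen <= length <= maxLen`,
#' inclusive on both ends; runs longer than `maxLen` are excluded
#' entirely, never clipped, because downstream bin sums use full run
#' lengths. Order is preserved.
#'
#' @param runs an `IRanges` or `GRanges` of runs.
#' @param minLen,maxLen inclusive length bounds in bp (`minLen >= 1`).
#' @return object of the same class, filtered.
#' @export
filterRuns <- function(runs, minLen = 13L, maxLen = 27L) {
  if (minLen < 1L) stop("minLen must be >= 1")
  if (minLen > maxLen) stop("minLen must be <= maxLen")
  runs[width(runs) >= minLen & width(runs) <= maxLen]
}

#' Scan a genome for intact A/T repeats
#'
#' Runs [findRuns()] independently on every chromosome for every
#' requested base (so runs never merge across records), filters to the
#' length window, and returns a sorted [RepeatIndex] whose `seqinfo`
#' records chromosome lengths.
#'
#' @param genome a `DNAStringSet` (see [readGenome()]).
#' @param bases bases to scan, default `c("A","T")` on the reference
#'   strand.
#' @param minLen,maxLen inclusive run-length window, default 13-27 bp.
#' @return a [RepeatIndex].
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 20)))
#' scanGenome(g)  # one A-run of length 20 (inside the 13-27 bp window)
#' @export
scanGenome <- function(genome, bases = c("A", "T"), minLen = 13L,
                       maxLen = 27L) {
  stopifnot(is(genome, "DNAStringSet"), length(genome) > 0L)
  if (minLen < 1L) stop("minLen must be >= 1")
  if (minLen > maxLen) stop("minLen must be <= maxLen")
  bases <- match.arg(bases, c("A", "C", "G", "T"), several.ok = TRUE)
  af <- Biostrings::alphabetFrequency(genome, baseOnly = FALSE)
  extra <- af[, setdiff(colnames(af), VALID_BASES), drop = FALSE]
  if (any(rowSums(extra) > 0))
    stop("illegal character(s) in record '",
         names(genome)[rowSums(extra) > 0][1L],
         "' (alphabet is A,C,G,T,N)")
  chroms <- names(genome)
  pieces <- list()
  for (ch in chroms) {
    bytes <- charToRaw(as.character(genome[[ch]]))
    for (b in bases) {
      r <- .findRunsRaw(bytes, b, validate = FALSE)
      sel <- r$length >= minLen & r$length <= maxLen
      if (!any(sel)) next
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = ch, start = r$start[sel], len = r$length[sel], base = b,
        stringsAsFactors = FALSE)
    }
  }
  si <- GenomeInfoDb::Seqinfo(seqnames = chroms,
                              seqlengths = width(genome))
  if (length(pieces)) {
    df <- do.call(rbind, pieces)
    df <- df[order(match(df$chrom, chroms), df$start), , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      factor(df$chrom, levels = chroms),
      IRanges::IRanges(df$start, width = df$len), seqinfo = si)
    S4Vectors::mcols(gr)$base <- df$base
  } else {
    gr <- GenomicRanges::GRanges(seqinfo = si)
    S4Vectors::mcols(gr)$base <- character(0)
  }
  new("RepeatIndex", runs = gr,
      params = list(minLen = as.integer(minLen),
                    maxLen = as.integer(maxLen), bases = bases))
}
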