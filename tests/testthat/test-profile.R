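test_that("default window has 200 contiguous 100-bp bins, 1-100 upstream", {
  g <- makeGene(tss1 = 50001L, strand = "+")
  w <- tssWindows(g)
  expect_length(w, 200L)
  expect_identical(unique(S4Vectors::mcols(w)$covered), 100L)
  up <- w[S4Vectors::mcols(w)$bin <= 100]
  # bins 1-100 jointly cover [40001, 50000] (10,000 bp upstream of the TSS)
  expect_identical(min(GenomicRanges::start(up)), 40001L)
  expect_identical(max(GenomicRanges::end(up)), 50000L)
  expect_identical(sum(S4Vectors::mcols(up)$covered), 10000L)
  # the TSS base opens bin 101
  b101 <- w[S4Vectors::mcols(w)$bin == 101]
  expect_identical(GenomicRanges::start(b101), 50001L)

  # minus strand: upstream is to the right, bin order mirrored
  gm <- makeGene(tss1 = 50000L, strand = "-", id = "g2")
  wm <- tssWindows(gm)
  upm <- wm[S4Vectors::mcols(wm)$bin <= 100]
  expect_identical(min(GenomicRanges::start(upm)), 50001L)
  expect_identical(max(GenomicRanges::end(upm)), 60000L)
  b1m <- wm[S4Vectors::mcols(wm)$bin == 1]
  expect_identical(GenomicRanges::end(b1m), 60000L)  # farthest upstream

  expect_error(tssWindows(g, upstream = 10050), "divisible")
  expect_error(tssWindows(g, binWidth = 0), "positive")
})

test_that("boundary truncation reduces covered bp, never bin count", {
  g <- makeGene(tss1 = 501L, strand = "+")  # 0-based tss = 500
  w <- tssWindows(g, chromLengths = c(chr1 = 100000L))
  expect_length(w, 200L)
  up <- S4Vectors::mcols(w)$covered[S4Vectors::mcols(w)$bin <= 100]
  expect_identical(sum(up), 500L)
  dn <- S4Vectors::mcols(w)$covered[S4Vectors::mcols(w)$bin > 100]
  expect_identical(sum(dn), 10000L)
})

test_that("bin assignment sums full contained lengths (12+13+15 = 40)", {
  g <- makeGene(tss1 = 50001L, strand = "+")
  w <- tssWindows(g)
  b <- w[S4Vectors::mcols(w)$bin == 42]
  s <- GenomicRanges::start(b)
  runs <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(s, s + 20L, s + 40L), width = c(12L, 13L, 15L)))
  total <- sum(vapply(seq_len(3), function(i)
    sum(assignRunToBins(runs[i], w)), numeric(1)))
  expect_identical(total, 40)
  # and every contribution lands in bin 42
  for (i in 1:3)
    expect_identical(names(assignRunToBins(runs[i], w)), "42")
})

test_that("a straddling run splits proportionately by position", {
  g <- makeGene(tss1 = 50001L, strand = "+")
  w <- tssWindows(g)
  b <- w[S4Vectors::mcols(w)$bin == 42]
  run <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(GenomicRanges::end(b) - 6L, width = 20L))
  got <- assignRunToBins(run, w)
  expect_identical(got, c("42" = 7, "43" = 13))

  # outside the window: empty
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e6, width = 20L))
  expect_length(assignRunToBins(far, w), 0L)
})

test_that("assignment conserves overlap length on random run/window pairs", {
  set.seed(515)
  g <- makeGene(tss1 = 50001L, strand = "+")
  w <- tssWindows(g)
  for (i in 1:200) {
    start <- sample(30000:70000, 1)
    len <- sample(1:400, 1)
    run <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start, width = len))
    overlap <- max(0, min(start + len - 1, 60000) - max(start, 40001) + 1)
    expect_equal(sum(assignRunToBins(run, w)), overlap)
  }
})

test_that("profiles place planted runs in the right bins, strand-aware", {
  # plus gene, one 15-bp A-run fully inside bin 42
  tss <- 50001L
  g <- makeGene(tss1 = tss, strand = "+")
  binStart <- tss - 10000L + 41L * 100L  # bin 42 start
  idx <- makeIndex("chr1", binStart + 10L, 15L, "A",
                   seqlen = c(chr1 = 200000L), minLen = 13L, maxLen = 27L)
  ps <- binProfiles(g, idx, base = "A")
  expect_identical(dim(binBp(ps)), c(1L, 200L))
  expect_identical(unname(binBp(ps)[1, 42]), 15)
  expect_identical(sum(binBp(ps)), 15)

  # same locus annotated on the minus strand: sense-mode A means
  # reference T, so the A-run is now invisible ...
  gm <- makeGene(tss1 = tss, strand = "-", id = "gm")
  psm <- binProfiles(gm, idx, base = "A")
  expect_identical(sum(binBp(psm)), 0)
  # ... but it appears in the sense-T profile, in the mirrored bin.
  # run occupies reference bin 42 counted from the left edge of the
  # minus-strand window [tss-9999, tss+10000]
  psmT <- binProfiles(gm, idx, base = "T")
  refBinFromLeft <- ((binStart + 10L) - (tss - 10000L + 1L)) %/% 100L + 1L
  expect_identical(unname(binBp(psmT)[1, 200L - refBinFromLeft + 1L]), 15)
  # reference mode ignores gene strand for the base label
  psmRef <- binProfiles(gm, idx, base = "A", strandMode = "reference")
  expect_identical(sum(binBp(psmRef)), 15)
})

test_that("reverse-complementing the genome and flipping strands leaves
           sense profiles unchanged", {
  cfg <- tinySimConfig(seed = 23, nDn = 4L, nNu = 10L, nUp = 4L)
  gen <- simulateGenome(cfg)
  idx <- gen$index
  ps <- binProfiles(gen$annotation, idx, base = "T",
                    upstream = cfg$upstream, downstream = cfg$downstream,
                    binWidth = cfg$binWidth)
  # transform: revcomp sequence, mirror coordinates, flip strands
  rc <- Biostrings::reverseComplement(gen$genome)
  names(rc) <- names(gen$genome)
  df <- gen$annotationDf
  L <- GenomeInfoDb::seqlengths(repeatRuns(idx))[df$chrom]
  flipped <- data.frame(
    gene_id = df$gene_id, chrom = df$chrom,
    strand = ifelse(df$strand == "+", "-", "+"),
    tss = unname(L) - 1L - df$tss,           # 0-based mirror
    gene_end = unname(L) - 1L - df$gene_end,
    stringsAsFactors = FALSE)
  annFlip <- repeatDensity:::.annotationFromDf(flipped, rc)
  idxFlip <- scanGenome(rc, minLen = cfg$minRunLen, maxLen = cfg$maxRunLen)
  psFlip <- binProfiles(annFlip, idxFlip, base = "T",
                        upstream = cfg$upstream,
                        downstream = cfg$downstream,
                        binWidth = cfg$binWidth)
  expect_equal(binBp(psFlip), binBp(ps))
  expect_equal(coveredBp(psFlip), coveredBp(ps))
})

test_that("densities follow the bp/Mbp definition", {
  g <- makeGene(tss1 = 50001L, strand = "+")
  idx <- makeIndex("chr1", c(44111L, 44161L), c(13L, 27L), c("A", "A"),
                   seqlen = c(chr1 = 200000L), minLen = 13L, maxLen = 27L)
  ps <- binProfiles(g, idx, base = "A")
  expect_equal(unname(geneWindowDensity(ps)), 1e6 * 40 / 20000)  # 2000 bp/Mbp

  # all-zero profile -> zero density
  idx0 <- makeIndex(character(0), integer(0), integer(0), character(0),
                    seqlen = c(chr1 = 200000L), minLen = 13L, maxLen = 27L)
  ps0 <- binProfiles(g, idx0, base = "A")
  expect_identical(unname(geneWindowDensity(ps0)), 0)

  # pooled group density: two genes, full coverage
  g2 <- c(makeGene(tss1 = 50001L, strand = "+"),
          makeGene(tss1 = 120001L, strand = "+", id = "g2"))
  idx2 <- makeIndex("chr1", c(44111L, 114111L), c(20L, 14L), c("A", "A"),
                    seqlen = c(chr1 = 400000L), minLen = 13L, maxLen = 27L)
  ps2 <- binProfiles(g2, idx2, base = "A")
  dp <- groupDensityProfile(ps2, label = "all")
  v <- binBp(ps2)[1, ]; w <- binBp(ps2)[2, ]
  expect_equal(dp@density, unname(1e6 * (v + w) / 200))
  expect_identical(dp@nGenes, 2L)
  # single gene: pooled profile equals that gene's own density
  dp1 <- groupDensityProfile(ps2, genes = "g1")
  expect_equal(dp1@density, unname(1e6 * v / 100))
  expect_equal(dp1@meanWindowDensity, unname(geneWindowDensity(ps2)["g1"]))
})

test_that("over-truncated windows are dropped with a warning", {
  # gEdge sits mid-way on a 6 kb chromosome: its 20 kb window keeps only
  # 6 kb (< 50%), so it must be dropped
  genes <- suppressWarnings(  # Seqinfo merge chatter from c()
    c(makeGene(tss1 = 50001L, strand = "+"),
      makeGene(tss1 = 3001L, strand = "+", chrom = "chr2",
               id = "gEdge", bodyLen = 2000L)))
  idx <- makeIndex("chr1", 44111L, 15L, "A",
                   seqlen = c(chr1 = 200000L, chr2 = 6000L),
                   minLen = 13L, maxLen = 27L)
  expect_warning(ps <- binProfiles(genes, idx, base = "A"), "truncated")
  expect_identical(geneIds(ps), "g1")
  expect_error(binProfiles(makeGene(tss1 = 50001L, chrom = "chrX"), idx,
                           base = "A"),
               "absent from repeat index")
})
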