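test_that("generation is fully deterministic given config and seed", {
  cfg <- tinySimConfig(seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emitFixtureBundle(cfg, d1, force = TRUE)
  emitFixtureBundle(cfg, d2, force = TRUE)
  for (f in dir(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  }
  # a different seed changes the genome
  d3 <- withr::local_tempdir()
  emitFixtureBundle(tinySimConfig(seed = 100), d3, force = TRUE)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "genome.fa"))),
    unname(tools::md5sum(file.path(d3, "genome.fa")))))
  # refusal to overwrite without force
  expect_error(emitFixtureBundle(cfg, d1), "force")
})

test_that("suppression leaves no background runs: zero planted means zero
           found", {
  cfg <- tinySimConfig(seed = 4, backgroundRunsPerWindow = 0)
  gen <- simulateGenome(cfg)
  expect_identical(nrow(gen$truth$runs), 0L)
  idx <- scanGenome(gen$genome, minLen = cfg$minRunLen,
                    maxLen = cfg$maxRunLen)
  expect_length(repeatRuns(idx), 0L)
})

test_that("planted runs are recovered exactly and are maximal", {
  cfg <- tinySimConfig(seed = 21, backgroundRunsPerWindow = 3)
  gen <- simulateGenome(cfg)
  tr <- gen$truth$runs
  expect_gt(nrow(tr), 50)
  idx <- scanGenome(gen$genome, minLen = cfg$minRunLen,
                    maxLen = cfg$maxRunLen)
  found <- repeatRuns(idx)
  expect_identical(length(found), nrow(tr))
  expect_identical(GenomicRanges::start(found), tr$start)
  expect_identical(GenomicRanges::width(found), tr$length)
  # maximality: flanking characters differ from the run base
  seqs <- as.character(gen$genome)
  for (i in sample(nrow(tr), 25)) {
    s <- tr$start[i]; e <- s + tr$length[i] - 1L
    chromSeq <- seqs[[tr$chrom[i]]]
    expect_identical(unique(strsplit(substr(chromSeq, s, e), "")[[1]]),
                     tr$ref_base[i])
    if (s > 1)
      expect_false(substr(chromSeq, s - 1, s - 1) == tr$ref_base[i])
    if (e < nchar(chromSeq))
      expect_false(substr(chromSeq, e + 1, e + 1) == tr$ref_base[i])
  }
})

test_that("binAligned placement stays within one bin; straddling crosses a
           boundary", {
  cfgA <- tinySimConfig(seed = 33, placement = "binAligned")
  genA <- simulateGenome(cfgA)
  trA <- genA$truth$runs
  binOf <- function(pos, tr, cfg, genes) {
    # reference-left bin index within the window
    g <- genes[match(tr$gene_id, genes$gene_id), ]
    tss1 <- g$tss + 1L
    winLeft <- ifelse(g$strand == "+", tss1 - cfg$upstream,
                      tss1 - cfg$downstream + 1L)
    (pos - winLeft) %/% cfg$binWidth
  }
  b1 <- binOf(trA$start, trA, cfgA, genA$truth$genes)
  b2 <- binOf(trA$start + trA$length - 1L, trA, cfgA, genA$truth$genes)
  expect_true(all(b1 == b2))

  cfgS <- tinySimConfig(seed = 34, placement = "straddling")
  genS <- simulateGenome(cfgS)
  trS <- genS$truth$runs
  s1 <- binOf(trS$start, trS, cfgS, genS$truth$genes)
  s2 <- binOf(trS$start + trS$length - 1L, trS, cfgS, genS$truth$genes)
  expect_true(all(s1 != s2))
})

test_that("realized Dn/Nu density ratio tracks the enrichment factor", {
  cfg <- tinySimConfig(seed = 55, nDn = 60L, nNu = 240L, nUp = 0L,
                       backgroundRunsPerWindow = 3, enrichmentFactor = 2)
  gen <- simulateGenome(cfg)
  ps <- binProfiles(gen$annotation, gen$index, base = "T",
                    upstream = cfg$upstream, downstream = cfg$downstream,
                    binWidth = cfg$binWidth)
  dens <- geneWindowDensity(ps)
  cls <- gen$truth$genes$class
  ratio <- mean(dens[cls == "Dn"]) / mean(dens[cls == "Nu"])
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("expression effects are planted as configured and shared between
           experiments", {
  cfg <- tinySimConfig(seed = 66, nDn = 40L, nNu = 200L, nUp = 40L,
                       sharedFraction = 0.5)
  gen <- simulateGenome(cfg)
  ex <- simulateExpression(cfg, gen$truth)
  tr <- ex$truth
  expect_identical(sum(tr$expClasses1 == "Dn"), 40L)
  expect_identical(sum(tr$expClasses2 == "Dn"), 40L)
  shared <- sum(tr$expClasses1 == "Dn" & tr$expClasses2 == "Dn")
  expect_identical(shared, 20L)

  # planted shift recovers the configured effect size on average
  m <- SummarizedExperiment::assay(ex$se1)
  grp <- SummarizedExperiment::colData(ex$se1)$group
  delta <- rowMeans(m[, grp == "test"]) - rowMeans(m[, grp == "control"])
  expect_equal(mean(delta[tr$expClasses1 == "Up"]), cfg$effectSize,
               tolerance = 0.2)
  expect_equal(mean(delta[tr$expClasses1 == "Nu"]), 0, tolerance = 0.1)

  # classifier recovers a reasonable share at 2 replicates, df = 2
  cls <- classifyGenes(ex$se1, experimentId = "e1")
  sens <- mean(classCalls(cls)[tr$expClasses1 != "Nu"] != "Nu")
  expect_gt(sens, 0.2)
})

test_that("fixture bundles parse cleanly through the package readers", {
  cfg <- tinySimConfig(seed = 77)
  d <- withr::local_tempdir()
  paths <- emitFixtureBundle(cfg, d, force = TRUE)
  genome <- readGenome(paths$genome)
  ann <- readAnnotation(paths$annotation, "tsv", genome = genome)
  expect_identical(length(ann), cfg$nGenes)
  groups <- c(test_rep1 = "test", test_rep2 = "test",
              control_rep1 = "control", control_rep2 = "control")
  se1 <- readExpression(paths$expr1, groups)
  expect_identical(nrow(se1), cfg$nGenes)
  rc <- validateConfig(paths$config)
  expect_length(attr(rc, "missing_inputs"), 0L)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  idx <- scanGenome(genome, minLen = cfg$minRunLen, maxLen = cfg$maxRunLen)
  expect_identical(length(repeatRuns(idx)), nrow(truth$runs))
})
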