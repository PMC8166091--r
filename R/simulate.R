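## Synthetic genomes, annotations and expression matrices with planted,
## fully recorded structure. The generator emulates the study inputs:
## a reference genome whose A/T homopolymer runs near TSSs occur at
## controlled per-window rates and lengths (13-27 bp, uniform), gene
## classes whose planted repeat density differs (Dn windows enriched for
## sense-strand T runs by `enrichmentFactor`), and two microarray-like
## experiments with 2 replicates per group and log-normal-scale
## expression whose up/down effects are partially shared. Background
## runs reaching the scanner's minimum length are actively suppressed so
## the truth table is exhaustive; the generator re-scans its own output
## to verify that planted runs are exactly the maximal runs present.

.BASE_RAW <- charToRaw("ACGT")

#' Simulation configuration
#'
#' Collects and validates every knob of the synthetic-data generator.
#' Defaults mirror the emulated study design: 13-27 bp uniform run
#' lengths, 10 kb/10 kb/100 bp window geometry, 2 replicates per group,
#' a 300/1500/300 Dn/Nu/Up class split, 3 expected background runs per
#' base per window, 2-fold T-run enrichment in Dn windows, and a
#' log-scale effect of 1.0 against replicate noise of 0.25 (a 4 x SD
#' effect).
#'
#' @param seed mandatory integer seed; the generator is fully
#'   deterministic given the config.
#' @param nChroms number of chromosomes.
#' @param nDn,nNu,nUp class sizes (gene counts).
#' @param geneSpacing distance between consecutive TSSs in bp; default
#'   keeps neighbouring windows disjoint.
#' @param chromLength chromosome length in bp; default fits the genes.
#' @param strandFractionPlus fraction of genes on the + strand.
#' @param minRunLen,maxRunLen planted run length window (uniform).
#' @param backgroundRunsPerWindow expected planted runs per base per
#'   gene window (Poisson).
#' @param enrichmentFactor rate multiplier for `enrichedBase` runs in
#'   `enrichedClass` windows.
#' @param enrichedClass,enrichedBase which class/sense-strand base is
#'   enriched.
#' @param upstream,downstream,binWidth window geometry used for placing
#'   runs and computing truth bins.
#' @param placement `"random"` (anywhere in the window),
#'   `"binAligned"` (fully inside one bin) or `"straddling"` (forced
#'   across a bin boundary, exercising proportional assignment).
#' @param suppressBackground break naturally arising A/T runs of
#'   `>= minRunLen` so the truth table is exhaustive; disable for
#'   calibration studies where truth = planted plus scanned background.
#' @param nReplicates replicates per expression group.
#' @param effectSize planted log-scale shift for Up/Dn genes.
#' @param noiseSd replicate noise SD (log scale).
#' @param sharedFraction fraction of planted Up/Dn genes shared between
#'   the two experiments.
#' @param baselineMean,baselineSd per-gene baseline log-intensity
#'   distribution.
#' @return a validated list of class `simConfig`.
#' @export
simConfig <- function(seed, nChroms = 1L, nDn = 300L, nNu = 1500L,
                      nUp = 300L, geneSpacing = NULL, chromLength = NULL,
                      strandFractionPlus = 0.5, minRunLen = 13L,
                      maxRunLen = 27L, backgroundRunsPerWindow = 3,
                      enrichmentFactor = 2, enrichedClass = "Dn",
                      enrichedBase = "T", upstream = 10000L,
                      downstream = 10000L, binWidth = 100L,
                      placement = c("random", "binAligned", "straddling"),
                      suppressBackground = TRUE, nReplicates = 2L,
                      effectSize = 1.0, noiseSd = 0.25,
                      sharedFraction = 0.7, baselineMean = 8,
                      baselineSd = 1.5) {
  placement <- match.arg(placement)
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed is mandatory (no silent nondeterminism)")
  seed <- as.integer(seed)
  nGenes <- nDn + nNu + nUp
  if (nGenes < 1L) stop("at least one gene required")
  if (min(nDn, nNu, nUp) < 0L) stop("class sizes must be >= 0")
  if (enrichmentFactor < 0) stop("enrichmentFactor must be >= 0")
  if (minRunLen < 1L || minRunLen > maxRunLen)
    stop("invalid run length window")
  if (upstream %% binWidth != 0L || downstream %% binWidth != 0L)
    stop("extents must be divisible by binWidth")
  if (nReplicates < 2L) stop("at least 2 replicates per group required")
  if (sharedFraction < 0 || sharedFraction > 1)
    stop("sharedFraction must be in [0,1]")
  window <- upstream + downstream
  if (is.null(geneSpacing)) geneSpacing <- window + 400L
  if (geneSpacing < window + 3L)
    stop("geneSpacing must exceed the window span so windows stay disjoint")
  margin <- max(upstream, downstream) + 200L
  perChrom <- ceiling(nGenes / nChroms)
  minChromLen <- 2L * margin + perChrom * geneSpacing
  if (is.null(chromLength)) chromLength <- minChromLen
  if (chromLength < minChromLen)
    stop("chromLength too small: windows must fit (need >= ",
         minChromLen, " bp)")
  structure(list(seed = seed, nChroms = as.integer(nChroms),
    nDn = as.integer(nDn), nNu = as.integer(nNu), nUp = as.integer(nUp),
    nGenes = as.integer(nGenes), geneSpacing = as.integer(geneSpacing),
    chromLength = as.integer(chromLength),
    strandFractionPlus = strandFractionPlus,
    minRunLen = as.integer(minRunLen), maxRunLen = as.integer(maxRunLen),
    backgroundRunsPerWindow = backgroundRunsPerWindow,
    enrichmentFactor = enrichmentFactor, enrichedClass = enrichedClass,
    enrichedBase = enrichedBase, upstream = as.integer(upstream),
    downstream = as.integer(downstream), binWidth = as.integer(binWidth),
    placement = placement, suppressBackground = suppressBackground,
    nReplicates = as.integer(nReplicates), effectSize = effectSize,
    noiseSd = noiseSd, sharedFraction = sharedFraction,
    baselineMean = baselineMean, baselineSd = baselineSd,
    margin = as.integer(margin)), class = "simConfig")
}

## break every A or T run of >= minLen into pieces of < minLen
.suppressRuns <- function(bytes, minLen) {
  for (b in c("A", "T")) {
    r <- .findRunsRaw(bytes, b, validate = FALSE)
    long <- which(r$length >= minLen)
    for (i in long) {
      pos <- seq(r$start[i] + minLen - 1L, r$start[i] + r$length[i] - 1L,
                 by = minLen)
      bytes[pos] <- sample(charToRaw("CG"), length(pos), replace = TRUE)
    }
  }
  bytes
}

#' Generate a synthetic genome, annotation and repeat truth table
#'
#' Builds `nChroms` chromosomes of i.i.d. uniform A/C/G/T background
#' with A/T homopolymers of scanner-detectable length suppressed, places
#' genes at regular spacing with random strands, assigns Dn/Nu/Up class
#' labels at random, and plants maximal homopolymer runs inside each
#' gene's TSS window: per gene and sense-strand base the run count is
#' Poisson with mean `backgroundRunsPerWindow`, multiplied by
#' `enrichmentFactor` for the enriched class/base. Planted runs get
#' non-matching flanking bases (verified by a post-hoc re-scan), so
#' every planted run is a maximal run of the emitted genome and — with
#' suppression on — the truth table is exactly the scanner's expected
#' output.
#'
#' @param config a [simConfig()].
#' @return list with `genome` (`DNAStringSet`), `annotation` (`GRanges`
#'   as from [readAnnotation()]), `annotationDf` (the 0-based TSV form),
#'   `truth` (list: `genes` with class labels, `runs` with exact
#'   coordinates, `config`) and `index` (the verifying [RepeatIndex]
#'   re-scan, `NULL` when background suppression is off).
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  cfg <- config
  chroms <- paste0("chr", seq_len(cfg$nChroms))
  perChrom <- ceiling(cfg$nGenes / cfg$nChroms)
  ## gene layout
  geneChrom <- rep(chroms, each = perChrom)[seq_len(cfg$nGenes)]
  geneIdxInChrom <- unlist(lapply(chroms, function(ch)
    seq_len(sum(geneChrom == ch))))
  tss1 <- cfg$margin + (geneIdxInChrom - 1L) * cfg$geneSpacing + 1L
  strandChar <- ifelse(stats::runif(cfg$nGenes) < cfg$strandFractionPlus,
                       "+", "-")
  classes <- sample(rep(c("Dn", "Nu", "Up"), c(cfg$nDn, cfg$nNu, cfg$nUp)))
  ids <- sprintf("g%04d", seq_len(cfg$nGenes))
  ## sequences; truth-run fields accumulate in flat vectors
  seqs <- list()
  acc <- new.env(parent = emptyenv())
  acc$chrom <- acc$ref <- acc$sense <- acc$gene <- acc$cls <- character(0)
  acc$start <- acc$len <- acc$bin <- integer(0)
  rawCG <- charToRaw("CG")
  rawAT <- charToRaw("AT")
  for (ch in chroms) {
    ## i.i.d. uniform base draw (inversion is markedly faster than
    ## sample.int at genome scale and equally uniform)
    bytes <- .BASE_RAW[1L + as.integer(4 * stats::runif(cfg$chromLength))]
    if (cfg$suppressBackground)
      bytes <- .suppressRuns(bytes, cfg$minRunLen)
    for (k in which(geneChrom == ch)) {
      bc <- .binCoords(tss1[k], strandChar[k], cfg$upstream,
                       cfg$downstream, cfg$binWidth)
      winStart <- min(bc$start); winEnd <- max(bc$end)
      occLo <- occHi <- integer(0)
      gStart <- gLen <- gBin <- integer(0)
      gRef <- gSense <- character(0)
      for (senseBase in c("A", "T")) {
        lambda <- cfg$backgroundRunsPerWindow *
          if (classes[k] == cfg$enrichedClass &&
              senseBase == cfg$enrichedBase) cfg$enrichmentFactor else 1
        nRuns <- stats::rpois(1L, lambda)
        if (nRuns == 0L) next
        refBase <- if (strandChar[k] == "+") senseBase else
          .complementBase(senseBase)
        refRaw <- charToRaw(refBase)
        for (r in seq_len(nRuns)) {
          len <- cfg$minRunLen +
            sample.int(cfg$maxRunLen - cfg$minRunLen + 1L, 1L) - 1L
          placed <- FALSE
          for (try in 1:80) {
            s <- switch(cfg$placement,
              random = winStart +
                sample.int(winEnd - len + 2L - winStart, 1L) - 1L,
              binAligned = {
                b <- sample.int(bc$n, 1L)
                bc$start[b] +
                  sample.int(bc$end[b] - len + 2L - bc$start[b], 1L) - 1L
              },
              straddling = {
                ## boundary between two reference-adjacent bins
                bnd <- sort(bc$start)[sample(2:bc$n, 1L)]
                bnd - sample(seq_len(len - 1L), 1L)
              })
            if (s < max(2L, winStart) ||
                s + len > min(cfg$chromLength, winEnd + 1L)) next
            if (length(occLo) == 0L ||
                all(s + len < occLo | s - 1L > occHi)) {
              occLo <- c(occLo, s - 1L)
              occHi <- c(occHi, s + len)
              placed <- TRUE
              break
            }
          }
          if (!placed) next
          bytes[s:(s + len - 1L)] <- refRaw
          for (fp in c(s - 1L, s + len))
            if (fp >= 1L && fp <= cfg$chromLength && bytes[fp] %in% rawAT)
              bytes[fp] <- sample(rawCG, 1L)
          gStart <- c(gStart, s)
          gLen <- c(gLen, len)
          gRef <- c(gRef, refBase)
          gSense <- c(gSense, senseBase)
          gBin <- c(gBin, if (strandChar[k] == "+")
            (s - winStart) %/% cfg$binWidth + 1L
            else bc$n - (s - winStart) %/% cfg$binWidth)
        }
      }
      if (length(gStart)) {
        acc$chrom <- c(acc$chrom, rep(ch, length(gStart)))
        acc$start <- c(acc$start, gStart)
        acc$len <- c(acc$len, gLen)
        acc$ref <- c(acc$ref, gRef)
        acc$sense <- c(acc$sense, gSense)
        acc$gene <- c(acc$gene, rep(ids[k], length(gStart)))
        acc$cls <- c(acc$cls, rep(classes[k], length(gStart)))
        acc$bin <- c(acc$bin, gBin)
      }
    }
    seqs[[ch]] <- rawToChar(bytes)
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chroms
  runsDf <- data.frame(chrom = acc$chrom, start = acc$start,
                       length = acc$len, ref_base = acc$ref,
                       sense_base = acc$sense, gene_id = acc$gene,
                       class = acc$cls, bin = acc$bin,
                       stringsAsFactors = FALSE)
  runsDf <- runsDf[order(match(runsDf$chrom, chroms), runsDf$start), ,
                   drop = FALSE]
  rownames(runsDf) <- NULL
  ## annotation (0-based TSV contract); gene body = downstream extent
  tss0 <- tss1 - 1L
  geneEnd0 <- ifelse(strandChar == "+", tss0 + cfg$downstream,
                     tss0 - cfg$downstream)
  annDf <- data.frame(gene_id = ids, chrom = geneChrom,
                      strand = strandChar, tss = tss0,
                      gene_end = geneEnd0, stringsAsFactors = FALSE)
  truth <- list(genes = cbind(annDf, class = classes,
                              stringsAsFactors = FALSE),
                runs = runsDf, config = unclass(cfg))
  index <- if (cfg$suppressBackground) .verifyPlanted(genome, truth, cfg)
           else NULL
  list(genome = genome, annotation = .annotationFromDf(annDf, genome),
       annotationDf = annDf, truth = truth, index = index)
}

## generator self-check: scanner output must equal the truth table
.verifyPlanted <- function(genome, truth, cfg) {
  idx <- scanGenome(genome, bases = c("A", "T"),
                    minLen = cfg$minRunLen, maxLen = cfg$maxRunLen)
  found <- repeatRuns(idx)
  tr <- truth$runs
  ok <- length(found) == nrow(tr) &&
    identical(as.character(seqnames(found)), tr$chrom) &&
    identical(start(found), as.integer(tr$start)) &&
    identical(width(found), as.integer(tr$length)) &&
    identical(S4Vectors::mcols(found)$base, tr$ref_base)
  if (!ok)
    stop("generator self-check failed: scanned runs differ from the ",
         "planted truth table")
  idx
}

#' Generate two planted-effect expression experiments
#'
#' Per-gene baseline log intensities are `N(baselineMean, baselineSd)`
#' and replicate noise `N(0, noiseSd)`. Null genes draw test and control
#' from the same distribution; planted Up/Dn genes shift the test-group
#' mean by `+/- effectSize`. Experiment 1 uses the genome truth classes;
#' experiment 2 keeps a `sharedFraction` of each planted set and redraws
#' the remainder from experiment 1's neutral pool, so the two
#' experiments overlap the way paired microarray contrasts do.
#'
#' @param config a [simConfig()].
#' @param truth truth list from [simulateGenome()].
#' @return list with `se1`, `se2` (`SummarizedExperiment`s with
#'   `colData$group`) and `truth` extended with `expClasses1`,
#'   `expClasses2`.
#' @export
simulateExpression <- function(config, truth) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed + 1L)
  cfg <- config
  ids <- truth$genes$gene_id
  n <- length(ids)
  cls1 <- setNames(truth$genes$class, ids)
  ## experiment 2 classes
  cls2 <- setNames(rep("Nu", n), ids)
  nuPool <- ids[cls1 == "Nu"]
  for (dir in c("Dn", "Up")) {
    planted <- ids[cls1 == dir]
    nShared <- round(cfg$sharedFraction * length(planted))
    shared <- if (length(planted)) sample(planted, nShared) else character(0)
    nNew <- length(planted) - nShared
    fresh <- if (nNew > 0) sample(nuPool, nNew) else character(0)
    nuPool <- setdiff(nuPool, fresh)
    cls2[c(shared, fresh)] <- dir
  }
  mu <- stats::rnorm(n, cfg$baselineMean, cfg$baselineSd)
  makeMat <- function(cls) {
    k <- cfg$nReplicates
    shift <- ifelse(cls == "Up", cfg$effectSize,
                    ifelse(cls == "Dn", -cfg$effectSize, 0))
    test <- matrix(stats::rnorm(n * k, mu + shift, cfg$noiseSd), n, k)
    ctrl <- matrix(stats::rnorm(n * k, mu, cfg$noiseSd), n, k)
    m <- cbind(test, ctrl)
    colnames(m) <- c(paste0("test_rep", seq_len(k)),
                     paste0("control_rep", seq_len(k)))
    rownames(m) <- ids
    m
  }
  toSe <- function(m) SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m),
    colData = S4Vectors::DataFrame(
      group = factor(rep(c("test", "control"), each = cfg$nReplicates),
                     levels = c("test", "control")),
      row.names = colnames(m)))
  truth$expClasses1 <- cls1
  truth$expClasses2 <- cls2
  list(se1 = toSe(makeMat(cls1)), se2 = toSe(makeMat(cls2)),
       truth = truth)
}

#' Write a self-contained synthetic fixture bundle
#'
#' Runs the full generator and writes everything the pipeline consumes:
#' `genome.fa`, `genes.tsv` (0-based annotation), `expr1.tsv` and
#' `expr2.tsv` (log intensities, 4 decimals), `truth.json`, and a
#' `config.yaml` directly consumable by [runPipeline()]. Identical
#' config and seed produce byte-identical files.
#'
#' @param config a [simConfig()].
#' @param outDir output directory (created if needed).
#' @param force overwrite a non-empty existing directory.
#' @return invisibly, the list of written paths.
#' @export
emitFixtureBundle <- function(config, outDir, force = FALSE) {
  stopifnot(inherits(config, "simConfig"))
  if (dir.exists(outDir) && length(dir(outDir)) > 0L && !force)
    stop("output directory exists and is not empty (use force = TRUE): ",
         outDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  gen <- simulateGenome(config)
  expr <- simulateExpression(config, gen$truth)
  paths <- list(
    genome = file.path(outDir, "genome.fa"),
    annotation = file.path(outDir, "genes.tsv"),
    expr1 = file.path(outDir, "expr1.tsv"),
    expr2 = file.path(outDir, "expr2.tsv"),
    truth = file.path(outDir, "truth.json"),
    config = file.path(outDir, "config.yaml"))
  Biostrings::writeXStringSet(gen$genome, paths$genome, width = 70L)
  utils::write.table(gen$annotationDf, paths$annotation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeExpr <- function(se, path) {
    m <- SummarizedExperiment::assay(se)
    df <- data.frame(gene_id = rownames(m), round(m, 4L),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  writeExpr(expr$se1, paths$expr1)
  writeExpr(expr$se2, paths$expr2)
  truthOut <- expr$truth
  jsonlite::write_json(truthOut, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  groups <- as.list(setNames(
    rep(c("test", "control"), each = config$nReplicates),
    c(paste0("test_rep", seq_len(config$nReplicates)),
      paste0("control_rep", seq_len(config$nReplicates)))))
  runCfg <- list(genome = "genome.fa", annotation = "genes.tsv",
    annotation_dialect = "tsv", expr1 = "expr1.tsv", expr2 = "expr2.tsv",
    groups1 = groups, groups2 = groups,
    min_len = config$minRunLen, max_len = config$maxRunLen,
    upstream = config$upstream, downstream = config$downstream,
    bin_width = config$binWidth, alpha = 0.05, p_cut = 0.05,
    strand_mode = "sense", bases = c("A", "T"), seed = config$seed)
  yaml::write_yaml(runCfg, paths$config)
  invisible(paths)
}
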