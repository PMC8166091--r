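test_that("per-gene t-test matches stats::t.test to high precision", {
  set.seed(88)
  mat <- matrix(rnorm(200 * 4, mean = 8, sd = 1), nrow = 200,
                dimnames = list(sprintf("g%03d", 1:200), NULL))
  se <- makeSe(mat)
  cls <- classifyGenes(se, experimentId = "e1")
  res <- testResults(cls)
  for (i in sample(200, 40)) {
    tt <- t.test(mat[i, 1:2], mat[i, 3:4], var.equal = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
    expect_identical(res$df[i], unname(tt$parameter))
  }
})

test_that("t-test edge cases: ties, antisymmetry, degenerate variance", {
  se <- makeSe(matrix(c(5, 5, 5, 5), nrow = 1,
                      dimnames = list("g1", NULL)))
  r <- geneTtest(se, "g1")
  expect_identical(r$t, 0)
  expect_identical(r$p, 1)
  expect_identical(r$direction, "flat")

  # swapping groups negates t, keeps p, flips direction
  m <- matrix(c(2.0, 2.2, 1.0, 1.1), nrow = 1,
              dimnames = list("g1", NULL))
  r1 <- geneTtest(makeSe(m), "g1")
  r2 <- geneTtest(makeSe(m[, c(3, 4, 1, 2), drop = FALSE]), "g1")
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  expect_identical(r1$direction, "up")
  expect_identical(r2$direction, "down")

  # zero pooled variance, unequal means: p = 0, flagged
  se0 <- makeSe(matrix(c(3, 3, 1, 1), nrow = 1,
                       dimnames = list("g1", NULL)))
  r0 <- geneTtest(se0, "g1")
  expect_identical(r0$p, 0)
  expect_true(r0$degenerate)
  expect_identical(r0$direction, "up")
})

test_that("classification partitions genes, thresholds inclusively, and is
           monotone in alpha", {
  set.seed(19)
  n <- 300L
  mat <- matrix(rnorm(n * 4, 8, 0.3), nrow = n,
                dimnames = list(sprintf("g%03d", 1:n), NULL))
  mat[1:30, 1:2] <- mat[1:30, 1:2] + 2       # planted up
  mat[31:60, 1:2] <- mat[31:60, 1:2] - 2     # planted down
  se <- makeSe(mat)
  cls <- classifyGenes(se, alpha = 0.05, experimentId = "e1")
  tab <- table(classCalls(cls))
  expect_identical(sum(tab), n)

  # inclusive threshold: alpha set exactly at an observed p keeps the gene
  res <- testResults(cls)
  pEdge <- res$p[res$call == "Nu"][which.min(res$p[res$call == "Nu"])]
  clsEdge <- classifyGenes(se, alpha = pEdge, experimentId = "e1")
  gEdge <- res$gene_id[res$p == pEdge][1]
  expect_true(classCalls(clsEdge)[gEdge] %in% c("Up", "Dn"))

  # monotonicity: smaller alpha never grows Up/Dn
  cls01 <- classifyGenes(se, alpha = 0.01, experimentId = "e1")
  for (d in c("Up", "Dn")) {
    g05 <- names(classCalls(cls))[classCalls(cls) == d]
    g01 <- names(classCalls(cls01))[classCalls(cls01) == d]
    expect_true(all(g01 %in% g05))
  }

  # planted effects at 4 x noise SD are mostly recovered
  expect_gt(mean(classCalls(cls)[1:30] == "Up"), 0.2)
  expect_gt(mean(classCalls(cls)[31:60] == "Dn"), 0.2)
})

test_that("pure-null classification calls Up+Dn at about the alpha rate", {
  set.seed(2024)
  rates <- replicate(30, {
    mat <- matrix(rnorm(400 * 4, 8, 0.25), nrow = 400,
                  dimnames = list(sprintf("g%03d", 1:400), NULL))
    calls <- classCalls(classifyGenes(makeSe(mat)))
    mean(calls != "Nu")
  })
  expect_gt(mean(rates), 0.02)
  expect_lt(mean(rates), 0.09)
})

test_that("intersection uses set semantics over the shared universe", {
  mkCls <- function(ids, dn, up, expId) {
    p <- setNames(rep(0.5, length(ids)), ids)
    p[c(dn, up)] <- 0.01
    dirn <- setNames(rep("flat", length(ids)), ids)
    dirn[dn] <- "down"; dirn[up] <- "up"
    call <- setNames(rep("Nu", length(ids)), ids)
    call[dn] <- "Dn"; call[up] <- "Up"
    new("GeneClassification", experimentId = expId, alpha = 0.05,
        results = data.frame(gene_id = ids, t = 0, df = 2, p = unname(p),
                             direction = unname(dirn), call = unname(call),
                             stringsAsFactors = FALSE))
  }
  ids <- letters[1:10]
  c1 <- mkCls(ids, dn = c("a", "b", "c"), up = "h", expId = "e1")
  c2 <- mkCls(ids, dn = c("b", "c", "d"), up = "i", expId = "e2")
  ir <- intersectCalls(c1, c2, "Dn")
  expect_setequal(intersectGenes(ir), c("b", "c"))
  expect_identical(unname(ir@counts["overlap"]), 2L)

  # hypergeometric overlap p equals the enumeration oracle
  k <- 2; n1 <- 3; n2 <- 3; N <- 10
  pOracle <- sum(dhyper(k:min(n1, n2), n1, N - n1, n2))
  expect_equal(ir@pValue, pOracle, tolerance = 1e-12)

  irUp <- intersectCalls(c1, c2, "Up")
  expect_length(intersectGenes(irUp), 0L)

  # disjoint universes error; partial overlap warns
  c3 <- mkCls(LETTERS[1:5], dn = "A", up = "B", expId = "e3")
  expect_error(intersectCalls(c1, c3, "Dn"), "universe")
  c4 <- mkCls(c(ids, "zz"), dn = "a", up = "h", expId = "e4")
  expect_warning(intersectCalls(c1, c4, "Dn"), "dropped")
})

test_that("p-value filtering requires the cut in both experiments", {
  mk <- function(pvals, expId) {
    ids <- names(pvals)
    new("GeneClassification", experimentId = expId, alpha = 0.05,
        results = data.frame(gene_id = ids, t = -1, df = 2,
                             p = unname(pvals), direction = "down",
                             call = ifelse(pvals <= 0.05, "Dn", "Nu"),
                             stringsAsFactors = FALSE))
  }
  p1 <- c(gA = 0.03, gB = 0.009, gC = 0.04)
  p2 <- c(gA = 0.008, gB = 0.008, gC = 0.03)
  c1 <- mk(p1, "e1"); c2 <- mk(p2, "e2")
  ir <- intersectCalls(c1, c2, "Dn")
  expect_setequal(intersectGenes(ir), c("gA", "gB", "gC"))
  # gA fails in experiment 1 at 0.01; gB passes both
  expect_identical(filterByPvalue(ir, c1, c2, 0.01), "gB")
  # cut equal to alpha is the identity on the intersection
  expect_setequal(filterByPvalue(ir, c1, c2, 0.05), intersectGenes(ir))
  expect_error(filterByPvalue(ir, c1, c2, 0.10), "alpha")
  # monotone: lower cut never grows the list
  expect_true(all(filterByPvalue(ir, c1, c2, 0.01) %in%
                  filterByPvalue(ir, c1, c2, 0.05)))
})
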