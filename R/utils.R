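.complementBase <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}

## Vectorized pooled-variance (Student) two-sample t-test, one test per
## row of the two matrices. Degenerate rows (zero pooled variance) give
## t = 0, p = 1 when the means are equal and |t| = Inf, p = 0 otherwise;
## the latter are flagged so callers can log them.
.pooledT <- function(testMat, ctrlMat) {
  testMat <- as.matrix(testMat)
  ctrlMat <- as.matrix(ctrlMat)
  stopifnot(nrow(testMat) == nrow(ctrlMat))
  n1 <- ncol(testMat); n2 <- ncol(ctrlMat)
  if (n1 < 2L || n2 < 2L)
    stop("at least 2 replicates required per group")
  m1 <- rowMeans(testMat); m2 <- rowMeans(ctrlMat)
  v1 <- rowSums((testMat - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrlMat - m2)^2) / (n2 - 1)
  df <- as.numeric(n1 + n2 - 2)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  delta <- m1 - m2
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- delta / se
  deg <- sp2 <= 0
  t[deg & delta == 0] <- 0
  t[deg & delta != 0] <- sign(delta[deg & delta != 0]) * Inf
  p <- 2 * stats::pt(-abs(t), df)
  list(t = as.numeric(t), p = as.numeric(p), df = df,
       mean1 = as.numeric(m1), mean2 = as.numeric(m2),
       degenerate = as.logical(deg & delta != 0))
}

## vector convenience wrapper
.pooledTVec <- function(x, y) {
  r <- .pooledT(matrix(x, nrow = 1L), matrix(y, nrow = 1L))
  lapply(r, `[`, 1L)
}
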