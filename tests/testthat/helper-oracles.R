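# Independent oracles used across the test files. These deliberately avoid
# the package's internal code paths.

# published ideal alanine coordinates (L-configuration): N, CA, C, O, CB
oracleAlanine <- matrix(c(
  -0.966,  0.493,  1.500,
   0.257,  0.418,  0.692,
  -0.094,  0.017, -0.716,
  -1.056, -0.682, -0.923,
   1.204, -0.620,  1.296
), nrow = 5, byrow = TRUE,
  dimnames = list(c("N", "CA", "C", "O", "CB"), NULL))

# Kabsch least-squares superposition of the oracle alanine's (N, CA, C)
# onto a target backbone; returns where the template's CB lands.
kabschCB <- function(n, ca, c) {
  X <- oracleAlanine[c("N", "CA", "C"), ]   # template
  Y <- rbind(n, ca, c)                      # target
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  s <- svd(t(Xc) %*% Yc)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  as.numeric(R %*% (oracleAlanine["CB", ] - cx) + cy)
}

# random rotation matrix, independent of the package's generator
oracleRotation <- function() {
  theta <- runif(1, 0, 2 * pi)
  axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# elementwise double-loop Euclidean distance matrix
bruteDistanceMatrix <- function(coords) {
  n <- nrow(coords)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    }
  }
  m
}

# exhaustive O(n^2) Mann-Whitney concordance probability (ties count 1/2)
concordanceAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# shared cloud-trained classifier (cached across test files)
.sharedEnv <- new.env(parent = emptyenv())
sharedCloudModel <- function() {
  if (is.null(.sharedEnv$model)) {
    ds <- makeFeatureClouds(1000, seed = 11)
    .sharedEnv$dataset <- ds
    .sharedEnv$model <- trainClassifier(ds, classifierConfig(seed = 5))
  }
  .sharedEnv$model
}
sharedCloudDataset <- function() {
  sharedCloudModel()
  .sharedEnv$dataset
}

# quiet fixture generation (repair-pass messages/warnings are expected)
quietStructure <- function(...) {
  suppressWarnings(suppressMessages(makeStructure(...)))
}
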