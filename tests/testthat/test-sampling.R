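# brute-force oracle: enumerate the crossing neighbour pairs of a bond and
# return the usable pair with the smallest CA-CA distance
oracleNegative <- function(s, bond) {
  res <- residues(s)
  co <- atomCoords(s)
  pos <- function(chain, resno) which(res$chain == chain & res$resno == resno)
  i <- pos(bond$chain1, bond$resno1)
  j <- pos(bond$chain2, bond$resno2)
  neigh <- function(i0, d) {
    k <- i0 + d
    if (k >= 1 && k <= nrow(res) && res$chain[k] == res$chain[i0]) k else NA
  }
  cand <- rbind(c(neigh(i, -1), neigh(j, -1)), c(neigh(i, -1), neigh(j, 1)),
                c(neigh(i, 1), neigh(j, -1)), c(neigh(i, 1), neigh(j, 1)))
  best <- NULL; bestD <- Inf
  for (r in seq_len(4)) {
    p <- cand[r, 1]; q <- cand[r, 2]
    if (is.na(p) || is.na(q) || p == q) next
    d <- sqrt(sum((co[p, "CA", ] - co[q, "CA", ])^2))
    if (d < bestD) { bestD <- d; best <- c(p, q) }
  }
  if (is.null(best)) return(NULL)
  sort(res$resno[best])
}

test_that("positive samples mirror the declared disulfide bonds", {
  fx <- quietStructure(20, 2, seed = 31)
  s <- readStructure(fx$path)
  pos <- extractPositives(s)
  expect_length(pos, 2L)
  expect_true(all(vapply(pos, function(p) p$label, integer(1)) == 1L))
  got <- t(vapply(pos, function(p) sort(c(p$a$resno, p$b$resno)), integer(2)))
  want <- t(apply(cbind(fx$truth$resno1, fx$truth$resno2), 1, sort))
  expect_equal(got[order(got[, 1]), ], want[order(want[, 1]), ])
  # structure without bonds yields no positives
  fx0 <- quietStructure(8, 0, seed = 32)
  expect_length(extractPositives(readStructure(fx0$path)), 0L)
})

test_that("negative derivation selects the shortest crossing pair", {
  for (seed in 1:8) {
    fx <- quietStructure(20, 2, seed = seed)
    s <- readStructure(fx$path)
    sb <- ssbonds(s)
    for (k in seq_len(nrow(sb))) {
      neg <- deriveNegative(s, sb[k, ])
      expect_false(is.null(neg))
      got <- sort(c(neg$a$resno, neg$b$resno))
      expect_equal(got, oracleNegative(s, sb[k, ]))
      # and agrees with the generator's own truth table
      tr <- fx$truth[fx$truth$resno1 == sb$resno1[k] &
                       fx$truth$resno2 == sb$resno2[k], ]
      expect_equal(got, sort(c(tr$neg_resno1, tr$neg_resno2)))
      # a derived negative is never itself a bonded pair
      expect_false(any(
        (sb$resno1 == got[1] & sb$resno2 == got[2]) |
          (sb$resno1 == got[2] & sb$resno2 == got[1])))
      expect_equal(neg$label, 0L)
    }
  }
})

test_that("negative derivation handles bonds at chain termini", {
  # bonded cysteine at residue 1: only the crossing pairs through residue 2
  # remain as candidates
  set.seed(99)
  n <- 5
  co <- array(NA_real_, dim = c(n, 5, 3))
  for (i in 1:n) {
    co[i, , ] <- makeResidue(seed = 100 + i, center = c(3.8 * i, 0, 0))
  }
  res <- data.frame(chain = "A", resno = 1:n, insert = "",
                    resid = c("CYS", "ALA", "CYS", "ALA", "ALA"),
                    cb_source = "observed", stringsAsFactors = FALSE)
  sb <- data.frame(chain1 = "A", resno1 = 1L, insert1 = "",
                   chain2 = "A", resno2 = 3L, insert2 = "",
                   stringsAsFactors = FALSE)
  s <- new("ProteinStructure", id = "toy", residues = res, coords = co,
           ssbonds = sb)
  neg <- deriveNegative(s, sb[1, ])
  # candidates: (2,2) invalid, (2,4) -> only usable pair
  expect_equal(sort(c(neg$a$resno, neg$b$resno)), c(2L, 4L))
})

test_that("dataset assembly balances, splits and reproduces deterministically", {
  fx <- quietStructure(20, 2, seed = 35)
  s <- readStructure(fx$path)
  pos <- extractPositives(s)
  sb <- ssbonds(s)
  negs <- lapply(seq_len(nrow(sb)), function(k) deriveNegative(s, sb[k, ]))
  # replicate to 100 positives + 100 negatives, then check the arithmetic
  samples <- c(rep(pos, 50), rep(negs, 50))
  ds <- datasetFromSamples(samples, testFraction = 0.25, seed = 7)
  expect_equal(sum(datasetSplit(ds) == "test"), 50L)
  expect_equal(sum(datasetSplit(ds) == "train"), 150L)
  expect_equal(sum(pairLabels(ds) == 1L), 100L)
  # same seed, same split
  ds2 <- datasetFromSamples(samples, testFraction = 0.25, seed = 7)
  expect_identical(datasetSplit(ds), datasetSplit(ds2))
  expect_identical(features(ds), features(ds2))
  # a missing negative leaves a warned imbalance
  expect_warning(datasetFromSamples(c(pos, negs[1]), 0.25, 1), "imbalance")
})

test_that("assembleDataset runs end to end over several structures", {
  structs <- lapply(41:44, function(sd) {
    readStructure(quietStructure(20, 2, seed = sd)$path)
  })
  ds <- assembleDataset(structs, testFraction = 0.25, seed = 2)
  expect_s4_class(ds, "PairDataset")
  expect_equal(length(pairLabels(ds)), 16L)   # 4 structures x (2 pos + 2 neg)
  expect_equal(sum(pairLabels(ds)), 8L)
  expect_equal(ncol(features(ds)), 45L)
  expect_error(assembleDataset(list()), "no structures")
})

test_that("curation filters by strict resolution and R-factor thresholds", {
  entries <- data.frame(
    id = c("a", "b", "c", "d", "e"),
    resolution = c(1.8, 2.0, 1.5, NA, 1.9),
    rfactor = c(0.20, 0.20, 0.25, 0.2, NA))
  kept <- curateFilter(entries, maxResolution = 2.0, maxRfactor = 0.25)
  expect_equal(kept$id, "a")   # 2.0 A and R 0.25 fall on the strict boundary
  allNA <- data.frame(id = "x", resolution = NA_real_, rfactor = NA_real_)
  expect_equal(nrow(curateFilter(allNA)), 0L)
})

test_that("datasets round-trip through CSV serialization", {
  fx <- quietStructure(20, 2, seed = 36)
  ds <- assembleDataset(list(readStructure(fx$path)), 0.25, 1)
  path <- tempfile(fileext = ".csv")
  writeDataset(ds, path)
  ds2 <- readDataset(path)
  expect_equal(features(ds2), features(ds), tolerance = 1e-12)
  expect_identical(pairLabels(ds2), pairLabels(ds))
  expect_identical(datasetSplit(ds2), datasetSplit(ds))
})

test_that("combined datasets stack samples from multiple sources", {
  a <- makeFeatureClouds(20, seed = 1)
  b <- makeFeatureClouds(10, seed = 2)
  ab <- combineDatasets(a, b)
  expect_equal(length(pairLabels(ab)), 60L)
  expect_equal(unname(features(ab)[1:40, ]), unname(features(a)))
})
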