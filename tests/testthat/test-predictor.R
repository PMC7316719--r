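test_that("pair enumeration covers all unordered residue pairs", {
  fx <- quietStructure(5, 0, seed = 51)
  s <- readStructure(fx$path)
  pairs <- enumeratePairs(s)
  expect_equal(nrow(pairs), 10L)
  # brute-force double loop
  want <- NULL
  for (i in 1:4) for (j in (i + 1):5) want <- rbind(want, c(i, j))
  expect_equal(unname(as.matrix(pairs)), want)
  # single residue: no pairs
  co <- array(makeResidue(seed = 1), dim = c(1, 5, 3))
  co[1, , ] <- makeResidue(seed = 1)
  s1 <- new("ProteinStructure", id = "one",
            residues = data.frame(chain = "A", resno = 1L, insert = "",
                                  resid = "ALA", cb_source = "observed",
                                  stringsAsFactors = FALSE),
            coords = co,
            ssbonds = data.frame(chain1 = character(), resno1 = integer(),
                                 insert1 = character(), chain2 = character(),
                                 resno2 = integer(), insert2 = character()))
  expect_equal(nrow(enumeratePairs(s1)), 0L)
})

test_that("prescreen applies the CA window and sequence-separation rule", {
  fx <- quietStructure(20, 1, seed = 53)
  s <- readStructure(fx$path)
  cfg <- prescreenConfig()
  kept <- prescreenPairs(enumeratePairs(s), s, cfg)
  # oracle re-filter
  co <- atomCoords(s)
  res <- residues(s)
  for (r in seq_len(nrow(kept))) {
    i <- kept$i[r]; j <- kept$j[r]
    d <- sqrt(sum((co[i, "CA", ] - co[j, "CA", ])^2))
    expect_true(d >= 3.0 && d <= 7.5)
    expect_true(res$chain[i] != res$chain[j] || abs(i - j) >= 2)
    expect_equal(kept$ca_distance[r], d)
  }
  # and nothing inside the window was missed
  all <- enumeratePairs(s)
  for (r in seq_len(nrow(all))) {
    i <- all$i[r]; j <- all$j[r]
    d <- sqrt(sum((co[i, "CA", ] - co[j, "CA", ])^2))
    inWin <- d >= 3.0 && d <= 7.5 &&
      (res$chain[i] != res$chain[j] || abs(i - j) >= 2)
    expect_equal(any(kept$i == i & kept$j == j), inWin)
  }
})

test_that("prescreen window boundaries are inclusive and the rest drops", {
  # hand-placed CA distances: 2.9 (below), 5.0 (inside), 7.6 (above);
  # a far-away middle residue keeps the tested pair two sequence
  # positions apart
  mk <- function(d) {
    co <- array(NA_real_, dim = c(3, 5, 3))
    co[1, , ] <- makeResidue(seed = 1, center = c(0, 0, 0))
    co[2, , ] <- makeResidue(seed = 3, center = c(100, 100, 100))
    co[3, , ] <- makeResidue(seed = 2, center = c(d, 0, 0))
    res <- data.frame(chain = "A", resno = c(1L, 2L, 5L), insert = "",
                      resid = "ALA", cb_source = "observed",
                      stringsAsFactors = FALSE)
    new("ProteinStructure", id = "toy", residues = res, coords = co,
        ssbonds = data.frame(chain1 = character(), resno1 = integer(),
                             insert1 = character(), chain2 = character(),
                             resno2 = integer(), insert2 = character()))
  }
  for (d in c(5.0, 3.0, 7.5)) {
    expect_equal(nrow(prescreenPairs(enumeratePairs(mk(d)), mk(d),
                                     prescreenConfig())), 1L)
  }
  for (d in c(2.9, 7.6)) {
    expect_equal(nrow(prescreenPairs(enumeratePairs(mk(d)), mk(d),
                                     prescreenConfig())), 0L)
  }
})

test_that("site prediction ranks records by descending score with exact ranks", {
  fit <- sharedCloudModel()
  fx <- quietStructure(20, 1, seed = 54)
  s <- readStructure(fx$path)
  pred <- predictSites(s, fit)
  n <- nrow(pred)
  expect_gt(n, 3L)
  expect_true(all(diff(pred$score) <= 0))
  expect_identical(pred$abs_rank, seq_len(n) - 1L)
  expect_equal(pred$rel_rank, pred$abs_rank / (n - 1))
  expect_true(all(pred$rel_rank >= 0 & pred$rel_rank <= 1))
  expect_equal(pred$rel_rank[1], 0)
  expect_equal(pred$rel_rank[n], 1)
  # scoring through predictSites equals direct scoring of the same pair
  k <- 3L
  f <- featurizePair(s, residueRef(pred$chain1[k], pred$resno1[k]),
                     residueRef(pred$chain2[k], pred$resno2[k]))
  expect_equal(pred$score[k], unname(scoreFeatures(fit, f)), tolerance = 1e-12)
  # predicted flag matches the threshold rule
  expect_identical(pred$predicted,
                   ifelse(pred$score >= classifierConfigOf(fit)$threshold,
                          "bonded", "nonbonded"))
})

test_that("three-record prediction lists get relative ranks 0, 0.5, 1", {
  fit <- sharedCloudModel()
  # three residues in a line, mutually inside the CA window where allowed:
  # place four residues such that exactly three pairs pass the prescreen
  fx <- quietStructure(20, 1, seed = 55)
  s <- readStructure(fx$path)
  pred <- predictSites(s, fit)
  top3 <- pred[1:3, ]
  expect_equal(top3$abs_rank, 0:2)
  # recompute relative ranks for a 3-record report
  rel <- top3$abs_rank / (3 - 1)
  expect_equal(rel, c(0, 0.5, 1))
})

test_that("a planted ideal-geometry pair is ranked first", {
  fit <- sharedCloudModel()
  for (seed in c(61, 62, 63)) {
    fx <- quietStructure(20, 1, seed = seed)
    s <- readStructure(fx$path)
    pred <- predictSites(s, fit)
    expect_equal(c(pred$resno1[1], pred$resno2[1]),
                 c(fx$truth$resno1, fx$truth$resno2))
    expect_equal(pred$predicted[1], "bonded")
  }
})

test_that("reports round-trip through CSV including empty ones", {
  fit <- sharedCloudModel()
  fx <- quietStructure(15, 1, seed = 56)
  s <- readStructure(fx$path)
  pred <- predictSites(s, fit)
  path <- tempfile(fileext = ".csv")
  writeReport(pred, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(pred))
  expect_equal(back$score, pred$score, tolerance = 1e-12)
  expect_identical(back$abs_rank, pred$abs_rank)
  expect_true(all(diff(back$abs_rank) == 1L))
  # zero records: header-only file
  empty <- pred[0, ]
  p0 <- tempfile(fileext = ".csv")
  writeReport(empty, p0)
  back0 <- utils::read.csv(p0)
  expect_equal(nrow(back0), 0L)
  expect_identical(names(back0), names(pred))
  suppressWarnings(
    expect_error(writeReport(pred, file.path(tempdir(), "nope", "x.csv"))))
})

test_that("native-cysteine pairs can be excluded from candidates", {
  fx <- quietStructure(20, 1, seed = 57)
  s <- readStructure(fx$path)
  withCys <- prescreenPairs(enumeratePairs(s), s, prescreenConfig())
  noCys <- prescreenPairs(enumeratePairs(s), s,
                          prescreenConfig(includeNativeCys = FALSE))
  res <- residues(s)
  expect_true(all(res$resid[noCys$i] != "CYS" & res$resid[noCys$j] != "CYS"))
  expect_gte(nrow(withCys), nrow(noCys))
})
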