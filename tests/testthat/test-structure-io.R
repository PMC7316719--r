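test_that("structures round-trip through PDB files at format precision", {
  fx <- quietStructure(12, 1, seed = 3)
  s1 <- readStructure(fx$path)
  expect_equal(nrow(residues(s1)), 12L)
  expect_equal(nrow(ssbonds(s1)), 1L)
  expect_lt(max(abs(atomCoords(s1) - atomCoords(fx$structure))), 1e-3 + 1e-9)

  p2 <- tempfile(fileext = ".pdb")
  writeStructure(s1, p2)
  s2 <- readStructure(p2)
  expect_lt(max(abs(atomCoords(s2) - atomCoords(s1))), 1e-3 + 1e-9)
  expect_equal(residues(s2)$resid, residues(s1)$resid)
  expect_equal(ssbonds(s2), ssbonds(s1))
})

test_that("files without SSBOND records yield an empty bond table", {
  fx <- quietStructure(8, 0, seed = 5)
  s <- readStructure(fx$path)
  expect_equal(nrow(ssbonds(s)), 0L)
  expect_equal(nrow(residues(s)), 8L)
})

test_that("CB reconstruction matches template superposition on perturbed backbones", {
  set.seed(42)
  for (k in 1:50) {
    R <- oracleRotation()
    t0 <- rnorm(3, sd = 20)
    res <- sweep(oracleAlanine %*% t(R), 2, t0, "+")
    # rigidly placed ideal backbone: reconstruction recovers the
    # template's observed CB
    cb <- buildCB(res[1, ], res[2, ], res[3, ])
    expect_lt(sqrt(sum((cb - kabschCB(res[1, ], res[2, ], res[3, ]))^2)), 0.25)
    expect_lt(sqrt(sum((cb - res[5, ])^2)), 0.25)
    # mildly distorted backbone: reconstruction still tracks the
    # superposition oracle
    resN <- res + matrix(rnorm(15, sd = 0.03), 5, 3)
    cbN <- buildCB(resN[1, ], resN[2, ], resN[3, ])
    cbOracle <- kabschCB(resN[1, ], resN[2, ], resN[3, ])
    expect_lt(sqrt(sum((cbN - cbOracle)^2)), 0.25)
  }
})

test_that("CB reconstruction is exactly equivariant under rigid motions", {
  set.seed(7)
  n0 <- oracleAlanine[1, ]; ca0 <- oracleAlanine[2, ]; c0 <- oracleAlanine[3, ]
  cb0 <- buildCB(n0, ca0, c0)
  worst <- 0
  for (k in 1:100) {
    R <- oracleRotation()
    t0 <- rnorm(3, sd = 50)
    cbT <- buildCB(as.numeric(R %*% n0 + t0), as.numeric(R %*% ca0 + t0),
                   as.numeric(R %*% c0 + t0))
    worst <- max(worst, sqrt(sum((cbT - (R %*% cb0 + t0))^2)))
  }
  expect_lt(worst, 1e-9)
})

test_that("degenerate backbones are rejected by CB reconstruction", {
  expect_error(buildCB(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
  expect_error(buildCB(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)))
})

test_that("pairAtoms stacks the ten atoms in the declared order", {
  fx <- quietStructure(6, 0, seed = 9)
  s <- readStructure(fx$path)
  a <- residueRef("A", 2); b <- residueRef("A", 5)
  m <- pairAtoms(s, a, b)
  expect_identical(dim(m), c(10L, 3L))
  expect_true(all(is.finite(m)))
  expect_identical(rownames(m),
                   c("N", "CA", "C", "O", "CB", "Np", "CAp", "Cp", "Op", "CBp"))
  # rows match direct indexing of the coordinate array
  co <- atomCoords(s)
  expect_equal(unname(m[1:5, ]), unname(co[2, , ]))
  expect_equal(unname(m[6:10, ]), unname(co[5, , ]))
  # swapped arguments swap the row blocks
  m2 <- pairAtoms(s, b, a)
  expect_equal(unname(m2[1:5, ]), unname(m[6:10, ]))
  expect_equal(unname(m2[6:10, ]), unname(m[1:5, ]))
  expect_error(pairAtoms(s, residueRef("A", 99), b), "not found")
})

test_that("incomplete residues and dangling SSBOND records are dropped with warnings", {
  # residue 2 lacks its O atom; the SSBOND references a residue not in the
  # coordinate section
  lines <- c(
    "SSBOND   1 CYS A    1    CYS A   50",
    "ATOM      1  N   CYS A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  CYS A   1       1.460   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   CYS A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   CYS A   1       1.500   2.300   0.700  1.00  0.00           O",
    "ATOM      5  CB  CYS A   1       2.000  -0.700  -1.200  1.00  0.00           C",
    "ATOM      6  N   ALA A   2      10.000   0.000   0.000  1.00  0.00           N",
    "ATOM      7  CA  ALA A   2      11.460   0.000   0.000  1.00  0.00           C",
    "ATOM      8  C   ALA A   2      12.000   1.400   0.000  1.00  0.00           C",
    "ATOM      9  CB  ALA A   2      12.000  -0.700  -1.200  1.00  0.00           C",
    "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  expect_warning(expect_warning(s <- readStructure(path), "dropped"),
                 "SSBOND")
  expect_equal(nrow(residues(s)), 1L)
  expect_equal(nrow(ssbonds(s)), 0L)
})

test_that("glycine residues are retained with a reconstructed CB", {
  fx <- quietStructure(10, 0, seed = 13, glycine = 4L)
  s <- readStructure(fx$path)
  res <- residues(s)
  expect_equal(res$resid[4], "GLY")
  expect_equal(res$cb_source[4], "reconstructed")
  expect_true(all(res$cb_source[-4] == "observed"))
  # reconstruction agrees with the CB the generator originally placed
  cbTrue <- atomCoords(fx$structure)[4, "CB", ]
  cbRec <- atomCoords(s)[4, "CB", ]
  expect_lt(sqrt(sum((cbRec - cbTrue)^2)), 0.1)
})

test_that("selenomethionine maps to methionine on read", {
  lines <- c(
    "ATOM      1  N   MSE A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  MSE A   1       1.460   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   MSE A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   MSE A   1       1.500   2.300   0.700  1.00  0.00           O",
    "ATOM      5  CB  MSE A   1       2.000  -0.700  -1.200  1.00  0.00           C",
    "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  s <- readStructure(path)
  expect_equal(residues(s)$resid, "MET")
})
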