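#' Reference to a residue in a structure
#'
#' A lightweight identifier for one residue: chain, author residue number
#' and insertion code. Insertion codes are part of residue identity.
#'
#' @param chain chain identifier (single character string).
#' @param resno author residue number (integer).
#' @param insert insertion code; `""` if none.
#' @return a list of class `ResidueRef` with fields `chain`, `resno`,
#'   `insert`.
#' @examples
#' residueRef("A", 7)
#' @export
residueRef <- function(chain, resno, insert = "") {
  stopifnot(is.character(chain), length(chain) == 1L,
            length(resno) == 1L, is.finite(resno))
  structure(list(chain = chain, resno = as.integer(resno),
                 insert = as.character(insert)),
            class = "ResidueRef")
}

#' @export
format.ResidueRef <- function(x, ...) {
  paste0(x$chain, ":", x$resno, x$insert)
}

#' @export
print.ResidueRef <- function(x, ...) {
  cat("ResidueRef", format(x), "\n")
  invisible(x)
}

.refKey <- function(chain, resno, insert = "") paste(chain, resno, insert)

# index of a residue in the residue table; 0 if absent
.resIndex <- function(x, chain, resno, insert = "") {
  res <- x@residues
  i <- which(res$chain == chain & res$resno == as.integer(resno) &
               res$insert == as.character(insert))
  if (length(i) == 0L) 0L else i[1L]
}

# Compare two refs lexicographically by (chain, resno, insert);
# TRUE if a <= b. Used for the canonical pair ordering.
.refLeq <- function(a, b) {
  if (a$chain != b$chain) return(a$chain < b$chain)
  if (a$resno != b$resno) return(a$resno < b$resno)
  a$insert <= b$insert
}

#' Order a residue pair canonically
#'
#' Residue pairs have no intrinsic order; for reproducible features the
#' residue with the lexicographically smaller (chain, resno, insert) comes
#' first. The classifier additionally symmetrizes over both orders, so the
#' convention only fixes serialization, not predictions.
#'
#' @param a,b `ResidueRef` objects.
#' @return list with elements `a`, `b` in canonical order.
#' @export
canonicalPair <- function(a, b) {
  if (.refLeq(a, b)) list(a = a, b = b) else list(a = b, b = a)
}

# Ideal alanine template (chemical component dictionary ideal coordinates,
# L-configuration). Rows N, CA, C, O, CB. Used for CB reconstruction checks
# and by the synthetic generator.
.ALA_TEMPLATE <- matrix(c(
  -0.966,  0.493,  1.500,
   0.257,  0.418,  0.692,
  -0.094,  0.017, -0.716,
  -1.056, -0.682, -0.923,
   1.204, -0.620,  1.296
), nrow = 5, byrow = TRUE,
  dimnames = list(c("N", "CA", "C", "O", "CB"), c("x", "y", "z")))

.CB_BOND_LENGTH <- 1.53       # Angstrom, CA-CB
.CB_ANGLE <- 109.47 * pi / 180  # tetrahedral N-CA-CB and C-CA-CB

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-8) stop("degenerate zero-length vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Reconstruct an ideal beta-carbon from backbone atoms
#'
#' Places CB at 1.53 A from CA with tetrahedral N-CA-CB and C-CA-CB angles
#' and L-amino-acid chirality. Used for glycine (which has no CB) so that
#' glycine positions can be treated as alanine-like mutation candidates,
#' and by the synthetic generator's self-consistency checks. The placement
#' is exactly equivariant under rigid-body motions of the backbone.
#'
#' @param n,ca,c numeric 3-vectors: coordinates of the backbone N, CA and
#'   C atoms in Angstrom.
#' @return numeric 3-vector, the ideal CB position.
#' @examples
#' buildCB(c(-0.966, 0.493, 1.5), c(0.257, 0.418, 0.692),
#'         c(-0.094, 0.017, -0.716))
#' @export
buildCB <- function(n, ca, c) {
  stopifnot(length(n) == 3L, length(ca) == 3L, length(c) == 3L,
            all(is.finite(c(n, ca, c))))
  u <- .unit(n - ca)   # CA -> N
  v <- .unit(c - ca)   # CA -> C
  perp <- .cross3(u, v)
  np <- sqrt(sum(perp^2))
  if (np < 1e-6) stop("collinear backbone atoms: cannot place CB")
  perp <- perp / np
  bis <- .unit(u + v)
  # CB direction d satisfies d.u = d.v = cos(tetrahedral); decompose in the
  # (bisector, plane-normal) basis. Sign of the normal component fixes
  # L-chirality (same side as natural residues).
  half <- sum(bis * u)               # cos of half the N-CA-C angle
  a_comp <- cos(.CB_ANGLE) / half
  if (a_comp^2 >= 1) stop("degenerate backbone geometry: cannot place CB")
  b_comp <- sqrt(1 - a_comp^2)
  d <- a_comp * bis + b_comp * perp
  as.numeric(ca + .CB_BOND_LENGTH * d)
}

# Parse SSBOND records from raw PDB lines (fixed-column format).
# bio3d does not expose SSBOND records, so these six fields are read here.
.parseSSBondLines <- function(lines) {
  sb <- lines[startsWith(lines, "SSBOND")]
  if (length(sb) == 0L) {
    return(data.frame(chain1 = character(), resno1 = integer(),
                      insert1 = character(), chain2 = character(),
                      resno2 = integer(), insert2 = character(),
                      stringsAsFactors = FALSE))
  }
  fld <- function(x, a, b) trimws(substr(x, a, b))
  data.frame(
    chain1 = fld(sb, 16, 16), resno1 = as.integer(fld(sb, 18, 21)),
    insert1 = fld(sb, 22, 22), chain2 = fld(sb, 30, 30),
    resno2 = as.integer(fld(sb, 32, 35)), insert2 = fld(sb, 36, 36),
    stringsAsFactors = FALSE
  )
}

#' Read a protein structure from a PDB file
#'
#' Parses coordinates with \pkg{bio3d}, keeps per residue the five heavy
#' atoms N, CA, C, O, CB, and extracts SSBOND records. Residues missing
#' any backbone atom (N, CA, C, O) are dropped with a warning, as are
#' non-glycine residues missing CB. Glycine residues are retained with a
#' CB reconstructed from the backbone ([buildCB()]). Common modified
#' residues (e.g. selenomethionine) are mapped to their parent standard
#' residue; other non-standard residues are dropped. For multi-model
#' (NMR) files only the requested model is used; alternate locations keep
#' conformer A.
#'
#' @param path path to a PDB file.
#' @param model model number for multi-model files (default 1, the first).
#' @param id identifier stored in the result; defaults to the file stem.
#' @return a [ProteinStructure-class] object. SSBOND records referencing
#'   residues absent from the coordinate section are dropped with a
#'   warning.
#' @examples
#' pdb <- makeStructure(nResidues = 8, nBonds = 1, seed = 1,
#'                      path = tempfile(fileext = ".pdb"))
#' s <- readStructure(pdb$path)
#' s
#' @export
readStructure <- function(path, model = 1L, id = NULL) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = (model > 1L), rm.alt = TRUE, verbose = FALSE),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e))
  )
  atoms <- pdb$atom
  if (model > 1L) {
    # bio3d keeps the atom table of model 1 and stacks coordinates in xyz
    if (nrow(pdb$xyz) < model) stop("model ", model, " not present in ", path)
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  }
  if (nrow(atoms) == 0L) stop("empty coordinate section in ", path)

  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$chain[is.na(atoms$chain)] <- ""
  mapped <- .NONSTANDARD_MAP[atoms$resid]
  atoms$resid <- ifelse(is.na(mapped), atoms$resid, unname(mapped))
  atoms <- atoms[atoms$resid %in% .STANDARD_AA &
                   atoms$elety %in% .ATOMS, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no standard amino-acid atoms found in ", path)

  key <- paste(atoms$chain, atoms$resno, atoms$insert)
  ukey <- unique(key)
  n <- length(ukey)
  coords <- array(NA_real_, dim = c(n, 5L, 3L),
                  dimnames = list(NULL, .ATOMS, c("x", "y", "z")))
  res <- data.frame(chain = character(n), resno = integer(n),
                    insert = character(n), resid = character(n),
                    cb_source = rep("observed", n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    rows <- atoms[key == ukey[i], , drop = FALSE]
    res$chain[i] <- rows$chain[1]; res$resno[i] <- rows$resno[1]
    res$insert[i] <- rows$insert[1]; res$resid[i] <- rows$resid[1]
    for (a in .ATOMS) {
      hit <- which(rows$elety == a)
      if (length(hit)) {
        coords[i, a, ] <- as.numeric(rows[hit[1L], c("x", "y", "z")])
      }
    }
  }

  backbone_ok <- apply(coords[, c("N", "CA", "C", "O"), , drop = FALSE], 1,
                       function(m) all(is.finite(m)))
  has_cb <- apply(coords[, "CB", , drop = FALSE], 1,
                  function(m) all(is.finite(m)))
  keep <- backbone_ok & (has_cb | res$resid == "GLY")
  # reconstruct CB for glycine (and note the source)
  gly <- which(keep & !has_cb)
  for (i in gly) {
    cb <- tryCatch(buildCB(coords[i, "N", ], coords[i, "CA", ], coords[i, "C", ]),
                   error = function(e) NULL)
    if (is.null(cb)) keep[i] <- FALSE else {
      coords[i, "CB", ] <- cb
      res$cb_source[i] <- "reconstructed"
    }
  }
  if (any(!keep)) {
    warning(sum(!keep), " residue(s) dropped in '", id,
            "' (incomplete N/CA/C/O/CB atom block)")
  }
  res <- res[keep, , drop = FALSE]
  coords <- coords[keep, , , drop = FALSE]
  if (nrow(res) == 0L) stop("no usable residues in ", path)

  o <- order(res$chain, res$resno, res$insert)
  res <- res[o, , drop = FALSE]
  coords <- coords[o, , , drop = FALSE]
  rownames(res) <- NULL

  sb <- .parseSSBondLines(lines)
  if (nrow(sb) > 0) {
    have <- paste(res$chain, res$resno, res$insert)
    ok <- paste(sb$chain1, sb$resno1, sb$insert1) %in% have &
      paste(sb$chain2, sb$resno2, sb$insert2) %in% have
    if (any(!ok)) {
      warning(sum(!ok), " SSBOND record(s) in '", id,
              "' reference residues absent from the model; dropped")
    }
    sb <- sb[ok, , drop = FALSE]
    # canonical storage: lexicographically smaller residue first
    for (k in seq_len(nrow(sb))) {
      a <- residueRef(sb$chain1[k], sb$resno1[k], sb$insert1[k])
      b <- residueRef(sb$chain2[k], sb$resno2[k], sb$insert2[k])
      p <- canonicalPair(a, b)
      sb[k, ] <- list(p$a$chain, p$a$resno, p$a$insert,
                      p$b$chain, p$b$resno, p$b$insert)
    }
    rownames(sb) <- NULL
  }

  new("ProteinStructure", id = id, residues = res, coords = coords,
      ssbonds = sb)
}

#' Write a ProteinStructure to a PDB file
#'
#' Emits SSBOND records followed by ATOM records for the five stored atoms
#' of each residue, at the format's three-decimal coordinate precision.
#' Round-tripping through [readStructure()] reproduces coordinates to
#' 1e-3 A.
#'
#' @param x a [ProteinStructure-class] object.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeStructure <- function(x, path) {
  stopifnot(is(x, "ProteinStructure"))
  res <- x@residues
  con <- file(path, "w")
  on.exit(close(con))
  sb <- x@ssbonds
  for (k in seq_len(nrow(sb))) {
    i1 <- .resIndex(x, sb$chain1[k], sb$resno1[k], sb$insert1[k])
    i2 <- .resIndex(x, sb$chain2[k], sb$resno2[k], sb$insert2[k])
    writeLines(sprintf("SSBOND %3d %3s %1s %4d%1s   %3s %1s %4d%1s",
                       k, res$resid[i1], sb$chain1[k], sb$resno1[k],
                       ifelse(sb$insert1[k] == "", " ", sb$insert1[k]),
                       res$resid[i2], sb$chain2[k], sb$resno2[k],
                       ifelse(sb$insert2[k] == "", " ", sb$insert2[k])), con)
  }
  serial <- 0L
  for (i in seq_len(nrow(res))) {
    for (a in .ATOMS) {
      serial <- serial + 1L
      name4 <- sprintf(" %-3s", a)   # element right of column 13 for C/N/O
      writeLines(sprintf("ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                         serial, name4, res$resid[i], res$chain[i],
                         res$resno[i],
                         ifelse(res$insert[i] == "", " ", res$insert[i]),
                         x@coords[i, a, 1], x@coords[i, a, 2],
                         x@coords[i, a, 3], 1.0, 0.0,
                         substr(a, 1, 1)), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Stack the ten atoms of a residue pair
#'
#' Returns the 10 x 3 coordinate block for a residue pair in the fixed
#' atom order N, CA, C, O, CB of the first residue followed by N', CA',
#' C', O', CB' of the second. Row order follows the argument order; see
#' [canonicalPair()] for the canonical convention used by the sampling
#' code.
#'
#' @param x a [ProteinStructure-class] object.
#' @param a,b `ResidueRef` objects present in `x`.
#' @return numeric 10 x 3 matrix with rownames
#'   `N, CA, C, O, CB, Np, CAp, Cp, Op, CBp`.
#' @export
pairAtoms <- function(x, a, b) {
  stopifnot(is(x, "ProteinStructure"))
  ia <- .resIndex(x, a$chain, a$resno, a$insert)
  ib <- .resIndex(x, b$chain, b$resno, b$insert)
  if (ia == 0L) stop("residue ", format(a), " not found in structure '",
                     x@id, "'")
  if (ib == 0L) stop("residue ", format(b), " not found in structure '",
                     x@id, "'")
  m <- rbind(x@coords[ia, , ], x@coords[ib, , ])
  rownames(m) <- c(.ATOMS, paste0(.ATOMS, "p"))
  colnames(m) <- c("x", "y", "z")
  m
}
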