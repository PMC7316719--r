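# One labelled residue-pair sample: refs, 10x3 coords (canonical order),
# label, provenance.
.makeSample <- function(structureId, a, b, coords, label, origin) {
  structure(list(structureId = structureId, a = a, b = b, coords = coords,
                 label = as.integer(label), origin = origin),
            class = "ResiduePairSample")
}

#' @export
print.ResiduePairSample <- function(x, ...) {
  cat("ResiduePairSample", format(x$a), "-", format(x$b),
      if (x$label == 1L) "(bonded)" else "(non-bonded)",
      "from", x$structureId, "\n")
  invisible(x)
}

#' Extract positive (disulfide-bonded) samples from a structure
#'
#' One sample per SSBOND record whose two residues both carry complete
#' five-atom blocks. Residue order within a sample is canonical
#' ([canonicalPair()]).
#'
#' @param x a [ProteinStructure-class] object.
#' @return list of `ResiduePairSample` objects with label 1.
#' @export
extractPositives <- function(x) {
  stopifnot(is(x, "ProteinStructure"))
  sb <- x@ssbonds
  out <- vector("list", nrow(sb))
  for (k in seq_len(nrow(sb))) {
    a <- residueRef(sb$chain1[k], sb$resno1[k], sb$insert1[k])
    b <- residueRef(sb$chain2[k], sb$resno2[k], sb$insert2[k])
    coords <- tryCatch(pairAtoms(x, a, b), error = function(e) NULL)
    if (is.null(coords)) {
      warning("skipping unusable disulfide ", format(a), "-", format(b),
              " in '", x@id, "'")
      next
    }
    out[[k]] <- .makeSample(x@id, a, b, coords, 1L,
                            paste0("SSBOND ", format(a), "-", format(b)))
  }
  out[!vapply(out, is.null, logical(1))]
}

# sequence neighbours of a residue: adjacency in the sorted residue list
# of its own chain (numbering gaps still count as neighbours)
.chainNeighbors <- function(x, ref) {
  res <- x@residues
  idx <- which(res$chain == ref$chain)
  pos <- match(.refKey(ref$chain, ref$resno, ref$insert),
               .refKey(res$chain[idx], res$resno[idx], res$insert[idx]))
  if (is.na(pos)) return(list(prev = NULL, nxt = NULL))
  mk <- function(i) {
    if (i < 1L || i > length(idx)) return(NULL)
    j <- idx[i]
    residueRef(res$chain[j], res$resno[j], res$insert[j])
  }
  list(prev = mk(pos - 1L), nxt = mk(pos + 1L))
}

.isSSBonded <- function(x, a, b) {
  sb <- x@ssbonds
  if (nrow(sb) == 0L) return(FALSE)
  p <- canonicalPair(a, b)
  any(sb$chain1 == p$a$chain & sb$resno1 == p$a$resno &
        sb$insert1 == p$a$insert & sb$chain2 == p$b$chain &
        sb$resno2 == p$b$resno & sb$insert2 == p$b$insert)
}

#' Derive the negative sample paired with a disulfide bond
#'
#' For a bond between residues C_i and C_j, the candidates are the four
#' crossing pairs of their sequence neighbours: (i-1, j-1), (i-1, j+1),
#' (i+1, j-1), (i+1, j+1), neighbours taken within each residue's own
#' chain. The candidate with the shortest CA-CA distance whose residues
#' both carry complete atom blocks becomes the negative sample; ties keep
#' the first candidate in the order above. Candidates that are themselves
#' disulfide-bonded in the structure are excluded.
#'
#' @param x a [ProteinStructure-class] object.
#' @param bond one row of `ssbonds(x)` (list or single-row data.frame).
#' @return a `ResiduePairSample` with label 0, or `NULL` when no crossing
#'   pair is usable (e.g. both cysteines at chain termini).
#' @export
deriveNegative <- function(x, bond) {
  stopifnot(is(x, "ProteinStructure"))
  a <- residueRef(bond$chain1, bond$resno1, bond$insert1)
  b <- residueRef(bond$chain2, bond$resno2, bond$insert2)
  na <- .chainNeighbors(x, a)
  nb <- .chainNeighbors(x, b)
  cands <- list(
    list(na$prev, nb$prev), list(na$prev, nb$nxt),
    list(na$nxt, nb$prev), list(na$nxt, nb$nxt)
  )
  best <- NULL
  bestD <- Inf
  for (cand in cands) {
    p <- cand[[1]]; q <- cand[[2]]
    if (is.null(p) || is.null(q)) next
    if (identical(.refKey(p$chain, p$resno, p$insert),
                  .refKey(q$chain, q$resno, q$insert))) next
    if (.isSSBonded(x, p, q)) next
    ip <- .resIndex(x, p$chain, p$resno, p$insert)
    iq <- .resIndex(x, q$chain, q$resno, q$insert)
    if (ip == 0L || iq == 0L) next
    d <- sqrt(sum((x@coords[ip, "CA", ] - x@coords[iq, "CA", ])^2))
    if (d < bestD) {
      bestD <- d
      best <- list(p = p, q = q)
    }
  }
  if (is.null(best)) return(NULL)
  pc <- canonicalPair(best$p, best$q)
  .makeSample(x@id, pc$a, pc$b, pairAtoms(x, pc$a, pc$b), 0L,
              paste0("neighbor-of SSBOND ", format(a), "-", format(b)))
}

#' Assemble a labelled train/test dataset from structures
#'
#' Extracts one positive sample per disulfide bond and one derived
#' negative per bond ([deriveNegative()]), featurizes every sample, and
#' assigns a seeded uniform random train/test split at the sample level.
#' Bonds whose negative derivation fails leave the dataset slightly
#' imbalanced; a warning reports the deficit.
#'
#' @param structures list of [ProteinStructure-class] objects.
#' @param testFraction fraction of samples assigned to the test split
#'   (default 0.24, the proportion used for the natural-bond benchmark).
#' @param seed integer seed controlling the split.
#' @return a [PairDataset-class] object.
#' @export
assembleDataset <- function(structures, testFraction = 0.24, seed = 1L) {
  if (length(structures) == 0L) stop("no structures supplied")
  stopifnot(testFraction > 0, testFraction < 1)
  samples <- list()
  for (s in structures) {
    pos <- extractPositives(s)
    samples <- c(samples, pos)
    sb <- s@ssbonds
    for (k in seq_len(nrow(sb))) {
      neg <- deriveNegative(s, sb[k, ])
      if (!is.null(neg)) samples <- c(samples, list(neg))
    }
  }
  if (length(samples) == 0L) stop("no usable samples in the supplied structures")
  datasetFromSamples(samples, testFraction = testFraction, seed = seed)
}

#' Build a PairDataset from a list of samples
#'
#' @param samples list of `ResiduePairSample` objects.
#' @param testFraction,seed see [assembleDataset()].
#' @return a [PairDataset-class] object.
#' @export
datasetFromSamples <- function(samples, testFraction = 0.24, seed = 1L) {
  n <- length(samples)
  stopifnot(n > 0L)
  feat <- t(vapply(samples,
                   function(s) flattenDistances(distanceMatrix(s$coords)),
                   numeric(45)))
  colnames(feat) <- featureNames()
  labels <- vapply(samples, function(s) s$label, integer(1))
  info <- do.call(rbind, lapply(samples, function(s) {
    data.frame(structure_id = s$structureId,
               chain1 = s$a$chain, resno1 = s$a$resno, insert1 = s$a$insert,
               chain2 = s$b$chain, resno2 = s$b$resno, insert2 = s$b$insert,
               origin = s$origin, stringsAsFactors = FALSE)
  }))
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos != nneg) {
    warning("dataset imbalance: ", npos, " positive vs ", nneg,
            " negative samples")
  }
  split <- .seededSplit(n, testFraction, seed)
  new("PairDataset", features = feat, labels = labels, sampleInfo = info,
      split = split)
}

# seeded uniform split without disturbing the caller's RNG state
.seededSplit <- function(n, testFraction, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  nTest <- round(n * testFraction)
  split <- rep("train", n)
  split[sample.int(n, nTest)] <- "test"
  split
}

#' Filter structure metadata by resolution and R-factor
#'
#' Keeps entries with resolution strictly better than `maxResolution` and
#' R-factor strictly below `maxRfactor`; entries lacking either value are
#' excluded. Defaults are the curation thresholds used for
#' sequence-identity-pruned training corpora (resolution better than
#' 2.0 A, R-factor below 0.25).
#'
#' @param entries data.frame with columns `resolution` and `rfactor`
#'   (NA where unknown); other columns pass through.
#' @param maxResolution resolution cutoff in Angstrom (strict).
#' @param maxRfactor R-factor cutoff (strict).
#' @return the filtered data.frame.
#' @export
curateFilter <- function(entries, maxResolution = 2.0, maxRfactor = 0.25) {
  stopifnot(is.data.frame(entries),
            all(c("resolution", "rfactor") %in% names(entries)))
  keep <- !is.na(entries$resolution) & !is.na(entries$rfactor) &
    entries$resolution < maxResolution & entries$rfactor < maxRfactor
  entries[keep, , drop = FALSE]
}

#' Write / read a PairDataset as CSV
#'
#' One row per sample: provenance columns, `label`, `split`, then the 45
#' feature columns in flattening order ([featureNames()]).
#'
#' @param x a [PairDataset-class] object.
#' @param path CSV file path.
#' @return `writeDataset`: invisibly, `path`. `readDataset`: the restored
#'   [PairDataset-class].
#' @export
writeDataset <- function(x, path) {
  stopifnot(is(x, "PairDataset"))
  df <- cbind(x@sampleInfo, label = x@labels, split = x@split,
              as.data.frame(x@features))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDataset
#' @export
readDataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fn <- featureNames()
  if (!all(fn %in% names(df))) stop("missing feature columns in ", path)
  feat <- as.matrix(df[, fn])
  info <- df[, setdiff(names(df), c(fn, "label", "split")), drop = FALSE]
  info$insert1 <- as.character(ifelse(is.na(info$insert1), "", info$insert1))
  info$insert2 <- as.character(ifelse(is.na(info$insert2), "", info$insert2))
  new("PairDataset", features = feat, labels = as.integer(df$label),
      sampleInfo = info, split = as.character(df$split))
}

#' Combine PairDatasets
#'
#' Row-binds the samples of several datasets (e.g. structure-derived
#' samples plus a synthetic benchmark), keeping each sample's split
#' assignment.
#'
#' @param ... [PairDataset-class] objects.
#' @return a single [PairDataset-class].
#' @export
combineDatasets <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) > 0L,
            all(vapply(parts, function(p) is(p, "PairDataset"), logical(1))))
  new("PairDataset",
      features = do.call(rbind, lapply(parts, function(p) p@features)),
      labels = unlist(lapply(parts, function(p) p@labels)),
      sampleInfo = do.call(rbind, lapply(parts, function(p) p@sampleInfo)),
      split = unlist(lapply(parts, function(p) p@split)))
}
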