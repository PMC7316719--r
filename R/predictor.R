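#' Prescreen configuration for candidate pairs
#'
#' Before scoring, candidate pairs are filtered by the CA-CA distance
#' window observed for natural disulfide bonds (3.0 to 7.5 A) and by a
#' minimal sequence separation that excludes trivially adjacent pairs
#' (adjacent disulfides are vanishingly rare). Set
#' `minSequenceSeparation = 0` to disable the separation filter.
#'
#' @param caMin,caMax CA-CA distance window in Angstrom (defaults 3.0 and
#'   7.5).
#' @param minSequenceSeparation minimal |sequence-position difference|
#'   within a chain (default 2); inter-chain pairs always pass.
#' @param includeNativeCys keep pairs involving native cysteines
#'   (default TRUE; an engineered cysteine may bond a native one).
#' @return a list with class `PrescreenConfig`.
#' @export
prescreenConfig <- function(caMin = 3.0, caMax = 7.5,
                            minSequenceSeparation = 2L,
                            includeNativeCys = TRUE) {
  stopifnot(caMin > 0, caMin < caMax, minSequenceSeparation >= 0L)
  structure(list(caMin = caMin, caMax = caMax,
                 minSequenceSeparation = as.integer(minSequenceSeparation),
                 includeNativeCys = isTRUE(includeNativeCys)),
            class = "PrescreenConfig")
}

#' Enumerate all candidate residue pairs of a structure
#'
#' All unordered pairs over the usable residues of all chains: n residues
#' yield n(n-1)/2 pairs.
#'
#' @param x a [ProteinStructure-class] object.
#' @return data.frame with integer columns `i`, `j` (row indices into
#'   `residues(x)`, `i < j`).
#' @export
enumeratePairs <- function(x) {
  stopifnot(is(x, "ProteinStructure"))
  n <- nrow(x@residues)
  if (n < 2L) {
    return(data.frame(i = integer(), j = integer()))
  }
  idx <- t(utils::combn(n, 2L))
  data.frame(i = idx[, 1], j = idx[, 2])
}

# per-chain sequence position of every residue (1-based within chain)
.seqPositions <- function(x) {
  res <- x@residues
  pos <- integer(nrow(res))
  for (ch in unique(res$chain)) {
    sel <- which(res$chain == ch)
    pos[sel] <- seq_along(sel)   # residues already sorted within chain
  }
  pos
}

#' Filter candidate pairs by CA distance and sequence separation
#'
#' @param pairs data.frame of `i`, `j` residue indices
#'   (from [enumeratePairs()]).
#' @param x the [ProteinStructure-class] the indices refer to.
#' @param config a `PrescreenConfig` ([prescreenConfig()]).
#' @return the subset of `pairs` whose CA-CA distance lies within
#'   `[caMin, caMax]` (inclusive) and which are either inter-chain or
#'   separated by at least `minSequenceSeparation` positions in sequence,
#'   with an added numeric column `ca_distance`.
#' @export
prescreenPairs <- function(pairs, x, config = prescreenConfig()) {
  stopifnot(is(x, "ProteinStructure"), inherits(config, "PrescreenConfig"))
  if (nrow(pairs) == 0L) {
    pairs$ca_distance <- numeric(0)
    return(pairs)
  }
  ca <- matrix(x@coords[, "CA", ], ncol = 3L)
  d <- sqrt(rowSums((ca[pairs$i, , drop = FALSE] -
                       ca[pairs$j, , drop = FALSE])^2))
  res <- x@residues
  pos <- .seqPositions(x)
  sameChain <- res$chain[pairs$i] == res$chain[pairs$j]
  sep <- abs(pos[pairs$i] - pos[pairs$j])
  keep <- d >= config$caMin & d <= config$caMax &
    (!sameChain | sep >= config$minSequenceSeparation)
  if (!config$includeNativeCys) {
    keep <- keep & res$resid[pairs$i] != "CYS" & res$resid[pairs$j] != "CYS"
  }
  out <- pairs[keep, , drop = FALSE]
  out$ca_distance <- d[keep]
  rownames(out) <- NULL
  out
}

#' Predict and rank disulfide engineering sites in a structure
#'
#' Enumerates all residue pairs, applies the CA-distance prescreen,
#' featurizes each surviving pair (glycines use their reconstructed CB,
#' i.e. are treated as alanine-substituted), scores them with the trained
#' network, and returns records sorted by descending score. The absolute
#' rank starts at 0 for the top-scoring pair; the relative rank is
#' `abs_rank / (total - 1)` (0 when only one prediction is made). Score
#' ties are broken by the (chain, residue number) of the first residue.
#'
#' @param x a [ProteinStructure-class] object.
#' @param model a trained [DisulfideClassifier-class].
#' @param config a `PrescreenConfig` ([prescreenConfig()]).
#' @return data.frame with one row per scored pair: `chain1`, `resno1`,
#'   `insert1`, `wt1` (wild-type 3-letter code), the same for the second
#'   residue, `ca_distance`, `score`, `predicted`
#'   (`"bonded"`/`"nonbonded"` at the model threshold), `abs_rank`,
#'   `rel_rank`.
#' @examples
#' ds <- makeFeatureClouds(500, seed = 1)
#' fit <- trainClassifier(ds, classifierConfig(seed = 1))
#' pdb <- makeStructure(nResidues = 12, nBonds = 1, seed = 2,
#'                      path = tempfile(fileext = ".pdb"))
#' s <- readStructure(pdb$path)
#' head(predictSites(s, fit))
#' @export
predictSites <- function(x, model, config = prescreenConfig()) {
  stopifnot(is(x, "ProteinStructure"), is(model, "DisulfideClassifier"))
  pairs <- prescreenPairs(enumeratePairs(x), x, config)
  res <- x@residues
  n <- nrow(pairs)
  if (n == 0L) {
    return(data.frame(chain1 = character(), resno1 = integer(),
                      insert1 = character(), wt1 = character(),
                      chain2 = character(), resno2 = integer(),
                      insert2 = character(), wt2 = character(),
                      ca_distance = numeric(), score = numeric(),
                      predicted = character(), abs_rank = integer(),
                      rel_rank = numeric(), stringsAsFactors = FALSE))
  }
  feat <- matrix(NA_real_, n, 45L)
  for (k in seq_len(n)) {
    # residues are stored sorted, so i < j is already the canonical order
    m <- rbind(x@coords[pairs$i[k], , ], x@coords[pairs$j[k], , ])
    feat[k, ] <- flattenDistances(distanceMatrix(m))
  }
  score <- scoreFeatures(model, feat)
  out <- data.frame(
    chain1 = res$chain[pairs$i], resno1 = res$resno[pairs$i],
    insert1 = res$insert[pairs$i], wt1 = res$resid[pairs$i],
    chain2 = res$chain[pairs$j], resno2 = res$resno[pairs$j],
    insert2 = res$insert[pairs$j], wt2 = res$resid[pairs$j],
    ca_distance = pairs$ca_distance, score = score,
    stringsAsFactors = FALSE
  )
  o <- order(-out$score, out$chain1, out$resno1, out$insert1,
             out$chain2, out$resno2, out$insert2)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out$predicted <- ifelse(out$score >= model@config$threshold,
                          "bonded", "nonbonded")
  out$abs_rank <- seq_len(n) - 1L
  out$rel_rank <- if (n > 1L) out$abs_rank / (n - 1L) else 0
  out
}

#' Write a prediction report to CSV
#'
#' One row per prediction in rank order, with the columns of
#' [predictSites()]. A run with zero predictions writes a header-only
#' file.
#'
#' @param records data.frame from [predictSites()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeReport <- function(records, path) {
  stopifnot(is.data.frame(records))
  tryCatch(utils::write.csv(records, path, row.names = FALSE),
           error = function(e) stop("cannot write report to '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}
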