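#' @import methods
NULL

# Atom order used throughout: the five heavy atoms retained per residue.
# Sgamma is deliberately excluded: its coordinates do not exist for
# candidate (non-cysteine) residues, and S-S distances would dominate the
# classifier.
.ATOMS <- c("N", "CA", "C", "O", "CB")

.STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# Common modified residues mapped to their parent standard residue.
.NONSTANDARD_MAP <- c(
  MSE = "MET", SEC = "CYS", CSO = "CYS", CME = "CYS", OCS = "CYS",
  PYL = "LYS", MLY = "LYS", KCX = "LYS", LLP = "LYS",
  SEP = "SER", TPO = "THR", PTR = "TYR", HYP = "PRO",
  HIC = "HIS", NEP = "HIS", MLZ = "LYS", PCA = "GLU"
)

#' ProteinStructure: residue-level view of a protein structure
#'
#' Holds, for every usable residue, the coordinates of the five heavy atoms
#' (N, CA, C, O, CB) plus the disulfide bonds declared in the source file.
#' Residues with an incomplete backbone are dropped at read time; glycine
#' CB atoms are reconstructed from the backbone with ideal geometry.
#'
#' @slot id single identifier string (file stem or PDB id).
#' @slot residues data.frame with one row per residue: `chain`, `resno`
#'   (author numbering), `insert` (insertion code, `""` if none), `resid`
#'   (3-letter amino-acid code) and `cb_source` (`"observed"` or
#'   `"reconstructed"`).
#' @slot coords numeric array of dimension `c(nres, 5, 3)`; second margin
#'   is the atom in the order N, CA, C, O, CB.
#' @slot ssbonds data.frame of disulfide bonds with columns `chain1`,
#'   `resno1`, `insert1`, `chain2`, `resno2`, `insert2`, stored with the
#'   lexicographically smaller (chain, resno, insert) first.
#'
#' @seealso [readStructure()], [writeStructure()], [pairAtoms()]
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  slots = c(
    id = "character",
    residues = "data.frame",
    coords = "array",
    ssbonds = "data.frame"
  )
)

setValidity("ProteinStructure", function(object) {
  msgs <- character()
  res <- object@residues
  need <- c("chain", "resno", "insert", "resid", "cb_source")
  if (!all(need %in% names(res))) {
    return(paste("residues must have columns", paste(need, collapse = ", ")))
  }
  if (length(dim(object@coords)) != 3L ||
      dim(object@coords)[2] != 5L || dim(object@coords)[3] != 3L) {
    msgs <- c(msgs, "coords must be an nres x 5 x 3 array")
  } else if (dim(object@coords)[1] != nrow(res)) {
    msgs <- c(msgs, "coords and residues disagree on residue count")
  }
  if (nrow(res) > 0) {
    if (!all(is.finite(object@coords))) {
      msgs <- c(msgs, "all coordinates must be finite")
    }
    key <- paste(res$chain, res$resno, res$insert)
    if (anyDuplicated(key)) {
      msgs <- c(msgs, "duplicate residue identifiers")
    }
    if (!all(res$resid %in% .STANDARD_AA)) {
      msgs <- c(msgs, "resid must be a standard 3-letter amino-acid code")
    }
    # residues sorted by chain then residue number then insertion code
    o <- order(res$chain, res$resno, res$insert)
    if (!identical(o, seq_len(nrow(res)))) {
      msgs <- c(msgs, "residues must be sorted by (chain, resno, insert)")
    }
  }
  sb <- object@ssbonds
  needb <- c("chain1", "resno1", "insert1", "chain2", "resno2", "insert2")
  if (!all(needb %in% names(sb))) {
    msgs <- c(msgs, paste("ssbonds must have columns",
                          paste(needb, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' PairDataset: labelled residue-pair samples for classifier training
#'
#' A balanced (or near-balanced) set of residue pairs, each represented by
#' its 45-dimensional pairwise-distance feature vector, a bonded (1) /
#' non-bonded (0) label, per-sample provenance, and a train/test split
#' assignment.
#'
#' @slot features numeric matrix, one row per sample, 45 columns named as
#'   by [featureNames()].
#' @slot labels integer vector of 0/1 labels, one per sample.
#' @slot sampleInfo data.frame of per-sample provenance (structure id,
#'   residue identifiers, origin tag); one row per sample.
#' @slot split character vector, `"train"` or `"test"` per sample.
#'
#' @seealso [assembleDataset()], [makeFeatureClouds()], [trainClassifier()]
#' @exportClass PairDataset
setClass("PairDataset",
  slots = c(
    features = "matrix",
    labels = "integer",
    sampleInfo = "data.frame",
    split = "character"
  )
)

setValidity("PairDataset", function(object) {
  msgs <- character()
  n <- nrow(object@features)
  if (ncol(object@features) != 45L) {
    msgs <- c(msgs, "features must have exactly 45 columns")
  }
  if (length(object@labels) != n) msgs <- c(msgs, "labels length != sample count")
  if (nrow(object@sampleInfo) != n) msgs <- c(msgs, "sampleInfo rows != sample count")
  if (length(object@split) != n) msgs <- c(msgs, "split length != sample count")
  if (n > 0) {
    if (!all(object@labels %in% c(0L, 1L))) msgs <- c(msgs, "labels must be 0 or 1")
    if (!all(object@split %in% c("train", "test"))) {
      msgs <- c(msgs, "split entries must be 'train' or 'test'")
    }
    if (!all(is.finite(object@features))) msgs <- c(msgs, "features must be finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' DisulfideClassifier: the trained fully connected network
#'
#' A 45-128-32-1 fully connected network with ReLU hidden activations and
#' a logistic output, together with its training configuration and
#' per-epoch training log. Scores are order-symmetric: a pair is scored in
#' both residue orientations and the two scores are averaged.
#'
#' @slot config list as produced by [classifierConfig()].
#' @slot weights list of weight matrices and bias vectors
#'   (`W1`, `b1`, `W2`, `b2`, `W3`, `b3`).
#' @slot trainingLog data.frame with one row per epoch: `epoch`, `loss`
#'   (mean binary cross-entropy), `accuracy` (training accuracy at the
#'   decision threshold).
#'
#' @seealso [trainClassifier()], [scoreFeatures()], [saveClassifier()]
#' @exportClass DisulfideClassifier
setClass("DisulfideClassifier",
  slots = c(
    config = "list",
    weights = "list",
    trainingLog = "data.frame"
  )
)

setValidity("DisulfideClassifier", function(object) {
  msgs <- character()
  sz <- object@config$layerSizes
  w <- object@weights
  if (!identical(sort(names(w)), sort(c("W1", "b1", "W2", "b2", "W3", "b3")))) {
    return("weights must contain W1,b1,W2,b2,W3,b3")
  }
  for (k in 1:3) {
    W <- w[[paste0("W", k)]]
    b <- w[[paste0("b", k)]]
    if (!identical(dim(W), as.integer(c(sz[k], sz[k + 1])))) {
      msgs <- c(msgs, sprintf("W%d has wrong shape", k))
    }
    if (length(b) != sz[k + 1]) msgs <- c(msgs, sprintf("b%d has wrong length", k))
  }
  thr <- object@config$threshold
  if (!is.numeric(thr) || thr <= 0 || thr >= 1) {
    msgs <- c(msgs, "threshold must lie in (0, 1)")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ProteinStructure", function(object) {
  res <- object@residues
  cat("ProteinStructure '", object@id, "': ", nrow(res), " residues in ",
      length(unique(res$chain)), " chain(s), ",
      nrow(object@ssbonds), " disulfide bond(s)\n", sep = "")
  if (any(res$cb_source == "reconstructed")) {
    cat("  CB reconstructed for ", sum(res$cb_source == "reconstructed"),
        " residue(s) (glycine)\n", sep = "")
  }
  invisible(NULL)
})

setMethod("show", "PairDataset", function(object) {
  n <- length(object@labels)
  cat("PairDataset: ", n, " samples (", sum(object@labels == 1L), " bonded, ",
      sum(object@labels == 0L), " non-bonded); ",
      sum(object@split == "train"), " train / ",
      sum(object@split == "test"), " test\n", sep = "")
  invisible(NULL)
})

setMethod("show", "DisulfideClassifier", function(object) {
  sz <- object@config$layerSizes
  cat("DisulfideClassifier: ", paste(sz, collapse = "-"),
      " fully connected network (ReLU hidden, logistic output)\n", sep = "")
  if (nrow(object@trainingLog) > 0) {
    last <- object@trainingLog[nrow(object@trainingLog), ]
    cat(sprintf("  trained %d epochs; final loss %.4f, training accuracy %.4f\n",
                nrow(object@trainingLog), last$loss, last$accuracy))
  } else {
    cat("  untrained\n")
  }
  invisible(NULL)
})

#' @rdname ProteinStructure-accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))
#' @rdname ProteinStructure-accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname ProteinStructure-accessors
#' @export
setGeneric("atomCoords", function(x, ...) standardGeneric("atomCoords"))
#' @rdname ProteinStructure-accessors
#' @export
setGeneric("ssbonds", function(x) standardGeneric("ssbonds"))

#' Accessors for ProteinStructure objects
#'
#' @param x a [ProteinStructure-class] object.
#' @param ... unused.
#' @return `structureId`: the identifier string. `residues`: the residue
#'   table. `atomCoords`: the `nres x 5 x 3` coordinate array.
#'   `ssbonds`: the disulfide-bond table.
#' @name ProteinStructure-accessors
#' @aliases structureId residues atomCoords ssbonds
NULL

setMethod("structureId", "ProteinStructure", function(x) x@id)
setMethod("residues", "ProteinStructure", function(x) x@residues)
setMethod("atomCoords", "ProteinStructure", function(x, ...) x@coords)
setMethod("ssbonds", "ProteinStructure", function(x) x@ssbonds)

#' @rdname PairDataset-accessors
#' @export
setGeneric("features", function(x, ...) standardGeneric("features"))
#' @rdname PairDataset-accessors
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))
#' @rdname PairDataset-accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname PairDataset-accessors
#' @export
setGeneric("datasetSplit", function(x) standardGeneric("datasetSplit"))

#' Accessors for PairDataset objects
#'
#' @param x a [PairDataset-class] object.
#' @param split optional, `"train"` or `"test"`, to restrict the feature
#'   matrix to one split.
#' @param ... unused.
#' @return `features`: the feature matrix (optionally restricted to one
#'   split). `pairLabels`: the 0/1 label vector. `sampleInfo`: per-sample
#'   provenance. `datasetSplit`: the split assignment vector.
#' @name PairDataset-accessors
#' @aliases features pairLabels sampleInfo datasetSplit
NULL

setMethod("features", "PairDataset", function(x, split = NULL, ...) {
  if (is.null(split)) return(x@features)
  split <- match.arg(split, c("train", "test"))
  x@features[x@split == split, , drop = FALSE]
})
setMethod("pairLabels", "PairDataset", function(x) x@labels)
setMethod("sampleInfo", "PairDataset", function(x) x@sampleInfo)
setMethod("datasetSplit", "PairDataset", function(x) x@split)

#' @rdname DisulfideClassifier-accessors
#' @export
setGeneric("classifierWeights", function(x) standardGeneric("classifierWeights"))
#' @rdname DisulfideClassifier-accessors
#' @export
setGeneric("classifierConfigOf", function(x) standardGeneric("classifierConfigOf"))
#' @rdname DisulfideClassifier-accessors
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))

#' Accessors for DisulfideClassifier objects
#'
#' @param x a [DisulfideClassifier-class] object.
#' @return `classifierWeights`: the list of weight matrices and bias
#'   vectors. `classifierConfigOf`: the configuration list.
#'   `trainingLog`: the per-epoch loss/accuracy table.
#' @name DisulfideClassifier-accessors
#' @aliases classifierWeights classifierConfigOf trainingLog
NULL

setMethod("classifierWeights", "DisulfideClassifier", function(x) x@weights)
setMethod("classifierConfigOf", "DisulfideClassifier", function(x) x@config)
setMethod("trainingLog", "DisulfideClassifier", function(x) x@trainingLog)

setMethod("initialize", "ProteinStructure", function(.Object, ...) {
  .Object <- callNextMethod(.Object, ...)
  if (length(dim(.Object@coords)) == 3L) {
    dimnames(.Object@coords) <- list(NULL, .ATOMS, c("x", "y", "z"))
  }
  .Object
})
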