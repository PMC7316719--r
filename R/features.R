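# Fixed flattening order of the 10x10 distance matrix: strict upper
# triangle, row-major, i.e. (1,2), (1,3), ..., (1,10), (2,3), ...
.featureIndexMap <- local({
  idx <- NULL
  function() {
    if (is.null(idx)) {
      pairs <- t(utils::combn(10L, 2L))
      # combn enumerates column-wise (1,2),(1,3),... which is exactly
      # row-major order over the strict upper triangle
      idx <<- pairs
    }
    idx
  }
})

.PAIR_ATOM_NAMES <- c("N", "CA", "C", "O", "CB", "Np", "CAp", "Cp", "Op", "CBp")

#' Names of the 45 distance features
#'
#' One name per flattened distance, `d_<atom1>_<atom2>`, in the fixed
#' row-major upper-triangle order. Atoms of the second residue carry a
#' `p` suffix (e.g. `d_CB_CBp` is the inter-residue CB-CB distance).
#'
#' @return character vector of length 45.
#' @examples
#' head(featureNames())
#' @export
featureNames <- function() {
  idx <- .featureIndexMap()
  paste0("d_", .PAIR_ATOM_NAMES[idx[, 1]], "_", .PAIR_ATOM_NAMES[idx[, 2]])
}

#' Pairwise distance matrix of a 10-atom coordinate block
#'
#' @param coords numeric 10 x 3 matrix of atom coordinates (Angstrom), as
#'   produced by [pairAtoms()].
#' @return symmetric 10 x 10 matrix of Euclidean distances with zero
#'   diagonal.
#' @examples
#' distanceMatrix(matrix(rnorm(30), 10, 3))
#' @export
distanceMatrix <- function(coords) {
  stopifnot(is.matrix(coords), nrow(coords) == 10L, ncol(coords) == 3L,
            all(is.finite(coords)))
  m <- as.matrix(stats::dist(coords))
  dimnames(m) <- list(.PAIR_ATOM_NAMES, .PAIR_ATOM_NAMES)
  m
}

#' Flatten a symmetric distance matrix to the 45-vector feature
#'
#' Extracts the strict upper triangle in row-major order. The diagonal is
#' zero and the matrix symmetric, so these 45 values carry all the
#' information of the 10 x 10 matrix.
#'
#' @param m symmetric 10 x 10 numeric matrix with zero diagonal.
#' @return named numeric vector of length 45 (names from
#'   [featureNames()]).
#' @export
flattenDistances <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == 10L, ncol(m) == 10L)
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix is not symmetric")
  idx <- .featureIndexMap()
  v <- m[cbind(idx[, 1], idx[, 2])]
  names(v) <- featureNames()
  v
}

#' Rebuild the 10 x 10 distance matrix from a 45-vector
#'
#' Inverse of [flattenDistances()].
#'
#' @param v numeric vector of length 45 in the package's flattening order.
#' @return symmetric 10 x 10 matrix with zero diagonal.
#' @export
unflattenDistances <- function(v) {
  stopifnot(length(v) == 45L, all(is.finite(v)))
  idx <- .featureIndexMap()
  m <- matrix(0, 10L, 10L, dimnames = list(.PAIR_ATOM_NAMES, .PAIR_ATOM_NAMES))
  m[cbind(idx[, 1], idx[, 2])] <- v
  m[cbind(idx[, 2], idx[, 1])] <- v
  m
}

# Permutation of the 45 feature positions induced by swapping the two
# residues (atoms 1..5 <-> 6..10). Used for training augmentation and
# order-symmetric scoring.
.swapPermutation <- local({
  perm <- NULL
  function() {
    if (is.null(perm)) {
      idx <- .featureIndexMap()
      p <- c(6:10, 1:5)
      key <- function(i, j) paste(pmin(i, j), pmax(i, j))
      orig <- key(idx[, 1], idx[, 2])
      swapped <- key(p[idx[, 1]], p[idx[, 2]])
      perm <<- match(swapped, orig)
    }
    perm
  }
})

#' Swap residue orientation of a feature vector
#'
#' Returns the feature vector the same pair would produce with the two
#' residues given in the opposite order.
#'
#' @param v numeric vector of length 45, or a matrix with 45 columns.
#' @return object of the same shape with permuted entries.
#' @export
swapFeatureOrientation <- function(v) {
  perm <- .swapPermutation()
  if (is.matrix(v)) {
    stopifnot(ncol(v) == 45L)
    out <- v[, perm, drop = FALSE]
    colnames(out) <- colnames(v)
    return(out)
  }
  stopifnot(length(v) == 45L)
  out <- v[perm]
  names(out) <- names(v)
  out
}

#' Distance feature for a residue pair of a structure
#'
#' Composes [pairAtoms()], [distanceMatrix()] and [flattenDistances()]
#' under the canonical pair ordering. Distances make the feature exactly
#' invariant to rigid-body motion of the input coordinates (and, by
#' construction, blind to mirror inversion).
#'
#' @param x a [ProteinStructure-class] object.
#' @param a,b `ResidueRef` objects present in `x`.
#' @return named numeric vector of length 45 (Angstrom).
#' @export
featurizePair <- function(x, a, b) {
  p <- canonicalPair(a, b)
  flattenDistances(distanceMatrix(pairAtoms(x, p$a, p$b)))
}
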