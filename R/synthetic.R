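#' Geometry specification for the synthetic benchmark
#'
#' Parameters of the synthetic residue-pair generator. Bonded-like
#' ("positive") pairs place the two CB atoms about 3.8 A apart (the
#' inter-CB distance of natural disulfides) with a CA-CA distance drawn
#' from 4.0-6.5 A, inside the window natural bonds occupy. Non-bonded
#' ("negative") pairs draw CA-CA from the full 3.0-7.5 A prescreen window
#' but point the CB atoms away from each other so the CB-CB distance
#' stays above 5.5 A. The two classes therefore have disjoint CB-CB
#' supports by construction: the benchmark is deliberately separable so
#' that classifier tests carry a provable bound, and it is labelled as
#' such wherever it is used.
#'
#' @param cbPositive target CB-CB distance for positive pairs (A).
#' @param caPositiveRange CA-CA sampling range for positives (A).
#' @param caNegativeRange CA-CA sampling range for negatives (A).
#' @param cbNegativeMin enforced lower bound on negative CB-CB (A).
#' @param jitter per-coordinate Gaussian noise sigma (A).
#' @return a list with class `GeometrySpec`.
#' @export
geometrySpec <- function(cbPositive = 3.8, caPositiveRange = c(4.0, 6.5),
                         caNegativeRange = c(3.0, 7.5), cbNegativeMin = 5.5,
                         jitter = 0.15) {
  stopifnot(cbPositive > 0, length(caPositiveRange) == 2L,
            caPositiveRange[1] < caPositiveRange[2],
            length(caNegativeRange) == 2L,
            caNegativeRange[1] < caNegativeRange[2],
            cbNegativeMin > cbPositive, jitter >= 0)
  structure(list(cbPositive = cbPositive, caPositiveRange = caPositiveRange,
                 caNegativeRange = caNegativeRange,
                 cbNegativeMin = cbNegativeMin, jitter = jitter),
            class = "GeometrySpec")
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
.randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# rotation taking unit vector `from` onto unit vector `to` (Rodrigues)
.alignRotation <- function(from, to) {
  from <- .unit(from); to <- .unit(to)
  v <- .cross3(from, to)
  cth <- sum(from * to)
  if (cth < -1 + 1e-12) {
    # antiparallel: rotate pi about any perpendicular axis
    p <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- .unit(.cross3(from, p))
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + cth)
}

# rotation by angle about a unit axis
.axisRotation <- function(axis, angle) {
  axis <- .unit(axis)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# place the ideal template with rotation R and CA at `ca`
.placeTemplate <- function(R, ca) {
  centered <- sweep(.ALA_TEMPLATE, 2, .ALA_TEMPLATE["CA", ])
  out <- centered %*% t(R)
  out <- sweep(out, 2, ca, "+")
  dimnames(out) <- dimnames(.ALA_TEMPLATE)
  out
}

# rotation placing the template with its CA->CB direction along `cbdir`,
# with a uniform random spin about that axis
.orientTowards <- function(cbdir) {
  tdir <- .unit(.ALA_TEMPLATE["CB", ] - .ALA_TEMPLATE["CA", ])
  spin <- .axisRotation(cbdir, stats::runif(1, 0, 2 * pi))
  spin %*% .alignRotation(tdir, cbdir)
}

#' Generate one ideal-geometry residue
#'
#' An alanine-like residue with ideal internal bond lengths and angles
#' and L-chirality, rigidly placed with its CA at `center` under the
#' given (or a seeded random) rotation.
#'
#' @param seed integer seed (used when `rotation` is `NULL` and for
#'   jitter).
#' @param center CA position, numeric 3-vector.
#' @param rotation optional 3 x 3 rotation matrix; random if `NULL`.
#' @param jitter per-coordinate Gaussian noise sigma in A (default 0).
#' @return numeric 5 x 3 matrix with rows N, CA, C, O, CB.
#' @examples
#' r <- makeResidue(seed = 1)
#' sqrt(sum((r["N", ] - r["CA", ])^2))   # ideal N-CA bond, about 1.46 A
#' @export
makeResidue <- function(seed = 1L, center = c(0, 0, 0), rotation = NULL,
                        jitter = 0) {
  stopifnot(length(center) == 3L, all(is.finite(center)), jitter >= 0)
  .withSeed(seed, {
    R <- if (is.null(rotation)) .randomRotation() else rotation
    out <- .placeTemplate(R, center)
    if (jitter > 0) out <- out + matrix(stats::rnorm(15, 0, jitter), 5, 3)
    out
  })
}

# one positive (disulfide-like) pair of 5x3 blocks; assumes RNG already set
.samplePositivePair <- function(spec) {
  repeat {
    A <- .placeTemplate(.orientTowards(c(1, 0, 0)) %*%
                          .axisRotation(c(1, 0, 0), stats::runif(1, 0, 2 * pi)),
                        c(0, 0, 0))
    cbA <- A["CB", ]
    # direction from CB_A to CB_B; resampled until a CA-CA distance in the
    # positive range is geometrically reachable
    for (try in 1:100) {
      u <- .unit(stats::rnorm(3))
      cbB <- cbA + spec$cbPositive * u
      r <- sqrt(sum(cbB^2))
      lo <- max(spec$caPositiveRange[1], r - .CB_BOND_LENGTH + 0.05)
      hi <- min(spec$caPositiveRange[2], r + .CB_BOND_LENGTH - 0.05)
      if (lo < hi) break
    }
    if (lo >= hi) next
    dca <- stats::runif(1, lo, hi)
    # CA_B lies on the intersection circle of spheres around the origin
    # (radius dca) and around CB_B (radius CA-CB bond)
    dd <- r
    e <- cbB / dd
    a <- (dd^2 + dca^2 - .CB_BOND_LENGTH^2) / (2 * dd)
    rc2 <- dca^2 - a^2
    if (rc2 <= 0) next
    rc <- sqrt(rc2)
    p <- if (abs(e[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- .unit(.cross3(e, p))
    e2 <- .cross3(e, e1)
    psi <- stats::runif(1, 0, 2 * pi)
    caB <- a * e + rc * (cos(psi) * e1 + sin(psi) * e2)
    B <- .placeTemplate(.orientTowards(.unit(cbB - caB)), caB)
    if (spec$jitter > 0) {
      A <- A + matrix(stats::rnorm(15, 0, spec$jitter), 5, 3)
      B <- B + matrix(stats::rnorm(15, 0, spec$jitter), 5, 3)
    }
    dcb <- sqrt(sum((A["CB", ] - B["CB", ])^2))
    dca_f <- sqrt(sum((A["CA", ] - B["CA", ])^2))
    # keep the classes' CB-CB supports disjoint and positives inside the
    # default prescreen window even after jitter
    if (dcb < spec$cbNegativeMin - 0.5 && dca_f >= 3.0 && dca_f <= 7.5) {
      return(list(A = A, B = B))
    }
  }
}

# one negative pair: any relative orientation whose CB atoms stay apart;
# assumes RNG already set
.sampleNegativePair <- function(spec) {
  repeat {
    A <- .placeTemplate(.randomRotation(), c(0, 0, 0))
    dca <- stats::runif(1, spec$caNegativeRange[1], spec$caNegativeRange[2])
    B <- .placeTemplate(.randomRotation(), c(-dca, 0, 0))
    if (spec$jitter > 0) {
      A <- A + matrix(stats::rnorm(15, 0, spec$jitter), 5, 3)
      B <- B + matrix(stats::rnorm(15, 0, spec$jitter), 5, 3)
    }
    if (sqrt(sum((A["CB", ] - B["CB", ])^2)) > spec$cbNegativeMin) {
      return(list(A = A, B = B))
    }
  }
}

#' Generate labelled feature clouds for benchmarking
#'
#' Samples `nPerClass` bonded-like and `nPerClass` non-bonded residue-pair
#' geometries from `spec`, featurizes them, and returns a balanced
#' [PairDataset-class] with a seeded train/test split. Because the two
#' classes' CB-CB supports are disjoint by construction, a single
#' threshold on the `d_CB_CBp` feature separates them perfectly — which
#' is what makes this benchmark useful for bounding classifier tests, and
#' what makes it easier than real structural data.
#'
#' @param nPerClass samples per class.
#' @param spec a `GeometrySpec` ([geometrySpec()]).
#' @param seed integer seed; generation is bit-reproducible.
#' @param testFraction fraction held out as the test split (default 0.25).
#' @return a [PairDataset-class] with `2 * nPerClass` samples.
#' @examples
#' ds <- makeFeatureClouds(100, seed = 1)
#' ds
#' @export
makeFeatureClouds <- function(nPerClass, spec = geometrySpec(), seed = 1L,
                              testFraction = 0.25) {
  stopifnot(nPerClass >= 1L, inherits(spec, "GeometrySpec"))
  .withSeed(seed, {
    n <- 2L * as.integer(nPerClass)
    feat <- matrix(NA_real_, n, 45L)
    labels <- integer(n)
    for (k in seq_len(nPerClass)) {
      pp <- .samplePositivePair(spec)
      feat[k, ] <- flattenDistances(distanceMatrix(rbind(pp$A, pp$B)))
      labels[k] <- 1L
      np <- .sampleNegativePair(spec)
      feat[nPerClass + k, ] <- flattenDistances(distanceMatrix(rbind(np$A, np$B)))
      labels[nPerClass + k] <- 0L
    }
    colnames(feat) <- featureNames()
    info <- data.frame(
      structure_id = "synthetic-cloud",
      chain1 = "A", resno1 = seq_len(n) * 2L - 1L, insert1 = "",
      chain2 = "A", resno2 = seq_len(n) * 2L, insert2 = "",
      origin = ifelse(labels == 1L, "synthetic-positive", "synthetic-negative"),
      stringsAsFactors = FALSE
    )
    nTest <- round(n * testFraction)
    split <- rep("train", n)
    split[sample.int(n, nTest)] <- "test"
    new("PairDataset", features = feat, labels = labels, sampleInfo = info,
        split = split)
  })
}

#' Generate a synthetic PDB structure with planted disulfide bonds
#'
#' Builds a random-coil chain of ideal alanine-like residues (CA steps of
#' 3.8 A with directional persistence), replaces `nBonds` residue pairs
#' with bonded-like geometry sampled from `spec`, declares them in SSBOND
#' records, and writes the result as a parseable PDB file. A truth table
#' lists each planted bond and the negative pair its sequence neighbours
#' should yield under the shortest-crossing-CA-distance rule, computed
#' directly from the final coordinates by exhaustive search over the (at
#' most four) crossing candidates. All coordinates are synthetic; no real
#' protein fold is emulated.
#'
#' @param nResidues chain length (must be at least `2 * nBonds + 2`).
#' @param nBonds number of planted disulfide bonds.
#' @param spec a `GeometrySpec` ([geometrySpec()]).
#' @param seed integer seed; generation is reproducible.
#' @param path output PDB path.
#' @param chains 1 (single chain A) or 2 (residues split over chains A
#'   and B; planted bonds become inter-chain).
#' @param glycine integer vector of residue positions to emit as glycine
#'   (their CB atoms are omitted from the file, exercising CB
#'   reconstruction on read).
#' @return a list: `path`, the written file; `structure`, the generated
#'   [ProteinStructure-class]; `truth`, the per-bond truth table with the
#'   expected negative pair; `prescreenFailFraction`, the fraction of
#'   truth negatives falling outside the default prescreen window.
#' @export
makeStructure <- function(nResidues, nBonds, spec = geometrySpec(),
                          seed = 1L, path = tempfile(fileext = ".pdb"),
                          chains = 1L, glycine = integer(0)) {
  stopifnot(nResidues >= 2L, nBonds >= 0L, inherits(spec, "GeometrySpec"),
            chains %in% c(1L, 2L))
  if (nBonds > 0L && nResidues < 2L * nBonds + 2L) {
    stop("nResidues must be at least 2 * nBonds + 2")
  }
  .withSeed(seed, {
    n <- as.integer(nResidues)
    # persistent random-walk CA trace, 3.8 A steps
    ca <- matrix(0, n, 3L)
    dir <- .unit(stats::rnorm(3))
    for (i in 2:n) {
      dir <- .unit(dir + 0.7 * stats::rnorm(3))
      ca[i, ] <- ca[i - 1L, ] + 3.8 * dir
    }
    coords <- array(NA_real_, dim = c(n, 5L, 3L),
                    dimnames = list(NULL, .ATOMS, c("x", "y", "z")))
    for (i in seq_len(n)) {
      coords[i, , ] <- .placeTemplate(.randomRotation(), ca[i, ])
    }

    # plant bonds: residue i from the left half, j from the right half
    bondIdx <- if (nBonds > 0L) {
      cbind(i = 2L * seq_len(nBonds),
            j = n - 2L * (nBonds - seq_len(nBonds)) - 1L)
    } else {
      cbind(i = integer(0), j = integer(0))
    }
    if (nBonds > 0L &&
        (anyDuplicated(c(bondIdx)) || any(bondIdx[, "i"] >= bondIdx[, "j"]))) {
      stop("infeasible request: cannot place ", nBonds,
           " disjoint bonds in ", n, " residues")
    }
    resid <- rep("ALA", n)
    for (k in seq_len(nBonds)) {
      pp <- .samplePositivePair(spec)
      R <- .randomRotation()
      shift <- ca[bondIdx[k, "i"], ]
      place <- function(block) {
        sweep((block - matrix(pp$A["CA", ], 5, 3, byrow = TRUE)) %*% t(R),
              2, shift, "+")
      }
      coords[bondIdx[k, "i"], , ] <- place(pp$A)
      coords[bondIdx[k, "j"], , ] <- place(pp$B)
      resid[bondIdx[k, c("i", "j")]] <- "CYS"
    }
    # planting moved the bonded residues: refresh the CA trace
    for (i in c(bondIdx)) ca[i, ] <- coords[i, "CA", ]
    # restore local chain continuity around each moved bond partner so
    # that its sequence neighbours (the source of derived negatives) sit
    # at realistic CA distances from the bond
    planted0 <- rep(FALSE, n)
    planted0[c(bondIdx)] <- TRUE
    for (k in seq_len(nBonds)) {
      j <- bondIdx[k, "j"]
      for (d in c(-1L, 1L)) {
        t_ <- j + d
        if (t_ < 1L || t_ > n || planted0[t_]) next
        repeat {
          u <- .unit(stats::rnorm(3))
          pos <- ca[j, ] + 3.8 * u
          if (sqrt(sum((pos - ca[bondIdx[k, "i"], ])^2)) >= 3.0) break
        }
        ca[t_, ] <- pos
        coords[t_, , ] <- .placeTemplate(.randomRotation(), ca[t_, ])
      }
    }

    # chain assignment and author numbering
    if (chains == 2L) {
      half <- n %/% 2L
      chain <- rep(c("A", "B"), c(half, n - half))
      resno <- c(seq_len(half), seq_len(n - half))
    } else {
      chain <- rep("A", n)
      resno <- seq_len(n)
    }

    # Repair pass: the planted pairs must be the only pairs with
    # bonded-like geometry. Any other pair inside the CA prescreen window
    # whose CB atoms fall closer than the negative-cloud bound first gets
    # the orientation of a (non-planted) member resampled; where no
    # orientation suffices, that member's CA is nudged away from the
    # offending partner and the constraint set recomputed. The truth
    # table is derived afterwards, from the final coordinates.
    planted <- rep(FALSE, n)
    planted[c(bondIdx)] <- TRUE
    isPlantedPair <- function(p, q) {
      any(bondIdx[, "i"] == pmin(p, q) & bondIdx[, "j"] == pmax(p, q))
    }
    sameCh <- outer(chain, chain, "==")
    cbGap <- function(p, q) {
      sqrt(sum((coords[p, "CB", ] - coords[q, "CB", ])^2))
    }
    # pairs the default prescreen would score: CA window plus the minimal
    # sequence separation of 2 (inter-chain pairs always qualify)
    windowPairs <- function() {
      caD <- as.matrix(stats::dist(ca))
      iw <- which(caD >= 3.0 & caD <= 7.5 & upper.tri(caD) &
                    (abs(row(caD) - col(caD)) >= 2L | !sameCh),
                  arr.ind = TRUE)
      iw[!apply(iw, 1, function(pq) isPlantedPair(pq[1], pq[2])), ,
         drop = FALSE]
    }
    for (round_ in seq_len(6L)) {
      inWindow <- windowPairs()
      partnersOf <- function(i0) {
        c(inWindow[inWindow[, 1] == i0, 2], inWindow[inWindow[, 2] == i0, 1])
      }
      minGapOf <- function(i0) {
        partners <- partnersOf(i0)
        if (length(partners) == 0L) return(Inf)
        min(vapply(partners, function(q) cbGap(i0, q), numeric(1)))
      }
      globalMin <- function() {
        if (nrow(inWindow) == 0L) return(Inf)
        min(vapply(seq_len(nrow(inWindow)), function(r_)
          cbGap(inWindow[r_, 1], inWindow[r_, 2]), numeric(1)))
      }
      constrained <- setdiff(unique(c(inWindow)), which(planted))
      # coordinate descent on orientations
      for (sweep in seq_len(20L)) {
        if (globalMin() >= spec$cbNegativeMin) break
        for (i0 in sample(constrained)) {
          cur <- minGapOf(i0)
          if (cur >= spec$cbNegativeMin) next
          bestBlock <- coords[i0, , ]
          bestGap <- cur
          for (t_ in seq_len(30L)) {
            coords[i0, , ] <- .placeTemplate(.randomRotation(), ca[i0, ])
            gap <- minGapOf(i0)
            if (gap > bestGap) {
              bestGap <- gap
              bestBlock <- coords[i0, , ]
            }
            if (bestGap >= spec$cbNegativeMin) break
          }
          coords[i0, , ] <- bestBlock
        }
      }
      if (globalMin() >= spec$cbNegativeMin) break
      # orientation alone insufficient: move stuck residues away from
      # their closest offending partner
      moved <- FALSE
      for (i0 in constrained) {
        partners <- partnersOf(i0)
        if (length(partners) == 0L) next
        gaps <- vapply(partners, function(q) cbGap(i0, q), numeric(1))
        if (min(gaps) >= spec$cbNegativeMin) next
        q <- partners[which.min(gaps)]
        dirAway <- ca[i0, ] - ca[q, ]
        nrm <- sqrt(sum(dirAway^2))
        dirAway <- if (nrm > 1e-6) dirAway / nrm else .unit(stats::rnorm(3))
        ca[i0, ] <- ca[i0, ] + 1.2 * dirAway + stats::rnorm(3, 0, 0.2)
        coords[i0, , ] <- .placeTemplate(.randomRotation(), ca[i0, ])
        moved <- TRUE
      }
      if (!moved) break
    }
    inWindow <- windowPairs()
    finalMin <- if (nrow(inWindow) == 0L) Inf else {
      min(vapply(seq_len(nrow(inWindow)), function(r_)
        cbGap(inWindow[r_, 1], inWindow[r_, 2]), numeric(1)))
    }
    if (finalMin < spec$cbNegativeMin) {
      warning("makeStructure: some non-planted in-window pairs remain ",
              "closer than the negative-cloud CB bound")
    }

    res <- data.frame(chain = chain, resno = as.integer(resno),
                      insert = "", resid = resid, cb_source = "observed",
                      stringsAsFactors = FALSE)
    sb <- data.frame(chain1 = chain[bondIdx[, "i"]],
                     resno1 = resno[bondIdx[, "i"]],
                     insert1 = rep("", nBonds),
                     chain2 = chain[bondIdx[, "j"]],
                     resno2 = resno[bondIdx[, "j"]],
                     insert2 = rep("", nBonds),
                     stringsAsFactors = FALSE)
    s <- new("ProteinStructure", id = "synthetic", residues = res,
             coords = coords, ssbonds = sb)

    # truth table: exhaustive minimum over the crossing neighbour pairs
    truth <- NULL
    nFail <- 0L
    for (k in seq_len(nBonds)) {
      i <- bondIdx[k, "i"]; j <- bondIdx[k, "j"]
      sameChain <- function(a, b) chain[a] == chain[b]
      neigh <- function(i0, d) {
        i1 <- i0 + d
        if (i1 >= 1L && i1 <= n && sameChain(i0, i1)) i1 else NA_integer_
      }
      cand <- rbind(c(neigh(i, -1L), neigh(j, -1L)),
                    c(neigh(i, -1L), neigh(j, +1L)),
                    c(neigh(i, +1L), neigh(j, -1L)),
                    c(neigh(i, +1L), neigh(j, +1L)))
      best <- NA_integer_; bestD <- Inf
      for (c_ in seq_len(nrow(cand))) {
        p <- cand[c_, 1]; q <- cand[c_, 2]
        if (is.na(p) || is.na(q) || p == q) next
        d <- sqrt(sum((ca_final <- coords[p, "CA", ] - coords[q, "CA", ])^2))
        if (d < bestD) { bestD <- d; best <- c_ }
      }
      p <- cand[best, 1]; q <- cand[best, 2]
      if (bestD < 3.0 || bestD > 7.5) nFail <- nFail + 1L
      truth <- rbind(truth, data.frame(
        chain1 = chain[i], resno1 = resno[i],
        chain2 = chain[j], resno2 = resno[j],
        neg_chain1 = chain[p], neg_resno1 = resno[p],
        neg_chain2 = chain[q], neg_resno2 = resno[q],
        neg_ca_distance = bestD, stringsAsFactors = FALSE))
    }
    if (is.null(truth)) {
      truth <- data.frame(chain1 = character(), resno1 = integer(),
                          chain2 = character(), resno2 = integer(),
                          neg_chain1 = character(), neg_resno1 = integer(),
                          neg_chain2 = character(), neg_resno2 = integer(),
                          neg_ca_distance = numeric(),
                          stringsAsFactors = FALSE)
    }

    writeStructure(s, path)
    glycine <- intersect(as.integer(glycine), setdiff(seq_len(n),
                                                      c(bondIdx)))
    if (length(glycine) > 0L) {
      # rewrite the requested residues as glycine without CB
      lines <- readLines(path)
      for (g in glycine) {
        tag <- sprintf("%3s %1s%4d", "ALA", chain[g], resno[g])
        hit <- grepl(paste0("^ATOM"), lines) &
          substr(lines, 18, 26) == tag
        cb <- hit & substr(lines, 13, 16) == " CB "
        lines <- lines[!cb]
        hit <- grepl("^ATOM", lines) & substr(lines, 18, 26) == tag
        substr(lines[hit], 18, 20) <- "GLY"
      }
      writeLines(lines, path)
    }
    frac <- if (nBonds > 0L) nFail / nBonds else 0
    if (frac > 0) {
      message(sprintf("makeStructure: %.0f%% of truth negatives fall outside the default prescreen window",
                      100 * frac))
    }
    list(path = path, structure = s, truth = truth,
         prescreenFailFraction = frac)
  })
}
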