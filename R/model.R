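# run code under a fixed seed, restoring the caller's RNG state afterwards
.withSeed <- function(seed, code) {
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
  force(code)
}

#' Configuration of the disulfide classifier network
#'
#' The architecture and training hyperparameters of the fully connected
#' classifier: a 45-dimensional input, hidden layers of 128 and 32 ReLU
#' units, and one logistic output unit. Training runs 10 epochs of
#' mini-batch stochastic gradient descent on binary cross-entropy with
#' learning rate 0.01 and batch size 100; a score at or above the 0.5
#' threshold classifies a pair as bonded.
#'
#' @param epochs number of training epochs (default 10).
#' @param learningRate SGD learning rate (default 0.01).
#' @param batchSize mini-batch size (default 100).
#' @param threshold decision threshold on the score, in (0, 1)
#'   (default 0.5).
#' @param seed integer seed pinning weight initialization and shuffling.
#' @return a list with class `ClassifierConfig`; `layerSizes` is fixed to
#'   `c(45, 128, 32, 1)`.
#' @examples
#' classifierConfig(seed = 7)
#' @export
classifierConfig <- function(epochs = 10L, learningRate = 0.01,
                             batchSize = 100L, threshold = 0.5, seed = 1L) {
  stopifnot(epochs >= 1L, learningRate > 0, batchSize >= 1L,
            threshold > 0, threshold < 1)
  structure(list(layerSizes = c(45L, 128L, 32L, 1L),
                 epochs = as.integer(epochs),
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 threshold = threshold,
                 seed = as.integer(seed)),
            class = "ClassifierConfig")
}

# forward pass; returns activations needed for backprop
.forward <- function(w, X) {
  Z1 <- sweep(X %*% w$W1, 2, w$b1, "+")
  A1 <- pmax(Z1, 0)
  Z2 <- sweep(A1 %*% w$W2, 2, w$b2, "+")
  A2 <- pmax(Z2, 0)
  Z3 <- sweep(A2 %*% w$W3, 2, w$b3, "+")
  P <- 1 / (1 + exp(-Z3))
  list(Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, P = P)
}

.bce <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

# seeded He-style uniform initialization: U(-sqrt(6/fan_in), +sqrt(6/fan_in))
.initWeights <- function(sizes) {
  w <- list()
  for (k in 1:3) {
    lim <- sqrt(6 / sizes[k])
    w[[paste0("W", k)]] <- matrix(stats::runif(sizes[k] * sizes[k + 1],
                                               -lim, lim),
                                  sizes[k], sizes[k + 1])
    w[[paste0("b", k)]] <- rep(0, sizes[k + 1])
  }
  w
}

#' Train the disulfide classifier
#'
#' Mini-batch SGD on binary cross-entropy over the training split of
#' `data`. Every sample is presented in both residue orientations (the
#' feature permutation of [swapFeatureOrientation()]), so the learned
#' score is symmetric under pair-order swap when combined with the
#' predict-time orientation averaging of [scoreFeatures()]. Weight
#' initialization and epoch shuffling are pinned by `config$seed`, making
#' training bit-reproducible.
#'
#' @param data a [PairDataset-class] with both classes present in its
#'   training split.
#' @param config a `ClassifierConfig` from [classifierConfig()].
#' @return a trained [DisulfideClassifier-class] object.
#' @examples
#' ds <- makeFeatureClouds(200, seed = 1)
#' fit <- trainClassifier(ds, classifierConfig(seed = 1))
#' fit
#' @export
trainClassifier <- function(data, config = classifierConfig()) {
  stopifnot(is(data, "PairDataset"), inherits(config, "ClassifierConfig"))
  X <- data@features[data@split == "train", , drop = FALSE]
  y <- data@labels[data@split == "train"]
  if (nrow(X) == 0L) stop("empty training split")
  if (length(unique(y)) < 2L) {
    stop("training data must contain both bonded and non-bonded samples")
  }
  # orientation augmentation: each pair in both residue orders
  X <- rbind(X, swapFeatureOrientation(X))
  y <- c(y, y)
  n <- nrow(X)
  sizes <- config$layerSizes
  lr <- config$learningRate
  bs <- config$batchSize

  log <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  w <- .withSeed(config$seed, {
    w <- .initWeights(sizes)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      sizes_b <- integer(0)
      for (start in seq(1L, n, by = bs)) {
        take <- ord[start:min(start + bs - 1L, n)]
        Xb <- X[take, , drop = FALSE]
        yb <- y[take]
        m <- length(take)
        fw <- .forward(w, Xb)
        losses <- c(losses, .bce(fw$P, yb))
        sizes_b <- c(sizes_b, m)
        # backprop for logistic output + BCE
        dZ3 <- (fw$P - yb) / m
        dW3 <- crossprod(fw$A2, dZ3)
        db3 <- colSums(dZ3)
        dA2 <- dZ3 %*% t(w$W3)
        dZ2 <- dA2 * (fw$Z2 > 0)
        dW2 <- crossprod(fw$A1, dZ2)
        db2 <- colSums(dZ2)
        dA1 <- dZ2 %*% t(w$W2)
        dZ1 <- dA1 * (fw$Z1 > 0)
        dW1 <- crossprod(Xb, dZ1)
        db1 <- colSums(dZ1)
        w$W3 <- w$W3 - lr * dW3; w$b3 <- w$b3 - lr * db3
        w$W2 <- w$W2 - lr * dW2; w$b2 <- w$b2 - lr * db2
        w$W1 <- w$W1 - lr * dW1; w$b1 <- w$b1 - lr * db1
      }
      p <- .forward(w, X)$P
      log <- rbind(log, data.frame(
        epoch = epoch,
        loss = sum(losses * sizes_b) / n,
        accuracy = mean((p >= config$threshold) == (y == 1L))
      ))
    }
    w
  })
  new("DisulfideClassifier", config = unclass(config), weights = w,
      trainingLog = log)
}

#' Score feature vectors with a trained classifier
#'
#' Runs the forward pass on a feature vector (or each row of a matrix) in
#' both residue orientations and averages the two logistic outputs, so
#' the score of a pair does not depend on which residue is listed first.
#'
#' @param model a trained [DisulfideClassifier-class].
#' @param f numeric vector of length 45, or a matrix with 45 columns.
#' @return numeric score(s) in `[0, 1]`; higher means more
#'   disulfide-compatible geometry.
#' @export
scoreFeatures <- function(model, f) {
  stopifnot(is(model, "DisulfideClassifier"))
  if (!is.matrix(f)) {
    if (length(f) != 45L) stop("feature vector must have length 45")
    f <- matrix(f, nrow = 1L)
  }
  if (ncol(f) != 45L) stop("feature matrix must have 45 columns")
  stopifnot(all(is.finite(f)))
  p1 <- .forward(model@weights, f)$P
  p2 <- .forward(model@weights, swapFeatureOrientation(f))$P
  as.numeric((p1 + p2) / 2)
}

#' Hard classification at the model threshold
#'
#' @param model a trained [DisulfideClassifier-class].
#' @param f feature vector or matrix (see [scoreFeatures()]).
#' @param threshold decision threshold; defaults to the model's configured
#'   value. A score at or above the threshold is classified bonded.
#' @return character vector of `"bonded"` / `"nonbonded"`.
#' @export
classifyFeatures <- function(model, f, threshold = NULL) {
  if (is.null(threshold)) threshold <- model@config$threshold
  stopifnot(threshold > 0, threshold < 1)
  ifelse(scoreFeatures(model, f) >= threshold, "bonded", "nonbonded")
}

.MODEL_FORMAT <- "DisulfideDesign-classifier"
.MODEL_VERSION <- 1L

#' Save / load a trained classifier
#'
#' The weight file is JSON: format tag and version, the configuration,
#' layer shapes, and flat weight arrays at full double precision, so a
#' reloaded model reproduces scores bit-identically.
#'
#' @param model a [DisulfideClassifier-class].
#' @param path file path for the JSON weight container.
#' @return `saveClassifier`: invisibly, `path`. `loadClassifier`: the
#'   restored [DisulfideClassifier-class]. Loading fails on truncated
#'   files, unknown format tags or inconsistent shapes.
#' @export
saveClassifier <- function(model, path) {
  stopifnot(is(model, "DisulfideClassifier"))
  w <- model@weights
  obj <- list(
    format = .MODEL_FORMAT, version = .MODEL_VERSION,
    config = model@config,
    shapes = lapply(w[c("W1", "W2", "W3")], dim),
    weights = lapply(w, as.numeric),
    trainingLog = model@trainingLog
  )
  # I(17): 17 significant digits, enough for doubles to round-trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse model file '", path,
                                           "': ", conditionMessage(e)))
  if (!identical(obj$format, .MODEL_FORMAT)) {
    stop("not a ", .MODEL_FORMAT, " file: ", path)
  }
  if (!identical(as.integer(obj$version), .MODEL_VERSION)) {
    stop("unsupported model file version: ", obj$version)
  }
  cfg <- obj$config
  cfg$layerSizes <- as.integer(cfg$layerSizes)
  sizes <- cfg$layerSizes
  w <- list()
  for (k in 1:3) {
    Wk <- obj$weights[[paste0("W", k)]]
    if (length(Wk) != sizes[k] * sizes[k + 1]) {
      stop("weight shape mismatch in model file: W", k)
    }
    w[[paste0("W", k)]] <- matrix(Wk, sizes[k], sizes[k + 1])
    bk <- obj$weights[[paste0("b", k)]]
    if (length(bk) != sizes[k + 1]) {
      stop("weight shape mismatch in model file: b", k)
    }
    w[[paste0("b", k)]] <- as.numeric(bk)
  }
  log <- as.data.frame(obj$trainingLog)
  new("DisulfideClassifier", config = cfg, weights = w, trainingLog = log)
}
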