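#' Reduce a feature table to principal-component scores
#'
#' Centred (not rescaled) PCA via [stats::prcomp()]; normalize first if
#' features are on different scales.  Component signs follow a fixed
#' convention — the loading of largest magnitude on each component is
#' made positive — so results are deterministic across platforms.
#'
#' @param t a [FeatureTable-class].
#' @param k number of components, at most `min(nrow - 1, ncol)`.
#' @return A [FeatureTable-class] of scores (`PC1`..`PCk`, provenance
#'   `"other"`), labels carried over.
#' @export
pcaReduce <- function(t, k) {
  stopifnot(is(t, "FeatureTable"))
  v <- featureValues(t)
  kmax <- min(nrow(v) - 1L, ncol(v))
  if (k < 1 || k > kmax)
    stop(sprintf("k must be in 1..%d for a %d x %d table", kmax,
                 nrow(v), ncol(v)))
  pr <- prcomp(v, center = TRUE, scale. = FALSE)
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pr$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  featureTable(scores, provenance = "other", labels = t@labels)
}

# Sammon stress E = (1/sum d) * sum (d - delta)^2 / d over pairs, with
# d the input-space and delta the embedding-space distances.
.sammonStress <- function(Y, D) {
  delta <- as.matrix(dist(Y))
  lower <- lower.tri(D)
  sum((D[lower] - delta[lower])^2 / D[lower]) / sum(D[lower])
}

.sammonGrad <- function(Y, D) {
  n <- nrow(Y)
  delta <- as.matrix(dist(Y))
  c0 <- sum(D[lower.tri(D)])
  G <- matrix(0, n, ncol(Y))
  for (i in seq_len(n)) {
    j <- setdiff(seq_len(n), i)
    dij <- D[i, j]; eij <- delta[i, j]
    w <- -2 * (dij - eij) / (dij * pmax(eij, 1e-12)) / c0
    diff <- sweep(-Y[j, , drop = FALSE], 2, Y[i, ], "+")  # y_i - y_j
    G[i, ] <- colSums(diff * w)
  }
  G
}

#' Sammon mapping of a feature table
#'
#' Nonlinear projection minimizing the distance-weighted stress
#' \deqn{E = \frac{1}{\sum_{i<j} d_{ij}} \sum_{i<j}
#'       \frac{(d_{ij}-\delta_{ij})^2}{d_{ij}},}
#' where d are input-space and delta embedding-space pairwise
#' distances.  Optimized by gradient descent with step halving from a
#' deterministic PCA initialization, so accepted iterations never
#' increase the stress.  Duplicate input rows (zero d) are perturbed by
#' seeded jitter of 1e-9 times the mean distance.
#'
#' @param t a [FeatureTable-class] with at least 3 rows.
#' @param targetDim embedding dimension (>= 1).
#' @param learningRate initial step size (default 0.3).
#' @param maxIters maximum accepted iterations (default 500).
#' @param tol convergence on relative stress change (default 1e-9).
#' @param seed seed for the duplicate-row jitter only; the optimization
#'   itself is deterministic.
#' @return list with `embedding` (a [FeatureTable-class], columns
#'   `SAM1`..), `stress` (final value) and `stressTrace`
#'   (non-increasing across accepted iterations).
#' @export
sammonMap <- function(t, targetDim = 2, learningRate = 0.3,
                      maxIters = 500, tol = 1e-9, seed = 1) {
  stopifnot(is(t, "FeatureTable"))
  X <- featureValues(t)
  if (nrow(X) < 3) stop("Sammon mapping needs at least 3 rows")
  if (targetDim < 1 || targetDim > min(nrow(X) - 1L, ncol(X)))
    stop("targetDim must be in 1..min(nrow - 1, ncol)")
  if (learningRate <= 0) stop("learningRate must be positive")
  D <- as.matrix(dist(X))
  if (any(D[lower.tri(D)] == 0)) {
    meanD <- mean(D[lower.tri(D)])
    if (meanD == 0) stop("all rows are identical; distances are degenerate")
    X <- X + .withSeed(seed, matrix(rnorm(length(X), sd = 1e-9 * meanD),
                                    nrow(X)))
    D <- as.matrix(dist(X))
    if (any(D[lower.tri(D)] == 0))
      stop("duplicate rows persist beyond the jitter tolerance")
    message("sammonMap: duplicate rows perturbed by seeded 1e-9 jitter")
  }
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  Y <- pr$x[, seq_len(targetDim), drop = FALSE]
  stress <- .sammonStress(Y, D)
  trace <- stress
  lr <- learningRate
  for (iter in seq_len(maxIters)) {
    G <- .sammonGrad(Y, D)
    accepted <- FALSE
    step <- lr
    for (h in 1:30) {
      cand <- Y - step * G
      sc <- .sammonStress(cand, D)
      if (is.finite(sc) && sc <= stress) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    converged <- (stress - sc) <= tol * max(stress, 1e-300)
    Y <- cand
    stress <- sc
    trace <- c(trace, stress)
    if (converged) break
  }
  rownames(Y) <- rownames(X)
  colnames(Y) <- paste0("SAM", seq_len(targetDim))
  list(embedding = featureTable(Y, provenance = "other",
                                labels = t@labels),
       stress = stress, stressTrace = trace, iterations = length(trace) - 1L)
}

# evaluate an expression under a temporary RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
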