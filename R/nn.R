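.ACTIVATION_CODES <- c(linear = 0L, relu = 1L, leaky_relu = 2L,
                       softplus = 3L, sigmoid = 4L, tanh = 5L)

#' Configuration of the feed-forward network
#'
#' The reference architecture is two hidden layers of 15 nodes with
#' ReLU activation; the output layer is affine (no activation), so the
#' target metric is modelled on its natural scale.  Training is
#' full-batch Adam on mean-squared error, run for `maxEpochs` or until
#' the relative loss change falls below `tol`.
#'
#' @param inputDim number of input features, or `NULL` to infer at fit
#'   time (features can drop out fold-wise when their range collapses).
#' @param hidden integer vector of hidden-layer widths (default
#'   `c(15, 15)`).
#' @param activation one of `"relu"`, `"leaky_relu"`, `"softplus"`,
#'   `"sigmoid"`, `"tanh"`, `"linear"`.
#' @param leakySlope negative-side slope for `leaky_relu` (default
#'   0.01).
#' @param learningRate Adam step size (default 1e-3).
#' @param maxEpochs full-batch epochs (default 5000).
#' @param tol relative-loss convergence tolerance (default 1e-10).
#' @param l2 optional L2 penalty (default 0: the reference setup has no
#'   regularization).
#' @param seed base seed; fold seeds are derived as `seed + fold`.
#' @param targetMetric selectivity metric the labels are trained on,
#'   see [toMetric()].
#' @return a validated config list of class `"nnConfig"`.
#' @examples
#' cfg <- nnConfig(activation = "relu", seed = 7)
#' @export
nnConfig <- function(inputDim = NULL, hidden = c(15L, 15L),
                     activation = "relu", leakySlope = 0.01,
                     learningRate = 1e-3, maxEpochs = 5000L,
                     tol = 1e-10, l2 = 0, seed = 1L,
                     targetMetric = "s_select") {
  activation <- match.arg(activation, names(.ACTIVATION_CODES))
  targetMetric <- match.arg(targetMetric, .SELECTIVITY_METRICS)
  hidden <- as.integer(hidden)
  if (any(hidden < 1L)) stop("hidden widths must be >= 1")
  if (learningRate <= 0) stop("learningRate must be > 0")
  if (maxEpochs < 1) stop("maxEpochs must be >= 1")
  if (l2 < 0) stop("l2 must be >= 0")
  structure(list(inputDim = if (is.null(inputDim)) NULL
                            else as.integer(inputDim),
                 hidden = hidden, activation = activation,
                 leakySlope = leakySlope, learningRate = learningRate,
                 maxEpochs = as.integer(maxEpochs), tol = tol, l2 = l2,
                 seed = as.integer(seed), targetMetric = targetMetric),
            class = "nnConfig")
}

#' Activation functions
#'
#' Scalar/vector evaluation of the supported hidden-layer activations;
#' softplus is computed overflow-safely as `max(x, 0) + log1p(exp(-|x|))`.
#'
#' @param kind activation name, see [nnConfig()].
#' @param x numeric vector.
#' @param leakySlope slope for `leaky_relu`.
#' @return numeric vector.
#' @examples
#' nnActivation("relu", c(-2, 3))       # 0 3
#' nnActivation("softplus", 0)          # log(2)
#' @export
nnActivation <- function(kind, x, leakySlope = 0.01) {
  kind <- match.arg(kind, names(.ACTIVATION_CODES))
  switch(kind,
         linear = x,
         relu = pmax(x, 0),
         leaky_relu = ifelse(x > 0, x, leakySlope * x),
         softplus = pmax(x, 0) + log1p(exp(-abs(x))),
         sigmoid = 1 / (1 + exp(-x)),
         tanh = tanh(x))
}

#' He-scaled seeded weight initialization
#'
#' Weights are drawn N(0, 2/fan_in) (He scaling, suited to
#' rectifier-family activations); biases start at zero.  Identical
#' (config, seed) gives bit-identical parameters.
#'
#' @param cfg an [nnConfig()] with `inputDim` set.
#' @param seed overrides `cfg$seed` when given (used for fold seeds).
#' @return list with `W` (list of weight matrices) and `b` (list of
#'   bias vectors).
#' @export
initializeNN <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "nnConfig"))
  if (is.null(cfg$inputDim))
    stop("inputDim must be set (or inferred via fitNNModel) before ",
         "initialization")
  widths <- c(cfg$inputDim, cfg$hidden, 1L)
  .withSeed(seed, {
    W <- vector("list", length(widths) - 1L)
    b <- vector("list", length(widths) - 1L)
    for (l in seq_along(W)) {
      fanIn <- widths[l]
      W[[l]] <- matrix(rnorm(widths[l + 1L] * fanIn, sd = sqrt(2 / fanIn)),
                       nrow = widths[l + 1L], ncol = fanIn)
      b[[l]] <- numeric(widths[l + 1L])
    }
    list(W = W, b = b)
  })
}

#' Forward pass of a parameter set
#'
#' @param params list with `W` and `b` as from [initializeNN()] or a
#'   fitted [NNModel-class]'s slots.
#' @param x numeric matrix (rows = samples) or a single feature vector,
#'   already normalized.
#' @param activation,leakySlope hidden-layer activation.
#' @return numeric vector of predictions (no output activation).
#' @export
nnForward <- function(params, x, activation = "relu", leakySlope = 0.01) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(params$W[[1]]))
    stop(sprintf("input has %d features but the network expects %d",
                 ncol(x), ncol(params$W[[1]])))
  as.numeric(
    nn_forward_cpp(x, params$W, params$b,
                   .ACTIVATION_CODES[[match.arg(activation,
                                                names(.ACTIVATION_CODES))]],
                   leakySlope))
}

# low-level trainer on an already-normalized matrix; returns W/b/trace
.trainRaw <- function(x, y, cfg, seed = cfg$seed) {
  if (nrow(x) < 2) stop("training needs at least 2 rows")
  if (any(!is.finite(y))) stop("labels must be finite")
  cfg$inputDim <- ncol(x)
  init <- initializeNN(cfg, seed = seed)
  fit <- nn_train_cpp(x, y, init$W, init$b,
                      .ACTIVATION_CODES[[cfg$activation]], cfg$leakySlope,
                      cfg$learningRate, cfg$maxEpochs, cfg$tol, cfg$l2)
  fit
}

#' Fit the network on (a subset of) a labeled feature table
#'
#' Fits min-max normalization on the training rows, scales them, trains
#' by full-batch Adam, and returns the model with its preprocessing
#' attached, so predictions on new ligands reuse the training-time
#' scaling (no leakage).
#'
#' @param t a labeled [FeatureTable-class].
#' @param cfg an [nnConfig()].
#' @param rows training rows (indices or ligand ids; default all).
#' @param seed training seed (default `cfg$seed`).
#' @return An [NNModel-class].
#' @examples
#' sim <- simulateFeatureTable(plantedSystem(seed = 3))
#' cfg <- nnConfig(maxEpochs = 200)
#' m <- fitNNModel(sim$train, cfg)
#' @export
fitNNModel <- function(t, cfg, rows = NULL, seed = cfg$seed) {
  stopifnot(is(t, "FeatureTable"), inherits(cfg, "nnConfig"))
  if (is.null(t@labels)) stop("fitting needs a labeled table")
  if (is.null(rows)) rows <- seq_len(nrow(featureValues(t)))
  if (is.character(rows)) rows <- match(rows, ligandIds(t))
  norm <- minmaxFit(t, rows)
  train <- t[rows, ]
  x <- featureValues(minmaxApply(train, norm))
  y <- toMetric(train@labels, cfg$targetMetric)
  fit <- .trainRaw(x, y, cfg, seed = seed)
  cfg$inputDim <- ncol(x)
  new("NNModel", weights = fit$W, biases = fit$b,
      config = unclass(cfg), norm = norm, targetMetric = cfg$targetMetric)
}

#' Predict selectivity (on the model's metric) for new ligands
#'
#' @param object an [NNModel-class].
#' @param newdata a [FeatureTable-class] containing at least the
#'   model's features.
#' @param ... unused.
#' @return named numeric vector of predictions on the model's target
#'   metric scale.
#' @export
setMethod("predict", "NNModel", function(object, newdata, ...) {
  stopifnot(is(newdata, "FeatureTable"))
  x <- featureValues(minmaxApply(newdata, object@norm))
  pred <- nnForward(list(W = object@weights, b = object@biases), x,
                    activation = object@config$activation,
                    leakySlope = object@config$leakySlope)
  setNames(pred, ligandIds(newdata))
})

#' Serialize / restore a fitted model as JSON
#'
#' The document stores the config, per-layer weights and biases, the
#' min-max parameters and the target metric; it is library-agnostic
#' (plain numbers only).
#'
#' @param model an [NNModel-class].
#' @param path JSON file path.
#' @return `saveNNModel`: `path` invisibly. `loadNNModel`: the
#'   restored [NNModel-class].
#' @export
saveNNModel <- function(model, path) {
  stopifnot(is(model, "NNModel"))
  doc <- list(config = model@config[!vapply(model@config, is.null,
                                            logical(1))],
              weights = model@weights, biases = model@biases,
              normalization = list(mins = as.list(model@norm@mins),
                                   maxs = as.list(model@norm@maxs),
                                   excluded = model@norm@excluded),
              target_metric = model@targetMetric)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveNNModel
#' @export
loadNNModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(nnConfig, doc$config[setdiff(names(doc$config),
                                              "inputDim")])
  cfg$inputDim <- doc$config$inputDim
  W <- lapply(doc$weights, function(w) {
    m <- as.matrix(w); storage.mode(m) <- "double"; m
  })
  b <- lapply(doc$biases, as.numeric)
  norm <- new("MinMaxParams",
              mins = unlist(doc$normalization$mins),
              maxs = unlist(doc$normalization$maxs),
              excluded = as.character(doc$normalization$excluded))
  new("NNModel", weights = W, biases = b, config = unclass(cfg),
      norm = norm, targetMetric = doc$target_metric)
}
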