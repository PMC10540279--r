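#' Anti-overfitting battery and model comparison
#'
#' A model trained on 17 ligands can memorise noise; these tests verify
#' that apparent skill vanishes when the signal is destroyed.
#' [yShuffleTest()] permutes the labels; [xyRandomizationTest()]
#' replaces features and/or labels with uniform random values.  A sound
#' model must lose all skill (R-squared near 0, RMSE near the label
#' spread) under both.  [metricBakeoff()] compares the five selectivity
#' encodings as training targets, and [ddgBaseline()] is the
#' conventional alternative: predicting er directly from computed
#' transition-state free-energy differences.
#'
#' @name validation-battery
NULL

.randomizationReport <- function(mode, rmse, rsq, reference) {
  structure(list(mode = mode, replicates = length(rmse),
                 rmse = rmse, rsq = rsq,
                 meanRmse = mean(rmse), sdRmse = sd(rmse),
                 meanRsq = mean(rsq, na.rm = TRUE),
                 sdRsq = sd(rsq, na.rm = TRUE),
                 referenceRmse = reference$rmse,
                 referenceRsq = reference$rsq),
            class = "randomizationReport")
}

#' @export
print.randomizationReport <- function(x, ...) {
  cat(sprintf("Randomization report (%s), %d replicates\n", x$mode,
              x$replicates))
  cat(sprintf("  shuffled/random: RMSE %.3f +/- %.3f | R^2 %.3f +/- %.3f\n",
              x$meanRmse, x$sdRmse, x$meanRsq, x$sdRsq))
  if (is.finite(x$referenceRmse))
    cat(sprintf("  reference run:   RMSE %.3f | R^2 %.3f\n",
                x$referenceRmse, x$referenceRsq))
  invisible(x)
}

#' Y-shuffling test
#'
#' Each replicate permutes the labels with a seeded permutation (the
#' features are untouched), runs full leave-one-out cross-validation,
#' and records RMSE and R-squared; the unpermuted reference run is
#' reported alongside.  For a model that learned real structure the
#' shuffled RMSEs are far above the reference.
#'
#' @param t a labeled [FeatureTable-class].
#' @param cfg an [nnConfig()].
#' @param replicates number of shuffles (default 20).
#' @param seed base seed; replicate i permutes under `seed + i`.
#' @param permutations optional list of explicit permutations (for
#'   controls; an identity permutation reproduces the reference run
#'   exactly).
#' @return a `randomizationReport` list: per-replicate `rmse`/`rsq`,
#'   their means and standard deviations, and the reference metrics.
#' @export
yShuffleTest <- function(t, cfg, replicates = 20, seed = 1,
                         permutations = NULL) {
  stopifnot(is(t, "FeatureTable"), inherits(cfg, "nnConfig"))
  if (is.null(t@labels)) stop("Y-shuffling needs labels")
  if (is.null(permutations)) {
    if (replicates < 1) stop("replicates must be >= 1")
    n <- nrow(featureValues(t))
    permutations <- lapply(seq_len(replicates), function(i)
      .withSeed(seed + i, sample(n)))
  }
  reference <- looCrossValidate(t, cfg)
  res <- lapply(seq_along(permutations), function(i) {
    perm <- permutations[[i]]
    tp <- t
    selectivityLabels(tp) <- t@labels[perm]
    cv <- tryCatch(looCrossValidate(tp, cfg), error = function(e)
      stop(sprintf("replicate %d: %s", i, conditionMessage(e)),
           call. = FALSE))
    c(cv@rmse, cv@rsq)
  })
  res <- do.call(rbind, res)
  .randomizationReport("y_shuffle", res[, 1], res[, 2],
                       list(rmse = reference@rmse, rsq = reference@rsq))
}

#' X/Y-randomization test
#'
#' Replicates draw fully random data and run leave-one-out
#' cross-validation: mode `"xy"` draws both features (uniform on
#' [0, 1]) and labels (uniform on `labelRange`); `"x"` keeps a real
#' table's labels and randomizes its features; `"y"` keeps the features
#' and randomizes the labels.  The expectation for any mode is no
#' correlation (mean R-squared about 0) and RMSE on the order of the
#' label spread.
#'
#' @param n,p samples and features for mode `"xy"` (defaults 17 and 15,
#'   the reference data regime).
#' @param labelRange range of the uniform random labels in S%.
#' @param cfg an [nnConfig()].
#' @param replicates number of replicates (default 20).
#' @param seed base seed; replicate i draws under `seed + i`.
#' @param mode `"xy"`, `"x"` or `"y"`.
#' @param table labeled [FeatureTable-class], required for the
#'   single-sided modes.
#' @return a `randomizationReport` (reference metrics are `NA` for mode
#'   `"xy"`, which has no reference run).
#' @export
xyRandomizationTest <- function(n = 17, p = 15, labelRange = c(0, 100),
                                cfg = nnConfig(), replicates = 20,
                                seed = 1, mode = c("xy", "x", "y"),
                                table = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "nnConfig"))
  if (replicates < 1) stop("replicates must be >= 1")
  if (mode != "xy") {
    if (is.null(table) || is.null(table@labels))
      stop("modes 'x' and 'y' need a labeled table to keep one side of")
    n <- nrow(featureValues(table))
    p <- ncol(featureValues(table))
  } else if (n < 3 || p < 1) {
    stop("need n >= 3 and p >= 1")
  }
  reference <- if (mode == "xy") list(rmse = NA_real_, rsq = NA_real_)
  else {
    cv <- looCrossValidate(table, cfg)
    list(rmse = cv@rmse, rsq = cv@rsq)
  }
  res <- lapply(seq_len(replicates), function(i) {
    ti <- switch(mode,
      xy = randomTable(n, p, labelRange = labelRange, seed = seed + i),
      x = {
        tr <- randomTable(n, p, labelRange = labelRange, seed = seed + i)
        v <- featureValues(tr)
        dimnames(v) <- dimnames(featureValues(table))
        featureTable(v, provenance = table@provenance,
                     labels = table@labels)
      },
      y = {
        tr <- randomTable(n, 1, labelRange = labelRange, seed = seed + i)
        ty <- table
        selectivityLabels(ty) <- tr@labels
        ty
      })
    cv <- tryCatch(looCrossValidate(ti, cfg), error = function(e)
      stop(sprintf("replicate %d: %s", i, conditionMessage(e)),
           call. = FALSE))
    c(cv@rmse, cv@rsq)
  })
  res <- do.call(rbind, res)
  .randomizationReport(paste0(mode, "_random"), res[, 1], res[, 2],
                       reference)
}

#' Five-metric model bake-off
#'
#' Trains one network per selectivity encoding (ee, er ratio, ln er,
#' S%, R%) on the training table, cross-validates each on it, and
#' evaluates all five on a common validation table after converting
#' every prediction to the S-percentage scale, so the validation RMSEs
#' are comparable across encodings.  The winner is the metric with the
#' lowest validation RMSE (ties broken toward `s_select`, then
#' lexicographically).  Out-of-domain predictions (e.g. a negative er
#' ratio) are clamped to the nearest valid value and counted, never
#' fatal.
#'
#' @param train,validation labeled [FeatureTable-class]s sharing
#'   feature names.
#' @param cfg an [nnConfig()]; its `targetMetric` is overridden per
#'   model.
#' @param trainCV run leave-one-out cross-validation on the training
#'   table for each metric (default `TRUE`).
#' @return list of class `"metricBakeoff"`: per-metric entries with
#'   the training `cv` ([CVResult-class] or `NULL`), the validation
#'   stats on S% (`rmse`, `rsq`, `slope`, `predictedS`, `clamped`), and
#'   `winner`.
#' @export
metricBakeoff <- function(train, validation, cfg = nnConfig(),
                          trainCV = TRUE) {
  stopifnot(is(train, "FeatureTable"), is(validation, "FeatureTable"))
  if (is.null(train@labels) || is.null(validation@labels))
    stop("both tables must be labeled")
  if (!setequal(featureNames(train), featureNames(validation)))
    stop("training and validation tables must share feature names")
  obsS <- sPercent(validation@labels)
  entries <- lapply(.SELECTIVITY_METRICS, function(metric) {
    cfgm <- cfg
    cfgm$targetMetric <- metric
    cv <- if (trainCV) looCrossValidate(train, cfgm) else NULL
    model <- fitNNModel(train, cfgm)
    pred <- as.numeric(predict(model, validation))
    conv <- .metricToS(pred, metric, majorLabel = "S")
    d <- .diagnostics(obsS, conv$s)
    list(metric = metric, cv = cv,
         validation = list(rmse = d$rmse, rsq = d$rsq, slope = d$slope,
                           predictedS = setNames(conv$s,
                                                 ligandIds(validation)),
                           clamped = conv$clamped))
  })
  names(entries) <- .SELECTIVITY_METRICS
  rmses <- vapply(entries, function(e) e$validation$rmse, numeric(1))
  ord <- order(rmses, names(rmses) != "s_select", names(rmses))
  structure(list(models = entries, winner = names(rmses)[ord[1]],
                 validationRmse = rmses),
            class = "metricBakeoff")
}

#' @export
print.metricBakeoff <- function(x, ...) {
  cat("Five-metric bake-off (validation RMSE on S%):\n")
  for (m in names(x$validationRmse))
    cat(sprintf("  %-9s %8.3f%s\n", m, x$validationRmse[[m]],
                if (m == x$winner) "  <- winner" else ""))
  invisible(x)
}

#' Free-energy baseline: predict er from computed ddG directly
#'
#' The conventional approach converts each ligand's computed
#' transition-state free-energy difference to an er through the
#' Boltzmann relation ([ddgToEr()]) and compares with experiment on
#' the S% scale.  Negative values are interpreted as favouring the
#' other enantiomer (with a message).  Because ~1 kcal/mol errors are
#' typical of the underlying energies and er responds exponentially,
#' this baseline degrades quickly with energy noise.
#'
#' @param ddg named numeric vector of free-energy differences
#'   (kcal/mol); positive favours `majorLabel`.
#' @param labels a [Selectivity-class] of experimental records.
#' @param labelIds ligand ids of `labels` (default `names(ddg)` when
#'   lengths match).
#' @param majorLabel enantiomer favoured by positive `ddg` (default
#'   "S").
#' @param temperature Kelvin.
#' @param nn optional [CVResult-class] of the network on the same
#'   ligands, echoed in the report for side-by-side comparison.
#' @return list of class `"ddgBaseline"` with `rmse`, `rsq`, `slope`
#'   on S%, per-ligand `predictedS`/`observedS`, and `nn` when given.
#' @export
ddgBaseline <- function(ddg, labels, labelIds = NULL, majorLabel = "S",
                        temperature = 298.15, nn = NULL) {
  stopifnot(is(labels, "Selectivity"))
  if (is.null(labelIds)) labelIds <- names(ddg)
  if (is.null(names(ddg)) || is.null(labelIds))
    stop("ddg values and labels must carry ligand ids")
  common <- intersect(names(ddg), labelIds)
  if (!length(common))
    stop("no overlapping ligand ids between ddg values and labels")
  ddg <- ddg[common]
  obs <- labels[match(common, labelIds)]
  flip <- ddg < 0
  if (any(flip))
    message(sum(flip), " negative ddg value(s) interpreted as favouring ",
            "the opposite enantiomer")
  other <- if (majorLabel == "S") "R" else "S"
  predS <- numeric(length(ddg))
  if (any(!flip))
    predS[!flip] <- sPercent(ddgToEr(ddg[!flip], majorLabel, temperature))
  if (any(flip))
    predS[flip] <- sPercent(ddgToEr(-ddg[flip], other, temperature))
  d <- .diagnostics(sPercent(obs), predS)
  structure(list(rmse = d$rmse, rsq = d$rsq, slope = d$slope,
                 predictedS = setNames(predS, common),
                 observedS = setNames(sPercent(obs), common),
                 temperature = temperature, nn = nn),
            class = "ddgBaseline")
}

#' @export
print.ddgBaseline <- function(x, ...) {
  cat(sprintf("ddG baseline (T = %.2f K): RMSE %.3f | R^2 %.3f | slope %.3f\n",
              x$temperature, x$rmse, x$rsq, x$slope))
  if (!is.null(x$nn))
    cat(sprintf("  network comparison:  RMSE %.3f | R^2 %.3f\n",
                x$nn@rmse, x$nn@rsq))
  invisible(x)
}
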