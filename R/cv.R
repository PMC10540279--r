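# regression diagnostics shared by LOO and evaluation reports
.diagnostics <- function(obs, pred) {
  rmse <- sqrt(mean((pred - obs)^2))
  flags <- character()
  if (sd(obs) == 0 || sd(pred) == 0) {
    rsq <- NA_real_; slope <- NA_real_; rsqAlt <- NA_real_
    flags <- "degenerate: constant observed or predicted values"
  } else {
    rsq <- cor(pred, obs)^2
    slope <- as.numeric(coef(lm(pred ~ obs))[2])
    rsqAlt <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  }
  list(rmse = rmse, rsq = rsq, slope = slope, rsqAlt = rsqAlt,
       flags = flags)
}

# convert a prediction on any metric scale to S%, clamping values that
# fall outside the metric's domain; returns values plus clamp count
.metricToS <- function(value, metric, majorLabel = "S") {
  clamped <- 0L
  v <- value
  if (metric == "ee") {
    bad <- v < 0 | v > 99.9
    clamped <- sum(bad)
    v <- pmin(pmax(v, 0), 99.9)
  } else if (metric == "er_ratio") {
    bad <- v <= 0
    clamped <- sum(bad)
    v[v <= 0] <- 1e-2
  } else if (metric %in% c("s_select", "r_select")) {
    bad <- v <= 0.05 | v >= 99.95
    clamped <- sum(bad)
    v <- pmin(pmax(v, 0.05), 99.95)
  }                                       # ln_er: every real value is valid
  rec <- fromMetric(v, metric, majorLabel = majorLabel)
  list(s = sPercent(rec), rec = rec, clamped = clamped)
}

.makeCVResult <- function(ids, obs, pred, metric, erStrings = character(),
                          extraFlags = character()) {
  d <- .diagnostics(obs, pred)
  new("CVResult", ligandIds = ids, observed = obs, predicted = pred,
      metric = metric, rmse = d$rmse, rsq = d$rsq, slope = d$slope,
      rsqAlt = d$rsqAlt, erPredicted = erStrings,
      flags = c(d$flags, extraFlags))
}

#' Leave-one-out cross-validation of the network
#'
#' Runs n train/predict cycles: each fold fits min-max normalization
#' and the network on the n-1 remaining ligands (fold seed =
#' `cfg$seed + fold`) and predicts the held-out one, so no information
#' about a ligand leaks into its own prediction.  Rows are sorted by
#' ligand id internally, making the result invariant to input row
#' order.  Diagnostics (RMSE, squared Pearson R, slope of predicted on
#' observed) are computed over the n held-out predictions.
#'
#' @param t a labeled [FeatureTable-class] with >= 3 rows.
#' @param cfg an [nnConfig()].
#' @return A [CVResult-class] on `cfg$targetMetric`'s scale.
#' @examples
#' sim <- simulateFeatureTable(plantedSystem(nTrain = 8, nFeatures = 4,
#'                                           seed = 2))
#' cv <- looCrossValidate(sim$train, nnConfig(maxEpochs = 200))
#' @export
looCrossValidate <- function(t, cfg) {
  stopifnot(is(t, "FeatureTable"), inherits(cfg, "nnConfig"))
  if (is.null(t@labels)) stop("LOO cross-validation needs labels")
  n <- nrow(featureValues(t))
  if (n < 3) stop("LOO cross-validation needs at least 3 ligands")
  t <- t[order(ligandIds(t)), ]
  ids <- ligandIds(t)
  obs <- toMetric(t@labels, cfg$targetMetric)
  pred <- numeric(n)
  for (fold in seq_len(n)) {
    model <- tryCatch(
      fitNNModel(t, cfg, rows = setdiff(seq_len(n), fold),
                 seed = cfg$seed + fold),
      error = function(e)
        stop(sprintf("fold %d (held-out ligand %s): %s", fold, ids[fold],
                     conditionMessage(e)), call. = FALSE))
    pred[fold] <- predict(model, t[fold, ])
  }
  conv <- .metricToS(pred, cfg$targetMetric)
  .makeCVResult(ids, obs, pred, cfg$targetMetric,
                erStrings = formatEr(conv$rec),
                extraFlags = if (conv$clamped)
                  sprintf("%d prediction(s) clamped for er display",
                          conv$clamped) else character())
}

#' Evaluate a fitted model on a labeled table
#'
#' Applies the model's stored normalization, predicts every ligand,
#' and reports RMSE / squared Pearson R / slope on the model's target
#' metric, alongside the predictions rendered as "R:S" er strings.
#'
#' @param model an [NNModel-class].
#' @param t a labeled [FeatureTable-class] whose features include the
#'   model's.
#' @param majorLabel enantiomer assigned the major role when rendering
#'   `ee` / `er_ratio` predictions as er strings.
#' @return A [CVResult-class].
#' @export
evaluateModel <- function(model, t, majorLabel = "S") {
  stopifnot(is(model, "NNModel"), is(t, "FeatureTable"))
  if (is.null(t@labels)) stop("evaluation needs labels")
  have <- featureNames(t)
  want <- names(model@norm@mins)
  missing <- setdiff(want, have)
  if (length(missing))
    stop("table lacks model features: ", paste(missing, collapse = ", "))
  pred <- as.numeric(predict(model, t))
  obs <- toMetric(t@labels, model@targetMetric)
  conv <- .metricToS(pred, model@targetMetric, majorLabel = majorLabel)
  .makeCVResult(ligandIds(t), obs, pred, model@targetMetric,
                erStrings = formatEr(conv$rec),
                extraFlags = if (conv$clamped)
                  sprintf("%d prediction(s) clamped for er display",
                          conv$clamped) else character())
}
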