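#' Run the end-to-end modelling workflow
#'
#' Ties the stages together: obtain feature tables (synthetic preset or
#' user CSVs), reduce the feature set, run leave-one-out
#' cross-validation, train the final model, and optionally run the
#' randomization battery and the five-metric bake-off.  Every artifact
#' is written under `outDir` together with a manifest (config hash,
#' seeds, outputs), and a re-run from the same config is bit-identical.
#'
#' Config keys (YAML/JSON file path or a named list):
#' \describe{
#'   \item{preset}{`"paper-regime"` to simulate the reference data
#'     regime (17/10/3 ligands, 15 features) via
#'     [simulateFeatureTable()].}
#'   \item{inputs}{alternatively: `features_csv` (+ optional
#'     `validation_csv`), or raw `geom_csv` / `electronic_csv` /
#'     `dispersion_csv` / `labels_csv` for [assembleFeatures()].}
#'   \item{selection}{`method` (`"manual"`, `"pca"`, `"sammon"`,
#'     `"none"`) and `k`.}
#'   \item{nn}{arguments for [nnConfig()] (snake_case accepted).}
#'   \item{validation}{`randomize` (logical), `replicates`, `bakeoff`
#'     (logical).}
#'   \item{seed}{master seed; stage seeds derive from it.}
#' }
#'
#' @param config list, or path to a YAML/JSON config file.
#' @param outDir output directory (created; default `config$out_dir`).
#' @param dryRun print the stage plan and return it without side
#'   effects.
#' @return invisibly, a list with the run artifacts (`cv`, `model`,
#'   `manifest`, ...); for `dryRun`, the stage plan.
#' @export
runPipeline <- function(config, outDir = NULL, dryRun = FALSE) {
  cfg <- .loadRunConfig(config)
  if (is.null(outDir)) outDir <- cfg$out_dir
  if (is.null(outDir) && !dryRun) stop("an output directory is required")
  plan <- c("load", "select", "loocv", "train",
            if (isTRUE(cfg$validation$randomize)) "randomize",
            if (isTRUE(cfg$validation$bakeoff)) "bakeoff")
  if (dryRun) {
    message("pipeline plan: ", paste(plan, collapse = " -> "))
    return(invisible(plan))
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[stereonn] stage ", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  tables <- stage("load", .pipelineLoad(cfg))
  train <- tables$train
  writeFeatureCsv(train, file.path(outDir, "features_train.csv"))
  if (!is.null(tables$val1))
    writeFeatureCsv(tables$val1, file.path(outDir, "features_val1.csv"))
  if (!is.null(tables$val2))
    writeFeatureCsv(tables$val2, file.path(outDir, "features_val2.csv"))

  sel <- cfg$selection
  reduced <- stage("select", .pipelineSelect(train, sel))
  writeFeatureCsv(reduced$train, file.path(outDir, "features_reduced.csv"))
  val1r <- if (!is.null(tables$val1)) reduced$apply(tables$val1)
  val2r <- if (!is.null(tables$val2)) reduced$apply(tables$val2)

  nnArgs <- .snakeToCamel(cfg$nn)
  nnArgs$seed <- nnArgs$seed %||% cfg$seed
  nncfg <- do.call(nnConfig, nnArgs)

  cv <- stage("loocv", looCrossValidate(reduced$train, nncfg))
  write.csv(asPairs(cv), file.path(outDir, "loocv_pairs.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(metric = cv@metric, rmse = cv@rmse,
                            rsq = cv@rsq, slope = cv@slope),
                       file.path(outDir, "loocv_metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  model <- stage("train", fitNNModel(reduced$train, nncfg))
  saveNNModel(model, file.path(outDir, "model.json"))

  reports <- list()
  if (isTRUE(cfg$validation$randomize)) {
    rep <- stage("randomize",
                 yShuffleTest(reduced$train, nncfg,
                              replicates = cfg$validation$replicates %||% 20,
                              seed = cfg$seed + 1000L))
    reports$randomization <- rep[c("mode", "replicates", "meanRmse",
                                   "sdRmse", "meanRsq", "sdRsq",
                                   "referenceRmse", "referenceRsq")]
  }
  if (isTRUE(cfg$validation$bakeoff)) {
    if (is.null(val1r))
      stop("stage 'bakeoff' failed: no validation table available")
    bo <- stage("bakeoff", metricBakeoff(reduced$train, val1r, nncfg,
                                         trainCV = FALSE))
    reports$bakeoff <- list(winner = bo$winner,
                            validation_rmse = as.list(bo$validationRmse))
  }
  if (length(reports))
    jsonlite::write_json(reports, file.path(outDir, "reports.json"),
                         auto_unbox = TRUE, digits = NA)

  cfgPath <- file.path(outDir, "config.json")
  # the output path is not part of the scientific configuration; keep
  # the recorded config (and its hash) location-independent
  jsonlite::write_json(cfg[setdiff(names(cfg), "out_dir")], cfgPath,
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "stereonn",
    version = as.character(utils::packageVersion("stereonn")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfgPath)),
    stages = plan,
    outputs = sort(setdiff(list.files(outDir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(tables = tables, reduced = reduced$train, cv = cv,
                 model = model, reports = reports, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.loadRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config$seed <- as.integer(config$seed %||% 1L)
  config$selection <- config$selection %||% list(method = "none")
  config$nn <- config$nn %||% list()
  config$validation <- config$validation %||% list()
  config
}

.snakeToCamel <- function(x) {
  if (!length(x)) return(list())
  names(x) <- gsub("_(\\w)", "\\U\\1", names(x), perl = TRUE)
  x
}

.pipelineLoad <- function(cfg) {
  if (identical(cfg$preset, "paper-regime")) {
    sim <- simulateFeatureTable(plantedSystem(seed = cfg$seed))
    return(sim[c("train", "val1", "val2")])
  }
  inp <- cfg$inputs
  if (is.null(inp)) stop("config needs a 'preset' or an 'inputs' block")
  if (!is.null(inp$features_csv)) {
    train <- readFeatureCsv(inp$features_csv)
    if (is.null(selectivityLabels(train)))
      stop("feature CSV has no er labels")
    val1 <- if (!is.null(inp$validation_csv))
      readFeatureCsv(inp$validation_csv)
    return(list(train = train, val1 = val1, val2 = NULL))
  }
  if (is.null(inp$labels_csv))
    stop("missing labels: supply inputs$labels_csv")
  train <- assembleFeatures(inp$geom_csv, electronic = inp$electronic_csv,
                            dispersion = inp$dispersion_csv,
                            labels = inp$labels_csv)
  list(train = train, val1 = NULL, val2 = NULL)
}

.pipelineSelect <- function(train, sel) {
  method <- sel$method %||% "none"
  k <- sel$k
  if (method == "none")
    return(list(train = train, apply = function(t) t))
  if (method == "manual") {
    ranking <- correlationRank(train)
    keep <- featureNames(selectManual(train, k, ranking))
    return(list(train = train[, featureNames(train) %in% keep],
                apply = function(t) t[, featureNames(t) %in% keep]))
  }
  if (method == "pca") {
    norm <- minmaxFit(train)
    pr <- prcomp(featureValues(minmaxApply(train, norm)), center = TRUE,
                 scale. = FALSE)
    applyPca <- function(t) {
      x <- featureValues(minmaxApply(t, norm))
      scores <- scale(x, center = pr$center, scale = FALSE) %*%
        pr$rotation[, seq_len(k), drop = FALSE]
      for (j in seq_len(k)) {
        load <- pr$rotation[, j]
        if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
      }
      colnames(scores) <- paste0("PC", seq_len(k))
      featureTable(scores, provenance = "other",
                   labels = selectivityLabels(t))
    }
    return(list(train = applyPca(train), apply = applyPca))
  }
  if (method == "sammon") {
    norm <- minmaxFit(train)
    emb <- sammonMap(minmaxApply(train, norm), targetDim = k)
    # out-of-sample rows are not embeddable by Sammon; validation
    # tables fall back to the PCA projection of the same data
    pr <- prcomp(featureValues(minmaxApply(train, norm)), center = TRUE,
                 scale. = FALSE)
    applyOut <- function(t) {
      x <- featureValues(minmaxApply(t, norm))
      scores <- scale(x, center = pr$center, scale = FALSE) %*%
        pr$rotation[, seq_len(k), drop = FALSE]
      colnames(scores) <- paste0("SAM", seq_len(k))
      featureTable(scores, provenance = "other",
                   labels = selectivityLabels(t))
    }
    return(list(train = emb$embedding, apply = applyOut))
  }
  stop("unknown selection method: ", method)
}
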