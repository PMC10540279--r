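#' Assemble a per-ligand feature table from its source files
#'
#' Joins the three feature families on `ligand_id`: geometric
#' descriptors (long format, as produced by [extractDescriptors()]),
#' externally computed electronic and dispersion features (wide CSV,
#' one column per feature), and experimental er labels.  The join is
#' strict: every ligand present in the geometry block must be covered
#' by each supplied source, and assembly fails loudly naming any gap.
#' Rows are sorted by ligand id and columns ordered geometric,
#' electronic, dispersion, so the result is independent of input row
#' order.
#'
#' @param geom data.frame or CSV path in long descriptor format
#'   (columns `ligand_id`, `name` (or `descriptor` + `role`), `value`).
#' @param electronic,dispersion optional data.frame or CSV path, wide:
#'   `ligand_id` plus one numeric column per feature.
#' @param labels optional data.frame or CSV path with columns
#'   `ligand_id` and `er` ("X:Y" strings, R:S convention).
#' @param erFormat printing convention of the label strings, see
#'   [parseEr()].
#' @return A [FeatureTable-class].
#' @examples
#' geom <- data.frame(ligand_id = rep(c("L1", "L2", "L3"), each = 2),
#'                    name = rep(c("planarity_proR", "planarity_proS"), 3),
#'                    value = runif(6))
#' aux <- data.frame(ligand_id = c("L1", "L2", "L3"),
#'                   c2_pop = runif(3), p_pop = runif(3))
#' assembleFeatures(geom, electronic = aux)
#' @export
assembleFeatures <- function(geom, electronic = NULL, dispersion = NULL,
                             labels = NULL, erFormat = "R:S") {
  geom <- .readTabular(geom)
  if (!is.null(geom$name)) {
    long <- geom[, c("ligand_id", "name", "value")]
  } else if (all(c("descriptor", "role") %in% names(geom))) {
    long <- data.frame(ligand_id = geom$ligand_id,
                       name = paste0(geom$descriptor,
                                     ifelse(geom$role == "pro_R",
                                            "_proR", "_proS")),
                       value = geom$value, stringsAsFactors = FALSE)
  } else {
    stop("geometry input needs columns ligand_id + name + value (or ",
         "ligand_id + descriptor + role + value)")
  }
  ids <- sort(unique(long$ligand_id))
  feats <- sort(unique(long$name))
  if (anyDuplicated(long[, c("ligand_id", "name")]))
    stop("duplicate geometric descriptor entries for the same ligand")
  m <- matrix(NA_real_, length(ids), length(feats),
              dimnames = list(ids, feats))
  m[cbind(match(long$ligand_id, ids), match(long$name, feats))] <- long$value
  if (any(is.na(m))) {
    gaps <- which(is.na(m), arr.ind = TRUE)
    stop("geometry block has gaps for: ",
         paste(unique(ids[gaps[, 1]]), collapse = ", "))
  }
  prov <- rep("geometric", ncol(m))

  addBlock <- function(m, prov, src, tag) {
    if (is.null(src)) return(list(m = m, prov = prov))
    src <- .readTabular(src)
    if (!"ligand_id" %in% names(src))
      stop(tag, " block needs a ligand_id column")
    missing <- setdiff(ids, src$ligand_id)
    if (length(missing))
      stop(tag, " block is missing ligands: ",
           paste(missing, collapse = ", "))
    src <- src[match(ids, src$ligand_id), , drop = FALSE]
    cols <- setdiff(names(src), "ligand_id")
    if (!length(cols)) stop(tag, " block has no feature columns")
    dup <- intersect(cols, colnames(m))
    if (length(dup))
      stop("duplicate feature names across blocks: ",
           paste(dup, collapse = ", "))
    block <- as.matrix(src[, cols, drop = FALSE])
    storage.mode(block) <- "double"
    if (any(is.na(block)))
      stop(tag, " block has missing values for: ",
           paste(unique(ids[which(is.na(block), arr.ind = TRUE)[, 1]]),
                 collapse = ", "))
    rownames(block) <- ids
    list(m = cbind(m, block), prov = c(prov, rep(tag, length(cols))))
  }
  b <- addBlock(m, prov, electronic, "electronic")
  b <- addBlock(b$m, b$prov, dispersion, "dispersion")
  m <- b$m; prov <- b$prov

  lab <- NULL
  if (!is.null(labels)) {
    labels <- .readTabular(labels)
    if (!all(c("ligand_id", "er") %in% names(labels)))
      stop("labels need columns ligand_id and er")
    missing <- setdiff(ids, labels$ligand_id)
    if (length(missing))
      stop("labels are missing ligands: ", paste(missing, collapse = ", "))
    labels <- labels[match(ids, labels$ligand_id), ]
    lab <- parseEr(labels$er, format = erFormat)
  }
  featureTable(m, provenance = prov, labels = lab)
}

.readTabular <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("input file not found: ", x)
    x <- read.csv(x, comment.char = "#", stringsAsFactors = FALSE)
  }
  as.data.frame(x, stringsAsFactors = FALSE)
}

#' Read and write FeatureTable CSVs
#'
#' The on-disk format is a plain CSV with a `ligand_id` column, one
#' column per feature, an optional `er` column ("R:S" strings), and a
#' leading `# provenance:` comment line recording per-feature tags.
#'
#' @param t a [FeatureTable-class].
#' @param path CSV path.
#' @param digits coordinate precision for writing.
#' @return `readFeatureCsv`: a [FeatureTable-class].
#'   `writeFeatureCsv`: `path`, invisibly.
#' @export
writeFeatureCsv <- function(t, path, digits = 12) {
  stopifnot(is(t, "FeatureTable"))
  header <- paste0("# provenance: ",
                   paste(sprintf("%s=%s", featureNames(t), t@provenance),
                         collapse = ","))
  df <- data.frame(ligand_id = ligandIds(t),
                   signif(featureValues(t), digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(t@labels)) df$er <- formatEr(t@labels, digits = 6)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCsv
#' @export
readFeatureCsv <- function(path) {
  first <- readLines(path, n = 1L)
  prov <- NULL
  if (startsWith(first, "# provenance:")) {
    spec <- strsplit(sub("^# provenance: *", "", first), ",")[[1]]
    kv <- strsplit(spec, "=", fixed = TRUE)
    prov <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 check.names = FALSE)
  if (!"ligand_id" %in% names(df)) stop("feature CSV needs a ligand_id column")
  lab <- NULL
  if ("er" %in% names(df)) {
    lab <- parseEr(df$er)
    df$er <- NULL
  }
  m <- as.matrix(df[, setdiff(names(df), "ligand_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$ligand_id
  if (is.null(prov)) prov <- setNames(rep("other", ncol(m)), colnames(m))
  featureTable(m, provenance = prov[colnames(m)], labels = lab)
}

#' Fit min-max normalization on a row subset
#'
#' Records the per-feature minimum and maximum over the fitting rows
#' only, so features scale into [0, 1] on those rows; rows outside the
#' fitting subset may map outside [0, 1] and are deliberately not
#' clipped.  Features with zero range on the subset are flagged as
#' excluded (they carry no information for the fit).
#'
#' @param t a [FeatureTable-class].
#' @param rows row indices or ligand ids of the fitting subset
#'   (default: all rows).
#' @return A [MinMaxParams-class].
#' @examples
#' m <- matrix(c(2, 4, 6, 5, 5, 5), 3, 2,
#'             dimnames = list(c("L1", "L2", "L3"), c("a", "const")))
#' p <- minmaxFit(featureTable(m))   # 'const' is excluded
#' @export
minmaxFit <- function(t, rows = NULL) {
  stopifnot(is(t, "FeatureTable"))
  v <- featureValues(t)
  if (is.null(rows)) rows <- seq_len(nrow(v))
  if (is.character(rows)) rows <- match(rows, rownames(v))
  if (!length(rows) || any(is.na(rows)))
    stop("fitting subset must be a non-empty set of existing rows")
  sub <- v[rows, , drop = FALSE]
  mins <- apply(sub, 2, min)
  maxs <- apply(sub, 2, max)
  excluded <- colnames(v)[maxs - mins < 1e-12]
  keep <- setdiff(colnames(v), excluded)
  new("MinMaxParams", mins = mins[keep], maxs = maxs[keep],
      excluded = excluded)
}

#' Apply fitted min-max normalization
#'
#' @param t a [FeatureTable-class] whose features cover the fitted
#'   ones.
#' @param p a [MinMaxParams-class] from [minmaxFit()].
#' @return A [FeatureTable-class] of scaled values; excluded
#'   (zero-range) features are dropped.
#' @export
minmaxApply <- function(t, p) {
  stopifnot(is(t, "FeatureTable"), is(p, "MinMaxParams"))
  v <- featureValues(t)
  want <- names(p@mins)
  missing <- setdiff(want, colnames(v))
  if (length(missing))
    stop("table lacks features required by the normalization: ",
         paste(missing, collapse = ", "))
  v <- v[, want, drop = FALSE]
  scaled <- sweep(sweep(v, 2, p@mins[want]), 2,
                  p@maxs[want] - p@mins[want], "/")
  featureTable(scaled, provenance = t@provenance[want], labels = t@labels)
}

#' Rank features by Pearson correlation with selectivity
#'
#' The manual feature-selection route: each feature's Pearson R against
#' the chosen selectivity metric, ordered by |R| descending (ties
#' broken by feature name).  Zero-variance features get R = 0 with a
#' flag rather than an error.
#'
#' @param t a labeled [FeatureTable-class] with at least 3 rows.
#' @param metric selectivity metric for the label side, see
#'   [toMetric()].
#' @return data.frame with columns `feature`, `r`, `abs_r`,
#'   `zero_variance`, ordered by rank.
#' @export
correlationRank <- function(t, metric = "s_select") {
  stopifnot(is(t, "FeatureTable"))
  if (is.null(t@labels)) stop("correlation ranking needs labeled rows")
  v <- featureValues(t)
  if (nrow(v) < 3) stop("correlation ranking needs at least 3 ligands")
  y <- toMetric(t@labels, metric)
  sds <- apply(v, 2, sd)
  r <- rep(0, ncol(v))
  ok <- sds > 0 & sd(y) > 0
  if (any(ok)) r[ok] <- as.numeric(cor(v[, ok, drop = FALSE], y))
  out <- data.frame(feature = colnames(v), r = r, abs_r = abs(r),
                    zero_variance = sds == 0, stringsAsFactors = FALSE)
  out[order(-out$abs_r, out$feature), , drop = FALSE]
}

#' Keep the top-k correlation-ranked features
#'
#' @param t a labeled [FeatureTable-class].
#' @param k number of features to keep (1..p).
#' @param ranking optional precomputed [correlationRank()] result (with
#'   a possibly different metric); computed on `t` when `NULL`.
#' @return A [FeatureTable-class] restricted to the selected features,
#'   original column order preserved.
#' @export
selectManual <- function(t, k, ranking = NULL) {
  stopifnot(is(t, "FeatureTable"))
  p <- ncol(featureValues(t))
  if (k < 1 || k > p)
    stop(sprintf("k must be in 1..%d, got %s", p, k))
  if (is.null(ranking)) ranking <- correlationRank(t)
  keep <- ranking$feature[seq_len(k)]
  t[, featureNames(t) %in% keep]
}
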