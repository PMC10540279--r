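#' S4 classes for transition-state structures and ligand feature tables
#'
#' @name stereonn-classes
#' @keywords internal
NULL

#' A molecular structure read from an XYZ block
#'
#' Holds element symbols and Cartesian coordinates (Angstrom) of one
#' transition-state structure, tagged with the ligand it belongs to and
#' whether it leads to the R or the S product.
#'
#' @slot ligandId character(1); ligand identifier (may be `NA` if the
#'   XYZ comment line carried no metadata).
#' @slot role `"pro_R"`, `"pro_S"` or `NA`.
#' @slot elements character vector of element symbols.
#' @slot coords numeric matrix, one row per atom, columns x/y/z in
#'   Angstrom.
#' @slot comment the raw XYZ comment line.
#' @exportClass XyzStructure
setClass("XyzStructure",
  representation(ligandId = "character", role = "character",
                 elements = "character", coords = "matrix",
                 comment = "character"),
  prototype(ligandId = NA_character_, role = NA_character_,
            comment = ""))

setValidity("XyzStructure", function(object) {
  msg <- character()
  n <- length(object@elements)
  if (!is.numeric(object@coords) || ncol(object@coords) != 3)
    msg <- c(msg, "coords must be a numeric matrix with 3 columns")
  else {
    if (nrow(object@coords) != n)
      msg <- c(msg, "number of elements and coordinate rows differ")
    if (any(!is.finite(object@coords)))
      msg <- c(msg, "all coordinates must be finite")
  }
  if (n < 4)
    msg <- c(msg, "a structure needs at least 4 atoms")
  if (!is.na(object@role) && !object@role %in% c("pro_R", "pro_S"))
    msg <- c(msg, "role must be 'pro_R', 'pro_S' or NA")
  if (length(msg)) msg else TRUE
})

#' Construct an XyzStructure
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n x 3) of Cartesian coordinates in
#'   Angstrom.
#' @param ligandId,role,comment optional metadata; `role` is `"pro_R"`
#'   or `"pro_S"`.
#' @return An [XyzStructure-class] object.
#' @examples
#' xyzStructure(c("Pd", "P", "C", "C"),
#'              rbind(c(0, 0, 0), c(2, 0, 0), c(-1, 1.5, 0), c(-1, -1.5, 0)),
#'              ligandId = "L1", role = "pro_S")
#' @export
xyzStructure <- function(elements, coords, ligandId = NA_character_,
                         role = NA_character_, comment = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  new("XyzStructure", ligandId = as.character(ligandId),
      role = as.character(role), elements = as.character(elements),
      coords = coords, comment = as.character(comment))
}

setMethod("show", "XyzStructure", function(object) {
  cat("XyzStructure:", length(object@elements), "atoms")
  if (!is.na(object@ligandId)) cat(" | ligand", object@ligandId)
  if (!is.na(object@role)) cat(" |", object@role)
  cat("\n  elements:", paste(head(object@elements, 8), collapse = " "),
      if (length(object@elements) > 8) "..." else "", "\n")
})

#' Donor-atom assignment for the Pd coordination environment
#'
#' Identifies, by atom index, the metal centre and the three atoms that
#' define its coordination plane: the phosphine P donor and the two
#' substrate carbons bound to Pd.  Donors are supplied explicitly
#' because the complexes are too specialised for generic bond
#' perception.
#'
#' @slot metalIndex integer(1), index of the Pd atom.
#' @slot donorIndices integer(3), the three donor atoms.
#' @slot pIndex integer(1), which donor is the phosphine P; must be one
#'   of `donorIndices`.
#' @exportClass DonorSet
setClass("DonorSet",
  representation(metalIndex = "integer", donorIndices = "integer",
                 pIndex = "integer"))

setValidity("DonorSet", function(object) {
  msg <- character()
  idx <- c(object@metalIndex, object@donorIndices)
  if (length(object@donorIndices) != 3)
    msg <- c(msg, "exactly three donor indices are required")
  if (anyDuplicated(idx))
    msg <- c(msg, "metal and donor indices must be distinct")
  if (any(idx < 1L))
    msg <- c(msg, "indices must be >= 1")
  if (!object@pIndex %in% object@donorIndices)
    msg <- c(msg, "pIndex must be one of the donor indices")
  if (length(msg)) msg else TRUE
})

#' Construct a DonorSet
#'
#' @param metal atom index of Pd.
#' @param donors integer vector of the three donor atom indices.
#' @param p index of the phosphine P donor (must be in `donors`).
#' @return A [DonorSet-class] object.
#' @examples
#' donorSet(metal = 1, donors = c(2, 3, 4), p = 2)
#' @export
donorSet <- function(metal, donors, p) {
  new("DonorSet", metalIndex = as.integer(metal),
      donorIndices = as.integer(donors), pIndex = as.integer(p))
}

setMethod("show", "DonorSet", function(object) {
  cat("DonorSet: Pd @", object@metalIndex, "| donors",
      paste(object@donorIndices, collapse = ","), "| P @",
      object@pIndex, "\n")
})

#' Enantiomer composition records
#'
#' A vectorised container for enantiomer percentages.  Each entry holds
#' the S and R percentages, which sum to 100 and are strictly inside
#' (0, 100) so that ratio and log encodings stay finite.
#'
#' @slot sPercent,numeric percentage of the S enantiomer.
#' @slot rPercent,numeric percentage of the R enantiomer.
#' @exportClass Selectivity
setClass("Selectivity",
  representation(sPercent = "numeric", rPercent = "numeric"))

setValidity("Selectivity", function(object) {
  s <- object@sPercent; r <- object@rPercent
  msg <- character()
  if (length(s) != length(r))
    msg <- c(msg, "sPercent and rPercent must have equal length")
  else if (length(s)) {
    if (any(!is.finite(s)) || any(!is.finite(r)))
      msg <- c(msg, "percentages must be finite")
    else {
      if (any(s <= 0) || any(r <= 0))
        msg <- c(msg, paste("both enantiomer percentages must be strictly",
                            "positive (ratios and logs must stay finite)"))
      if (any(abs(s + r - 100) > 1e-9))
        msg <- c(msg, "percentages must sum to 100 (tolerance 1e-9)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct Selectivity records
#'
#' Supply either `s` or `r` (the other is completed to 100), or both.
#'
#' @param s,r numeric vectors of S / R percentages in (0, 100).
#' @return A [Selectivity-class] object.
#' @examples
#' selectivity(s = c(90, 50))
#' selectivity(r = 90)          # 90:10 er in the R:S printing convention
#' @export
selectivity <- function(s = NULL, r = NULL) {
  if (is.null(s) && is.null(r))
    stop("supply at least one of 's' and 'r'")
  if (is.null(s)) s <- 100 - r
  if (is.null(r)) r <- 100 - s
  new("Selectivity", sPercent = as.numeric(s), rPercent = as.numeric(r))
}

setMethod("length", "Selectivity", function(x) length(x@sPercent))

setMethod("show", "Selectivity", function(object) {
  n <- length(object)
  cat("Selectivity records (R:S), n =", n, "\n")
  k <- min(n, 6L)
  if (k) cat(" ", paste(sprintf("%.1f:%.1f", object@rPercent[seq_len(k)],
                                object@sPercent[seq_len(k)]),
                        collapse = "  "),
             if (n > k) "..." else "", "\n")
})

setMethod("[", "Selectivity", function(x, i, j, ..., drop = TRUE) {
  selectivity(s = x@sPercent[i], r = x@rPercent[i])
})

setClassUnion("SelectivityOrNULL", c("Selectivity", "NULL"))

#' Ligand-by-feature tables
#'
#' The central tabular container: a numeric matrix of feature values
#' with one row per ligand, per-feature provenance tags and optional
#' experimental selectivity labels.
#'
#' @slot values numeric matrix; rownames are ligand ids, colnames are
#'   feature names (both unique).
#' @slot provenance named character vector, one of `"geometric"`,
#'   `"electronic"`, `"dispersion"`, `"other"` per feature.
#' @slot labels a [Selectivity-class] of length `nrow(values)`, or
#'   `NULL` for unlabeled tables.
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(values = "matrix", provenance = "character",
                 labels = "SelectivityOrNULL"),
  prototype(labels = NULL))

setValidity("FeatureTable", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "rownames (ligand ids) must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "colnames (feature names) must be present and unique")
  if (any(!is.finite(v)))
    msg <- c(msg, "feature values must be finite (no gaps after assembly)")
  if (length(object@provenance) != ncol(v) ||
      !identical(names(object@provenance), colnames(v)))
    msg <- c(msg, "provenance must be named to match the feature columns")
  if (!all(object@provenance %in% .PROVENANCE_LEVELS))
    msg <- c(msg, sprintf("provenance tags must be one of: %s",
                          paste(.PROVENANCE_LEVELS, collapse = ", ")))
  if (!is.null(object@labels) && length(object@labels) != nrow(v))
    msg <- c(msg, "labels must have one record per ligand row")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix with ligand rownames and feature
#'   colnames.
#' @param provenance character vector of per-feature tags (recycled if
#'   length 1); one of `"geometric"`, `"electronic"`, `"dispersion"`,
#'   `"other"`.
#' @param labels optional [Selectivity-class] labels, one per row.
#' @return A [FeatureTable-class] object.
#' @examples
#' m <- matrix(runif(6), 3, 2,
#'             dimnames = list(c("L1", "L2", "L3"), c("f1", "f2")))
#' featureTable(m, provenance = "geometric")
#' @export
featureTable <- function(values, provenance = "other", labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(provenance) == 1L)
    provenance <- rep(provenance, ncol(values))
  names(provenance) <- colnames(values)
  new("FeatureTable", values = values, provenance = provenance,
      labels = labels)
}

setMethod("show", "FeatureTable", function(object) {
  v <- object@values
  cat("FeatureTable:", nrow(v), "ligands x", ncol(v), "features",
      if (is.null(object@labels)) "(unlabeled)" else "(labeled)", "\n")
  tab <- table(factor(object@provenance, levels = .PROVENANCE_LEVELS))
  cat("  provenance:",
      paste(sprintf("%s=%d", names(tab)[tab > 0], tab[tab > 0]),
            collapse = " "), "\n")
  cat("  ligands:", paste(head(rownames(v), 5), collapse = ", "),
      if (nrow(v) > 5) "..." else "", "\n")
})

setMethod("[", "FeatureTable", function(x, i, j, ..., drop = TRUE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  v <- x@values[i, j, drop = FALSE]
  featureTable(v, provenance = x@provenance[colnames(v)],
               labels = if (is.null(x@labels)) NULL else x@labels[i])
})

#' Min-max normalization parameters
#'
#' Per-feature minimum and maximum fitted on a training subset; features
#' with zero range on that subset are recorded as excluded rather than
#' scaled.
#'
#' @slot mins,maxs named numeric vectors over the retained features.
#' @slot excluded character vector of zero-range feature names.
#' @exportClass MinMaxParams
setClass("MinMaxParams",
  representation(mins = "numeric", maxs = "numeric",
                 excluded = "character"))

setValidity("MinMaxParams", function(object) {
  msg <- character()
  if (!identical(names(object@mins), names(object@maxs)))
    msg <- c(msg, "mins and maxs must cover the same features")
  if (any(object@maxs < object@mins))
    msg <- c(msg, "max must be >= min for every retained feature")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MinMaxParams", function(object) {
  cat("MinMaxParams:", length(object@mins), "features scaled,",
      length(object@excluded), "excluded (zero range)\n")
})

#' A trained feed-forward network with its preprocessing
#'
#' Bundles layer weights and biases with the activation/config used to
#' train them, the min-max normalization fitted on the training rows,
#' and the selectivity metric the output is expressed on.  Predictions
#' through [predict()] therefore reproduce training-time preprocessing
#' exactly.
#'
#' @slot weights list of weight matrices (rows = layer width, cols =
#'   fan-in).
#' @slot biases list of bias vectors.
#' @slot config the `nnConfig()` list used for training.
#' @slot norm a [MinMaxParams-class] fitted on the training rows.
#' @slot targetMetric one of `"ee"`, `"er_ratio"`, `"ln_er"`,
#'   `"s_select"`, `"r_select"`.
#' @exportClass NNModel
setClass("NNModel",
  representation(weights = "list", biases = "list", config = "list",
                 norm = "MinMaxParams", targetMetric = "character"))

setValidity("NNModel", function(object) {
  msg <- character()
  if (length(object@weights) != length(object@biases))
    msg <- c(msg, "weights and biases must have one entry per layer")
  dims_ok <- TRUE
  for (l in seq_along(object@weights)) {
    W <- object@weights[[l]]
    if (any(!is.finite(W)) || any(!is.finite(object@biases[[l]])))
      msg <- c(msg, "all parameters must be finite")
    if (nrow(W) != length(object@biases[[l]])) dims_ok <- FALSE
    if (l > 1 && ncol(W) != nrow(object@weights[[l - 1]])) dims_ok <- FALSE
  }
  if (!dims_ok)
    msg <- c(msg, "layer shapes must chain input -> hidden -> scalar output")
  if (length(object@weights) &&
      nrow(object@weights[[length(object@weights)]]) != 1)
    msg <- c(msg, "the output layer must produce a single value")
  if (!object@targetMetric %in% .SELECTIVITY_METRICS)
    msg <- c(msg, "unknown target metric")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NNModel", function(object) {
  widths <- vapply(object@weights, nrow, integer(1))
  cat("NNModel:", ncol(object@weights[[1]]), "inputs ->",
      paste(widths[-length(widths)], collapse = "-"), "-> 1 |",
      object@config$activation, "| target", object@targetMetric, "\n")
})

#' Predicted-vs-observed results with regression diagnostics
#'
#' One (observed, predicted) pair per ligand on a given selectivity
#' metric, with the three overfitting diagnostics used throughout:
#' RMSE, squared Pearson correlation, and the slope of the least-squares
#' fit of predicted on observed (1 for a faithful model).
#'
#' @slot ligandIds character vector.
#' @slot observed,predicted numeric vectors on `metric`'s scale.
#' @slot metric the selectivity metric of the pairs.
#' @slot rmse,rsq,slope numeric diagnostics (`rsq`/`slope` are `NA` and
#'   flagged when observed values are degenerate).
#' @slot rsqAlt coefficient-of-determination variant of R-squared
#'   (1 - SS_res/SS_tot), logged alongside the Pearson form.
#' @slot erPredicted predictions converted to "R:S" strings (may be
#'   empty).
#' @slot flags character notes, e.g. degenerate diagnostics or clamped
#'   conversions.
#' @exportClass CVResult
setClass("CVResult",
  representation(ligandIds = "character", observed = "numeric",
                 predicted = "numeric", metric = "character",
                 rmse = "numeric", rsq = "numeric", slope = "numeric",
                 rsqAlt = "numeric", erPredicted = "character",
                 flags = "character"),
  prototype(erPredicted = character(), flags = character()))

setValidity("CVResult", function(object) {
  msg <- character()
  n <- length(object@ligandIds)
  if (length(object@observed) != n || length(object@predicted) != n)
    msg <- c(msg, "one observed and one predicted value per ligand")
  if (length(object@rmse) != 1 || (is.finite(object@rmse) && object@rmse < 0))
    msg <- c(msg, "rmse must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult (%s): n = %d | RMSE %.4g | R^2 %.4g | slope %.4g\n",
              object@metric, length(object@ligandIds), object@rmse,
              object@rsq, object@slope))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

#' @rdname cvResultAsDataFrame
#' @export
setGeneric("asPairs", function(x) standardGeneric("asPairs"))

#' Predicted-vs-observed pairs of a CVResult as a data.frame
#'
#' @name cvResultAsDataFrame
#' @param x a [CVResult-class].
#' @return data.frame with columns `ligand_id`, `observed`, `predicted`
#'   (and `er_predicted` when available).
#' @export
setMethod("asPairs", "CVResult", function(x) {
  out <- data.frame(ligand_id = x@ligandIds, observed = x@observed,
                    predicted = x@predicted, stringsAsFactors = FALSE)
  if (length(x@erPredicted) == length(x@ligandIds))
    out$er_predicted <- x@erPredicted
  out
})
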