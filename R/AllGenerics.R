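#' Accessors for stereonn objects
#'
#' Slot access goes through these accessors rather than `@`.
#'
#' @param x a stereonn S4 object.
#' @return `ligandIds`, `featureNames`: character vectors.
#'   `featureValues`: the numeric ligand-by-feature matrix.
#'   `provenance`: named character vector of per-feature tags.
#'   `selectivityLabels`: a [Selectivity-class] or `NULL`.
#'   `sPercent`, `rPercent`: numeric vectors of enantiomer percentages.
#' @examples
#' m <- matrix(1:4 / 4, 2, 2, dimnames = list(c("L1", "L2"), c("a", "b")))
#' ft <- featureTable(m, labels = selectivity(s = c(80, 60)))
#' ligandIds(ft)
#' sPercent(selectivityLabels(ft))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ligandIds", function(x) standardGeneric("ligandIds"))
#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("selectivityLabels",
           function(x) standardGeneric("selectivityLabels"))
#' @rdname accessors
#' @export
setGeneric("sPercent", function(x) standardGeneric("sPercent"))
#' @rdname accessors
#' @export
setGeneric("rPercent", function(x) standardGeneric("rPercent"))

#' @rdname accessors
#' @export
setMethod("ligandIds", "FeatureTable", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("featureNames", "FeatureTable", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureTable", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("provenance", "FeatureTable", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("selectivityLabels", "FeatureTable", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("sPercent", "Selectivity", function(x) x@sPercent)
#' @rdname accessors
#' @export
setMethod("rPercent", "Selectivity", function(x) x@rPercent)

#' @rdname accessors
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))
#' @rdname accessors
#' @export
setMethod("elements", "XyzStructure", function(x) x@elements)
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setMethod("coords", "XyzStructure", function(x) x@coords)
#' @rdname accessors
#' @export
setMethod("ligandIds", "XyzStructure", function(x) x@ligandId)

#' @rdname accessors
#' @export
setGeneric("structureRole", function(x) standardGeneric("structureRole"))
#' @rdname accessors
#' @export
setMethod("structureRole", "XyzStructure", function(x) x@role)

#' Replace the labels of a FeatureTable
#'
#' @param x a [FeatureTable-class].
#' @param value a [Selectivity-class] of length `nrow(x)`, or `NULL`.
#' @return the modified [FeatureTable-class].
#' @export
setGeneric("selectivityLabels<-",
           function(x, value) standardGeneric("selectivityLabels<-"))
#' @rdname selectivityLabels-set
#' @export
setMethod("selectivityLabels<-", "FeatureTable", function(x, value) {
  x@labels <- value
  validObject(x)
  x
})
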