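#' Geometric descriptors of the Pd coordination environment
#'
#' The selectivity-bearing geometry of the coupling transition state is
#' summarised by a handful of descriptors of the three-coordinate Pd
#' centre: how far Pd is displaced from the plane of its donor atoms
#' ([planarity()]), how far the in-plane donor arrangement deviates from
#' an ideal 120/120/120 Y-shape ([yNess()]), the angle between the
#' Pd-P bond and the out-of-plane direction
#' ([projectedMetalAngle()]), and plain bond lengths and angles.
#' All values are invariant under rigid motions of the structure.
#'
#' @name geometry-descriptors
NULL

.checkIndex <- function(s, i, what = "atom index") {
  i <- as.integer(i)
  n <- nrow(s@coords)
  if (any(is.na(i)) || any(i < 1L) || any(i > n))
    stop(sprintf("%s out of range (structure has %d atoms): %s",
                 what, n, paste(i, collapse = ", ")))
  i
}

.checkDonorSet <- function(s, d) {
  stopifnot(is(s, "XyzStructure"), is(d, "DonorSet"))
  .checkIndex(s, c(d@metalIndex, d@donorIndices))
  pd <- which(s@elements == "Pd")
  if (length(pd) != 1L)
    stop("descriptor operations require exactly one Pd atom, found ",
         length(pd))
  if (d@metalIndex != pd)
    stop("DonorSet metalIndex (", d@metalIndex,
         ") does not point at the Pd atom (index ", pd, ")")
  invisible(TRUE)
}

.rad2deg <- function(x) x * 180 / pi

#' @describeIn geometry-descriptors Euclidean distance between atoms
#'   `i` and `j`, in Angstrom.
#' @param s an [XyzStructure-class].
#' @param i,j,k atom indices (for [bondAngle()], `j` is the vertex).
#' @return `bondLength`: distance in Angstrom. `bondAngle`,
#'   `projectedMetalAngle`, `yNess`: degrees. `planarity`: Angstrom.
#'   `bestFitPlane`: list with unit `normal` and `centroid`.
#' @examples
#' s <- parseXyz("4\nligand=L1 role=pro_S\nPd 0 0 0.3\nP 2 0 0\nC -1 1.7 0\nC -1 -1.7 0")
#' d <- donorSet(metal = 1, donors = 2:4, p = 2)
#' planarity(s, d)
#' yNess(s, d)
#' @export
bondLength <- function(s, i, j) {
  i <- .checkIndex(s, i); j <- .checkIndex(s, j)
  if (i == j) stop("bond length requires two distinct atoms")
  sqrt(sum((s@coords[i, ] - s@coords[j, ])^2))
}

#' @describeIn geometry-descriptors Angle i-j-k at vertex `j`, in
#'   [0, 180] degrees.
#' @export
bondAngle <- function(s, i, j, k) {
  i <- .checkIndex(s, i); j <- .checkIndex(s, j); k <- .checkIndex(s, k)
  if (anyDuplicated(c(i, j, k)))
    stop("bond angle requires three distinct atoms")
  .vectorAngle(s@coords[i, ] - s@coords[j, ], s@coords[k, ] - s@coords[j, ])
}

.vectorAngle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < .DEGENERACY_TOL || nv < .DEGENERACY_TOL)
    stop("degenerate geometry: coincident atoms give a zero-length arm")
  .rad2deg(acos(max(-1, min(1, sum(u * v) / (nu * nv)))))
}

#' @describeIn geometry-descriptors Least-squares plane through the
#'   selected atoms (total least squares via SVD); errors on collinear
#'   points.
#' @param indices at least three atom indices.
#' @export
bestFitPlane <- function(s, indices) {
  indices <- .checkIndex(s, indices)
  if (length(indices) < 3) stop("a plane needs at least 3 points")
  pts <- s@coords[indices, , drop = FALSE]
  .fitPlane(pts)
}

.fitPlane <- function(pts) {
  centroid <- colMeans(pts)
  centered <- sweep(pts, 2, centroid)
  sv <- svd(centered)
  # collinear points leave only one meaningful direction
  if (sv$d[2] < .DEGENERACY_TOL)
    stop("degenerate geometry: points are collinear, plane undefined")
  normal <- sv$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  list(normal = normal, centroid = centroid)
}

.pointPlaneDistance <- function(p, plane) {
  sum((p - plane$centroid) * plane$normal)   # signed
}

#' @describeIn geometry-descriptors Unsigned perpendicular distance of
#'   the Pd atom from the plane through the three donor atoms
#'   (Angstrom); 0 iff Pd is coplanar with its donors.
#' @param d a [DonorSet-class] valid for `s`.
#' @export
planarity <- function(s, d) {
  .checkDonorSet(s, d)
  plane <- bestFitPlane(s, d@donorIndices)
  abs(.pointPlaneDistance(s@coords[d@metalIndex, ], plane))
}

#' @describeIn geometry-descriptors Angle at Pd between the Pd-to-P
#'   bond and the direction from the foot of Pd's perpendicular on the
#'   donor plane up to Pd (degrees).  With Pd out of plane and P in the
#'   plane this angle always exceeds 90 degrees; it is undefined
#'   (error) when Pd lies in the donor plane to within the 1e-6
#'   Angstrom degeneracy tolerance.
#' @export
projectedMetalAngle <- function(s, d) {
  .checkDonorSet(s, d)
  plane <- bestFitPlane(s, d@donorIndices)
  pd <- s@coords[d@metalIndex, ]
  h <- .pointPlaneDistance(pd, plane)
  if (abs(h) <= .DEGENERACY_TOL)
    stop("Pd lies in the donor plane (|offset| <= 1e-6 Angstrom); the ",
         "projected-metal angle is undefined for planar complexes -- ",
         "use planarity() to detect this case")
  foot <- pd - h * plane$normal
  .vectorAngle(s@coords[d@pIndex, ] - pd, pd - foot)
}

#' @describeIn geometry-descriptors Total absolute deviation of the
#'   three in-plane donor-Pd-donor angles from 120 degrees, measured
#'   after projecting Pd and the donors onto the donor best-fit plane;
#'   0 iff the projected complex is an ideal Y.  Invariant under donor
#'   relabeling.
#' @export
yNess <- function(s, d) {
  .checkDonorSet(s, d)
  plane <- bestFitPlane(s, d@donorIndices)
  proj <- function(p) p - .pointPlaneDistance(p, plane) * plane$normal
  pdP <- proj(s@coords[d@metalIndex, ])
  arms <- lapply(d@donorIndices, function(i) proj(s@coords[i, ]) - pdP)
  lens <- vapply(arms, function(a) sqrt(sum(a^2)), numeric(1))
  if (any(lens < .DEGENERACY_TOL))
    stop("degenerate projection: a donor projects onto the projected Pd")
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  angles <- vapply(pairs, function(p)
    .vectorAngle(arms[[p[1]]], arms[[p[2]]]), numeric(1))
  sum(abs(angles - 120))
}

# descriptor request registry: fixed names plus parameterized
# "bond:i,j" and "angle:i,j,k" forms (1-based atom indices)
.resolveDescriptor <- function(request) {
  if (request == "planarity")
    return(list(name = "planarity", units = "angstrom",
                fn = function(s, d) planarity(s, d)))
  if (request == "y_ness")
    return(list(name = "y_ness", units = "degrees",
                fn = function(s, d) yNess(s, d)))
  if (request %in% c("projected_angle", "projected_metal_angle"))
    return(list(name = "projected_angle", units = "degrees",
                fn = function(s, d) projectedMetalAngle(s, d)))
  if (grepl("^bond:", request)) {
    idx <- as.integer(strsplit(sub("^bond:", "", request), ",")[[1]])
    if (length(idx) != 2 || any(is.na(idx)))
      stop("bond descriptor must be 'bond:i,j', got ", sQuote(request))
    return(list(name = sprintf("bond_%d_%d", idx[1], idx[2]),
                units = "angstrom",
                fn = function(s, d) bondLength(s, idx[1], idx[2])))
  }
  if (grepl("^angle:", request)) {
    idx <- as.integer(strsplit(sub("^angle:", "", request), ",")[[1]])
    if (length(idx) != 3 || any(is.na(idx)))
      stop("angle descriptor must be 'angle:i,j,k', got ", sQuote(request))
    return(list(name = sprintf("angle_%d_%d_%d", idx[1], idx[2], idx[3]),
                units = "degrees",
                fn = function(s, d) bondAngle(s, idx[1], idx[2], idx[3])))
  }
  stop("unknown descriptor request: ", sQuote(request))
}

#' Compute descriptors for a pro_R / pro_S transition-state pair
#'
#' Evaluates each requested descriptor on both structures of a ligand's
#' transition-state pair.  Rows are ordered deterministically by
#' (descriptor name, role) and feature names are suffixed `_proR` /
#' `_proS`.
#'
#' @param pair a list with elements `pro_R` and `pro_S`, both
#'   [XyzStructure-class] objects sharing one ligand id.
#' @param d a [DonorSet-class] valid for both structures.
#' @param descriptors character vector of requests: `"planarity"`,
#'   `"y_ness"`, `"projected_angle"`, or parameterized `"bond:i,j"` /
#'   `"angle:i,j,k"` with 1-based atom indices.
#' @return A data.frame with columns `ligand_id`, `descriptor`, `role`,
#'   `name`, `value`, `units` (zero rows for an empty request).
#' @examples
#' toy <- simulateToyComplexes(pdOffset = 0.3)[[1]]
#' d <- donorSet(metal = 1, donors = 2:4, p = 2)
#' computeDescriptors(toy[c("pro_R", "pro_S")], d,
#'                    c("planarity", "y_ness"))
#' @export
computeDescriptors <- function(pair, d,
                               descriptors = c("planarity", "y_ness",
                                               "projected_angle")) {
  stopifnot(is.list(pair), all(c("pro_R", "pro_S") %in% names(pair)))
  sR <- pair$pro_R; sS <- pair$pro_S
  idR <- sR@ligandId; idS <- sS@ligandId
  if (!identical(idR, idS))
    stop("pro_R and pro_S structures belong to different ligands: ",
         idR, " vs ", idS)
  if (!length(descriptors))
    return(data.frame(ligand_id = character(), descriptor = character(),
                      role = character(), name = character(),
                      value = numeric(), units = character(),
                      stringsAsFactors = FALSE))
  resolved <- lapply(descriptors, .resolveDescriptor)
  resolved <- resolved[order(vapply(resolved, `[[`, "", "name"))]
  rows <- lapply(resolved, function(desc) {
    vals <- lapply(c(pro_R = "pro_R", pro_S = "pro_S"), function(role) {
      s <- if (role == "pro_R") sR else sS
      tryCatch(desc$fn(s, d), error = function(e)
        stop(sprintf("ligand %s (%s, %s): %s", idR, role, desc$name,
                     conditionMessage(e)), call. = FALSE))
    })
    data.frame(ligand_id = idR, descriptor = desc$name,
               role = c("pro_R", "pro_S"),
               name = paste0(desc$name, c("_proR", "_proS")),
               value = c(vals$pro_R, vals$pro_S), units = desc$units,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract descriptor tables for a directory of transition-state pairs
#'
#' Convenience wrapper: [readXyzDir()] + [computeDescriptors()] over
#' every ligand, optionally written as the long-format descriptor CSV
#' (columns `ligand_id, descriptor, role, name, value, units`) consumed
#' by [assembleFeatures()].
#'
#' @param dir directory of `.xyz` files (see [readXyzDir()]).
#' @param d a [DonorSet-class] shared by all structures (the complexes
#'   share one atom-ordering convention).
#' @param descriptors as in [computeDescriptors()].
#' @param out optional CSV path.
#' @return The combined descriptor data.frame (invisibly when `out` is
#'   given).
#' @export
extractDescriptors <- function(dir, d,
                               descriptors = c("planarity", "y_ness",
                                               "projected_angle"),
                               out = NULL) {
  pairs <- readXyzDir(dir)
  tab <- do.call(rbind, lapply(pairs, computeDescriptors, d = d,
                               descriptors = descriptors))
  rownames(tab) <- NULL
  if (!is.null(out)) {
    write.csv(tab, out, row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}
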