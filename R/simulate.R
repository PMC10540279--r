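#' Specification of a planted-signal synthetic data regime
#'
#' Describes the statistical shape of the data the method targets: a
#' deliberately small training set (17 ligands), two further
#' experimental validation sets (10 and 3), up to 15 features on
#' [0, 1], a nonlinear map from a few informative features to the
#' latent S-selectivity, and additive label noise on the S% scale.
#' The three default informative features are named after the factors
#' that matter chemically (electron population at C2, Pd out-of-plane
#' displacement, the ring-junction bond angle) purely as a naming
#' convention — the simulated columns are abstract.
#'
#' @param nTrain,nVal1,nVal2 set sizes (defaults 17, 10, 3).
#' @param nFeatures number of features (default 15).
#' @param informative indices of the informative features (default
#'   1:3).
#' @param coefficients signal coefficients, one per informative feature
#'   (default `c(60, -45, 40)` S-points; with the hinge nonlinearity
#'   this puts the latent signal s.d. near 13 S-points).
#' @param nonlinearity `"hinge"` (`max(f - 0.5, 0)`), `"interaction"`
#'   (centred pairwise products) or `"none"` (centred linear).
#' @param baseline latent S% at zero signal (default 70: the emulated
#'   ligand family is predominantly S-selective, which keeps the ee and
#'   er-ratio encodings invertible toward S; set 50 for a symmetric
#'   regime).
#' @param noiseSd s.d. of the additive Gaussian label noise in
#'   S-points (default 4; see [noiseSdFromDdg()] to derive a value
#'   from a free-energy error).
#' @param seed integer seed.
#' @return a validated spec list of class `"plantedSystem"`.
#' @export
plantedSystem <- function(nTrain = 17, nVal1 = 10, nVal2 = 3,
                          nFeatures = 15, informative = 1:3,
                          coefficients = c(60, -45, 40),
                          nonlinearity = c("hinge", "interaction",
                                           "none"),
                          baseline = 70, noiseSd = 4, seed = 1) {
  nonlinearity <- match.arg(nonlinearity)
  if (min(nTrain, nVal1, nVal2) < 1) stop("set sizes must be >= 1")
  if (baseline <= 1 || baseline >= 99)
    stop("baseline must lie inside (1, 99)")
  if (length(informative) != length(coefficients))
    stop("one coefficient per informative feature")
  if (any(informative < 1) || any(informative > nFeatures))
    stop("informative indices must lie within 1..nFeatures")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  structure(list(nTrain = nTrain, nVal1 = nVal1, nVal2 = nVal2,
                 nFeatures = nFeatures, informative = informative,
                 coefficients = coefficients, nonlinearity = nonlinearity,
                 baseline = baseline, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "plantedSystem")
}

.plantedLatent <- function(sys, f) {
  idx <- sys$informative
  g <- switch(sys$nonlinearity,
    none = f[, idx, drop = FALSE] - 0.5,
    hinge = pmax(f[, idx, drop = FALSE] - 0.5, 0),
    interaction = {
      nxt <- idx[c(seq_along(idx)[-1], 1L)]
      f[, idx, drop = FALSE] * f[, nxt, drop = FALSE] - 0.25
    })
  pmin(pmax(sys$baseline + as.numeric(g %*% sys$coefficients), 1), 99)
}

#' Simulate planted-signal feature tables
#'
#' Draws features uniform on [0, 1], computes the latent S% through
#' the planted map (clipped to [1, 99] so every selectivity encoding
#' stays finite), adds Gaussian label noise on the S% scale, and splits
#' the rows into training and two validation tables.  The ground-truth
#' latent map is returned so recovery can be scored.
#'
#' @param sys a [plantedSystem()] spec.
#' @return list with `train`, `val1`, `val2` (labeled
#'   [FeatureTable-class]s) and `truth` (a function mapping a feature
#'   matrix to latent S%).
#' @examples
#' sim <- simulateFeatureTable(plantedSystem(seed = 11))
#' dim(featureValues(sim$train))   # 17 x 15
#' @export
simulateFeatureTable <- function(sys) {
  stopifnot(inherits(sys, "plantedSystem"))
  n <- sys$nTrain + sys$nVal1 + sys$nVal2
  p <- sys$nFeatures
  feats <- sprintf("f%02d", seq_len(p))
  prov <- rep("other", p)
  if (identical(sort(sys$informative), 1:3) && p >= 3) {
    feats[1:3] <- c("c2_electron_pop", "pd_planarity", "p_ring_angle")
    prov[1:3] <- c("electronic", "geometric", "geometric")
  }
  out <- .withSeed(sys$seed, {
    f <- matrix(runif(n * p), n, p)
    latent <- .plantedLatent(sys, f)
    obs <- latent + rnorm(n, sd = sys$noiseSd)
    list(f = f, obs = obs)
  })
  obs <- pmin(pmax(out$obs, 1), 99)
  ids <- c(sprintf("L%02d", seq_len(sys$nTrain)),
           sprintf("V%02d", seq_len(sys$nVal1)),
           sprintf("W%02d", seq_len(sys$nVal2)))
  dimnames(out$f) <- list(ids, feats)
  grp <- rep(c("train", "val1", "val2"),
             c(sys$nTrain, sys$nVal1, sys$nVal2))
  mk <- function(which) {
    sel <- grp == which
    featureTable(out$f[sel, , drop = FALSE], provenance = prov,
                 labels = selectivity(s = obs[sel]))
  }
  list(train = mk("train"), val1 = mk("val1"), val2 = mk("val2"),
       truth = function(f) .plantedLatent(sys, as.matrix(f)))
}

#' Label noise on the S% scale equivalent to a free-energy error
#'
#' First-order (delta-method) propagation of a Gaussian error on the
#' transition-state free-energy difference into the S percentage,
#' evaluated at a reference composition:
#' \eqn{\sigma_S = \sigma_{\Delta\Delta G} \cdot S(100-S)/(100\,RT)}.
#' At 298.15 K around 80:20, a 1 kcal/mol energy error corresponds to
#' about 27 S-points — the sensitivity that makes purely
#' energy-based er prediction fragile.
#'
#' @param sdDdg s.d. of the free-energy error in kcal/mol.
#' @param refS reference S% at which to linearize (default 80).
#' @param temperature Kelvin.
#' @return s.d. on the S% scale.
#' @export
noiseSdFromDdg <- function(sdDdg, refS = 80, temperature = 298.15) {
  if (refS <= 0 || refS >= 100) stop("refS must be inside (0, 100)")
  sdDdg * refS * (100 - refS) / 100 /
    (.GAS_CONSTANT_KCAL * temperature)
}

#' Fully random labeled feature table
#'
#' Features uniform on [0, 1], labels uniform on `labelRange`
#' (S-percent scale, nudged off the open-interval bounds), seeded.
#' This is the input of the X/Y-randomization null.
#'
#' @param n,p ligands and features.
#' @param labelRange numeric length-2 range of the uniform labels.
#' @param seed integer seed.
#' @return a labeled [FeatureTable-class].
#' @export
randomTable <- function(n, p, labelRange = c(0, 100), seed = 1) {
  if (n < 1 || p < 1) stop("need n >= 1 and p >= 1")
  out <- .withSeed(seed, {
    list(f = matrix(runif(n * p), n, p),
         y = runif(n, labelRange[1], labelRange[2]))
  })
  dimnames(out$f) <- list(sprintf("R%03d", seq_len(n)),
                          sprintf("f%02d", seq_len(p)))
  y <- pmin(pmax(out$y, 1e-6), 100 - 1e-6)
  featureTable(out$f, provenance = "other", labels = selectivity(s = y))
}

#' Simulate toy trigonal Pd complexes with known descriptor values
#'
#' Builds idealized three-coordinate Pd complexes analytically: the
#' three donors (P and two C) lie in a plane at the given inter-donor
#' angles, and Pd sits `pdOffset` Angstrom above it — so by
#' construction planarity equals `pdOffset` and the Y-shape deviation
#' equals `sum(|angles - 120|)`.  Each structure is then rigidly
#' rotated/translated (seeded) and optionally jittered; the pre-jitter
#' analytic descriptor values are returned as ground truth.
#'
#' @param n number of ligand pairs (default 1).
#' @param angles three positive donor-Pd-donor angles summing to 360
#'   degrees.
#' @param pdOffset Pd displacement along the plane normal (Angstrom).
#' @param pDonorDistance,donorDistance Pd-donor distances (Angstrom).
#' @param jitterSd per-coordinate Gaussian jitter (Angstrom, default
#'   0).
#' @param seed integer seed.
#' @return list of `n` entries, each `list(pro_R, pro_S, truth)`, with
#'   `truth` holding `planarity`, `y_ness` and `projected_angle` (`NA`
#'   when `pdOffset` is 0).
#' @examples
#' toy <- simulateToyComplexes(angles = c(130, 115, 115), pdOffset = 0.3)
#' toy[[1]]$truth
#' @export
simulateToyComplexes <- function(n = 1, angles = c(120, 120, 120),
                                 pdOffset = 0.3, pDonorDistance = 2.2,
                                 donorDistance = 2.0, jitterSd = 0,
                                 seed = 1) {
  if (length(angles) != 3 || any(angles <= 0) ||
      abs(sum(angles) - 360) > 1e-9)
    stop("angles must be three positive values summing to 360 degrees")
  if (pDonorDistance <= 0 || donorDistance <= 0)
    stop("distances must be positive")
  az <- cumsum(c(0, angles[1], angles[2])) * pi / 180
  r <- c(pDonorDistance, donorDistance, donorDistance)
  base <- rbind(c(0, 0, pdOffset),                       # Pd
                cbind(r * cos(az), r * sin(az), 0))      # P, C, C
  measured <- function(a) min(a, 360 - a)
  truth <- list(
    planarity = pdOffset,
    y_ness = sum(abs(vapply(c(angles[1], angles[1] + angles[2],
                              angles[2]), measured, numeric(1)) - 120)),
    projected_angle = if (pdOffset > .DEGENERACY_TOL)
      acos(-pdOffset / sqrt(pDonorDistance^2 + pdOffset^2)) * 180 / pi
    else NA_real_)
  lapply(seq_len(n), function(i) {
    pair <- .withSeed(seed + i, {
      lapply(c(pro_R = "pro_R", pro_S = "pro_S"), function(role) {
        q <- qr.Q(qr(matrix(rnorm(9), 3)))
        if (det(q) < 0) q[, 1] <- -q[, 1]
        pts <- base %*% t(q)
        pts <- sweep(pts, 2, runif(3, -5, 5), "+")
        if (jitterSd > 0)
          pts <- pts + matrix(rnorm(length(pts), sd = jitterSd),
                              nrow(pts))
        xyzStructure(c("Pd", "P", "C", "C"), pts,
                     ligandId = sprintf("T%02d", i), role = role)
      })
    })
    c(pair, list(truth = truth))
  })
}
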