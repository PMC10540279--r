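test_that("bond lengths and angles match hand-derived values", {
  s <- xyzStructure(c("Pd", "P", "C", "C"),
                    rbind(c(0, 0, 0), c(0, 0, 2), c(1, 1, 1), c(2, 2, 2)))
  expect_equal(bondLength(s, 1, 2), 2)
  expect_equal(bondLength(s, 3, 4), sqrt(3), tolerance = 1e-12)
  expect_equal(bondLength(s, 4, 3), bondLength(s, 3, 4))
  expect_error(bondLength(s, 2, 2), "distinct")
  expect_error(bondLength(s, 1, 9), "out of range")

  a <- xyzStructure(c("C", "C", "C", "C"),
                    rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)))
  expect_equal(bondAngle(a, 1, 2, 3), 90)
  b <- xyzStructure(c("C", "C", "C", "C"),
                    rbind(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0), c(1, 1, 0)))
  expect_equal(bondAngle(b, 1, 2, 3), 180)
  expect_equal(bondAngle(b, 1, 2, 4), 45, tolerance = 1e-10)
  # coincident atoms give a zero-length arm
  z <- xyzStructure(c("C", "C", "C", "C"),
                    rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_error(bondAngle(z, 2, 1, 3), "degenerate")
})

test_that("bestFitPlane is the least-squares plane", {
  s <- xyzStructure(rep("C", 5),
                    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                          c(2, 3, 0), c(5, 5, 5)))
  p <- bestFitPlane(s, 1:4)
  expect_equal(abs(p$normal[3]), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(p$normal^2)), 1, tolerance = 1e-12)

  # 4 points at z = +d/-d symmetric in xy -> plane z = 0
  sym <- xyzStructure(rep("C", 4),
                      rbind(c(1, 0, 0.2), c(0, 1, -0.2),
                            c(-1, 0, 0.2), c(0, -1, -0.2)))
  psym <- bestFitPlane(sym, 1:4)
  expect_equal(abs(psym$normal[3]), 1, tolerance = 1e-12)
  expect_equal(sum(psym$centroid * psym$normal), 0, tolerance = 1e-12)

  # eigen-decomposition oracle on a random 5-point cloud: residual sum
  # of squared point-plane distances = smallest eigenvalue of the
  # scatter matrix
  set.seed(11)
  pts <- matrix(rnorm(15), 5, 3)
  cl <- xyzStructure(rep("C", 5), pts)
  pl <- bestFitPlane(cl, 1:5)
  resid <- sum((sweep(pts, 2, pl$centroid) %*% pl$normal)^2)
  scatter <- crossprod(sweep(pts, 2, colMeans(pts)))
  expect_equal(resid, min(eigen(scatter, symmetric = TRUE)$values),
               tolerance = 1e-10)
  # collinear points have no unique plane
  lin <- xyzStructure(rep("C", 4),
                      rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2), c(3, 3, 3)))
  expect_error(bestFitPlane(lin, 1:4), "collinear")
})

test_that("planarity is the unsigned Pd-to-donor-plane distance", {
  d <- stdDonors()
  expect_equal(planarity(flatComplex(0), d), 0, tolerance = 1e-12)
  expect_equal(planarity(flatComplex(0.3), d), 0.3, tolerance = 1e-12)
  expect_equal(planarity(flatComplex(-0.3), d), 0.3, tolerance = 1e-12)
})

test_that("projected-metal angle matches hand trigonometry and exceeds 90", {
  d <- stdDonors()
  s <- flatComplex(0.5)
  # Pd at (0,0,0.5), P at (2,0,0): angle between Pd->P = (2,0,-0.5) and
  # the foot->Pd direction (0,0,0.5) is acos(-0.5/sqrt(4.25)) = 104.04
  expect_equal(projectedMetalAngle(s, d),
               acos(-0.5 / sqrt(4.25)) * 180 / pi, tolerance = 1e-10)
  expect_equal(round(projectedMetalAngle(s, d), 2), 104.04)
  for (off in c(0.1, 0.5, 1.5))
    expect_gt(projectedMetalAngle(flatComplex(off), d), 90)
  expect_error(projectedMetalAngle(flatComplex(0), d), "undefined")
})

test_that("yNess measures in-plane deviation from an ideal Y", {
  d <- stdDonors()
  toys <- simulateToyComplexes(angles = c(120, 120, 120), pdOffset = 0)
  expect_equal(yNess(toys[[1]]$pro_R, d), 0, tolerance = 1e-9)
  skew <- simulateToyComplexes(angles = c(130, 115, 115), pdOffset = 0)
  expect_equal(yNess(skew[[1]]$pro_R, d), 20, tolerance = 1e-9)
  # invariant under donor relabeling
  s <- skew[[1]]$pro_R
  for (perm in list(c(3, 2, 4), c(4, 3, 2))) {
    dperm <- donorSet(1, perm, p = 2)
    expect_equal(yNess(s, dperm), yNess(s, d), tolerance = 1e-9)
  }
})

test_that("all descriptors are rigid-motion invariant", {
  d <- stdDonors()
  s <- simulateToyComplexes(angles = c(128, 117, 115), pdOffset = 0.37,
                            seed = 2)[[1]]$pro_R
  ref <- c(planarity(s, d), yNess(s, d), projectedMetalAngle(s, d),
           bondLength(s, 1, 2), bondAngle(s, 2, 1, 3))
  for (seed in 1:5) {
    m <- rigidMotion(s, seed)
    got <- c(planarity(m, d), yNess(m, d), projectedMetalAngle(m, d),
             bondLength(m, 1, 2), bondAngle(m, 2, 1, 3))
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("computeDescriptors labels, orders and propagates errors", {
  pr <- flatComplex(0, role = "pro_R")
  ps <- flatComplex(0.3, role = "pro_S")
  d <- stdDonors()
  out <- computeDescriptors(list(pro_R = pr, pro_S = ps), d, "planarity")
  expect_equal(out$value, c(0, 0.3), tolerance = 1e-12)
  expect_identical(out$name, c("planarity_proR", "planarity_proS"))

  full <- computeDescriptors(list(pro_R = ps, pro_S = ps), d,
                             c("y_ness", "planarity", "bond:1,2"))
  # deterministic ordering by (descriptor name, role)
  expect_identical(full$descriptor,
                   rep(c("bond_1_2", "planarity", "y_ness"), each = 2))
  expect_identical(full$role, rep(c("pro_R", "pro_S"), 3))
  # identical structures give equal _proR/_proS values
  expect_equal(full$value[c(1, 3, 5)], full$value[c(2, 4, 6)])
  expect_identical(full$units,
                   rep(c("angstrom", "angstrom", "degrees"), each = 2))

  expect_identical(nrow(computeDescriptors(list(pro_R = pr, pro_S = ps),
                                           d, character())), 0L)
  ps2 <- flatComplex(0.3, ligand = "other", role = "pro_S")
  expect_error(computeDescriptors(list(pro_R = pr, pro_S = ps2), d,
                                  "planarity"), "different ligands")
  # degenerate geometry errors carry the ligand id
  expect_error(computeDescriptors(list(pro_R = pr, pro_S = ps), d,
                                  "projected_angle"), "ligand L1")
})
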