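test_that("planted tables are seeded, sized and reproducible", {
  sys <- plantedSystem(seed = 11)
  sim1 <- simulateFeatureTable(sys)
  sim2 <- simulateFeatureTable(sys)
  expect_identical(featureValues(sim1$train), featureValues(sim2$train))
  expect_identical(sPercent(selectivityLabels(sim1$val2)),
                   sPercent(selectivityLabels(sim2$val2)))
  expect_identical(dim(featureValues(sim1$train)), c(17L, 15L))
  expect_identical(dim(featureValues(sim1$val1)), c(10L, 15L))
  expect_identical(dim(featureValues(sim1$val2)), c(3L, 15L))
  expect_true(all(featureValues(sim1$train) >= 0 &
                  featureValues(sim1$train) <= 1))
  # the three informative columns carry domain names and provenance
  expect_true(all(c("c2_electron_pop", "pd_planarity", "p_ring_angle")
                  %in% featureNames(sim1$train)))
  expect_identical(unname(provenance(sim1$train)[1:3]),
                   c("electronic", "geometric", "geometric"))
})

test_that("noiseless linear planting gives labels affine in the feature", {
  sys <- plantedSystem(nFeatures = 4, informative = 1, coefficients = 30,
                       nonlinearity = "none", noiseSd = 0, seed = 3)
  sim <- simulateFeatureTable(sys)
  f <- featureValues(sim$train)[, 1]
  s <- sPercent(selectivityLabels(sim$train))
  fit <- lm(s ~ f)
  expect_equal(unname(coef(fit)), c(70 - 15, 30), tolerance = 1e-9)
  expect_equal(abs(cor(f, s)), 1, tolerance = 1e-12)
  # ground-truth handle reproduces the latent map
  expect_equal(as.numeric(sim$truth(featureValues(sim$train))), s,
               tolerance = 1e-12)
})

test_that("delta-method noise helper matches a numerical derivative", {
  got <- noiseSdFromDdg(1, refS = 80)
  sDdg <- function(g) sPercent(ddgToEr(g, "S"))
  h <- 1e-6
  g80 <- erToDdg(selectivity(s = 80))
  oracle <- (sDdg(g80 + h) - sDdg(g80 - h)) / (2 * h)
  expect_equal(got, oracle, tolerance = 1e-6)
  expect_equal(round(got, 1), 27.0)
  # scales linearly in the energy error
  expect_equal(noiseSdFromDdg(0.5, refS = 80), got / 2, tolerance = 1e-12)
})

test_that("toy complexes reproduce their analytic descriptor values", {
  d <- donorSet(1, 2:4, 2)
  ideal <- simulateToyComplexes(angles = c(120, 120, 120), pdOffset = 0,
                                seed = 1)[[1]]
  expect_equal(planarity(ideal$pro_R, d), 0, tolerance = 1e-9)
  expect_equal(yNess(ideal$pro_R, d), 0, tolerance = 1e-9)
  expect_identical(ideal$truth$planarity, 0)
  expect_true(is.na(ideal$truth$projected_angle))

  skew <- simulateToyComplexes(angles = c(130, 115, 115), pdOffset = 0.3,
                               seed = 2)[[1]]
  expect_equal(skew$truth$y_ness, 20)
  expect_equal(skew$truth$planarity, 0.3)
  for (s in list(skew$pro_R, skew$pro_S)) {
    expect_equal(planarity(s, d), skew$truth$planarity, tolerance = 1e-9)
    expect_equal(yNess(s, d), skew$truth$y_ness, tolerance = 1e-9)
    expect_equal(projectedMetalAngle(s, d), skew$truth$projected_angle,
                 tolerance = 1e-9)
  }
  expect_error(simulateToyComplexes(angles = c(100, 100, 100)),
               "summing to 360")
})

test_that("jittered toy complexes stay near their analytic truth", {
  d <- donorSet(1, 2:4, 2)
  toys <- simulateToyComplexes(n = 100, angles = c(130, 115, 115),
                               pdOffset = 0.3, jitterSd = 0.01,
                               seed = 42)
  errs <- vapply(toys, function(tc)
    c(abs(planarity(tc$pro_R, d) - tc$truth$planarity),
      abs(yNess(tc$pro_R, d) - tc$truth$y_ness),
      abs(projectedMetalAngle(tc$pro_R, d) - tc$truth$projected_angle)),
    numeric(3))
  expect_lt(max(errs[1, ]), 5 * 0.01)        # planarity, Angstrom
  expect_lt(max(errs[2, ]), 4)               # y-ness, degrees
  expect_lt(max(errs[3, ]), 1.5)             # projected angle, degrees
})

test_that("random tables have uniform features and valid labels", {
  t <- randomTable(17, 15, seed = 4)
  expect_identical(dim(featureValues(t)), c(17L, 15L))
  expect_identical(featureValues(randomTable(17, 15, seed = 4)),
                   featureValues(t))
  s <- sPercent(selectivityLabels(t))
  expect_true(all(s > 0 & s < 100))
  big <- randomTable(1000, 3, seed = 9)
  mu <- colMeans(featureValues(big))
  expect_true(all(mu > 0.4 & mu < 0.6))
})

test_that("LOO error degrades monotonically with label noise", {
  rmse <- vapply(c(0, 2, 5, 10), function(ns) {
    mean(vapply(1:4, function(s) {
      sim <- simulateFeatureTable(plantedSystem(noiseSd = ns, seed = s))
      looCrossValidate(sim$train, nnConfig(seed = s))@rmse
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
})
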