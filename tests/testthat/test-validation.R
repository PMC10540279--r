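valPlanted <- function(seed = 2) {
  simulateFeatureTable(plantedSystem(nTrain = 8, nFeatures = 4,
                                     informative = 1:3, noiseSd = 2,
                                     seed = seed))
}

fastCfg <- function(...) nnConfig(maxEpochs = 400, learningRate = 1e-2,
                                  ...)

test_that("y-shuffling preserves the label multiset and supports controls", {
  t <- valPlanted()$train
  cfg <- fastCfg(seed = 1)
  # an identity permutation replicate equals the reference run exactly
  rep0 <- yShuffleTest(t, cfg, permutations = list(seq_len(8)))
  expect_identical(rep0$rmse[1], rep0$referenceRmse)
  expect_identical(rep0$rsq[1], rep0$referenceRsq)

  # seeded permutations shuffle, never alter, the labels
  perms <- lapply(1:4, function(i)
    stereonn:::.withSeed(1 + i, sample(8)))
  for (p in perms) expect_identical(sort(p), 1:8)
  rep1 <- yShuffleTest(t, cfg, replicates = 4, seed = 1)
  rep2 <- yShuffleTest(t, cfg, replicates = 4, seed = 1)
  expect_identical(rep1$rmse, rep2$rmse)     # reproducible under seed
  expect_identical(rep1$mode, "y_shuffle")
  expect_length(rep1$rsq, 4)
})

test_that("randomization modes keep the promised side fixed", {
  sim <- valPlanted(seed = 3)
  cfg <- fastCfg(seed = 1)
  rxy <- xyRandomizationTest(n = 6, p = 3, cfg = cfg, replicates = 2,
                             seed = 2)
  expect_identical(rxy$mode, "xy_random")
  expect_length(rxy$rmse, 2)
  expect_true(is.na(rxy$referenceRmse))

  rx <- xyRandomizationTest(cfg = cfg, replicates = 2, seed = 2,
                            mode = "x", table = sim$train)
  expect_identical(rx$mode, "x_random")
  expect_false(is.na(rx$referenceRmse))
  ry <- xyRandomizationTest(cfg = cfg, replicates = 2, seed = 2,
                            mode = "y", table = sim$train)
  expect_identical(ry$mode, "y_random")
  expect_error(xyRandomizationTest(cfg = cfg, mode = "x"),
               "need a labeled table")
})

test_that("metric bake-off reports five comparable models and a winner", {
  sim <- valPlanted(seed = 4)
  bo <- metricBakeoff(sim$train, sim$val1, fastCfg(seed = 1),
                      trainCV = FALSE)
  expect_named(bo$models,
               c("ee", "er_ratio", "ln_er", "s_select", "r_select"))
  expect_length(bo$validationRmse, 5)
  expect_identical(unname(bo$validationRmse[bo$winner]),
                   min(bo$validationRmse))
  # predictions are all on the S% scale
  for (e in bo$models)
    expect_true(all(e$validation$predictedS > 0 &
                    e$validation$predictedS < 100))
  # with trainCV, per-metric CVResults are attached
  bo2 <- metricBakeoff(sim$train, sim$val1, fastCfg(seed = 1),
                       trainCV = TRUE)
  expect_s4_class(bo2$models$s_select$cv, "CVResult")
  expect_error(metricBakeoff(sim$train, sim$val1[, 1:2], fastCfg()),
               "share feature names")
})

test_that("out-of-domain metric predictions are clamped, not fatal", {
  conv <- stereonn:::.metricToS(c(-5, 50, 120), "ee")
  expect_equal(conv$clamped, 2L)
  expect_true(all(conv$s >= 50 & conv$s < 100))
  conv2 <- stereonn:::.metricToS(c(-1, 2), "er_ratio")
  expect_equal(conv2$clamped, 1L)
  expect_true(all(is.finite(conv2$s)))
  conv3 <- stereonn:::.metricToS(c(-20, 140), "s_select")
  expect_equal(conv3$clamped, 2L)
  # ln_er accepts every real value
  expect_equal(stereonn:::.metricToS(c(-30, 30), "ln_er")$clamped, 0L)
})

test_that("ddG baseline achieves perfect scores on self-consistent input", {
  obs <- selectivity(s = c(89, 80, 61, 94, 70))
  ids <- sprintf("L%d", 1:5)
  ddg <- erToDdg(obs)
  rep <- ddgBaseline(setNames(ddg, ids), obs, labelIds = ids)
  expect_equal(rep$rmse, 0, tolerance = 1e-9)
  expect_equal(rep$rsq, 1, tolerance = 1e-9)
  expect_equal(rep$slope, 1, tolerance = 1e-9)

  # negative ddg flips the favoured enantiomer with a message
  obs2 <- selectivity(s = c(89, 30))
  dd2 <- c(1, -0.5)
  names(dd2) <- c("A", "B")
  expect_message(rep2 <- ddgBaseline(dd2, obs2, labelIds = c("A", "B")),
                 "opposite enantiomer")
  expect_lt(rep2$predictedS[["B"]], 50)

  expect_error(ddgBaseline(setNames(ddg, ids), obs,
                           labelIds = sprintf("X%d", 1:5)),
               "no overlapping")
})

test_that("permutation skill gap: planted signal beats shuffled labels", {
  # small but decisive regime: strong signal, little noise
  sim <- simulateFeatureTable(plantedSystem(nTrain = 10, nFeatures = 4,
                                            noiseSd = 1, seed = 1))
  rep <- yShuffleTest(sim$train, fastCfg(seed = 1), replicates = 6,
                      seed = 7)
  expect_lt(rep$referenceRmse, rep$meanRmse)
})
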