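makeGeomLong <- function(ids = c("L1", "L2", "L3")) {
  data.frame(ligand_id = rep(ids, each = 2),
             name = rep(c("planarity_proR", "planarity_proS"),
                        length(ids)),
             value = seq_len(2 * length(ids)) / 10,
             stringsAsFactors = FALSE)
}

test_that("assembleFeatures joins blocks with strict coverage", {
  aux <- data.frame(ligand_id = c("L3", "L1", "L2"),
                    c2_pop = c(3, 1, 2), p_pop = c(6, 4, 5))
  t <- assembleFeatures(makeGeomLong(), electronic = aux)
  expect_identical(dim(featureValues(t)), c(3L, 4L))
  expect_identical(ligandIds(t), c("L1", "L2", "L3"))
  # column order: geometric block then electronic
  expect_identical(featureNames(t),
                   c("planarity_proR", "planarity_proS", "c2_pop", "p_pop"))
  expect_identical(unname(provenance(t)),
                   c("geometric", "geometric", "electronic", "electronic"))
  expect_equal(featureValues(t)["L2", "c2_pop"], 2)

  # shuffled input rows give the identical table
  geom2 <- makeGeomLong()[sample(6), ]
  t2 <- assembleFeatures(geom2, electronic = aux[c(2, 3, 1), ])
  expect_identical(featureValues(t2), featureValues(t))

  expect_error(assembleFeatures(makeGeomLong(),
                                electronic = aux[aux$ligand_id != "L2", ]),
               "missing ligands: L2")
  dup <- data.frame(ligand_id = c("L1", "L2", "L3"), planarity_proR = 1:3)
  expect_error(assembleFeatures(makeGeomLong(), electronic = dup),
               "duplicate feature")
})

test_that("assembleFeatures attaches er labels and dispersion block", {
  labels <- data.frame(ligand_id = c("L1", "L2", "L3"),
                       er = c("11:89", "20:80", "45:55"))
  disp <- data.frame(ligand_id = c("L1", "L2", "L3"), disp_e = c(1, 2, 3))
  t <- assembleFeatures(makeGeomLong(), dispersion = disp, labels = labels)
  expect_equal(sPercent(selectivityLabels(t)), c(89, 80, 55))
  expect_identical(unname(provenance(t))[3], "dispersion")
  expect_error(assembleFeatures(makeGeomLong(),
                                labels = labels[-2, ]),
               "missing ligands: L2")
})

test_that("feature CSV round-trips values, provenance and labels", {
  path <- withr::local_tempfile(fileext = ".csv")
  t <- tinyTable()
  writeFeatureCsv(t, path)
  t2 <- readFeatureCsv(path)
  expect_equal(featureValues(t2), featureValues(t), tolerance = 1e-9)
  expect_identical(provenance(t2), provenance(t))
  expect_equal(sPercent(selectivityLabels(t2)),
               sPercent(selectivityLabels(t)), tolerance = 1e-4)
})

test_that("min-max normalization fits on the subset only", {
  t <- tinyTable()
  p <- minmaxFit(t, rows = 1:3)
  expect_equal(unname(p@mins["a"]), 2)
  expect_equal(unname(p@maxs["a"]), 6)
  expect_identical(p@excluded, "const")

  scaled <- minmaxApply(t, p)
  expect_equal(unname(featureValues(scaled)[, "a"]), c(0, 0.5, 1, 1.5))
  expect_false("const" %in% featureNames(scaled))
  # rows used for fitting always land in [0, 1]
  expect_true(all(featureValues(minmaxApply(t[1:3, ], p)) >= 0 &
                  featureValues(minmaxApply(t[1:3, ], p)) <= 1))

  # no leakage: corrupting out-of-subset rows changes nothing
  v <- featureValues(t)
  v[4, ] <- c(1e6, -1e6, 42)
  t.bad <- featureTable(v, provenance = provenance(t), labels = t@labels)
  p.bad <- minmaxFit(t.bad, rows = 1:3)
  expect_identical(p.bad@mins, p@mins)
  expect_identical(p.bad@maxs, p@maxs)

  expect_error(minmaxFit(t, rows = integer()), "non-empty")
  expect_error(minmaxApply(t[, 1], p), "lacks features")
})

test_that("correlationRank matches the textbook formula and orders by |R|", {
  t <- tinyTable()
  rk <- correlationRank(t, metric = "s_select")
  y <- c(60, 70, 80, 90)
  handR <- function(x) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  v <- featureValues(t)
  expect_equal(rk$r[rk$feature == "a"], handR(v[, "a"]), tolerance = 1e-12)
  expect_equal(rk$r[rk$feature == "b"], handR(v[, "b"]), tolerance = 1e-12)
  expect_identical(rk$feature[1], "a")          # perfectly linear in y
  expect_equal(rk$r[1], 1)
  expect_true(rk$zero_variance[rk$feature == "const"])
  expect_equal(rk$r[rk$feature == "const"], 0)

  # a feature equal to -label ranks first by |R|
  v2 <- cbind(v, neg = -y)
  t2 <- featureTable(v2, labels = t@labels)
  rk2 <- correlationRank(t2)
  expect_identical(rk2$feature[1], "a")         # tie broken by name
  expect_equal(abs(rk2$r[rk2$feature == "neg"]), 1, tolerance = 1e-12)

  # invariant under affine rescaling of a feature
  v3 <- v
  v3[, "b"] <- 100 - 7 * v3[, "b"]
  rk3 <- correlationRank(featureTable(v3, labels = t@labels))
  expect_equal(abs(rk3$r[rk3$feature == "b"]),
               abs(rk$r[rk$feature == "b"]), tolerance = 1e-12)
})

test_that("selectManual keeps top-k features in original column order", {
  t <- tinyTable()
  expect_identical(featureNames(selectManual(t, 3)), featureNames(t))
  expect_identical(featureNames(selectManual(t, 1)), "a")
  expect_error(selectManual(t, 0), "k must be")
  expect_error(selectManual(t, 9), "k must be")

  # planted-signal recovery: informative features dominate |R| once the
  # sample is large enough for the noise-feature correlations to shrink
  sim <- simulateFeatureTable(plantedSystem(nTrain = 120, nFeatures = 15,
                                            noiseSd = 2,
                                            nonlinearity = "none",
                                            seed = 8))
  sel <- selectManual(sim$train, 3)
  expect_identical(sort(featureNames(sel)),
                   sort(c("c2_electron_pop", "pd_planarity",
                          "p_ring_angle")))
})
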