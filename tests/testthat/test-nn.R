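test_that("activation functions match their closed forms", {
  expect_equal(nnActivation("relu", c(-2, 0, 3)), c(0, 0, 3))
  expect_equal(nnActivation("leaky_relu", -2), -0.02)
  expect_equal(nnActivation("leaky_relu", 3), 3)
  expect_equal(nnActivation("softplus", 0), log(2))
  expect_equal(round(nnActivation("softplus", 0), 7), 0.6931472)
  # overflow-safe at extreme arguments
  expect_equal(nnActivation("softplus", 800), 800)
  expect_equal(nnActivation("softplus", -800), 0)
  expect_equal(nnActivation("sigmoid", 0), 0.5)
  expect_equal(nnActivation("tanh", 1), tanh(1))
  expect_equal(nnActivation("linear", -4.2), -4.2)
})

test_that("initialization is seeded, He-scaled and reproducible", {
  cfg <- nnConfig(inputDim = 6, hidden = c(5, 4))
  a <- initializeNN(cfg, seed = 3)
  b <- initializeNN(cfg, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, initializeNN(cfg, seed = 4)))
  expect_identical(dim(a$W[[1]]), c(5L, 6L))
  expect_identical(dim(a$W[[3]]), c(1L, 4L))
  expect_true(all(vapply(a$b, function(x) all(x == 0), logical(1))))
  # sampling check on a wide layer: var ~ 2 / fan_in within 20 %
  wide <- initializeNN(nnConfig(inputDim = 50, hidden = 1000), seed = 5)
  expect_equal(var(as.numeric(wide$W[[1]])), 2 / 50, tolerance = 0.2)
})

test_that("forward pass reproduces hand arithmetic", {
  # 2-input, 1 hidden relu node: 2*relu(x1 - x2) + 1
  params <- list(W = list(matrix(c(1, -1), 1, 2), matrix(2, 1, 1)),
                 b = list(0, 1))
  expect_equal(nnForward(params, c(3, 1), activation = "relu"), 5)
  expect_equal(nnForward(params, c(1, 3), activation = "relu"), 1)
  # all-zero weights: output bias for every input
  z <- list(W = list(matrix(0, 3, 2), matrix(0, 1, 3)),
            b = list(numeric(3), 7))
  expect_equal(nnForward(z, matrix(runif(10), 5, 2)), rep(7, 5))
  expect_error(nnForward(params, c(1, 2, 3)), "expects 2")
})

test_that("a linear-activation network is a single affine map", {
  set.seed(2)
  init <- initializeNN(nnConfig(inputDim = 4, hidden = c(3, 3)), seed = 2)
  x <- matrix(rnorm(20), 5, 4)
  out <- nnForward(init, x, activation = "linear")
  A <- init$W[[3]] %*% init$W[[2]] %*% init$W[[1]]
  c0 <- init$W[[3]] %*% (init$W[[2]] %*% init$b[[1]] + init$b[[2]]) +
    init$b[[3]]
  expect_equal(out, as.numeric(x %*% t(A)) + as.numeric(c0),
               tolerance = 1e-12)
})

test_that("analytic gradients match finite differences for all activations", {
  codes <- stereonn:::.ACTIVATION_CODES
  set.seed(7)
  x <- matrix(runif(12), 3, 4)
  y <- runif(3)
  cfg <- nnConfig(inputDim = 4, hidden = c(5, 4))
  init <- initializeNN(cfg, seed = 3)
  h <- 1e-6
  for (a in names(codes)) {
    g <- stereonn:::nn_loss_grad_cpp(x, y, init$W, init$b, codes[[a]],
                                     0.01, 0)
    for (l in seq_along(init$W)) {
      idx <- seq_len(length(init$W[[l]]))
      for (k in idx) {
        Wp <- init$W; Wp[[l]][k] <- Wp[[l]][k] + h
        Wm <- init$W; Wm[[l]][k] <- Wm[[l]][k] - h
        fd <- (stereonn:::nn_loss_grad_cpp(x, y, Wp, init$b, codes[[a]],
                                           0.01, 0)$loss -
               stereonn:::nn_loss_grad_cpp(x, y, Wm, init$b, codes[[a]],
                                           0.01, 0)$loss) / (2 * h)
        an <- g$gW[[l]][k]
        expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-8), 1e-5)
      }
      # bias gradients of the layer
      for (k in seq_along(init$b[[l]])) {
        bp <- init$b; bp[[l]][k] <- bp[[l]][k] + h
        bm <- init$b; bm[[l]][k] <- bm[[l]][k] - h
        fd <- (stereonn:::nn_loss_grad_cpp(x, y, init$W, bp, codes[[a]],
                                           0.01, 0)$loss -
               stereonn:::nn_loss_grad_cpp(x, y, init$W, bm, codes[[a]],
                                           0.01, 0)$loss) / (2 * h)
        an <- g$gb[[l]][k]
        expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-8), 1e-5)
      }
    }
  }
})

test_that("training drives a realizable target below 1% of label spread", {
  set.seed(42)
  x <- matrix(runif(17 * 15), 17, 15)
  teacher <- initializeNN(nnConfig(inputDim = 15), seed = 99)
  y <- nnForward(teacher, x)
  fit <- stereonn:::.trainRaw(x, y, nnConfig(inputDim = 15), seed = 1)
  pred <- as.numeric(stereonn:::nn_forward_cpp(x, fit$W, fit$b, 1L, 0.01))
  expect_lt(sqrt(mean((pred - y)^2)), 0.01 * sd(y))
  # loss trace is finite and ends near zero
  expect_true(all(is.finite(fit$loss_trace)))
})

test_that("a linear-activation network recovers ordinary least squares", {
  set.seed(42)
  x <- matrix(runif(17 * 3), 17, 3)
  y <- as.numeric(5 + x %*% c(2, -3, 1))     # exactly linear, noiseless
  fit <- stereonn:::.trainRaw(x, y, nnConfig(inputDim = 3,
                                             activation = "linear"),
                              seed = 2)
  pred <- as.numeric(stereonn:::nn_forward_cpp(x, fit$W, fit$b, 0L, 0.01))
  ols <- as.numeric(fitted(lm(y ~ x)))
  expect_equal(pred, ols, tolerance = 1e-4)
})

test_that("training is deterministic under a fixed seed", {
  sim <- simulateFeatureTable(plantedSystem(nTrain = 8, nFeatures = 4,
                                            seed = 2))
  cfg <- nnConfig(maxEpochs = 300, seed = 5)
  m1 <- fitNNModel(sim$train, cfg)
  m2 <- fitNNModel(sim$train, cfg)
  expect_identical(m1@weights, m2@weights)
  expect_identical(predict(m1, sim$val1), predict(m2, sim$val1))
})

test_that("model JSON serialization round-trips predictions", {
  sim <- simulateFeatureTable(plantedSystem(nTrain = 8, nFeatures = 4,
                                            seed = 3))
  m <- fitNNModel(sim$train, nnConfig(maxEpochs = 200, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  saveNNModel(m, path)
  m2 <- loadNNModel(path)
  expect_equal(predict(m2, sim$val1), predict(m, sim$val1),
               tolerance = 1e-12)
  expect_identical(m2@targetMetric, m@targetMetric)
  expect_identical(m2@norm@excluded, m@norm@excluded)
})
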