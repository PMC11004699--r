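test_that("hidden output matrix matches a hand-computed oracle", {
  # zero weights and biases: sigmoid(0) everywhere
  H <- elmHiddenMatrix(matrix(rnorm(6), 2, 3), matrix(0, 4, 3), rep(0, 4))
  expect_equal(H, matrix(0.5, 2, 4), ignore_attr = TRUE)
  # 1x1 identity-like case
  expect_equal(elmHiddenMatrix(matrix(0, 1, 1), matrix(1, 1, 1), 0)[1, 1],
               0.5)
  # frozen 3x2 case computed independently before the build
  X <- rbind(c(1, 2), c(0, 1), c(-1, 0.5))
  W <- rbind(c(0.5, -1), c(2, 0.3))
  b <- c(0.1, -0.2)
  expected <- rbind(c(0.19781611144141825, 0.9168273035060777),
                    c(0.289050497374996, 0.5249791874789399),
                    c(0.289050497374996, 0.11405238127979084))
  expect_equal(elmHiddenMatrix(X, W, b), expected, tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_error(elmHiddenMatrix(matrix(0, 2, 3), matrix(0, 4, 2), rep(0, 4)),
               "width")
  expect_error(elmHiddenMatrix(matrix(0, 2, 3), matrix(0, 4, 3), rep(0, 3)),
               "bias")
})

test_that("output weights are the minimum-norm least-squares solution", {
  set.seed(31)
  # square nonsingular: exact inverse solve
  H <- matrix(rnorm(16), 4, 4)
  Tm <- matrix(rnorm(8), 4, 2)
  beta <- solveOutputWeights(H, Tm)
  expect_equal(beta, solve(H, Tm), tolerance = 1e-9)
  # overdetermined: residual is the global least-squares minimum
  H <- matrix(rnorm(40 * 10), 40, 10)
  Tm <- matrix(rnorm(40 * 2), 40, 2)
  beta <- solveOutputWeights(H, Tm)
  base <- sum((H %*% beta - Tm)^2)
  ginv_beta <- MASS::ginv(H) %*% Tm
  expect_equal(base, sum((H %*% ginv_beta - Tm)^2), tolerance = 1e-8)
  for (i in 1:1000) {
    delta <- matrix(rnorm(20, sd = 0.01), 10, 2)
    expect_gte(sum((H %*% (beta + delta) - Tm)^2), base - 1e-10)
  }
})

test_that("rank-deficient systems return the smallest-norm solution", {
  # H has rank 1; all least-squares solutions satisfy beta1 + beta2 = 1
  H <- matrix(1, 2, 2)
  Tm <- matrix(1, 2, 1)
  beta <- solveOutputWeights(H, Tm)
  expect_equal(sum(beta), 1, tolerance = 1e-12)
  # enumerate the one-parameter solution family; (0.5, 0.5) minimizes norm
  family <- seq(-2, 3, by = 0.1)
  norms <- vapply(family, function(a) a^2 + (1 - a)^2, numeric(1))
  expect_lte(sum(beta^2), min(norms) + 1e-12)
  expect_equal(as.numeric(beta), c(0.5, 0.5), tolerance = 1e-12)
  # all-zero H degenerates to the zero solution
  expect_equal(solveOutputWeights(matrix(0, 3, 2), matrix(1, 3, 1)),
               matrix(0, 2, 1), ignore_attr = TRUE)
})

test_that("ELM interpolates when hidden nodes match the sample count", {
  set.seed(12)
  x <- matrix(rnorm(10 * 3), 10, 3)
  y <- rep(0:1, 5)
  model <- elmTrain(x, y, hiddenCount = 10, seed = 5)
  pred <- elmPredict(model, x)
  expect_equal(as.integer(pred$class), y)
  tmat <- cbind(as.numeric(y == 0), as.numeric(y == 1))
  expect_lte(sum((pred$scores - tmat)^2), 1e-6)
})

test_that("prediction scores match hand computation and ties break low", {
  W <- matrix(c(0.5, -1), 1, 2)
  model <- new("ELMModel", inputWeights = W, biases = 0.2,
               activation = "sigmoid",
               outputWeights = matrix(c(2, -1), 1, 2),
               classLevels = c("0", "1"))
  x <- matrix(c(1, 0.5), 1, 2)
  h <- 1 / (1 + exp(-(0.5 * 1 - 1 * 0.5 + 0.2)))
  pred <- elmPredict(model, x)
  expect_equal(as.numeric(pred$scores), c(2 * h, -1 * h), tolerance = 1e-12)
  expect_equal(pred$class, "0")
  # zero output weights give exactly tied scores; first class wins
  tied <- new("ELMModel", inputWeights = W, biases = 0.2,
              activation = "sigmoid",
              outputWeights = matrix(0, 1, 2), classLevels = c("0", "1"))
  expect_equal(elmPredict(tied, x)$class, "0")
})

test_that("agent codec is an exact round trip with row-major layout", {
  W <- matrix(1:6 + 0.5, 2, 3, byrow = TRUE)
  b <- c(-1, 2)
  v <- agentEncode(W, b)
  expect_length(v, 8)
  # row-major: node 1's weights first
  expect_equal(v[1:3], W[1, ])
  dec <- agentDecode(v, 2, 3)
  expect_equal(dec$weights, W)
  expect_equal(dec$biases, b)
  expect_error(agentDecode(v, 2, 4), "length")
})

test_that("the SSE fitness matches an independent computation and is order-invariant", {
  set.seed(40)
  x <- matrix(rnorm(5 * 2), 5, 2)
  y <- c(0, 1, 1, 0, 1)
  tmat <- cbind(as.numeric(y == 0), as.numeric(y == 1))
  W <- matrix(runif(6, -1, 1), 3, 2)
  b <- runif(3, -1, 1)
  agent <- agentEncode(W, b)
  fit <- elmFitness(agent, x, tmat, hiddenCount = 3)
  # independent route: MASS pseudoinverse and elementwise sums
  H <- 1 / (1 + exp(-(x %*% t(W) + matrix(b, 5, 3, byrow = TRUE))))
  beta <- MASS::ginv(H) %*% tmat
  sse <- 0
  resid <- tmat - H %*% beta
  for (i in 1:5) for (k in 1:2) sse <- sse + resid[i, k]^2
  expect_equal(fit, sse, tolerance = 1e-10)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(elmFitness(agent, x[perm, ], tmat[perm, ], 3), fit,
               tolerance = 1e-10)
  # interpolating configuration: hidden nodes = samples
  W5 <- matrix(runif(10, -1, 1), 5, 2)
  b5 <- runif(5, -1, 1)
  expect_lte(elmFitness(agentEncode(W5, b5), x, tmat, 5), 1e-6)
})

test_that("optimizer-tuned ELM separates Gaussian clusters and beats random draws", {
  ds <- toyClusters(n = 100, d = 5, sep = 6)
  fit <- trainElmAgoa(ds$inputs, ds$labels, hiddenCount = 10,
                      control = agoaControl(populationSize = 10,
                                            maxIterations = 12, seed = 3))
  pred <- elmPredict(fit$model, ds$inputs)
  expect_gte(mean(as.integer(pred$class) == ds$labels), 0.95)
  # fitness trace non-increasing, and the reported best matches the model
  expect_true(all(diff(convergenceHistory(fit$result)) <= 0))
  # same seed, same model
  fit2 <- trainElmAgoa(ds$inputs, ds$labels, hiddenCount = 10,
                       control = agoaControl(populationSize = 10,
                                             maxIterations = 12, seed = 3))
  expect_identical(hiddenWeights(fit$model), hiddenWeights(fit2$model))
  expect_identical(outputWeights(fit$model), outputWeights(fit2$model))
  # tuned SSE no worse than the median of random (W, b) draws
  tmat <- cbind(as.numeric(ds$labels == 0), as.numeric(ds$labels == 1))
  set.seed(99)
  randomSSE <- replicate(35, {
    agent <- runif(10 * 5 + 10, -1, 1)
    elmFitness(agent, ds$inputs, tmat, 10)
  })
  expect_lte(bestFitness(fit$result), median(randomSSE))
  expect_error(trainElmAgoa(ds$inputs, rep(1, 100), hiddenCount = 5),
               "2 classes")
})

test_that("models survive a JSON round trip", {
  set.seed(3)
  x <- matrix(rnorm(30), 15, 2)
  y <- rep(0:1, c(7, 8))
  model <- elmTrain(x, y, hiddenCount = 4, seed = 2)
  path <- tempfile(fileext = ".json")
  writeELMModel(model, path)
  back <- readELMModel(path)
  expect_equal(hiddenWeights(back), hiddenWeights(model),
               ignore_attr = TRUE)
  expect_equal(outputWeights(back), outputWeights(model),
               ignore_attr = TRUE)
  expect_equal(classLevels(back), classLevels(model))
  expect_identical(elmPredict(back, x)$class, elmPredict(model, x)$class)
})
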