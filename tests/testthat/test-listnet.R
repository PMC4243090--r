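# ListNet: top-one probabilities, cross-entropy loss, analytic gradient
# (checked against finite differences) and gradient-descent training.

test_that("top-one probabilities are a stable softmax", {
  expect_equal(topOneProbabilities(c(1, 1, 1)), rep(1 / 3, 3))
  expect_equal(topOneProbabilities(5), 1)
  expect_equal(topOneProbabilities(c(0, log(2))), c(1 / 3, 2 / 3))
  # overflow safety
  p <- topOneProbabilities(c(1000, 1001))
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("the loss matches its closed forms", {
  # uniform predicted distribution: L = ln 2 regardless of labels' shape
  expect_equal(listnetLoss(c(1, 0), c(0, 0)), log(2), tolerance = 1e-12)
  # single element: both distributions are (1)
  expect_equal(listnetLoss(0.7, 3.2), 0)
  # z = y attains the entropy lower bound
  y <- c(0.9, 0.2, 0.5, 0.1)
  py <- topOneProbabilities(y)
  expect_equal(listnetLoss(y, y), -sum(py * log(py)), tolerance = 1e-12)
  # and any other z is worse
  expect_gt(listnetLoss(y, rev(y)), listnetLoss(y, y))
  expect_error(listnetLoss(c(1, 0), c(1, 0, 0)), "same length")
})

test_that("analytic gradient agrees with central finite differences", {
  set.seed(41)
  h <- 1e-6
  for (rep in 1:100) {
    n <- sample(2:8, 1L)
    inst <- queryInstance(rep, matrix(runif(n * 3), ncol = 3), runif(n))
    w <- rnorm(3)
    g <- listnetGradient(w, inst)
    for (k in 1:3) {
      e <- c(0, 0, 0); e[k] <- h
      num <- (listnetLoss(inst$labels,
                          as.vector(inst$features %*% (w + e))) -
              listnetLoss(inst$labels,
                          as.vector(inst$features %*% (w - e)))) / (2 * h)
      expect_lt(abs(g[k] - num), 1e-6)
    }
  }
})

test_that("degenerate instances have zero gradient", {
  instZero <- queryInstance(1L, matrix(0, 4, 3), c(0.2, 0.4, 0.1, 0.9))
  expect_equal(listnetGradient(c(1, 2, 3), instZero), c(0, 0, 0))
  inst1 <- queryInstance(1L, matrix(runif(3), 1, 3), 0.5)
  expect_equal(listnetGradient(c(1, 2, 3), inst1), c(0, 0, 0))
})

test_that("training with zero iterations returns the initial weights", {
  insts <- generateLtrInstances(5L, 4L, seed = 5L)
  m <- trainListnet(insts, nIterations = 0L, initWeights = c(0.2, 0.3, 0.5))
  expect_equal(unname(modelWeights(m)), c(0.2, 0.3, 0.5))
  expect_length(lossTrace(m), 1L)
})

test_that("the training loss trace is non-increasing at the default step", {
  insts <- generateLtrInstances(50L, 8L, noiseSd = 0.05, seed = 6L)
  m <- trainListnet(insts, learningRate = 0.01, nIterations = 300L)
  expect_true(all(diff(lossTrace(m)) <= 1e-12 * abs(lossTrace(m)[1])))
})

test_that("labels driven by one feature give it the dominant weight", {
  set.seed(43)
  insts <- lapply(1:40, function(i) {
    x <- matrix(runif(8 * 3), ncol = 3)
    queryInstance(i, x, x[, 1])
  })
  m <- trainListnet(insts, nIterations = 500L)
  w <- modelWeights(m)
  expect_gt(w[["go"]], 0)
  expect_equal(which.max(abs(w)), 1L, ignore_attr = TRUE)
})

test_that("permuting a list permutes scores and leaves the loss unchanged", {
  set.seed(44)
  x <- matrix(runif(6 * 3), ncol = 3)
  y <- runif(6)
  w <- c(0.1, 0.2, 0.7)
  m <- new("RankingModel",
           weights = setNames(w, c("go", "lda", "textrank")),
           lossTrace = numeric(0), learningRate = 0.01, nIterations = 0L)
  z <- predictScores(m, x)
  p <- sample(6)
  expect_equal(predictScores(m, x[p, ]), z[p])
  expect_equal(listnetLoss(y[p], z[p]), listnetLoss(y, z),
               tolerance = 1e-12)
})

test_that("prediction is the plain dot product with arity checking", {
  m <- new("RankingModel",
           weights = setNames(c(0.1, 0.2, 0.7), c("go", "lda", "textrank")),
           lossTrace = numeric(0), learningRate = 0.01, nIterations = 0L)
  expect_equal(predictScores(m, c(0.5, 0.0, 0.4)), 0.33)
  zero <- new("RankingModel",
              weights = setNames(c(0, 0, 0), c("go", "lda", "textrank")),
              lossTrace = numeric(0), learningRate = 0.01,
              nIterations = 0L)
  expect_equal(predictScores(zero, matrix(runif(12), ncol = 3)),
               rep(0, 4))
  proj <- new("RankingModel",
              weights = setNames(c(1, 0, 0), c("go", "lda", "textrank")),
              lossTrace = numeric(0), learningRate = 0.01,
              nIterations = 0L)
  x <- matrix(runif(9), ncol = 3)
  expect_equal(predictScores(proj, x), unname(x[, 1]))
  expect_error(predictScores(m, matrix(1, 2, 2)), "arity")
})

test_that("relevance labels are description cosines with the empty guard", {
  st <- statsWithIdf(c(gene = 1, protein = 2, cell = 2))
  expect_equal(relevanceLabel(c("gene", "protein"), c("gene", "cell"), st),
               0.2, tolerance = 1e-12)
  d <- c("zinc", "ion")
  expect_equal(relevanceLabel(d, d, st), 1)
  expect_equal(relevanceLabel(c("actin"), d, st), 0)
  expect_error(relevanceLabel(d, character(0), st), "empty reference")
})

test_that("ranking model files round trip", {
  insts <- generateLtrInstances(10L, 5L, seed = 7L)
  m <- trainListnet(insts, nIterations = 50L)
  f <- tempfile()
  writeRankingModel(m, f)
  m2 <- readRankingModel(f)
  expect_equal(modelWeights(m2), modelWeights(m))
  expect_equal(m2@learningRate, m@learningRate)
  expect_equal(m2@nIterations, m@nIterations)
})
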