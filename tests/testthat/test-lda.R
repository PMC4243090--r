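# Collapsed-Gibbs LDA: determinism, closed forms, topic recovery on
# separable corpora, topic-word selection and serialization.

# two-topic corpus over disjoint vocabularies A and B
separableCorpus <- function(nDocsPerTopic = 15L, docLen = 40L,
                            seed = 61L) {
  A <- paste0("a", sprintf("%02d", 1:20))
  B <- paste0("b", sprintf("%02d", 1:20))
  # skewed within-topic word probabilities define a true top-10
  p <- (20:1)^2
  withSeed(seed, {
    docsA <- replicate(nDocsPerTopic,
                       sample(A, docLen, TRUE, prob = p), simplify = FALSE)
    docsB <- replicate(nDocsPerTopic,
                       sample(B, docLen, TRUE, prob = p), simplify = FALSE)
    list(docs = c(docsA, docsB), A = A, B = B,
         trueTop = list(A[1:10], B[1:10]))
  })
}

test_that("identical inputs and seed give a bit-identical model", {
  sc <- separableCorpus()
  m1 <- fitLda(sc$docs, K = 2L, nIterations = 50L, seed = 9L)
  m2 <- fitLda(sc$docs, K = 2L, nIterations = 50L, seed = 9L)
  expect_identical(m1@topicWordDist, m2@topicWordDist)
  m3 <- fitLda(sc$docs, K = 2L, nIterations = 50L, seed = 10L)
  expect_false(identical(m1@topicWordDist, m3@topicWordDist))
})

test_that("topic rows are distributions and input guards fire", {
  sc <- separableCorpus()
  m <- fitLda(sc$docs, K = 3L, nIterations = 20L, seed = 1L)
  expect_equal(rowSums(m@topicWordDist), rep(1, 3), tolerance = 1e-9)
  expect_error(fitLda(list(), K = 1L), "at least")
  expect_error(fitLda(list(character(0))), "empty vocabulary")
  expect_error(fitLda(list(c("a", "b")), K = 5L), "vocabulary size")
})

test_that("K = 1 recovers the smoothed corpus word frequencies", {
  docs <- list(c("x", "x", "y"), c("y", "z"))
  m <- fitLda(docs, K = 1L, nIterations = 10L, seed = 3L)
  counts <- c(x = 2, y = 2, z = 1)
  expected <- (counts + 0.01) / (5 + 3 * 0.01)
  expect_equal(m@topicWordDist[1, names(expected)], expected,
               tolerance = 1e-12)
})

test_that("a one-word corpus puts that word on top of every topic", {
  docs <- list(rep("solo", 12L), c("solo", "other"))
  m <- fitLda(docs, K = 2L, nIterations = 20L, seed = 2L)
  tops <- apply(m@topicWordDist, 1L, function(p)
    m@vocabulary[which.max(p)])
  expect_true(all(tops == "solo"))
})

test_that("well-separated topics are recovered (>= 80% of true top-10)", {
  sc <- separableCorpus()
  m <- fitLda(sc$docs, K = 2L, nIterations = 300L, seed = 5L)
  top10 <- apply(m@topicWordDist, 1L, function(p)
    m@vocabulary[order(-p)][1:10], simplify = FALSE)
  # match fitted topics to true topics by vocabulary block
  hitsPerTrue <- vapply(sc$trueTop, function(tt)
    max(vapply(top10, function(ft) length(intersect(ft, tt)), integer(1))),
    integer(1))
  expect_true(all(hitsPerTrue >= 8L))
  # and each fitted topic's top words stay within one block
  inA <- vapply(top10, function(ft) all(ft %in% sc$A), logical(1))
  inB <- vapply(top10, function(ft) all(ft %in% sc$B), logical(1))
  expect_true(all(inA | inB))
  expect_true(any(inA) && any(inB))
})

test_that("topic-word selection follows the summed document posterior", {
  sc <- separableCorpus()
  m <- fitLda(sc$docs, K = 2L, nIterations = 300L, seed = 5L)
  geneDocs <- sc$docs[1:3]   # pure topic-A documents
  tw <- selectTopicWords(m, geneDocs, topM = 10L)
  expect_lte(length(tw$words), 10L)
  expect_true(all(tw$words %in% sc$A))
  # brute-force posterior sum over topics, computed independently
  lphi <- log(m@topicWordDist)
  post <- sapply(geneDocs, function(d) {
    idx <- match(d, m@vocabulary)
    lp <- vapply(1:2, function(k)
      log(m@alpha) + sum(lphi[k, idx]), numeric(1))
    p <- exp(lp - max(lp)); p / sum(p)
  })
  expect_equal(tw$sourceTopic, which.max(rowSums(post)))
  # K = 1: the only topic wins whatever the documents
  m1 <- fitLda(sc$docs, K = 1L, nIterations = 20L, seed = 5L)
  expect_equal(selectTopicWords(m1, sc$docs[28:30], 5L)$sourceTopic, 1L)
  expect_error(selectTopicWords(m, list(), 5L), "at least one")
})

test_that("topic model files round trip", {
  sc <- separableCorpus()
  m <- fitLda(sc$docs, K = 2L, nIterations = 30L, seed = 8L)
  f <- tempfile()
  writeTopicModel(m, f)
  m2 <- readTopicModel(f)
  expect_equal(m2@topicWordDist, m@topicWordDist, tolerance = 1e-14)
  expect_identical(m2@vocabulary, m@vocabulary)
  expect_equal(m2@alpha, m@alpha)
  expect_equal(m2@seed, m@seed)
})
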