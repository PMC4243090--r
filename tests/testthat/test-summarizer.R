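# Greedy redundancy-penalised selection and the per-gene composition.

test_that("the hand-traced duplicate example selects sentences 1 then 3", {
  # sentence 2 duplicates sentence 1 (similarity 1), sentence 3 is
  # dissimilar; after picking 1, sentence 2 drops to 0.9 - 1.0 = -0.1
  st <- uniformStats(c("zinc", "ion", "bind", "actin", "myosin"))
  toks <- list(c("zinc", "ion"), c("zinc", "ion"), c("actin", "myosin"))
  s <- selectSummary(c("s1", "s2", "s3"), toks, c(0.9, 0.9, 0.5), st,
                     omega = 1, targetLength = 2L)
  expect_identical(s@sentenceIds, c("s1", "s3"))
  expect_equal(s@selectionScores, c(0.9, 0.5))
  expect_equal(s@originalScores, c(0.9, 0.5))
})

test_that("omega = 0 reduces to plain top-k (sort-based oracle)", {
  set.seed(71)
  vocab <- paste0("w", 1:30)
  st <- uniformStats(vocab)
  for (rep in 1:20) {
    n <- sample(3:12, 1L)
    toks <- replicate(n, sample(vocab, 5L, TRUE), simplify = FALSE)
    scores <- runif(n)
    ids <- paste0("s", seq_len(n))
    k <- sample(1:n, 1L)
    s <- selectSummary(ids, toks, scores, st, omega = 0,
                       targetLength = k)
    expect_identical(s@sentenceIds, ids[order(-scores)][seq_len(k)])
  }
})

test_that("selection edge cases: single candidate, exhaustion, empty set", {
  st <- uniformStats(c("zinc"))
  s1 <- selectSummary("only", list(c("zinc")), 0.4, st, targetLength = 5L)
  expect_identical(s1@sentenceIds, "only")
  expect_length(s1@sentences, 1L)
  expect_warning(
    s0 <- selectSummary(character(0), list(), numeric(0), st),
    "empty candidate")
  expect_length(s0@sentenceIds, 0L)
})

test_that("ties break toward the earlier candidate", {
  st <- uniformStats(c("aa", "bb", "cc", "dd"))
  toks <- list(c("aa"), c("bb"), c("cc"))
  s <- selectSummary(c("s1", "s2", "s3"), toks, c(0.5, 0.5, 0.5), st,
                     omega = 1, targetLength = 2L)
  expect_identical(s@sentenceIds, c("s1", "s2"))
})

test_that("selection scores are non-increasing along the pick order", {
  set.seed(72)
  vocab <- paste0("w", 1:20)
  st <- uniformStats(vocab)
  for (rep in 1:20) {
    n <- sample(4:10, 1L)
    toks <- replicate(n, sample(vocab, 6L, TRUE), simplify = FALSE)
    s <- selectSummary(paste0("s", 1:n), toks, runif(n), st, omega = 1,
                       targetLength = n)
    expect_true(all(diff(s@selectionScores) <= 1e-12))
  }
})

test_that("a verbatim duplicate is never selected under a large penalty", {
  set.seed(73)
  vocab <- paste0("w", 1:16)
  st <- uniformStats(vocab)
  for (rep in 1:20) {
    base <- lapply(0:3, function(i) vocab[i * 4 + 1:4])  # disjoint
    toks <- c(base, base[1])            # candidate 5 duplicates candidate 1
    scores <- runif(5, 0.2, 0.9)
    scores[5] <- scores[1] - 1e-9       # duplicate nearly ties the original
    omega <- max(scores) + 1
    s <- selectSummary(paste0("s", 1:5), toks, scores, st, omega = omega,
                       targetLength = 4L)
    expect_false("s5" %in% s@sentenceIds)
  }
})

test_that("summarizeGene picks a verbatim reference copy first", {
  fx <- writeTinyCorpus()
  corpus <- buildGeneCorpus(fx$corpus, fx$gene2go, fx$references)
  # append a document whose first sentence is the reference verbatim
  lines <- readLines(fx$corpus)
  extra <- jsonlite::toJSON(list(gene_id = 814629L, doc_id = "dref",
    text = "This protein binds zinc ions and nucleic acids. Filler text follows here."),
    auto_unbox = TRUE)
  writeLines(c(lines, extra), fx$corpus)
  corpus <- buildGeneCorpus(fx$corpus, fx$gene2go, fx$references)
  st <- corpusStats(corpus)
  m <- new("RankingModel",
           weights = setNames(c(0.4, 0.3, 0.3), c("go", "lda", "textrank")),
           lossTrace = numeric(0), learningRate = 0.01, nIterations = 0L)
  topicWords <- c("protein", "bind", "zinc", "ion", "nucleic", "acid")
  s <- summarizeGene(corpus, 814629L, m, topicWords, stats = st,
                     targetLength = 3L)
  expect_s4_class(s, "GeneSummary")
  expect_identical(s@sentenceIds[1], "dref#0")
  expect_lte(length(s@sentences), 3L)
})

test_that("a gene with exactly targetLength candidates selects them all", {
  fx <- writeTinyCorpus()
  corpus <- buildGeneCorpus(fx$corpus, fx$gene2go, fx$references)
  m <- new("RankingModel",
           weights = setNames(c(1, 1, 1), c("go", "lda", "textrank")),
           lossTrace = numeric(0), learningRate = 0.01, nIterations = 0L)
  s <- summarizeGene(corpus, 814630L, m, c("kinas"), targetLength = 3L)
  expect_setequal(s@sentenceIds,
                  corpus@sentences$sentence_id[
                    corpus@sentences$gene_id == 814630L])
})

test_that("summaries round trip through the JSONL output format", {
  fx <- writeTinyCorpus()
  corpus <- buildGeneCorpus(fx$corpus, fx$gene2go, fx$references)
  m <- new("RankingModel",
           weights = setNames(c(0.1, 0.2, 0.7), c("go", "lda", "textrank")),
           lossTrace = numeric(0), learningRate = 0.01, nIterations = 0L)
  s <- summarizeGene(corpus, 814630L, m, c("kinas"), targetLength = 2L)
  out <- tempfile(fileext = ".jsonl")
  txt <- tempfile(fileext = ".txt")
  writeSummariesJsonl(list(s), out, textPath = txt)
  back <- readSummariesJsonl(out)
  expect_length(back, 1L)
  expect_equal(back[[1]]@geneId, 814630L)
  expect_identical(back[[1]]@sentences, s@sentences)
  expect_equal(back[[1]]@selectionScores, s@selectionScores)
  expect_true(any(grepl("Gene 814630", readLines(txt))))
})
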