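# Text preprocessing, the gene2go dialect, corpus assembly and idf
# statistics.

test_that("Porter stemmer reproduces the published vocabulary pairs", {
  pairs <- c(caresses = "caress", ponies = "poni", ties = "ti",
             cats = "cat", feed = "feed", agreed = "agre",
             plastered = "plaster", motoring = "motor", sing = "sing",
             conflated = "conflat", sized = "size", hopping = "hop",
             failing = "fail", filing = "file", happy = "happi",
             sky = "sky", relational = "relat", conditional = "condit",
             rational = "ration", digitizer = "digit",
             operator = "oper", feudalism = "feudal",
             decisiveness = "decis", hopefulness = "hope",
             formality = "formal", sensitivity = "sensit",
             sensibility = "sensibl", triplicate = "triplic",
             formative = "form", electricity = "electr",
             electrical = "electr", hopeful = "hope", goodness = "good",
             allowance = "allow", inference = "infer",
             adjustable = "adjust", defensible = "defens",
             replacement = "replac", adoption = "adopt",
             activate = "activ", effective = "effect",
             controlling = "control", rolling = "roll",
             generalizations = "gener", oscillators = "oscil",
             binding = "bind", proteins = "protein")
  expect_identical(porterStem(names(pairs)), unname(pairs))
  # uppercase input is lowercased; short and non-alphabetic tokens pass
  expect_identical(porterStem(c("Binding", "of", "w0042")),
                   c("bind", "of", "w0042"))
})

test_that("sentence splitting follows the terminator-then-uppercase rule", {
  expect_identical(
    splitSentences("The gene encodes a protein. It binds zinc."),
    c("The gene encodes a protein.", "It binds zinc."))
  expect_identical(splitSentences(""), character(0))
  expect_identical(splitSentences("   \t "), character(0))
  one <- "A single clause without terminal punctuation"
  expect_identical(splitSentences(one), one)
  # abbreviation and initial exceptions suppress false breaks
  expect_length(splitSentences("Shown by Smith et al. Previous work agreed."), 1L)
  expect_length(splitSentences("Grown in E. coli cultures overnight."), 1L)
  # lowercase continuation is never a break
  expect_length(splitSentences("approx. 5 mg was used. see text"), 1L)
  # concatenation reproduces the input modulo whitespace
  txt <- "First point! Second point? Third one ends here."
  parts <- splitSentences(txt)
  expect_identical(gsub("\\s+", "", paste(parts, collapse = "")),
                   gsub("\\s+", "", txt))
})

test_that("preprocessing stems, lowercases and strips stopwords", {
  expect_identical(preprocessText("binding proteins", character(0)),
                   c("bind", "protein"))
  sw <- defaultStopwords()
  expect_identical(preprocessText("the of and", sw), character(0))
  expect_identical(preprocessText("", sw), character(0))
  expect_false(any(preprocessText("The protein binds the zinc ion", sw)
                   %in% sw))
  # single characters are dropped, order preserved
  expect_identical(preprocessText("a zinc b ion c", character(0)),
                   c("zinc", "ion"))
  # idempotent on its own output for this vocabulary
  toks <- preprocessText("binding proteins regulate transcription", sw)
  expect_identical(preprocessText(paste(toks, collapse = " "), sw), toks)
})

test_that("gene2go parsing matches the annotation dialect", {
  fx <- writeTinyCorpus()
  ann <- readGene2go(fx$gene2go)
  expect_equal(nrow(ann), 5L)
  # evidence code after the space is stripped from GO_ID
  expect_identical(ann$go_id[4], "GO:0008270")
  expect_identical(ann$go_term[4], "zinc ion binding")
  expect_identical(ann$category[4], "Function")
  expect_equal(ann$tax_id[1], 3702L)
  expect_equal(ann$gene_id[1], 814629L)

  # empty file -> empty table
  empty <- tempfile()
  writeLines(character(0), empty)
  expect_equal(nrow(readGene2go(empty)), 0L)

  # malformed rows raise errors naming the line
  bad <- tempfile()
  writeLines(c("3702\t814629"), bad)
  expect_error(readGene2go(bad), "line 1")
  writeLines(c("3702\t814629\tGO:0008270\tzinc ion binding\tFunction",
               "3702\tnotanumber\tGO:0000001\tx\tProcess"), bad)
  expect_error(readGene2go(bad), "line 2")
})

test_that("gene2go write/read round trip is the identity", {
  fx <- writeTinyCorpus()
  ann <- readGene2go(fx$gene2go)
  out <- tempfile()
  writeGene2go(ann, out)
  expect_identical(readGene2go(out), ann)
})

test_that("GO word sets are stemmed unions over the gene's annotations", {
  fx <- writeTinyCorpus()
  ann <- readGene2go(fx$gene2go)
  sw <- defaultStopwords()
  ws <- goWordSet(ann, 814629L, sw)
  # stems of "nucleic acid binding", "zinc ion binding" and the
  # underscore-separated placeholders
  expect_true(all(c("nucleic", "acid", "bind", "zinc", "ion",
                    "cellular", "compon", "biolog", "process") %in% ws))
  expect_false(anyDuplicated(ws) > 0)  # "bind" appears once despite 2 terms
  expect_identical(goWordSet(ann, 999L, sw), character(0))
})

test_that("idf follows 1 + ln(N / n_w) with its boundary cases", {
  docs <- c(list(rep("ubiquitous", 3L)),
            replicate(9L, "ubiquitous", simplify = FALSE))
  docs[[1]] <- c(docs[[1]], "rare")
  st <- computeCorpusStats(docs)
  expect_equal(nDocuments(st), 10L)
  expect_equal(unname(st@idf["ubiquitous"]), 1.0)
  expect_equal(unname(st@idf["rare"]), 1 + log(10), tolerance = 1e-12)
  expect_equal(unname(st@idf["rare"]), 3.302585, tolerance = 1e-6)
  one <- computeCorpusStats(list(c("solo")))
  expect_equal(unname(one@idf["solo"]), 1.0)
  expect_error(computeCorpusStats(list()), "at least one")
})

test_that("idf is bounded below by 1 and decreasing in document frequency", {
  set.seed(11)
  vocab <- paste0("w", 1:30)
  docs <- replicate(12L, sample(vocab, 8L), simplify = FALSE)
  st <- computeCorpusStats(docs)
  expect_true(all(st@idf >= 1 - 1e-12))
  ord <- order(st@docFrequency)
  expect_true(all(diff(st@idf[ord]) <= 1e-12))
})

test_that("buildGeneCorpus assembles sentences, tokens and references", {
  fx <- writeTinyCorpus()
  corpus <- buildGeneCorpus(fx$corpus, fx$gene2go, fx$references)
  expect_s4_class(corpus, "GeneCorpus")
  expect_identical(geneIds(corpus), c(814629L, 814630L))
  gs <- corpus@sentences
  expect_equal(sum(gs$gene_id == 814629L & gs$doc_id == "d1"), 3L)
  expect_equal(gs$position[gs$doc_id == "d1"], 0:2)
  expect_false(any(vapply(corpus@tokens, function(t)
    any(t %in% corpus@stopwords), logical(1))))
  st <- corpusStats(corpus)
  expect_equal(nDocuments(st), 3L)
})

test_that("JSONL readers validate records", {
  bad <- tempfile()
  writeLines('{"gene_id": 1}', bad)
  expect_error(readCorpusJsonl(bad), "lacks field")
  writeLines("not json at all {", bad)
  expect_error(readCorpusJsonl(bad), "line 1")
})
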