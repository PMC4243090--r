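# Synthetic gene corpora with planted structure: each gene carries a GO
# word set and a dominant topic; "signal" sentences mix GO and topic words
# with background vocabulary, noise sentences draw from the background
# only, and the reference description is built from the planted signal
# sentences with light synonym substitution (so even perfect selection
# scores ROUGE < 1). Everything is a pure function of config + seed.

# readable biomedical-flavoured word pool used for the start of the
# vocabulary; the remainder is filled with synthetic w#### tokens
.bioWordPool <- c(
  "kinase", "receptor", "membrane", "protein", "enzyme", "ligand",
  "domain", "helix", "chromatin", "histone", "promoter", "enhancer",
  "transcript", "ribosome", "mitochondria", "cytoplasm", "nucleus",
  "vesicle", "tubulin", "actin", "myosin", "collagen", "integrin",
  "cadherin", "apoptosis", "autophagy", "glycolysis", "oxidation",
  "phosphatase", "ubiquitin", "proteasome", "chaperone", "operon",
  "plasmid", "codon", "intron", "exon", "telomere", "centromere",
  "cytokine", "interferon", "antibody", "antigen", "epitope", "peptide",
  "hormone", "insulin", "glucose", "lipid", "sterol")

#' Configuration for the synthetic corpus generator
#'
#' Defaults describe the desk-scale study corpus: 30 genes, four abstracts
#' of six sentences each per gene, a 300-word vocabulary split into four
#' planted topics, six GO words per gene, signal sentences drawing 70% of
#' their tokens from the gene's GO and topic words, and a 10% synonym
#' substitution rate when paraphrasing reference descriptions.
#'
#' @param nGenes,docsPerGene,sentencesPerDoc corpus dimensions.
#' @param vocabSize background vocabulary size.
#' @param nTopics number of planted topics.
#' @param goWordsPerGene GO words planted per gene.
#' @param signalFraction fraction of a signal sentence's tokens drawn from
#'   the gene's GO/topic words, in `[0, 1]`.
#' @param noiseRate synonym substitution rate in reference descriptions,
#'   in `[0, 1]`.
#' @param signalPerGene number of planted high-relevance sentences per
#'   gene (the reference is built from these).
#' @param seed RNG seed.
#' @return validated config list of class `fixtureConfig`.
#' @export
fixtureConfig <- function(nGenes = 30L, docsPerGene = 4L,
                          sentencesPerDoc = 6L, vocabSize = 300L,
                          nTopics = 4L, goWordsPerGene = 6L,
                          signalFraction = 0.7, noiseRate = 0.1,
                          signalPerGene = 5L, seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes),
              docsPerGene = as.integer(docsPerGene),
              sentencesPerDoc = as.integer(sentencesPerDoc),
              vocabSize = as.integer(vocabSize),
              nTopics = as.integer(nTopics),
              goWordsPerGene = as.integer(goWordsPerGene),
              signalFraction = signalFraction, noiseRate = noiseRate,
              signalPerGene = as.integer(signalPerGene),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(nGenes >= 1L, docsPerGene >= 1L, sentencesPerDoc >= 1L,
              vocabSize >= 1L, nTopics >= 1L, goWordsPerGene >= 1L,
              signalPerGene >= 1L, signalFraction >= 0, signalFraction <= 1,
              noiseRate >= 0, noiseRate <= 1)
  })
  # vocabulary layout: topics | GO pool | synonyms | background
  topicBlock <- cfg$nTopics * 24L
  goBlock <- cfg$nGenes * cfg$goWordsPerGene
  synBlock <- 40L
  if (cfg$vocabSize < 60L)
    stop("vocabulary too small: need at least 60 background words")
  structure(cfg, class = "fixtureConfig",
            topicBlock = topicBlock, goBlock = goBlock, synBlock = synBlock)
}

.makeVocab <- function(n) {
  extra <- max(0L, n - length(.bioWordPool))
  c(.bioWordPool[seq_len(min(n, length(.bioWordPool)))],
    sprintf("w%04d", seq_len(extra)))
}

.renderSentence <- function(words) {
  # sprinkle stopwords so preprocessing has something to remove
  out <- character(0)
  for (w in words) {
    if (runif(1) < 0.25)
      out <- c(out, sample(c("the", "of", "and", "in", "this"), 1L))
    out <- c(out, w)
  }
  s <- paste(out, collapse = " ")
  paste0(toupper(substr(s, 1L, 1L)), substr(s, 2L, nchar(s)), ".")
}

#' Generate a synthetic gene corpus
#'
#' Writes the three pipeline input files (gene2go TSV, abstract corpus
#' JSONL, reference-description JSONL) into `dir` and returns the planted
#' ground truth. Deterministic under `config$seed`; the caller's RNG state
#' is untouched.
#'
#' Per gene: `goWordsPerGene` GO annotation rows (two words per GO term),
#' `docsPerGene` abstracts of `sentencesPerDoc` sentences,
#' `signalPerGene` of which are planted signal sentences whose tokens are
#' drawn from the gene's GO words and its dominant topic's words with
#' probability `signalFraction` (background otherwise). The reference
#' description concatenates the planted sentences with words replaced by
#' synonyms at rate `noiseRate`.
#'
#' @param config a [fixtureConfig()].
#' @param dir output directory (created if missing).
#' @return list with `paths` (gene2go, corpus, references), `truth`
#'   (per-gene list: GO words, topic index, signal sentence ids) and
#'   `config`.
#' @export
generateCorpus <- function(config, dir = tempfile("fixture")) {
  stopifnot(inherits(config, "fixtureConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withSeed(config$seed, .generateCorpusImpl(config, dir))
}

.generateCorpusImpl <- function(config, dir) {
  nTopicWords <- 24L
  vocabNeeded <- attr(config, "topicBlock") + attr(config, "goBlock") +
    attr(config, "synBlock") + config$vocabSize
  vocab <- .makeVocab(vocabNeeded)
  ofs <- 0L
  topicWords <- lapply(seq_len(config$nTopics), function(k)
    vocab[(k - 1L) * nTopicWords + seq_len(nTopicWords)])
  ofs <- attr(config, "topicBlock")
  goPool <- vocab[ofs + seq_len(attr(config, "goBlock"))]
  ofs <- ofs + attr(config, "goBlock")
  synPool <- vocab[ofs + seq_len(attr(config, "synBlock"))]
  ofs <- ofs + attr(config, "synBlock")
  background <- vocab[ofs + seq_len(config$vocabSize)]

  geneIds <- 1000L + seq_len(config$nGenes)
  goRows <- list()
  corpusRecs <- list()
  refRecs <- list()
  truth <- list()
  goCounter <- 0L

  for (g in seq_len(config$nGenes)) {
    gid <- geneIds[g]
    goWords <- goPool[(g - 1L) * config$goWordsPerGene +
                        seq_len(config$goWordsPerGene)]
    topicIdx <- ((g - 1L) %% config$nTopics) + 1L
    signalVocab <- c(goWords, topicWords[[topicIdx]])

    # gene2go rows: two GO words per term name
    termStarts <- seq(1L, length(goWords), by = 2L)
    for (ts in termStarts) {
      goCounter <- goCounter + 1L
      term <- paste(goWords[ts:min(ts + 1L, length(goWords))],
                    collapse = " ")
      goRows[[length(goRows) + 1L]] <- data.frame(
        tax_id = 9606L, gene_id = gid,
        go_id = sprintf("GO:%07d", goCounter), go_term = term,
        category = c("Component", "Function", "Process")[
          (goCounter - 1L) %% 3L + 1L],
        stringsAsFactors = FALSE)
    }

    # place signal sentences at deterministic-random slots
    nSent <- config$docsPerGene * config$sentencesPerDoc
    nSignal <- min(config$signalPerGene, nSent)
    signalSlots <- sort(sample.int(nSent, nSignal))
    signalSentences <- character(0)
    signalIds <- character(0)
    slot <- 0L
    for (dIdx in seq_len(config$docsPerGene)) {
      docId <- sprintf("g%d_doc%d", gid, dIdx)
      sents <- character(config$sentencesPerDoc)
      for (sIdx in seq_len(config$sentencesPerDoc)) {
        slot <- slot + 1L
        len <- sample(8:12, 1L)
        if (slot %in% signalSlots) {
          fromSignal <- runif(len) < config$signalFraction
          words <- ifelse(fromSignal,
                          sample(signalVocab, len, replace = TRUE),
                          sample(background, len, replace = TRUE))
          sents[sIdx] <- .renderSentence(words)
          signalSentences <- c(signalSentences, sents[sIdx])
          signalIds <- c(signalIds, paste0(docId, "#", sIdx - 1L))
        } else {
          words <- sample(background, len, replace = TRUE)
          sents[sIdx] <- .renderSentence(words)
        }
      }
      corpusRecs[[length(corpusRecs) + 1L]] <-
        list(gene_id = gid, doc_id = docId,
             text = paste(sents, collapse = " "))
    }

    # reference: planted sentences, synonym-substituted at noiseRate
    refSents <- vapply(signalSentences, function(s) {
      words <- strsplit(s, " ", fixed = TRUE)[[1]]
      swap <- runif(length(words)) < config$noiseRate
      words[swap] <- sample(synPool, sum(swap), replace = TRUE)
      s2 <- paste(words, collapse = " ")
      if (!grepl("\\.$", s2)) s2 <- paste0(s2, ".")
      s2
    }, character(1), USE.NAMES = FALSE)
    refRecs[[length(refRecs) + 1L]] <-
      list(gene_id = gid, summary_text = paste(refSents, collapse = " "))
    truth[[as.character(gid)]] <- list(go_words = goWords,
                                       topic = topicIdx,
                                       topic_words = topicWords[[topicIdx]],
                                       signal_ids = signalIds)
  }

  paths <- list(gene2go = file.path(dir, "gene2go.tsv"),
                corpus = file.path(dir, "corpus.jsonl"),
                references = file.path(dir, "references.jsonl"))
  writeGene2go(do.call(rbind, goRows), paths$gene2go)
  .writeJsonl(corpusRecs, paths$corpus)
  .writeJsonl(refRecs, paths$references)
  list(paths = paths, truth = truth, config = config)
}

#' Generate synthetic ranking instances with known true weights
#'
#' Drives parameter-recovery experiments: features are uniform on
#' `[0, 1]^3`; within each list the labels are the softmax of the true
#' scores `w* . x` (a rank-consistent transform) plus Gaussian noise,
#' clipped to `[0, 1]`. Deterministic under `seed`.
#'
#' @param nLists number of query lists.
#' @param listLength sentences per list (`>= 2`).
#' @param trueWeights the generating weight triple (default
#'   `(0.1, 0.2, 0.7)`, the canonical recovery setting).
#' @param noiseSd standard deviation of the label noise (`>= 0`).
#' @param seed RNG seed.
#' @return list of [queryInstance()] objects; the generating weights are
#'   attached as attribute `trueWeights`.
#' @export
generateLtrInstances <- function(nLists, listLength = 10L,
                                 trueWeights = c(0.1, 0.2, 0.7),
                                 noiseSd = 0.05, seed = 1L) {
  stopifnot(nLists >= 1L, listLength >= 2L, noiseSd >= 0,
            length(trueWeights) == 3L)
  withSeed(seed, {
    out <- lapply(seq_len(nLists), function(i) {
      x <- matrix(runif(listLength * 3L), ncol = 3L)
      t <- as.vector(x %*% trueWeights)
      y <- topOneProbabilities(t)
      if (noiseSd > 0) y <- y + rnorm(listLength, sd = noiseSd)
      y <- pmin(1, pmax(0, y))
      queryInstance(i, x, y)
    })
    attr(out, "trueWeights") <- trueWeights
    out
  })
}
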