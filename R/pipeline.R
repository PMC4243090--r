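# End-to-end workflow: train feature weights on the training split, rank
# and summarise the test split, evaluate against reference descriptions.
# Every step is deterministic given the config and seed.

#' Pipeline configuration
#'
#' Collects every tunable of the workflow with its default: LDA
#' (`K = 10` topics, `topM = 24` topic words, 1000 Gibbs sweeps),
#' TextRank (damping `d = 0.85`, tolerance 1e-6), training (step size
#' 0.01, 1000 iterations, cosine labels), selection (redundancy penalty
#' `omega = 1`, five-sentence summaries) and the train/test split rule
#' (by sorted gene id, first `trainFrac` for training).
#'
#' @param corpusPath,gene2goPath,referencePath input files (see
#'   [buildGeneCorpus()]).
#' @param modelPath,topicModelPath,outputPath artefact files.
#' @param stopwordsPath optional stopword file overriding the packaged
#'   list.
#' @param K,topM,ldaIterations,alpha,beta LDA settings (`alpha` defaults
#'   to `50 / K`).
#' @param d,tolerance,maxIterations,denominator TextRank settings.
#' @param learningRate,nIterations,labelMode training settings;
#'   `labelMode` is `"eq3"` (cosine labels, default) or `"rouge_grade"`
#'   (0-4 ROUGE grades rescaled to `[0, 1]`).
#' @param omega,targetLength summary selection settings.
#' @param trainFrac fraction of genes (sorted by id) used for training.
#' @param globalTopicSet if `TRUE`, one corpus-wide topic word set is used
#'   for every gene instead of per-gene topic selection.
#' @param seed RNG seed for every stochastic step.
#' @return config list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(corpusPath = NULL, gene2goPath = NULL,
                           referencePath = NULL, modelPath = NULL,
                           topicModelPath = NULL, outputPath = NULL,
                           stopwordsPath = NULL,
                           K = 10L, topM = 24L, ldaIterations = 1000L,
                           alpha = 50 / K, beta = 0.01,
                           d = 0.85, tolerance = 1e-6,
                           maxIterations = 1000L, denominator = "weight",
                           learningRate = 0.01, nIterations = 1000L,
                           labelMode = c("eq3", "rouge_grade"),
                           omega = 1.0, targetLength = 5L,
                           trainFrac = 2 / 3, globalTopicSet = FALSE,
                           seed = 1L) {
  labelMode <- match.arg(labelMode)
  stopifnot(omega >= 0, d > 0, d < 1, targetLength >= 1L,
            trainFrac > 0, trainFrac <= 1)
  structure(list(corpusPath = corpusPath, gene2goPath = gene2goPath,
                 referencePath = referencePath, modelPath = modelPath,
                 topicModelPath = topicModelPath, outputPath = outputPath,
                 stopwordsPath = stopwordsPath, K = as.integer(K),
                 topM = as.integer(topM),
                 ldaIterations = as.integer(ldaIterations), alpha = alpha,
                 beta = beta, d = d, tolerance = tolerance,
                 maxIterations = as.integer(maxIterations),
                 denominator = denominator, learningRate = learningRate,
                 nIterations = as.integer(nIterations),
                 labelMode = labelMode, omega = omega,
                 targetLength = as.integer(targetLength),
                 trainFrac = trainFrac, globalTopicSet = globalTopicSet,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

.configStopwords <- function(config) {
  if (is.null(config$stopwordsPath)) defaultStopwords()
  else defaultStopwords(config$stopwordsPath)
}

.loadCorpus <- function(config, withReferences = TRUE) {
  for (p in c(config$corpusPath, config$gene2goPath))
    if (is.null(p) || !file.exists(p))
      stop("missing input file: ", if (is.null(p)) "(unset)" else p)
  buildGeneCorpus(config$corpusPath, config$gene2goPath,
                  if (withReferences) config$referencePath else NULL,
                  stopwords = .configStopwords(config))
}

#' Split gene ids into training and test sets
#'
#' Genes are sorted by identifier; the first `trainFrac` fraction trains
#' the model and the remainder is the test set (the 2000/1000 convention
#' generalised to a fraction).
#'
#' @param ids integer gene ids.
#' @param trainFrac fraction in (0, 1].
#' @return list with `train` and `test` id vectors.
#' @export
splitGenes <- function(ids, trainFrac = 2 / 3) {
  ids <- sort(unique(ids))
  nTrain <- max(1L, min(length(ids), floor(length(ids) * trainFrac)))
  list(train = ids[seq_len(nTrain)],
       test = if (nTrain < length(ids))
         ids[(nTrain + 1L):length(ids)] else integer(0))
}

# documents (token lists) per gene, used for per-gene topic selection
.geneDocTokens <- function(corpus, geneId) {
  idx <- which(corpus@sentences$gene_id == geneId)
  unname(lapply(split(corpus@tokens[idx], corpus@sentences$doc_id[idx]),
                function(x) unlist(x)))
}

# topic word set for each requested gene (or one global set)
.topicWordsByGene <- function(corpus, topicModel, geneIds, config) {
  if (config$globalTopicSet) {
    allDocs <- lapply(geneIds, function(g) unlist(.geneDocTokens(corpus, g)))
    tw <- selectTopicWords(topicModel, allDocs, config$topM)
    return(setNames(rep(list(tw$words), length(geneIds)),
                    as.character(geneIds)))
  }
  out <- lapply(geneIds, function(g)
    selectTopicWords(topicModel, .geneDocTokens(corpus, g),
                     config$topM)$words)
  setNames(out, as.character(geneIds))
}

#' Assemble training instances from a corpus
#'
#' For every requested gene with a non-empty reference description,
#' computes the three-feature matrix of its candidate sentences and the
#' relevance labels (cosine to the description by default, or rescaled
#' 0-4 ROUGE grades). Genes without candidates or without a reference are
#' skipped with a warning.
#'
#' @param corpus a [GeneCorpus-class].
#' @param topicWordsByGene named list: gene id -> topic word set.
#' @param stats a [CorpusStats-class].
#' @param geneIds genes to build instances for.
#' @param config a [pipelineConfig()].
#' @return list of [queryInstance()] objects.
#' @export
buildInstances <- function(corpus, topicWordsByGene, stats, geneIds,
                           config = pipelineConfig()) {
  instances <- list()
  for (g in geneIds) {
    gs <- .geneSentences(corpus, g)
    if (!nrow(gs$table)) {
      warning("gene ", g, " has no candidate sentences; skipped",
              call. = FALSE)
      next
    }
    refTokens <- .geneReferenceTokens(corpus, g)
    if (is.null(refTokens) || !length(refTokens)) {
      warning("gene ", g, " has no usable reference description; skipped",
              call. = FALSE)
      next
    }
    feats <- computeSentenceFeatures(
      gs$tokens, goWordSet(corpus@annotations, g, corpus@stopwords),
      topicWordsByGene[[as.character(g)]], stats,
      d = config$d, tolerance = config$tolerance,
      maxIterations = config$maxIterations,
      denominator = config$denominator)
    labels <- switch(config$labelMode,
      eq3 = vapply(gs$tokens, relevanceLabel, numeric(1),
                   descriptionTokens = refTokens, stats = stats),
      rouge_grade = vapply(gs$tokens, gradeRouge, integer(1),
                           referenceTokens = refTokens) / 4)
    instances[[length(instances) + 1L]] <-
      queryInstance(g, feats, labels, gs$table$sentence_id)
  }
  instances
}

#' Export a feature table
#'
#' Flattens query instances into the TSV layout
#' `gene_id  sentence_id  go_score  lda_score  textrank_score  label`.
#'
#' @param instances list of [queryInstance()] objects.
#' @param path optional path; when given the TSV is written there.
#' @return the table, invisibly when written.
#' @export
featureTable <- function(instances, path = NULL) {
  tab <- do.call(rbind, lapply(instances, function(inst)
    data.frame(gene_id = inst$gene_id, sentence_id = inst$sentence_ids,
               go_score = inst$features[, "go"],
               lda_score = inst$features[, "lda"],
               textrank_score = inst$features[, "textrank"],
               label = inst$labels, stringsAsFactors = FALSE,
               row.names = NULL)))
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Train the ranking model from corpus files
#'
#' Builds the corpus, fits the LDA model on the training genes' reference
#' descriptions, assembles features and labels for the training split,
#' runs gradient descent and (when paths are configured) writes the
#' ranking and topic model files.
#'
#' @param config a [pipelineConfig()] with input paths set.
#' @param verbose log the loss every 100 iterations summary to stderr.
#' @return list with `model` ([RankingModel-class]), `topicModel`,
#'   `instances`, `split` and `stats`.
#' @export
runTrain <- function(config, verbose = FALSE) {
  corpus <- .loadCorpus(config)
  stats <- corpusStats(corpus)
  split <- splitGenes(geneIds(corpus), config$trainFrac)

  refIdx <- match(split$train, corpus@references$gene_id)
  refDocs <- corpus@referenceTokens[refIdx[!is.na(refIdx)]]
  refDocs <- refDocs[lengths(refDocs) > 0]
  if (!length(refDocs))
    stop("no reference descriptions available to fit the topic model")
  topicModel <- fitLda(refDocs, K = config$K, alpha = config$alpha,
                       beta = config$beta,
                       nIterations = config$ldaIterations,
                       seed = config$seed)
  topicWords <- .topicWordsByGene(corpus, topicModel, split$train, config)
  instances <- buildInstances(corpus, topicWords, stats, split$train,
                              config)
  if (!length(instances)) stop("no usable training instances")
  model <- trainListnet(instances, learningRate = config$learningRate,
                        nIterations = config$nIterations)
  if (verbose) {
    tr <- lossTrace(model)
    at <- unique(c(seq(1L, length(tr), by = 100L), length(tr)))
    message(paste(sprintf("iter %d: loss %.6f", at - 1L, tr[at]),
                  collapse = "\n"))
  }
  if (!is.null(config$modelPath)) writeRankingModel(model, config$modelPath)
  if (!is.null(config$topicModelPath))
    writeTopicModel(topicModel, config$topicModelPath)
  list(model = model, topicModel = topicModel, instances = instances,
       split = split, stats = stats)
}

#' Summarize the test split
#'
#' Applies a trained ranking model to every test gene: scores the
#' candidate sentences and selects a redundancy-penalised summary of at
#' most `targetLength` sentences. A gene with fewer candidates than the
#' target length yields a shorter summary with a warning.
#'
#' @param config a [pipelineConfig()].
#' @param model a [RankingModel-class]; read from `config$modelPath` when
#'   omitted.
#' @param topicModel a [TopicModel-class]; read from
#'   `config$topicModelPath` when omitted.
#' @param geneIdsToSummarize genes to summarise; defaults to the test
#'   split.
#' @return named list of [GeneSummary-class] objects, written to
#'   `config$outputPath` (JSONL) when set.
#' @export
runSummarize <- function(config, model = NULL, topicModel = NULL,
                         geneIdsToSummarize = NULL) {
  if (is.null(model)) model <- readRankingModel(config$modelPath)
  if (is.null(topicModel))
    topicModel <- readTopicModel(config$topicModelPath)
  corpus <- .loadCorpus(config)
  stats <- corpusStats(corpus)
  if (is.null(geneIdsToSummarize))
    geneIdsToSummarize <- splitGenes(geneIds(corpus), config$trainFrac)$test
  topicWords <- .topicWordsByGene(corpus, topicModel, geneIdsToSummarize,
                                  config)
  summaries <- lapply(geneIdsToSummarize, function(g) {
    s <- summarizeGene(corpus, g, model, topicWords[[as.character(g)]],
                       stats = stats, omega = config$omega,
                       targetLength = config$targetLength, d = config$d,
                       tolerance = config$tolerance,
                       maxIterations = config$maxIterations,
                       denominator = config$denominator)
    if (length(s@sentences) < config$targetLength)
      warning("gene ", g, ": only ", length(s@sentences),
              " candidate sentences; summary shorter than target",
              call. = FALSE)
    s
  })
  names(summaries) <- as.character(geneIdsToSummarize)
  if (!is.null(config$outputPath))
    writeSummariesJsonl(summaries, config$outputPath)
  summaries
}

#' Evaluate summaries against reference descriptions
#'
#' ROUGE-1, ROUGE-2 and ROUGE-SU4 recall (plus precision and F) per gene
#' and their corpus means. By default summary and reference text are
#' preprocessed (stemmed, stopword-stripped) with the same tokenizer the
#' system ranks with; `rawTokens = TRUE` evaluates on plain lowercase
#' tokens instead. Genes missing from the references are listed and
#' excluded with a warning.
#'
#' @param summaries list of [GeneSummary-class] objects.
#' @param references data.frame (gene_id, summary_text) as from
#'   [readReferencesJsonl()].
#' @param stopwords stopword vector used in preprocessing mode.
#' @param rawTokens evaluate without stemming/stopword removal.
#' @return list with `perGene` (data.frame gene_id, metric, recall,
#'   precision, f_measure) and `means` (named mean recalls).
#' @export
evaluateSummaries <- function(summaries, references,
                              stopwords = defaultStopwords(),
                              rawTokens = FALSE) {
  tokenize <- function(text) {
    if (rawTokens) {
      toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
      toks[nchar(toks) >= 2L]
    } else preprocessText(text, stopwords)
  }
  ids <- vapply(summaries, function(s) s@geneId, integer(1))
  missing <- setdiff(ids, references$gene_id)
  if (length(missing))
    warning("no reference for gene(s) ",
            paste(missing, collapse = ", "), "; excluded", call. = FALSE)
  rows <- list()
  for (s in summaries) {
    if (s@geneId %in% missing) next
    refText <- references$summary_text[match(s@geneId,
                                             references$gene_id)]
    refTok <- tokenize(refText)
    candTok <- tokenize(paste(s@sentences, collapse = " "))
    if (!length(candTok))
      warning("gene ", s@geneId, ": empty summary scores 0",
              call. = FALSE)
    res <- list(rougeN(candTok, refTok, 1L), rougeN(candTok, refTok, 2L),
                rougeSU4(candTok, refTok))
    for (r in res)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = s@geneId, metric = r$metric, recall = r$recall,
        precision = r$precision, f_measure = r$f_measure,
        stringsAsFactors = FALSE)
  }
  perGene <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = integer(0), metric = character(0),
               recall = numeric(0), precision = numeric(0),
               f_measure = numeric(0), stringsAsFactors = FALSE)
  metrics <- c("ROUGE-1", "ROUGE-2", "ROUGE-SU4")
  means <- vapply(metrics, function(m)
    mean(perGene$recall[perGene$metric == m]), numeric(1))
  list(perGene = perGene, means = means)
}

#' Random-selection baseline summaries
#'
#' The trivial comparator: `targetLength` sentences drawn uniformly
#' without replacement from each gene's candidates. Deterministic under
#' `seed`.
#'
#' @param corpus a [GeneCorpus-class].
#' @param geneIdsToSummarize genes to summarise.
#' @param targetLength sentences per summary (default 5).
#' @param seed RNG seed.
#' @return named list of [GeneSummary-class] objects.
#' @export
randomBaselineSummaries <- function(corpus, geneIdsToSummarize,
                                    targetLength = 5L, seed = 1L) {
  withSeed(seed, {
    out <- lapply(geneIdsToSummarize, function(g) {
      gs <- .geneSentences(corpus, g)
      n <- nrow(gs$table)
      take <- sample.int(n, min(targetLength, n))
      new("GeneSummary", geneId = as.integer(g),
          sentenceIds = gs$table$sentence_id[take],
          sentences = gs$table$raw_text[take],
          selectionScores = rep(0, length(take)),
          originalScores = rep(0, length(take)),
          targetLength = as.integer(targetLength))
    })
    names(out) <- as.character(geneIdsToSummarize)
    out
  })
}

#' Generate fixture files from a pipeline config
#'
#' Thin wrapper over [generateCorpus()] that drops the three file paths
#' into a config-friendly list.
#'
#' @param config a [fixtureConfig()].
#' @param dir output directory.
#' @return see [generateCorpus()].
#' @export
runSimulate <- function(config = fixtureConfig(), dir = tempfile("sim")) {
  generateCorpus(config, dir)
}

#' Run the full experiment on one corpus
#'
#' Trains on the training split, summarises the test split with the
#' learned model and with the random baseline (averaged over
#' `nRandomDraws` draws), and evaluates all of them. The feature subset
#' can be restricted (weights of excluded features are clamped to zero
#' and excluded from training) for ablation experiments.
#'
#' @param config a [pipelineConfig()] with input paths set.
#' @param features character subset of `c("go", "lda", "textrank")` to
#'   use.
#' @param nRandomDraws random-baseline repetitions (0 disables the
#'   baseline).
#' @return list with `model`, `summaries`, `evaluation` (means and
#'   per-gene table), `randomMeans` (mean recalls of the baseline, or
#'   NULL).
#' @export
runExperiment <- function(config, features = c("go", "lda", "textrank"),
                          nRandomDraws = 10L) {
  stopifnot(all(features %in% c("go", "lda", "textrank")),
            length(features) >= 1L)
  trained <- runTrain(config)
  mask <- c("go", "lda", "textrank") %in% features
  if (!all(mask)) {
    # ablation: retrain on the restricted feature set, zero the rest
    restricted <- lapply(trained$instances, function(inst) {
      f <- inst$features
      f[, !mask] <- 0
      queryInstance(inst$gene_id, f, inst$labels, inst$sentence_ids)
    })
    model <- trainListnet(restricted, learningRate = config$learningRate,
                          nIterations = config$nIterations)
    w <- modelWeights(model)
    w[!mask] <- 0
    model@weights <- w
  } else model <- trained$model
  summaries <- runSummarize(config, model = model,
                            topicModel = trained$topicModel)
  corpus <- .loadCorpus(config)
  evaluation <- evaluateSummaries(summaries, corpus@references,
                                  stopwords = corpus@stopwords)
  randomMeans <- NULL
  if (nRandomDraws > 0L) {
    testIds <- trained$split$test
    draws <- vapply(seq_len(nRandomDraws), function(k) {
      rb <- randomBaselineSummaries(corpus, testIds,
                                    targetLength = config$targetLength,
                                    seed = config$seed + k)
      ev <- suppressWarnings(
        evaluateSummaries(rb, corpus@references,
                          stopwords = corpus@stopwords))
      ev$means
    }, numeric(3))
    randomMeans <- rowMeans(draws)
  }
  list(model = model, summaries = summaries, evaluation = evaluation,
       randomMeans = randomMeans)
}
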