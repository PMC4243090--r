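# Summary assembly: per-gene feature computation, model scoring, and the
# greedy redundancy-penalised sentence selection
#   Score(s_j) <- Score(s_j) - omega * sim(s_i, s_j)
# applied after each pick s_i, until the target length is reached.

#' Feature matrix for one gene's candidate sentences
#'
#' Computes the three sentence features for a query gene: GO relevance,
#' topic relevance and TextRank centrality over the gene's own
#' sentence-similarity graph. The TextRank column is min-max scaled to
#' `[0, 1]` within the gene (a query-local normalisation that puts all
#' three features on a common bounded scale; a gene whose sentences all
#' tie gets zeros).
#'
#' @param tokens list of preprocessed sentence token vectors.
#' @param goWords the gene's GO word set ([goWordSet()]).
#' @param topicWords the gene's topic word set (`$words` of
#'   [selectTopicWords()]).
#' @param stats a [CorpusStats-class].
#' @param d,tolerance,maxIterations TextRank parameters (see
#'   [textrankScores()]).
#' @param denominator TextRank normalisation variant.
#' @return numeric matrix, one row per sentence, columns `go`, `lda`,
#'   `textrank`.
#' @export
computeSentenceFeatures <- function(tokens, goWords, topicWords, stats,
                                    d = 0.85, tolerance = 1e-6,
                                    maxIterations = 1000L,
                                    denominator = "weight") {
  n <- length(tokens)
  stopifnot(n >= 1L)
  go <- vapply(tokens, goRelevanceScore, numeric(1), goWords = goWords)
  lda <- vapply(tokens, topicRelevanceScore, numeric(1),
                topicWords = topicWords)
  graph <- buildSimilarityGraph(tokens, stats)
  tr <- textrankScores(graph, d = d, tolerance = tolerance,
                       maxIterations = maxIterations,
                       denominator = denominator)$score
  rng <- range(tr)
  trScaled <- if (diff(rng) > 0) (tr - rng[1]) / diff(rng) else rep(0, n)
  cbind(go = go, lda = lda, textrank = unname(trScaled))
}

#' Greedy redundancy-penalised sentence selection
#'
#' Starting from model scores, repeatedly selects the highest-scoring
#' remaining candidate and penalises every remaining candidate's score by
#' `omega` times its tf-idf cosine similarity to the sentence just
#' selected; penalties accumulate across iterations. Ties are broken by
#' original candidate order. Stops at `targetLength` sentences or when
#' candidates run out.
#'
#' @param sentenceIds,tokens,scores parallel vectors: identifiers,
#'   preprocessed tokens (list) and initial model scores.
#' @param rawText optional parallel raw sentence text.
#' @param stats a [CorpusStats-class] (for the similarity penalty).
#' @param geneId gene identifier recorded in the summary.
#' @param omega redundancy penalty weight, `>= 0` (default 1, the
#'   empirical setting).
#' @param targetLength summary length in sentences (default 5).
#' @return a [GeneSummary-class]; empty (with a warning) if no candidates.
#' @export
selectSummary <- function(sentenceIds, tokens, scores, stats,
                          rawText = NULL, geneId = NA_integer_,
                          omega = 1, targetLength = 5L) {
  stopifnot(omega >= 0, targetLength >= 1L,
            length(sentenceIds) == length(tokens),
            length(tokens) == length(scores))
  if (is.null(rawText)) rawText <- rep("", length(scores))
  n <- length(scores)
  if (n == 0L) {
    warning("empty candidate set: returning empty summary", call. = FALSE)
    return(new("GeneSummary", geneId = as.integer(geneId),
               sentenceIds = character(0), sentences = character(0),
               selectionScores = numeric(0), originalScores = numeric(0),
               targetLength = as.integer(targetLength)))
  }
  current <- scores
  remaining <- rep(TRUE, n)
  pick <- integer(0)
  pickScore <- numeric(0)
  while (length(pick) < targetLength && any(remaining)) {
    idxRem <- which(remaining)
    best <- idxRem[which.max(current[idxRem])]  # first max = earliest order
    pick <- c(pick, best)
    pickScore <- c(pickScore, current[best])
    remaining[best] <- FALSE
    for (j in which(remaining)) {
      current[j] <- current[j] -
        omega * tfidfCosine(tokens[[best]], tokens[[j]], stats)
    }
  }
  new("GeneSummary", geneId = as.integer(geneId),
      sentenceIds = as.character(sentenceIds[pick]),
      sentences = as.character(rawText[pick]),
      selectionScores = pickScore, originalScores = scores[pick],
      targetLength = as.integer(targetLength))
}

#' Summarize one gene end to end
#'
#' Composes the pipeline for a single query gene: feature computation,
#' model scoring and greedy redundancy-penalised selection. Deterministic
#' given its inputs. The summary holds `min(targetLength, n)` sentences.
#'
#' @param corpus a [GeneCorpus-class].
#' @param geneId the query gene.
#' @param model a [RankingModel-class].
#' @param topicWords topic word set for this gene.
#' @param stats corpus statistics (defaults to [corpusStats()] of the
#'   corpus).
#' @param omega,targetLength selection parameters (see [selectSummary()]).
#' @param d,tolerance,maxIterations,denominator TextRank parameters.
#' @return a [GeneSummary-class].
#' @export
summarizeGene <- function(corpus, geneId, model, topicWords,
                          stats = corpusStats(corpus), omega = 1,
                          targetLength = 5L, d = 0.85, tolerance = 1e-6,
                          maxIterations = 1000L, denominator = "weight") {
  gs <- .geneSentences(corpus, geneId)
  if (!nrow(gs$table)) stop("gene ", geneId, " has no candidate sentences")
  goWords <- goWordSet(corpus@annotations, geneId, corpus@stopwords)
  feats <- computeSentenceFeatures(gs$tokens, goWords, topicWords, stats,
                                   d = d, tolerance = tolerance,
                                   maxIterations = maxIterations,
                                   denominator = denominator)
  scores <- predictScores(model, feats)
  selectSummary(gs$table$sentence_id, gs$tokens, scores, stats,
                rawText = gs$table$raw_text, geneId = geneId,
                omega = omega, targetLength = targetLength)
}

#' Write summaries as JSON lines plus plain text
#'
#' One JSONL record per gene:
#' `{"gene_id":..., "sentences":[...], "scores":[...],
#' "original_scores":[...]}`. When `textPath` is given, a human-readable
#' rendering (one block per gene) is written alongside.
#'
#' @param summaries list of [GeneSummary-class] objects.
#' @param path JSONL output path.
#' @param textPath optional plain-text output path.
#' @export
writeSummariesJsonl <- function(summaries, path, textPath = NULL) {
  recs <- lapply(summaries, function(s)
    list(gene_id = s@geneId, sentences = as.list(s@sentences),
         scores = as.list(s@selectionScores),
         original_scores = as.list(s@originalScores)))
  .writeJsonl(recs, path)
  if (!is.null(textPath)) {
    blocks <- vapply(summaries, function(s)
      paste0("Gene ", s@geneId, "\n",
             paste0("  ", s@sentences, collapse = "\n")), character(1))
    writeLines(paste(blocks, collapse = "\n\n"), textPath)
  }
  invisible(path)
}

#' Read summaries written by [writeSummariesJsonl()]
#' @param path JSONL summaries path.
#' @return list of [GeneSummary-class] objects (sentence ids are not
#'   stored in the file and come back as positional placeholders).
#' @export
readSummariesJsonl <- function(path) {
  recs <- .readJsonl(path, c("gene_id", "sentences", "scores"))
  lapply(recs, function(r) {
    sents <- unlist(r$sentences)
    if (is.null(sents)) sents <- character(0)
    scores <- as.numeric(unlist(r$scores))
    orig <- if (!is.null(r$original_scores))
      as.numeric(unlist(r$original_scores)) else scores
    new("GeneSummary", geneId = as.integer(r$gene_id),
        sentenceIds = if (length(sents))
          paste0("sent", seq_along(sents)) else character(0),
        sentences = as.character(sents), selectionScores = scores,
        originalScores = orig,
        targetLength = max(1L, length(sents)))
  })
}
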